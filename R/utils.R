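# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate `code` under a temporary RNG state seeded with `seed`;
# the caller's RNG stream is untouched. seed = NULL runs code as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# scalar numeric check with a readable error
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  ok_lo <- if (open_lower) x > lower else x >= lower
  ok_hi <- if (open_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi) {
    stop(sprintf("`%s` = %g is outside %s%g, %g%s", name, x,
                 if (open_lower) "(" else "[", lower, upper,
                 if (open_upper) ")" else "]"), call. = FALSE)
  }
  invisible(x)
}

VALID_ALLELES <- c("A", "C", "G", "T")

allele_complement <- function(a) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  out <- unname(comp[a])
  out[is.na(a)] <- NA_character_
  out
}

is_palindromic_pair <- function(ea, oa) {
  !is.na(ea) & !is.na(oa) & allele_complement(ea) == oa
}
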