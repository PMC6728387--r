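# shared builders for small in-code fixtures

# minimal snp_assoc data frame
make_assoc <- function(snp_id, ea, beta, se, oa = NA, eaf = NA, p = NA) {
  snp_assoc(data.frame(snp_id = snp_id, effect_allele = ea, other_allele = oa,
                       eaf = eaf, beta = beta, se = se, p = p,
                       stringsAsFactors = FALSE),
            check_p = FALSE)
}

# harmonized set with J SNPs from plain vectors
make_hset <- function(bx, by, sx = rep(0.001, length(bx)),
                      sy = rep(0.01, length(bx))) {
  harmonized_set(sprintf("rs%03d", seq_along(bx)), bx, sx, by, sy)
}

# write a small summary-statistics file and return its path
write_sumstats <- function(df, sep = "\t", ext = ".tsv") {
  path <- tempfile(fileext = ext)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}
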