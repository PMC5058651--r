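# Independent brute-force oracle for the one-sided Fisher exact test:
# enumerate every 2x2 table with the observed margins via exact binomial
# coefficients (lchoose) and sum the probabilities of tables whose tumor
# alt count is at least the observed one.
fisher_enum_oracle <- function(alt_tumor, ref_tumor, alt_normal, ref_normal) {
  td <- alt_tumor + ref_tumor
  nd <- alt_normal + ref_normal
  K <- alt_tumor + alt_normal
  ks <- max(0L, K - nd):min(td, K)
  pr <- exp(lchoose(td, ks) + lchoose(nd, K - ks) - lchoose(td + nd, K))
  sum(pr[ks >= alt_tumor])
}

# A clean somatic SNV candidate row in the internal table schema,
# overridable field by field.
make_candidate <- function(...) {
  row <- list(sample_id = "S1", chrom = "chr1", pos = 1000L, ref = "C",
              alt = "T", variant_class = "snv",
              context = "ACGTACGTACCGTACGTACGT", consequence = "missense",
              gene = NA_character_,
              t_ref_fwd = 18L, t_ref_rev = 17L, t_alt_fwd = 8L, t_alt_rev = 7L,
              n_ref_fwd = 25L, n_ref_rev = 25L, n_alt_fwd = 0L, n_alt_rev = 0L)
  over <- list(...)
  row[names(over)] <- over
  as.data.frame(row, stringsAsFactors = FALSE)
}
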