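# Shared builders for summary-statistic fixtures.

make_record <- function(variant_id = "rs1", chrom = "1", pos = 100L,
                        ea = "A", oa = "G", eaf = 0.3, beta = 0.1,
                        se = 0.02, pval = NULL, n = 10000L, info = 1) {
  pval <- pval %||% (2 * stats::pnorm(-abs(beta / se)))
  data.frame(variant_id = variant_id, chrom = chrom, pos = pos, ea = ea,
             oa = oa, eaf = eaf, beta = beta, se = se, pval = pval,
             n = n, info = info, stringsAsFactors = FALSE)
}

make_stats <- function(m = 5, beta = rep(0.01, m), se = rep(0.02, m),
                       eaf = rep(0.3, m), pos = 100L * seq_len(m),
                       chrom = "1") {
  do.call(rbind, lapply(seq_len(m), function(i)
    make_record(sprintf("rs%d", i), chrom, pos[i], eaf = eaf[i],
                beta = beta[i], se = se[i])))
}

quant_meta <- function(name = "LF", n = 10000) trait_meta(name, "quantitative", n)

cc_meta <- function(name = "CV", n = 10000, phi = 0.3)
  trait_meta(name, "case_control", n, case_fraction = phi)

`%||%` <- function(x, y) if (is.null(x)) y else x

# Aligned pair straight from z-scores (shared variant frame).
# GWAS-scale standard errors so z = 10 is a genuinely decisive signal
# after Wakefield shrinkage.
pair_from_z <- function(z1, z2, pos = NULL, se = 0.02) {
  m <- length(z1)
  pos <- pos %||% (100L * seq_len(m))
  data.frame(variant_id = sprintf("rs%d", seq_len(m)), chrom = "1",
             pos = pos, ea = "A", oa = "G",
             eaf_1 = 0.3, beta_1 = z1 * se, se_1 = se, pval_1 = 1,
             n_1 = 1e4, info_1 = 1,
             eaf_2 = 0.3, beta_2 = z2 * se, se_2 = se, pval_2 = 1,
             n_2 = 1e4, info_2 = 1, stringsAsFactors = FALSE)
}
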