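# Published effect estimates bundled for worked examples and checks.

#' Published UK Biobank shared-signal effects for FVC
#'
#' Effect estimates, as published, for the seven genes whose FVC
#' association shares a variant with one or more cardiovascular traits
#' in UK Biobank (lung-development candidate-gene colocalisation).
#' Effects are reported with the effect allele chosen as the allele
#' detrimental to lung function, so every `lung_beta` is negative;
#' cardiovascular effects are odds ratios for binary traits (HTN, CHD)
#' and betas for continuous traits (SBP, DBP, pulse pressure, CIMT).
#' The `oa` column is a synthetic placeholder frame (the published
#' tables do not print the other allele; direction logic never needs
#' it because all rows share one frame).
#'
#' @return `data.frame` with one row per gene-CV-trait pair.
#' @export
ukb_fvc_h4_effects <- function() {
  utils::read.delim(system.file("extdata", "ukb_fvc_h4_direction.tsv",
                                package = "colocpipe"),
                    stringsAsFactors = FALSE)
}

#' Published FinnGen replication inputs for shared HTN/CHD signals
#'
#' UK Biobank discovery and FinnGen replication odds ratios and
#' two-sided p-values for the seven genes whose lung-function signal
#' colocalises with hypertension or coronary heart disease (nine
#' gene-trait tests in total; one signal used an LD proxy). The effect
#' allele is the lung-detrimental allele throughout.
#'
#' @return `data.frame` with one row per gene-CV-trait test.
#' @export
finngen_replication_inputs <- function() {
  utils::read.delim(system.file("extdata", "finngen_htn_chd_replication.tsv",
                                package = "colocpipe"),
                    stringsAsFactors = FALSE)
}
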