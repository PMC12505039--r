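#' Priors for colocalisation
#'
#' Per-variant prior probabilities that a variant is associated with
#' trait 1 only (`p1`), trait 2 only (`p2`) or both (`p12`), and the
#' prior standard deviation of a true effect used in the Wakefield
#' approximate Bayes factor (`w_sd_quant` on the quantitative trait
#' scale, `w_sd_cc` on the log-odds scale).
#'
#' @param p1,p2,p12 Per-variant prior probabilities; `0 < p12 <=
#'   min(p1, p2)` is required.
#' @param w_sd_quant,w_sd_cc Prior effect standard deviations (> 0).
#' @return An object of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         w_sd_quant = 0.15, w_sd_cc = 0.2) {
  assert_that(p1 > 0 && p2 > 0 && p12 > 0, "priors must be positive")
  assert_that(p12 <= min(p1, p2), "p12 must be <= min(p1, p2)")
  assert_that(w_sd_quant > 0 && w_sd_cc > 0, "w_sd must be > 0")
  structure(list(p1 = p1, p2 = p2, p12 = p12,
                 w_sd_quant = w_sd_quant, w_sd_cc = w_sd_cc),
            class = "coloc_priors")
}

check_prior_mass <- function(priors, m) {
  assert_that(m * (priors$p1 + priors$p2 + priors$p12) < 1,
              "priors leave no mass for the null with m = %d variants", m)
}

w_sd_for <- function(priors, meta) {
  if (meta$trait_type == "case_control") priors$w_sd_cc else priors$w_sd_quant
}

#' Wakefield log approximate Bayes factor
#'
#' For an estimate `beta` with standard error `se` and a normal effect
#' prior with standard deviation `w_sd`: with `V = se^2`, `W = w_sd^2`,
#' `r = W / (V + W)` and `z = beta / se`, the log Bayes factor of
#' association against the null is `0.5 * (log(1 - r) + r * z^2)`.
#' Vectorised over `beta`/`se`.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s), > 0.
#' @param w_sd Prior effect standard deviation (>= 0; 0 gives lABF = 0).
#' @return Log Bayes factor(s).
#' @export
wakefield_labf <- function(beta, se, w_sd) {
  assert_that(all(se > 0), "se must be > 0")
  assert_that(w_sd >= 0, "w_sd must be >= 0")
  V <- se^2
  W <- w_sd^2
  r <- W / (V + W)
  z2 <- (beta / se)^2
  0.5 * (log1p(-r) + r * z2)
}

# Log hypothesis sums from two labf vectors, all in log space. The H3
# sum runs over distinct-variant pairs: for regions up to a few hundred
# variants the off-diagonal terms are enumerated exactly (the subtraction
# identity sum_i sum_j - sum_ii loses precision when one variant
# dominates both traits); beyond that the logdiff identity is used.
# H3 is exactly -Inf for m = 1 (no distinct-variant configuration).
coloc_logsums <- function(l1, l2, priors) {
  m <- length(l1)
  ls1 <- logsumexp(l1)
  ls2 <- logsumexp(l2)
  ls12 <- logsumexp(l1 + l2)
  lh3 <- if (m == 1) {
    -Inf
  } else if (m <= 300) {
    cross <- outer(l1, l2, "+")
    logsumexp(cross[row(cross) != col(cross)])
  } else {
    logdiff(ls1 + ls2, ls12)
  }
  c(h0 = 0,
    h1 = log(priors$p1) + ls1,
    h2 = log(priors$p2) + ls2,
    h3 = log(priors$p1) + log(priors$p2) + lh3,
    h4 = log(priors$p12) + ls12)
}

#' Bayesian colocalisation of two traits over one region
#'
#' Computes per-variant Wakefield log approximate Bayes factors for each
#' trait and the posterior probabilities of the five single-causal-variant
#' hypotheses: H0 (no association), H1 (trait 1 only), H2 (trait 2
#' only), H3 (both traits, distinct variants) and H4 (both traits, one
#' shared variant). Hypothesis sums are accumulated in log space
#' (log-sum-exp), so regions with very strong signals (|z| of 20 and
#' beyond) do not overflow.
#'
#' @param pair Aligned two-trait table from [align_traits()] (columns
#'   `beta_1`, `se_1`, `beta_2`, `se_2`, one allele frame).
#' @param meta_1,meta_2 [trait_meta()] for the two traits; the trait type
#'   selects the prior effect scale (`w_sd_quant` vs `w_sd_cc`).
#' @param priors A [coloc_priors()].
#' @return An object of class `coloc_abf`: list with `pp` (named
#'   `PP0 ... PP4`, summing to 1), `labf_1`, `labf_2`, `snp_pp_h4` (the
#'   per-variant posterior of being the shared variant, conditional on
#'   H4), `variant_ids`, `pos`, `n_variants` and `priors`.
#' @seealso [classify_coloc()], [finemap_abf()], [brute_force_coloc()]
#' @export
coloc_abf <- function(pair, meta_1, meta_2, priors = coloc_priors()) {
  stopifnot(inherits(meta_1, "trait_meta"), inherits(meta_2, "trait_meta"),
            inherits(priors, "coloc_priors"))
  m <- nrow(pair)
  assert_that(m >= 1, "region error: no shared variants to colocalise")
  check_prior_mass(priors, m)
  l1 <- wakefield_labf(pair$beta_1, pair$se_1, w_sd_for(priors, meta_1))
  l2 <- wakefield_labf(pair$beta_2, pair$se_2, w_sd_for(priors, meta_2))
  logs <- coloc_logsums(l1, l2, priors)
  pp <- exp(logs - logsumexp(logs))
  pp <- pp / sum(pp)
  names(pp) <- paste0("PP", 0:4)
  l12 <- l1 + l2
  snp_pp_h4 <- exp(l12 - logsumexp(l12))
  structure(list(pp = pp, labf_1 = l1, labf_2 = l2, snp_pp_h4 = snp_pp_h4,
                 variant_ids = pair$variant_id, pos = pair$pos,
                 n_variants = m, priors = priors,
                 traits = c(meta_1$trait_name, meta_2$trait_name)),
            class = "coloc_abf")
}

#' @export
print.coloc_abf <- function(x, ...) {
  cat(sprintf("Colocalisation of %s vs %s over %d variants\n",
              x$traits[1], x$traits[2], x$n_variants))
  print(round(x$pp, 4))
  top <- which.max(x$snp_pp_h4)
  cat(sprintf("Top shared variant (given H4): %s (snp PP %.3f)\n",
              x$variant_ids[top], x$snp_pp_h4[top]))
  invisible(x)
}

#' @export
summary.coloc_abf <- function(object, threshold = 0.70, ...) {
  lab <- classify_coloc(object, threshold)
  out <- c(as.list(object$pp),
           list(n_variants = object$n_variants, label = lab,
                threshold = threshold))
  structure(out, class = "summary.coloc_abf")
}

#' @export
print.summary.coloc_abf <- function(x, ...) {
  cat(sprintf("n_variants = %d; classification at PP >= %.2f: %s\n",
              x$n_variants, x$threshold, x$label))
  print(round(unlist(x[paste0("PP", 0:4)]), 4))
  invisible(x)
}

#' Classify a colocalisation result
#'
#' H4 if `PP4 >= threshold`; otherwise H3 if `PP3 >= threshold`;
#' otherwise the highest-posterior hypothesis if it reaches the
#' threshold; otherwise `"none"`.
#'
#' @param result A [coloc_abf()] result.
#' @param threshold Posterior-probability threshold in (0, 1\]
#'   (default 0.70).
#' @return One of `"H4" "H3" "H2" "H1" "H0" "none"`.
#' @export
classify_coloc <- function(result, threshold = 0.70) {
  assert_that(threshold > 0 && threshold <= 1,
              "threshold must be in (0, 1]")
  pp <- result$pp
  if (pp[["PP4"]] >= threshold) return("H4")
  if (pp[["PP3"]] >= threshold) return("H3")
  k <- which.max(pp)
  if (pp[[k]] >= threshold) return(sub("PP", "H", names(pp)[k]))
  "none"
}

#' Single-trait fine mapping under one causal variant
#'
#' Per-variant posterior probability of being the causal variant,
#' conditional on the region containing exactly one:
#' `snp_pp_i = exp(labf_i) / sum_j exp(labf_j)` (computed in log space).
#' The posterior of no association (`pp_null`) weighs the null
#' configuration, at prior mass `1 - m * p1`, against the m
#' single-causal configurations at prior `p1` each.
#'
#' @param stats Summary-statistic `data.frame` for one trait.
#' @param meta A [trait_meta()] selecting the prior effect scale.
#' @param priors A [coloc_priors()]; `m * p1` must be < 1.
#' @return An object of class `finemap_abf`: list with `variant_ids`,
#'   `pos`, `labf`, `snp_pp` (sums to 1) and `pp_null`.
#' @export
finemap_abf <- function(stats, meta, priors = coloc_priors()) {
  stopifnot(inherits(meta, "trait_meta"))
  m <- nrow(stats)
  assert_that(m >= 1, "need at least one variant")
  null_mass <- 1 - m * priors$p1
  assert_that(null_mass > 0,
              "prior mass 1 - m*p1 must be positive (m = %d)", m)
  labf <- wakefield_labf(stats$beta, stats$se, w_sd_for(priors, meta))
  snp_pp <- exp(labf - logsumexp(labf))
  log_alt <- log(priors$p1) + logsumexp(labf)
  pp_null <- exp(log(null_mass) - logsumexp(c(log(null_mass), log_alt)))
  structure(list(variant_ids = stats$variant_id, pos = stats$pos,
                 labf = labf, snp_pp = snp_pp / sum(snp_pp),
                 pp_null = pp_null, trait = meta$trait_name),
            class = "finemap_abf")
}

#' @export
print.finemap_abf <- function(x, ...) {
  top <- order(x$snp_pp, decreasing = TRUE)[seq_len(min(3, length(x$snp_pp)))]
  cat(sprintf("Fine mapping of %s over %d variants (pp_null = %.3f)\n",
              x$trait %||% "trait", length(x$snp_pp), x$pp_null))
  print(data.frame(variant_id = x$variant_ids[top],
                   snp_pp = round(x$snp_pp[top], 4)))
  invisible(x)
}

#' Exhaustive-enumeration colocalisation oracle
#'
#' Independently recomputes the H0-H4 posteriors by explicitly looping
#' over every single-causal configuration — the null; trait 1 causal at
#' i; trait 2 causal at j; both causal at distinct (i, j); a shared
#' causal at i — with prior weights 1, `p1`, `p2`, `p1*p2` and `p12`,
#' multiplying in the corresponding Bayes factors on the linear scale
#' and normalising. Deliberately naive (O(m^2), no log-space tricks):
#' it exists as a test oracle for [coloc_abf()] and refuses regions with
#' more than 12 variants.
#'
#' @inheritParams coloc_abf
#' @return A list with `pp` as in [coloc_abf()].
#' @export
brute_force_coloc <- function(pair, meta_1, meta_2, priors = coloc_priors()) {
  m <- nrow(pair)
  assert_that(m <= 12, "brute-force oracle limited to m <= 12 (got %d)", m)
  check_prior_mass(priors, m)
  L1 <- exp(wakefield_labf(pair$beta_1, pair$se_1, w_sd_for(priors, meta_1)))
  L2 <- exp(wakefield_labf(pair$beta_2, pair$se_2, w_sd_for(priors, meta_2)))
  s <- c(h0 = 1, h1 = 0, h2 = 0, h3 = 0, h4 = 0)
  for (i in seq_len(m)) {
    s["h1"] <- s["h1"] + priors$p1 * L1[i]
    s["h2"] <- s["h2"] + priors$p2 * L2[i]
    s["h4"] <- s["h4"] + priors$p12 * L1[i] * L2[i]
    for (j in seq_len(m)) {
      if (i != j)
        s["h3"] <- s["h3"] + priors$p1 * priors$p2 * L1[i] * L2[j]
    }
  }
  pp <- s / sum(s)
  names(pp) <- paste0("PP", 0:4)
  list(pp = pp)
}
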