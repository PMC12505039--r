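#' Per-variant linear association
#'
#' Ordinary least squares of a quantitative phenotype on the additive
#' genotype dosage plus covariates plus an intercept; a desk-scale
#' stand-in for the whole-genome regression stage of a biobank GWAS
#' (which additionally conditions on polygenic background and
#' relatedness). Returns the genotype coefficient with its standard
#' error and two-sided Wald p-value as one summary-statistic row; the
#' reported `eaf` is the observed effect-allele frequency in the
#' analysis sample.
#'
#' @param data An `individual_data` object (see [simulate_individual()]).
#' @param variant_index Column of the genotype matrix to test.
#' @return A one-row summary-statistic `data.frame` (see [sumstats]).
#' @export
linear_assoc <- function(data, variant_index) {
  stopifnot(inherits(data, "individual_data"))
  g <- data$genotypes[, variant_index]
  y <- data$phenotype
  k <- if (is.null(data$covariates)) 0L else ncol(data$covariates)
  assert_that(length(y) > k + 2, "need n > k + 2 observations")
  if (stats::var(g) == 0) stopf("degenerate fit: genotype column is constant")
  df <- data.frame(y = y, g = g)
  if (k > 0) df <- cbind(df, as.data.frame(data$covariates))
  fit <- stats::lm(y ~ ., data = df)
  if (any(is.na(stats::coef(fit))))
    stopf("degenerate fit: collinear design (genotype or covariate aliased)")
  tss <- sum((y - mean(y))^2)
  if (stats::deviance(fit) <= 1e-16 * max(tss, .Machine$double.xmin))
    stopf("degenerate fit: residual variance is zero")
  sm <- summary(fit)$coefficients
  assoc_record(data, variant_index, beta = sm["g", 1], se = sm["g", 2],
               pval = sm["g", 4], n = length(y))
}

#' Per-variant logistic association
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via [stats::glm()]) of a binary phenotype on the additive
#' genotype dosage plus covariates. The effect is reported on the
#' log-odds scale with its Wald standard error and two-sided p-value.
#'
#' @inheritParams linear_assoc
#' @return A one-row summary-statistic `data.frame`.
#' @export
logistic_assoc <- function(data, variant_index) {
  stopifnot(inherits(data, "individual_data"))
  g <- data$genotypes[, variant_index]
  y <- data$phenotype
  assert_that(all(y %in% 0:1), "phenotype must be binary 0/1")
  assert_that(length(unique(y)) == 2, "both classes must be present")
  if (stats::var(g) == 0) stopf("degenerate fit: genotype column is constant")
  df <- data.frame(y = y, g = g)
  if (!is.null(data$covariates)) df <- cbind(df, as.data.frame(data$covariates))
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = df, family = stats::binomial(),
               control = list(epsilon = 1e-10, maxit = 50)))
  sm <- summary(fit)$coefficients
  if (!fit$converged || abs(sm["g", 1]) > 15)
    stopf("separation: logistic fit did not converge to a finite effect")
  assoc_record(data, variant_index, beta = sm["g", 1], se = sm["g", 2],
               pval = sm["g", 4], n = length(y))
}

assoc_record <- function(data, j, beta, se, pval, n) {
  data.frame(variant_id = data$variant_ids[j], chrom = data$chrom,
             pos = data$pos[j], ea = data$ea[j], oa = data$oa[j],
             eaf = mean(data$genotypes[, j]) / 2,
             beta = beta, se = se, pval = max(pval, .Machine$double.xmin),
             n = n, info = 1, stringsAsFactors = FALSE)
}

#' Association scan over all variants of a region
#'
#' Applies [linear_assoc()] or [logistic_assoc()] (by the data's trait
#' type) to every genotype column.
#'
#' @param data An `individual_data` object.
#' @return A summary-statistic `data.frame`, one row per variant.
#' @export
assoc_scan <- function(data) {
  f <- if (data$trait_type == "case_control") logistic_assoc else linear_assoc
  out <- do.call(rbind, lapply(seq_along(data$variant_ids),
                               function(j) f(data, j)))
  rownames(out) <- NULL
  out
}

#' Fixed-effect (inverse-variance) meta-analysis of one variant
#'
#' Combines k studies' estimates for the same variant with weights
#' `w_i = 1/se_i^2`: `beta_meta = sum(w beta) / sum(w)` and
#' `se_meta = 1/sqrt(sum(w))`, with a two-sided normal Wald p-value.
#' All studies must report the same variant in the same allele frame
#' (use [orient_record()] first).
#'
#' @param stats_list List of one-row summary-statistic `data.frame`s for
#'   a single variant.
#' @return A one-row `data.frame` with `variant_id`, `beta_meta`,
#'   `se_meta`, `pval_meta`, `n_effective`, `k_studies`.
#' @export
fixed_effect_meta <- function(stats_list) {
  assert_that(length(stats_list) >= 1, "need at least one study")
  ref <- stats_list[[1]]
  for (s in stats_list[-1]) {
    if (s$variant_id != ref$variant_id)
      stopf("meta-analysis across different variants (%s vs %s)",
            ref$variant_id, s$variant_id)
    if (s$ea != ref$ea || s$oa != ref$oa)
      stopf("harmonisation error: allele frames differ for %s; orient first",
            ref$variant_id)
  }
  beta <- vapply(stats_list, function(s) s$beta, 0)
  se <- vapply(stats_list, function(s) s$se, 0)
  w <- 1 / se^2
  beta_meta <- sum(w * beta) / sum(w)
  se_meta <- 1 / sqrt(sum(w))
  z <- beta_meta / se_meta
  data.frame(variant_id = ref$variant_id, beta_meta = beta_meta,
             se_meta = se_meta, pval_meta = 2 * stats::pnorm(-abs(z)),
             n_effective = sum(vapply(stats_list, function(s) s$n, 0)),
             k_studies = length(stats_list), stringsAsFactors = FALSE)
}

#' Variant-wise fixed-effect meta-analysis of two summary-stat sets
#'
#' Aligns the two sets onto study 1's allele frame with [align_traits()]
#' and meta-analyses each shared variant, returning a summary-statistic
#' `data.frame` usable downstream (e.g. pooling a biobank and a
#' consortium CHD analysis before colocalisation).
#'
#' @param stats1,stats2 Summary-statistic `data.frame`s.
#' @return A summary-statistic `data.frame` on study 1's allele frame.
#' @export
meta_sumstats <- function(stats1, stats2) {
  pair <- align_traits(stats1, stats2)
  w1 <- 1 / pair$se_1^2
  w2 <- 1 / pair$se_2^2
  beta <- (w1 * pair$beta_1 + w2 * pair$beta_2) / (w1 + w2)
  se <- 1 / sqrt(w1 + w2)
  z <- beta / se
  data.frame(variant_id = pair$variant_id, chrom = pair$chrom,
             pos = pair$pos, ea = pair$ea, oa = pair$oa, eaf = pair$eaf_1,
             beta = beta, se = se, pval = 2 * stats::pnorm(-abs(z)),
             n = pair$n_1 + pair$n_2, info = pmin(pair$info_1, pair$info_2),
             stringsAsFactors = FALSE)
}
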