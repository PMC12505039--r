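#' Scenario specification for a simulated two-trait region
#'
#' Encodes the ground truth of one simulated LD-structured region under a
#' single colocalisation hypothesis:
#' \itemize{
#'   \item H0 — no causal variant for either trait;
#'   \item H1 — a causal variant for trait 1 only;
#'   \item H2 — a causal variant for trait 2 only;
#'   \item H3 — distinct causal variants for the two traits;
#'   \item H4 — one shared causal variant.
#' }
#'
#' @param hypothesis One of `"H0" ... "H4"`.
#' @param m_variants Number of variants in the region.
#' @param ld_rho AR(1) LD decay parameter in \[0, 1): the allelic
#'   correlation between variants i and j is `ld_rho^|i-j|`. Ignored if
#'   `ld` is given.
#' @param ld Optional explicit [ld_matrix()].
#' @param freqs Effect-allele frequencies, recycled to `m_variants`;
#'   each in (0.01, 0.99).
#' @param causal_1,causal_2 Causal variant indices (1-based) as the
#'   hypothesis requires.
#' @param beta_1,beta_2 Causal effect sizes (trait units per allele copy
#'   for quantitative traits; log odds ratio for case-control traits).
#'   Must be non-zero whenever the hypothesis declares a causal variant.
#' @param n_1,n_2 GWAS sample sizes for the two traits.
#' @param trait_types Length-2 character vector, each `"quantitative"` or
#'   `"case_control"`.
#' @param case_fraction_2 Case fraction for trait 2 when case-control.
#' @param resid_sd Residual phenotype standard deviation used to scale
#'   quantitative non-centrality (default 1).
#' @param seed Integer seed making the region reproducible.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(hypothesis = c("H0", "H1", "H2", "H3", "H4"),
                          m_variants, ld_rho = 0.5, ld = NULL,
                          freqs = 0.3, causal_1 = NULL, causal_2 = NULL,
                          beta_1 = 0, beta_2 = 0, n_1 = 10000, n_2 = 10000,
                          trait_types = c("quantitative", "quantitative"),
                          case_fraction_2 = NULL, resid_sd = 1, seed = 1L) {
  hypothesis <- match.arg(hypothesis)
  assert_that(m_variants >= 1, "m_variants must be >= 1")
  if (is.null(ld)) {
    assert_that(ld_rho >= 0 && ld_rho < 1, "ld_rho must be in [0,1)")
  } else {
    assert_that(nrow(ld) == m_variants, "explicit LD must be m x m")
  }
  freqs <- rep_len(freqs, m_variants)
  assert_that(all(freqs > 0.01 & freqs < 0.99),
              "freqs must lie in (0.01, 0.99)")
  assert_that(all(trait_types %in% c("quantitative", "case_control")) &&
                length(trait_types) == 2, "trait_types must be a valid pair")
  if (trait_types[2] == "case_control")
    assert_that(is_scalar_number(case_fraction_2) && case_fraction_2 > 0 &&
                  case_fraction_2 < 1, "case_fraction_2 required in (0,1)")
  valid_idx <- function(i) !is.null(i) && i >= 1 && i <= m_variants
  has1 <- hypothesis %in% c("H1", "H3", "H4")
  has2 <- hypothesis %in% c("H2", "H3", "H4")
  assert_that(has1 == valid_idx(causal_1),
              "%s requires causal_1 %s", hypothesis,
              if (has1) "to be a valid index" else "to be absent")
  assert_that(has2 == valid_idx(causal_2),
              "%s requires causal_2 %s", hypothesis,
              if (has2) "to be a valid index" else "to be absent")
  if (hypothesis == "H3")
    assert_that(causal_1 != causal_2, "H3 requires distinct causal variants")
  if (hypothesis == "H4")
    assert_that(causal_1 == causal_2, "H4 requires a shared causal variant")
  if (has1) assert_that(beta_1 != 0, "causal_1 declared but beta_1 is 0")
  if (has2) assert_that(beta_2 != 0, "causal_2 declared but beta_2 is 0")
  structure(list(hypothesis = hypothesis, m_variants = as.integer(m_variants),
                 ld_rho = ld_rho, ld = ld, freqs = freqs,
                 causal_1 = causal_1, causal_2 = causal_2,
                 beta_1 = beta_1, beta_2 = beta_2,
                 n_1 = as.integer(n_1), n_2 = as.integer(n_2),
                 trait_types = trait_types, case_fraction_2 = case_fraction_2,
                 resid_sd = resid_sd, seed = as.integer(seed)),
            class = "scenario_spec")
}

#' AR(1) LD matrix
#'
#' `r[i, j] = rho^|i-j|`, a symmetric positive-definite correlation
#' structure mimicking distance-decaying LD along a region.
#'
#' @param m Number of variants.
#' @param rho Decay parameter in \[0, 1).
#' @param variant_ids Optional ids (default `v001 ...`).
#' @param pos Optional positions (default `1000 * 1:m`).
#' @return An [ld_matrix()].
#' @export
make_ld_ar1 <- function(m, rho, variant_ids = NULL, pos = NULL) {
  assert_that(rho >= 0 && rho < 1, "rho must be in [0,1)")
  r <- rho ^ abs(outer(seq_len(m), seq_len(m), "-"))
  if (is.null(variant_ids)) variant_ids <- sprintf("v%03d", seq_len(m))
  if (is.null(pos)) pos <- 1000L * seq_len(m)
  ld_matrix(r, variant_ids, pos = pos)
}

# Cholesky factor with fallbacks for matrices that are PSD only up to
# rounding: diagonal inflation first, then an eigenvalue clip.
chol_psd <- function(r) {
  ch <- tryCatch(chol(r), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  ch <- tryCatch(chol(r + diag(1e-8, nrow(r))), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  e <- eigen(r, symmetric = TRUE)
  if (min(e$values) < -0.05)
    stopf("LD matrix is not positive semi-definite")
  v <- pmax(e$values, 1e-8)
  r2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(r2))
  chol(r2 / outer(d, d))
}

# P(X < h, Y < k) for standard bivariate normal with correlation rho.
phi2 <- function(h, k, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(h) * stats::pnorm(k))
  s <- sqrt(1 - rho^2)
  stats::integrate(function(x)
    stats::dnorm(x) * stats::pnorm((k - rho * x) / s),
    -Inf, h, rel.tol = 1e-10)$value
}

# Allelic (binary) correlation produced by thresholding a latent
# bivariate normal with correlation rho at the freq quantiles.
binary_corr <- function(rho, qi, qj, fi, fj) {
  (phi2(qi, qj, rho) - fi * fj) / sqrt(fi * (1 - fi) * fj * (1 - fj))
}

# Latent correlation whose thresholded alleles have correlation target
# (inverse tetrachoric map); monotone in rho, solved by uniroot.
latent_corr <- function(target, qi, qj, fi, fj) {
  if (abs(target) < 1e-4) return(target)
  stats::uniroot(function(rho) binary_corr(rho, qi, qj, fi, fj) - target,
                 interval = c(-0.99999, 0.99999), tol = 1e-8)$root
}

# Elementwise inverse-tetrachoric adjustment of a target allelic
# correlation matrix, cached over its distinct (f_i, f_j, r) entries.
latent_ld <- function(r, freqs) {
  q <- stats::qnorm(freqs)
  out <- diag(nrow(r))
  idx <- which(upper.tri(r) & abs(r) >= 1e-4, arr.ind = TRUE)
  small <- which(upper.tri(r) & abs(r) < 1e-4, arr.ind = TRUE)
  out[small] <- r[small]
  out[small[, c(2, 1), drop = FALSE]] <- r[small]
  if (nrow(idx) == 0) return(out)
  key <- paste(pmin(freqs[idx[, 1]], freqs[idx[, 2]]),
               pmax(freqs[idx[, 1]], freqs[idx[, 2]]),
               signif(r[idx], 12))
  cache <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    val <- cache[[key[k]]]
    if (is.null(val)) {
      val <- latent_corr(r[i, j], q[i], q[j], freqs[i], freqs[j])
      cache[[key[k]]] <- val
    }
    out[i, j] <- out[j, i] <- val
  }
  out
}

#' Simulate genotypes under a target LD structure
#'
#' Gaussian-copula haplotype model: each haplotype is a latent
#' multivariate normal draw thresholded at the allele-frequency
#' quantile; a genotype is the sum of two independent haplotypes, so
#' dosages are in \{0, 1, 2\} and the expected allele frequency equals
#' `freqs` exactly. Because thresholding attenuates correlation, the
#' latent correlations are pre-inflated by the inverse tetrachoric map
#' so that the allelic correlation of the generated haplotypes matches
#' `ld` in expectation (disable with `match_ld = FALSE` to threshold
#' the latent correlation as-is).
#'
#' @param n Number of individuals (0 allowed).
#' @param freqs Effect-allele frequencies, recycled to the LD dimension.
#' @param ld An [ld_matrix()].
#' @param seed Optional integer seed.
#' @param match_ld Apply the inverse-tetrachoric adjustment (default
#'   `TRUE`).
#' @return An `n x m` integer matrix with variant ids as column names.
#' @export
simulate_genotypes <- function(n, freqs, ld, seed = NULL, match_ld = TRUE) {
  m <- nrow(ld)
  freqs <- rep_len(freqs, m)
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(0L, n, m, dimnames = list(NULL, rownames(ld)))
  if (n == 0) return(out)
  thr <- stats::qnorm(freqs)
  lat <- if (match_ld) latent_ld(unclass(ld), freqs) else unclass(ld)
  ch <- chol_psd(lat)
  for (hap in 1:2) {
    z <- matrix(stats::rnorm(n * m), n, m) %*% ch
    out <- out + (sweep(z, 2, thr, "<") * 1L)
  }
  storage.mode(out) <- "integer"
  out
}

#' Simulate a quantitative phenotype with one additive causal variant
#'
#' `y = beta * g_causal + covariates %*% covar_effects + N(0, noise_sd)`.
#' With `causal_index = NULL` or `beta = 0` the phenotype is independent
#' of all genotypes.
#'
#' @param geno Genotype matrix from [simulate_genotypes()].
#' @param covariates Optional `n x k` covariate matrix.
#' @param causal_index Column index of the causal variant, or `NULL`.
#' @param beta Additive effect per effect-allele copy.
#' @param noise_sd Residual standard deviation (>= 0; 0 gives a
#'   noise-free phenotype exactly proportional to the causal dosage when
#'   covariate effects are zero).
#' @param covar_effects Covariate effects (default all 0).
#' @param seed Optional integer seed.
#' @return Numeric phenotype vector.
#' @export
simulate_quant_trait <- function(geno, covariates = NULL, causal_index = NULL,
                                 beta = 0, noise_sd = 1, covar_effects = NULL,
                                 seed = NULL) {
  assert_that(noise_sd >= 0, "noise_sd must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(geno)
  y <- if (noise_sd > 0) stats::rnorm(n, sd = noise_sd) else numeric(n)
  if (!is.null(causal_index)) y <- y + beta * geno[, causal_index]
  if (!is.null(covariates)) {
    covar_effects <- covar_effects %||% rep(0, ncol(covariates))
    y <- y + as.vector(covariates %*% covar_effects)
  }
  y
}

#' Simulate a binary phenotype under a logistic model
#'
#' Case probability is `plogis(intercept + log_or * g_causal +
#' covariates %*% covar_effects)`.
#'
#' @inheritParams simulate_quant_trait
#' @param log_or Log odds ratio per effect-allele copy.
#' @param intercept Logistic intercept controlling baseline prevalence.
#' @return Integer 0/1 phenotype vector.
#' @export
simulate_binary_trait <- function(geno, covariates = NULL, causal_index = NULL,
                                  log_or = 0, intercept = 0,
                                  covar_effects = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(geno)
  eta <- rep(intercept, n)
  if (!is.null(causal_index)) eta <- eta + log_or * geno[, causal_index]
  if (!is.null(covariates)) {
    covar_effects <- covar_effects %||% rep(0, ncol(covariates))
    eta <- eta + as.vector(covariates %*% covar_effects)
  }
  stats::rbinom(n, 1L, stats::plogis(eta))
}

#' Pulse pressure from systolic and diastolic blood pressure
#'
#' Elementwise `sbp - dbp` (mm Hg).
#'
#' @param sbp,dbp Equal-length numeric vectors.
#' @return Numeric vector of pulse pressures.
#' @export
derive_pulse_pressure <- function(sbp, dbp) {
  assert_that(length(sbp) == length(dbp), "sbp and dbp lengths differ")
  sbp - dbp
}

#' Hypertension case status
#'
#' Case iff `sbp >= 140` mm Hg or `dbp >= 90` mm Hg or on
#' antihypertensive treatment.
#'
#' @param sbp,dbp Blood pressures (mm Hg).
#' @param treated Logical vector: on antihypertensive treatment.
#' @return Integer 0/1 vector.
#' @export
derive_htn <- function(sbp, dbp, treated = FALSE) {
  treated <- rep_len(treated, length(sbp))
  assert_that(length(sbp) == length(dbp), "sbp and dbp lengths differ")
  as.integer(sbp >= 140 | dbp >= 90 | treated)
}

# Per-variant standard error of a marginal GWAS effect under
# Hardy-Weinberg dosage variance 2f(1-f): quantitative traits
# se = resid_sd / sqrt(2 n f (1-f)); case-control (log-odds scale)
# se = 1 / sqrt(2 n phi (1-phi) f (1-f)).
sumstat_se <- function(n, freqs, trait_type, case_fraction = NULL,
                       resid_sd = 1) {
  v <- 2 * freqs * (1 - freqs)
  if (trait_type == "case_control")
    1 / sqrt(n * case_fraction * (1 - case_fraction) * v)
  else
    resid_sd / sqrt(n * v)
}

# Non-centrality of the causal variant's z-score.
causal_lambda <- function(beta, n, f, trait_type, case_fraction = NULL,
                          resid_sd = 1) {
  beta / sumstat_se(n, f, trait_type, case_fraction, resid_sd)
}

make_stats_frame <- function(ld, z, se, freqs, n) {
  beta <- z * se
  data.frame(variant_id = rownames(ld), chrom = "1",
             pos = attr(ld, "pos") %||% (1000L * seq_len(nrow(ld))),
             ea = "A", oa = "G", eaf = freqs, beta = beta, se = se,
             pval = 2 * stats::pnorm(-abs(z)), n = n, info = 1,
             stringsAsFactors = FALSE)
}

#' Simulate two-trait summary statistics directly from LD
#'
#' Fast path that bypasses individual-level data: the vector of
#' per-variant z-scores for each trait is drawn from a multivariate
#' normal with covariance `R` (the LD matrix) and mean `R e_c lambda`,
#' where `e_c` indicates the causal variant and `lambda` is its
#' non-centrality (`beta * sqrt(2 n f (1-f)) / resid_sd` for quantitative
#' traits, with the extra `sqrt(phi (1-phi))` factor for case-control
#' traits). Z-scores are converted to beta/se using the same
#' Hardy-Weinberg variance formulas.
#'
#' @param spec A [scenario_spec()].
#' @return A `simulated_region`: list with `ld`, `stats_1`, `stats_2`
#'   (summary-statistic `data.frame`s) and `truth` (the spec).
#' @export
simulate_sumstats_direct <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  m <- spec$m_variants
  ld <- spec$ld %||% make_ld_ar1(m, spec$ld_rho)
  R <- unclass(ld)
  set.seed(spec$seed)
  draw_trait <- function(causal, beta, n, type, phi) {
    mu <- rep(0, m)
    if (!is.null(causal)) {
      lam <- causal_lambda(beta, n, spec$freqs[causal], type, phi,
                           spec$resid_sd)
      mu <- R[, causal] * lam
    }
    z <- as.vector(MASS::mvrnorm(1, mu = mu, Sigma = R))
    se <- sumstat_se(n, spec$freqs, type, phi, spec$resid_sd)
    make_stats_frame(ld, z, se, spec$freqs, n)
  }
  stats_1 <- draw_trait(spec$causal_1, spec$beta_1, spec$n_1,
                        spec$trait_types[1], NULL)
  stats_2 <- draw_trait(spec$causal_2, spec$beta_2, spec$n_2,
                        spec$trait_types[2], spec$case_fraction_2)
  structure(list(ld = ld, stats_1 = stats_1, stats_2 = stats_2,
                 truth = spec),
            class = "simulated_region")
}

#' Simulate individual-level data for one trait of a scenario
#'
#' Generates genotypes under the scenario's LD, optional standard-normal
#' covariate columns (emulating age, sex, array, centre and ancestry
#' principal components) and the phenotype for the requested trait, plus
#' a random sample flag (an asthma analogue) for exclusion-sensitivity
#' runs.
#'
#' @param spec A [scenario_spec()].
#' @param trait Which trait to generate (1 or 2).
#' @param n Sample size (defaults to the spec's `n_1`/`n_2`).
#' @param k_covariates Number of covariate columns.
#' @param covar_effects Covariate effects (default 0).
#' @param flag_fraction Expected fraction of flagged samples.
#' @param intercept Logistic intercept for case-control traits; defaults
#'   to `qlogis(case_fraction_2)`.
#' @return An object of class `individual_data`: list with `genotypes`,
#'   `covariates`, `phenotype`, `sample_flags`, `variant_ids`, `ea`, `oa`,
#'   `pos`, `chrom` and `trait_type`.
#' @export
simulate_individual <- function(spec, trait = 1, n = NULL, k_covariates = 0,
                                covar_effects = NULL, flag_fraction = 0,
                                intercept = NULL) {
  stopifnot(inherits(spec, "scenario_spec"), trait %in% 1:2)
  m <- spec$m_variants
  ld <- spec$ld %||% make_ld_ar1(m, spec$ld_rho)
  n <- n %||% if (trait == 1) spec$n_1 else spec$n_2
  type <- spec$trait_types[trait]
  causal <- if (trait == 1) spec$causal_1 else spec$causal_2
  beta <- if (trait == 1) spec$beta_1 else spec$beta_2
  set.seed(spec$seed + trait)
  geno <- simulate_genotypes(n, spec$freqs, ld)
  covariates <- if (k_covariates > 0)
    matrix(stats::rnorm(n * k_covariates), n, k_covariates,
           dimnames = list(NULL, paste0("cov", seq_len(k_covariates))))
  if (type == "case_control") {
    intercept <- intercept %||% stats::qlogis(spec$case_fraction_2)
    phen <- simulate_binary_trait(geno, covariates, causal, beta, intercept,
                                  covar_effects)
  } else {
    phen <- simulate_quant_trait(geno, covariates, causal, beta,
                                 spec$resid_sd, covar_effects)
  }
  flags <- stats::runif(n) < flag_fraction
  structure(list(genotypes = geno, covariates = covariates,
                 phenotype = phen, sample_flags = flags,
                 variant_ids = rownames(ld), ea = rep("A", m),
                 oa = rep("G", m), pos = attr(ld, "pos") %||%
                   (1000L * seq_len(m)),
                 chrom = "1", trait_type = type, ld = ld),
            class = "individual_data")
}
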