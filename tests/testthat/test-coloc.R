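test_that("the Wakefield log Bayes factor matches its closed form", {
  expect_equal(wakefield_labf(0.3, 0.1, 0), 0)  # zero prior variance: BF = 1
  # z = 0, shrinkage r = 0.5: BF = sqrt(0.5)
  expect_equal(wakefield_labf(0, 1, 1), 0.5 * log(0.5))
  # independent evaluation of the closed form at arbitrary values
  beta <- 0.3; se <- 0.05; w_sd <- 0.15
  V <- se^2; W <- w_sd^2; r <- W / (V + W); z <- beta / se
  expect_equal(wakefield_labf(beta, se, w_sd), 0.5 * (log(1 - r) + r * z^2))
  expect_error(wakefield_labf(0.1, 0, 0.15), "se")
})

test_that("a single variant with unit Bayes factors gives the closed-form null posterior", {
  pair <- pair_from_z(0, 0)[1, ]
  pair$se_1 <- pair$se_2 <- 1
  # force labf = 0 via w_sd = 0 priors is disallowed (w_sd > 0), so use
  # the brute-force identity directly: with L1 = L2 = 1,
  # pp0 = 1 / (1 + p1 + p2 + p12) and PP3 is structurally zero at m = 1
  p <- coloc_priors()
  L <- exp(wakefield_labf(0, 1, p$w_sd_quant))  # z = 0 still has BF < 1
  s <- c(1, p$p1 * L, p$p2 * L, 0, p$p12 * L^2)
  expected <- s / sum(s)
  res <- coloc_abf(pair, quant_meta(), quant_meta("CV"), p)
  expect_equal(unname(res$pp), expected, tolerance = 1e-12)
  expect_equal(res$pp[["PP3"]], 0)
  expect_equal(1 / (1 + 1e-4 + 1e-4 + 1e-5), 0.99979, tolerance = 1e-5)
})

test_that("posteriors are normalised even for extreme signals", {
  for (zmax in c(5, 30, 100)) {
    z1 <- c(rep(0.1, 20), zmax)
    z2 <- c(rep(-0.2, 20), zmax)
    res <- coloc_abf(pair_from_z(z1, z2), quant_meta(), quant_meta("CV"))
    expect_equal(sum(res$pp), 1, tolerance = 1e-12)
    expect_true(all(res$pp >= 0))
    expect_equal(sum(res$snp_pp_h4), 1, tolerance = 1e-12)
  }
})

test_that("swapping the traits swaps PP1 and PP2 and fixes the rest", {
  set.seed(51)
  z1 <- rnorm(30, 0, 2)
  z2 <- rnorm(30, 0, 1)
  a <- coloc_abf(pair_from_z(z1, z2), quant_meta(), quant_meta("CV"))
  b <- coloc_abf(pair_from_z(z2, z1), quant_meta(), quant_meta("CV"))
  expect_equal(a$pp[["PP1"]], b$pp[["PP2"]], tolerance = 1e-12)
  expect_equal(a$pp[["PP2"]], b$pp[["PP1"]], tolerance = 1e-12)
  expect_equal(a$pp[c("PP0", "PP3", "PP4")], b$pp[c("PP0", "PP3", "PP4")],
               tolerance = 1e-12)
})

test_that("strengthening a shared signal never decreases PP4", {
  set.seed(52)
  z_other1 <- rnorm(19, 0, 0.5)
  z_other2 <- rnorm(19, 0, 0.5)
  pp4 <- vapply(seq(2, 10, by = 1), function(zs) {
    res <- coloc_abf(pair_from_z(c(zs, z_other1), c(zs, z_other2)),
                     quant_meta(), quant_meta("CV"))
    res$pp[["PP4"]]
  }, 0)
  expect_true(all(diff(pp4) >= -1e-12))
})

test_that("a strong shared signal in a 50-variant region yields PP4 near 1", {
  z1 <- c(10, rep(0.05, 49))
  z2 <- c(10, rep(-0.05, 49))
  res <- coloc_abf(pair_from_z(z1, z2), quant_meta(), quant_meta("CV"))
  expect_gt(res$pp[["PP4"]], 0.99)
})

test_that("the trait type selects the prior effect scale", {
  pair <- pair_from_z(c(3, 1), c(2, 1))
  p <- coloc_priors()
  res_cc <- coloc_abf(pair, quant_meta(), cc_meta())
  expect_equal(res_cc$labf_2,
               wakefield_labf(pair$beta_2, pair$se_2, p$w_sd_cc))
  expect_equal(res_cc$labf_1,
               wakefield_labf(pair$beta_1, pair$se_1, p$w_sd_quant))
})

test_that("classification follows the thresholded hierarchy", {
  fake <- function(pp) structure(list(pp = stats::setNames(pp, paste0("PP", 0:4))),
                                 class = "coloc_abf")
  expect_equal(classify_coloc(fake(c(0, 0, 0, 0.1, 0.9))), "H4")
  expect_equal(classify_coloc(fake(c(0, 0.05, 0.05, 0.75, 0.1))), "H3")
  expect_equal(classify_coloc(fake(c(0.3, 0.2, 0.2, 0.15, 0.15))), "none")
  expect_equal(classify_coloc(fake(c(0.9, 0.05, 0.02, 0.02, 0.01))), "H0")
  # H4 wins even when PP3 is larger, provided PP4 reaches the threshold
  expect_equal(classify_coloc(fake(c(0, 0, 0, 0.25, 0.75)), 0.7), "H4")
  expect_error(classify_coloc(fake(rep(0.2, 5)), threshold = 0), "threshold")
})

test_that("fine mapping assigns single-causal posteriors by Bayes factor", {
  s <- make_stats(10, beta = rep(0, 10), se = rep(1, 10))
  fm <- finemap_abf(s, quant_meta())
  expect_equal(fm$snp_pp, rep(0.1, 10))  # symmetry
  expect_equal(sum(fm$snp_pp), 1, tolerance = 1e-12)

  # craft one variant whose labf exceeds the others by exactly 10:
  # with common se the labf difference is r * (z1^2 - z0^2) / 2
  p <- coloc_priors()
  r <- p$w_sd_quant^2 / (1 + p$w_sd_quant^2)
  z1 <- sqrt(20 / r)
  s2 <- make_stats(10, beta = c(z1, rep(0, 9)), se = rep(1, 10))
  fm2 <- finemap_abf(s2, quant_meta(), p)
  expect_equal(fm2$labf[1] - fm2$labf[2], 10, tolerance = 1e-12)
  expect_equal(fm2$snp_pp[1], exp(10) / (exp(10) + 9), tolerance = 1e-10)
  expect_equal(exp(10) / (exp(10) + 9), 0.99959, tolerance = 1e-4)

  s1 <- make_stats(1)
  expect_equal(finemap_abf(s1, quant_meta())$snp_pp, 1)
})

test_that("the null posterior uses the residual prior mass", {
  s <- make_stats(5, beta = rep(0, 5), se = rep(1, 5))
  p <- coloc_priors()
  fm <- finemap_abf(s, quant_meta(), p)
  L <- exp(wakefield_labf(0, 1, p$w_sd_quant))
  expected <- (1 - 5 * p$p1) / ((1 - 5 * p$p1) + 5 * p$p1 * L)
  expect_equal(fm$pp_null, expected, tolerance = 1e-12)
  big <- make_stats(3)
  expect_error(finemap_abf(big, quant_meta(), coloc_priors(p1 = 0.4)),
               "prior mass")
})

test_that("prior validation enforces the configuration constraints", {
  expect_error(coloc_priors(p12 = 1e-3), "p12")
  expect_error(coloc_priors(w_sd_quant = 0), "w_sd")
  pair <- pair_from_z(rep(0, 5), rep(0, 5))
  expect_error(coloc_abf(pair, quant_meta(), quant_meta("CV"),
                         coloc_priors(p1 = 0.1, p2 = 0.1, p12 = 0.05)),
               "mass")
})

test_that("the enumeration oracle agrees with the log-space implementation", {
  # all-zero labf: posteriors proportional to configuration counts
  p <- coloc_priors()
  m <- 6
  pair <- pair_from_z(rep(0, m), rep(0, m))
  pair$se_1 <- pair$se_2 <- 1
  L <- exp(wakefield_labf(0, 1, p$w_sd_quant))
  s <- c(1, m * p$p1 * L, m * p$p2 * L, m * (m - 1) * p$p1 * p$p2 * L^2,
         m * p$p12 * L^2)
  bf <- brute_force_coloc(pair, quant_meta(), quant_meta("CV"), p)
  expect_equal(unname(bf$pp), s / sum(s), tolerance = 1e-12)

  set.seed(53)
  for (i in 1:25) {
    m <- sample(1:12, 1)
    pair <- pair_from_z(rnorm(m, 0, 3), rnorm(m, 0, 3))
    a <- coloc_abf(pair, quant_meta(), cc_meta())
    b <- brute_force_coloc(pair, quant_meta(), cc_meta())
    expect_equal(unname(a$pp), unname(b$pp), tolerance = 1e-10)
  }
  expect_error(brute_force_coloc(pair_from_z(rep(0, 13), rep(0, 13)),
                                 quant_meta(), quant_meta("CV")),
               "m <= 12")
})
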