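test_that("records re-orient to a target allele frame by swap or strand complement", {
  rec <- make_record(ea = "A", oa = "G", beta = 0.5, eaf = 0.3)
  expect_identical(orient_record(rec, "A", "G"), rec)

  swapped <- orient_record(make_record(ea = "G", oa = "A", beta = 0.5,
                                       eaf = 0.3), "A", "G")
  expect_equal(swapped$beta, -0.5)
  expect_equal(swapped$eaf, 0.7)
  expect_equal(swapped$ea, "A")

  # T/C is the opposite-strand reading of A/G
  comp <- orient_record(make_record(ea = "T", oa = "C", beta = 0.5,
                                    eaf = 0.3), "A", "G")
  expect_equal(comp$beta, 0.5)
  expect_equal(comp$ea, "A")
  # strand complement plus swap
  comp_swap <- orient_record(make_record(ea = "C", oa = "T", beta = 0.5,
                                         eaf = 0.3), "A", "G")
  expect_equal(comp_swap$beta, -0.5)
  expect_equal(comp_swap$eaf, 0.7)

  expect_error(orient_record(make_record(ea = "A", oa = "C"), "A", "G"),
               "harmonisation")
})

test_that("orientation is an involution: flipping twice restores the record", {
  rec <- make_record(ea = "A", oa = "G", beta = -0.25, eaf = 0.81)
  there <- orient_record(rec, "G", "A")
  back <- orient_record(there, "A", "G")
  expect_equal(back$beta, rec$beta)
  expect_equal(back$eaf, rec$eaf)
})

test_that("the top fine-mapped variant breaks ties by position then id", {
  fm <- structure(list(variant_ids = c("b", "a", "c"),
                       pos = c(100L, 200L, 300L),
                       snp_pp = c(0.1, 0.8, 0.1)),
                  class = "finemap_abf")
  expect_equal(top_variant(fm), "a")
  fm_tie <- structure(list(variant_ids = c("zz", "aa"),
                           pos = c(100L, 200L),
                           snp_pp = c(0.5, 0.5)),
                      class = "finemap_abf")
  expect_equal(top_variant(fm_tie), "zz")  # position 100 wins over id order
  fm_one <- structure(list(variant_ids = "only", pos = 1L, snp_pp = 1),
                      class = "finemap_abf")
  expect_equal(top_variant(fm_one), "only")
})

test_that("ld_r2 returns the squared correlation entry", {
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- -0.9
  ld <- ld_matrix(r, c("a", "b", "c"))
  expect_equal(ld_r2(ld, "a", "a"), 1)
  expect_equal(ld_r2(ld, "a", "b"), 0.81)
  expect_equal(ld_r2(ld, "a", "c"), 0)
  expect_error(ld_r2(ld, "a", "nope"), "not present")
})

# Build a region where each trait peaks decisively on its own variant
# (z-profiles too discordant for a single shared causal variant, so the
# posterior favours H3) while the two peaks are tightly linked — the
# configuration the H4-equivalence rule exists for.
linked_h3_fixture <- function(r12 = 0.95) {
  m <- 10
  r <- diag(m)
  r[1, 2] <- r[2, 1] <- r12
  ld <- ld_matrix(r, sprintf("rs%d", 1:m), pos = 100L * (1:m))
  z1 <- c(9, 5, rep(0.1, m - 2))
  z2 <- c(5, 9, rep(-0.1, m - 2))
  pair <- pair_from_z(z1, z2)
  cl <- coloc_abf(pair, quant_meta(), quant_meta("CV"))
  s1 <- make_stats(m, beta = z1 * 0.02, se = rep(0.02, m))
  s2 <- make_stats(m, beta = z2 * 0.02, se = rep(0.02, m))
  list(cl = cl, fm1 = finemap_abf(s1, quant_meta()),
       fm2 = finemap_abf(s2, quant_meta("CV")), ld = ld)
}

test_that("H3 pairs with tightly linked top variants are promoted to H4-equivalent", {
  fx <- linked_h3_fixture(0.95)
  expect_equal(classify_coloc(fx$cl), "H3")
  sig <- classify_signal(fx$cl, fx$fm1, fx$fm2, fx$ld, gene = "G1")
  expect_equal(sig$label, "H4_EQUIVALENT")
  expect_equal(sort(c(sig$top_variant_1, sig$top_variant_2)),
               c("rs1", "rs2"))
  expect_equal(sig$r2_top, 0.95^2)
  expect_equal(sig$gene, "G1")
})

test_that("H3 pairs below the LD floor stay H3; H4 passes through", {
  fx <- linked_h3_fixture(0.5)  # r2 = 0.25 < 0.8
  sig <- classify_signal(fx$cl, fx$fm1, fx$fm2, fx$ld)
  expect_equal(sig$label, "H3")

  m <- 10
  ld <- make_ld_ar1(m, 0.3, variant_ids = sprintf("rs%d", 1:m))
  z <- c(10, rep(0.1, m - 1))
  pair <- pair_from_z(z, z)
  cl <- coloc_abf(pair, quant_meta(), quant_meta("CV"))
  s <- make_stats(m, beta = z * 0.02, se = rep(0.02, m))
  fm <- finemap_abf(s, quant_meta())
  sig4 <- classify_signal(cl, fm, fm, ld)
  expect_equal(sig4$label, "H4")
  expect_equal(sig4$top_variant_1, sig4$top_variant_2)
  expect_false(sig4$label == "H4_EQUIVALENT")
})

test_that("direction assessment canonicalises to the lung-detrimental allele", {
  fvc <- ukb_fvc_h4_effects()
  tns1 <- fvc[fvc$gene == "TNS1", ]
  lung <- make_record(tns1$variant_id[1], ea = tns1$ea[1], oa = tns1$oa[1],
                      beta = tns1$lung_beta[1], eaf = 0.39)
  cv <- do.call(rbind, lapply(seq_len(nrow(tns1)), function(i) {
    b <- if (tns1$cv_type[i] == "case_control") log(tns1$cv_effect[i]) else
      tns1$cv_effect[i]
    make_record(tns1$variant_id[i], ea = tns1$ea[i], oa = tns1$oa[i],
                beta = b, eaf = 0.39)
  }))
  cv$trait <- tns1$cv_trait
  cv$trait_type <- tns1$cv_type
  da <- assess_direction(lung, cv)
  expect_equal(da$oriented_ea, "A")
  expect_lt(da$lung_beta, 0)
  expect_true(all(da$effects$consistent))
  expect_true(da$overall_consistent)
  # odds ratios only reported for the binary traits
  expect_equal(is.na(da$effects$oriented_or),
               tns1$cv_type == "quantitative")
})

test_that("direction assessment is invariant to the arriving allele frame", {
  lung <- make_record(ea = "A", oa = "G", beta = 5, eaf = 0.3)
  cv <- make_record(ea = "A", oa = "G", beta = 0.1, eaf = 0.3)
  cv$trait <- "SBP"; cv$trait_type <- "quantitative"
  da <- assess_direction(lung, cv)
  # lung beta +5 on A means G is detrimental; the co-oriented CV effect
  # flips sign and becomes inconsistent
  expect_equal(da$oriented_ea, "G")
  expect_equal(da$effects$oriented_beta, -0.1)
  expect_false(da$overall_consistent)

  # deliver the same records pre-flipped: identical conclusion
  lung_f <- orient_record(lung, "G", "A")
  cv_f <- orient_record(cv, "G", "A")
  cv_f$trait <- "SBP"; cv_f$trait_type <- "quantitative"
  da2 <- assess_direction(lung_f, cv_f)
  expect_equal(da2$effects$oriented_beta, da$effects$oriented_beta)
  expect_equal(da2$oriented_ea, da$oriented_ea)

  lung0 <- make_record(beta = 0)
  expect_error(assess_direction(lung0, cv), "exactly 0")
})

test_that("published FVC shared signals are all direction-consistent", {
  fvc <- ukb_fvc_h4_effects()
  genes <- unique(fvc$gene)
  consistent <- vapply(genes, function(g) {
    rows <- fvc[fvc$gene == g, ]
    lung <- make_record(rows$variant_id[1], ea = rows$ea[1], oa = rows$oa[1],
                        beta = rows$lung_beta[1], eaf = 0.5)
    cv <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
      b <- if (rows$cv_type[i] == "case_control") log(rows$cv_effect[i]) else
        rows$cv_effect[i]
      make_record(rows$variant_id[i], ea = rows$ea[i], oa = rows$oa[i],
                  beta = b, eaf = 0.5)
    }))
    cv$trait <- rows$cv_trait
    cv$trait_type <- rows$cv_type
    assess_direction(lung, cv)$overall_consistent
  }, TRUE)
  expect_length(genes, 7)
  expect_true(all(consistent))
})
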