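#' Re-express a summary-statistic record in a target allele frame
#'
#' If the record's alleles already equal the target pair, it is returned
#' unchanged. If they are the same pair with effect and other allele
#' swapped, the beta is negated and the frequency reflected
#' (`eaf -> 1 - eaf`). If the record is on the opposite strand, its
#' alleles are complemented first and the same rule applied. Any other
#' allele pair is a harmonisation error.
#'
#' @param record One-row summary-statistic `data.frame`.
#' @param target_ea,target_oa Target effect and other allele.
#' @param .error If `FALSE`, return `NULL` instead of erroring on an
#'   incompatible pair (used internally by [align_traits()]).
#' @return The re-oriented one-row `data.frame` (or `NULL`).
#' @export
orient_record <- function(record, target_ea, target_oa, .error = TRUE) {
  ea <- record$ea
  oa <- record$oa
  flip <- function(r) {
    tmp <- r$ea; r$ea <- r$oa; r$oa <- tmp
    r$beta <- -r$beta
    r$eaf <- 1 - r$eaf
    r
  }
  if (ea == target_ea && oa == target_oa) return(record)
  if (ea == target_oa && oa == target_ea) {
    out <- flip(record)
    out$ea <- target_ea; out$oa <- target_oa
    return(out)
  }
  cea <- unname(complement_allele(ea))
  coa <- unname(complement_allele(oa))
  if (cea == target_ea && coa == target_oa) {
    record$ea <- cea; record$oa <- coa
    return(record)
  }
  if (cea == target_oa && coa == target_ea) {
    record$ea <- cea; record$oa <- coa
    return(flip(record))
  }
  if (.error)
    stopf("harmonisation error: alleles %s/%s incompatible with target %s/%s",
          ea, oa, target_ea, target_oa)
  NULL
}

#' Top fine-mapped variant
#'
#' The variant with maximal single-causal posterior; exact ties are
#' broken by smallest genomic position, then lexicographically by id.
#'
#' @param fm A [finemap_abf()] result.
#' @return A `variant_id`.
#' @export
top_variant <- function(fm) {
  stopifnot(inherits(fm, "finemap_abf"))
  best <- which(fm$snp_pp == max(fm$snp_pp))
  if (length(best) > 1) {
    pos <- fm$pos %||% seq_along(fm$snp_pp)
    best <- best[order(pos[best], fm$variant_ids[best])]
  }
  fm$variant_ids[best[1]]
}

#' Squared allelic correlation between two variants
#'
#' @param ld An [ld_matrix()].
#' @param v1,v2 Variant ids present in the matrix.
#' @return `r^2` in \[0, 1\].
#' @export
ld_r2 <- function(ld, v1, v2) {
  for (v in c(v1, v2))
    if (!v %in% rownames(ld))
      stopf("variant %s not present in LD matrix", v)
  unname(ld[v1, v2]^2)
}

#' Classify a trait pair, promoting tightly linked H3 signals
#'
#' Applies [classify_coloc()] and then the H4-equivalence rule: an H3
#' pair whose two traits' top fine-mapped variants are in high LD
#' (`r^2 > r2_threshold`) is effectively a shared signal and is labelled
#' `H4_EQUIVALENT`; the labels `H4`, `H1`, `H2`, `H0` and `NONE` pass
#' through unchanged.
#'
#' @param coloc A [coloc_abf()] result.
#' @param fm1,fm2 [finemap_abf()] results for the two traits.
#' @param ld [ld_matrix()] covering the top variants.
#' @param pp_threshold Posterior threshold for colocalisation
#'   (default 0.70).
#' @param r2_threshold LD floor for H4-equivalence; promotion requires
#'   `r^2` strictly greater than this (default 0.8).
#' @param gene Optional gene label carried into the output.
#' @return A one-row `data.frame` of class `pair_classification` with
#'   `gene`, `trait_1`, `trait_2`, `label`, `top_variant_1`,
#'   `top_variant_2`, `r2_top` and `pp_used`.
#' @export
classify_signal <- function(coloc, fm1, fm2, ld, pp_threshold = 0.70,
                            r2_threshold = 0.8, gene = NA_character_) {
  stopifnot(inherits(coloc, "coloc_abf"))
  base <- toupper(classify_coloc(coloc, pp_threshold))
  t1 <- top_variant(fm1)
  t2 <- top_variant(fm2)
  r2 <- ld_r2(ld, t1, t2)
  label <- base
  pp_used <- max(coloc$pp)
  if (base == "H4") {
    shared <- coloc$variant_ids[which.max(coloc$snp_pp_h4)]
    t1 <- t2 <- shared
    r2 <- 1
    pp_used <- coloc$pp[["PP4"]]
  } else if (base == "H3") {
    pp_used <- coloc$pp[["PP3"]]
    if (r2 > r2_threshold && t1 != t2) label <- "H4_EQUIVALENT"
  }
  structure(data.frame(gene = gene, trait_1 = coloc$traits[1],
                       trait_2 = coloc$traits[2], label = label,
                       top_variant_1 = t1, top_variant_2 = t2,
                       r2_top = r2, pp_used = unname(pp_used),
                       stringsAsFactors = FALSE),
            class = c("pair_classification", "data.frame"))
}

#' Direction-of-effect assessment in the lung-detrimental allele frame
#'
#' Re-orients every record so that the effect allele is the allele
#' detrimental to lung function (oriented lung beta < 0), then checks,
#' per cardiovascular trait, whether the oriented effect supports the
#' hypothesis that lower lung function accompanies higher cardiovascular
#' risk: odds ratio > 1 (oriented log-odds > 0) for binary traits, or
#' beta > 0 for continuous traits.
#'
#' @param lung_record One-row summary-statistic `data.frame` for the
#'   lung function trait at the anchor variant (beta must be non-zero).
#' @param cv_records Summary-statistic `data.frame` (one row per
#'   cardiovascular trait at the same variant) with extra columns
#'   `trait` and `trait_type`.
#' @return An object of class `direction_assessment`: list with
#'   `oriented_ea`, `lung_beta` (oriented, < 0), a per-trait `effects`
#'   data.frame (`trait`, `trait_type`, `oriented_beta`, `oriented_or`,
#'   `consistent`) and `overall_consistent`.
#' @export
assess_direction <- function(lung_record, cv_records) {
  assert_that(nrow(lung_record) == 1, "lung_record must be a single row")
  if (lung_record$beta == 0)
    stopf("lung beta is exactly 0: detrimental-allele frame undefined")
  # canonical frame: the allele that lowers lung function is the EA
  if (lung_record$beta > 0)
    lung_record <- orient_record(lung_record, lung_record$oa, lung_record$ea)
  effects <- do.call(rbind, lapply(seq_len(nrow(cv_records)), function(i) {
    rec <- orient_record(cv_records[i, , drop = FALSE],
                         lung_record$ea, lung_record$oa)
    binary <- cv_records$trait_type[i] == "case_control"
    data.frame(trait = cv_records$trait[i],
               trait_type = cv_records$trait_type[i],
               oriented_beta = rec$beta,
               oriented_or = if (binary) exp(rec$beta) else NA_real_,
               consistent = rec$beta > 0,
               stringsAsFactors = FALSE)
  }))
  rownames(effects) <- NULL
  structure(list(variant_id = lung_record$variant_id,
                 oriented_ea = lung_record$ea,
                 lung_beta = lung_record$beta,
                 effects = effects,
                 overall_consistent = all(effects$consistent)),
            class = "direction_assessment")
}

#' @export
print.direction_assessment <- function(x, ...) {
  cat(sprintf("%s: lung-detrimental allele %s (oriented lung beta %.3f)\n",
              x$variant_id, x$oriented_ea, x$lung_beta))
  print(x$effects)
  cat(sprintf("overall consistent: %s\n", x$overall_consistent))
  invisible(x)
}
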