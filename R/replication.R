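#' One-sided replication p-value
#'
#' Replication is defined as an effect in the same direction as the
#' discovery cohort, so the replication cohort's two-sided p-value is
#' converted to a one-sided p: `p/2` when the replication effect has the
#' discovery sign, `1 - p/2` otherwise. Both betas must be expressed in
#' the same allele frame.
#'
#' @param beta_discovery Discovery effect (non-zero).
#' @param beta_replication Replication effect; exactly 0 means the
#'   direction is undefined and `p_one`/`direction_same` are `NA`
#'   (classified `UNTESTABLE` downstream).
#' @param p_two_sided Replication two-sided p-value in (0, 1].
#' @return List with `p_one` and `direction_same`.
#' @export
one_sided_p <- function(beta_discovery, beta_replication, p_two_sided) {
  assert_that(p_two_sided > 0 && p_two_sided <= 1,
              "p_two_sided must be in (0,1]")
  assert_that(beta_discovery != 0, "discovery beta must be non-zero")
  if (beta_replication == 0)
    return(list(p_one = NA_real_, direction_same = NA))
  same <- sign(beta_discovery) == sign(beta_replication)
  list(p_one = if (same) p_two_sided / 2 else 1 - p_two_sided / 2,
       direction_same = same)
}

#' Multiplicity plan for replication
#'
#' @param m_tests Number of replication tests carried to the cohort
#'   (explicit input, never inferred).
#' @param alpha Family-wise alpha (default 0.05).
#' @return Object of class `multiplicity_plan` with the Bonferroni
#'   `threshold = alpha / m_tests`.
#' @export
multiplicity_plan <- function(m_tests, alpha = 0.05) {
  assert_that(m_tests >= 1, "m_tests must be >= 1")
  assert_that(alpha > 0 && alpha < 1, "alpha must be in (0,1)")
  structure(list(alpha = alpha, m_tests = as.integer(m_tests),
                 threshold = alpha / m_tests),
            class = "multiplicity_plan")
}

#' Bonferroni-corrected significance threshold
#'
#' @param plan A [multiplicity_plan()].
#' @return `alpha / m_tests`.
#' @export
bonferroni_threshold <- function(plan) {
  stopifnot(inherits(plan, "multiplicity_plan"))
  plan$alpha / plan$m_tests
}

#' Classify a replication outcome
#'
#' `BONFERRONI` when the one-sided p beats `alpha / m_tests`; `NOMINAL`
#' when it beats `alpha` only; `NOT_REPLICATED` otherwise or when the
#' direction differs; `UNTESTABLE` when the direction is undefined
#' (`NA` inputs, e.g. a zero replication effect or no usable proxy).
#'
#' @param p_one One-sided p-value.
#' @param direction_same Logical from [one_sided_p()].
#' @param plan A [multiplicity_plan()].
#' @return One of `"BONFERRONI" "NOMINAL" "NOT_REPLICATED" "UNTESTABLE"`.
#' @export
classify_replication <- function(p_one, direction_same, plan) {
  stopifnot(inherits(plan, "multiplicity_plan"))
  if (is.na(p_one) || is.na(direction_same)) return("UNTESTABLE")
  if (!direction_same) return("NOT_REPLICATED")
  if (p_one < bonferroni_threshold(plan)) return("BONFERRONI")
  if (p_one < plan$alpha) return("NOMINAL")
  "NOT_REPLICATED"
}

#' Find an LD proxy for a variant missing from a replication cohort
#'
#' Among the cohort's available variants, returns the one with maximal
#' `r^2` to the target provided it reaches `r2_min`; exact ties are
#' broken by genomic position then id. The target itself, when
#' available, is its own proxy with `r^2 = 1`.
#'
#' @param target Target `variant_id` (must be in the LD matrix).
#' @param available Character vector of variant ids present in the
#'   replication cohort.
#' @param ld An [ld_matrix()].
#' @param r2_min Minimum acceptable `r^2` (default 0.8).
#' @return List with `variant_id` and `r2`, or `NULL` when no variant
#'   reaches `r2_min` (the signal is then untestable in that cohort).
#' @export
find_proxy <- function(target, available, ld, r2_min = 0.8) {
  if (!target %in% rownames(ld))
    stopf("variant %s not present in LD matrix", target)
  available <- intersect(available, rownames(ld))
  if (length(available) == 0) return(NULL)
  r2 <- stats::setNames(as.numeric(ld[target, available])^2, available)
  best <- which(r2 == max(r2))
  if (length(best) > 1) {
    pos <- (attr(ld, "pos") %||% seq_len(nrow(ld)))[match(names(r2)[best],
                                                          rownames(ld))]
    best <- best[order(pos, names(r2)[best])]
  }
  if (r2[best[1]] < r2_min) return(NULL)
  list(variant_id = names(r2)[best[1]], r2 = unname(r2[best[1]]))
}

#' Replicate discovery signals in an external cohort
#'
#' For each discovery signal (row: `gene`, `variant_id`, discovery
#' `beta` in the discovery allele frame, `ea`, `oa`), looks the variant
#' up in the replication summary statistics — substituting the best LD
#' proxy at `r^2 >= r2_min` when absent — orients the replication record
#' to the discovery frame, computes the one-sided p and classifies it
#' under the cohort's multiplicity plan.
#'
#' @param signals `data.frame` with columns `gene`, `variant_id`, `ea`,
#'   `oa`, `beta` (discovery effect) and optionally `trait`.
#' @param repl_stats Replication-cohort summary-statistic `data.frame`.
#' @param plan A [multiplicity_plan()].
#' @param ld Optional [ld_matrix()] enabling proxy search.
#' @param r2_min Proxy LD floor (default 0.8).
#' @return `data.frame` with one row per signal: `gene`, `trait`,
#'   `variant_used`, `is_proxy`, `proxy_r2`, `direction_same`, `p_one`,
#'   `status`.
#' @export
replicate_signals <- function(signals, repl_stats, plan, ld = NULL,
                              r2_min = 0.8) {
  out <- lapply(seq_len(nrow(signals)), function(i) {
    sig <- signals[i, , drop = FALSE]
    row <- data.frame(gene = sig$gene,
                      trait = sig$trait %||% NA_character_,
                      variant_used = NA_character_, is_proxy = FALSE,
                      proxy_r2 = NA_real_, direction_same = NA,
                      p_one = NA_real_, status = "UNTESTABLE",
                      stringsAsFactors = FALSE)
    use <- sig$variant_id
    if (!use %in% repl_stats$variant_id) {
      if (is.null(ld)) return(row)
      proxy <- find_proxy(use, repl_stats$variant_id, ld, r2_min)
      if (is.null(proxy)) return(row)
      row$is_proxy <- TRUE
      row$proxy_r2 <- proxy$r2
      use <- proxy$variant_id
    }
    rec <- repl_stats[repl_stats$variant_id == use, , drop = FALSE]
    if (row$is_proxy) {
      # proxy alleles differ from the target's; the direction is carried
      # through the sign of the allelic correlation in the LD matrix
      rec$beta <- rec$beta * sign(ld[sig$variant_id, use])
    } else {
      rec <- orient_record(rec, sig$ea, sig$oa)
    }
    row$variant_used <- use
    os <- one_sided_p(sig$beta, rec$beta, rec$pval)
    row$direction_same <- os$direction_same
    row$p_one <- os$p_one
    row$status <- classify_replication(os$p_one, os$direction_same, plan)
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
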