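#' Pipeline configuration
#'
#' Collects every threshold the analysis uses so nothing is hard-coded
#' downstream: QC floors (MAF, INFO), the colocalisation posterior
#' threshold, the LD floor for H4-equivalence, priors, replication
#' multiplicity plans and the master seed. No multiplicity correction is
#' applied across colocalisation pairs themselves — the Bayesian
#' posteriors already carry the prior odds — only the replication stage
#' corrects for its test count.
#'
#' @param regions List of [region()] objects.
#' @param lung_traits,cv_traits Named lists of [trait_meta()].
#' @param priors A [coloc_priors()].
#' @param pp_threshold Colocalisation posterior threshold (default 0.70).
#' @param r2_equivalence LD floor for promoting H3 to H4-equivalent
#'   (default 0.8).
#' @param maf_min,info_min QC floors (defaults 0.01 and 0.5).
#' @param replication_plans Named list (cohort -> [multiplicity_plan()]).
#' @param proxy_r2_min LD floor for replication proxies (default 0.8).
#' @param exclusion_flag Name of the sample flag used by
#'   [run_sensitivity()].
#' @param seed Integer master seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(regions, lung_traits, cv_traits,
                            priors = coloc_priors(), pp_threshold = 0.70,
                            r2_equivalence = 0.8, maf_min = 0.01,
                            info_min = 0.5, replication_plans = list(),
                            proxy_r2_min = 0.8, exclusion_flag = NULL,
                            seed = 1L) {
  assert_that(length(regions) >= 1, "at least one region is required")
  assert_that(length(lung_traits) >= 1 && length(cv_traits) >= 1,
              "at least one trait per side is required")
  assert_that(pp_threshold > 0 && pp_threshold <= 1,
              "pp_threshold must be in (0,1]")
  assert_that(r2_equivalence > 0 && r2_equivalence <= 1,
              "r2_equivalence must be in (0,1]")
  structure(list(regions = regions, lung_traits = lung_traits,
                 cv_traits = cv_traits, priors = priors,
                 pp_threshold = pp_threshold,
                 r2_equivalence = r2_equivalence, maf_min = maf_min,
                 info_min = info_min, replication_plans = replication_plans,
                 proxy_r2_min = proxy_r2_min,
                 exclusion_flag = exclusion_flag, seed = as.integer(seed)),
            class = "pipeline_config")
}

# One trait's input: either a summary-statistic data.frame or
# individual-level data (run through the association stage first).
resolve_trait_stats <- function(input, exclude_flagged = FALSE) {
  if (inherits(input, "individual_data")) {
    if (exclude_flagged) {
      keep <- !input$sample_flags
      assert_that(any(keep), "all samples excluded by the sensitivity flag")
      input$genotypes <- input$genotypes[keep, , drop = FALSE]
      if (!is.null(input$covariates))
        input$covariates <- input$covariates[keep, , drop = FALSE]
      input$phenotype <- input$phenotype[keep]
      input$sample_flags <- input$sample_flags[keep]
    }
    assoc_scan(input)
  } else {
    validate_sumstats(input)
  }
}

#' Run the colocalisation pipeline end-to-end
#'
#' For every region and every lung-function x cardiovascular trait pair:
#' QC filtering (MAF/INFO floors), region extraction, the association
#' stage when individual-level data are supplied, alignment onto a
#' shared allele frame, Bayesian colocalisation, fine mapping of both
#' traits, classification with H4-equivalence promotion, direction of
#' effect for shared signals, and replication in any supplied cohorts.
#' Deterministic given the config seed.
#'
#' @param config A [pipeline_config()].
#' @param inputs List with `traits` (named list: trait name -> summary
#'   stats or `individual_data`; names must cover all configured traits),
#'   `ld` (an [ld_matrix()] covering the analysed variants), and
#'   optionally `replication` (named list: cohort -> summary stats).
#' @param sensitivity Internal; set by [run_sensitivity()].
#' @return Object of class `coloc_report`: list with `coloc_table`,
#'   `direction_table`, `replication_table` and `run_log`.
#' @export
run_pipeline <- function(config, inputs, sensitivity = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  assert_that(!is.null(inputs$traits), "inputs$traits is required")
  assert_that(!is.null(inputs$ld), "inputs$ld is required")
  set.seed(config$seed)
  all_traits <- c(config$lung_traits, config$cv_traits)
  missing_tr <- setdiff(names(all_traits), names(inputs$traits))
  assert_that(length(missing_tr) == 0, "no input for trait(s): %s",
              paste(missing_tr, collapse = ", "))

  run_log <- list(seed = config$seed, sensitivity = sensitivity,
                  counts = list())
  stats <- list()
  for (tr in names(all_traits)) {
    raw <- resolve_trait_stats(inputs$traits[[tr]],
                               exclude_flagged = sensitivity)
    filt <- qc_filter(raw, config$maf_min, config$info_min)
    run_log$counts[[tr]] <- c(read = nrow(raw),
                              qc_removed = attr(filt, "n_removed"),
                              retained = nrow(filt))
    stats[[tr]] <- filt
  }

  coloc_rows <- list()
  direction_rows <- list()
  replication_rows <- list()
  for (reg in config$regions) {
    for (lt in names(config$lung_traits)) {
      for (ct in names(config$cv_traits)) {
        s1 <- extract_region(stats[[lt]], reg)
        s2 <- extract_region(stats[[ct]], reg)
        pair <- align_traits(s1, s2)
        if (nrow(pair) == 0)
          stopf("stage coloc, region %s, pair %s vs %s: no shared variants",
                reg$gene, lt, ct)
        m1 <- config$lung_traits[[lt]]
        m2 <- config$cv_traits[[ct]]
        cl <- coloc_abf(pair, m1, m2, config$priors)
        fm1 <- finemap_abf(stats_from_pair(pair, 1), m1, config$priors)
        fm2 <- finemap_abf(stats_from_pair(pair, 2), m2, config$priors)
        sig <- classify_signal(cl, fm1, fm2, inputs$ld,
                               config$pp_threshold, config$r2_equivalence,
                               gene = reg$gene)
        coloc_rows[[length(coloc_rows) + 1L]] <-
          cbind(sig, as.data.frame(as.list(round(cl$pp, 6))),
                n_variants = cl$n_variants)

        if (sig$label %in% c("H4", "H4_EQUIVALENT")) {
          # H4-equivalent pairs are anchored at the CV trait's top
          # variant; H4 pairs at the shared top variant.
          anchor <- if (sig$label == "H4") sig$top_variant_1 else
            sig$top_variant_2
          lung_rec <- pair_record(pair, anchor, 1)
          cv_rec <- pair_record(pair, anchor, 2)
          cv_rec$trait <- ct
          cv_rec$trait_type <- m2$trait_type
          da <- assess_direction(lung_rec, cv_rec)
          direction_rows[[length(direction_rows) + 1L]] <-
            data.frame(gene = reg$gene, lung_trait = lt, cv_trait = ct,
                       variant_id = anchor, oriented_ea = da$oriented_ea,
                       lung_beta = da$lung_beta,
                       cv_effect = da$effects$oriented_beta[1],
                       consistent = da$effects$consistent[1],
                       stringsAsFactors = FALSE)
          for (cohort in names(inputs$replication %||% list())) {
            plan <- config$replication_plans[[cohort]]
            if (is.null(plan)) next
            sig_df <- data.frame(gene = reg$gene, trait = ct,
                                 variant_id = anchor,
                                 ea = lung_rec$ea, oa = lung_rec$oa,
                                 beta = cv_rec$beta,
                                 stringsAsFactors = FALSE)
            rr <- replicate_signals(sig_df, inputs$replication[[cohort]],
                                    plan, ld = inputs$ld,
                                    r2_min = config$proxy_r2_min)
            rr$cohort <- cohort
            rr$lung_trait <- lt
            replication_rows[[length(replication_rows) + 1L]] <- rr
          }
        }
      }
    }
  }
  bind <- function(rows) if (length(rows)) {
    out <- do.call(rbind, rows); rownames(out) <- NULL; out
  } else NULL
  structure(list(coloc_table = bind(coloc_rows),
                 direction_table = bind(direction_rows),
                 replication_table = bind(replication_rows),
                 run_log = run_log, config = config),
            class = "coloc_report")
}

stats_from_pair <- function(pair, trait) {
  sfx <- if (trait == 1) "_1" else "_2"
  data.frame(variant_id = pair$variant_id, chrom = pair$chrom,
             pos = pair$pos, ea = pair$ea, oa = pair$oa,
             eaf = pair[[paste0("eaf", sfx)]],
             beta = pair[[paste0("beta", sfx)]],
             se = pair[[paste0("se", sfx)]],
             pval = pair[[paste0("pval", sfx)]],
             n = pair[[paste0("n", sfx)]],
             info = pair[[paste0("info", sfx)]],
             stringsAsFactors = FALSE)
}

pair_record <- function(pair, variant, trait) {
  stats <- stats_from_pair(pair, trait)
  rec <- stats[stats$variant_id == variant, , drop = FALSE]
  assert_that(nrow(rec) == 1, "variant %s not in aligned pair", variant)
  rec
}

#' @export
print.coloc_report <- function(x, ...) {
  n_pairs <- if (is.null(x$coloc_table)) 0L else nrow(x$coloc_table)
  cat(sprintf("Colocalisation report: %d trait pair(s)%s\n", n_pairs,
              if (x$run_log$sensitivity) " [sensitivity run]" else ""))
  if (n_pairs) {
    cat("\nLabels:\n")
    print(table(x$coloc_table$label))
    shown <- x$coloc_table[c("gene", "trait_1", "trait_2", "label",
                             "PP3", "PP4")]
    print(utils::head(shown, 10))
  }
  if (!is.null(x$replication_table)) {
    cat("\nReplication:\n")
    print(table(x$replication_table$cohort, x$replication_table$status))
  }
  invisible(x)
}

#' Sample-exclusion sensitivity run
#'
#' Re-runs the full pipeline after excluding flagged samples (e.g. an
#' asthma analogue) from every individual-level input, re-doing the
#' association stage and all downstream stages. Requires at least one
#' individual-level input carrying sample flags.
#'
#' @param config A [pipeline_config()]; its `exclusion_flag` (or the
#'   `flag` argument) names the exclusion.
#' @param inputs As in [run_pipeline()].
#' @param flag Label recorded in the run log.
#' @return A `coloc_report` marked as a sensitivity run.
#' @export
run_sensitivity <- function(config, inputs, flag = NULL) {
  flag <- flag %||% config$exclusion_flag
  assert_that(!is.null(flag), "no exclusion flag configured")
  has_flags <- any(vapply(inputs$traits, inherits, TRUE, "individual_data"))
  assert_that(has_flags,
              "sensitivity run needs individual-level inputs with sample flags")
  out <- run_pipeline(config, inputs, sensitivity = TRUE)
  out$run_log$exclusion_flag <- flag
  out
}

#' Write packaged synthetic fixture regions
#'
#' Writes one simulated region per hypothesis H0-H4 as the package's
#' standard file set: a summary-statistic TSV per trait, the LD matrix
#' with its id sidecar, and a JSON truth sidecar recording the
#' generating scenario.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; file contents are stable given the seed.
#' @param m_variants,ld_rho,lambda Region size, LD decay and causal
#'   non-centrality shared by the five fixtures.
#' @return Invisibly, the named list of per-hypothesis file sets.
#' @export
generate_fixtures <- function(out_dir, seed = 1L, m_variants = 50,
                              ld_rho = 0.5, lambda = 8) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n <- 10000L
  f <- 0.3
  beta <- lambda * sumstat_se(n, f, "quantitative")
  c_lo <- max(1L, round(m_variants * 0.1))
  c_hi <- max(c_lo + 1L, round(m_variants * 0.9))
  c_mid <- max(1L, round(m_variants / 2))
  specs <- list(
    H0 = scenario_spec("H0", m_variants, ld_rho, freqs = f, seed = seed),
    H1 = scenario_spec("H1", m_variants, ld_rho, freqs = f,
                       causal_1 = c_mid, beta_1 = beta, seed = seed + 1L),
    H2 = scenario_spec("H2", m_variants, ld_rho, freqs = f,
                       causal_2 = c_mid, beta_2 = beta, seed = seed + 2L),
    H3 = scenario_spec("H3", m_variants, ld_rho, freqs = f,
                       causal_1 = c_lo, causal_2 = c_hi,
                       beta_1 = beta, beta_2 = beta, seed = seed + 3L),
    H4 = scenario_spec("H4", m_variants, ld_rho, freqs = f,
                       causal_1 = c_mid, causal_2 = c_mid,
                       beta_1 = beta, beta_2 = beta, seed = seed + 4L))
  out <- lapply(names(specs), function(h) {
    spec <- specs[[h]]
    sim <- simulate_sumstats_direct(spec)
    base <- file.path(out_dir, tolower(h))
    files <- c(stats_1 = paste0(base, "_trait1.tsv"),
               stats_2 = paste0(base, "_trait2.tsv"),
               ld = paste0(base, "_ld.txt"),
               ids = paste0(base, "_ld_ids.txt"),
               truth = paste0(base, "_truth.json"))
    write_sumstats(sim$stats_1, files[["stats_1"]])
    write_sumstats(sim$stats_2, files[["stats_2"]])
    write_ld(sim$ld, files[["ld"]], files[["ids"]])
    truth <- spec[c("hypothesis", "m_variants", "ld_rho", "causal_1",
                    "causal_2", "beta_1", "beta_2", "n_1", "n_2",
                    "trait_types", "seed")]
    jsonlite::write_json(truth, files[["truth"]], auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    files
  })
  names(out) <- names(specs)
  invisible(out)
}
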