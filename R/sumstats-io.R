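#' Canonical summary-statistic columns
#'
#' A summary-statistic set is a plain `data.frame` with one row per variant
#' and the canonical columns `variant_id`, `chrom`, `pos`, `ea`, `oa`,
#' `eaf`, `beta`, `se`, `pval`, `n`, `info`. Effects (`beta`) are on the
#' trait scale for quantitative traits and on the log-odds scale for
#' case-control traits; `ea` is the effect allele in whose dosage frame
#' `beta` and `eaf` are expressed.
#'
#' @name sumstats
NULL

SUMSTATS_COLS <- c("variant_id", "chrom", "pos", "ea", "oa",
                   "eaf", "beta", "se", "pval", "n", "info")

#' Trait metadata
#'
#' @param trait_name Trait label, e.g. `"FVC"` or `"HTN"`.
#' @param trait_type `"quantitative"` or `"case_control"`.
#' @param n_total Total sample size.
#' @param case_fraction Fraction of cases; required iff `trait_type`
#'   is `"case_control"`.
#' @return An object of class `trait_meta`.
#' @export
trait_meta <- function(trait_name, trait_type = c("quantitative", "case_control"),
                       n_total, case_fraction = NULL) {
  trait_type <- match.arg(trait_type)
  assert_that(is_scalar_number(n_total) && n_total >= 1,
              "n_total must be a positive integer")
  if (trait_type == "case_control") {
    assert_that(is_scalar_number(case_fraction) && case_fraction > 0 &&
                  case_fraction < 1,
                "case_fraction in (0,1) is required for case-control traits")
  } else {
    assert_that(is.null(case_fraction),
                "case_fraction must be absent for quantitative traits")
  }
  structure(list(trait_name = trait_name, trait_type = trait_type,
                 n_total = as.integer(n_total), case_fraction = case_fraction),
            class = "trait_meta")
}

#' Gene region
#'
#' Coordinates are 1-based and inclusive on both ends; `flank` bases are
#' added on each side when extracting variants.
#'
#' @param gene Gene label.
#' @param chrom Chromosome.
#' @param start,end Region boundaries (1-based inclusive), `start <= end`.
#' @param flank Non-negative flank in bases (default 0: variants strictly
#'   within the gene boundaries).
#' @return An object of class `region`.
#' @export
region <- function(gene, chrom, start, end, flank = 0) {
  assert_that(start <= end, "region start must be <= end")
  assert_that(flank >= 0, "flank must be non-negative")
  structure(list(gene = gene, chrom = as.character(chrom),
                 start = as.integer(start), end = as.integer(end),
                 flank = as.integer(flank)),
            class = "region")
}

#' LD matrix of allelic correlations
#'
#' @param r Square numeric matrix of pairwise allelic correlations in
#'   \[-1, 1\] with unit diagonal.
#' @param variant_ids Variant identifiers, one per row/column.
#' @param pos Optional genomic positions used for deterministic
#'   tie-breaking in top-variant and proxy lookups.
#' @return A numeric matrix of class `ld_matrix` with `dimnames` set to
#'   the variant ids and an optional `pos` attribute.
#' @export
ld_matrix <- function(r, variant_ids, pos = NULL) {
  r <- as.matrix(r)
  m <- nrow(r)
  assert_that(ncol(r) == m, "LD matrix must be square")
  assert_that(length(variant_ids) == m,
              "variant_ids length must match LD dimension")
  if (max(abs(r)) > 1 + 1e-6)
    warning("LD entries beyond [-1,1] by more than 1e-6; clipping")
  r[r > 1] <- 1
  r[r < -1] <- -1
  assert_that(max(abs(r - t(r))) < 1e-8, "LD matrix must be symmetric")
  assert_that(max(abs(diag(r) - 1)) < 1e-8, "LD diagonal must be 1")
  dimnames(r) <- list(variant_ids, variant_ids)
  if (!is.null(pos)) {
    assert_that(length(pos) == m, "pos length must match LD dimension")
    attr(r, "pos") <- as.integer(pos)
  }
  class(r) <- c("ld_matrix", class(r))
  r
}

validate_sumstats <- function(x, where = "sumstats") {
  missing_cols <- setdiff(SUMSTATS_COLS, names(x))
  if (length(missing_cols))
    stopf("%s: missing required column(s): %s", where,
          paste(missing_cols, collapse = ", "))
  bad_row <- function(cond, what) {
    i <- which(cond)
    if (length(i))
      stopf("%s: %s in row(s) %s", where, what,
            paste(utils::head(i, 5), collapse = ", "))
  }
  x$ea <- toupper(x$ea)
  x$oa <- toupper(x$oa)
  for (col in c("pos", "eaf", "beta", "se", "pval", "n", "info")) {
    if (!is.numeric(x[[col]]))
      stopf("%s: column '%s' is not numeric", where, col)
    bad_row(is.na(x[[col]]), sprintf("missing/non-numeric '%s'", col))
  }
  bad_row(!(x$ea %in% VALID_ALLELES) | !(x$oa %in% VALID_ALLELES),
          "allele not in {A,C,G,T} (only biallelic SNVs are supported)")
  bad_row(x$ea == x$oa, "effect allele equals other allele")
  bad_row(x$eaf <= 0 | x$eaf >= 1, "eaf outside (0,1)")
  bad_row(x$se <= 0, "standard error must be > 0")
  bad_row(x$pval <= 0 | x$pval > 1, "p-value outside (0,1]")
  bad_row(x$n < 1, "sample size must be positive")
  bad_row(x$info < 0 | x$info > 1, "info outside [0,1]")
  bad_row(duplicated(x$variant_id), "duplicate variant_id")
  x
}

#' Read GWAS summary statistics
#'
#' Reads a tab-separated table with a header row, maps columns to the
#' canonical names, uppercases alleles and validates every row. Malformed
#' rows are rejected with their row index in the error message.
#'
#' @param path Path to a TSV file.
#' @param meta Optional [trait_meta()] attached as the `"meta"` attribute.
#' @param col_map Named character vector mapping canonical names to the
#'   file's header names, for files not using the canonical header.
#' @return A validated summary-statistic `data.frame` (see [sumstats]).
#' @export
read_sumstats <- function(path, meta = NULL, col_map = NULL) {
  assert_that(file.exists(path), "file not found: %s", path)
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "#")
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      assert_that(col_map[[canon]] %in% names(x),
                  "mapped column '%s' not found in %s", col_map[[canon]], path)
      names(x)[names(x) == col_map[[canon]]] <- canon
    }
  }
  x <- validate_sumstats(x, where = path)
  x <- x[SUMSTATS_COLS]
  if (!is.null(meta)) attr(x, "meta") <- meta
  x
}

#' Write GWAS summary statistics
#'
#' Emits the canonical tab-separated layout with a deterministic column
#' order. Numeric values are written with 15 significant digits so that a
#' write-then-read round trip preserves them to at least 12 digits.
#'
#' @param x Summary-statistic `data.frame`.
#' @param path Output path.
#' @export
write_sumstats <- function(x, path) {
  x <- validate_sumstats(x)[SUMSTATS_COLS]
  y <- x
  for (col in c("eaf", "beta", "se", "pval", "info"))
    y[[col]] <- formatC(x[[col]], digits = 15, format = "g")
  utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter variants on minor allele frequency and imputation quality
#'
#' Retains exactly the variants with `min(eaf, 1-eaf) >= maf_min` and
#' `info >= info_min`, preserving order. The number of removed variants is
#' recorded in the `"n_removed"` attribute.
#'
#' @param x Summary-statistic `data.frame`.
#' @param maf_min Minor-allele-frequency floor (default 0.01).
#' @param info_min Imputation-quality floor (default 0.5).
#' @return The filtered `data.frame`.
#' @export
qc_filter <- function(x, maf_min = 0.01, info_min = 0.5) {
  assert_that(maf_min >= 0 && maf_min <= 1, "maf_min must be in [0,1]")
  assert_that(info_min >= 0 && info_min <= 1, "info_min must be in [0,1]")
  maf <- pmin(x$eaf, 1 - x$eaf)
  keep <- maf >= maf_min & x$info >= info_min
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "meta") <- attr(x, "meta")
  out
}

#' Extract the variants of a gene region
#'
#' Keeps variants on the region's chromosome with
#' `start - flank <= pos <= end + flank`, inclusive on both ends.
#'
#' @param x Summary-statistic `data.frame`.
#' @param region A [region()].
#' @return The subset `data.frame`, ordered by position.
#' @export
extract_region <- function(x, region) {
  stopifnot(inherits(region, "region"))
  lo <- region$start - region$flank
  hi <- region$end + region$flank
  keep <- x$chrom == region$chrom & x$pos >= lo & x$pos <= hi
  out <- x[keep, , drop = FALSE]
  out <- out[order(out$pos, out$variant_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "meta") <- attr(x, "meta")
  out
}

#' Align two traits' summary statistics onto a shared variant frame
#'
#' Intersects by `variant_id` and re-expresses the second trait's effect
#' and frequency in the first trait's effect-allele frame (negating the
#' beta and reflecting the frequency when the alleles are swapped,
#' resolving strand flips by complementing). Variants whose allele pairs
#' are incompatible are dropped, as are strand-ambiguous (palindromic
#' A/T or C/G) variants whose frequency in either trait is too close to
#' 0.5 (`min(eaf, 1-eaf) > ambiguous_maf`) for strand resolution.
#'
#' @param stats1,stats2 Summary-statistic `data.frame`s with unique
#'   variant ids.
#' @param ambiguous_maf Palindromic variants with MAF above this in either
#'   trait are dropped (default 0.4).
#' @return A paired `data.frame` keyed by `variant_id` with columns
#'   `variant_id`, `chrom`, `pos`, `ea`, `oa`, then `eaf_1`, `beta_1`,
#'   `se_1`, `pval_1`, `n_1`, `info_1` and the same for trait 2, all in
#'   trait 1's allele frame. Counts of unmatched, incompatible and
#'   ambiguous drops are in the `"dropped"` attribute.
#' @export
align_traits <- function(stats1, stats2, ambiguous_maf = 0.4) {
  stats1 <- validate_sumstats(stats1, "stats1")
  stats2 <- validate_sumstats(stats2, "stats2")
  shared <- intersect(stats1$variant_id, stats2$variant_id)
  n_unmatched <- (nrow(stats1) - length(shared)) + (nrow(stats2) - length(shared))
  s1 <- stats1[match(shared, stats1$variant_id), , drop = FALSE]
  s2 <- stats2[match(shared, stats2$variant_id), , drop = FALSE]

  keep <- logical(length(shared))
  n_incompatible <- 0L
  n_ambiguous <- 0L
  if (length(shared)) {
    for (i in seq_along(shared)) {
      rec2 <- orient_record(s2[i, , drop = FALSE], s1$ea[i], s1$oa[i],
                            .error = FALSE)
      if (is.null(rec2)) {
        n_incompatible <- n_incompatible + 1L
        next
      }
      if (is_palindromic(s1$ea[i], s1$oa[i])) {
        maf_max <- max(min(s1$eaf[i], 1 - s1$eaf[i]),
                       min(rec2$eaf, 1 - rec2$eaf))
        if (maf_max > ambiguous_maf) {
          n_ambiguous <- n_ambiguous + 1L
          next
        }
      }
      s2[i, ] <- rec2
      keep[i] <- TRUE
    }
  }
  s1 <- s1[keep, , drop = FALSE]
  s2 <- s2[keep, , drop = FALSE]
  out <- data.frame(variant_id = s1$variant_id, chrom = s1$chrom,
                    pos = s1$pos, ea = s1$ea, oa = s1$oa,
                    eaf_1 = s1$eaf, beta_1 = s1$beta, se_1 = s1$se,
                    pval_1 = s1$pval, n_1 = s1$n, info_1 = s1$info,
                    eaf_2 = s2$eaf, beta_2 = s2$beta, se_2 = s2$se,
                    pval_2 = s2$pval, n_2 = s2$n, info_2 = s2$info,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "dropped") <- c(unmatched = n_unmatched,
                            incompatible = n_incompatible,
                            ambiguous = n_ambiguous)
  out
}

#' Read / write an LD matrix as plain text
#'
#' The matrix is stored as a whitespace-separated square numeric table and
#' the variant ids as a one-per-line sidecar file. Values are clipped to
#' \[-1, 1\] on read, with a warning when an entry exceeds 1 by more than
#' 1e-6.
#'
#' @param matrix_path Path to the square numeric matrix file.
#' @param ids_path Path to the variant-id sidecar (one id per line, or
#'   two tab-separated columns id and position).
#' @return An [ld_matrix()].
#' @export
read_ld <- function(matrix_path, ids_path) {
  r <- as.matrix(utils::read.table(matrix_path, header = FALSE))
  ids <- utils::read.table(ids_path, header = FALSE,
                           stringsAsFactors = FALSE, sep = "\t")
  pos <- if (ncol(ids) >= 2) as.integer(ids[[2]]) else NULL
  ld_matrix(unname(r), ids[[1]], pos = pos)
}

#' @rdname read_ld
#' @param ld An [ld_matrix()] to write.
#' @export
write_ld <- function(ld, matrix_path, ids_path) {
  utils::write.table(formatC(unclass(ld), digits = 15, format = "g"),
                     matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ids <- data.frame(id = rownames(ld))
  pos <- attr(ld, "pos")
  if (!is.null(pos)) ids$pos <- pos
  utils::write.table(ids, ids_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(matrix_path)
}

#' Read gene-region definitions
#'
#' Reads a 4-column BED-like TSV (`chrom`, `start`, `end`, `gene`).
#' Coordinates in the file are taken as 1-based inclusive unless
#' `one_based = FALSE`, in which case the usual BED half-open 0-based
#' convention is converted on read.
#'
#' @param path Path to the region file (no header).
#' @param one_based Whether the file's coordinates are already 1-based
#'   inclusive (default `TRUE`).
#' @param flank Flank applied to every region.
#' @return A list of [region()] objects.
#' @export
read_regions <- function(path, one_based = TRUE, flank = 0) {
  x <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end", "gene"))
  start <- if (one_based) x$start else x$start + 1L
  lapply(seq_len(nrow(x)), function(i)
    region(x$gene[i], x$chrom[i], start[i], x$end[i], flank = flank))
}
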