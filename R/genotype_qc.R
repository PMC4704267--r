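#' Remove distorted and poorly called markers
#'
#' Applies the two locus filters used before map construction: a marker is
#' eliminated if its missing fraction exceeds `max_missing` (strictly), or
#' if a chi-square test of its homozygous A:B counts against the 1:1 RIL
#' expectation (1 df, heterozygous and missing calls excluded, no
#' continuity correction) is significant at `alpha`. Markers with no
#' informative (homozygous) call are removed and flagged uninformative.
#'
#' @param g A [genotype_matrix()].
#' @param max_missing Missing-fraction ceiling (default 0.10; a marker at
#'   exactly the threshold survives).
#' @param alpha Distortion significance level (default 0.01).
#' @return List with elements `genotypes` (filtered matrix, marker order
#'   preserved) and `report` (a `qc_report`: counts removed per reason plus
#'   a per-marker table of missing fraction, chi2 and p).
#' @export
filter_markers <- function(g, max_missing = 0.10, alpha = 0.01) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!length(g$marker_ids) || !length(g$line_ids)) {
    stop("empty genotype matrix")
  }
  calls <- g$calls
  n_lines <- ncol(calls)
  n_missing <- rowSums(calls == "MISSING")
  missing_frac <- n_missing / n_lines
  nA <- rowSums(calls == "A")
  nB <- rowSums(calls == "B")
  tot <- nA + nB
  chi2 <- ifelse(tot > 0, (nA - nB)^2 / tot, NA_real_)
  p <- ifelse(tot > 0, pchisq(chi2, df = 1, lower.tail = FALSE), NA_real_)
  uninformative <- tot == 0
  drop_missing <- missing_frac > max_missing
  drop_distort <- !uninformative & !drop_missing & p < alpha
  keep <- !(drop_missing | drop_distort | uninformative)
  per_marker <- data.frame(marker_id = g$marker_ids,
                           missing_fraction = missing_frac,
                           chi2 = chi2, p = p,
                           removed = ifelse(drop_missing, "missing",
                                     ifelse(uninformative, "uninformative",
                                     ifelse(drop_distort, "distortion",
                                            "retained"))),
                           stringsAsFactors = FALSE)
  report <- structure(list(
    n_input_markers = length(g$marker_ids),
    n_markers_removed_missing = sum(drop_missing),
    n_markers_removed_distortion = sum(drop_distort),
    n_markers_removed_uninformative = sum(uninformative & !drop_missing),
    continuity_correction = FALSE,
    per_marker = per_marker), class = "qc_report")
  out <- genotype_matrix(calls[keep, , drop = FALSE], g$population_id)
  list(genotypes = out, report = report)
}

#' Remove lines with excessive missing data
#'
#' A line is removed if its missing fraction over the (already
#' marker-filtered) matrix strictly exceeds `max_missing`. Removing every
#' line is an error.
#'
#' @param g A [genotype_matrix()].
#' @param max_missing Missing-fraction ceiling (default 0.10).
#' @return List with `genotypes` and `report` (`n_lines_removed_missing`
#'   and a per-line table).
#' @export
filter_lines <- function(g, max_missing = 0.10) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!length(g$marker_ids) || !length(g$line_ids)) {
    stop("empty genotype matrix")
  }
  missing_frac <- colSums(g$calls == "MISSING") / nrow(g$calls)
  keep <- missing_frac <= max_missing
  if (!any(keep)) stop("all lines removed: population is empty after QC")
  report <- structure(list(
    n_input_lines = length(g$line_ids),
    n_lines_removed_missing = sum(!keep),
    per_line = data.frame(line_id = g$line_ids,
                          missing_fraction = missing_frac,
                          removed = !keep, stringsAsFactors = FALSE)),
    class = "qc_report")
  out <- genotype_matrix(g$calls[, keep, drop = FALSE], g$population_id)
  list(genotypes = out, report = report)
}

#' Marker-then-line QC in the fixed order used before mapping
#'
#' @inheritParams filter_markers
#' @return List with `genotypes`, `marker_report`, `line_report`.
#' @export
qc_genotypes <- function(g, max_missing = 0.10, alpha = 0.01) {
  fm <- filter_markers(g, max_missing = max_missing, alpha = alpha)
  fl <- filter_lines(fm$genotypes, max_missing = max_missing)
  list(genotypes = fl$genotypes, marker_report = fm$report,
       line_report = fl$report)
}
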