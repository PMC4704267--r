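#' Anchor unplaced scaffolds via their mapped markers
#'
#' Each scaffold carrying at least one marker present in a supplied map is
#' assigned to the chromosome of that marker's linkage group (via the
#' group-to-chromosome assignment). Scaffolds whose markers land on
#' different groups within one map, or whose populations disagree on the
#' chromosome, are flagged as conflicting and not anchored. The genetic
#' position is the median cM of the scaffold's markers, kept separately per
#' population (maps have different scales, so no cross-population
#' averaging). Orientation is the sign of the rank correlation between
#' in-scaffold offset and cM and requires at least two markers with
#' distinct cM and distinct offsets; otherwise `UNKNOWN`.
#'
#' @param scaffolds A [scaffold_set()].
#' @param maps List of one or two `linkage_map`s (named; names become the
#'   support labels).
#' @param assignments List (parallel to `maps`) of results of
#'   [assign_groups_to_chromosomes()], or named chromosome-per-group
#'   vectors.
#' @return List of class `anchor_result`: `anchors` (one row per scaffold:
#'   `scaffold_id`, `length`, `chromosome`, `orientation`, `support`,
#'   per-population `cM_<name>`), `skipped` (ids with reason), and
#'   `summary` (`n_anchored`, `total_length` counting each scaffold once).
#' @export
anchor_scaffolds <- function(scaffolds, maps, assignments) {
  stopifnot(inherits(scaffolds, "scaffold_set"))
  if (inherits(maps, "linkage_map")) maps <- list(pop1 = maps)
  if (is.null(names(maps))) {
    names(maps) <- paste0("pop", seq_along(maps))
  }
  asg <- lapply(assignments, function(a) {
    if (is.list(a) && !is.null(a$assignment)) a$assignment else a
  })
  if (is.null(names(asg))) names(asg) <- names(maps)
  anchors <- list()
  skipped <- list()
  for (k in seq_len(nrow(scaffolds$scaffolds))) {
    sid <- scaffolds$scaffolds$scaffold_id[k]
    slen <- scaffolds$scaffolds$length[k]
    mk <- scaffolds$markers[scaffolds$markers$scaffold_id == sid, ]
    per_pop <- list()
    chrom_votes <- character(0)
    for (pop in names(maps)) {
      loci <- maps[[pop]]$loci
      hit <- merge(mk, loci, by = "marker_id")
      if (!nrow(hit)) next
      grps <- unique(hit$group)
      if (length(grps) > 1L) {
        per_pop[[pop]] <- list(conflict = TRUE)
        next
      }
      chrom <- unname(asg[[pop]][grps])
      per_pop[[pop]] <- list(conflict = FALSE, chromosome = chrom,
                             cM = median(hit$cM), hits = hit)
      if (!is.na(chrom)) chrom_votes <- c(chrom_votes, chrom)
    }
    if (!length(per_pop)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        scaffold_id = sid, reason = "no mapped marker",
        stringsAsFactors = FALSE)
      next
    }
    if (any(vapply(per_pop, `[[`, logical(1), "conflict"))) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        scaffold_id = sid, reason = "conflicting anchor (multiple groups)",
        stringsAsFactors = FALSE)
      next
    }
    if (length(unique(chrom_votes)) > 1L) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        scaffold_id = sid, reason = "conflicting anchor (populations)",
        stringsAsFactors = FALSE)
      next
    }
    if (!length(chrom_votes)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        scaffold_id = sid, reason = "group not assigned to a chromosome",
        stringsAsFactors = FALSE)
      next
    }
    # orientation from pooled (offset, cM) ranks; needs 2 distinct of each
    ori <- "UNKNOWN"
    for (pop in names(per_pop)) {
      hit <- per_pop[[pop]]$hits
      if (is.null(hit) || nrow(hit) < 2L) next
      if (length(unique(hit$cM)) < 2L ||
          length(unique(hit$offset)) < 2L) next
      rho <- suppressWarnings(cor(hit$offset, hit$cM, method = "spearman"))
      if (is.na(rho) || rho == 0) next
      ori <- if (rho > 0) "+" else "-"
      break
    }
    row <- data.frame(scaffold_id = sid, length = slen,
                      chromosome = chrom_votes[1L], orientation = ori,
                      support = paste(names(per_pop), collapse = "+"),
                      stringsAsFactors = FALSE)
    for (pop in names(maps)) {
      row[[paste0("cM_", pop)]] <-
        if (!is.null(per_pop[[pop]]) && !per_pop[[pop]]$conflict)
          per_pop[[pop]]$cM else NA_real_
    }
    anchors[[length(anchors) + 1L]] <- row
  }
  anc <- if (length(anchors)) do.call(rbind, anchors) else NULL
  structure(list(
    anchors = anc,
    skipped = if (length(skipped)) do.call(rbind, skipped) else NULL,
    summary = list(
      n_anchored = if (is.null(anc)) 0L else nrow(anc),
      total_length = if (is.null(anc)) 0 else sum(anc$length))),
    class = "anchor_result")
}

#' @export
print.anchor_result <- function(x, ...) {
  cat(sprintf("<anchor_result> %d scaffolds anchored, %s bp total\n",
              x$summary$n_anchored,
              format(x$summary$total_length, big.mark = ",")))
  invisible(x)
}
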