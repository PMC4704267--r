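#' Build a Marey map for one chromosome
#'
#' Pairs the genetic position (cM) of every marker shared between a map and
#' a placement with its physical position (bp), sorted by bp. If the rank
#' correlation between cM and bp is negative the map orientation is flipped
#' (cM mirrored to `max - cM`). Residual non-monotone points are dropped
#' greedily (longest non-decreasing subsequence retained) and their count
#' reported.
#'
#' @param map A `linkage_map`.
#' @param placement A [physical_placement()].
#' @param chromosome Chromosome to extract.
#' @param group Optional linkage group to use; defaults to the group with
#'   most markers on the chromosome.
#' @param min_markers Density floor (default 10).
#' @return Object of class `marey_map`: `chromosome`, `points`
#'   (data.frame `bp`, `cM`), `n_dropped`, `flipped`.
#' @export
build_marey <- function(map, placement, chromosome, group = NULL,
                        min_markers = 10L) {
  pl <- as.data.frame(placement)
  pl <- pl[pl$chromosome == chromosome, ]
  merged <- merge(map$loci, pl, by = "marker_id")
  if (!is.null(group)) merged <- merged[merged$group == group, ]
  else if (nrow(merged)) {
    tab <- table(merged$group)
    merged <- merged[merged$group == names(tab)[which.max(tab)], ]
  }
  if (nrow(merged) < min_markers) {
    stop("insufficient density: ", nrow(merged), " shared markers on ",
         chromosome)
  }
  merged <- merged[order(merged$position), ]
  merged <- merged[!duplicated(merged$position), ]
  rk <- suppressWarnings(cor(merged$cM, merged$position,
                             method = "spearman"))
  flipped <- !is.na(rk) && rk < 0
  cm <- if (flipped) max(merged$cM) - merged$cM else merged$cM
  keep <- .lnds(cm)
  structure(list(chromosome = chromosome,
                 points = data.frame(bp = merged$position[keep],
                                     cM = cm[keep]),
                 n_dropped = length(cm) - length(keep),
                 dropped_bp = merged$position[setdiff(seq_along(cm), keep)],
                 flipped = flipped),
            class = "marey_map")
}

# indices of a longest non-decreasing subsequence (patience sorting)
.lnds <- function(x) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  tails <- numeric(0)
  tails_idx <- integer(0)
  prev <- integer(n)
  for (i in seq_len(n)) {
    j <- findInterval(x[i], tails, left.open = FALSE) # last tail <= x[i]
    # replace first tail strictly greater than x[i]
    k <- j + 1L
    prev[i] <- if (j >= 1L) tails_idx[j] else 0L
    tails[k] <- x[i]
    tails_idx[k] <- i
    length(tails) <- k
    length(tails_idx) <- k
  }
  out <- integer(0)
  i <- tails_idx[length(tails_idx)]
  while (i > 0L) {
    out <- c(i, out)
    i <- prev[i]
  }
  out
}

# Continuous piecewise-linear least squares with breakpoints b (length 0,
# 1 or 2) using the hinge basis {1, x, (x-b1)+, (x-b2)+}; returns fit
# summary or NULL when degenerate.
.pwl_fit <- function(x, y, b) {
  X <- cbind(1, x)
  for (bb in b) X <- cbind(X, pmax(x - bb, 0))
  fit <- tryCatch(stats::lm.fit(X, y), error = function(e) NULL)
  if (is.null(fit) || any(is.na(fit$coefficients))) return(NULL)
  rss <- sum(fit$residuals^2)
  beta <- fit$coefficients
  slopes <- cumsum(beta[-1L])
  list(rss = rss, slopes = slopes, breaks = b)
}

#' Delimit the heterochromatic block of a Marey map
#'
#' Fits a continuous segmented-linear model of cumulative genetic distance
#' against physical distance and reads the heterochromatic interval off the
#' two inflection points: 3-segment fits (interior low-slope block) and
#' 2-segment fits (block abutting a chromosome end) are both searched, with
#' breakpoints on a marker-position grid refined to marker resolution and
#' segments at least `min_segment` bp. Among candidates whose low-slope
#' segment has slope at most `slope_ratio_max` times the smaller flanking
#' slope, the minimum-RSS fit wins; when none qualifies the chromosome is
#' reported all-euchromatic.
#'
#' @param m A `marey_map`.
#' @param slope_ratio_max Heterochromatin slope ceiling relative to the
#'   mean flank slope (default 0.25).
#' @param min_segment Minimum segment length in bp (default 2e6).
#' @param chromosome_length Total chromosome length used for the partition
#'   entry (defaults to the last marker position).
#' @param grid_max Coarse-search grid size (breakpoints are refined to
#'   marker resolution afterwards).
#' @return One-row data.frame: `chromosome`, `length`, `het_start`,
#'   `het_end` (bp, NA when all-euchromatic), `het_slope`, `flank_slope`,
#'   `rss`.
#' @export
delimit_heterochromatin <- function(m, slope_ratio_max = 0.25,
                                    min_segment = 2e6,
                                    chromosome_length = NULL,
                                    grid_max = 80L) {
  x <- m$points$bp
  y <- m$points$cM
  len <- if (is.null(chromosome_length)) max(x) else chromosome_length
  cand_all <- sort(unique(x))
  grid <- if (length(cand_all) > grid_max)
    cand_all[unique(round(seq(1, length(cand_all), length.out = grid_max)))]
  else cand_all
  best <- NULL
  eval_cand <- function(b, kind) {
    fit <- .pwl_fit(x, y, b)
    if (is.null(fit)) return(NULL)
    sl <- fit$slopes
    if (kind == "mid") {
      het <- sl[2L]; flank <- min(sl[1L], sl[3L])
      hs <- b[1L]; he <- b[2L]
    } else if (kind == "start") {
      het <- sl[1L]; flank <- sl[2L]
      hs <- 0; he <- b[1L]
    } else {
      het <- sl[2L]; flank <- sl[1L]
      hs <- b[1L]; he <- len
    }
    if (flank <= 0) return(NULL)
    ok <- het <= slope_ratio_max * flank && het >= -1e-9
    list(rss = fit$rss, hs = hs, he = he, het = het, flank = flank,
         ok = ok)
  }
  consider <- function(res) {
    if (!is.null(res) && res$ok &&
        (is.null(best) || res$rss < best$rss)) best <<- res
  }
  # 3-segment interior block
  lo <- min(x); hi <- max(x)
  g1 <- grid[grid >= lo + min_segment & grid <= hi - 2 * min_segment]
  for (b1 in g1) {
    g2 <- grid[grid >= b1 + min_segment & grid <= hi - min_segment]
    for (b2 in g2) consider(eval_cand(c(b1, b2), "mid"))
  }
  # 2-segment: block at chromosome start or end
  g0 <- grid[grid >= lo + min_segment & grid <= hi - min_segment]
  for (b in g0) {
    consider(eval_cand(b, "start"))
    consider(eval_cand(b, "end"))
  }
  if (is.null(best)) {
    return(data.frame(chromosome = m$chromosome, length = len,
                      het_start = NA_real_, het_end = NA_real_,
                      het_slope = NA_real_, flank_slope = NA_real_,
                      rss = NA_real_, stringsAsFactors = FALSE))
  }
  # refine each breakpoint over all marker positions near the coarse optimum
  step <- if (length(grid) > 1) max(diff(grid)) else 0
  refine <- function(hs, he) {
    interior <- hs > 0 && he < len
    b1s <- if (hs > 0)
      cand_all[abs(cand_all - hs) <= step] else NA
    b2s <- if (he < len)
      cand_all[abs(cand_all - he) <= step] else NA
    for (b1 in b1s) for (b2 in b2s) {
      b <- c(if (!is.na(b1)) b1, if (!is.na(b2)) b2)
      kind <- if (interior) "mid" else if (is.na(b1)) "start" else "end"
      if (kind == "mid" && (b[2L] - b[1L] < min_segment)) next
      consider(eval_cand(b, kind))
    }
  }
  refine(best$hs, best$he)
  data.frame(chromosome = m$chromosome, length = len,
             het_start = best$hs, het_end = best$he,
             het_slope = best$het, flank_slope = best$flank,
             rss = best$rss, stringsAsFactors = FALSE)
}

#' Partition every chromosome of a map/placement pair
#'
#' Convenience wrapper running [build_marey()] and
#' [delimit_heterochromatin()] per chromosome.
#'
#' @inheritParams build_marey
#' @inheritParams delimit_heterochromatin
#' @param chromosome_lengths Named bp lengths (defaults to last marker).
#' @return A [chromatin_partition()].
#' @export
partition_chromatin <- function(map, placement, chromosome_lengths = NULL,
                                slope_ratio_max = 0.25, min_segment = 2e6) {
  pl <- as.data.frame(placement)
  chroms <- sort(unique(pl$chromosome))
  rows <- lapply(chroms, function(ch) {
    m <- build_marey(map, placement, ch)
    len <- if (!is.null(chromosome_lengths)) chromosome_lengths[[ch]]
           else NULL
    delimit_heterochromatin(m, slope_ratio_max, min_segment,
                            chromosome_length = len)
  })
  df <- do.call(rbind, rows)
  chromatin_partition(df$chromosome, df$length, df$het_start, df$het_end)
}

#' Summarize a chromatin partition
#'
#' Interval arithmetic in the continuous coordinates the partitions are
#' stated in: the heterochromatic total is the sum of `het_end - het_start`
#' over chromosomes, the euchromatic total is the assembly length minus it,
#' and fractions are reported against the assembly length, rounded to whole
#' percent.
#'
#' @param p A [chromatin_partition()].
#' @param chromosome_lengths Optional named bp vector overriding the
#'   partition's per-chromosome lengths.
#' @param total_length Optional declared assembly total (bp); defaults to
#'   the sum of chromosome lengths. The declared total may exceed the sum
#'   of per-chromosome interval bounds when sequence beyond the last
#'   delimited interval is counted in the assembly.
#' @return List `het_bp`, `euch_bp`, `het_mb`, `euch_mb`, `het_pct`,
#'   `euch_pct`, `total_bp`.
#' @export
summarize_partition <- function(p, chromosome_lengths = NULL,
                                total_length = NULL) {
  stopifnot(inherits(p, "chromatin_partition"))
  len <- p$length
  if (!is.null(chromosome_lengths)) {
    len <- unname(chromosome_lengths[p$chromosome])
  }
  has <- !is.na(p$het_start) & !is.na(p$het_end)
  if (any(has & p$het_end > len)) {
    stop("heterochromatic interval exceeds chromosome length")
  }
  het <- sum((p$het_end - p$het_start)[has])
  total <- if (is.null(total_length)) sum(len) else total_length
  euch <- total - het
  list(het_bp = het, euch_bp = euch,
       het_mb = het / 1e6, euch_mb = euch / 1e6,
       het_pct = round(100 * het / total),
       euch_pct = round(100 * euch / total),
       total_bp = total)
}
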