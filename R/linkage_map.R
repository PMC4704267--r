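#' Kosambi mapping function
#'
#' Converts a recombination fraction to an additive map distance allowing
#' for interference: `d = 25 * ln((1 + 2r) / (1 - 2r))` cM. Fractions at or
#' above 0.5 are clamped to `0.5 - 1e-6` before evaluation; negative input
#' is rejected.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @return Map distance(s) in cM.
#' @export
kosambi <- function(r) {
  if (any(r < 0)) stop("recombination fraction must be >= 0")
  r <- pmin(r, 0.5 - 1e-6)
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Haldane map function and inverse
#'
#' `haldane(r)` gives `-50 * ln(1 - 2r)` cM; `haldane_inverse(d)` gives the
#' recombination fraction of a distance `d` cM under no interference. The
#' simulator operates in this no-interference world, so these give exact
#' expectations for synthetic data.
#'
#' @param r Recombination fraction(s); `d` distance(s) in cM.
#' @return Distance in cM, or recombination fraction.
#' @export
haldane <- function(r) -50 * log(1 - 2 * pmin(r, 0.5 - 1e-9))

#' @rdname haldane
#' @param d Map distance(s) in cM.
#' @export
haldane_inverse <- function(d) (1 - exp(-2 * d / 100)) / 2

#' Expected recombinant-line fraction in selfing-derived RILs
#'
#' The fixation-limit relation of Haldane and Waddington for RILs by
#' selfing: `R = 2r / (1 + 2r)`, and its inverse `r = R / (2 (1 - R))`
#' (clamped to `[0, 0.5]`).
#'
#' @param r Meiotic recombination fraction.
#' @return Expected observed recombinant-line fraction `R`.
#' @export
ril_R_from_r <- function(r) 2 * r / (1 + 2 * r)

#' @rdname ril_R_from_r
#' @param R Observed recombinant-line fraction.
#' @export
ril_r_from_R <- function(R) pmin(pmax(R / (2 * (1 - R)), 0), 0.5)

#' Two-point linkage between a pair of markers
#'
#' Informative lines are those homozygous at both markers; among them the
#' recombinant fraction `R_hat` is the share of A/B or B/A patterns. The
#' meiotic fraction `r_hat` follows by the RIL-by-selfing inversion, and
#' the LOD is `k log10(R/0.5) + (n-k) log10((1-R)/0.5)` with the convention
#' `0 * log10(0) = 0`.
#'
#' @param g A [genotype_matrix()].
#' @param i,j Marker ids or row indices.
#' @return List of class `pairwise_linkage`: `R_hat`, `r_hat`, `lod`,
#'   `n_informative`, `n_recombinant`.
#' @export
pairwise_linkage <- function(g, i, j) {
  stopifnot(inherits(g, "genotype_matrix"))
  ci <- g$calls[i, ]
  cj <- g$calls[j, ]
  hom <- ci %in% c("A", "B") & cj %in% c("A", "B")
  n <- sum(hom)
  if (n == 0) stop("uninformative pair: no line homozygous at both markers")
  k <- sum(ci[hom] != cj[hom])
  R <- k / n
  lod <- .ril_lod(k, n)
  structure(list(R_hat = R, r_hat = ril_r_from_R(R), lod = lod,
                 n_informative = n, n_recombinant = k),
            class = "pairwise_linkage")
}

.ril_lod <- function(k, n) {
  R <- k / n
  t1 <- if (k > 0) k * log10(R / 0.5) else 0
  t2 <- if (k < n) (n - k) * log10((1 - R) / 0.5) else 0
  t1 + t2
}

# All-pairs two-point statistics via +1/-1/0 encoding and crossproducts.
# Returns list of matrices: R (recombinant-line fraction, NA where no
# informative line), lod, n (informative lines), k (recombinants).
.pairwise_all <- function(g) {
  enc <- matrix(0, nrow(g$calls), ncol(g$calls))
  enc[g$calls == "A"] <- 1
  enc[g$calls == "B"] <- -1
  P <- tcrossprod(enc)            # same - different
  Q <- tcrossprod(abs(enc))       # informative
  K <- (Q - P) / 2                # different (recombinant)
  R <- ifelse(Q > 0, K / Q, NA_real_)
  lodm <- matrix(0, nrow(Q), ncol(Q))
  pos <- Q > 0
  Rp <- R[pos]
  Kp <- K[pos]
  Qp <- Q[pos]
  lodm[pos] <- ifelse(Kp > 0, Kp * log10(pmax(Rp, 1e-300) / 0.5), 0) +
    ifelse(Kp < Qp, (Qp - Kp) * log10((1 - Rp) / 0.5), 0)
  rownames(R) <- colnames(R) <- g$marker_ids
  dimnames(lodm) <- dimnames(Q) <- dimnames(K) <- dimnames(R)
  list(R = R, lod = lodm, n = Q, k = K)
}

#' Partition markers into linkage groups at a LOD threshold
#'
#' Builds the graph whose edges join marker pairs with two-point LOD at or
#' above the threshold and returns its connected components.
#'
#' @param g A [genotype_matrix()] of (typically binned) markers.
#' @param lod_threshold Grouping threshold (default 11).
#' @param pairs Optional precomputed result of the internal all-pairs
#'   statistics (used by [build_linkage_map()] to avoid recomputation).
#' @return Named integer vector: group index per marker id.
#' @export
group_markers <- function(g, lod_threshold = 11, pairs = NULL) {
  if (is.null(pairs)) pairs <- .pairwise_all(g)
  adj <- pairs$lod >= lod_threshold
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)$membership
  # renumber components by first-appearance order for determinism
  first <- !duplicated(comp)
  remap <- setNames(seq_len(sum(first)), comp[first])
  setNames(as.integer(remap[as.character(comp)]), g$marker_ids)
}

#' Order the markers of one linkage group and assign cM positions
#'
#' The ordering minimizes the sum of adjacent meiotic recombination
#' fractions: a minimum-spanning-tree backbone is built on the r-hat
#' weighted complete graph, an initial order is read off the tree by a
#' depth-first sweep from one end of its diameter path, and the order is
#' refined by segment-reversal (2-opt; unbounded window by default, with an
#' optional window cap for very large groups) until
#' no improving move remains. Positions are cumulative Kosambi distances
#' over adjacent pairs, anchored at 0. When a placement is supplied the
#' orientation with positive rank correlation to physical position is
#' chosen; otherwise the orientation putting the lexicographically smaller
#' terminal marker first.
#'
#' @param g A [genotype_matrix()].
#' @param members Marker ids of one group.
#' @param placement Optional [physical_placement()] used to orient the
#'   group.
#' @param window 2-opt window width.
#' @param pairs Optional precomputed all-pairs statistics.
#' @return data.frame `marker_id`, `cM` in map order.
#' @export
order_group <- function(g, members, placement = NULL, window = Inf,
                        pairs = NULL) {
  members <- as.character(members)
  if (length(members) == 1L) {
    return(data.frame(marker_id = members, cM = 0,
                      stringsAsFactors = FALSE))
  }
  if (is.null(pairs)) {
    sub <- genotype_matrix(g$calls[members, , drop = FALSE],
                           g$population_id)
    pairs <- .pairwise_all(sub)
    r <- ril_r_from_R(pairs$R)
  } else {
    r <- ril_r_from_R(pairs$R[members, members, drop = FALSE])
  }
  r[is.na(r)] <- 0.5
  diag(r) <- 0
  ord <- .mst_seriate(r)
  ord <- .two_opt(ord, r, window)
  ids <- members[ord]
  ids <- .orient_order(ids, placement)
  adj_r <- r[cbind(match(ids[-length(ids)], members),
                   match(ids[-1L], members))]
  data.frame(marker_id = ids, cM = cumsum(c(0, kosambi(adj_r))),
             stringsAsFactors = FALSE)
}

.mst_seriate <- function(r) {
  m <- nrow(r)
  gr <- igraph::graph_from_adjacency_matrix(r, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  tr <- igraph::mst(gr)
  # diameter endpoint, then DFS order from it
  far <- igraph::farthest_vertices(tr)$vertices[1L]
  as.integer(igraph::dfs(tr, root = far)$order)
}

# windowed 2-opt: reverse segments of length <= window while the total
# adjacent-r objective improves; ties broken against moving (stable)
.two_opt <- function(ord, r, window) {
  m <- length(ord)
  if (m < 3L) return(ord)
  repeat {
    improved <- FALSE
    for (i in seq_len(m - 1L)) {
      jmax <- min(m, i + window - 1L)
      for (j in (i + 1L):jmax) {
        left <- if (i > 1L) r[ord[i - 1L], ord[i]] else 0
        right <- if (j < m) r[ord[j], ord[j + 1L]] else 0
        new_left <- if (i > 1L) r[ord[i - 1L], ord[j]] else 0
        new_right <- if (j < m) r[ord[i], ord[j + 1L]] else 0
        if (new_left + new_right < left + right - 1e-12) {
          ord[i:j] <- rev(ord[i:j])
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  ord
}

.orient_order <- function(ids, placement) {
  if (!is.null(placement)) {
    pl <- as.data.frame(placement)
    shared <- intersect(ids, pl$marker_id)
    if (length(shared) >= 2L) {
      pos <- pl$position[match(shared, pl$marker_id)]
      rk <- cor(match(shared, ids), pos, method = "spearman")
      if (!is.na(rk) && rk < 0) return(rev(ids))
      if (!is.na(rk)) return(ids)
    }
  }
  if (ids[1L] > ids[length(ids)]) rev(ids) else ids
}

#' Construct a linkage map object
#'
#' @param loci data.frame with columns `group`, `marker_id`, `cM`; within a
#'   group cM must be non-decreasing.
#' @param population_id Population label.
#' @return Object of class `linkage_map` with elements `population_id`,
#'   `loci` and `lengths` (cM span per group).
#' @export
linkage_map_obj <- function(loci, population_id = "pop") {
  stopifnot(all(c("group", "marker_id", "cM") %in% names(loci)))
  loci <- loci[order(loci$group), ]
  for (gid in unique(loci$group)) {
    cm <- loci$cM[loci$group == gid]
    if (is.unsorted(cm, strictly = FALSE)) {
      stop("cM not non-decreasing within group ", gid)
    }
  }
  if (anyDuplicated(loci$marker_id)) {
    stop("marker in more than one group: ",
         loci$marker_id[duplicated(loci$marker_id)][1L])
  }
  lengths <- tapply(loci$cM, loci$group, function(x) max(x) - min(x))
  structure(list(population_id = population_id,
                 loci = loci[, c("group", "marker_id", "cM")],
                 lengths = lengths,
                 total_length_cM = sum(lengths)),
            class = "linkage_map")
}

#' @export
print.linkage_map <- function(x, ...) {
  cat(sprintf("<linkage_map> population '%s': %d loci in %d groups, %.1f cM\n",
              x$population_id, nrow(x$loci),
              length(unique(x$loci$group)), x$total_length_cM))
  invisible(x)
}

#' Build a linkage map from a QC-filtered genotype matrix
#'
#' Orchestrates the mapping stage: bin markers with identical segregation
#' patterns, group the representatives at the LOD threshold, order each
#' group, assign Kosambi cM, orient against the placement when given, and
#' re-expand the bins.
#'
#' @param g A QC-filtered [genotype_matrix()].
#' @param lod_threshold Grouping LOD (default 11).
#' @param placement Optional [physical_placement()] for orientation.
#' @param window 2-opt window.
#' @return A `linkage_map`.
#' @export
build_linkage_map <- function(g, lod_threshold = 11, placement = NULL,
                              window = Inf) {
  bins <- bin_markers(g)
  reps <- bin_representatives(bins)
  sub <- genotype_matrix(g$calls[reps, , drop = FALSE], g$population_id)
  pairs <- .pairwise_all(sub)
  grp <- group_markers(sub, lod_threshold, pairs = pairs)
  loci <- do.call(rbind, lapply(sort(unique(grp)), function(gid) {
    members <- names(grp)[grp == gid]
    ord <- order_group(sub, members, placement = placement,
                       window = window, pairs = pairs)
    cbind(group = sprintf("LG%02d", gid), ord)
  }))
  expand_bins(linkage_map_obj(loci, g$population_id), bins)
}

#' Write / read a linkage map TSV
#'
#' Columns `group`, `marker_id`, `cM` (3 decimals).
#' @param map A `linkage_map`; `path` a file path.
#' @param path File path.
#' @export
write_linkage_map <- function(map, path) {
  df <- map$loci
  df$cM <- sprintf("%.3f", df$cM)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_linkage_map
#' @param population_id Label attached on read.
#' @export
read_linkage_map <- function(path, population_id = "pop") {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "character", "numeric"))
  linkage_map_obj(df, population_id)
}
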