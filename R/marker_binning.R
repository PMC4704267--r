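#' Cluster markers with identical segregation patterns
#'
#' Markers whose call vectors are exactly equal (including at `MISSING`
#' positions) are collapsed into one bin; only the representative — the
#' first member in input order — is carried into linkage analysis, and the
#' other members are re-inserted at its map position afterwards by
#' [expand_bins()].
#'
#' @param g A [genotype_matrix()] (normally QC-filtered).
#' @return Object of class `bin_set`: list with `bins` (data.frame
#'   `representative`, `member`) and `patterns` (named pattern key per
#'   representative).
#' @export
bin_markers <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  key <- apply(g$calls, 1L, paste, collapse = "")
  first <- !duplicated(key)
  rep_of <- setNames(g$marker_ids[first], key[first])
  bins <- data.frame(representative = unname(rep_of[key]),
                     member = g$marker_ids, stringsAsFactors = FALSE)
  structure(list(bins = bins,
                 patterns = setNames(key[first], g$marker_ids[first])),
            class = "bin_set")
}

#' Representative markers of a bin set
#' @param bins A `bin_set`.
#' @return Character vector of representative marker ids in input order.
#' @export
bin_representatives <- function(bins) {
  unique(bins$bins$representative)
}

#' Re-insert binned markers at their representative's map position
#'
#' Every representative in `bins` must be present in the map; members are
#' placed at the representative's cM, co-located members ordered by
#' marker id for determinism.
#'
#' @param map A `linkage_map` built on representatives.
#' @param bins A `bin_set` from [bin_markers()].
#' @return A `linkage_map` containing every member marker.
#' @export
expand_bins <- function(map, bins) {
  stopifnot(inherits(map, "linkage_map"), inherits(bins, "bin_set"))
  reps_in_map <- map$loci$marker_id
  missing <- setdiff(unique(bins$bins$representative), reps_in_map)
  if (length(missing)) {
    stop("representative absent from map: ", missing[1L])
  }
  merged <- merge(map$loci, bins$bins,
                  by.x = "marker_id", by.y = "representative")
  out <- data.frame(group = merged$group, marker_id = merged$member,
                    cM = merged$cM, stringsAsFactors = FALSE)
  out <- out[order(out$group, out$cM, out$marker_id), ]
  linkage_map_obj(out, map$population_id)
}
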