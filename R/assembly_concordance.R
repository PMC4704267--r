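#' Construct a correction ledger
#'
#' A Table-2-style ledger of assembly corrections: each entry delimits a
#' marker interval on a chromosome and prescribes an action —
#' `REORIENT`, `MOVE` (to a target chromosome), `MOVE_AND_REORIENT`,
#' `REPOSITION_WITHIN` or `COMPLEX` — with a support class recording which
#' population(s) demand it.
#'
#' @param entries data.frame with columns `chromosome`, `first_marker`,
#'   `last_marker`, `span_start`, `span_end`, `action`, `target` (NA except
#'   for moves).
#' @param support `"BOTH"`, `"POP1_ONLY"` or `"POP2_ONLY"`, recycled.
#' @return Object of class `correction_ledger`.
#' @export
correction_ledger <- function(entries, support = "POP1_ONLY") {
  acts <- c("REORIENT", "MOVE", "MOVE_AND_REORIENT", "REPOSITION_WITHIN",
            "COMPLEX")
  if (nrow(entries)) {
    stopifnot(all(entries$action %in% acts))
    bad <- entries$action %in% c("MOVE", "MOVE_AND_REORIENT") &
      !is.na(entries$target) & entries$target == entries$chromosome
    if (any(bad)) stop("MOVE target equals source chromosome")
    if (any(entries$span_end < entries$span_start)) {
      stop("malformed physical span")
    }
    entries$support <- rep_len(support, nrow(entries))
  } else {
    entries$support <- character(0)
  }
  counts <- table(factor(entries$support,
                         c("BOTH", "POP1_ONLY", "POP2_ONLY")))
  structure(list(entries = entries, counts = as.list(counts)),
            class = "correction_ledger")
}

#' @export
print.correction_ledger <- function(x, ...) {
  cat(sprintf("<correction_ledger> %d entries (BOTH %d, POP1 %d, POP2 %d)\n",
              nrow(x$entries), x$counts$BOTH, x$counts$POP1_ONLY,
              x$counts$POP2_ONLY))
  invisible(x)
}

#' Assign linkage groups to chromosomes by majority vote
#'
#' Each group is assigned to the chromosome holding the majority of its
#' placed markers. Groups tied between chromosomes are left unresolved and
#' flagged, as are chromosomes claimed by more than one group.
#'
#' @param map A `linkage_map`.
#' @param placement A [physical_placement()].
#' @return List with `assignment` (named chromosome per group, NA where
#'   unresolved), `conflicts` (chromosomes claimed twice) and `ties`
#'   (groups with tied majorities).
#' @export
assign_groups_to_chromosomes <- function(map, placement) {
  pl <- as.data.frame(placement)
  loci <- map$loci
  merged <- merge(loci, pl, by = "marker_id")
  if (!nrow(merged)) stop("map and placement share no markers")
  groups <- unique(loci$group)
  assignment <- setNames(rep(NA_character_, length(groups)), groups)
  ties <- character(0)
  for (gid in groups) {
    tab <- table(merged$chromosome[merged$group == gid])
    if (!length(tab)) next
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) ties <- c(ties, gid) else assignment[gid] <- top
  }
  assigned <- assignment[!is.na(assignment)]
  conflicts <- unique(assigned[duplicated(assigned)])
  list(assignment = assignment, conflicts = unname(conflicts), ties = ties)
}

# Lone-outlier pre-pass: an interior marker is a singleton (mapping noise)
# when its value falls outside its neighbors' interval, the neighbors are
# monotone without it, AND the surrounding context is itself
# non-decreasing — the last condition keeps the terminal markers of a
# genuinely inverted block (whose neighbors belong to a decreasing run)
# out of the singleton class.
.find_singletons <- function(cm) {
  m <- length(cm)
  if (m < 3L) return(integer(0))
  i <- 2:(m - 1L)
  prev <- cm[i - 1L]
  nxt <- cm[i + 1L]
  d <- diff(cm)
  # context must be strictly increasing: a tie (co-located binned markers)
  # next to the candidate is ambiguous and may be the edge of an inverted
  # block, so it is left for segmentation to decide
  ctx_left <- c(TRUE, d[seq_len(m - 3L)] > 0)            # cm[i-2] < cm[i-1]
  ctx_right <- if (m >= 4L) c(d[3:(m - 1L)] > 0, TRUE) else TRUE
  # ctx_right: cm[i+1] < cm[i+2]
  out <- i[prev <= nxt & (cm[i] < prev | cm[i] > nxt) &
             ctx_left & ctx_right]
  out
}

# Maximal decreasing runs -> candidate inverted blocks; ties (diff == 0,
# typically co-located binned markers) are tolerated inside a decreasing
# run, but a run must contain at least one strict decrease. Remaining
# markers form monotone non-decreasing runs, split further at forward cM
# jumps larger than `jump_cM` so that a displaced block does not get
# absorbed into its neighbor's run.
.segment_runs <- function(cm, jump_cM = Inf) {
  m <- length(cm)
  if (m == 1L) {
    return(data.frame(from = 1L, to = 1L, dir = "inc"))
  }
  d <- diff(cm)
  dec <- d <= 0
  runs <- rle(dec)
  # demote runs that are mostly ties: a credible inverted block shows at
  # least two strict decreases unless it is a pure two-marker decrease
  ends0 <- cumsum(runs$lengths)
  starts0 <- ends0 - runs$lengths + 1L
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    dd <- d[starts0[k]:ends0[k]]
    if (any(dd == 0) && sum(dd < 0) < 2L) runs$values[k] <- FALSE
  }
  runs <- rle(inverse.rle(runs))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  segs <- list()
  add_inc <- function(from, to) {
    while (from <= to) {
      jumps <- which(diff(cm[from:to]) > jump_cM)
      stop_at <- if (length(jumps)) from + jumps[1L] - 1L else to
      segs[[length(segs) + 1L]] <<- data.frame(from = from, to = stop_at,
                                               dir = "inc")
      from <- stop_at + 1L
    }
  }
  cursor <- 1L
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    a <- starts[k]          # first decreasing pair index
    b <- ends[k] + 1L       # marker index of run end
    if (a > cursor) add_inc(cursor, a - 1L)
    segs[[length(segs) + 1L]] <- data.frame(from = a, to = b, dir = "dec")
    cursor <- b + 1L
  }
  if (cursor <= m) add_inc(cursor, m)
  do.call(rbind, segs)
}

# A two-marker decreasing "run" that is not flank-consistent is a junction
# between displaced runs, not an inversion: donate its first marker to the
# left run and its second to the right run when monotone-compatible, so
# displaced blocks keep their exact marker boundaries.
.repair_junctions <- function(segs, cm) {
  if (nrow(segs) < 2L) return(segs)
  repeat {
    changed <- FALSE
    for (s in seq_len(nrow(segs))) {
      if (segs$dir[s] != "dec") next
      idx <- segs$from[s]:segs$to[s]
      if (length(idx) != 2L) next
      left_hi <- if (s > 1L) max(cm[segs$from[s - 1L]:segs$to[s - 1L]])
                 else NULL
      right_lo <- if (s < nrow(segs))
        min(cm[segs$from[s + 1L]:segs$to[s + 1L]]) else NULL
      between <- (is.null(left_hi) || min(cm[idx]) >= left_hi - 1e-9) &&
        (is.null(right_lo) || max(cm[idx]) <= right_lo + 1e-9)
      if (between) next
      give_left <- !is.null(left_hi) && segs$dir[s - 1L] == "inc" &&
        cm[idx[1L]] >= left_hi - 1e-9
      give_right <- !is.null(right_lo) && segs$dir[s + 1L] == "inc" &&
        cm[idx[2L]] <= right_lo + 1e-9
      if (!give_left && !give_right) next
      if (give_left) segs$to[s - 1L] <- idx[1L]
      if (give_right) segs$from[s + 1L] <- idx[2L]
      keep_from <- if (give_left) idx[2L] else idx[1L]
      keep_to <- if (give_right) idx[1L] else idx[2L]
      if (give_left && give_right) {
        segs <- segs[-s, ]
      } else {
        segs$from[s] <- keep_from
        segs$to[s] <- keep_to
        segs$dir[s] <- "inc"
      }
      changed <- TRUE
      break
    }
    if (!changed) break
  }
  segs
}

#' Detect assembly regions discordant with a linkage map
#'
#' Compares genetic order (one linkage map) against physical order (one
#' placement) chromosome by chromosome. Markers whose linkage group differs
#' from the chromosome's assigned group form maximal same-group runs and
#' yield `MOVE` entries (single markers allowed; internally reversed runs
#' become `MOVE_AND_REORIENT`). The remaining markers are segmented into
#' maximal monotone runs of genetic position: strictly decreasing runs of
#' at least `min_run` markers yield `REORIENT`; non-decreasing runs flanked
#' on both sides whose cM interval does not lie between its physical
#' neighbors' yield `REPOSITION_WITHIN`. Lone outlier markers are reported
#' as singletons, never as corrections. A chromosome whose cM-vs-bp rank
#' correlation is negative is flagged as whole-chromosome orientation and
#' analysed in the reversed sense rather than reported as per-segment
#' noise. Chromosomes accumulating more than `complex_threshold` entries
#' collapse to a single `COMPLEX` entry spanning them.
#'
#' @param map A `linkage_map`.
#' @param placement A [physical_placement()].
#' @param min_run Minimum markers in a REORIENT run (default 2).
#' @param complex_threshold Entries per chromosome above which the
#'   chromosome collapses to one COMPLEX entry (default 5).
#' @param jump_cM Forward cM jump at which a monotone run is split so a
#'   displaced block is not absorbed into a neighboring run (default 10).
#' @param assignment Optional precomputed result of
#'   [assign_groups_to_chromosomes()].
#' @param support Support label stamped on the entries.
#' @return List of class `concordance_result`: `ledger`
#'   (a [correction_ledger()]), `singletons` (data.frame), and
#'   `chromosome_orientation` (named `+`/`-` per chromosome).
#' @export
detect_corrections <- function(map, placement, min_run = 2L,
                               complex_threshold = 5L, jump_cM = 10,
                               assignment = NULL,
                               support = "POP1_ONLY") {
  pl <- as.data.frame(placement)
  loci <- map$loci
  shared <- merge(loci, pl, by = "marker_id")
  if (!nrow(shared)) stop("map and placement share no markers")
  if (is.null(assignment)) {
    assignment <- assign_groups_to_chromosomes(map, placement)
  }
  asg <- assignment$assignment
  group_of_chrom <- setNames(names(asg), asg)
  entries <- list()
  singles <- list()
  orientation <- c()
  for (ch in sort(unique(shared$chromosome))) {
    dat <- shared[shared$chromosome == ch, ]
    dat <- dat[order(dat$position), ]
    own_group <- group_of_chrom[ch]
    if (is.na(own_group)) next
    foreign <- dat$group != own_group
    # (a) MOVE runs: maximal runs of the same foreign group
    if (any(foreign)) {
      runs <- rle(paste0(foreign, "|", dat$group))
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (k in seq_along(runs$values)) {
        if (!startsWith(runs$values[k], "TRUE")) next
        idx <- starts[k]:ends[k]
        grp <- dat$group[idx[1L]]
        tgt <- unname(asg[grp])
        # unassigned group, or a second group claiming this chromosome
        # (an assignment conflict, not a move): no entry
        if (is.na(tgt) || tgt == ch) next
        cm_run <- dat$cM[idx]
        reversed <- length(idx) >= 2L && all(diff(cm_run) < 0)
        entries[[length(entries) + 1L]] <- data.frame(
          chromosome = ch, first_marker = dat$marker_id[idx[1L]],
          last_marker = dat$marker_id[idx[length(idx)]],
          span_start = dat$position[idx[1L]],
          span_end = dat$position[idx[length(idx)]],
          action = if (reversed) "MOVE_AND_REORIENT" else "MOVE",
          target = tgt, stringsAsFactors = FALSE)
      }
    }
    # (b) native markers: monotone-run segmentation of genetic position
    nat <- dat[!foreign, ]
    if (nrow(nat) < 2L) next
    rk <- suppressWarnings(cor(nat$cM, nat$position, method = "spearman"))
    flip <- !is.na(rk) && rk < 0
    orientation[ch] <- if (flip) "-" else "+"
    cm <- if (flip) -nat$cM else nat$cM
    sing <- .find_singletons(cm)
    if (length(sing)) {
      singles[[length(singles) + 1L]] <- data.frame(
        chromosome = ch, marker_id = nat$marker_id[sing],
        position = nat$position[sing], cM = nat$cM[sing],
        stringsAsFactors = FALSE)
    }
    keep <- setdiff(seq_len(nrow(nat)), sing)
    nat2 <- nat[keep, ]
    cm2 <- cm[keep]
    if (nrow(nat2) < 2L) next
    segs <- .segment_runs(cm2, jump_cM = jump_cM)
    segs <- .repair_junctions(segs, cm2)
    eps <- 1e-9
    for (s in seq_len(nrow(segs))) {
      idx <- segs$from[s]:segs$to[s]
      n_mk <- length(idx)
      run_lo <- min(cm2[idx]); run_hi <- max(cm2[idx])
      left_hi <- if (s > 1L)
        max(cm2[segs$from[s - 1L]:segs$to[s - 1L]]) else NULL
      right_lo <- if (s < nrow(segs))
        min(cm2[segs$from[s + 1L]:segs$to[s + 1L]]) else NULL
      between <- (is.null(left_hi) || run_lo >= left_hi - eps) &&
        (is.null(right_lo) || run_hi <= right_lo + eps)
      if (segs$dir[s] == "dec") {
        # a genuine in-place inversion is flanked consistently: its cM
        # interval fits between its neighbors'. A decreasing junction
        # between two displaced runs does not, and is not an inversion.
        if (n_mk < min_run || !between) next
        entries[[length(entries) + 1L]] <- data.frame(
          chromosome = ch, first_marker = nat2$marker_id[idx[1L]],
          last_marker = nat2$marker_id[idx[n_mk]],
          span_start = nat2$position[idx[1L]],
          span_end = nat2$position[idx[n_mk]],
          action = "REORIENT", target = NA_character_,
          stringsAsFactors = FALSE)
      } else if (s > 1L && s < nrow(segs)) {
        # displaced monotone run: cM interval not between both flanks'
        # (terminal runs have only one physical neighbor and are exempt)
        if (between || n_mk < min_run) next
        entries[[length(entries) + 1L]] <- data.frame(
          chromosome = ch, first_marker = nat2$marker_id[idx[1L]],
          last_marker = nat2$marker_id[idx[n_mk]],
          span_start = nat2$position[idx[1L]],
          span_end = nat2$position[idx[n_mk]],
          action = "REPOSITION_WITHIN", target = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  ent <- if (length(entries)) do.call(rbind, entries) else
    data.frame(chromosome = character(0), first_marker = character(0),
               last_marker = character(0), span_start = numeric(0),
               span_end = numeric(0), action = character(0),
               target = character(0), stringsAsFactors = FALSE)
  # COMPLEX collapse
  if (nrow(ent)) {
    keep <- rep(TRUE, nrow(ent))
    extra <- list()
    for (ch in unique(ent$chromosome)) {
      rows <- which(ent$chromosome == ch)
      if (length(rows) > complex_threshold) {
        keep[rows] <- FALSE
        extra[[length(extra) + 1L]] <- data.frame(
          chromosome = ch,
          first_marker = ent$first_marker[rows[
            which.min(ent$span_start[rows])]],
          last_marker = ent$last_marker[rows[
            which.max(ent$span_end[rows])]],
          span_start = min(ent$span_start[rows]),
          span_end = max(ent$span_end[rows]),
          action = "COMPLEX", target = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
    ent <- rbind(ent[keep, ], do.call(rbind, extra))
    ent <- ent[order(ent$chromosome, ent$span_start), ]
  }
  structure(list(ledger = correction_ledger(ent, support),
                 singletons = if (length(singles)) do.call(rbind, singles)
                              else NULL,
                 chromosome_orientation = orientation,
                 assignment = assignment),
            class = "concordance_result")
}

#' Merge two single-population ledgers into a supported ledger
#'
#' Entries with the same action and overlapping physical spans on the same
#' chromosome in both ledgers merge to one `BOTH` entry over the
#' intersection's bounding markers; unmatched entries keep their
#' single-population support.
#'
#' @param l1,l2 `correction_ledger`s derived from the same placement.
#' @return A merged `correction_ledger`.
#' @export
merge_support <- function(l1, l2) {
  e1 <- l1$entries
  e2 <- l2$entries
  if (nrow(e1)) e1$support <- "POP1_ONLY"
  if (nrow(e2)) e2$support <- "POP2_ONLY"
  used2 <- rep(FALSE, nrow(e2))
  out <- list()
  for (i in seq_len(nrow(e1))) {
    hit <- which(!used2 &
                   e2$chromosome == e1$chromosome[i] &
                   e2$action == e1$action[i] &
                   e2$span_start <= e1$span_end[i] &
                   e2$span_end >= e1$span_start[i])
    if (length(hit)) {
      j <- hit[1L]
      used2[j] <- TRUE
      a <- max(e1$span_start[i], e2$span_start[j])
      b <- min(e1$span_end[i], e2$span_end[j])
      fm <- if (e1$span_start[i] >= e2$span_start[j])
        e1$first_marker[i] else e2$first_marker[j]
      lm <- if (e1$span_end[i] <= e2$span_end[j])
        e1$last_marker[i] else e2$last_marker[j]
      out[[length(out) + 1L]] <- data.frame(
        chromosome = e1$chromosome[i], first_marker = fm, last_marker = lm,
        span_start = a, span_end = b, action = e1$action[i],
        target = e1$target[i], support = "BOTH", stringsAsFactors = FALSE)
    } else {
      out[[length(out) + 1L]] <- e1[i, ]
    }
  }
  for (j in which(!used2)) out[[length(out) + 1L]] <- e2[j, ]
  ent <- if (length(out)) do.call(rbind, out) else e1
  ent <- ent[order(ent$chromosome, ent$span_start), ]
  lg <- correction_ledger(ent[, setdiff(names(ent), "support")],
                          support = ent$support)
  lg
}

#' Apply a correction ledger to a placement
#'
#' `REORIENT` reflects marker positions within the span (an involution, so
#' re-applying restores the input); `MOVE` and `MOVE_AND_REORIENT` remove
#' the span's markers from the source chromosome and append them past the
#' target chromosome's current end, preserving (for plain moves) or
#' reversing (for move-and-reorient) internal order; `REPOSITION_WITHIN`
#' re-appends the span at its own chromosome's end. `COMPLEX` entries are
#' not mechanically applicable and are skipped with a warning. Overlapping
#' entries are rejected before any mutation. An AGP layout describing the
#' resulting chromosome composition is emitted alongside.
#'
#' @param placement A [physical_placement()].
#' @param ledger A [correction_ledger()].
#' @return List with `placement` (corrected) and `agp` (data.frame layout
#'   consumable by [write_agp()]).
#' @export
apply_corrections <- function(placement, ledger) {
  pl <- as.data.frame(placement)
  ent <- ledger$entries
  if (nrow(ent)) {
    for (ch in unique(ent$chromosome)) {
      rows <- ent[ent$chromosome == ch, ]
      rows <- rows[order(rows$span_start), ]
      if (nrow(rows) > 1L &&
          any(rows$span_start[-1L] <= rows$span_end[-nrow(rows)])) {
        stop("overlapping correction entries on ", ch)
      }
    }
  }
  segments <- list()  # AGP provenance
  for (i in seq_len(nrow(ent))) {
    act <- ent$action[i]
    if (act == "COMPLEX") {
      warning("COMPLEX entry on ", ent$chromosome[i],
              " skipped (not mechanically applicable)")
      next
    }
    ch <- ent$chromosome[i]
    in_span <- pl$chromosome == ch &
      pl$position >= ent$span_start[i] & pl$position <= ent$span_end[i]
    if (!any(in_span)) next
    pos <- pl$position[in_span]
    if (act == "REORIENT") {
      pl$position[in_span] <- ent$span_start[i] + ent$span_end[i] - pos
      segments[[length(segments) + 1L]] <- data.frame(
        object = ch, source = ch, src_start = ent$span_start[i],
        src_end = ent$span_end[i], orientation = "-")
    } else {
      tgt <- if (act == "REPOSITION_WITHIN") ch else ent$target[i]
      new_off <- pos - ent$span_start[i] + 1
      ori <- "+"
      if (act == "MOVE_AND_REORIENT") {
        new_off <- ent$span_end[i] - pos + 1
        ori <- "-"
      }
      tgt_max <- if (any(pl$chromosome == tgt & !in_span))
        max(pl$position[pl$chromosome == tgt & !in_span]) else 0
      pl$chromosome[in_span] <- tgt
      pl$position[in_span] <- tgt_max + new_off
      segments[[length(segments) + 1L]] <- data.frame(
        object = tgt, source = ch, src_start = ent$span_start[i],
        src_end = ent$span_end[i], orientation = ori)
    }
  }
  out <- physical_placement(pl$marker_id, pl$chromosome, pl$position,
                            assembly_id = paste0(
                              attr(placement, "assembly_id"), "_corrected"))
  agp <- .agp_from_ledger(placement, ledger)
  list(placement = out, agp = agp)
}

# Decompose each chromosome into ordered pieces implied by the ledger:
# REORIENT splits the native backbone and flips the middle piece in place;
# moves cut the piece out and append it to the target's piece list. Object
# coordinates are laid out consecutively with 100-bp map gaps.
.agp_from_ledger <- function(placement, ledger) {
  pl <- as.data.frame(placement)
  chroms <- sort(unique(pl$chromosome))
  pieces <- lapply(chroms, function(ch) {
    data.frame(source = ch, s = 1,
               e = max(pl$position[pl$chromosome == ch]),
               orientation = "+", stringsAsFactors = FALSE)
  })
  names(pieces) <- chroms
  split_piece <- function(ch, a, b) {
    # split the native piece of `ch` containing [a, b]; return index of
    # the middle piece after splitting
    d <- pieces[[ch]]
    k <- which(d$source == ch & d$s <= a & d$e >= b & d$orientation == "+")
    if (!length(k)) return(NA_integer_)
    k <- k[1L]
    row <- d[k, ]
    parts <- list()
    if (row$s < a) parts[[length(parts) + 1L]] <-
      data.frame(source = ch, s = row$s, e = a - 1, orientation = "+")
    mid_at <- length(parts) + 1L
    parts[[mid_at]] <- data.frame(source = ch, s = a, e = b,
                                  orientation = "+")
    if (row$e > b) parts[[length(parts) + 1L]] <-
      data.frame(source = ch, s = b + 1, e = row$e, orientation = "+")
    new <- do.call(rbind, parts)
    pieces[[ch]] <<- rbind(if (k > 1) d[seq_len(k - 1L), ], new,
                           if (k < nrow(d)) d[(k + 1L):nrow(d), ])
    k + mid_at - 1L
  }
  ent <- ledger$entries
  for (i in seq_len(nrow(ent))) {
    act <- ent$action[i]
    if (act == "COMPLEX") next
    ch <- ent$chromosome[i]
    k <- split_piece(ch, ent$span_start[i], ent$span_end[i])
    if (is.na(k)) next
    if (act == "REORIENT") {
      pieces[[ch]]$orientation[k] <- "-"
    } else {
      tgt <- if (act == "REPOSITION_WITHIN" || is.na(ent$target[i]))
        ch else ent$target[i]
      piece <- pieces[[ch]][k, ]
      piece$orientation <- if (act == "MOVE_AND_REORIENT") "-" else "+"
      pieces[[ch]] <- pieces[[ch]][-k, ]
      pieces[[tgt]] <- rbind(pieces[[tgt]], piece)
    }
  }
  rows <- list()
  for (ch in chroms) {
    d <- pieces[[ch]]
    span <- d$e - d$s + 1
    beg <- cumsum(c(1, head(span, -1) + 100))
    rows[[length(rows) + 1L]] <- data.frame(
      object = ch, object_beg = beg, object_end = beg + span - 1,
      component_id = d$source, component_beg = d$s, component_end = d$e,
      orientation = d$orientation, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
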