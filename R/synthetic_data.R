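#' Define a model genome for simulation
#'
#' A model genome is a set of chromosomes, each with a physical length, a
#' monotone piecewise-linear true Marey map (bp -> cM knots, first knot at
#' (1, 0)), and a sorted list of marker positions. The Marey map encodes the
#' euchromatin/heterochromatin recombination-rate contrast: a low-slope
#' middle block flanked by high-slope arms.
#'
#' @param chromosomes List of chromosome descriptors, each a list with
#'   `name`, `length` (bp), `knots` (matrix/data.frame with columns `bp`,
#'   `cM`, monotone non-decreasing, first row `(1, 0)`), and `markers`
#'   (sorted bp vector).
#' @return Object of class `genome_model`.
#' @export
genome_model <- function(chromosomes) {
  for (ch in chromosomes) {
    stopifnot(!is.null(ch$name), !is.null(ch$length),
              !is.null(ch$knots), !is.null(ch$markers))
    kn <- as.data.frame(ch$knots)
    if (kn$bp[1L] != 1 || kn$cM[1L] != 0) {
      stop("first Marey knot must be (1, 0) on ", ch$name)
    }
    if (is.unsorted(kn$bp) || is.unsorted(kn$cM)) {
      stop("Marey knots must be monotone non-decreasing on ", ch$name)
    }
    if (is.unsorted(ch$markers)) stop("marker positions must be sorted")
  }
  structure(list(chromosomes = chromosomes), class = "genome_model")
}

#' True genetic position of physical coordinates under a genome model
#'
#' Linear interpolation of the chromosome's Marey knots; coordinates past the
#' last knot extend with the terminal slope.
#'
#' @param model A [genome_model()].
#' @param chromosome Chromosome name.
#' @param bp Physical positions.
#' @return Genetic positions in cM.
#' @export
true_cM <- function(model, chromosome, bp) {
  ch <- NULL
  for (c0 in model$chromosomes) if (c0$name == chromosome) ch <- c0
  if (is.null(ch)) stop("unknown chromosome: ", chromosome)
  kn <- as.data.frame(ch$knots)
  stats::approx(kn$bp, kn$cM, xout = bp, rule = 2)$y +
    pmax(bp - max(kn$bp), 0) *
      (kn$cM[nrow(kn)] - kn$cM[nrow(kn) - 1L]) /
      (kn$bp[nrow(kn)] - kn$bp[nrow(kn) - 1L])
}

#' Default desk-scale model genome
#'
#' Five chromosomes of 40-60 Mb and 100-130 cM, each with one
#' low-recombination middle block (slope ratio 1:10 against the arms) and
#' 500 markers placed uniformly at random, mimicking the structure of a
#' small plant genome with pericentromeric heterochromatin.
#'
#' @param n_chromosomes,n_markers Number of chromosomes and markers per
#'   chromosome.
#' @param seed Integer seed controlling lengths, block bounds and marker
#'   placement.
#' @return A [genome_model()].
#' @export
default_genome <- function(n_chromosomes = 5, n_markers = 500, seed = 1) {
  set.seed(seed)
  chroms <- vector("list", n_chromosomes)
  for (k in seq_len(n_chromosomes)) {
    len <- round(runif(1, 40e6, 60e6))
    total_cM <- runif(1, 100, 130)
    het_lo <- runif(1, 0.25, 0.40) * len
    het_hi <- runif(1, 0.60, 0.75) * len
    # slope ratio 1:10 between het block and euchromatic arms
    arm_bp <- (het_lo - 1) + (len - het_hi)
    het_bp <- het_hi - het_lo
    s_arm <- total_cM / (arm_bp + het_bp / 10)
    s_het <- s_arm / 10
    cm_lo <- s_arm * (het_lo - 1)
    cm_hi <- cm_lo + s_het * het_bp
    knots <- data.frame(bp = c(1, het_lo, het_hi, len),
                        cM = c(0, cm_lo, cm_hi,
                               cm_hi + s_arm * (len - het_hi)))
    markers <- sort(sample.int(len, n_markers))
    chroms[[k]] <- list(name = sprintf("chr%02d", k), length = len,
                        knots = knots, markers = markers)
  }
  genome_model(chroms)
}

# One meiosis for all lines at once: the gamete haplotype choice along a
# chromosome is a two-state Markov chain (Haldane, no interference), with
# switch probability between adjacent markers equal to the Haldane
# recombination fraction of their true genetic separation.
.gametes <- function(h1, h2, switch_p) {
  n <- nrow(h1)
  m <- ncol(h1)
  start <- rbinom(n, 1L, 0.5)
  state <- matrix(0L, n, m)
  state[, 1L] <- start
  if (m > 1L) {
    sw <- matrix(rbinom(n * (m - 1L), 1L, rep(switch_p, each = n)),
                 nrow = n)
    for (j in 2:m) state[, j] <- state[, j - 1L] + sw[, j - 1L]
    state <- state %% 2L
  }
  state * h2 + (1L - state) * h1
}

#' Simulate an F(1+k)-derived RIL population
#'
#' Each line descends from a single F1 by `selfing_generations` rounds of
#' self-fertilization. Crossovers follow a no-interference (Haldane) point
#' process on the true genetic scale of the genome model, realized at marker
#' resolution as a two-state Markov chain whose switch probabilities are the
#' Haldane recombination fractions of adjacent marker separations. Calls are
#' then perturbed: with probability `error_rate` a call is resampled to a
#' different symbol, and with probability `missing_rate` it is masked.
#'
#' @param model A [genome_model()].
#' @param n_lines Number of RILs (>= 1).
#' @param selfing_generations Rounds of selfing past F1 (4 gives F5-derived
#'   lines, the default).
#' @param error_rate,missing_rate Per-call perturbation probabilities.
#' @param distortion Optional named per-marker viability weight in (0, 1]:
#'   at each affected marker, lines carrying the B allele are resampled as
#'   whole lines with the given retention probability (a crude gametic /
#'   zygotic selection stand-in producing segregation distortion).
#' @param seed Integer seed.
#' @param population_id Label for the output matrix.
#' @return A [genotype_matrix()] whose markers are named
#'   `<chromosome>_<bp>`.
#' @export
simulate_population <- function(model, n_lines,
                                selfing_generations = 4,
                                error_rate = 0, missing_rate = 0,
                                distortion = NULL, seed = 1,
                                population_id = "simpop") {
  if (n_lines < 1) stop("n_lines must be >= 1")
  if (selfing_generations < 1) stop("selfing_generations must be >= 1")
  for (p in c(error_rate, missing_rate)) {
    if (p < 0 || p > 1) stop("rates must lie in [0, 1]")
  }
  set.seed(seed)
  blocks <- list()
  for (ch in model$chromosomes) {
    m <- length(ch$markers)
    cm <- true_cM(model, ch$name, ch$markers)
    d_morgan <- diff(cm) / 100
    switch_p <- (1 - exp(-2 * d_morgan)) / 2
    h1 <- matrix(0L, n_lines, m)
    h2 <- matrix(1L, n_lines, m)
    for (g in seq_len(selfing_generations)) {
      g1 <- .gametes(h1, h2, switch_p)
      g2 <- .gametes(h1, h2, switch_p)
      h1 <- g1
      h2 <- g2
    }
    dose <- h1 + h2
    calls <- matrix("H", n_lines, m)
    calls[dose == 0L] <- "A"
    calls[dose == 2L] <- "B"
    colnames(calls) <- sprintf("%s_%d", ch$name, ch$markers)
    blocks[[ch$name]] <- calls
  }
  calls <- t(do.call(cbind, blocks))  # markers x lines
  colnames(calls) <- sprintf("L%04d", seq_len(n_lines))
  if (!is.null(distortion)) {
    for (mk in intersect(names(distortion), rownames(calls))) {
      w <- distortion[[mk]]
      hit <- calls[mk, ] == "B" & runif(ncol(calls)) > w
      if (any(hit)) calls[mk, hit] <- "A"
    }
  }
  if (error_rate > 0) {
    err <- which(matrix(runif(length(calls)) < error_rate, nrow(calls)))
    for (k in err) {
      calls[k] <- sample(setdiff(c("A", "B", "H"), calls[k]), 1L)
    }
  }
  if (missing_rate > 0) {
    calls[matrix(runif(length(calls)) < missing_rate, nrow(calls))] <-
      "MISSING"
  }
  genotype_matrix(calls, population_id)
}

#' True physical placement of a genome model's markers
#'
#' @param model A [genome_model()].
#' @param assembly_id Assembly label.
#' @return A [physical_placement()] with marker ids `<chromosome>_<bp>`.
#' @export
model_placement <- function(model, assembly_id = "truth") {
  mk <- ch <- character(0)
  pos <- numeric(0)
  for (c0 in model$chromosomes) {
    mk <- c(mk, sprintf("%s_%d", c0$name, c0$markers))
    ch <- c(ch, rep(c0$name, length(c0$markers)))
    pos <- c(pos, c0$markers)
  }
  physical_placement(mk, ch, pos, assembly_id = assembly_id)
}

#' Linkage map implied by a genome model's truth
#'
#' One group per chromosome with every marker at its true genetic position;
#' used to exercise the concordance stage independently of the mapping
#' stage.
#'
#' @param model A [genome_model()].
#' @param population_id Label.
#' @return A `linkage_map` (see [linkage_map_obj()]).
#' @export
model_truth_map <- function(model, population_id = "truth") {
  loci <- do.call(rbind, lapply(model$chromosomes, function(ch) {
    data.frame(group = ch$name,
               marker_id = sprintf("%s_%d", ch$name, ch$markers),
               cM = true_cM(model, ch$name, ch$markers),
               stringsAsFactors = FALSE)
  }))
  linkage_map_obj(loci, population_id)
}

# sample `n` disjoint marker-index intervals of sizes in [lo, hi], at
# least two untouched markers between intervals; `taken` is a mutable
# environment holding one logical vector per chromosome so successive
# calls for different error classes stay disjoint
.sample_intervals <- function(chrom_sizes, taken, n, lo, hi,
                              cap = Inf, per_chrom = NULL) {
  out <- list()
  chrom_names <- names(chrom_sizes)
  if (is.null(per_chrom)) {
    per_chrom <- setNames(integer(length(chrom_sizes)), chrom_names)
  }
  attempts <- 0L
  while (length(out) < n) {
    attempts <- attempts + 1L
    if (attempts > 5000L) stop("infeasible corruption counts for genome")
    ch <- chrom_names[sample.int(length(chrom_names), 1L)]
    if (per_chrom[ch] >= cap) next
    m <- chrom_sizes[[ch]]
    w <- if (lo >= hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
    if (m < w + 4L) next
    a <- sample.int(m - w + 1L, 1L)
    b <- a + w - 1L
    lo_pad <- max(1L, a - 2L)
    hi_pad <- min(m, b + 2L)
    if (any(taken[[ch]][lo_pad:hi_pad])) next
    taken[[ch]][lo_pad:hi_pad] <- TRUE
    per_chrom[ch] <- per_chrom[ch] + 1L
    out[[length(out) + 1L]] <- list(chromosome = ch, from = a, to = b)
  }
  out
}

#' Plant assembly errors into a true placement
#'
#' Selects disjoint, well-separated marker intervals and corrupts them:
#' inversions reflect physical positions within the interval;
#' translocations reassign the interval to the end of a different
#' chromosome (half of them also inverted); detachments remove the interval
#' into a named scaffold with 1-based offsets. A truth ledger of
#' Table-2-style correction entries (the corrections that would restore the
#' truth) is emitted, and the generator verifies that applying it to the
#' corrupted placement restores the true chromosome assignment and marker
#' order.
#'
#' @param true_assembly A [physical_placement()] (e.g. [model_placement()]).
#' @param n_inversions,n_translocations,n_detached_scaffolds Error counts.
#' @param seed Integer seed.
#' @param inversion_size,translocation_size,detachment_size Length-2 integer
#'   ranges of interval sizes in markers.
#' @return A list of class `truth_set` with elements `true_assembly`,
#'   `corrupted_assembly`, `planted_errors` (a `correction_ledger`),
#'   `detached_scaffolds` (a [scaffold_set()]) and `detached_truth`
#'   (data.frame scaffold -> true chromosome).
#' @export
corrupt_assembly <- function(true_assembly, n_inversions = 8,
                             n_translocations = 4,
                             n_detached_scaffolds = 10, seed = 1,
                             inversion_size = c(5L, 12L),
                             translocation_size = c(3L, 8L),
                             detachment_size = c(2L, 5L)) {
  set.seed(seed)
  pl <- as.data.frame(true_assembly)
  pl <- pl[order(pl$chromosome, pl$position), ]
  chroms <- unique(pl$chromosome)
  if (length(chroms) < 2 && n_translocations > 0) {
    stop("translocations need at least two chromosomes")
  }
  sizes <- as.list(vapply(chroms, function(ch) sum(pl$chromosome == ch),
                          integer(1)))
  names(sizes) <- chroms
  taken <- lapply(sizes, function(m) logical(m))
  # entry-generating intervals are capped per chromosome so the ledger
  # never trips the COMPLEX collapse under default counts
  iv_inv <- .sample_intervals(sizes, taken, n_inversions,
                              inversion_size[1], inversion_size[2], cap = 3L)
  for (s in iv_inv) taken[[s$chromosome]][
    max(1, s$from - 2):min(sizes[[s$chromosome]], s$to + 2)] <- TRUE
  iv_tra <- .sample_intervals(sizes, taken, n_translocations,
                              translocation_size[1], translocation_size[2])
  for (s in iv_tra) taken[[s$chromosome]][
    max(1, s$from - 2):min(sizes[[s$chromosome]], s$to + 2)] <- TRUE
  iv_det <- .sample_intervals(sizes, taken, n_detached_scaffolds,
                              detachment_size[1], detachment_size[2])
  idx_by_chrom <- split(seq_len(nrow(pl)), pl$chromosome)
  entry <- list()
  corrupted <- pl
  detached_scaf <- data.frame(scaffold_id = character(0), length = numeric(0))
  detached_mk <- data.frame(scaffold_id = character(0),
                            marker_id = character(0), offset = numeric(0))
  detached_truth <- data.frame(scaffold_id = character(0),
                               chromosome = character(0))
  entry_count <- setNames(integer(length(chroms)), chroms)
  drop_rows <- integer(0)
  for (span in iv_inv) {
    rows <- idx_by_chrom[[span$chromosome]][span$from:span$to]
    mk <- pl$marker_id[rows]
    pos <- pl$position[rows]
    src <- span$chromosome
    corrupted$position[rows] <- pos[1L] + pos[length(pos)] - pos
    entry_count[src] <- entry_count[src] + 1L
    # boundary markers named in corrupted-assembly order (reflection puts
    # the true last marker first), matching what detection sees
    entry[[length(entry) + 1L]] <- data.frame(
      chromosome = src, first_marker = mk[length(mk)],
      last_marker = mk[1L],
      span_start = pos[1L], span_end = pos[length(pos)],
      action = "REORIENT", target = NA_character_,
      stringsAsFactors = FALSE)
  }
  for (k in seq_along(iv_tra)) {
    span <- iv_tra[[k]]
    rows <- idx_by_chrom[[span$chromosome]][span$from:span$to]
    mk <- pl$marker_id[rows]
    pos <- pl$position[rows]
    src <- span$chromosome
    cand <- setdiff(chroms, src)
    # one block per (source, target) pair: adjacent appended blocks from
    # the same source group would merge into a single detected run
    if (length(entry)) {
      prev <- do.call(rbind, entry)
      used <- prev$chromosome[!is.na(prev$target) & prev$target == src]
      cand <- setdiff(cand, used)
    }
    if (!length(cand)) stop("infeasible translocation targets")
    tgt <- cand[which.min(entry_count[cand])]
    invert <- (k %% 2L == 0L)
    tgt_max <- max(corrupted$position[corrupted$chromosome == tgt])
    off <- pos - pos[1L] + 1L
    if (invert) off <- pos[length(pos)] - pos + 1L
    new_pos <- tgt_max + off
    ord <- order(new_pos)
    corrupted$chromosome[rows] <- tgt
    corrupted$position[rows] <- new_pos
    entry_count[tgt] <- entry_count[tgt] + 1L
    entry[[length(entry) + 1L]] <- data.frame(
      chromosome = tgt, first_marker = mk[ord][1L],
      last_marker = mk[ord][length(mk)],
      span_start = min(new_pos), span_end = max(new_pos),
      action = if (invert) "MOVE_AND_REORIENT" else "MOVE",
      target = src, stringsAsFactors = FALSE)
  }
  for (span in iv_det) {
    rows <- idx_by_chrom[[span$chromosome]][span$from:span$to]
    mk <- pl$marker_id[rows]
    pos <- pl$position[rows]
    sid <- sprintf("scaffold_%03d", nrow(detached_scaf) + 1L)
    margin <- 500
    len <- (pos[length(pos)] - pos[1L]) + 2 * margin
    detached_scaf <- rbind(detached_scaf,
                           data.frame(scaffold_id = sid, length = len))
    detached_mk <- rbind(detached_mk, data.frame(
      scaffold_id = sid, marker_id = mk, offset = pos - pos[1L] + margin))
    detached_truth <- rbind(detached_truth, data.frame(
      scaffold_id = sid, chromosome = span$chromosome))
    drop_rows <- c(drop_rows, rows)
  }
  if (length(drop_rows)) corrupted <- corrupted[-drop_rows, ]
  ledger <- correction_ledger(do.call(rbind, c(entry, list(
    data.frame(chromosome = character(0), first_marker = character(0),
               last_marker = character(0), span_start = numeric(0),
               span_end = numeric(0), action = character(0),
               target = character(0), stringsAsFactors = FALSE)))),
    support = "BOTH")
  corrupted_pl <- physical_placement(
    corrupted$marker_id, corrupted$chromosome, corrupted$position,
    assembly_id = paste0(attr(true_assembly, "assembly_id"), "_corrupted"))
  scafs <- scaffold_set(detached_scaf, detached_mk)
  ts <- structure(list(true_assembly = true_assembly,
                       corrupted_assembly = corrupted_pl,
                       planted_errors = ledger,
                       detached_scaffolds = scafs,
                       detached_truth = detached_truth,
                       seed = seed),
                  class = "truth_set")
  .check_truth_set(ts)
  ts
}

# generator self-check: applying the planted ledger to the corrupted
# placement must restore (i) every marker's true chromosome, (ii) exact
# true positions for markers that never changed chromosome (inversions are
# reflections, hence involutions), and (iii) the true internal order of
# each moved block (its absolute bp differs because moves re-append).
.check_truth_set <- function(ts) {
  res <- suppressWarnings(
    apply_corrections(ts$corrupted_assembly, ts$planted_errors))
  got <- as.data.frame(res$placement)
  want <- as.data.frame(ts$true_assembly)
  want <- want[want$marker_id %in% got$marker_id, ]
  if (!identical(sort(got$marker_id), sort(want$marker_id))) {
    stop("truth-set check failed: marker sets differ")
  }
  gw <- merge(got, want, by = "marker_id", suffixes = c("_got", "_true"))
  if (!all(gw$chromosome_got == gw$chromosome_true)) {
    stop("truth-set check failed: chromosome assignment not restored")
  }
  ent <- ts$planted_errors$entries
  moved_rows <- which(ent$action %in% c("MOVE", "MOVE_AND_REORIENT"))
  cor_df <- as.data.frame(ts$corrupted_assembly)
  moved_mk <- character(0)
  for (i in moved_rows) {
    blk <- cor_df$marker_id[cor_df$chromosome == ent$chromosome[i] &
                              cor_df$position >= ent$span_start[i] &
                              cor_df$position <= ent$span_end[i]]
    moved_mk <- c(moved_mk, blk)
    sub <- gw[gw$marker_id %in% blk, ]
    if (any(rank(sub$position_got) != rank(sub$position_true))) {
      stop("truth-set check failed: moved block order not restored")
    }
  }
  stay <- gw[!(gw$marker_id %in% moved_mk), ]
  if (any(stay$position_got != stay$position_true)) {
    stop("truth-set check failed: positions of unmoved markers changed")
  }
  invisible(TRUE)
}
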