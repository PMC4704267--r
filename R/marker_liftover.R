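#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#'   matchPattern readDNAStringSet writeXStringSet
#' @importFrom BiocGenerics start end width
NULL

.as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
    return(genome)
  }
  if (is.character(genome)) return(DNAStringSet(genome))
  genome
}

.check_primer <- function(p, what) {
  if (!nzchar(p) || grepl("[^ACGT]", p)) {
    stop(what, " must be a nonempty uppercase ACGT string")
  }
  p
}

#' In-silico PCR with exact primer matching
#'
#' Locates all products a primer pair would amplify: the forward primer is
#' matched exactly (no gaps, no mismatches; IUPAC ambiguity codes in the
#' genome count as mismatches) on both strands, and the reverse complement
#' of the reverse primer must match downstream on the same strand within
#' `max_amplicon`. Product coordinates are 1-based inclusive and span the
#' primer outer ends.
#'
#' @param genome A `DNAStringSet`, named character vector of sequences, or
#'   FASTA path.
#' @param forward,reverse Primer sequences (>= 15 bp, uppercase ACGT).
#' @param max_amplicon Maximum product length in bp (default 10000).
#' @return data.frame `chromosome`, `strand`, `start`, `end`, `length`
#'   (zero rows when there is no product).
#' @export
insilico_pcr <- function(genome, forward, reverse, max_amplicon = 10000) {
  genome <- .as_genome(genome)
  .check_primer(forward, "forward primer")
  .check_primer(reverse, "reverse primer")
  if (nchar(forward) < 15 || nchar(reverse) < 15) {
    stop("primers must be at least 15 bp")
  }
  fwd <- DNAString(forward)
  rev_rc <- reverseComplement(DNAString(reverse))
  # minus-strand product: roles swap, i.e. reverse primer anneals to the
  # plus strand (as its reverse complement's reverse...): equivalent to
  # finding `reverse` on the plus strand followed by revcomp(forward)
  rev_p <- DNAString(reverse)
  fwd_rc <- reverseComplement(DNAString(forward))
  out <- list()
  scan <- function(chr, subject, left, right, strand) {
    ls <- start(matchPattern(left, subject, fixed = TRUE))
    if (!length(ls)) return()
    rs <- start(matchPattern(right, subject, fixed = TRUE))
    if (!length(rs)) return()
    re <- rs + length(right) - 1L
    for (s in ls) {
      hit <- re[rs > s & re - s + 1L <= max_amplicon]
      for (e in hit) {
        out[[length(out) + 1L]] <<- data.frame(
          chromosome = chr, strand = strand, start = s, end = e,
          length = e - s + 1L, stringsAsFactors = FALSE)
      }
    }
  }
  for (k in seq_along(genome)) {
    chr <- names(genome)[k]
    subject <- genome[[k]]
    scan(chr, subject, fwd, rev_rc, "+")
    scan(chr, subject, rev_p, fwd_rc, "-")
  }
  if (!length(out)) {
    return(data.frame(chromosome = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$chromosome, res$start, res$strand), ]
}

#' Seeded ungapped alignment of a source sequence
#'
#' Emulates a high-identity megablast search: exact seed words of
#' `seed` bp tiled along the source are looked up in the genome (both
#' strands), each seed hit is extended ungapped along its diagonal over the
#' full source, and hits are retained when overall identity is at least
#' `min_identity` over at least `min_coverage` of the source length.
#' Overlapping hits on one diagonal are merged to the best. Seed words
#' occurring more than `max_seed_hits` times are discarded as
#' low-complexity.
#'
#' @param genome Sequences as in [insilico_pcr()].
#' @param source Source sequence (>= `seed` bp). `N` positions in the
#'   source match anything (used for SNP alleles); ambiguity codes in the
#'   genome count as mismatches.
#' @param seed Seed word length (default 50).
#' @param min_identity Identity cutoff (default 0.99).
#' @param min_coverage Fraction of source length that must align
#'   (default 0.95).
#' @param max_seed_hits Low-complexity guard (default 1000).
#' @return data.frame `chromosome`, `strand`, `start`, `end`, `identity`.
#' @export
match_source <- function(genome, source, seed = 50L, min_identity = 0.99,
                         min_coverage = 0.95, max_seed_hits = 1000L) {
  genome <- .as_genome(genome)
  src <- toupper(source)
  L <- nchar(src)
  if (L < seed) stop("source shorter than seed length")
  offsets <- unique(c(seq(1L, L - seed + 1L, by = seed), L - seed + 1L))
  hits <- list()
  src_fwd <- src
  # minus-strand hits: align revcomp(source) to the plus strand
  src_rev <- as.character(reverseComplement(DNAString(src)))
  for (k in seq_along(genome)) {
    chr <- names(genome)[k]
    subj <- as.character(genome[[k]])
    for (strand in c("+", "-")) {
      s_use <- if (strand == "+") src_fwd else src_rev
      starts_seen <- integer(0)
      for (off in offsets) {
        word <- substr(s_use, off, off + seed - 1L)
        if (grepl("N", word, fixed = TRUE)) next
        m <- matchPattern(DNAString(word), genome[[k]], fixed = TRUE)
        if (length(m) > max_seed_hits) next
        for (st in start(m)) {
          a_start <- st - off + 1L   # diagonal: genome pos of source pos 1
          if (a_start %in% starts_seen) next
          starts_seen <- c(starts_seen, a_start)
          g_from <- max(a_start, 1L)
          g_to <- min(a_start + L - 1L, nchar(subj))
          cov <- (g_to - g_from + 1L) / L
          if (cov < min_coverage) next
          s_from <- g_from - a_start + 1L
          s_chars <- strsplit(substr(s_use, s_from,
                                     s_from + (g_to - g_from)), "")[[1L]]
          g_chars <- strsplit(substr(subj, g_from, g_to), "")[[1L]]
          match_ok <- s_chars == g_chars | s_chars == "N"
          ident <- sum(match_ok) / length(s_chars)
          if (ident >= min_identity) {
            hits[[length(hits) + 1L]] <- data.frame(
              chromosome = chr, strand = strand, start = g_from,
              end = g_to, identity = ident, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(chromosome = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      identity = numeric(0), stringsAsFactors = FALSE))
  }
  res <- unique(do.call(rbind, hits))
  # merge overlapping hits, keeping the best identity
  res <- res[order(res$chromosome, res$start, -res$identity), ]
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))[-1L]) {
    prev <- max(which(keep[seq_len(i - 1L)]))
    if (res$chromosome[i] == res$chromosome[prev] &&
        res$start[i] <= res$end[prev]) {
      if (res$identity[i] > res$identity[prev]) {
        keep[prev] <- FALSE
      } else {
        keep[i] <- FALSE
      }
    }
  }
  res <- res[keep, ]
  rownames(res) <- NULL
  res
}

#' SSR marker descriptor
#'
#' @param ssr_id Identifier.
#' @param forward_primer,reverse_primer Primer sequences (uppercase ACGT).
#' @param motif Repeat unit of 2-4 bp.
#' @param source_sequence Source (flanking) sequence of the locus.
#' @param expected_amplicon_length Expected e-PCR product length in bp.
#' @return Object of class `ssr_descriptor`.
#' @export
ssr_descriptor <- function(ssr_id, forward_primer, reverse_primer, motif,
                           source_sequence, expected_amplicon_length) {
  .check_primer(forward_primer, "forward primer")
  .check_primer(reverse_primer, "reverse primer")
  if (!(nchar(motif) %in% 2:4)) {
    stop("motif must be a di-, tri- or tetranucleotide")
  }
  structure(list(ssr_id = ssr_id, forward_primer = forward_primer,
                 reverse_primer = reverse_primer, motif = toupper(motif),
                 source_sequence = toupper(source_sequence),
                 expected_amplicon_length = expected_amplicon_length),
            class = "ssr_descriptor")
}

#' SNP marker descriptor
#'
#' @param snp_id Identifier.
#' @param flank_5prime,flank_3prime Flanking sequences (combined length at
#'   least 50 bp).
#' @param alleles Allele string, e.g. `"A/G"` (informational).
#' @return Object of class `snp_descriptor`.
#' @export
snp_descriptor <- function(snp_id, flank_5prime, flank_3prime,
                           alleles = "N/N") {
  if (nchar(flank_5prime) + nchar(flank_3prime) < 50) {
    stop("combined flanks must be at least 50 bp")
  }
  structure(list(snp_id = snp_id, flank_5prime = toupper(flank_5prime),
                 flank_3prime = toupper(flank_3prime), alleles = alleles),
            class = "snp_descriptor")
}

#' Position an SSR marker on an assembly
#'
#' A genomic region qualifies when (a) the primer pair yields an e-PCR
#' product there, (b) a source-sequence hit overlaps the product, (c) the
#' product length equals the expected amplicon length within
#' `length_tolerance`, and (d) at least `min_motif_copies` tandem copies of
#' the motif lie between the primer inner ends. Exactly one qualifying
#' region gives `UNAMBIGUOUS`; several give `AMBIGUOUS`; none gives
#' `UNPLACED`, with per-criterion diagnostics recording the furthest
#' criterion reached by any product.
#'
#' @param genome Sequences as in [insilico_pcr()].
#' @param ssr An [ssr_descriptor()].
#' @param length_tolerance Allowed deviation from the expected amplicon
#'   length in bp (default 0: the expected length is required exactly).
#' @param min_motif_copies Tandem-copy floor for the motif check
#'   (default 5).
#' @param max_amplicon Passed to [insilico_pcr()].
#' @return List of class `placement_result`: `marker_id`, `status`,
#'   `position` (`chromosome`, `bp` of the product start) when
#'   unambiguous, `diagnostics`.
#' @export
place_ssr <- function(genome, ssr, length_tolerance = 0,
                      min_motif_copies = 5L, max_amplicon = 10000) {
  genome <- .as_genome(genome)
  prods <- insilico_pcr(genome, ssr$forward_primer, ssr$reverse_primer,
                        max_amplicon = max_amplicon)
  diag <- list(n_products = nrow(prods), n_source_hits = 0L,
               n_length_ok = 0L, n_motif_ok = 0L)
  if (!nrow(prods)) {
    return(.placement_result(ssr$ssr_id, "UNPLACED", NULL, diag,
                             failed = "pcr_product"))
  }
  src_hits <- match_source(genome, ssr$source_sequence)
  qual <- logical(nrow(prods))
  for (i in seq_len(nrow(prods))) {
    overlap <- any(src_hits$chromosome == prods$chromosome[i] &
                     src_hits$start <= prods$end[i] &
                     src_hits$end >= prods$start[i])
    if (!overlap) next
    diag$n_source_hits <- diag$n_source_hits + 1L
    if (abs(prods$length[i] - ssr$expected_amplicon_length) >
        length_tolerance) next
    diag$n_length_ok <- diag$n_length_ok + 1L
    inner_from <- prods$start[i] +
      nchar(if (prods$strand[i] == "+") ssr$forward_primer
            else ssr$reverse_primer)
    inner_to <- prods$end[i] -
      nchar(if (prods$strand[i] == "+") ssr$reverse_primer
            else ssr$forward_primer)
    if (inner_to < inner_from) next
    between <- substr(as.character(
      genome[[prods$chromosome[i]]]), inner_from, inner_to)
    motif <- if (prods$strand[i] == "+") ssr$motif else
      as.character(reverseComplement(DNAString(ssr$motif)))
    tandem <- strrep(motif, min_motif_copies)
    if (!grepl(tandem, between, fixed = TRUE)) next
    diag$n_motif_ok <- diag$n_motif_ok + 1L
    qual[i] <- TRUE
  }
  failed <- if (!any(qual)) {
    if (diag$n_source_hits == 0L) "source_overlap"
    else if (diag$n_length_ok == 0L) "amplicon_length"
    else "motif_between_primers"
  } else NA_character_
  n_regions <- sum(qual)
  status <- if (n_regions == 1L) "UNAMBIGUOUS"
            else if (n_regions > 1L) "AMBIGUOUS" else "UNPLACED"
  pos <- if (status == "UNAMBIGUOUS") {
    i <- which(qual)
    list(chromosome = prods$chromosome[i], bp = prods$start[i])
  } else NULL
  .placement_result(ssr$ssr_id, status, pos, diag, failed)
}

#' Position a SNP marker on an assembly by its flanks
#'
#' The flanks are concatenated with one wildcard position at the SNP site
#' and matched with [match_source()]; a single qualifying hit gives
#' `UNAMBIGUOUS` with the wildcard's genomic coordinate as the position.
#'
#' @param genome Sequences as in [insilico_pcr()].
#' @param snp A [snp_descriptor()].
#' @param ... Passed to [match_source()].
#' @return A `placement_result` (see [place_ssr()]).
#' @export
place_snp <- function(genome, snp, ...) {
  genome <- .as_genome(genome)
  query <- paste0(snp$flank_5prime, "N", snp$flank_3prime)
  hits <- match_source(genome, query, ...)
  diag <- list(n_hits = nrow(hits))
  status <- if (nrow(hits) == 1L) "UNAMBIGUOUS"
            else if (nrow(hits) > 1L) "AMBIGUOUS" else "UNPLACED"
  pos <- NULL
  if (status == "UNAMBIGUOUS") {
    off5 <- nchar(snp$flank_5prime)
    bp <- if (hits$strand == "+") hits$start + off5 else
      hits$end - off5
    pos <- list(chromosome = hits$chromosome, bp = bp)
  }
  .placement_result(snp$snp_id, status, pos, diag,
                    failed = if (status == "UNPLACED") "no_hit"
                             else NA_character_)
}

.placement_result <- function(id, status, position, diagnostics, failed) {
  structure(list(marker_id = id, status = status, position = position,
                 diagnostics = diagnostics, failed_criterion = failed),
            class = "placement_result")
}

#' @export
print.placement_result <- function(x, ...) {
  loc <- if (!is.null(x$position))
    sprintf(" at %s:%d", x$position$chromosome, x$position$bp) else ""
  cat(sprintf("<placement_result> %s: %s%s\n", x$marker_id, x$status, loc))
  invisible(x)
}
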