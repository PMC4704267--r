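#' @importFrom stats median cor pchisq rbinom runif setNames
#' @importFrom utils read.table write.table head tail modifyList
NULL

GENO_SYMBOLS <- c("A", "B", "H", "MISSING")

#' Construct a validated RIL genotype matrix
#'
#' The central container of the mapping stage: a markers x lines table of
#' biallelic calls, where `"A"` is the allele of the reference parent, `"B"`
#' the alternate parent, `"H"` a residual heterozygote and `"MISSING"` a
#' failed call.
#'
#' @param calls Character matrix (markers in rows, lines in columns) with
#'   entries in `A`, `B`, `H`, `MISSING`. Row and column names supply marker
#'   and line identifiers unless given explicitly.
#' @param population_id Single string naming the population.
#' @param marker_ids,line_ids Optional identifier vectors overriding dimnames.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `population_id`, `marker_ids`, `line_ids` and `calls`.
#' @export
genotype_matrix <- function(calls, population_id = "pop",
                            marker_ids = rownames(calls),
                            line_ids = colnames(calls)) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix")
  if (is.null(marker_ids) || is.null(line_ids)) {
    stop("marker and line identifiers are required")
  }
  if (anyDuplicated(marker_ids)) {
    stop("duplicate marker_id: ", marker_ids[duplicated(marker_ids)][1L])
  }
  if (anyDuplicated(line_ids)) {
    stop("duplicate line_id: ", line_ids[duplicated(line_ids)][1L])
  }
  bad <- which(!(calls %in% GENO_SYMBOLS))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(calls)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(calls)) + 1L
    stop(sprintf("illegal genotype symbol '%s' at marker '%s', line '%s'",
                 calls[bad[1L]], marker_ids[i], line_ids[j]))
  }
  dimnames(calls) <- list(marker_ids, line_ids)
  structure(list(population_id = population_id,
                 marker_ids = as.character(marker_ids),
                 line_ids = as.character(line_ids),
                 calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> population '%s': %d markers x %d lines\n",
              x$population_id, length(x$marker_ids), length(x$line_ids)))
  invisible(x)
}

#' Read a genotype CSV
#'
#' First column `marker_id`, header row of line identifiers, cells in
#' `A`, `B`, `H` plus the missing spellings `-`, `NA`, `.` (all normalized to
#' `MISSING`). Ragged rows, duplicated identifiers and any other symbol are
#' rejected with the offending cell named.
#'
#' @param path File path.
#' @param population_id Population label attached to the result.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, population_id = "pop") {
  lines <- readLines(path)
  if (!length(lines)) stop("empty genotype file: ", path)
  fields <- strsplit(lines, ",", fixed = TRUE)
  header <- fields[[1L]]
  ncol_expect <- length(header)
  line_ids <- header[-1L]
  body <- fields[-1L]
  nf <- lengths(body)
  if (any(nf != ncol_expect)) {
    k <- which(nf != ncol_expect)[1L]
    stop(sprintf("ragged row %d (marker '%s'): %d fields, expected %d",
                 k + 1L, body[[k]][1L], nf[k], ncol_expect))
  }
  marker_ids <- vapply(body, `[`, character(1), 1L)
  calls <- matrix("", nrow = length(body), ncol = length(line_ids))
  for (k in seq_along(body)) calls[k, ] <- body[[k]][-1L]
  calls[calls %in% c("-", "NA", ".", "")] <- "MISSING"
  bad <- which(!(calls %in% GENO_SYMBOLS))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(calls)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(calls)) + 1L
    stop(sprintf("illegal symbol '%s' at row %d (marker '%s'), column '%s'",
                 calls[bad[1L]], i + 1L, marker_ids[i], line_ids[j]))
  }
  genotype_matrix(calls, population_id,
                  marker_ids = marker_ids, line_ids = line_ids)
}

#' Write a genotype CSV
#'
#' Inverse of [read_genotypes()]; `MISSING` is written as `-`.
#'
#' @param g A [genotype_matrix()].
#' @param path Output file path.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  out <- g$calls
  out[out == "MISSING"] <- "-"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("marker_id", g$line_ids), collapse = ","), con)
  writeLines(paste(g$marker_ids, apply(out, 1L, paste, collapse = ","),
                   sep = ","), con)
  invisible(path)
}

#' Construct a physical placement table
#'
#' Maps markers to 1-based positions on the chromosomes of a named assembly.
#'
#' @param marker_id,chromosome,position Parallel vectors (positions are
#'   1-based bp integers).
#' @param assembly_id Assembly version label.
#' @param sequence_dict Optional character vector of legal chromosome names;
#'   when given, records on other sequences are rejected.
#' @return An object of class `physical_placement`: a data.frame with columns
#'   `marker_id`, `chromosome`, `position` plus attributes `assembly_id` and
#'   `sequence_dict`.
#' @export
physical_placement <- function(marker_id, chromosome, position,
                               assembly_id = "assembly",
                               sequence_dict = NULL) {
  marker_id <- as.character(marker_id)
  chromosome <- as.character(chromosome)
  position <- as.numeric(position)
  stopifnot(length(marker_id) == length(chromosome),
            length(marker_id) == length(position))
  if (anyDuplicated(marker_id)) {
    stop("duplicate marker_id in placement: ",
         marker_id[duplicated(marker_id)][1L])
  }
  if (length(position) && any(position < 1 | position != round(position))) {
    k <- which(position < 1 | position != round(position))[1L]
    stop(sprintf("illegal position %s for marker '%s' (must be integer >= 1)",
                 format(position[k]), marker_id[k]))
  }
  if (!is.null(sequence_dict)) {
    bad <- setdiff(unique(chromosome), sequence_dict)
    if (length(bad)) stop("chromosome not in sequence dictionary: ", bad[1L])
  }
  structure(data.frame(marker_id = marker_id, chromosome = chromosome,
                       position = position, stringsAsFactors = FALSE),
            assembly_id = assembly_id, sequence_dict = sequence_dict,
            class = c("physical_placement", "data.frame"))
}

#' Read / write a placement TSV
#'
#' Tab-separated columns `marker_id`, `chromosome`, `position` with a header
#' row; round-trip stable.
#'
#' @param path File path.
#' @param assembly_id Assembly label attached on read.
#' @return `read_placement` returns a [physical_placement()].
#' @export
read_placement <- function(path, assembly_id = "assembly") {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "character", "numeric"))
  physical_placement(df$marker_id, df$chromosome, df$position,
                     assembly_id = assembly_id)
}

#' @rdname read_placement
#' @param placement A [physical_placement()].
#' @export
write_placement <- function(placement, path) {
  stopifnot(inherits(placement, "physical_placement"))
  df <- as.data.frame(placement)
  df$position <- format(df$position, scientific = FALSE, trim = TRUE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a scaffold set
#'
#' Unanchored scaffolds and the markers they carry, with 1-based offsets.
#'
#' @param scaffolds data.frame with columns `scaffold_id`, `length`.
#' @param markers data.frame with columns `scaffold_id`, `marker_id`,
#'   `offset` (1-based bp within the scaffold).
#' @return Object of class `scaffold_set`.
#' @export
scaffold_set <- function(scaffolds, markers) {
  stopifnot(all(c("scaffold_id", "length") %in% names(scaffolds)),
            all(c("scaffold_id", "marker_id", "offset") %in% names(markers)))
  if (anyDuplicated(scaffolds$scaffold_id)) {
    stop("duplicate scaffold_id: ",
         scaffolds$scaffold_id[duplicated(scaffolds$scaffold_id)][1L])
  }
  bad <- setdiff(markers$scaffold_id, scaffolds$scaffold_id)
  if (length(bad)) stop("marker on undeclared scaffold: ", bad[1L])
  len <- setNames(scaffolds$length, scaffolds$scaffold_id)
  viol <- markers$offset < 1 | markers$offset > len[markers$scaffold_id]
  if (any(viol)) {
    k <- which(viol)[1L]
    stop(sprintf("offset %s of marker '%s' outside scaffold '%s' (length %s)",
                 format(markers$offset[k]), markers$marker_id[k],
                 markers$scaffold_id[k],
                 format(len[markers$scaffold_id[k]])))
  }
  structure(list(scaffolds = scaffolds[, c("scaffold_id", "length")],
                 markers = markers[, c("scaffold_id", "marker_id", "offset")]),
            class = "scaffold_set")
}

#' Read / write a scaffold TSV
#'
#' Long format, one row per marker: `scaffold_id`, `length`, `marker_id`,
#' `offset`. Scaffolds without markers get a row with empty `marker_id`.
#'
#' @param path File path.
#' @export
read_scaffolds <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "numeric", "character",
                                  "numeric"), na.strings = "")
  scaffolds <- unique(df[, c("scaffold_id", "length")])
  markers <- df[!is.na(df$marker_id) & nzchar(df$marker_id),
                c("scaffold_id", "marker_id", "offset")]
  scaffold_set(scaffolds, markers)
}

#' @rdname read_scaffolds
#' @param scaffolds A [scaffold_set()].
#' @export
write_scaffolds <- function(scaffolds, path) {
  stopifnot(inherits(scaffolds, "scaffold_set"))
  m <- merge(scaffolds$scaffolds, scaffolds$markers,
             by = "scaffold_id", all.x = TRUE)
  m <- m[order(m$scaffold_id, m$offset), ]
  m$length <- format(m$length, scientific = FALSE, trim = TRUE)
  m$offset <- ifelse(is.na(m$offset), "",
                     format(m$offset, scientific = FALSE, trim = TRUE))
  m$marker_id[is.na(m$marker_id)] <- ""
  write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an AGP v2.1 layout
#'
#' Serializes an ordered set of component pieces per chromosome object.
#' Between consecutive components a map-supported gap of unknown size is
#' emitted (`U 100 scaffold yes map`). Object coordinates must be 1-based
#' inclusive, strictly ascending and non-overlapping within an object.
#'
#' @param layout data.frame with columns `object`, `object_beg`, `object_end`,
#'   `component_id`, `component_beg`, `component_end`, `orientation`
#'   (`+` or `-`).
#' @param path Output file path.
#' @export
write_agp <- function(layout, path) {
  need <- c("object", "object_beg", "object_end", "component_id",
            "component_beg", "component_end", "orientation")
  stopifnot(all(need %in% names(layout)))
  if (!all(layout$orientation %in% c("+", "-"))) {
    stop("orientation must be '+' or '-'")
  }
  span_obj <- layout$object_end - layout$object_beg
  span_cmp <- layout$component_end - layout$component_beg
  if (any(span_obj != span_cmp)) {
    k <- which(span_obj != span_cmp)[1L]
    stop("object/component span mismatch for component ",
         layout$component_id[k])
  }
  layout <- layout[order(layout$object, layout$object_beg), ]
  out <- character(0)
  for (obj in unique(layout$object)) {
    rows <- layout[layout$object == obj, ]
    if (any(rows$object_beg[-1L] <= rows$object_end[-nrow(rows)])) {
      stop("overlapping object coordinates on ", obj)
    }
    part <- 0L
    for (k in seq_len(nrow(rows))) {
      if (k > 1L) {
        gap_beg <- rows$object_end[k - 1L] + 1L
        gap_end <- rows$object_beg[k] - 1L
        if (gap_end >= gap_beg) {
          part <- part + 1L
          out <- c(out, paste(obj, gap_beg, gap_end, part,
                              "U", 100, "scaffold", "yes", "map",
                              sep = "\t"))
        }
      }
      part <- part + 1L
      out <- c(out, paste(obj, rows$object_beg[k], rows$object_end[k], part,
                          "W", rows$component_id[k], rows$component_beg[k],
                          rows$component_end[k], rows$orientation[k],
                          sep = "\t"))
    }
  }
  writeLines(c("##agp-version\t2.1", out), path)
  invisible(path)
}

#' Construct a chromatin partition
#'
#' Per-chromosome heterochromatic interval (1-based inclusive bp; may be
#' absent) with the euchromatic complement implied by the chromosome length.
#'
#' @param chromosome Character vector of chromosome names.
#' @param length Chromosome lengths in bp.
#' @param het_start,het_end Heterochromatic interval bounds in bp
#'   (`NA` for all-euchromatic chromosomes). `het_start` may be 0 when the
#'   block abuts the chromosome start.
#' @return Object of class `chromatin_partition` (a data.frame).
#' @export
chromatin_partition <- function(chromosome, length,
                                het_start = NA_real_, het_end = NA_real_) {
  n <- base::length(chromosome)
  df <- data.frame(chromosome = as.character(chromosome),
                   length = as.numeric(length),
                   het_start = rep_len(as.numeric(het_start), n),
                   het_end = rep_len(as.numeric(het_end), n),
                   stringsAsFactors = FALSE)
  has <- !is.na(df$het_start) & !is.na(df$het_end)
  if (any(has & df$het_end < df$het_start)) {
    k <- which(has & df$het_end < df$het_start)[1L]
    stop("heterochromatic interval end < start on ", df$chromosome[k])
  }
  if (any(has & df$het_end > df$length)) {
    k <- which(has & df$het_end > df$length)[1L]
    stop("heterochromatic interval exceeds chromosome length on ",
         df$chromosome[k])
  }
  structure(df, class = c("chromatin_partition", "data.frame"))
}

#' Write / read a chromatin partition as BED
#'
#' Internal 1-based inclusive intervals are converted to BED's 0-based
#' half-open convention only here. The name field is `heterochromatin` or
#' `euchromatin`; euchromatic rows are the complement of the het interval
#' within `[1, length]`.
#'
#' @param partition A [chromatin_partition()].
#' @param path Output file path.
#' @export
write_bed <- function(partition, path) {
  stopifnot(inherits(partition, "chromatin_partition"))
  rows <- character(0)
  for (k in seq_len(nrow(partition))) {
    chr <- partition$chromosome[k]
    len <- partition$length[k]
    hs <- partition$het_start[k]
    he <- partition$het_end[k]
    if (is.na(hs) || is.na(he)) {
      rows <- c(rows, paste(chr, 0, len, "euchromatin", sep = "\t"))
      next
    }
    if (hs > 1) {
      rows <- c(rows, paste(chr, 0, hs - 1, "euchromatin", sep = "\t"))
    }
    rows <- c(rows, paste(chr, max(hs - 1, 0), he, "heterochromatin",
                          sep = "\t"))
    if (he < len) {
      rows <- c(rows, paste(chr, he, len, "euchromatin", sep = "\t"))
    }
  }
  writeLines(c("#chrom\tstart\tend\tname", rows), path)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed_partition <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) {
    return(chromatin_partition(character(0), numeric(0)))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  df <- data.frame(chromosome = vapply(f, `[`, character(1), 1L),
                   start = as.numeric(vapply(f, `[`, character(1), 2L)),
                   end = as.numeric(vapply(f, `[`, character(1), 3L)),
                   name = vapply(f, `[`, character(1), 4L),
                   stringsAsFactors = FALSE)
  chrs <- unique(df$chromosome)
  len <- vapply(chrs, function(ch) max(df$end[df$chromosome == ch]),
                numeric(1))
  hs <- he <- rep(NA_real_, length(chrs))
  for (k in seq_along(chrs)) {
    het <- df[df$chromosome == chrs[k] & df$name == "heterochromatin", ]
    if (nrow(het)) {
      hs[k] <- het$start[1L] + 1
      he[k] <- het$end[1L]
      if (het$start[1L] == 0) hs[k] <- ifelse(he[k] > 0, hs[k], 0)
    }
  }
  chromatin_partition(chrs, len, hs, he)
}
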