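.FIXTURE_FILES <- c(
  table2 = "table2_corrections.tsv",
  table3 = "table3_scaffolds.tsv",
  table4 = "table4_chromatin.tsv")

.FIXTURE_MD5 <- c(
  table2 = "907fe294a9111753ef4349db966e3c66",
  table3 = "f6a2ecf10959d799508e006da4c2de89",
  table4 = "b0b4a83f9ea3f0340d66f5216a7f018a")

#' Load a packaged reference-table transcription
#'
#' The package ships transcriptions of the published correction ledger
#' (`table2`), the anchored-scaffold table (`table3`) and the
#' heterochromatin partition (`table4`) for the soybean Glyma1.01 ->
#' Wm82.a2.v1 curation. Files are checksum-verified against packaged
#' digests before parsing.
#'
#' - `table2`: a [correction_ledger()] (comments mapped onto actions:
#'   re-orientations, moves with their target chromosome, within-chromosome
#'   repositionings, and one complex multi-change region) with support
#'   classes `BOTH` / `POP1_ONLY` (WP) / `POP2_ONLY` (EW).
#' - `table3`: list with a [scaffold_set()], per-population anchor records
#'   (`records`), ready-made single-group-per-linkage-group maps
#'   (`maps`) and linkage-group-to-chromosome `assignments`.
#' - `table4`: list with a [chromatin_partition()] (bp units) and the
#'   published assembly total (`assembly_total_bp` = 949.2 Mb).
#'
#' @param name One of `"table2"`, `"table3"`, `"table4"`.
#' @return See details above.
#' @export
load_table_fixture <- function(name = c("table2", "table3", "table4")) {
  name <- match.arg(name)
  path <- system.file("extdata", .FIXTURE_FILES[[name]],
                      package = "mapforge")
  if (!nzchar(path)) stop("fixture not installed: ", name)
  digest <- unname(tools::md5sum(path))
  if (digest != .FIXTURE_MD5[[name]]) {
    stop("fixture checksum mismatch for ", name,
         ": got ", digest, ", expected ", .FIXTURE_MD5[[name]])
  }
  switch(name,
         table2 = .load_table2(path),
         table3 = .load_table3(path),
         table4 = .load_table4(path))
}

.load_table2 <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, quote = "")
  action <- character(nrow(df))
  target <- rep(NA_character_, nrow(df))
  for (i in seq_len(nrow(df))) {
    cm <- df$comment[i]
    if (cm == "Re-orient") {
      action[i] <- "REORIENT"
    } else if (grepl("^Move to Gm", cm)) {
      action[i] <- "MOVE"
      target[i] <- sub("^Move to ", "", cm)
    } else if (grepl("^Re-orient and move to ", cm)) {
      action[i] <- "MOVE_AND_REORIENT"
      target[i] <- sub("^Re-orient and move to ", "", cm)
    } else if (cm == "Move and Re-orient") {
      action[i] <- "MOVE_AND_REORIENT"
    } else if (cm == "Move to top of chromosome") {
      action[i] <- "REPOSITION_WITHIN"
    } else if (cm == "A number of changes needed") {
      action[i] <- "COMPLEX"
    } else stop("unrecognized comment: ", cm)
  }
  support <- ifelse(df$support == "WP and EW", "BOTH",
                    ifelse(df$support == "WP", "POP1_ONLY", "POP2_ONLY"))
  entries <- data.frame(chromosome = df$first_chr,
                        first_marker = df$first_snp,
                        last_marker = df$last_snp,
                        span_start = pmin(df$first_pos, df$last_pos),
                        span_end = pmax(df$first_pos, df$last_pos),
                        action = action, target = target,
                        stringsAsFactors = FALSE)
  correction_ledger(entries, support = support)
}

.load_table3 <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, na.strings = ".")
  scaffolds <- unique(df[, c("scaffold_id", "scaffold_length")])
  names(scaffolds) <- c("scaffold_id", "length")
  markers <- data.frame(scaffold_id = df$scaffold_id,
                        marker_id = df$snp_id, offset = df$offset,
                        stringsAsFactors = FALSE)
  ss <- scaffold_set(scaffolds, markers)
  make_map <- function(lg, cm, pop) {
    hit <- !is.na(lg)
    loci <- data.frame(group = sprintf("LG%02d", lg[hit]),
                       marker_id = df$snp_id[hit], cM = cm[hit],
                       stringsAsFactors = FALSE)
    loci <- loci[order(loci$group, loci$cM, loci$marker_id), ]
    linkage_map_obj(loci, pop)
  }
  maps <- list(WP = make_map(df$lg_wp, df$cM_wp, "WP"),
               EW = make_map(df$lg_ew, df$cM_ew, "EW"))
  lg_all <- sort(unique(c(df$lg_wp, df$lg_ew)))
  assignment <- setNames(sprintf("Gm%02d", lg_all),
                         sprintf("LG%02d", lg_all))
  list(scaffolds = ss, records = df, maps = maps,
       assignments = list(WP = assignment, EW = assignment))
}

.load_table4 <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  part <- chromatin_partition(df$chromosome,
                              round(df$length_mb * 1e6),
                              round(df$het_start_mb * 1e6),
                              round(df$het_end_mb * 1e6))
  list(partition = part, assembly_total_bp = 949.2e6)
}
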