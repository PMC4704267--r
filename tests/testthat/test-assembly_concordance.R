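# helper: build a map/placement pair where genetic positions follow a
# supplied per-marker cM vector along physical order on one chromosome
toy_pair <- function(cm, chromosome = "c1", group = "LG01") {
  n <- length(cm)
  ids <- sprintf("%s_m%02d", chromosome, seq_len(n))
  pl <- physical_placement(ids, rep(chromosome, n), seq_len(n) * 1000)
  loci <- data.frame(group = group, marker_id = ids, cM = cm)
  loci <- loci[order(loci$cM), ]
  list(map = linkage_map_obj(loci, "p"), placement = pl)
}

test_that("group-to-chromosome assignment is majority vote with flagged
           ties and conflicts", {
  ids <- sprintf("m%02d", 1:10)
  pl <- physical_placement(ids, rep(c("c1", "c2"), c(9, 1)), 1:10 * 100)
  map <- linkage_map_obj(data.frame(group = "LG01", marker_id = ids,
                                    cM = 0:9), "p")
  asg <- assign_groups_to_chromosomes(map, pl)
  expect_equal(unname(asg$assignment["LG01"]), "c1")

  pl_tie <- physical_placement(ids, rep(c("c1", "c2"), 5), 1:10 * 100)
  asg_tie <- assign_groups_to_chromosomes(map, pl_tie)
  expect_true(is.na(asg_tie$assignment["LG01"]))
  expect_equal(asg_tie$ties, "LG01")
})

test_that("a concordant chromosome yields an empty ledger", {
  tp <- toy_pair(cumsum(runif(20, 0.2, 1)))
  res <- detect_corrections(tp$map, tp$placement)
  expect_equal(nrow(res$ledger$entries), 0L)
  expect_null(res$singletons)
})

test_that("a reversed interior block is reported as one REORIENT with
           exact boundaries", {
  cm <- as.numeric(1:10)
  cm[4:7] <- rev(cm[4:7])
  tp <- toy_pair(cm)
  res <- detect_corrections(tp$map, tp$placement)
  ent <- res$ledger$entries
  expect_equal(nrow(ent), 1L)
  expect_equal(ent$action, "REORIENT")
  expect_equal(ent$first_marker, "c1_m04")
  expect_equal(ent$last_marker, "c1_m07")
})

test_that("an interior block displaced in cM is REPOSITION_WITHIN and a
           lone outlier is a singleton, not a correction", {
  # markers 5-7 carry cM that belongs at the chromosome start
  cm <- c(10, 11, 12, 13, 0.5, 1.0, 1.5, 14, 15, 16)
  tp <- toy_pair(cm)
  res <- detect_corrections(tp$map, tp$placement)
  ent <- res$ledger$entries
  expect_equal(ent$action, "REPOSITION_WITHIN")
  expect_equal(ent$first_marker, "c1_m05")
  expect_equal(ent$last_marker, "c1_m07")

  cm2 <- as.numeric(1:10)
  cm2[5] <- 30  # lone outlier
  tp2 <- toy_pair(cm2)
  res2 <- detect_corrections(tp2$map, tp2$placement)
  expect_equal(nrow(res2$ledger$entries), 0L)
  expect_equal(res2$singletons$marker_id, "c1_m05")
})

test_that("foreign-group runs become MOVE entries (reversed ones
           MOVE_AND_REORIENT), single markers allowed", {
  ids1 <- sprintf("c1_m%02d", 1:8)
  ids2 <- sprintf("c2_m%02d", 1:6)
  lone <- "c2_lone"
  pl <- physical_placement(
    c(ids1, ids2, lone),
    c(rep("c1", 8), rep("c2", 6), "c1"),
    c(1:8 * 1000, 1:6 * 1000, 9000))
  loci <- rbind(
    data.frame(group = "LG01", marker_id = ids1, cM = 1:8),
    data.frame(group = "LG02", marker_id = ids2, cM = 1:6),
    data.frame(group = "LG02", marker_id = lone, cM = 6.5))
  map <- linkage_map_obj(loci[order(loci$group, loci$cM), ], "p")
  res <- detect_corrections(map, pl)
  ent <- res$ledger$entries
  expect_equal(nrow(ent), 1L)
  expect_equal(ent$action, "MOVE")
  expect_equal(ent$first_marker, lone)
  expect_equal(ent$target, "c2")
})

test_that("globally reversing a chromosome is flagged as orientation, not
           as per-segment corrections", {
  cm <- cumsum(runif(15, 0.2, 1))
  tp <- toy_pair(cm)
  fwd <- detect_corrections(tp$map, tp$placement)
  pl <- as.data.frame(tp$placement)
  rev_pl <- physical_placement(pl$marker_id, pl$chromosome,
                               max(pl$position) + 1000 - pl$position)
  bwd <- detect_corrections(tp$map, rev_pl)
  expect_equal(nrow(bwd$ledger$entries), nrow(fwd$ledger$entries))
  expect_equal(unname(bwd$chromosome_orientation["c1"]), "-")
  expect_equal(unname(fwd$chromosome_orientation["c1"]), "+")
})

test_that("support merging intersects same-action overlapping entries", {
  e <- data.frame(chromosome = "c1", first_marker = "a", last_marker = "b",
                  span_start = 100, span_end = 500, action = "REORIENT",
                  target = NA_character_, stringsAsFactors = FALSE)
  l1 <- correction_ledger(e, "POP1_ONLY")
  l2 <- correction_ledger(e, "POP2_ONLY")
  m <- merge_support(l1, l2)
  expect_equal(nrow(m$entries), 1L)
  expect_equal(m$entries$support, "BOTH")
  expect_equal(m$counts$BOTH, 1L)

  e2 <- e
  e2$span_start <- 900
  e2$span_end <- 1200
  m2 <- merge_support(l1, correction_ledger(e2, "POP2_ONLY"))
  expect_equal(nrow(m2$entries), 2L)
  expect_setequal(m2$entries$support, c("POP1_ONLY", "POP2_ONLY"))

  set.seed(50)
  for (i in 1:10) {
    s1 <- sort(sample.int(1000, 2))
    s2 <- sort(sample.int(1000, 2))
    ov <- s1[1] <= s2[2] && s2[1] <= s1[2]
    ea <- e; ea$span_start <- s1[1]; ea$span_end <- s1[2]
    eb <- e; eb$span_start <- s2[1]; eb$span_end <- s2[2]
    mm <- merge_support(correction_ledger(ea, "POP1_ONLY"),
                        correction_ledger(eb, "POP2_ONLY"))
    expect_equal(nrow(mm$entries), if (ov) 1L else 2L)
    if (ov) {
      expect_equal(mm$entries$span_start, max(s1[1], s2[1]))
      expect_equal(mm$entries$span_end, min(s1[2], s2[2]))
    }
  }
})

test_that("applying corrections: identity on empty ledger, reflection on
           REORIENT, rejection of overlaps", {
  pl <- physical_placement(sprintf("m%d", 1:6), rep("c1", 6),
                           c(100, 200, 300, 400, 500, 600))
  empty <- correction_ledger(data.frame(
    chromosome = character(0), first_marker = character(0),
    last_marker = character(0), span_start = numeric(0),
    span_end = numeric(0), action = character(0),
    target = character(0), stringsAsFactors = FALSE))
  out <- apply_corrections(pl, empty)
  expect_equal(as.data.frame(out$placement), as.data.frame(pl),
               ignore_attr = TRUE)

  led <- correction_ledger(data.frame(
    chromosome = "c1", first_marker = "m2", last_marker = "m4",
    span_start = 200, span_end = 400, action = "REORIENT",
    target = NA_character_, stringsAsFactors = FALSE))
  out2 <- apply_corrections(pl, led)
  got <- as.data.frame(out2$placement)
  expect_equal(got$position[match(c("m2", "m3", "m4"), got$marker_id)],
               c(400, 300, 200))
  expect_equal(got$position[match(c("m1", "m5", "m6"), got$marker_id)],
               c(100, 500, 600))
  # emitted AGP is valid and carries the reflected piece
  path <- withr::local_tempfile(fileext = ".agp")
  write_agp(out2$agp, path)
  expect_length(validate_agp(path), 0L)
  expect_true(any(out2$agp$orientation == "-"))

  twice <- correction_ledger(rbind(led$entries[, 1:7], data.frame(
    chromosome = "c1", first_marker = "m3", last_marker = "m5",
    span_start = 300, span_end = 500, action = "REORIENT",
    target = NA_character_)))
  expect_error(apply_corrections(pl, twice), "overlapping")
})

test_that("corrupt -> detect -> apply restores the truth up to move
           insertion positions, and a second detection pass is clean", {
  gen <- tiny_genome(4, 150, seed = 60)
  truth <- corrupt_assembly(model_placement(gen), 4, 2, 0, seed = 61)
  map <- model_truth_map(gen)
  res <- detect_corrections(map, truth$corrupted_assembly,
                            support = "BOTH")
  app <- apply_corrections(truth$corrupted_assembly, res$ledger)
  got <- as.data.frame(app$placement)
  want <- as.data.frame(truth$true_assembly)
  gw <- merge(got, want, by = "marker_id", suffixes = c("_got", "_true"))
  expect_true(all(gw$chromosome_got == gw$chromosome_true))
  # unmoved markers restored exactly
  moved <- unlist(lapply(which(res$ledger$entries$action %in%
                                 c("MOVE", "MOVE_AND_REORIENT")),
                         function(i) {
    e <- res$ledger$entries[i, ]
    cor_df <- as.data.frame(truth$corrupted_assembly)
    cor_df$marker_id[cor_df$chromosome == e$chromosome &
                       cor_df$position >= e$span_start &
                       cor_df$position <= e$span_end]
  }))
  stay <- gw[!(gw$marker_id %in% moved), ]
  expect_equal(stay$position_got, stay$position_true)
  # second pass: nothing left to fix
  res2 <- detect_corrections(map, app$placement, support = "BOTH")
  expect_equal(nrow(res2$ledger$entries), 0L)
})

test_that("more than five entries on a chromosome collapse to COMPLEX", {
  cm <- as.numeric(1:40)
  for (s in seq(1, 36, by = 6)) cm[s:(s + 2)] <- rev(cm[s:(s + 2)])
  tp <- toy_pair(cm)
  res <- detect_corrections(tp$map, tp$placement)
  ent <- res$ledger$entries
  expect_equal(ent$action, "COMPLEX")
  expect_equal(nrow(ent), 1L)
})
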