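test_that("Kosambi function evaluates its closed form and guards bounds", {
  expect_equal(kosambi(0), 0)
  expect_equal(kosambi(0.1), 25 * log(1.2 / 0.8))
  expect_equal(kosambi(0.1), 10.13663, tolerance = 1e-5)
  expect_error(kosambi(-0.01), ">= 0")
  expect_equal(kosambi(0.7), kosambi(0.5))  # clamped
  r <- seq(0.001, 0.499, by = 0.001)
  expect_true(all(kosambi(r) >= 100 * r))  # map distance >= naive cM
})

test_that("two-point statistics follow the stated estimator and LOD", {
  col <- rep(c("A", "B"), 50)
  g <- genotype_matrix(rbind(m1 = col, m2 = col, m3 = rev(col)), "p",
                       line_ids = sprintf("l%d", 1:100))
  pl <- pairwise_linkage(g, "m1", "m2")
  expect_equal(pl$R_hat, 0)
  expect_equal(pl$r_hat, 0)
  expect_equal(pl$lod, 100 * log10(2), tolerance = 1e-9)

  # half recombinant: no linkage
  half <- c(rep("A", 50), rep("B", 50))
  other <- c(rep("A", 25), rep("B", 50), rep("A", 25))
  g2 <- genotype_matrix(rbind(m1 = half, m2 = other), "p",
                        line_ids = sprintf("l%d", 1:100))
  pl2 <- pairwise_linkage(g2, "m1", "m2")
  expect_equal(pl2$R_hat, 0.5)
  expect_equal(pl2$r_hat, 0.5)
  expect_equal(pl2$lod, 0)

  # k = 25 of n = 100
  m2 <- col
  flip <- 1:25 * 4 - 1  # flip 25 positions
  m2[flip] <- setdiff(c("A", "B"), m2[flip])[1]
  m2 <- ifelse(seq_along(col) %in% flip,
               ifelse(col == "A", "B", "A"), col)
  g3 <- genotype_matrix(rbind(m1 = col, m2 = m2), "p",
                        line_ids = sprintf("l%d", 1:100))
  pl3 <- pairwise_linkage(g3, "m1", "m2")
  expect_equal(pl3$R_hat, 0.25)
  expect_equal(pl3$r_hat, 0.25 / 1.5)

  # H and MISSING excluded
  g4 <- genotype_matrix(rbind(m1 = c("A", "H", "B", "MISSING"),
                              m2 = c("A", "B", "B", "A")), "p",
                        line_ids = sprintf("l%d", 1:4))
  expect_equal(pairwise_linkage(g4, "m1", "m2")$n_informative, 2L)
  g5 <- genotype_matrix(rbind(m1 = c("H", "H"), m2 = c("A", "B")), "p",
                        line_ids = c("l1", "l2"))
  expect_error(pairwise_linkage(g5, "m1", "m2"), "uninformative")
})

test_that("LOD grouping returns connected components of the lod graph", {
  # two co-segregating clusters with no cross linkage
  set.seed(40)
  a <- sample(c("A", "B"), 200, TRUE)
  b <- sample(c("A", "B"), 200, TRUE)
  g <- genotype_matrix(rbind(a1 = a, a2 = a, b1 = b, b2 = b), "p",
                       line_ids = sprintf("l%d", 1:200))
  grp <- group_markers(g, lod_threshold = 11)
  expect_equal(grp[["a1"]], grp[["a2"]])
  expect_equal(grp[["b1"]], grp[["b2"]])
  expect_false(grp[["a1"]] == grp[["b1"]])
  # threshold 0 joins everything
  expect_equal(length(unique(group_markers(g, 0))), 1L)
})

test_that("grouping agrees with a brute-force flood fill on random graphs", {
  set.seed(41)
  for (i in 1:5) {
    n <- 12L
    lod <- matrix(0, n, n, dimnames = list(sprintf("x%02d", 1:n),
                                           sprintf("x%02d", 1:n)))
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      if (runif(1) < 0.15) lod[a, b] <- lod[b, a] <- 12
    }
    fake_pairs <- list(lod = lod)
    fake_g <- list(marker_ids = rownames(lod))
    got <- group_markers(fake_g, 11, pairs = fake_pairs)
    # BFS oracle
    seen <- rep(NA_integer_, n)
    comp <- 0L
    for (s in 1:n) {
      if (!is.na(seen[s])) next
      comp <- comp + 1L
      queue <- s
      while (length(queue)) {
        v <- queue[1L]
        queue <- queue[-1L]
        if (!is.na(seen[v])) next
        seen[v] <- comp
        queue <- c(queue, which(lod[v, ] >= 11 & is.na(seen)))
      }
    }
    # same partition up to relabeling
    expect_equal(length(unique(got)), length(unique(seen)))
    expect_true(all(tapply(seen, got, function(x) length(unique(x))) == 1))
  }
})

test_that("ordering matches the exhaustive optimum for small groups", {
  gen <- tiny_genome(1, 7, seed = 13)
  g <- simulate_population(gen, 400, seed = 14)
  members <- g$marker_ids
  ord <- order_group(g, members)
  # exhaustive oracle over all permutations of adjacent r-hat sums
  r <- matrix(0, 7, 7, dimnames = list(members, members))
  for (a in 1:6) for (b in (a + 1):7) {
    r[a, b] <- r[b, a] <- pairwise_linkage(g, members[a], members[b])$r_hat
  }
  score <- function(p) sum(r[cbind(p[-length(p)], p[-1L])])
  perms <- all_perms(7L)
  best <- min(apply(perms, 1L, score))
  got <- score(match(ord$marker_id, members))
  expect_equal(got, best, tolerance = 1e-12)
})

test_that("co-segregating representatives sit adjacent at zero gap and a
           singleton group maps to 0 cM", {
  col <- rep(c("A", "B", "A", "B"), 25)
  near <- col
  near[1] <- "B"
  g <- genotype_matrix(rbind(m1 = col, m2 = col, m3 = near), "p",
                       line_ids = sprintf("l%d", 1:100))
  ord <- order_group(g, c("m1", "m2", "m3"))
  i1 <- which(ord$marker_id == "m1")
  i2 <- which(ord$marker_id == "m2")
  expect_equal(abs(i1 - i2), 1L)
  expect_equal(ord$cM[i1], ord$cM[i2])
  single <- order_group(g, "m1")
  expect_equal(single, data.frame(marker_id = "m1", cM = 0))
})

test_that("reversing a group leaves its length invariant and placement
           fixes the orientation deterministically", {
  gen <- tiny_genome(1, 30, seed = 15)
  g <- simulate_population(gen, 500, seed = 16)
  pl <- model_placement(gen)
  fwd <- order_group(g, g$marker_ids, placement = pl)
  expect_gt(cor(match(fwd$marker_id, as.data.frame(pl)$marker_id),
                as.data.frame(pl)$position[
                  match(fwd$marker_id, as.data.frame(pl)$marker_id)],
                method = "spearman"), 0)
  rev_pl <- physical_placement(
    as.data.frame(pl)$marker_id, as.data.frame(pl)$chromosome,
    max(as.data.frame(pl)$position) + 1 - as.data.frame(pl)$position)
  bwd <- order_group(g, g$marker_ids, placement = rev_pl)
  expect_equal(max(fwd$cM), max(bwd$cM), tolerance = 1e-9)
  expect_equal(fwd$marker_id, rev(bwd$marker_id))
})

test_that("a full map recovers simulated chromosome structure", {
  gen <- tiny_genome(2, 50, seed = 17)
  g <- simulate_population(gen, 600, seed = 18, missing_rate = 0.02)
  qc <- qc_genotypes(g)
  map <- build_linkage_map(qc$genotypes, lod_threshold = 11,
                          placement = model_placement(gen))
  expect_equal(length(unique(map$loci$group)), 2L)
  pl <- as.data.frame(model_placement(gen))
  for (gid in unique(map$loci$group)) {
    loci <- map$loci[map$loci$group == gid, ]
    mg <- merge(loci, pl, by = "marker_id")
    top <- names(sort(table(mg$chromosome), decreasing = TRUE))[1L]
    mg <- mg[mg$chromosome == top, ]
    expect_gt(cor(mg$cM, mg$position, method = "spearman"), 0.99)
  }
  # map TSV round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_linkage_map(map, path)
  back <- read_linkage_map(path, map$population_id)
  expect_equal(back$loci$marker_id, map$loci$marker_id)
  expect_equal(back$loci$cM, map$loci$cM, tolerance = 1e-3)
})
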