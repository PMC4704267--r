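test_that("genotype CSV round-trips and normalizes missing spellings", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("marker_id,l1,l2,l3",
               "m1,A,B,H",
               "m2,-,NA,."), path)
  g <- read_genotypes(path)
  expect_equal(dim(g$calls), c(2L, 3L))
  expect_equal(unname(g$calls[2, ]), rep("MISSING", 3))

  set.seed(1)
  for (i in 1:5) {
    g0 <- genotype_matrix(rand_calls(8, 6), "p")
    p2 <- withr::local_tempfile(fileext = ".csv")
    write_genotypes(g0, p2)
    g1 <- read_genotypes(p2, "p")
    expect_identical(g1$calls, g0$calls)
  }
})

test_that("genotype reader rejects bad input naming the offender", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("marker_id,l1,l2", "m1,A,X"), path)
  expect_error(read_genotypes(path), "X.*m1.*l2")
  writeLines(c("marker_id,l1,l2", "m1,A"), path)
  expect_error(read_genotypes(path), "ragged.*m1")
  writeLines(c("marker_id,l1,l2", "m1,A,B", "m1,B,A"), path)
  expect_error(read_genotypes(path), "duplicate marker_id: m1")
})

test_that("placement TSV round-trips; invalid records rejected", {
  p <- physical_placement("BARC_1.01_Gm02_22523407_T_C", "Gm02", 22523407)
  expect_equal(nrow(p), 1L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_placement(p, path)
  expect_equal(as.data.frame(read_placement(path)), as.data.frame(p))

  writeLines("marker_id\tchromosome\tposition", path)
  expect_equal(nrow(read_placement(path)), 0L)

  set.seed(2)
  p0 <- physical_placement(sprintf("m%02d", 1:20),
                           sample(c("c1", "c2"), 20, TRUE),
                           sample.int(1e6, 20))
  write_placement(p0, path)
  expect_equal(as.data.frame(read_placement(path)), as.data.frame(p0))

  expect_error(physical_placement("m1", "c1", 0), "position")
  expect_error(physical_placement(c("m1", "m1"), c("c1", "c1"), c(1, 2)),
               "duplicate")
  expect_error(physical_placement("m1", "c9", 5, sequence_dict = "c1"),
               "sequence dictionary")
})

test_that("scaffold sets validate offsets and round-trip", {
  sc <- data.frame(scaffold_id = c("s1", "s2"), length = c(1000, 500))
  mk <- data.frame(scaffold_id = c("s1", "s1"), marker_id = c("a", "b"),
                   offset = c(10, 990))
  ss <- scaffold_set(sc, mk)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scaffolds(ss, path)
  ss2 <- read_scaffolds(path)
  expect_setequal(ss2$scaffolds$scaffold_id, sc$scaffold_id)
  expect_equal(ss2$markers[order(ss2$markers$marker_id), ],
               mk[order(mk$marker_id), ], ignore_attr = TRUE)
  mk$offset[1] <- 2000
  expect_error(scaffold_set(sc, mk), "outside scaffold")
})

test_that("AGP writer emits valid v2.1 with map gaps", {
  path <- withr::local_tempfile(fileext = ".agp")
  one <- data.frame(object = "chr1", object_beg = 1, object_end = 1000,
                    component_id = "scafA", component_beg = 1,
                    component_end = 1000, orientation = "+")
  write_agp(one, path)
  lines <- readLines(path)
  expect_match(lines[2], "^chr1\t1\t1000\t1\tW\tscafA\t1\t1000\t\\+$")
  expect_length(validate_agp(path), 0L)

  two <- rbind(one, data.frame(object = "chr1", object_beg = 1101,
                               object_end = 1600, component_id = "scafB",
                               component_beg = 1, component_end = 500,
                               orientation = "-"))
  write_agp(two, path)
  lines <- readLines(path)
  expect_match(lines[3], "U\t100\tscaffold\tyes\tmap")
  expect_match(lines[4], "-$")
  expect_length(validate_agp(path), 0L)

  set.seed(3)
  for (i in 1:5) {
    n <- sample(2:5, 1)
    span <- sample.int(2000, n)
    beg <- cumsum(c(1, head(span, -1) + sample(c(0, 150), n - 1, TRUE)))
    layout <- data.frame(object = "chrX", object_beg = beg,
                         object_end = beg + span - 1,
                         component_id = sprintf("s%d", seq_len(n)),
                         component_beg = 1, component_end = span,
                         orientation = sample(c("+", "-"), n, TRUE))
    write_agp(layout, path)
    expect_length(validate_agp(path), 0L)
  }

  bad <- rbind(one, one)
  expect_error(write_agp(bad, path), "overlapping")
})

test_that("BED conversion is the only 0-based boundary and round-trips", {
  p <- chromatin_partition("Chr01", 56.8e6, 8.1e6, 47.4e6)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(p, path)
  lines <- readLines(path)
  expect_equal(lines[3], "Chr01\t8099999\t47400000\theterochromatin")

  empty <- chromatin_partition(character(0), numeric(0))
  write_bed(empty, path)
  expect_equal(readLines(path), "#chrom\tstart\tend\tname")

  set.seed(4)
  for (i in 1:5) {
    len <- sample(2e7:6e7, 1)
    hs <- sample(1e6:1e7, 1)
    he <- hs + sample(5e6:9e6, 1)
    p0 <- chromatin_partition(c("c1", "c2"), c(len, len),
                              c(hs, NA), c(he, NA))
    write_bed(p0, path)
    p1 <- read_bed_partition(path)
    expect_equal(as.data.frame(p1), as.data.frame(p0), ignore_attr = TRUE)
  }

  expect_error(chromatin_partition("c1", 100, 50, 40), "end < start")
})
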