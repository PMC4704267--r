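revcomp_str <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = "")
}

test_that("in-silico PCR finds planted products and enforces exactness", {
  set.seed(90)
  fwd <- rand_seq(20)
  rv <- rand_seq(20)
  insert <- paste0(fwd, rand_seq(20), revcomp_str(rv))
  seqs <- c(chr1 = paste0(rand_seq(100), insert, rand_seq(100)))
  prods <- insilico_pcr(seqs, fwd, rv)
  expect_equal(nrow(prods), 1L)
  expect_equal(prods$start, 101L)
  expect_equal(prods$length, nchar(insert))
  expect_equal(prods$strand, "+")

  # one mismatch in the genome copy of the forward primer: no product
  mut <- insert
  substr(mut, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                               substr(mut, 5, 5))[1L]
  seqs_mut <- c(chr1 = paste0(rand_seq(100), mut, rand_seq(100)))
  expect_equal(nrow(insilico_pcr(seqs_mut, fwd, rv)), 0L)

  # opposite-strand locus: plant the revcomp of the whole insert
  seqs2 <- c(chr1 = paste0(rand_seq(50), insert, rand_seq(50)),
             chr2 = paste0(rand_seq(50), revcomp_str(insert),
                           rand_seq(50)))
  prods2 <- insilico_pcr(seqs2, fwd, rv)
  expect_equal(nrow(prods2), 2L)
  expect_setequal(prods2$strand, c("+", "-"))

  expect_error(insilico_pcr(seqs, "ACGTACGTACGT", rv), "15 bp")
  expect_error(insilico_pcr(seqs, "NOTDNA!", rv), "ACGT")
})

test_that("in-silico PCR agrees with a brute-force all-substring scanner", {
  set.seed(91)
  fwd <- rand_seq(18)
  rv <- rand_seq(18)
  insert <- paste0(fwd, rand_seq(30), revcomp_str(rv))
  chr1 <- paste0(rand_seq(8000), insert, rand_seq(6000), insert,
                 rand_seq(4000))
  chr2 <- paste0(rand_seq(5000), revcomp_str(insert), rand_seq(9000))
  seqs <- c(chr1 = chr1, chr2 = chr2)
  got <- insilico_pcr(seqs, fwd, rv)
  oracle <- brute_pcr(seqs, fwd, rv)
  rownames(got) <- NULL
  expect_equal(got[, c("chromosome", "strand", "start", "end")],
               oracle[, c("chromosome", "strand", "start", "end")])
  expect_equal(nrow(got), 4L)  # two self products, one cross-insert product, one minus-strand
})

test_that("source matching retains only near-perfect, near-full-length
           hits and merges duplicates", {
  set.seed(92)
  src <- rand_seq(400)
  seqs <- c(chr1 = paste0(rand_seq(500), src, rand_seq(500)))
  hit <- match_source(seqs, src)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$identity, 1.0)
  expect_equal(hit$start, 501L)
  expect_equal(hit$end, 900L)

  # 2% scattered substitutions over 500 bp fail a 0.99 cutoff
  src2 <- rand_seq(500)
  mut <- strsplit(src2, "")[[1L]]
  at <- seq(25, 500, by = 50)
  mut[at] <- vapply(mut[at], function(x) {
    setdiff(c("A", "C", "G", "T"), x)[1L]
  }, character(1))
  seqs2 <- c(chr1 = paste0(rand_seq(300), paste(mut, collapse = ""),
                           rand_seq(300)))
  expect_equal(nrow(match_source(seqs2, src2)), 0L)

  # duplicated source: two hits
  seqs3 <- c(chr1 = paste0(rand_seq(200), src, rand_seq(200), src,
                           rand_seq(200)))
  expect_equal(nrow(match_source(seqs3, src)), 2L)
})

test_that("SSR placement demands product, source overlap, exact length and
           the tandem motif between primers", {
  set.seed(93)
  locus <- make_ssr_locus("SSR1")
  seqs <- c(chr1 = paste0(rand_seq(300), locus$insert, rand_seq(300)))
  res <- place_ssr(seqs, locus$descriptor)
  expect_equal(res$status, "UNAMBIGUOUS")
  expect_equal(res$position$chromosome, "chr1")
  expect_equal(res$position$bp, 301L)

  # delete the motif tract between the primers
  d <- locus$descriptor
  no_motif <- paste0(d$forward_primer, rand_seq(30),
                     revcomp_str(d$reverse_primer))
  d2 <- ssr_descriptor("SSR1nm", d$forward_primer, d$reverse_primer,
                       d$motif, source_sequence = no_motif,
                       expected_amplicon_length = nchar(no_motif))
  seqs2 <- c(chr1 = paste0(rand_seq(300), no_motif, rand_seq(300)))
  res2 <- place_ssr(seqs2, d2)
  expect_equal(res2$status, "UNPLACED")
  expect_equal(res2$failed_criterion, "motif_between_primers")

  # wrong amplicon length fails criterion (c)
  d3 <- ssr_descriptor("SSR1len", d$forward_primer, d$reverse_primer,
                       d$motif, source_sequence = locus$insert,
                       expected_amplicon_length =
                         nchar(locus$insert) + 10)
  res3 <- place_ssr(seqs, d3)
  expect_equal(res3$status, "UNPLACED")
  expect_equal(res3$failed_criterion, "amplicon_length")

  # locus duplicated on two chromosomes: AMBIGUOUS
  seqs4 <- c(chr1 = paste0(rand_seq(300), locus$insert, rand_seq(300)),
             chr2 = paste0(rand_seq(100), locus$insert, rand_seq(100)))
  expect_equal(place_ssr(seqs4, locus$descriptor)$status, "AMBIGUOUS")
})

test_that("SNP placement positions the wildcard coordinate and grades
           ambiguity", {
  set.seed(94)
  chr <- rand_seq(2000)
  flank5 <- substr(chr, 901, 980)
  flank3 <- substr(chr, 982, 1061)
  snp <- snp_descriptor("SNP1", flank5, flank3, "A/G")
  res <- place_snp(c(chr1 = chr), snp)
  expect_equal(res$status, "UNAMBIGUOUS")
  expect_equal(res$position$bp, 981L)

  absent <- snp_descriptor("SNP2", rand_seq(80), rand_seq(80))
  expect_equal(place_snp(c(chr1 = chr), absent)$status, "UNPLACED")

  dup <- c(chr1 = chr, chr2 = chr)
  expect_equal(place_snp(dup, snp)$status, "AMBIGUOUS")
  expect_error(snp_descriptor("S", "ACGT", "ACGT"), "50 bp")
})

test_that("reverse-complementing the genome mirrors placements with
           flipped strand", {
  set.seed(95)
  locus <- make_ssr_locus("SSRrc")
  chr <- paste0(rand_seq(250), locus$insert, rand_seq(150))
  res_f <- place_ssr(c(chr1 = chr), locus$descriptor)
  res_r <- place_ssr(c(chr1 = revcomp_str(chr)), locus$descriptor)
  expect_equal(res_f$status, "UNAMBIGUOUS")
  expect_equal(res_r$status, "UNAMBIGUOUS")
  L <- nchar(chr)
  ins <- nchar(locus$insert)
  expect_equal(res_r$position$bp, L - (res_f$position$bp + ins - 1L) + 1L)
})
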