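# Independent oracles and builders shared across the suite. These
# re-derive expectations from first principles (exact Markov chains, brute
# force scans, exhaustive enumeration) and never call the code paths they
# check.

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_calls <- function(n_mk, n_ln, missing = 0.05) {
  syms <- c("A", "B", "H", "MISSING")
  p <- c((1 - missing) * c(0.45, 0.45, 0.10), missing)
  matrix(sample(syms, n_mk * n_ln, TRUE, p), n_mk, n_ln,
         dimnames = list(sprintf("m%03d", seq_len(n_mk)),
                         sprintf("l%03d", seq_len(n_ln))))
}

# --- exact two-locus selfing chain ------------------------------------
# state = unordered pair of haplotypes; haplotypes 1=AB 2=Ab 3=aB 4=ab
.gamete_dist <- function(h1, h2, r) {
  p <- numeric(4)
  if (h1 == h2) {
    p[h1] <- 1
    return(p)
  }
  a <- c(h1, h2)
  al1 <- c(1, 1, 2, 2)[a]
  al2 <- c(1, 2, 1, 2)[a]
  hap_of <- function(x, y) (x - 1L) * 2L + y
  p[hap_of(al1[1], al2[1])] <- p[hap_of(al1[1], al2[1])] + (1 - r) / 2
  p[hap_of(al1[2], al2[2])] <- p[hap_of(al1[2], al2[2])] + (1 - r) / 2
  p[hap_of(al1[1], al2[2])] <- p[hap_of(al1[1], al2[2])] + r / 2
  p[hap_of(al1[2], al2[1])] <- p[hap_of(al1[2], al2[1])] + r / 2
  p
}

# expected recombinant-line fraction among doubly homozygous individuals
# after k rounds of selfing from an AB/ab F1, at meiotic fraction r
f5_expected_R <- function(r, k = 4) {
  states <- rbind(t(utils::combn(1:4, 2)), cbind(1:4, 1:4))
  ns <- nrow(states)
  prob <- numeric(ns)
  prob[states[, 1] == 1 & states[, 2] == 4] <- 1
  for (gen in seq_len(k)) {
    newp <- numeric(ns)
    for (s in which(prob > 1e-15)) {
      gd <- .gamete_dist(states[s, 1], states[s, 2], r)
      for (i in 1:4) for (j in i:4) {
        pr <- if (i == j) gd[i]^2 else 2 * gd[i] * gd[j]
        if (pr == 0) next
        t <- which(states[, 1] == i & states[, 2] == j)
        newp[t] <- newp[t] + prob[s] * pr
      }
    }
    prob <- newp
  }
  hom <- vapply(1:4, function(h) {
    prob[states[, 1] == h & states[, 2] == h]
  }, numeric(1))
  (hom[2] + hom[3]) / sum(hom)
}

# --- brute-force e-PCR scanner ----------------------------------------
# all-substring exact scan for primer products on both strands
brute_pcr <- function(seqs, fwd, rev, max_amplicon = 10000) {
  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]),
          collapse = "")
  }
  find_all <- function(subject, pat) {
    k <- nchar(pat)
    n <- nchar(subject)
    if (n < k) return(integer(0))
    idx <- seq_len(n - k + 1L)
    idx[substring(subject, idx, idx + k - 1L) == pat]
  }
  out <- list()
  for (chr in names(seqs)) {
    subject <- seqs[[chr]]
    combos <- list(c(fwd, revcomp(rev), "+"), c(rev, revcomp(fwd), "-"))
    for (cb in combos) {
      ls <- find_all(subject, cb[1])
      rs <- find_all(subject, cb[2])
      for (s in ls) {
        for (rp in rs) {
          e <- rp + nchar(cb[2]) - 1L
          if (rp > s && e - s + 1L <= max_amplicon) {
            out[[length(out) + 1L]] <- data.frame(
              chromosome = chr, strand = cb[3], start = s, end = e,
              length = e - s + 1L, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chromosome = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chromosome, res$start, res$strand), ]
  rownames(res) <- NULL
  res
}

# --- AGP v2.1 grammar checker -----------------------------------------
validate_agp <- function(path) {
  lines <- readLines(path)
  stopifnot(lines[1] == "##agp-version\t2.1")
  body <- lines[-1]
  problems <- character(0)
  f <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(f) != 9L)) problems <- c(problems, "field count != 9")
  obj <- vapply(f, `[`, character(1), 1L)
  beg <- as.numeric(vapply(f, `[`, character(1), 2L))
  end <- as.numeric(vapply(f, `[`, character(1), 3L))
  part <- as.numeric(vapply(f, `[`, character(1), 4L))
  type <- vapply(f, `[`, character(1), 5L)
  if (!all(type %in% c("W", "U", "N"))) {
    problems <- c(problems, "bad component type")
  }
  for (o in unique(obj)) {
    i <- which(obj == o)
    if (any(part[i] != seq_along(i))) {
      problems <- c(problems, paste("part numbers not sequential on", o))
    }
    if (any(beg[i][-1L] != end[i][-length(i)] + 1L)) {
      problems <- c(problems, paste("object coords not contiguous on", o))
    }
    if (any(end[i] < beg[i])) problems <- c(problems, "end < beg")
  }
  w <- which(type == "W")
  cb <- as.numeric(vapply(f[w], `[`, character(1), 7L))
  ce <- as.numeric(vapply(f[w], `[`, character(1), 8L))
  ori <- vapply(f[w], `[`, character(1), 9L)
  if (any(ce - cb != end[w] - beg[w])) {
    problems <- c(problems, "component span != object span")
  }
  if (!all(ori %in% c("+", "-"))) problems <- c(problems, "bad orientation")
  problems
}

# --- planted SSR/SNP locus builders -----------------------------------
make_ssr_locus <- function(id, motif_copies = 8L) {
  fwd <- rand_seq(20)
  rv <- rand_seq(20)
  motif <- paste(sample(c("A", "C", "G", "T"), 2), collapse = "")
  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]),
          collapse = "")
  }
  mid <- paste0(rand_seq(10), strrep(motif, motif_copies), rand_seq(10))
  insert <- paste0(fwd, mid, revcomp(rv))
  list(descriptor = ssr_descriptor(id, fwd, rv, motif,
                                   source_sequence = insert,
                                   expected_amplicon_length = nchar(insert)),
       insert = insert)
}

plant_inserts <- function(chrom_seqs, inserts, spacing = 2500L,
                          from = 1000L) {
  # round-robin placement of inserts across chromosomes; returns genome
  # and a record of (chromosome, planted start)
  rec <- data.frame(id = names(inserts), chromosome = "", start = 0L,
                    stringsAsFactors = FALSE)
  offsets <- setNames(rep(from, length(chrom_seqs)), names(chrom_seqs))
  for (i in seq_along(inserts)) {
    ch <- names(chrom_seqs)[((i - 1L) %% length(chrom_seqs)) + 1L]
    at <- offsets[[ch]]
    s <- chrom_seqs[[ch]]
    chrom_seqs[[ch]] <- paste0(substr(s, 1, at - 1L), inserts[[i]],
                               substr(s, at, nchar(s)))
    rec$chromosome[i] <- ch
    rec$start[i] <- at
    offsets[[ch]] <- at + nchar(inserts[[i]]) + spacing
  }
  # planted starts for earlier inserts on the same chromosome stay valid
  # because insertions proceed left to right
  list(genome = chrom_seqs, record = rec)
}

# all permutations of 1..n as a matrix (rows), n <= 8
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (k in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      row <- row + 1L
      out[row, ] <- append(sub[k, ], n, after = pos - 1L)
    }
  }
  out
}

# small deterministic model genome helper
tiny_genome <- function(n_chrom = 2L, n_markers = 60L, seed = 42L) {
  default_genome(n_chrom, n_markers, seed = seed)
}
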