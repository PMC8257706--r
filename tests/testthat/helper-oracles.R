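# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementation: CIGAR expansion into
# explicit (reference position, read base) pairs, quadratic interval scans,
# PMF summation, and exhaustive ECDF evaluation.

# expand a read into one (refpos, base) pair per aligned base
oracle_expand_cigar <- function(pos, cigar, seq) {
  lens <- as.integer(regmatches(cigar, gregexpr("\\d+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z]", cigar))[[1]]
  refpos <- integer(0)
  base <- character(0)
  rp <- pos
  qp <- 1L
  for (i in seq_along(ops)) {
    if (ops[i] == "M") {
      for (k in seq_len(lens[i])) {
        refpos <- c(refpos, rp)
        base <- c(base, substr(seq, qp, qp))
        rp <- rp + 1L
        qp <- qp + 1L
      }
    } else if (ops[i] %in% c("N", "D")) {
      rp <- rp + lens[i]
    } else if (ops[i] %in% c("I", "S")) {
      qp <- qp + lens[i]
    }
  }
  data.frame(refpos = refpos, base = base)
}

oracle_assign <- function(chrom, pos, cigar, seq, snps) {
  pairs <- oracle_expand_cigar(pos, cigar, seq)
  s <- snps[snps$chrom == chrom, ]
  g1 <- 0L; g2 <- 0L; seen <- 0L
  for (i in seq_len(nrow(s))) {
    hit <- which(pairs$refpos == s$pos[i])
    if (length(hit)) {
      seen <- seen + 1L
      if (pairs$base[hit] == s$ref[i]) g1 <- g1 + 1L
      if (pairs$base[hit] == s$alt[i]) g2 <- g2 + 1L
    }
  }
  cat_ <- if (g1 >= 1 && g2 >= 1) "CONFLICTING"
  else if (g1 >= 1) "GENOME1"
  else if (g2 >= 1) "GENOME2"
  else "UNASSIGNED"
  list(category = cat_, n_snps_seen = seen, n_g1_bases = g1, n_g2_bases = g2)
}

# nested-loop SNP set intersection on (chrom, pos, ref, alt)
oracle_intersect_snps <- function(a, b) {
  keep <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] && a$pos[i] == b$pos[j] &&
          a$ref[i] == b$ref[j] && a$alt[i] == b$alt[j]) {
        keep[i] <- TRUE
        break
      }
    }
  }
  a[keep, ]
}

# quadratic overlap scan over 1-based closed intervals
oracle_overlapping <- function(a, b) {
  hit <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] <= b$end[j] && b$start[j] <= a$end[i]) {
        hit[i] <- TRUE
        break
      }
    }
  }
  hit
}

# exhaustive min-gap scan; NA when no peak shares the chromosome
oracle_nearest <- function(a, b) {
  out <- rep(NA_integer_, nrow(a))
  for (i in seq_len(nrow(a))) {
    best <- NA_integer_
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      d <- if (a$start[i] <= b$end[j] && b$start[j] <= a$end[i]) 0L
      else if (b$start[j] > a$end[i]) b$start[j] - a$end[i] - 1L
      else a$start[i] - b$end[j] - 1L
      if (is.na(best) || d < best) best <- d
    }
    out[i] <- best
  }
  out
}

# sup over all pooled thresholds of |ECDF_x - ECDF_y|
oracle_ks_D <- function(x, y) {
  D <- 0
  for (t in c(x, y)) {
    d <- abs(mean(x <= t) - mean(y <= t))
    if (d > D) D <- d
  }
  D
}

# upper tail by PMF summation
oracle_hyper <- function(k, K, n, N) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# textbook step-up BH
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- Inf
  for (i in rev(seq_len(m))) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- min(prev, 1)
  }
  q
}

# random SNP set over short chromosomes
random_snps <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000L) {
  pos <- sample.int(max_pos, n)
  chrom <- sample(chroms, n, replace = TRUE)
  dup <- duplicated(paste(chrom, pos))
  chrom <- chrom[!dup]; pos <- pos[!dup]
  ref <- sample(c("A", "C", "G", "T"), length(pos), replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1), USE.NAMES = FALSE)
  snp_table(chrom, pos, ref, alt)
}

# random reads with mixed CIGAR shapes over a known sequence space
random_reads <- function(n, chroms = c("chr1", "chr2"), max_pos = 800L) {
  shapes <- c("50M", "20M200N30M", "5S45M", "25M1D25M", "20M2I28M", "48M2S")
  data.table::data.table(
    read_id = sprintf("r%05d", seq_len(n)),
    chrom = sample(chroms, n, replace = TRUE),
    pos = sample.int(max_pos, n, replace = TRUE),
    cigar = sample(shapes, n, replace = TRUE),
    seq = vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = ""),
      character(1)),
    strand = sample(c("+", "-"), n, replace = TRUE),
    mate_pos = NA_integer_,
    is_first = TRUE,
    flag = 0L)
}
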