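mk_aln <- function(...) {
  d <- data.table::data.table(...)
  defaults <- list(cigar = "5M", seq = "AAAAA", strand = "+",
                   mate_pos = NA_integer_, is_first = TRUE, flag = 0L)
  for (nm in names(defaults))
    if (is.null(d[[nm]])) d[[nm]] <- rep(defaults[[nm]], nrow(d))
  d
}

test_that("duplicate removal keeps one record per (chrom,pos,strand,mate) key", {
  a <- mk_aln(read_id = c("a", "b"), chrom = "chr1", pos = c(10L, 10L))
  expect_equal(nrow(dedupe_alignments(a)), 1)
  # opposite strands are distinct molecules
  b <- mk_aln(read_id = c("a", "b"), chrom = "chr1", pos = c(10L, 10L),
              strand = c("+", "-"))
  expect_equal(nrow(dedupe_alignments(b)), 2)
  # distinct mate positions are distinct fragments
  d <- mk_aln(read_id = c("a", "b"), chrom = "chr1", pos = c(10L, 10L),
              mate_pos = c(100L, 200L))
  expect_equal(nrow(dedupe_alignments(d)), 2)
})

test_that("planted duplicate keys are removed exactly", {
  set.seed(5)
  base <- mk_aln(read_id = sprintf("r%03d", 1:83), chrom = "chr1",
                 pos = sort(sample.int(500, 83, replace = FALSE)))
  dup_idx <- sample.int(83, 17)
  dups <- base[dup_idx]
  dups$read_id <- paste0(dups$read_id, "_dup")
  all <- rbind(base, dups)
  data.table::setorderv(all, c("chrom", "pos"))
  out <- dedupe_alignments(all)
  expect_equal(nrow(out), 83)
  expect_equal(attr(out, "n_removed"), 17L)
  # oracle: distinct keys
  key <- paste(all$chrom, all$pos, all$strand, all$mate_pos)
  expect_equal(nrow(out), length(unique(key)))
})

test_that("unsorted input is refused with advice to sort", {
  a <- mk_aln(read_id = c("a", "b"), chrom = "chr1", pos = c(50L, 10L))
  expect_error(dedupe_alignments(a), "sort")
})

snps1 <- snp_table(c("chr1", "chr1"), c(103L, 106L), c("A", "C"), c("G", "T"))

test_that("single-read assignment follows the SNP base", {
  # read covers pos 101..105; SNP at 103 ref A alt G
  r_alt <- list(chrom = "chr1", pos = 101L, cigar = "5M", seq = "TTGTT")
  expect_equal(assign_read(r_alt, snps1)$category, "GENOME2")
  r_ref <- list(chrom = "chr1", pos = 101L, cigar = "5M", seq = "TTATT")
  expect_equal(assign_read(r_ref, snps1)$category, "GENOME1")
  # no SNP covered
  r_no <- list(chrom = "chr1", pos = 300L, cigar = "5M", seq = "TTTTT")
  expect_equal(assign_read(r_no, snps1)$category, "UNASSIGNED")
  expect_equal(assign_read(r_no, snps1)$n_snps_seen, 0L)
  # two SNPs, one base per genome
  r_conf <- list(chrom = "chr1", pos = 101L, cigar = "6M", seq = "TTATTT")
  r_conf$seq <- "TTATTT"  # pos 103 -> A (g1), pos 106 -> T (g2)
  r_conf$cigar <- "6M"
  expect_equal(assign_read(r_conf, snps1)$category, "CONFLICTING")
  # a base matching neither allele is uninformative, not conflicting
  r_err <- list(chrom = "chr1", pos = 101L, cigar = "5M", seq = "TTCTT")
  res <- assign_read(r_err, snps1)
  expect_equal(res$category, "UNASSIGNED")
  expect_equal(res$n_snps_seen, 1L)
})

test_that("the CIGAR walk skips SNPs under intron gaps and handles clips", {
  # 10M100N10M starting at 1: M covers 1..10 and 111..120
  snps <- snp_table(c("chr1", "chr1"), c(50L, 115L), c("A", "A"), c("G", "G"))
  seq20 <- paste(rep("A", 20), collapse = "")
  r <- list(chrom = "chr1", pos = 1L, cigar = "10M100N10M", seq = seq20)
  res <- assign_read(r, snps)
  expect_equal(res$n_snps_seen, 1L)  # the one at 115; 50 is inside the gap
  expect_equal(res$category, "GENOME1")
  # soft clip shifts the read frame
  r2 <- list(chrom = "chr1", pos = 113L, cigar = "3S5M",
             seq = "TTTAAGAA")  # M covers 113..117, read offset 4..8
  res2 <- assign_read(r2, snps)
  expect_equal(res2$n_snps_seen, 1L)
  expect_equal(res2$category, "GENOME2")  # base at 115 is read pos 6 -> G
  expect_error(assign_read(list(chrom = "chr1", pos = 1L, cigar = "10M",
                                seq = "AAA"), snps),
               "mismatch")
})

test_that("assignment agrees with the CIGAR-expansion oracle on random reads", {
  set.seed(19)
  snps <- random_snps(300, max_pos = 1200L)
  reads <- random_reads(2000)
  sidx <- aseimprint:::snp_index(snps)
  sdf <- as.data.frame(snps)
  for (i in seq_len(nrow(reads))) {
    got <- assign_read(reads[i], sidx)
    want <- oracle_assign(reads$chrom[i], reads$pos[i], reads$cigar[i],
                          reads$seq[i], sdf)
    expect_identical(got$category, want$category)
    expect_identical(got$n_snps_seen, want$n_snps_seen)
    expect_identical(got$n_g1_bases, want$n_g1_bases)
    expect_identical(got$n_g2_bases, want$n_g2_bases)
  }
})

test_that("fragment assignment combines mates by the category rule", {
  r_g1 <- mk_aln(read_id = "f", chrom = "chr1", pos = 101L, seq = "TTATT")
  r_un <- mk_aln(read_id = "f", chrom = "chr1", pos = 300L, seq = "TTTTT")
  r_g2 <- mk_aln(read_id = "f", chrom = "chr1", pos = 101L, seq = "TTGTT")
  expect_equal(assign_fragment(r_g1, r_un, snps1)$category, "GENOME1")
  expect_equal(assign_fragment(r_g1, r_g2, snps1)$category, "CONFLICTING")
  expect_equal(assign_fragment(r_un, NULL, snps1)$category, "UNASSIGNED")
  bad <- mk_aln(read_id = "g", chrom = "chr1", pos = 300L, seq = "TTTTT")
  expect_error(assign_fragment(r_g1, bad, snps1), "read id")
})

test_that("splitting partitions fragments exhaustively and exclusively", {
  empty <- mk_aln(read_id = character(0), chrom = character(0),
                  pos = integer(0))
  sp0 <- split_alignments(empty, snps1)
  expect_equal(unname(sp0$summary),c(0L, 0L, 0L, 0L, 0L))
  cfg <- sim_config(seed = 21, n_genes = 12, error_rate = 0.002)
  sim <- simulate_genomes(cfg)
  truth <- simulate_gene_truth(cfg)
  aln <- simulate_alignments(cfg, sim, truth, n_fragments = 1500)
  sp <- split_alignments(aln, sim$snps)
  s <- sp$summary
  expect_equal(s[["g1"]] + s[["g2"]] + s[["unassigned"]] + s[["conflicting"]],
               s[["total"]])
  expect_equal(s[["total"]], length(unique(aln$read_id)))
  # the two output streams are disjoint
  expect_length(intersect(sp$genome1$read_id, sp$genome2$read_id), 0)
})

test_that("error-free simulated fragments always go to their truth genome", {
  cfg <- sim_config(seed = 8, n_genes = 12, error_rate = 0)
  sim <- simulate_genomes(cfg)
  truth <- simulate_gene_truth(cfg)
  aln <- simulate_alignments(cfg, sim, truth, n_fragments = 3000)
  sp <- split_alignments(aln, sim$snps)
  m <- merge(sp$assignments, attr(aln, "fragments"), by = "read_id")
  expect_equal(sum(m$category == "CONFLICTING"), 0)
  informative <- m[m$n_snps_seen > 0, ]
  expect_gt(nrow(informative), 1000)
  expect_true(all(informative$category ==
                    ifelse(informative$true_allele == "M",
                           "GENOME2", "GENOME1")))
})

test_that("maternal fraction of split fragments tracks the simulated truth", {
  cfg <- sim_config(seed = 31, n_genes = 20, error_rate = 0,
                    class_props = c(biallelic = 1, maternal = 0,
                                    paternal = 0),
                    rho_biallelic = 0.7)
  sim <- simulate_genomes(cfg)
  truth <- simulate_gene_truth(cfg)
  aln <- simulate_alignments(cfg, sim, truth, n_fragments = 4000)
  sp <- split_alignments(aln, sim$snps)
  frac <- sp$summary[["g2"]] / (sp$summary[["g1"]] + sp$summary[["g2"]])
  n_inf <- sp$summary[["g1"]] + sp$summary[["g2"]]
  expect_lt(abs(frac - 0.7), 3 * sqrt(0.7 * 0.3 / n_inf))
})

test_that("SAM round-trip preserves records, tags and header", {
  cfg <- sim_config(seed = 4, n_genes = 8)
  sim <- simulate_genomes(cfg)
  truth <- simulate_gene_truth(cfg)
  aln <- simulate_alignments(cfg, sim, truth, n_fragments = 100)
  path <- tempfile(fileext = ".sam")
  write_sam(aln, path)
  back <- read_sam(path)
  expect_equal(attr(back, "header"), attr(aln, "header"))
  for (col in c("read_id", "chrom", "pos", "cigar", "seq", "strand",
                "mate_pos", "is_first", "true_allele", "true_gene"))
    expect_equal(back[[col]], aln[[col]], label = col)
})
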