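test_that("the simulator is fully deterministic under a fixed seed", {
  cfg <- sim_config(seed = 33, n_genes = 10)
  a <- simulate_genomes(cfg)
  b <- simulate_genomes(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(as.data.frame(a$snps), as.data.frame(b$snps))
  ta <- simulate_gene_truth(cfg)
  tb <- simulate_gene_truth(cfg)
  expect_identical(ta, tb)
  ca <- simulate_counts(cfg, ta)
  cb <- simulate_counts(cfg, ta)
  expect_identical(ca$bulk, cb$bulk)
  expect_identical(ca$mat, cb$mat)
  aa <- simulate_alignments(cfg, a, ta, n_fragments = 200)
  ab <- simulate_alignments(cfg, a, ta, n_fragments = 200)
  expect_identical(as.data.frame(aa), as.data.frame(ab))
  # a different seed changes the data
  other <- simulate_genomes(sim_config(seed = 34, n_genes = 10))
  expect_false(identical(as.character(a$genome), as.character(other$genome)))
})

test_that("SNP density follows the configured rate", {
  cfg0 <- sim_config(seed = 1, snp_rate = 0, n_chroms = 1,
                     chrom_length_bp = 5e5, n_genes = 4)
  expect_equal(nrow(simulate_genomes(cfg0)$snps), 0)
  cfg <- sim_config(seed = 2, snp_rate = 4e-3, n_chroms = 1,
                    chrom_length_bp = 1e6, n_genes = 4,
                    peak_far_bp = 1e5)
  n <- nrow(simulate_genomes(cfg)$snps)
  expect_lt(abs(n - 4000), 3 * sqrt(1e6 * 4e-3 * (1 - 4e-3)))
})

test_that("allelic count layers sum to the bulk layer by construction", {
  cfg <- sim_config(seed = 3, n_genes = 40)
  cnt <- simulate_counts(cfg)
  expect_identical(cnt$mat + cnt$pat, cnt$bulk)
  expect_true(all(cnt$mat >= 0) && all(cnt$pat >= 0))
  # rho = 1 silences the paternal layer
  cfg1 <- sim_config(seed = 3, n_genes = 20,
                     class_props = c(biallelic = 0, maternal = 1,
                                     paternal = 0),
                     rho_maternal = 1, loi_fraction = 0)
  cnt1 <- simulate_counts(cfg1)
  expect_true(all(cnt1$pat == 0))
  # balanced genes hover around ratio 0.5
  cfg5 <- sim_config(seed = 4, n_genes = 50,
                     class_props = c(biallelic = 1, maternal = 0,
                                     paternal = 0),
                     mu_log_mean = log(500), mu_log_sd = 0.2)
  cnt5 <- simulate_counts(cfg5)
  ratio <- sum(cnt5$mat) / sum(cnt5$bulk)
  expect_lt(abs(ratio - 0.5), 3 * sqrt(0.25 / sum(cnt5$bulk)))
})

test_that("fragments carry their allele sequence and no-SNP reads are neutral", {
  cfg <- sim_config(seed = 6, n_genes = 8, error_rate = 0)
  g <- simulate_genomes(cfg)
  truth <- simulate_gene_truth(cfg)
  aln <- simulate_alignments(cfg, g, truth, n_fragments = 300)
  # paternal (genome-1) reads must equal the reference substring exactly
  ref <- as.character(g$genome)
  pat_reads <- aln[aln$true_allele == "P" & aln$cigar == "125M"]
  for (i in seq_len(min(nrow(pat_reads), 50))) {
    expect_identical(pat_reads$seq[i],
                     substring(ref[[pat_reads$chrom[i]]], pat_reads$pos[i],
                               pat_reads$pos[i] + 124L))
  }
  # maternal reads differ from the reference only at SNP positions
  mat_reads <- aln[aln$true_allele == "M" & aln$cigar == "125M"]
  sidx <- aseimprint:::snp_index(g$snps)
  for (i in seq_len(min(nrow(mat_reads), 50))) {
    refseq <- substring(ref[[mat_reads$chrom[i]]], mat_reads$pos[i],
                        mat_reads$pos[i] + 124L)
    diffs <- which(strsplit(refseq, "")[[1]] !=
                     strsplit(mat_reads$seq[i], "")[[1]])
    spos <- sidx[[mat_reads$chrom[i]]]$pos
    expect_true(all((mat_reads$pos[i] + diffs - 1L) %in% spos))
  }
})

test_that("spliced fixtures exercise the intron gap in the CIGAR walk", {
  cfg <- sim_config(seed = 16, n_genes = 8, error_rate = 0, spliced = TRUE)
  g <- simulate_genomes(cfg)
  truth <- simulate_gene_truth(cfg)
  aln <- simulate_alignments(cfg, g, truth, n_fragments = 400)
  expect_true(any(grepl("N", aln$cigar)))
  sp <- split_alignments(aln, g$snps)
  m <- merge(sp$assignments, attr(aln, "fragments"), by = "read_id")
  inf <- m[m$category %in% c("GENOME1", "GENOME2"), ]
  expect_true(all(inf$category ==
                    ifelse(inf$true_allele == "M", "GENOME2", "GENOME1")))
})

test_that("peak placement separates imprinted and control genes", {
  cfg <- sim_config(seed = 9, n_genes = 30)
  truth <- simulate_gene_truth(cfg)
  peaks <- simulate_peaks(cfg, truth)
  d <- nearest_peak_distance(truth_gene_models(truth), peaks)
  d <- merge(d, truth[, c("gene_id", "class")], by = "gene_id")
  imp <- d$distance_bp[d$class != "biallelic"]
  ctl <- d$distance_bp[d$class == "biallelic"]
  expect_true(all(imp <= cfg$peak_near_bp))
  expect_true(all(ctl >= cfg$peak_far_bp))
  # degenerate near-offset: every imprinted gene at distance zero
  cfg0 <- sim_config(seed = 9, n_genes = 30, peak_near_bp = 0)
  d0 <- nearest_peak_distance(truth_gene_models(truth),
                              simulate_peaks(cfg0, truth))
  d0 <- merge(d0, truth[, c("gene_id", "class")], by = "gene_id")
  expect_true(all(d0$distance_bp[d0$class != "biallelic"] == 0))
})

test_that("a written simulation round-trips through the file readers", {
  dir <- file.path(tempdir(), "simrt")
  cfg <- sim_config(seed = 12, n_genes = 10)
  sim <- write_simulation(cfg, dir, n_fragments = 150)
  snps <- read_snp_table(file.path(dir, "snps.vcf"))
  expect_equal(nrow(snps), nrow(sim$genomes$snps))
  genome <- read_genome(file.path(dir, "reference.fa"))
  expect_identical(as.character(genome), as.character(sim$genomes$genome))
  models <- read_gene_models(file.path(dir, "genes.gtf"))
  expect_setequal(models$genes$gene_id, sim$truth$gene_id)
  aln <- read_sam(file.path(dir, "wt_alignments.sam"))
  expect_equal(nrow(aln), nrow(sim$alignments))
  peaks <- read_peaks(file.path(dir, "peaks.bed"))
  expect_equal(GenomicRanges::start(peaks), GenomicRanges::start(sim$peaks))
  unlink(dir, recursive = TRUE)
})
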