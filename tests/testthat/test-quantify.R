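test_that("GTF exon unions merge overlapping exons", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t11\t50\t.\t+\t.\tgene_id "gA";',
    'chr1\tx\texon\t41\t80\t.\t+\t.\tgene_id "gA";',
    'chr1\tx\texon\t200\t250\t.\t-\t.\tgene_id "gB";',
    'chr1\tx\texon\t300\t320\t.\t-\t.\tgene_id "gB";',
    'chr2\tx\texon\t5\t15\t.\t+\t.\tgene_id "gC";'), gtf)
  m <- read_gene_models(gtf)
  w <- sum(IRanges::width(m$exons[["gA"]]))
  expect_equal(w, 70)  # [11,80] after union
  expect_equal(length(m$exons[["gA"]]), 1)
  expect_equal(sum(IRanges::width(m$exons[["gB"]])), 51 + 21)
  expect_equal(m$genes[m$genes$gene_id == "gB"]$tss, 320)  # minus strand
  expect_equal(m$genes[m$genes$gene_id == "gC"]$start, 5)
})

test_that("BED12 blocks become exons; BED single intervals one exon", {
  bed <- tempfile(fileext = ".bed")
  # one 2-block gene: blocks at [100,150) and [300,360) zero-based
  writeLines("chr1\t100\t360\tgX\t0\t+\t100\t360\t0\t2\t50,60\t0,200", bed)
  m <- read_gene_models(bed)
  ex <- m$exons[["gX"]]
  expect_equal(GenomicRanges::start(ex), c(101, 301))
  expect_equal(GenomicRanges::end(ex), c(150, 360))
  bed3 <- tempfile(fileext = ".bed")
  writeLines("chr1\t10\t90\tgY", bed3)
  m2 <- read_gene_models(bed3)
  expect_equal(sum(IRanges::width(m2$exons[["gY"]])), 80)
})

test_that("GTF writer round-trips simulated gene models", {
  cfg <- sim_config(seed = 2, n_genes = 10)
  truth <- simulate_gene_truth(cfg)
  models <- truth_gene_models(truth)
  path <- tempfile(fileext = ".gtf")
  write_gene_models(models, path)
  back <- read_gene_models(path)
  expect_equal(back$genes$gene_id, models$genes$gene_id)
  expect_equal(back$genes$start, models$genes$start)
  expect_equal(back$genes$end, models$genes$end)
})

test_that("fragment counting honours exon overlap and ambiguity rules", {
  models <- gene_models(c("g1", "g2"), "chr1", c(101L, 501L), c(200L, 600L))
  aln <- data.table::data.table(
    read_id = c("in1", "in1", "span", "out"),
    chrom = "chr1",
    pos = c(110L, 150L, 180L, 900L),
    cigar = c("20M", "20M", "330M", "20M"),
    seq = c(strrep("A", 20), strrep("A", 20), strrep("A", 330), strrep("A", 20)),
    strand = "+", mate_pos = NA_integer_, is_first = TRUE, flag = 0L)
  cnt <- count_fragments(aln, models)
  expect_equal(unname(cnt["g1"]), 1L)   # both mates inside g1 count once
  expect_equal(unname(cnt["g2"]), 0L)   # spanning fragment discarded
  expect_equal(attr(cnt, "n_ambiguous"), 1L)
  expect_equal(attr(cnt, "n_unassigned"), 1L)
})

test_that("counting recovers simulator truth exactly when genes are disjoint", {
  cfg <- sim_config(seed = 13, n_genes = 15, error_rate = 0)
  sim <- simulate_genomes(cfg)
  truth <- simulate_gene_truth(cfg)
  aln <- simulate_alignments(cfg, sim, truth, n_fragments = 1000)
  cnt <- count_fragments(aln, truth_gene_models(truth))
  want <- table(factor(attr(aln, "fragments")$true_gene,
                       levels = truth$gene_id))
  expect_equal(unname(as.integer(cnt[truth$gene_id])),
               unname(as.integer(want)))
  expect_lte(sum(cnt), length(unique(aln$read_id)))
})

test_that("low-expression and X-chromosome filters apply the strict cutoff", {
  bulk <- matrix(c(5, 4, 4, 4, 0, 0), 3, 2, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  kept <- filter_low_expression(bulk, cfg = ase_config())
  expect_equal(rownames(kept), "a")  # totals 9, 8, 0; strict > 8
  chrom <- c(a = "chr1", b = "chr1", x = "chrX")
  bulk2 <- matrix(c(100, 100, 100, 100, 500, 500), 3, 2, byrow = TRUE,
                  dimnames = list(c("a", "b", "x"), c("s1", "s2")))
  expect_equal(rownames(filter_low_expression(bulk2, chrom)), c("a", "b"))
  empty <- bulk[0, , drop = FALSE]
  expect_equal(nrow(filter_low_expression(empty)), 0)
})

test_that("median-of-ratios size factors match hand-computed values", {
  eq <- matrix(c(3, 3, 7, 7, 12, 12), 3, 2, byrow = TRUE)
  expect_equal(unname(estimate_size_factors(eq)), c(1, 1))
  m <- matrix(c(2, 4, 3, 6, 4, 8), 3, 2, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  sf <- estimate_size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  # permutation invariance
  expect_equal(estimate_size_factors(m[c(3, 1, 2), ]), sf)
  # scaling one column by c: the geometric means move too, so the factor
  # RATIO between the scaled and unscaled samples scales by c
  m2 <- m; m2[, 2] <- m2[, 2] * 5
  sf2 <- estimate_size_factors(m2)
  expect_equal(unname(sf2), c(1 / sqrt(10), sqrt(10)), tolerance = 1e-12)
  expect_equal(sf2[[2]] / sf2[[1]], 5 * sf[[2]] / sf[[1]], tolerance = 1e-12)
  # no reference gene
  z <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_error(estimate_size_factors(z), "reference")
})

test_that("allelic normalization shares the bulk divisor and preserves ratios", {
  mat <- matrix(c(10, 20), 1, 2, dimnames = list("g", c("s1", "s2")))
  pat <- matrix(c(30, 10), 1, 2, dimnames = list("g", c("s1", "s2")))
  sf <- c(s1 = 2, s2 = 1)
  out <- normalize_allelic_counts(mat, pat, sf)
  expect_equal(unname(out$mat[1, ]), c(5, 20))
  expect_equal(unname(out$pat[1, ]), c(15, 10))
  expect_equal(out$mat / (out$mat + out$pat), mat / (mat + pat))
  set.seed(99)
  rm <- matrix(rpois(60, 30), 10, 6,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  rp <- matrix(rpois(60, 30), 10, 6, dimnames = dimnames(rm))
  rsf <- stats::setNames(runif(6, 0.5, 2), colnames(rm))
  nrm <- normalize_allelic_counts(rm, rp, rsf)
  expect_equal(nrm$mat / (nrm$mat + nrm$pat), rm / (rm + rp))
  expect_error(normalize_allelic_counts(rm, rp, rsf * 0), "positive")
})

test_that("allelic coverage filter needs failure in every wild-type replicate", {
  nm <- matrix(c(4, 4, 4, 6, 5, 0), 3, 2, byrow = TRUE,
               dimnames = list(c("both_low", "one_ok", "boundary"),
                               c("wt1", "wt2")))
  np <- matrix(c(5, 5, 5, 5, 5, 0), 3, 2, byrow = TRUE, dimnames = dimnames(nm))
  kept <- filter_allelic(nm, np, c("wt1", "wt2"))
  # sums: (9,9) removed; (9,11) kept; (10,0) kept (10 is not < 10)
  expect_setequal(kept, c("one_ok", "boundary"))
  expect_error(filter_allelic(nm, np, character(0)), "non-empty")
})

test_that("marker Z-scores standardise after UQ and reference adjustment", {
  bulk <- matrix(c(100, 220, 50, 55, 10, 44, 80, 88, 30, 33), 5, 2,
                 byrow = TRUE,
                 dimnames = list(c("Actb", "m1", "m2", "m3", "m4"),
                                 c("s1", "s2")))
  # the reference gene itself is constant (=1) after adjustment -> warning
  expect_warning(z <- marker_zscores(bulk, "Actb"), "constant")
  expect_equal(unname(z["Actb", ]), c(0, 0))
  # two samples: every non-constant gene is +/- 1/sqrt(2) with sample SD
  nonzero <- z[abs(z[, 1]) > 1e-12, ]
  expect_true(all(abs(abs(nonzero) - 1 / sqrt(2)) < 1e-12))
  # a gene proportional to Actb is constant after adjustment
  z2 <- suppressWarnings(marker_zscores(rbind(bulk, flat = bulk["Actb", ] * 3),
                                        "Actb"))
  expect_equal(unname(z2["flat", ]), c(0, 0))
  # scaling one sample's raw column leaves its Z column unchanged
  bulk3 <- bulk; bulk3[, 2] <- bulk3[, 2] * 10
  expect_equal(suppressWarnings(marker_zscores(bulk3, "Actb")), z)
  expect_error(marker_zscores(bulk, "nope"), "not in matrix")
})
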