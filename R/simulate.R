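#' Simulation configuration for a hybrid F1 cross
#'
#' Defines the study-like conditions the simulator emulates: a diploid
#' genome pair differing at known SNP positions at a density of about 4.5
#' SNPs/kb (the JF1 vs B6 divergence is above 4/kb), paired-end 2 x 125 bp
#' fragments, negative-binomial gene counts with two biological replicates
#' per condition, imprinted genes with strong parental bias (maternal rho
#' 0.95, paternal rho 0.05, biallelic 0.5), a configurable fraction of
#' imprinted genes losing imprinting (rho -> 0.5) in the mutant condition,
#' condition-dependent fold changes, library-size differences, and peak
#' intervals placed near imprinted genes and far from controls.
#'
#' @param seed integer seed; every simulator function derives its RNG
#'   stream from it, so outputs are fully reproducible.
#' @param n_chroms,chrom_length_bp genome shape.
#' @param n_genes,gene_length_bp number and length of (single-exon,
#'   non-overlapping) genes, placed deterministically along the
#'   chromosomes.
#' @param snp_rate SNPs per bp between the two strains.
#' @param class_props named proportions for gene classes
#'   (`biallelic`/`maternal`/`paternal`); must sum to 1.
#' @param rho_maternal,rho_paternal,rho_biallelic true maternal allelic
#'   fractions per class.
#' @param loi_fraction fraction of imprinted genes that lose imprinting
#'   (rho -> 0.5) in the mutant condition.
#' @param n_replicates biological replicates per condition.
#' @param mu_log_mean,mu_log_sd log-normal distribution of gene mean
#'   expression.
#' @param nb_dispersion NB dispersion alpha (Var = mu + alpha mu^2).
#' @param de_fraction,de_log2_fc fraction of genes with a planted fold
#'   change and its magnitude (sign randomised).
#' @param library_size_factors per-sample relative library sizes, recycled
#'   over samples.
#' @param read_length,fragment_size read geometry (bp).
#' @param error_rate per-base sequencing error probability.
#' @param spliced emit spliced (M-N-M) first mates to exercise the CIGAR
#'   walk.
#' @param intron_length_bp N-gap length for spliced reads.
#' @param peak_near_bp,peak_far_bp,peak_width_bp peak placement: imprinted
#'   genes get a peak within `peak_near_bp` of the gene, control genes a
#'   decoy at least `peak_far_bp` away.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L, chrom_length_bp = 3e6,
                       n_genes = 60L, gene_length_bp = 2000L,
                       snp_rate = 0.0045,
                       class_props = c(biallelic = 0.7, maternal = 0.15,
                                       paternal = 0.15),
                       rho_maternal = 0.95, rho_paternal = 0.05,
                       rho_biallelic = 0.5,
                       loi_fraction = 0.5,
                       n_replicates = 2L,
                       mu_log_mean = log(200), mu_log_sd = 1,
                       nb_dispersion = 0.05,
                       de_fraction = 0.1, de_log2_fc = 2,
                       library_size_factors = c(1, 1.25, 0.8, 1.1),
                       read_length = 125L, fragment_size = 300L,
                       error_rate = 0.001,
                       spliced = FALSE, intron_length_bp = 200L,
                       peak_near_bp = 5e4, peak_far_bp = 1e6,
                       peak_width_bp = 600L) {
  stopifnot(abs(sum(class_props) - 1) < 1e-8,
            all(names(class_props) %in% c("biallelic", "maternal", "paternal")),
            rho_maternal >= 0, rho_maternal <= 1,
            rho_paternal >= 0, rho_paternal <= 1,
            snp_rate >= 0, error_rate >= 0, error_rate < 1,
            fragment_size >= read_length,
            gene_length_bp >= fragment_size)
  structure(as.list(environment()), class = "sim_config")
}

.sim_seed <- function(cfg, stream) {
  # distinct, platform-stable substreams per simulator stage; double
  # arithmetic avoids 32-bit overflow for large user seeds
  set.seed(as.integer((as.numeric(cfg$seed) * 1000 + stream) %% 2147483647))
}

#' Simulate the reference genome and strain SNPs
#'
#' The reference plays the genome-1 (B6, paternal) role; SNP alternate
#' alleles define genome 2 (JF1, maternal). SNP positions are i.i.d. at
#' `snp_rate` per bp.
#'
#' @param cfg a [sim_config()].
#' @return list with `genome` (a [Biostrings::DNAStringSet]) and `snps`
#'   (a SNP `data.table`).
#' @export
simulate_genomes <- function(cfg) {
  .sim_seed(cfg, 1L)
  bases <- c("A", "C", "G", "T")
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  seqs <- vapply(chroms, function(ch)
    paste(sample(bases, cfg$chrom_length_bp, replace = TRUE), collapse = ""),
    character(1))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms
  chrom <- character(0); pos <- integer(0); ref <- character(0); alt <- character(0)
  for (ch in chroms) {
    n_snp <- stats::rbinom(1, cfg$chrom_length_bp, cfg$snp_rate)
    if (n_snp == 0) next
    p <- sort(sample.int(cfg$chrom_length_bp, n_snp))
    r <- substring(seqs[[ch]], p, p)
    a <- vapply(r, function(b) sample(setdiff(bases, b), 1), character(1),
                USE.NAMES = FALSE)
    chrom <- c(chrom, rep(ch, n_snp)); pos <- c(pos, p)
    ref <- c(ref, r); alt <- c(alt, a)
  }
  list(genome = genome, snps = snp_table(chrom, pos, ref, alt))
}

#' Simulate gene placement and per-gene truth
#'
#' Genes are single-exon, non-overlapping, placed deterministically along
#' the chromosomes with wide spacing; classes, expression means and
#' planted fold changes are drawn under the configured proportions. The
#' returned table is the gene-level truth manifest.
#'
#' @param cfg a [sim_config()].
#' @return a `data.table` with `gene_id`, coordinates, `class`, true
#'   maternal fraction per condition (`rho_wt`, `rho_mut`, with
#'   `loi_fraction` of imprinted genes reset to 0.5 in the mutant),
#'   `log2_fc`, `mu` and `dispersion`.
#' @export
simulate_gene_truth <- function(cfg) {
  .sim_seed(cfg, 2L)
  n <- cfg$n_genes
  cls <- sample(names(cfg$class_props), n, replace = TRUE,
                prob = cfg$class_props)
  # Imprinted genes cluster at the left end of each chromosome, control
  # (biallelic) genes at the right, separated by a buffer wider than the
  # far-peak distance: binding-site peaks placed near the imprinted block
  # are then guaranteed to be far from every control gene, mirroring the
  # clustering of imprinted loci around their control regions.
  margin <- 5e4
  spacing <- cfg$gene_length_bp + 1000L
  buffer <- cfg$peak_far_bp + cfg$peak_near_bp + cfg$peak_width_bp + 1e4
  chrom_of <- paste0("chr", ((seq_len(n) - 1L) %% cfg$n_chroms) + 1L)
  start <- integer(n)
  for (ch in unique(chrom_of)) {
    on_ch <- which(chrom_of == ch)
    imp <- on_ch[cls[on_ch] != "biallelic"]
    ctl <- on_ch[cls[on_ch] == "biallelic"]
    pos <- margin + 1L
    for (i in imp) { start[i] <- as.integer(pos); pos <- pos + spacing }
    pos <- pos + buffer
    for (i in ctl) { start[i] <- as.integer(pos); pos <- pos + spacing }
    # room for the decoy peaks placed peak_far_bp beyond the control block
    need <- pos + cfg$peak_far_bp +
      length(ctl) * (cfg$peak_width_bp + 200L) + margin
    if (need > cfg$chrom_length_bp)
      stop("chromosomes too short for the requested gene count; need ~",
           format(need, big.mark = ","), " bp")
  }
  chrom <- chrom_of
  end <- as.integer(start + cfg$gene_length_bp - 1L)
  rho <- c(biallelic = cfg$rho_biallelic, maternal = cfg$rho_maternal,
           paternal = cfg$rho_paternal)[cls]
  imprinted <- cls %in% c("maternal", "paternal")
  loi <- imprinted & stats::runif(n) < cfg$loi_fraction
  rho_mut <- ifelse(loi, 0.5, rho)
  lfc <- ifelse(stats::runif(n) < cfg$de_fraction,
                cfg$de_log2_fc * sample(c(-1, 1), n, replace = TRUE), 0)
  data.table::data.table(
    gene_id = sprintf("gene%03d", seq_len(n)),
    chrom = chrom, start = start, end = end, strand = "+",
    class = cls, rho_wt = unname(rho), rho_mut = rho_mut,
    loses_imprinting = loi,
    log2_fc = lfc,
    mu = stats::rlnorm(n, cfg$mu_log_mean, cfg$mu_log_sd),
    dispersion = cfg$nb_dispersion)
}

#' Gene models of a simulated gene set
#'
#' @param truth output of [simulate_gene_truth()].
#' @return gene models (see [gene-models]).
#' @export
truth_gene_models <- function(truth) {
  gene_models(truth$gene_id, truth$chrom, truth$start, truth$end,
              truth$strand)
}

#' Simulate bulk and allele-resolved count matrices
#'
#' Per gene and sample the total count is NB with mean
#' `s_j mu_i 2^(lfc_i x_j)` and dispersion `alpha_i`; the maternal count
#' is binomial in the total with the condition's true maternal fraction;
#' the paternal count is the remainder, so maternal + paternal equals the
#' bulk count by construction.
#'
#' @param cfg a [sim_config()].
#' @param truth gene truth from [simulate_gene_truth()]; generated when
#'   `NULL`.
#' @return list with matrices `bulk`, `mat`, `pat`, the `truth` table, and
#'   `samples` (`sample_id`, `condition`, `size_factor`).
#' @export
simulate_counts <- function(cfg, truth = NULL) {
  if (is.null(truth)) truth <- simulate_gene_truth(cfg)
  .sim_seed(cfg, 3L)
  conditions <- rep(c("wt", "mut"), each = cfg$n_replicates)
  sample_id <- paste0(conditions, rep(seq_len(cfg$n_replicates), 2))
  sf <- rep_len(cfg$library_size_factors, length(sample_id))
  n <- nrow(truth)
  bulk <- mat <- matrix(0L, n, length(sample_id),
                        dimnames = list(truth$gene_id, sample_id))
  for (j in seq_along(sample_id)) {
    x <- as.numeric(conditions[j] == "mut")
    mu <- sf[j] * truth$mu * 2^(truth$log2_fc * x)
    tot <- stats::rnbinom(n, mu = mu, size = 1 / truth$dispersion)
    rho <- if (x == 1) truth$rho_mut else truth$rho_wt
    m <- stats::rbinom(n, tot, rho)
    bulk[, j] <- tot
    mat[, j] <- m
  }
  pat <- bulk - mat
  list(bulk = bulk, mat = mat, pat = pat, truth = truth,
       samples = data.table::data.table(sample_id = sample_id,
                                        condition = conditions,
                                        size_factor = sf))
}

# substitute the alternate allele at SNP positions -> genome-2 haplotype
.haplotype2 <- function(genome, snps) {
  out <- genome
  for (ch in intersect(names(genome), unique(snps$chrom))) {
    s <- snps[snps$chrom == ch]
    out[[ch]] <- Biostrings::replaceLetterAt(genome[[ch]], s$pos, s$alt)
  }
  out
}

.add_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  n_err <- stats::rbinom(length(seqs), nchar(seqs), rate)
  for (i in which(n_err > 0)) {
    pos <- sample.int(nchar(seqs[i]), n_err[i])
    ch <- strsplit(seqs[i], "")[[1]]
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(bases, b), 1),
                      character(1), USE.NAMES = FALSE)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate paired-end alignments with allele-of-origin truth
#'
#' Fragments are placed uniformly within gene spans; sequences are copied
#' from the haplotype of the fragment's allele of origin (the alternate
#' allele substituted at SNP positions for genome-2 fragments), with
#' per-base errors at `error_rate`. Each fragment yields a forward first
#' mate and a reverse second mate of `read_length` bp; with
#' `cfg$spliced`, first mates get an M-N-M CIGAR spanning an intron-like
#' gap. Truth tags record the allele (`M`/`P`) and gene of origin.
#'
#' @param cfg a [sim_config()].
#' @param genomes output of [simulate_genomes()].
#' @param truth gene truth table.
#' @param mat_frags,pat_frags named per-gene fragment counts for the
#'   sample being simulated; defaults draw `n_fragments` fragments with
#'   per-gene allele of origin `rho_wt`.
#' @param n_fragments total fragments when explicit counts are not given.
#' @return an alignment `data.table` sorted by `(chrom, pos)`, two rows
#'   per fragment, with `true_allele` and `true_gene` columns; the truth
#'   manifest of emitted fragments is in `attr(x, "fragments")`.
#' @export
simulate_alignments <- function(cfg, genomes, truth,
                                mat_frags = NULL, pat_frags = NULL,
                                n_fragments = 2e4) {
  .sim_seed(cfg, 4L)
  if (is.null(mat_frags) || is.null(pat_frags)) {
    gene_of <- sample(nrow(truth), n_fragments, replace = TRUE)
    is_mat <- stats::runif(n_fragments) < truth$rho_wt[gene_of]
    mat_frags <- tabulate(gene_of[is_mat], nrow(truth))
    pat_frags <- tabulate(gene_of[!is_mat], nrow(truth))
    names(mat_frags) <- names(pat_frags) <- truth$gene_id
  }
  mat_frags <- mat_frags[truth$gene_id]
  pat_frags <- pat_frags[truth$gene_id]
  hap1 <- as.character(genomes$genome)
  hap2 <- as.character(.haplotype2(genomes$genome, genomes$snps))
  gene_idx <- rep(seq_len(nrow(truth)), mat_frags + pat_frags)
  allele <- unlist(mapply(function(m, p) c(rep("M", m), rep("P", p)),
                          mat_frags, pat_frags, SIMPLIFY = FALSE))
  n <- length(gene_idx)
  if (!n) stop("no fragments to simulate")
  g <- truth[gene_idx]
  rl <- cfg$read_length; fs <- cfg$fragment_size
  intron <- if (cfg$spliced) cfg$intron_length_bp else 0L
  span <- fs + intron
  if (any(g$end - g$start + 1L < span))
    stop("gene span shorter than the (spliced) fragment span")
  frag_start <- g$start + floor(stats::runif(n) * (g$end - g$start + 1L - span))
  hap <- ifelse(allele == "M", hap2[g$chrom], hap1[g$chrom])
  r2_start <- frag_start + span - rl
  if (cfg$spliced) {
    half <- rl %/% 2L
    r1_cigar <- rep(sprintf("%dM%dN%dM", half, intron, rl - half), n)
    r1_seq <- paste0(substring(hap, frag_start, frag_start + half - 1L),
                     substring(hap, frag_start + half + intron,
                               frag_start + intron + rl - 1L))
  } else {
    r1_cigar <- rep(sprintf("%dM", rl), n)
    r1_seq <- substring(hap, frag_start, frag_start + rl - 1L)
  }
  r2_seq <- substring(hap, r2_start, r2_start + rl - 1L)
  r1_seq <- .add_errors(r1_seq, cfg$error_rate)
  r2_seq <- .add_errors(r2_seq, cfg$error_rate)
  read_id <- sprintf("frag%06d", seq_len(n))
  aln <- data.table::data.table(
    read_id = rep(read_id, 2),
    chrom = rep(g$chrom, 2),
    pos = c(frag_start, r2_start),
    cigar = c(r1_cigar, rep(sprintf("%dM", rl), n)),
    seq = c(r1_seq, r2_seq),
    strand = rep(c("+", "-"), each = n),
    mate_pos = c(r2_start, frag_start),
    is_first = rep(c(TRUE, FALSE), each = n),
    flag = c(rep(.pair_flag(TRUE, FALSE), n),
             rep(.pair_flag(FALSE, TRUE), n)),
    true_allele = rep(allele, 2),
    true_gene = rep(g$gene_id, 2))
  data.table::setorderv(aln, c("chrom", "pos"))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genomes$genome),
                   Biostrings::width(genomes$genome)))
  data.table::setattr(aln, "header", hdr)
  data.table::setattr(aln, "fragments",
                      data.table::data.table(read_id = read_id,
                                             true_allele = allele,
                                             true_gene = g$gene_id))
  aln[]
}

#' Simulate binding-site peaks spatially linked to imprinted genes
#'
#' Every imprinted gene gets one peak placed within `peak_near_bp`
#' downstream of the gene span; every biallelic control gene gets a decoy
#' peak at least `peak_far_bp` away, emulating binding sites concentrated
#' at imprinted loci.
#'
#' @param cfg a [sim_config()].
#' @param truth gene truth table.
#' @return a named `GRanges` of peaks.
#' @export
simulate_peaks <- function(cfg, truth) {
  .sim_seed(cfg, 5L)
  imprinted <- truth$class %in% c("maternal", "paternal")
  start <- integer(nrow(truth))
  # one peak just downstream of each imprinted gene
  gap <- floor(stats::runif(sum(imprinted)) * (cfg$peak_near_bp + 1))
  start[imprinted] <- truth$end[imprinted] + 1L + as.integer(gap)
  # decoy peaks in a block beyond the whole control block, so every
  # control gene is at least peak_far_bp from any peak
  for (ch in unique(truth$chrom)) {
    ctl <- which(!imprinted & truth$chrom == ch)
    if (!length(ctl)) next
    base <- max(truth$end[truth$chrom == ch]) + cfg$peak_far_bp + 1L
    start[ctl] <- as.integer(base +
      (seq_along(ctl) - 1L) * (cfg$peak_width_bp + 200L))
  }
  gr <- GenomicRanges::GRanges(
    truth$chrom, IRanges::IRanges(start, start + cfg$peak_width_bp - 1L))
  names(gr) <- paste0("peak_", truth$gene_id)
  gr
}

#' Write a SNP table as a minimal VCF 4.2 file
#'
#' @param snps SNP `data.table`.
#' @param path output path.
#' @export
write_vcf <- function(snps, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                  snps$chrom, snps$pos, snps$ref, snps$alt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a full simulated study to a directory
#'
#' Emits the reference FASTA, the SNP VCF, a GTF of gene models, a BED of
#' peaks, one SAM of truth-tagged wild-type alignments, count matrices,
#' the sample sheet and the truth manifest, all as plain text.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created).
#' @param n_fragments fragments in the emitted SAM.
#' @return invisibly, the list of generated objects.
#' @export
write_simulation <- function(cfg, dir, n_fragments = 2e4) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genomes <- simulate_genomes(cfg)
  truth <- simulate_gene_truth(cfg)
  counts <- simulate_counts(cfg, truth)
  aln <- simulate_alignments(cfg, genomes, truth, n_fragments = n_fragments)
  peaks <- simulate_peaks(cfg, truth)
  write_genome(genomes$genome, file.path(dir, "reference.fa"))
  write_vcf(genomes$snps, file.path(dir, "snps.vcf"))
  write_gene_models(truth_gene_models(truth), file.path(dir, "genes.gtf"))
  write_peaks(peaks, file.path(dir, "peaks.bed"))
  write_sam(aln, file.path(dir, "wt_alignments.sam"))
  for (layer in c("bulk", "mat", "pat"))
    data.table::fwrite(
      data.table::data.table(gene_id = rownames(counts[[layer]]),
                             counts[[layer]]),
      file.path(dir, paste0("counts_", layer, ".tsv")), sep = "\t")
  data.table::fwrite(counts$samples, file.path(dir, "samples.tsv"), sep = "\t")
  data.table::fwrite(truth, file.path(dir, "truth_genes.tsv"), sep = "\t")
  invisible(list(genomes = genomes, truth = truth, counts = counts,
                 alignments = aln, peaks = peaks))
}
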