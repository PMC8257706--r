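#' Convert alignments to GRanges of aligned blocks
#'
#' Expands each record's CIGAR into its M segments (the bases actually
#' aligned to the reference); N/D gaps contribute no block.
#'
#' @param alignments an alignment `data.table`.
#' @return a [GenomicRanges::GRanges] with metadata column `read_id`.
#' @keywords internal
aligned_blocks <- function(alignments) {
  a <- alignments
  simple <- grepl("^\\d+M$", a$cigar)
  starts <- integer(0); ends <- integer(0); chroms <- character(0)
  ids <- character(0)
  if (any(simple)) {
    len <- as.integer(sub("M$", "", a$cigar[simple]))
    starts <- a$pos[simple]
    ends <- a$pos[simple] + len - 1L
    chroms <- a$chrom[simple]
    ids <- a$read_id[simple]
  }
  for (i in which(!simple)) {
    cg <- parse_cigar(a$cigar[i])
    refp <- a$pos[i]
    for (k in seq_along(cg$op)) {
      if (cg$op[k] == "M") {
        starts <- c(starts, refp); ends <- c(ends, refp + cg$len[k] - 1L)
        chroms <- c(chroms, a$chrom[i]); ids <- c(ids, a$read_id[i])
        refp <- refp + cg$len[k]
      } else if (cg$op[k] %in% c("N", "D")) {
        refp <- refp + cg$len[k]
      }
    }
  }
  GenomicRanges::GRanges(chroms, IRanges::IRanges(starts, ends),
                         read_id = ids)
}

#' Count fragments per gene
#'
#' A fragment (read pair sharing a `read_id`) counts once for a gene when at
#' least one aligned base overlaps the gene's exon union; fragments whose
#' aligned bases touch the exons of more than one gene are discarded as
#' ambiguous, and fragments touching no exon are intergenic. This mirrors
#' the default semantics of paired fragment counting in featureCounts.
#'
#' @param alignments a deduplicated alignment `data.table` for one sample.
#' @param models gene models (see [gene-models]).
#' @return a named integer vector over all genes in `models`, with
#'   attributes `n_ambiguous` and `n_unassigned` (fragment counts).
#' @export
count_fragments <- function(alignments, models) {
  gene_ids <- names(models$exons)
  counts <- stats::setNames(integer(length(gene_ids)), gene_ids)
  n_frag <- length(unique(alignments$read_id))
  if (!nrow(alignments)) {
    attr(counts, "n_ambiguous") <- 0L
    attr(counts, "n_unassigned") <- 0L
    return(counts)
  }
  blocks <- aligned_blocks(alignments)
  hits <- GenomicRanges::findOverlaps(blocks, models$exons, ignore.strand = TRUE)
  pairs <- unique(data.table::data.table(
    read_id = blocks$read_id[S4Vectors::queryHits(hits)],
    gene = S4Vectors::subjectHits(hits)))
  genes_per_frag <- pairs[, list(n = data.table::uniqueN(gene)), by = "read_id"]
  unambiguous <- genes_per_frag$read_id[genes_per_frag$n == 1L]
  hit1 <- pairs[pairs$read_id %in% unambiguous]
  tab <- hit1[, list(count = data.table::uniqueN(read_id)), by = "gene"]
  counts[gene_ids[tab$gene]] <- tab$count
  attr(counts, "n_ambiguous") <- sum(genes_per_frag$n > 1L)
  attr(counts, "n_unassigned") <- n_frag - nrow(genes_per_frag)
  counts
}

#' Count fragments per gene across samples
#'
#' @param sample_alignments named list of alignment `data.table`s, one per
#'   sample.
#' @param models gene models.
#' @return an integer matrix genes x samples.
#' @export
count_matrix <- function(sample_alignments, models) {
  stopifnot(length(sample_alignments) > 0, !is.null(names(sample_alignments)))
  cols <- lapply(sample_alignments, count_fragments, models = models)
  mat <- do.call(cbind, lapply(cols, as.integer))
  dimnames(mat) <- list(names(models$exons), names(sample_alignments))
  mat
}

#' Filter out low-expression genes and excluded chromosomes
#'
#' Genes on `cfg$excluded_chroms` are removed, then genes whose grand total
#' across all samples is not strictly greater than `cfg$min_bulk_count`.
#'
#' @param bulk counts matrix (genes x samples).
#' @param gene_chrom named character vector mapping gene id to chromosome;
#'   genes absent from it are kept (chromosome unknown).
#' @param cfg an [ase_config()].
#' @return the filtered matrix.
#' @export
filter_low_expression <- function(bulk, gene_chrom = NULL, cfg = ase_config()) {
  keep <- rep(TRUE, nrow(bulk))
  if (!is.null(gene_chrom) && nrow(bulk)) {
    chrom <- gene_chrom[rownames(bulk)]
    keep <- keep & !(chrom %in% cfg$excluded_chroms)
  }
  keep <- keep & rowSums(bulk) > cfg$min_bulk_count
  bulk[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' For each gene the geometric mean of its counts across samples is taken;
#' genes with a positive geometric mean (no zero count) are the reference
#' set. A sample's size factor is the median over reference genes of the
#' ratio of its count to the gene's geometric mean.
#'
#' @param counts matrix (genes x samples), at least one reference gene.
#' @return named positive numeric vector of per-sample size factors.
#' @export
estimate_size_factors <- function(counts) {
  stopifnot(is.matrix(counts), ncol(counts) >= 1)
  loggeo <- rowMeans(log(counts))
  ref <- is.finite(loggeo)
  if (!any(ref))
    stop("no reference gene: every gene has a zero count in some sample")
  sf <- apply(counts, 2, function(cnt)
    stats::median(cnt[ref] / exp(loggeo[ref])))
  if (any(!is.finite(sf) | sf <= 0))
    stop("non-positive size factor estimated; check for empty samples")
  sf
}

#' Normalize allele-resolved counts by the bulk size factors
#'
#' Both parental alleles of a sample originate from the same library, so
#' maternal and paternal counts are divided by the same bulk size factor;
#' the within-sample allelic ratio is therefore unchanged.
#'
#' @param mat,pat maternal and paternal count matrices sharing dimnames.
#' @param size_factors per-sample factors from [estimate_size_factors()] on
#'   the matching bulk matrix.
#' @return list with `mat` and `pat` normalized matrices.
#' @export
normalize_allelic_counts <- function(mat, pat, size_factors) {
  stopifnot(identical(dimnames(mat), dimnames(pat)))
  if (any(size_factors <= 0)) stop("size factors must be positive")
  sf <- size_factors[colnames(mat)]
  if (any(is.na(sf))) stop("size factors missing for some samples")
  list(mat = sweep(mat, 2, sf, "/"), pat = sweep(pat, 2, sf, "/"))
}

#' Filter genes by allelic coverage in wild-type replicates
#'
#' A gene is removed only when its normalized maternal+paternal sum is below
#' `cfg$min_allelic_norm` in every wild-type replicate; reaching the
#' threshold in a single replicate keeps it.
#'
#' @param norm_mat,norm_pat normalized allelic matrices.
#' @param wt_sample_ids wild-type sample names.
#' @param cfg an [ase_config()].
#' @return character vector of retained gene ids.
#' @export
filter_allelic <- function(norm_mat, norm_pat, wt_sample_ids,
                           cfg = ase_config()) {
  if (!length(wt_sample_ids)) stop("wt_sample_ids must be non-empty")
  if (!all(wt_sample_ids %in% colnames(norm_mat)))
    stop("unknown wild-type sample id(s)")
  tot <- norm_mat[, wt_sample_ids, drop = FALSE] +
    norm_pat[, wt_sample_ids, drop = FALSE]
  rownames(norm_mat)[rowSums(tot >= cfg$min_allelic_norm) > 0]
}

#' Marker Z-scores after upper-quartile and reference-gene adjustment
#'
#' Each sample's counts are divided by the upper quartile of its nonzero
#' counts, then by the adjusted value of a housekeeping reference gene
#' (beta-actin in the original analysis); finally each gene is standardised
#' across samples (mean 0, sample SD 1). Genes constant after adjustment get
#' a zero row with a warning.
#'
#' @param bulk counts matrix (genes x samples).
#' @param reference_gene_id row name of the housekeeping gene; must have a
#'   nonzero count in every sample.
#' @return matrix of Z-scores, same dimnames as `bulk`.
#' @export
marker_zscores <- function(bulk, reference_gene_id) {
  if (!reference_gene_id %in% rownames(bulk))
    stop("reference gene ", reference_gene_id, " not in matrix")
  uq <- apply(bulk, 2, function(x) {
    nz <- x[x > 0]
    if (!length(nz)) stop("sample with all-zero counts")
    stats::quantile(nz, 0.75, names = FALSE)
  })
  adj <- sweep(bulk, 2, uq, "/")
  refv <- adj[reference_gene_id, ]
  if (any(refv <= 0))
    stop("reference gene has zero count in some sample")
  adj <- sweep(adj, 2, refv, "/")
  mu <- rowMeans(adj)
  sd <- apply(adj, 1, stats::sd)
  z <- (adj - mu) / sd
  flat <- sd == 0 | !is.finite(sd)
  if (any(flat)) {
    warning(sum(flat), " gene(s) constant across samples; Z set to 0")
    z[flat, ] <- 0
  }
  z
}
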