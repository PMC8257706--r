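#' Gene models
#'
#' Gene models are held as a list with two components: `exons`, a named
#' [GenomicRanges::GRangesList] of per-gene exon unions (reduced, sorted,
#' 1-based closed), and `genes`, a `data.table` with `gene_id`, `chrom`,
#' `strand`, `start`, `end` (the gene span) and `tss` (strand-aware
#' transcription start).
#'
#' @name gene-models
NULL

.finish_gene_models <- function(exons) {
  exons <- GenomicRanges::reduce(exons)
  span <- unlist(range(exons))
  strand <- as.character(S4Vectors::runValue(GenomicRanges::strand(exons)))
  strand[!strand %in% c("+", "-")] <- "+"
  genes <- data.table::data.table(
    gene_id = names(exons),
    chrom = as.character(S4Vectors::runValue(GenomicRanges::seqnames(exons))),
    strand = strand,
    start = GenomicRanges::start(span),
    end = GenomicRanges::end(span))
  genes$tss <- ifelse(genes$strand == "-", genes$end, genes$start)
  data.table::setkeyv(genes, "gene_id")
  list(exons = exons, genes = genes[])
}

#' Build single-exon gene models from coordinates
#'
#' @param gene_id,chrom,start,end,strand parallel vectors (1-based closed
#'   coordinates).
#' @return gene models (see [gene-models]).
#' @export
gene_models <- function(gene_id, chrom, start, end, strand = "+") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand)
  names(gr) <- gene_id
  .finish_gene_models(GenomicRanges::split(gr, factor(gene_id, unique(gene_id))))
}

#' Read gene models from GTF or BED12
#'
#' GTF exon features are grouped by their `gene_id` attribute; BED12 blocks
#' are grouped by the `name` column. Overlapping exons of a gene (and
#' duplicate gene entries) are merged into the exon union.
#'
#' @param path a `.gtf`/`.gff` or `.bed` file.
#' @return gene models (see [gene-models]).
#' @export
read_gene_models <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gtf", "gff", "gff2", "gff3")) {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "exon"]
    if (!length(gr)) stop("no exon features in ", path)
    ex <- GenomicRanges::split(GenomicRanges::granges(gr), gr$gene_id)
  } else if (ext %in% c("bed", "bed12")) {
    gr <- rtracklayer::import(path, format = "bed")
    if (is.null(gr$name)) stop("BED input must carry gene names (column 4)")
    if (!is.null(gr$blocks)) {
      # BED12 blocks are relative to the feature start
      abs <- IRanges::shift(gr$blocks, GenomicRanges::start(gr) - 1L)
      ex <- GenomicRanges::GRanges(
        rep(GenomicRanges::seqnames(gr), lengths(abs)),
        unlist(abs),
        strand = rep(GenomicRanges::strand(gr), lengths(abs)))
      ex <- GenomicRanges::split(ex, rep(gr$name, lengths(abs)))
    } else {
      ex <- GenomicRanges::split(GenomicRanges::granges(gr), gr$name)
    }
  } else {
    stop("unknown gene-model format: .", ext, " (expected GTF or BED)")
  }
  .finish_gene_models(ex)
}

#' Write single/multi-exon gene models as GTF
#'
#' @param models gene models (see [gene-models]).
#' @param path output path.
#' @export
write_gene_models <- function(models, path) {
  ex <- unlist(models$exons)
  gid <- rep(names(models$exons), lengths(models$exons))
  lines <- sprintf(
    '%s\taseimprint\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
    as.character(GenomicRanges::seqnames(ex)),
    GenomicRanges::start(ex), GenomicRanges::end(ex),
    as.character(GenomicRanges::strand(ex)), gid)
  writeLines(lines, path)
  invisible(path)
}
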