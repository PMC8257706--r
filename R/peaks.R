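#' Read peak intervals from BED
#'
#' @param path BED3/BED6 file (0-based half-open on disk; returned as
#'   1-based closed [GenomicRanges::GRanges], the in-memory convention).
#' @return a `GRanges`, named from column 4 when present.
#' @export
read_peaks <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (!is.null(gr$name)) names(gr) <- gr$name
  gr
}

#' Write intervals as BED
#'
#' @param peaks a `GRanges`.
#' @param path output path.
#' @export
write_peaks <- function(peaks, path) {
  rtracklayer::export(peaks, path, format = "bed")
  invisible(path)
}

#' Intersect two peak sets
#'
#' Default semantics mirror `bedtools intersect -u`: the members of `a`
#' with at least 1 bp overlap with any member of `b`, each reported once.
#' `mode = "fragments"` instead returns the merged overlap fragments
#' (`bedtools intersect` without `-u`, merged).
#'
#' @param a,b `GRanges` peak sets.
#' @param mode `"first-set"` (default) or `"fragments"`.
#' @return a `GRanges`.
#' @export
intersect_peaks <- function(a, b, mode = c("first-set", "fragments")) {
  mode <- match.arg(mode)
  if (mode == "first-set") {
    hits <- GenomicRanges::findOverlaps(a, b, ignore.strand = TRUE)
    a[sort(unique(S4Vectors::queryHits(hits)))]
  } else {
    GenomicRanges::intersect(GenomicRanges::granges(a),
                             GenomicRanges::granges(b), ignore.strand = TRUE)
  }
}

#' Distance of each gene to its nearest peak
#'
#' Genes whose span overlaps a peak get distance 0; otherwise the distance
#' is the gap in bp to the closest peak on the same chromosome. Genes on a
#' chromosome without peaks get `NA` (cross-chromosome "closest" is
#' undefined). The gene anchor is the full gene span, not the TSS.
#'
#' @param genes gene models (see [gene-models]) or a named `GRanges`.
#' @param peaks a `GRanges` of peak intervals.
#' @return a `data.table` with `gene_id`, `distance_bp`, and the nearest
#'   peak's coordinates (`peak_chrom`, `peak_start`, `peak_end`; `NA` when
#'   no peak shares the chromosome).
#' @export
nearest_peak_distance <- function(genes, peaks) {
  gr <- if (methods::is(genes, "GRanges")) genes else
    GenomicRanges::GRanges(genes$genes$chrom,
                           IRanges::IRanges(genes$genes$start,
                                            genes$genes$end),
                           gene_id = genes$genes$gene_id)
  ids <- if (!is.null(gr$gene_id)) gr$gene_id else names(gr)
  if (is.null(ids)) ids <- as.character(seq_along(gr))
  # peak-free chromosomes are a designed NA, not a problem to warn about
  hits <- suppressWarnings(
    GenomicRanges::distanceToNearest(gr, peaks, ignore.strand = TRUE))
  out <- data.table::data.table(
    gene_id = ids,
    distance_bp = NA_integer_,
    peak_chrom = NA_character_, peak_start = NA_integer_,
    peak_end = NA_integer_)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  out$distance_bp[qh] <- as.integer(S4Vectors::mcols(hits)$distance)
  out$peak_chrom[qh] <- as.character(GenomicRanges::seqnames(peaks))[sh]
  out$peak_start[qh] <- GenomicRanges::start(peaks)[sh]
  out$peak_end[qh] <- GenomicRanges::end(peaks)[sh]
  out[]
}

#' Genes within a distance threshold of a peak
#'
#' @param distances output of [nearest_peak_distance()].
#' @param threshold_bp strict upper bound in bp (distance 0, i.e. overlap,
#'   always qualifies); `NA` distances are excluded.
#' @return character vector of gene ids.
#' @export
within_distance <- function(distances, threshold_bp) {
  stopifnot(threshold_bp > 0)
  distances$gene_id[!is.na(distances$distance_bp) &
                      distances$distance_bp < threshold_bp]
}

# Asymptotic Kolmogorov survival function Q(lambda) = 2 sum (-1)^(k-1)
# exp(-2 k^2 lambda^2).
.kolmogorov_sf <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(p, 0))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum over the pooled sample points of the absolute
#' difference between the two empirical CDFs; the p-value comes from the
#' asymptotic Kolmogorov distribution evaluated at `sqrt(ne) D` with
#' effective size `ne = n_x n_y / (n_x + n_y)`.
#'
#' @param x,y numeric samples (e.g. gene-to-peak distances of two gene
#'   sets); `NA`s are dropped.
#' @return list with `D`, `p_value`, `n_x`, `n_y`.
#' @export
ks_two_sample <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  pooled <- sort(unique(c(x, y)))
  fx <- stats::ecdf(x)(pooled)
  fy <- stats::ecdf(y)(pooled)
  D <- max(abs(fx - fy))
  ne <- length(x) * length(y) / (length(x) + length(y))
  list(D = D, p_value = .kolmogorov_sf(sqrt(ne) * D),
       n_x = length(x), n_y = length(y))
}

#' Empirical CDF points for plotting
#'
#' @param x numeric sample.
#' @return a `data.table` with sorted `value` and `ecdf` columns.
#' @export
ecdf_points <- function(x) {
  x <- sort(x[!is.na(x)])
  data.table::data.table(value = x, ecdf = seq_along(x) / length(x))
}
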