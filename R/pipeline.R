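#' Run the count-level imprinting analysis end to end
#'
#' From bulk and allele-resolved count matrices: filters low-expression
#' genes (and excluded chromosomes), estimates median-of-ratios size
#' factors from the bulk counts, normalizes the allelic layers with the
#' same per-sample factors, filters genes on wild-type allelic coverage,
#' computes allelic ratios / proportion tests / classes per condition,
#' runs the simplified NB Wald differential expression between conditions,
#' and integrates everything into the loss-of-imprinting table.
#'
#' @param bulk,mat,pat count matrices sharing dimnames (genes x samples).
#' @param wt_sample_ids,mut_sample_ids sample names of the two conditions.
#' @param gene_chrom optional named chromosome vector for the X-filter.
#' @param cfg an [ase_config()].
#' @param require_significance gate wild-type monoallelic calls on the
#'   BH-adjusted proportion test.
#' @return list with `size_factors`, `genes_tested`, `genes_allelic`,
#'   `wt_ase`, `mut_ase`, `de`, `integration`.
#' @export
run_ase_pipeline <- function(bulk, mat, pat, wt_sample_ids, mut_sample_ids,
                             gene_chrom = NULL, cfg = ase_config(),
                             require_significance = FALSE) {
  stopifnot(identical(dimnames(bulk), dimnames(mat)),
            identical(dimnames(bulk), dimnames(pat)))
  samples <- c(wt_sample_ids, mut_sample_ids)
  stopifnot(all(samples %in% colnames(bulk)))
  bulk <- filter_low_expression(bulk[, samples, drop = FALSE], gene_chrom, cfg)
  mat <- mat[rownames(bulk), samples, drop = FALSE]
  pat <- pat[rownames(bulk), samples, drop = FALSE]
  sf <- estimate_size_factors(bulk)
  norm <- normalize_allelic_counts(mat, pat, sf)
  keep <- filter_allelic(norm$mat, norm$pat, wt_sample_ids, cfg)
  wt_ase <- ase_test(norm$mat[keep, wt_sample_ids, drop = FALSE],
                     norm$pat[keep, wt_sample_ids, drop = FALSE],
                     mat[keep, wt_sample_ids, drop = FALSE],
                     pat[keep, wt_sample_ids, drop = FALSE],
                     cfg, require_significance = require_significance)
  mut_ase <- ase_test(norm$mat[keep, mut_sample_ids, drop = FALSE],
                      norm$pat[keep, mut_sample_ids, drop = FALSE],
                      mat[keep, mut_sample_ids, drop = FALSE],
                      pat[keep, mut_sample_ids, drop = FALSE],
                      cfg, require_significance = FALSE)
  group <- factor(rep(c("wt", "mut"), c(length(wt_sample_ids),
                                        length(mut_sample_ids))),
                  levels = c("wt", "mut"))
  de <- nb_wald_de(bulk, group, size_factors = sf, cfg = cfg)
  integration <- integrate_table(de, wt_ase, mut_ase, cfg)
  list(size_factors = sf, genes_tested = rownames(bulk),
       genes_allelic = keep, wt_ase = wt_ase, mut_ase = mut_ase,
       de = de, integration = integration)
}
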