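#' Analysis configuration
#'
#' Bundles the thresholds used throughout the pipeline. Defaults follow the
#' hybrid ESC/NPC study design this package reimplements: genes with a grand
#' total of more than `min_bulk_count` fragments across all samples are kept;
#' genes need at least `min_allelic_norm` normalized allelic counts
#' (maternal + paternal) in at least one wild-type replicate; allelic ratios
#' at or below `tau_pat` are called paternally expressed and at or above
#' `tau_mat` maternally expressed; `alpha` is the FDR level for significance
#' calls; `distance_threshold_bp` selects genes near binding sites; genes on
#' `excluded_chroms` (the X, subject to random inactivation rather than
#' imprinting) are dropped before analysis.
#'
#' @param min_bulk_count strict lower bound on the total bulk fragment count
#'   per gene (genes kept when total > `min_bulk_count`).
#' @param min_allelic_norm minimum normalized maternal+paternal count a gene
#'   must reach in at least one wild-type replicate.
#' @param tau_pat,tau_mat allelic-ratio classification bounds; a gene is
#'   monoallelic when its mean ratio is `<= tau_pat` or `>= tau_mat`.
#' @param alpha adjusted p-value threshold for significance.
#' @param distance_threshold_bp strict upper bound (bp) for "near a binding
#'   site".
#' @param excluded_chroms character vector of chromosomes removed before
#'   analysis.
#' @param delta minimum ratio shift (towards or past 0.5) required to call a
#'   reduced or inverted allelic bias between conditions.
#'
#' @return a list of class `ase_config`.
#' @export
ase_config <- function(min_bulk_count = 8,
                       min_allelic_norm = 10,
                       tau_pat = 0.33,
                       tau_mat = 0.67,
                       alpha = 0.05,
                       distance_threshold_bp = 1e5,
                       excluded_chroms = "chrX",
                       delta = 0.1) {
  stopifnot(tau_pat > 0, tau_pat < 0.5, tau_mat > 0.5, tau_mat < 1,
            alpha > 0, alpha < 1, min_bulk_count >= 0,
            min_allelic_norm >= 0, distance_threshold_bp > 0, delta >= 0)
  structure(list(min_bulk_count = min_bulk_count,
                 min_allelic_norm = min_allelic_norm,
                 tau_pat = tau_pat, tau_mat = tau_mat, alpha = alpha,
                 distance_threshold_bp = distance_threshold_bp,
                 excluded_chroms = excluded_chroms, delta = delta),
            class = "ase_config")
}
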