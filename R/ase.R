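#' Per-gene allelic ratio
#'
#' The allelic ratio of a replicate is the maternal count divided by the
#' maternal+paternal sum (JF1 / (B6 + JF1)); 0.5 means biallelic
#' expression. Replicates with no allelic counts are excluded from the
#' mean; when no replicate has counts the result is `NA`.
#'
#' @param mat_counts,pat_counts per-replicate (normalized) allelic counts.
#' @return list with `per_replicate_ratios` (NA where a replicate had no
#'   counts) and `mean_ratio`.
#' @export
allelic_ratio <- function(mat_counts, pat_counts) {
  stopifnot(length(mat_counts) == length(pat_counts),
            all(mat_counts >= 0), all(pat_counts >= 0))
  tot <- mat_counts + pat_counts
  r <- ifelse(tot > 0, mat_counts / tot, NA_real_)
  list(per_replicate_ratios = r,
       mean_ratio = if (all(is.na(r))) NA_real_ else mean(r, na.rm = TRUE))
}

#' Classify allelic expression from the mean ratio
#'
#' Ratios at or below `tau_pat` are paternally expressed, at or above
#' `tau_mat` maternally expressed, otherwise biallelic (monoallelic bands
#' `[0, 0.33]` and `[0.67, 1]` by default, boundaries inclusive). With
#' `require_significance`, a monoallelic call additionally needs an
#' adjusted p-value below `cfg$alpha`, else it is downgraded to biallelic.
#'
#' @param mean_ratio allelic ratio in `[0, 1]` or `NA`.
#' @param q_value BH-adjusted p-value of the allelic-imbalance test (may be
#'   `NA` when significance is not required).
#' @param cfg an [ase_config()].
#' @param require_significance gate monoallelic calls on `q_value <
#'   cfg$alpha`.
#' @return one of `"MATERNAL"`, `"PATERNAL"`, `"BIALLELIC"`, `NA`.
#' @export
classify_allelic <- function(mean_ratio, q_value = NA_real_,
                             cfg = ase_config(),
                             require_significance = FALSE) {
  if (is.na(mean_ratio)) return(NA_character_)
  stopifnot(mean_ratio >= 0, mean_ratio <= 1)
  cls <- if (mean_ratio <= cfg$tau_pat) "PATERNAL"
         else if (mean_ratio >= cfg$tau_mat) "MATERNAL"
         else "BIALLELIC"
  if (require_significance && cls != "BIALLELIC" &&
      (is.na(q_value) || q_value >= cfg$alpha))
    cls <- "BIALLELIC"
  cls
}

#' Proportion test for allelic imbalance
#'
#' Two-sided test of a balanced maternal proportion (H0: p = 0.5) on raw
#' pooled allelic counts. The default engine is the exact binomial test
#' with tail doubling, `p = min(1, 2 min(P(X <= k), P(X >= k)))`; a
#' chi-square test with continuity correction is available via `engine`.
#'
#' @param pooled_mat,pooled_pat raw integer counts pooled across
#'   replicates.
#' @param engine `"exact"` (binomial tail doubling) or `"chisq"`
#'   (continuity-corrected).
#' @return the two-sided p-value, or `NA` when both counts are zero.
#' @export
proportion_test <- function(pooled_mat, pooled_pat, engine = c("exact", "chisq")) {
  engine <- match.arg(engine)
  k <- round(pooled_mat); n <- round(pooled_mat + pooled_pat)
  if (n < 1) return(NA_real_)
  if (engine == "exact") {
    lower <- stats::pbinom(k, n, 0.5)
    upper <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
    min(1, 2 * min(lower, upper))
  } else {
    stats::prop.test(k, n, p = 0.5, correct = TRUE)$p.value
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control; a thin validating wrapper around
#' [stats::p.adjust()] that preserves `NA`s and input order.
#'
#' @param p_values numeric vector in `[0, 1]` (NA allowed).
#' @return q-values in input order.
#' @export
adjust_bh <- function(p_values) {
  ok <- is.na(p_values) | (p_values >= 0 & p_values <= 1)
  if (!all(ok)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Per-gene allele-specific expression results for one condition
#'
#' Computes replicate and mean allelic ratios from normalized counts, the
#' proportion test on raw pooled counts, BH-adjusted q-values across genes,
#' and the allelic class.
#'
#' @param norm_mat,norm_pat normalized allelic matrices (genes x
#'   replicates of one condition).
#' @param raw_mat,raw_pat matching raw (integer) allelic matrices used for
#'   the test.
#' @param cfg an [ase_config()].
#' @param require_significance gate monoallelic calls on `q < cfg$alpha`
#'   (used for wild-type calls in the original design).
#' @param engine test engine, see [proportion_test()].
#' @return a `data.table` with `gene_id`, per-replicate `ratio_*` columns,
#'   `mean_ratio`, `pooled_mat`, `pooled_pat`, `p_value`, `q_value`,
#'   `allelic_class`.
#' @export
ase_test <- function(norm_mat, norm_pat, raw_mat, raw_pat,
                     cfg = ase_config(), require_significance = FALSE,
                     engine = "exact") {
  stopifnot(identical(dimnames(norm_mat), dimnames(norm_pat)),
            identical(rownames(norm_mat), rownames(raw_mat)),
            identical(rownames(norm_mat), rownames(raw_pat)))
  genes <- rownames(norm_mat)
  rat <- lapply(seq_along(genes), function(i)
    allelic_ratio(norm_mat[i, ], norm_pat[i, ]))
  ratios <- do.call(rbind, lapply(rat, `[[`, "per_replicate_ratios"))
  mean_ratio <- vapply(rat, `[[`, numeric(1), "mean_ratio")
  pooled_mat <- rowSums(raw_mat)
  pooled_pat <- rowSums(raw_pat)
  p <- mapply(proportion_test, pooled_mat, pooled_pat,
              MoreArgs = list(engine = engine))
  q <- adjust_bh(p)
  cls <- vapply(seq_along(genes), function(i)
    classify_allelic(mean_ratio[i], q[i], cfg, require_significance),
    character(1))
  out <- data.table::data.table(gene_id = genes)
  for (j in seq_len(ncol(ratios)))
    out[[paste0("ratio_", colnames(norm_mat)[j])]] <- ratios[, j]
  out$mean_ratio <- mean_ratio
  out$pooled_mat <- pooled_mat
  out$pooled_pat <- pooled_pat
  out$p_value <- p
  out$q_value <- q
  out$allelic_class <- cls
  out[]
}

#' Compare allelic status between conditions (loss of imprinting)
#'
#' For a gene monoallelic in the wild type, classifies the mutant
#' behaviour: `BIALLELIC_IN_MUTANT` when the mutant ratio falls strictly
#' inside the biallelic interval; `BIAS_INVERTED` when the bias switched
#' parental direction by more than `cfg$delta`; `BIAS_REDUCED` when the
#' mutant is still monoallelic in the same direction but at least
#' `cfg$delta` closer to 0.5; otherwise `UNCHANGED`. A missing mutant
#' result gives `NOT_TESTABLE`.
#'
#' @param wt_ratio,mut_ratio mean allelic ratios of the two conditions.
#' @param wt_class the wild-type allelic class (must be monoallelic).
#' @param cfg an [ase_config()].
#' @return one of `"BIALLELIC_IN_MUTANT"`, `"BIAS_REDUCED"`,
#'   `"BIAS_INVERTED"`, `"UNCHANGED"`, `"NOT_TESTABLE"`.
#' @export
compare_conditions <- function(wt_ratio, mut_ratio, wt_class,
                               cfg = ase_config()) {
  if (!wt_class %in% c("MATERNAL", "PATERNAL"))
    stop("transition is defined only for wild-type monoallelic genes")
  if (is.na(mut_ratio)) return("NOT_TESTABLE")
  if (mut_ratio > cfg$tau_pat && mut_ratio < cfg$tau_mat)
    return("BIALLELIC_IN_MUTANT")
  if (sign(mut_ratio - 0.5) != sign(wt_ratio - 0.5) &&
      abs(mut_ratio - 0.5) > cfg$delta)
    return("BIAS_INVERTED")
  if (sign(mut_ratio - 0.5) == sign(wt_ratio - 0.5) &&
      abs(mut_ratio - 0.5) < abs(wt_ratio - 0.5) - cfg$delta)
    return("BIAS_REDUCED")
  "UNCHANGED"
}
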