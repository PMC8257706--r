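#' Method-of-moments dispersion estimates
#'
#' Per-gene dispersion of the NB model `Var = mu + alpha mu^2`, estimated
#' from the pooled within-group variance of normalized counts:
#' `alpha = (w - xim * m) / m^2`, with `m` the mean normalized count, `w`
#' the pooled within-group variance and `xim` the mean inverse size factor
#' (which accounts for the shot-noise term on the normalized scale).
#'
#' @param norm normalized counts matrix.
#' @param group two-level factor over columns.
#' @param size_factors per-sample size factors.
#' @return numeric vector of raw (possibly negative) dispersion estimates.
#' @keywords internal
dispersion_mom <- function(norm, group, size_factors) {
  lv <- levels(group)
  n <- ncol(norm)
  ss <- 0
  for (g in lv) {
    sub <- norm[, group == g, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
  }
  w <- ss / (n - length(lv))
  m <- rowMeans(norm)
  xim <- mean(1 / size_factors)
  (w - xim * m) / m^2
}

#' Fit the parametric dispersion trend alpha(mu) = a0 + a1/mu
#'
#' Least-squares fit of the gene-wise dispersion estimates against inverse
#' mean, made outlier-resistant by one trimming pass (residuals beyond 5
#' MADs refitted away). All finite estimates enter the fit, including
#' negative ones: the raw moment estimator is unbiased but right-skewed,
#' and truncating at zero (or a median-type robust fit) would pull the
#' trend systematically below the true dispersion, inflating the Wald
#' test. Falls back to a flat trend when too few genes inform the fit.
#'
#' @param alpha_mom raw dispersions from [dispersion_mom()].
#' @param base_mean mean normalized counts.
#' @return list with coefficients `a0`, `a1` and `trend(mu)` function.
#' @keywords internal
dispersion_trend <- function(alpha_mom, base_mean) {
  use <- is.finite(alpha_mom) & base_mean > 0
  if (sum(use) >= 10) {
    x <- 1 / base_mean[use]; y <- alpha_mom[use]
    fit <- stats::lm(y ~ x)
    r <- stats::resid(fit)
    s <- stats::mad(r)
    keep <- if (s > 0) abs(r) <= 5 * s else rep(TRUE, length(r))
    fit <- stats::lm(y[keep] ~ x[keep])
    a0 <- max(unname(stats::coef(fit)[1]), 1e-6)
    a1 <- max(unname(stats::coef(fit)[2]), 0)
  } else {
    a0 <- if (any(use & alpha_mom > 0))
      stats::median(alpha_mom[use & alpha_mom > 0]) else 0.1
    a0 <- max(a0, 1e-6)
    a1 <- 0
  }
  list(a0 = a0, a1 = a1,
       trend = function(mu) a0 + a1 / pmax(mu, 1e-8))
}

# Shrink gene-wise dispersions towards the trend in log space. The prior
# weight is the ratio of the sampling variance of a log dispersion
# estimate (chi-square approximation, trigamma(df/2)) to a fixed prior
# variance, so pooling is strong at few replicates and relaxes as df
# grows. Genes without a positive raw estimate take the trend value.
# Floored at 1% of the trend.
.shrink_dispersion <- function(alpha_mom, trend_val, prior_weight = 1) {
  out <- trend_val
  pos <- is.finite(alpha_mom) & alpha_mom > 0
  out[pos] <- exp((log(alpha_mom[pos]) + prior_weight * log(trend_val[pos])) /
                    (1 + prior_weight))
  pmax(pmin(out, 100), 0.01 * trend_val, 1e-8)
}

# Single-gene NB IRLS for log mu_j = log s_j + b0 + b1 x_j with fixed
# dispersion. Returns c(b0, b1, se_b1) on the natural-log scale.
.nb_irls <- function(k, x, log_sf, alpha, tol = 1e-8, max_iter = 100) {
  mean_pos <- mean(k / exp(log_sf))
  b <- c(log(max(mean_pos, 1e-4)), 0)
  X <- cbind(1, x)
  for (it in seq_len(max_iter)) {
    eta <- log_sf + X %*% b
    mu <- pmin(exp(eta), 1e12)
    w <- as.vector(mu / (1 + alpha * mu))
    z <- as.vector(X %*% b) + (k - as.vector(mu)) / as.vector(mu)
    xtw <- crossprod(X, X * w)
    bnew <- tryCatch(solve(xtw, crossprod(X, w * z)),
                     error = function(e) NULL)
    if (is.null(bnew)) break
    bnew <- pmin(pmax(as.vector(bnew), -30), 30)
    if (max(abs(bnew - b)) < tol) { b <- bnew; break }
    b <- bnew
  }
  eta <- log_sf + X %*% b
  mu <- pmin(exp(eta), 1e12)
  w <- as.vector(mu / (1 + alpha * mu))
  xtw <- crossprod(X, X * w)
  se <- tryCatch(sqrt(diag(solve(xtw)))[2], error = function(e) NA_real_)
  c(b[1], b[2], se)
}

#' Simplified negative-binomial Wald differential expression
#'
#' Fits, per gene, the NB mean model `mu_ij = s_j q_i 2^(beta_i x_j)` with
#' a two-level design, dispersion estimated by method of moments, shrunk in
#' log space towards a parametric trend `a0 + a1/mu` fitted across genes,
#' and the fold change estimated by iteratively reweighted least squares.
#' Significance is a two-sided Wald test of `beta_i = 0`, BH-adjusted.
#'
#' This is a deliberately simplified engine in the spirit of the
#' median-of-ratios NB framework: no outlier refitting, no independent
#' filtering, no fold-change shrinkage.
#'
#' @param bulk counts matrix (genes x samples), already filtered for low
#'   counts.
#' @param group_labels vector over samples with exactly two levels; the
#'   first level (or factor level 1) is the reference (wild type).
#' @param size_factors optional per-sample size factors; estimated from
#'   `bulk` when `NULL`.
#' @param cfg an [ase_config()]; `cfg$alpha` gates the `direction` calls.
#' @return a `data.table` with `gene_id`, `base_mean`, `log2_fc`
#'   (second level vs reference), `se`, `p_value`, `padj`, `direction`
#'   (`UP`/`DOWN`/`UNCHANGED`).
#' @export
nb_wald_de <- function(bulk, group_labels, size_factors = NULL,
                       cfg = ase_config()) {
  group <- factor(group_labels)
  if (nlevels(group) != 2) stop("exactly two groups are required")
  if (length(group) != ncol(bulk)) stop("one group label per sample required")
  if (ncol(bulk) < 2) stop("at least two samples are required")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(bulk)
  sf <- size_factors
  x <- as.numeric(group == levels(group)[2])
  norm <- sweep(bulk, 2, sf, "/")
  base_mean <- rowMeans(norm)
  alpha_mom <- dispersion_mom(norm, group, sf)
  tr <- dispersion_trend(alpha_mom, base_mean)
  df <- ncol(bulk) - 2L
  prior_var <- 0.04
  prior_weight <- trigamma(max(df, 1) / 2) / prior_var
  disp <- .shrink_dispersion(alpha_mom, tr$trend(base_mean), prior_weight)
  log_sf <- log(sf)
  n_genes <- nrow(bulk)
  lfc <- numeric(n_genes); se <- numeric(n_genes); p <- numeric(n_genes)
  for (i in seq_len(n_genes)) {
    k <- bulk[i, ]
    if (all(k == 0)) { lfc[i] <- 0; se[i] <- NA_real_; p[i] <- 1; next }
    fit <- .nb_irls(k, x, log_sf, disp[i])
    lfc[i] <- fit[2] / log(2)
    se[i] <- fit[3] / log(2)
    stat <- fit[2] / fit[3]
    p[i] <- if (is.finite(stat)) 2 * stats::pnorm(-abs(stat)) else 1
  }
  padj <- adjust_bh(p)
  direction <- ifelse(padj < cfg$alpha & lfc > 0, "UP",
                      ifelse(padj < cfg$alpha & lfc < 0, "DOWN", "UNCHANGED"))
  data.table::data.table(gene_id = rownames(bulk), base_mean = base_mean,
                         log2_fc = lfc, se = se, p_value = p, padj = padj,
                         direction = direction)
}

#' Hypergeometric enrichment of imprinted genes among DE genes
#'
#' Upper-tail probability `P(X >= k)` of drawing at least `k` imprinted
#' genes in `n` differentially expressed genes from a universe of `N`
#' tested genes containing `K` imprinted ones.
#'
#' @param k imprinted and differentially expressed genes.
#' @param K imprinted genes in the universe.
#' @param n differentially expressed genes.
#' @param N universe size (genes surviving the expression filter).
#' @return the enrichment p-value.
#' @export
hypergeom_enrichment <- function(k, K, n, N) {
  stopifnot(k >= 0, K >= 0, n >= 0, N >= 1)
  if (k > min(K, n) || n > N || K > N)
    stop("inconsistent hypergeometric counts (need k <= min(K, n), n <= N, K <= N)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

.wt_class_label <- c(MATERNAL = "Maternal", PATERNAL = "Paternal")
.transition_label <- c(BIALLELIC_IN_MUTANT = "Biallelic",
                       BIAS_REDUCED = "All. bias reduced",
                       BIAS_INVERTED = "All. bias inverted",
                       UNCHANGED = "Unchanged",
                       NOT_TESTABLE = "Not testable")
.direction_label <- c(UP = "Up-regulated", DOWN = "Down-regulated",
                      UNCHANGED = "Unchanged")

#' Integrate allelic status with global expression change
#'
#' Builds one row per wild-type monoallelic gene joining its wild-type
#' allelic class, the mutant-condition transition (loss of imprinting) and
#' the global differential-expression direction, rendered with the
#' conventional vocabulary (Maternal/Paternal, Biallelic, All. bias
#' reduced/inverted, Up-/Down-regulated, Unchanged). Genes missing from
#' the mutant allelic results or the DE results are reported as not
#' testable.
#'
#' @param de output of [nb_wald_de()].
#' @param wt_ase [ase_test()] output for the wild-type condition.
#' @param mut_ase [ase_test()] output for the mutant condition.
#' @param cfg an [ase_config()].
#' @param domain_label optional named character vector mapping gene ids to
#'   imprinted-domain labels.
#' @return a `data.table` with `gene_id`, `domain_label`,
#'   `wt_allelic_class`, `mut_transition`, `global_change`, plus the raw
#'   enum columns `wt_class`, `transition`, `direction`.
#' @export
integrate_table <- function(de, wt_ase, mut_ase, cfg = ase_config(),
                            domain_label = NULL) {
  imprinted <- wt_ase[wt_ase$allelic_class %in% c("MATERNAL", "PATERNAL"), ]
  rows <- lapply(seq_len(nrow(imprinted)), function(i) {
    g <- imprinted$gene_id[i]
    wt_class <- imprinted$allelic_class[i]
    mi <- match(g, mut_ase$gene_id)
    transition <- if (is.na(mi) || is.na(mut_ase$mean_ratio[mi]))
      "NOT_TESTABLE"
    else compare_conditions(imprinted$mean_ratio[i],
                            mut_ase$mean_ratio[mi], wt_class, cfg)
    di <- match(g, de$gene_id)
    direction <- if (is.na(di)) NA_character_ else de$direction[di]
    data.table::data.table(
      gene_id = g,
      domain_label = if (is.null(domain_label)) NA_character_
                     else unname(domain_label[g]),
      wt_class = wt_class,
      transition = transition,
      direction = direction,
      wt_allelic_class = unname(.wt_class_label[wt_class]),
      mut_transition = unname(.transition_label[transition]),
      global_change = if (is.na(di)) "Not testable"
                      else unname(.direction_label[direction]))
  })
  if (!length(rows))
    return(data.table::data.table(
      gene_id = character(0), domain_label = character(0),
      wt_class = character(0), transition = character(0),
      direction = character(0), wt_allelic_class = character(0),
      mut_transition = character(0), global_change = character(0)))
  data.table::rbindlist(rows)
}
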