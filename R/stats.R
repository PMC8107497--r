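#' Nonparametric AUC with cluster-robust variance
#'
#' Area under the ROC curve by Mann-Whitney pair counting (ties scored
#' 0.5), with the variance estimated from cluster-level structural
#' components so that correlated observations from the same cluster (e.g.
#' two eyes of one participant) are handled. With singleton clusters the
#' estimator reduces to the usual DeLong-type variance. Scores must be
#' oriented so larger values indicate disease.
#'
#' @param scores numeric vector.
#' @param labels logical (or 0/1): `TRUE` = diseased.
#' @param clusters cluster identifiers (default: one observation per
#'   cluster).
#' @return Object of class `roc_result`: `auc`, `se`, `ci95`, `n_pos`,
#'   `n_neg`, `n_clusters`.
#' @export
auc_clustered <- function(scores, labels, clusters = seq_along(scores)) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels),
            length(clusters) == length(scores))
  M <- sum(labels); N <- sum(!labels)
  if (M == 0 || N == 0) stop("both classes must be present")
  x <- scores[labels]; y <- scores[!labels]
  cx <- clusters[labels]; cy <- clusters[!labels]

  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(psi)
  v10 <- rowMeans(psi)                     # per diseased obs
  v01 <- colMeans(psi)                     # per normal obs

  cl <- unique(c(cx, cy))
  X <- vapply(cl, function(ci) sum(v10[cx == ci]), 0)
  Y <- vapply(cl, function(ci) sum(v01[cy == ci]), 0)
  m_i <- vapply(cl, function(ci) sum(cx == ci), 0)
  n_i <- vapply(cl, function(ci) sum(cy == ci), 0)
  dx <- X - m_i * auc
  dy <- Y - n_i * auc
  I10 <- sum(m_i > 0); I01 <- sum(n_i > 0); I <- length(cl)
  s10 <- if (I10 > 1) I10 / (I10 - 1) * sum(dx[m_i > 0]^2) else 0
  s01 <- if (I01 > 1) I01 / (I01 - 1) * sum(dy[n_i > 0]^2) else 0
  s11 <- if (I > 1) I / (I - 1) * sum(dx * dy) else 0
  var_auc <- s10 / M^2 + s01 / N^2 + 2 * s11 / (M * N)
  se <- sqrt(max(var_auc, 0))
  structure(list(auc = auc, se = se,
                 ci95 = c(max(0, auc - 1.96 * se), min(1, auc + 1.96 * se)),
                 n_pos = M, n_neg = N, n_clusters = I),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f ± %.3f (95%% CI %.3f-%.3f; %d+/%d-, %d clusters)\n",
              x$auc, x$se, x$ci95[1], x$ci95[2], x$n_pos, x$n_neg,
              x$n_clusters))
  invisible(x)
}

#' Sensitivity at fixed specificity via a KDE cutoff
#'
#' The diagnostic cutoff is placed at the quantile of the *normal* score
#' distribution corresponding to the target specificity, with the
#' distribution smoothed by a Gaussian kernel density estimate (Silverman's
#' bandwidth); the cutoff solves the smoothed CDF by bisection. Sensitivity
#' is the fraction of disease scores beyond the cutoff.
#'
#' @param normal_scores,disease_scores numeric vectors.
#' @param specificity target specificity in (0, 1).
#' @param direction `"higher"` if larger scores indicate disease, `"lower"`
#'   otherwise.
#' @return Sensitivity in [0, 1]; the cutoff is attached as attribute
#'   `"cutoff"`.
#' @export
sensitivity_at_specificity <- function(normal_scores, disease_scores,
                                       specificity = 0.99,
                                       direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  stopifnot(specificity > 0, specificity < 1, length(normal_scores) >= 10)
  if (stats::sd(normal_scores) == 0) stop("degenerate normal scores")
  h <- stats::bw.nrd0(normal_scores)
  kcdf <- function(q) mean(stats::pnorm((q - normal_scores) / h))
  target <- if (direction == "higher") specificity else 1 - specificity
  lo <- min(normal_scores) - 6 * h; hi <- max(normal_scores) + 6 * h
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (kcdf(mid) < target) lo <- mid else hi <- mid
    if (hi - lo < 1e-10 * (abs(hi) + abs(lo) + 1)) break
  }
  cutoff <- (lo + hi) / 2
  sens <- if (direction == "higher") mean(disease_scores > cutoff)
          else mean(disease_scores < cutoff)
  attr(sens, "cutoff") <- cutoff
  sens
}

#' Exact McNemar test on paired detections
#'
#' Compares two diagnostic rules applied to the same eyes through the exact
#' binomial test on the discordant pairs. With no discordant pair the
#' p-value is 1.
#'
#' @param detect_a,detect_b logical vectors of per-eye detections.
#' @return Two-sided exact p-value.
#' @export
mcnemar_exact <- function(detect_a, detect_b) {
  stopifnot(length(detect_a) == length(detect_b))
  b <- sum(detect_a & !detect_b); c <- sum(!detect_a & detect_b)
  if (b + c == 0) return(1)
  stats::binom.test(b, b + c, 0.5)$p.value
}

#' Pooled between-repeat standard deviation
#'
#' Repeatability metric: the square root of the within-eye, within-
#' superpixel variance between repeated scans, pooled over all eyes and
#' superpixels.
#'
#' @param repeats list with one element per eye, each a matrix of
#'   `n_repeats x n_superpixels` values (dB).
#' @return Pooled SD in dB.
#' @export
pooled_sd <- function(repeats) {
  vars <- unlist(lapply(repeats, function(m) {
    m <- as.matrix(m)
    if (nrow(m) < 2) stop("each eye needs at least 2 repeats")
    apply(m, 2, stats::var)
  }))
  sqrt(mean(vars, na.rm = TRUE))
}

#' Compare two Pearson correlations by paired bootstrap
#'
#' Both parameters are correlated with the same outcome on the same eyes;
#' eyes are resampled with replacement and the two-sided p-value for the
#' difference `r(x1, y) - r(x2, y)` is read from the bootstrap
#' distribution.
#'
#' @param x1,x2,y numeric vectors on the same eyes.
#' @param reps bootstrap replicates.
#' @param seed RNG seed.
#' @return List `r1`, `r2`, `diff`, `p`.
#' @export
pearson_compare_bootstrap <- function(x1, x2, y, reps = 2000, seed = 1) {
  stopifnot(length(x1) == length(y), length(x2) == length(y))
  set.seed(seed)
  n <- length(y)
  d <- replicate(reps, {
    ii <- sample.int(n, n, replace = TRUE)
    stats::cor(x1[ii], y[ii]) - stats::cor(x2[ii], y[ii])
  })
  d <- d[is.finite(d)]
  p <- 2 * min(mean(d <= 0), mean(d >= 0))
  list(r1 = stats::cor(x1, y), r2 = stats::cor(x2, y),
       diff = stats::cor(x1, y) - stats::cor(x2, y), p = min(p, 1))
}

#' Gaussian-mixture clustering of loss patterns
#'
#' Unsupervised clustering of eyes in the (focal loss, average reflectance)
#' plane by a full-covariance Gaussian mixture (\pkg{mclust}), used to
#' separate no-loss, mixed diffuse/focal, and predominantly focal loss
#' phenotypes.
#'
#' @param x numeric matrix, one row per eye, two (or more) feature columns.
#' @param k number of components.
#' @param seed RNG seed (clustering initialisation is deterministic but the
#'   seed guards any stochastic fallback).
#' @return List `labels` (integer vector), `means` (component means by
#'   column), `model` (the fitted `Mclust` object).
#' @export
gmm_cluster <- function(x, k = 3, seed = 1) {
  x <- as.matrix(x)
  set.seed(seed)
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller frame
  fit <- mclust::Mclust(x, G = k,
                        modelNames = if (k >= 2) "VVV", verbose = FALSE)
  if (is.null(fit)) fit <- mclust::Mclust(x, G = k, verbose = FALSE)
  list(labels = fit$classification, means = t(fit$parameters$mean),
       model = fit)
}

#' Two-segment piecewise regression against visual-field severity
#'
#' Fits independent linear regressions of a parameter on VF mean deviation
#' above and below a fixed breakpoint (default -6 dB), with per-segment
#' Pearson correlation and p-value. Captures the floor effect: structural
#' parameters track severity only in early disease.
#'
#' @param x VF mean deviation (dB).
#' @param y parameter values.
#' @param breakpoint fixed breakpoint (dB); not estimated.
#' @return List `slope_hi`, `r_hi`, `p_hi`, `n_hi` (segment `x >
#'   breakpoint`) and the `_lo` analogues (`x < breakpoint`); segments with
#'   fewer than 3 complete pairs are flagged `NA`.
#' @export
piecewise_fit <- function(x, y, breakpoint = -6) {
  seg <- function(sel) {
    sel <- sel & is.finite(x) & is.finite(y)
    if (sum(sel) < 3 || stats::sd(x[sel]) == 0 || stats::sd(y[sel]) == 0)
      return(list(slope = NA_real_, r = NA_real_, p = NA_real_, n = sum(sel)))
    ct <- stats::cor.test(x[sel], y[sel])
    list(slope = unname(stats::coef(stats::lm(y[sel] ~ x[sel]))[2]),
         r = unname(ct$estimate), p = ct$p.value, n = sum(sel))
  }
  hi <- seg(x > breakpoint); lo <- seg(x < breakpoint)
  list(slope_hi = hi$slope, r_hi = hi$r, p_hi = hi$p, n_hi = hi$n,
       slope_lo = lo$slope, r_lo = lo$r, p_lo = lo$p, n_lo = lo$n)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Thin wrapper over [stats::wilcox.test()]: exact for small untied
#' samples, normal approximation with tie correction otherwise.
#'
#' @param group_a,group_b numeric vectors.
#' @return Two-sided p-value.
#' @export
wilcoxon_ranksum <- function(group_a, group_b) {
  suppressWarnings(stats::wilcox.test(group_a, group_b)$p.value)
}
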