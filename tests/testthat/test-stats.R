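# Diagnostic-accuracy and association statistics.

brute_auc <- function(x, y) {
  # exhaustive pair counting oracle: P(disease > normal) + 0.5 ties
  mean(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

test_that("clustered AUC equals exhaustive pair counting", {
  r <- auc_clustered(c(3, 4, 1, 2, 3), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(r$auc, 5.5 / 6)

  perfect <- auc_clustered(c(10, 11, 1, 2), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1)

  set.seed(1)
  sc <- rnorm(400); lb <- sample(c(TRUE, FALSE), 400, replace = TRUE)
  r0 <- auc_clustered(sc, lb)
  expect_lt(abs(r0$auc - 0.5), 3 * r0$se)

  expect_error(auc_clustered(1:5, rep(TRUE, 5)), "both classes")
})

test_that("clustered variance reduces to the DeLong form for singletons", {
  set.seed(2)
  x <- rnorm(12, 1); y <- rnorm(15)
  r <- auc_clustered(c(x, y), c(rep(TRUE, 12), rep(FALSE, 15)))
  # DeLong: var = var(V10)/m + var(V01)/n with structural components
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi); v01 <- colMeans(psi)
  delong <- var(v10) / length(x) + var(v01) / length(y)
  expect_equal(r$se^2, delong, tolerance = 1e-12)
  expect_true(r$ci95[1] <= r$auc && r$auc <= r$ci95[2])
})

test_that("clustering two eyes per participant widens the variance", {
  set.seed(3)
  n <- 40
  subj <- rep(1:n, each = 2)
  base <- rnorm(n)[subj]                      # strong intereye correlation
  scores <- base + rnorm(2 * n, 0, 0.3)
  labels <- rep(c(TRUE, FALSE), n)[order(runif(2 * n))]
  scores[labels] <- scores[labels] + 1
  naive <- auc_clustered(scores, labels)
  clust <- auc_clustered(scores, labels, subj)
  expect_equal(naive$auc, clust$auc)
  expect_gt(clust$se, 0.8 * naive$se)         # typically larger, never tiny
})

test_that("flipping labels mirrors the AUC around one half", {
  set.seed(4)
  sc <- rnorm(60); lb <- rep(c(TRUE, FALSE), 30)
  expect_equal(auc_clustered(sc, lb)$auc + auc_clustered(sc, !lb)$auc, 1)
})

test_that("sensitivity at specificity matches the Gaussian closed form", {
  set.seed(5)
  sens <- mean(replicate(3, sensitivity_at_specificity(
    rnorm(1e5), rnorm(1e5, -3), 0.99, direction = "lower")))
  expect_lt(abs(sens - pnorm(3 + qnorm(0.01))), 0.01)

  # exchangeable disease scores: sensitivity ~ 1 - specificity
  s2 <- sensitivity_at_specificity(rnorm(20000), rnorm(20000), 0.95,
                                   direction = "lower")
  expect_lt(abs(s2 - 0.05), 0.01)

  # complete separation
  expect_equal(as.numeric(
    sensitivity_at_specificity(rnorm(50, 10), rnorm(50, -10), 0.99,
                               direction = "lower")), 1)
  expect_error(sensitivity_at_specificity(rep(1, 50), rnorm(10)),
               "degenerate")
})

test_that("sensitivity is non-increasing in the target specificity", {
  set.seed(6)
  nrm <- rnorm(5000); dis <- rnorm(2000, -1.5)
  s <- vapply(c(0.8, 0.9, 0.95, 0.99),
              function(sp) sensitivity_at_specificity(nrm, dis, sp,
                                                      direction = "lower"), 0)
  expect_true(all(diff(s) <= 0))
})

test_that("exact McNemar follows the binomial closed form", {
  a <- c(rep(TRUE, 8), rep(TRUE, 10)); b <- c(rep(FALSE, 8), rep(TRUE, 10))
  expect_equal(mcnemar_exact(a, b), 2 * 0.5^8)
  expect_equal(mcnemar_exact(a, a), 1)
  a5 <- c(rep(TRUE, 5), rep(FALSE, 5)); b5 <- !a5
  expect_equal(mcnemar_exact(a5, b5), 1)
})

test_that("pooled SD matches the direct variance computation", {
  reps <- list(matrix(rep(1:4, 2), 2, 4, byrow = TRUE))
  expect_equal(pooled_sd(reps), 0)

  m <- rbind(rep(1, 4), rep(-1, 4))           # two repeats at +-1 around 0
  expect_equal(pooled_sd(list(m)), sd(c(1, -1)))

  set.seed(7)
  eyes <- lapply(1:5, function(i) matrix(rnorm(2 * 160), 2, 160))
  oracle <- sqrt(mean(unlist(lapply(eyes, function(m) apply(m, 2, var)))))
  expect_equal(pooled_sd(eyes), oracle)
  # translation invariance per eye/superpixel
  shifted <- lapply(eyes, function(m) sweep(m, 2, runif(160, -5, 5), "+"))
  expect_equal(pooled_sd(shifted), pooled_sd(eyes))
  expect_error(pooled_sd(list(matrix(1, 1, 4))), "2 repeats")
})

test_that("bootstrap comparison of correlations discriminates and is fair", {
  set.seed(8)
  n <- 100
  y <- rnorm(n)
  out <- pearson_compare_bootstrap(y, rnorm(n), y, reps = 500, seed = 1)
  expect_equal(out$r1, 1)
  expect_lt(out$p, 0.01)

  x <- rnorm(n)
  same <- pearson_compare_bootstrap(x, x, y, reps = 200, seed = 1)
  expect_equal(same$diff, 0)
  expect_equal(same$p, 1)
  expect_equal(cor(-x, y), -cor(x, y))
})

test_that("GMM clustering recovers well-separated groups", {
  set.seed(9)
  blobs <- rbind(cbind(rnorm(60, 0, 0.2), rnorm(60, 0, 0.2)),
                 cbind(rnorm(60, 5, 0.2), rnorm(60, 0, 0.2)),
                 cbind(rnorm(60, 2.5, 0.2), rnorm(60, 4, 0.2)))
  truth <- rep(1:3, each = 60)
  cl <- gmm_cluster(blobs, k = 3, seed = 1)
  tab <- table(truth, cl$labels)
  expect_gte(sum(apply(tab, 1, max)) / length(truth), 0.98)
  one <- gmm_cluster(blobs, k = 1, seed = 1)
  expect_equal(unique(one$labels), 1L)
})

test_that("piecewise regression exposes the floor effect", {
  x <- seq(-20, 2, length.out = 100)
  pw <- piecewise_fit(x, x)
  expect_equal(pw$slope_hi, 1, tolerance = 1e-9)
  expect_equal(pw$slope_lo, 1, tolerance = 1e-9)
  expect_equal(pw$r_hi, 1); expect_equal(pw$r_lo, 1)

  set.seed(10)
  x2 <- c(runif(25, -20, -6), runif(25, -6, 2))
  y2 <- pmax(x2, -6) + rnorm(50, 0, 0.8)      # floor below -6 dB
  pw2 <- piecewise_fit(x2, y2)
  expect_gt(pw2$r_hi, 0.9)
  expect_lt(abs(pw2$r_lo), 0.3)

  pw3 <- piecewise_fit(runif(20, 0, 2), rnorm(20))   # empty low segment
  expect_true(is.na(pw3$slope_lo)); expect_equal(pw3$n_lo, 0)
})

test_that("rank-sum test is exact for small samples and rank-invariant", {
  a <- 1:5; b <- 6:10
  expect_equal(wilcoxon_ranksum(a, b), 2 / choose(10, 5))
  expect_equal(wilcoxon_ranksum(exp(a), exp(b)), wilcoxon_ranksum(a, b))
  x <- rnorm(30)
  expect_gt(wilcoxon_ranksum(x, x), 0.99)
})
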