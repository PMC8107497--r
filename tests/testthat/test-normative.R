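# Normative model: LME fit, covariate adjustment, cutoffs, 0.632+ bootstrap.

toy_model <- function(b_age = 0, b_axl = 0, b_int = 0, mu = rep(0, 160),
                      sigma = rep(1, 160)) {
  cuts <- normative_cutoffs(mu, sigma)
  structure(list(coefficients = c(age = b_age, axial_length = b_axl,
                                  age_axl = b_int),
                 reference_age = 50, reference_axl = 23.6,
                 mu = mu, sigma = sigma, q5 = cuts$q5, q1 = cuts$q1,
                 n_superpixels = 160, method = "fast"),
            class = "nfl_normative")
}

test_that("LME recovers generating covariate effects within 2 SE", {
  sc <- make_cohort(sim_config(), seed = 21)
  fit <- fit_normative(sc$cohort)
  expect_lt(abs(coef(fit)["age"] - (-0.03)), 2 * fit$se["age"])
  expect_lt(abs(coef(fit)["axial_length"] - (-0.4)),
            2 * fit$se["axial_length"])
  # balanced data: fast path slopes coincide with the mixed-model slopes
  fast <- fit_normative(sc$cohort, method = "fast")
  expect_equal(coef(fast), coef(fit), tolerance = 1e-6)
})

test_that("degenerate covariate designs fail loudly, naming the culprit", {
  sc <- make_cohort(sim_config(), seed = 22)
  sc$cohort$info$age <- 60
  sc$cohort$info$axial_length <- 24
  expect_error(fit_normative(sc$cohort), "collinear")
  sc2 <- make_cohort(sim_config(n_normal = 10, n_ppg = 0, n_pg = 0),
                     seed = 23)
  expect_error(fit_normative(sc2$cohort), "at least")
})

test_that("null covariate effects are declared non-significant ~95% of runs", {
  hits <- 0L
  for (i in 1:60) {
    sc <- make_cohort(sim_config(n_normal = 35, n_ppg = 0, n_pg = 0,
                                 beta_age = 0, beta_axl = 0), seed = 400 + i)
    f <- fit_normative(sc$cohort, method = "fast")
    hits <- hits + (f$p_values["age"] < 0.05) + (f$p_values["axial_length"] < 0.05)
  }
  # 120 tests at nominal 5%: expect ~6 false positives, bound generously
  expect_lt(hits, 120 * 0.05 + 3 * sqrt(120 * 0.05 * 0.95))
})

test_that("adjustment is the identity at the reference point and invertible", {
  m <- toy_model(b_age = -0.03, b_axl = -0.4, b_int = 0.001)
  v <- rnorm(160)
  expect_equal(adjust_reflectance(v, 50, 23.6, m), v)
  expect_equal(adjust_reflectance(v, 70, 25, toy_model()), v)   # zero coefs
  # age 60, only the age term: +0.3 dB shift
  m2 <- toy_model(b_age = -0.03)
  expect_equal(adjust_reflectance(v, 60, 23.6, m2), v + 0.3)
  # exact inverse of the generating shift
  shift <- -0.03 * 15 - 0.4 * 1.2 + 0.001 * 15 * 1.2
  expect_equal(adjust_reflectance(v + shift, 65, 24.8, m), v)
  expect_error(adjust_reflectance(v, NA, 24, m), "covariates")
})

test_that("cutoffs are the Gaussian 5% and 1% quantiles", {
  cu <- normative_cutoffs(0, 1)
  expect_equal(cu$q5, qnorm(0.05)); expect_equal(cu$q1, qnorm(0.01))
  expect_equal(round(cu$q5, 4), -1.6449)
  expect_equal(round(cu$q1, 4), -2.3263)
  cu2 <- normative_cutoffs(2, 2)
  expect_equal(2 - cu2$q5, 2 * (0 - cu$q5))   # scale equivariance
  expect_error(normative_cutoffs(0, 0), "positive")
})

test_that("empirical exceedance of the 5% cutoff matches its level", {
  set.seed(31)
  mu <- rnorm(160); sigma <- runif(160, 1, 2.5)
  cu <- normative_cutoffs(mu, sigma)
  draws <- 10000
  x <- matrix(rnorm(draws * 160, mu, sigma), ncol = 160, byrow = TRUE)
  fpr <- mean(sweep(x, 2, cu$q5, "<"))
  ci <- 2.576 * sqrt(0.05 * 0.95 / (draws * 160))
  expect_lt(abs(fpr - 0.05), ci + 1e-4)
})

test_that("adjusted normal values pass the Shapiro-Wilk normality check", {
  rejections <- 0L
  for (i in 1:20) {
    sc <- make_cohort(sim_config(n_normal = 35, n_ppg = 0, n_pg = 0),
                      seed = 600 + i)
    s <- summary(fit_normative(sc$cohort, method = "fast"))
    rejections <- rejections + (s$shapiro_p < 0.05)
  }
  expect_lte(rejections, 2)                  # >= 90% non-rejection
})

test_that("predict returns the full per-eye diagnostic result", {
  sc <- make_cohort(sim_config(), seed = 24)
  fit <- fit_normative(sc$cohort, method = "fast")
  pr <- predict(fit, sc$cohort)
  expect_equal(nrow(pr), 100)
  expect_true(all(pr$low_count_1 <= pr$low_count_5))
  expect_true(all(pr$focal_loss <= 0))
  expect_true(all((pr$focal_loss == 0) == (pr$low_count_5 == 0)))
  expect_true(all(pr$pattern %in% c("diffuse", "wedge", "other_grouping",
                                    "isolated", "none")))
  sig <- attr(pr, "significance")
  expect_equal(dim(sig), c(100, 160))
  # glaucoma eyes score worse than normals on every parameter
  expect_lt(mean(pr$focal_loss[pr$group == "PG"]),
            mean(pr$focal_loss[pr$group == "normal"]))
  expect_gt(mean(pr$low_count_5[pr$group == "PG"]),
            mean(pr$low_count_5[pr$group == "normal"]))
})

test_that("0.632+ bootstrap is seeded, covers all eyes, and is honest", {
  sc <- make_cohort(sim_config(n_normal = 25, n_ppg = 5, n_pg = 5), seed = 25)
  b1 <- bootstrap_632(sc$cohort, n_trials = 60, seed = 9)
  b2 <- bootstrap_632(sc$cohort, n_trials = 60, seed = 9)
  expect_identical(b1, b2)                   # seeding contract
  expect_true(all(b1$n_trials_used > 0))
  # glaucoma eyes are scored in every trial
  expect_true(all(b1$n_trials_used[b1$group != "normal"] == 60))

  inbag <- attr(b1, "inbag")
  expect_equal(dim(inbag), c(60, 25))
  unique_frac <- mean(rowMeans(inbag > 0))
  expect_lt(abs(unique_frac - (1 - (1 - 1 / 25)^25)), 0.03)

  # optimism: cross-validated normal low-counts >= resubstitution on average
  fit <- fit_normative(sc$cohort, method = "fast")
  resub <- predict(fit, sc$cohort)
  nrm <- b1$group == "normal"
  expect_gte(mean(b1$low_count_5[nrm]), mean(resub$low_count_5[nrm]) - 0.1)
})
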