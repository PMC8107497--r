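#' Eye cohort container
#'
#' Pairs a per-eye covariate table with the matrix of superpixel reflectance
#' vectors. One analyzed eye per participant is assumed throughout, so eyes
#' double as clusters in the ROC machinery unless stated otherwise.
#'
#' @param values numeric matrix, one row per eye, one column per superpixel
#'   (dB, adjusted or raw).
#' @param info data frame with one row per eye; must contain `eye_id`,
#'   `group` (factor or character: `"normal"`, `"PPG"`, `"PG"`), `age`
#'   (years), `axial_length` (mm); optionally `gender`, `vf_md` (dB) and
#'   thickness columns.
#' @return An object of class `nfl_cohort`.
#' @export
nfl_cohort <- function(values, info) {
  values <- as.matrix(values)
  stopifnot(is.data.frame(info), nrow(info) == nrow(values))
  need <- c("eye_id", "group", "age", "axial_length")
  miss <- setdiff(need, names(info))
  if (length(miss)) stop("info lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(info$eye_id)) stop("duplicate eye_id (one eye per participant)")
  structure(list(values = values, info = info), class = "nfl_cohort")
}

#' @export
print.nfl_cohort <- function(x, ...) {
  cat(sprintf("<nfl_cohort> %d eyes x %d superpixels\n",
              nrow(x$values), ncol(x$values)))
  print(table(x$info$group))
  invisible(x)
}

#' Gaussian percentile cutoffs per superpixel
#'
#' Under the normality assumption for adjusted normal-eye reflectance
#' (checked by Shapiro-Wilk in [summary.nfl_normative()]), the 5% and 1%
#' cutoffs are plug-in Gaussian quantiles of the per-superpixel reference
#' distribution.
#'
#' @param mu,sigma per-superpixel reference means and SDs (dB).
#' @return List with vectors `q5` and `q1`.
#' @export
normative_cutoffs <- function(mu, sigma) {
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("sigma must be positive for every superpixel")
  list(q5 = mu + stats::qnorm(0.05) * sigma,
       q1 = mu + stats::qnorm(0.01) * sigma)
}

#' Fit the normative reflectance model
#'
#' Fits, on the normal eyes only, the covariate model of superpixel
#' reflectance used to age/axial-length-adjust all eyes, then builds the
#' per-superpixel Gaussian reference distributions and percentile cutoffs
#' from the adjusted normal values.
#'
#' The default fit is a linear mixed-effects regression with random
#' intercepts for superpixel location and for eye (the eye term carries the
#' within-eye correlation, keeping the covariate standard errors honest)
#' and age, axial length, their interaction and gender as fixed effects
#' (REML via \pkg{lme4}/\pkg{lmerTest}). Covariates are centred at the
#' reference point (age 50 years, axial length `reference_axl` mm) so the
#' adjustment is exactly the identity there. Gender is retained in the fit
#' (it absorbs variance and yields a significance estimate) but the
#' adjustment itself uses only age, axial length and their interaction.
#'
#' `method = "fast"` exploits the balance of complete superpixel data: the
#' fixed-effect slopes of the random-intercept model coincide with those of
#' an ordinary regression of per-eye mean reflectance on the covariates.
#' It is used inside the 0.632+ bootstrap loop and flagged in the output;
#' it provides no per-superpixel random-effect decomposition.
#'
#' @param cohort an [nfl_cohort()]; only rows with `group == "normal"` are
#'   used for fitting.
#' @param method `"lme"` (default) or `"fast"`.
#' @param reference_age,reference_axl covariate reference point (50 yr;
#'   23.6 mm, the normal-group mean axial length).
#' @param normalization_constant optional linear-scale map normalization
#'   constant to carry alongside the model (see [normalization_constant()]).
#' @param min_normals minimum usable normal eyes.
#' @return An object of class `nfl_normative`; see [predict.nfl_normative()].
#' @export
fit_normative <- function(cohort, method = c("lme", "fast"),
                          reference_age = 50, reference_axl = 23.6,
                          normalization_constant = NULL,
                          min_normals = 20) {
  method <- match.arg(method)
  stopifnot(inherits(cohort, "nfl_cohort"))
  nrm <- cohort$info$group == "normal"
  if (sum(nrm) < min_normals)
    stop("need at least ", min_normals, " normal eyes, got ", sum(nrm))
  info <- cohort$info[nrm, , drop = FALSE]
  vals <- cohort$values[nrm, , drop = FALSE]
  if (any(!stats::complete.cases(info[c("age", "axial_length")])))
    stop("missing age/axial_length among normal eyes")

  age_c <- info$age - reference_age
  axl_c <- info$axial_length - reference_axl
  use_gender <- !is.null(info$gender) && length(unique(info$gender)) > 1
  X <- cbind(age = age_c, axial_length = axl_c, age_axl = age_c * axl_c,
             if (use_gender) stats::model.matrix(~gender, info)[, -1, drop = FALSE])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    drop <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)] - 1L]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(drop, collapse = ", "))
  }

  n_sp <- ncol(vals)
  if (method == "lme") {
    long <- data.frame(
      y = as.vector(t(vals)),
      sp = factor(rep(seq_len(n_sp), times = nrow(vals))),
      eye = factor(rep(seq_len(nrow(vals)), each = n_sp)),
      age_c = rep(age_c, each = n_sp),
      axl_c = rep(axl_c, each = n_sp))
    if (use_gender) long$gender <- rep(info$gender, each = n_sp)
    long <- long[is.finite(long$y), ]
    # random intercepts for superpixel location AND eye: the eye term
    # carries the within-eye correlation, without which the covariate SEs
    # would be far too optimistic
    fml <- if (use_gender) y ~ age_c * axl_c + gender + (1 | sp) + (1 | eye)
           else y ~ age_c * axl_c + (1 | sp) + (1 | eye)
    fit <- lmerTest::lmer(fml, data = long, REML = TRUE)
    ct <- stats::coef(summary(fit))
    pick <- function(nm) if (nm %in% rownames(ct)) ct[nm, ] else
      c(Estimate = 0, `Std. Error` = NA, df = NA, `t value` = NA,
        `Pr(>|t|)` = NA)
    rows <- rbind(age = pick("age_c"), axial_length = pick("axl_c"),
                  age_axl = pick("age_c:axl_c"))
    coefs <- rows[, "Estimate"]
    se <- rows[, "Std. Error"]
    pval <- rows[, "Pr(>|t|)"]
    gender_row <- grep("^gender", rownames(ct), value = TRUE)
    gender_effect <- if (length(gender_row))
      ct[gender_row[1], c("Estimate", "Std. Error", "Pr(>|t|)")] else NULL
  } else {
    eye_mean <- rowMeans(vals, na.rm = TRUE)
    df <- data.frame(y = eye_mean, age_c = age_c, axl_c = axl_c)
    if (use_gender) df$gender <- info$gender
    fml <- if (use_gender) y ~ age_c * axl_c + gender else y ~ age_c * axl_c
    fit <- stats::lm(fml, data = df)
    ct <- stats::coef(summary(fit))
    pick <- function(nm) if (nm %in% rownames(ct)) ct[nm, ] else rep(NA_real_, 4)
    rows <- rbind(age = pick("age_c"), axial_length = pick("axl_c"),
                  age_axl = pick("age_c:axl_c"))
    coefs <- rows[, 1]; se <- rows[, 2]; pval <- rows[, 4]
    gender_effect <- NULL
  }
  names(coefs) <- names(se) <- names(pval) <-
    c("age", "axial_length", "age_axl")

  model <- structure(list(coefficients = coefs, se = se, p_values = pval,
                          gender_effect = gender_effect,
                          reference_age = reference_age,
                          reference_axl = reference_axl,
                          method = method, n_normal = sum(nrm),
                          n_superpixels = n_sp,
                          normalization_constant = normalization_constant),
                     class = "nfl_normative")
  adj <- adjust_reflectance(vals, info$age, info$axial_length, model)
  mu <- colMeans(adj, na.rm = TRUE)
  sigma <- apply(adj, 2, stats::sd, na.rm = TRUE)
  cuts <- normative_cutoffs(mu, sigma)
  model$mu <- mu; model$sigma <- sigma
  model$q5 <- cuts$q5; model$q1 <- cuts$q1
  model$adjusted_normals <- adj
  model
}

#' Age and axial-length adjustment
#'
#' Removes the fitted covariate effect, mapping each value to its equivalent
#' at the reference point (age 50 years, reference axial length):
#' `adjusted = value - b_age*(age - 50) - b_axl*(AL - ref) -
#' b_int*(age - 50)*(AL - ref)`.
#'
#' @param values superpixel vector, or matrix with one row per eye.
#' @param age,axial_length per-eye covariates (recycled to rows of `values`).
#' @param model a fitted `nfl_normative`.
#' @return Adjusted values, same shape as `values`.
#' @export
adjust_reflectance <- function(values, age, axial_length, model) {
  stopifnot(inherits(model, "nfl_normative"))
  if (any(is.na(age)) || any(is.na(axial_length)))
    stop("missing covariates")
  b <- model$coefficients
  a <- age - model$reference_age
  x <- axial_length - model$reference_axl
  shift <- b["age"] * a + b["axial_length"] * x + b["age_axl"] * a * x
  if (is.matrix(values)) sweep(values, 1, shift, "-") else values - shift
}

#' @export
print.nfl_normative <- function(x, ...) {
  cat(sprintf("<nfl_normative> %s fit on %d normal eyes, %d superpixels\n",
              x$method, x$n_normal, x$n_superpixels))
  cat("  coefficients (dB/yr, dB/mm, dB/(yr*mm)):\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.nfl_normative <- function(object, ...) object$coefficients

#' Summary of a normative fit
#'
#' Coefficient table (estimate, SE, p), reference-distribution summaries and
#' a Shapiro-Wilk check of the normality assumption. Because superpixel
#' values within one eye are correlated, the check standardizes the
#' adjusted normal values per superpixel and tests an independent subsample
#' holding one superpixel per eye (deterministically rotating through the
#' superpixels), so the test's null distribution is valid.
#'
#' @param object a fitted `nfl_normative`.
#' @param ... ignored.
#' @export
summary.nfl_normative <- function(object, ...) {
  z <- scale(object$adjusted_normals, center = object$mu,
             scale = object$sigma)
  pick <- cbind(seq_len(nrow(z)),
                (seq_len(nrow(z)) * 37L) %% ncol(z) + 1L)
  zi <- z[pick]
  zi <- zi[is.finite(zi)]
  sw <- stats::shapiro.test(zi)
  out <- list(
    coefficients = cbind(estimate = object$coefficients, se = object$se,
                         p = object$p_values),
    gender_effect = object$gender_effect,
    sigma_mean = mean(object$sigma), sigma_peak = max(object$sigma),
    shapiro_p = sw$p.value, method = object$method,
    n_normal = object$n_normal)
  class(out) <- "summary.nfl_normative"
  out
}

#' @export
print.summary.nfl_normative <- function(x, ...) {
  cat(sprintf("Normative model (%s fit, %d normal eyes)\n", x$method, x$n_normal))
  print(round(x$coefficients, 5))
  cat(sprintf("mean superpixel SD %.2f dB, peak %.2f dB\n",
              x$sigma_mean, x$sigma_peak))
  cat(sprintf("Shapiro-Wilk on standardized adjusted values: P = %.2f\n",
              x$shapiro_p))
  invisible(x)
}

#' @export
plot.nfl_normative <- function(x, ...) {
  n_seg <- 5
  n_tr <- x$n_superpixels / n_seg
  m <- matrix(x$mu, nrow = n_seg)
  graphics::matplot(seq_len(n_tr), t(m), type = "l", lty = 1,
                    xlab = "track (1 = temporal, counterclockwise)",
                    ylab = "normative mean reflectance (dB)",
                    main = "Normative superpixel means by segment", ...)
  graphics::legend("bottomright", legend = paste("segment", seq_len(n_seg)),
                   col = seq_len(n_seg), lty = 1, cex = 0.7)
  invisible(x)
}

#' Diagnostic parameters for new eyes
#'
#' Adjusts each eye's superpixel vector for age and axial length, compares
#' it with the normative cutoffs and returns the three diagnostic
#' parameters plus the defect-pattern label.
#'
#' @param object a fitted `nfl_normative`.
#' @param cohort an `nfl_cohort` (or a list with `values` and `info`).
#' @param ... ignored.
#' @return Data frame with one row per eye: `eye_id`, `group`,
#'   `average_reflectance`, `low_count_5`, `low_count_1`, `focal_loss`,
#'   `pattern`. The adjusted matrix and the significance label matrix are
#'   attached as attributes `"adjusted"` and `"significance"`.
#' @export
predict.nfl_normative <- function(object, cohort, ...) {
  stopifnot(ncol(cohort$values) == object$n_superpixels)
  adj <- adjust_reflectance(cohort$values, cohort$info$age,
                            cohort$info$axial_length, object)
  n_seg <- 5; n_tr <- object$n_superpixels / n_seg
  res <- data.frame(
    eye_id = cohort$info$eye_id, group = cohort$info$group,
    average_reflectance = apply(adj, 1, average_reflectance),
    low_count_5 = apply(adj, 1, low_reflectance_count, cutoffs = object$q5),
    low_count_1 = apply(adj, 1, low_reflectance_count, cutoffs = object$q1),
    focal_loss = apply(adj, 1, focal_reflectance_loss, mu = object$mu,
                       cutoffs = object$q5),
    pattern = apply(adj, 1, function(v)
      classify_pattern(v < object$q5, n_tracks = n_tr, n_segments = n_seg)),
    stringsAsFactors = FALSE)
  sig <- t(apply(adj, 1, significance_map, q5 = object$q5, q1 = object$q1))
  attr(res, "adjusted") <- adj
  attr(res, "significance") <- sig
  res
}

#' 0.632+ bootstrap cross-validated diagnostic parameters
#'
#' Reduces resubstitution optimism in the diagnostic parameters: in each
#' trial the normal eyes are resampled with replacement, the adjustment and
#' cutoffs are fitted on the in-bag normals (about 63.2% unique eyes), and
#' the parameters are computed for the out-of-bag normals and for all
#' glaucoma eyes. Each eye's parameters are averaged over the trials in
#' which it was evaluated.
#'
#' @param cohort an [nfl_cohort()] with normal and glaucoma eyes.
#' @param n_trials bootstrap trials (>= 50).
#' @param seed RNG seed (required, for reproducibility).
#' @param method fit method per trial; the balanced `"fast"` fit is the
#'   default for speed.
#' @return Data frame as [predict.nfl_normative()] plus `n_trials_used`;
#'   the in-bag index matrix is attached as attribute `"inbag"`.
#' @export
bootstrap_632 <- function(cohort, n_trials = 200, seed, method = "fast") {
  stopifnot(inherits(cohort, "nfl_cohort"), n_trials >= 50)
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  nrm_idx <- which(cohort$info$group == "normal")
  gla_idx <- which(cohort$info$group != "normal")
  n <- nrow(cohort$values)
  num_cols <- c("average_reflectance", "low_count_5", "low_count_1",
                "focal_loss")
  acc <- matrix(0, n, length(num_cols), dimnames = list(NULL, num_cols))
  cnt <- integer(n)
  inbag <- matrix(0L, n_trials, length(nrm_idx))
  for (tr in seq_len(n_trials)) {
    bag <- sample(nrm_idx, length(nrm_idx), replace = TRUE)
    inbag[tr, ] <- tabulate(match(bag, nrm_idx), nbins = length(nrm_idx))
    oob <- setdiff(nrm_idx, bag)
    train <- nfl_cohort(cohort$values[bag, , drop = FALSE],
                        transform(cohort$info[bag, , drop = FALSE],
                                  eye_id = paste0("bag", seq_along(bag))))
    mod <- fit_normative(train, method = method)
    test_idx <- c(oob, gla_idx)
    if (!length(test_idx)) next
    test <- nfl_cohort(cohort$values[test_idx, , drop = FALSE],
                       cohort$info[test_idx, , drop = FALSE])
    pr <- predict(mod, test)
    acc[test_idx, ] <- acc[test_idx, ] + as.matrix(pr[num_cols])
    cnt[test_idx] <- cnt[test_idx] + 1L
  }
  if (any(cnt == 0))
    stop("eye(s) never out-of-bag after ", n_trials,
         " trials; increase n_trials: ",
         paste(cohort$info$eye_id[cnt == 0], collapse = ", "))
  out <- data.frame(eye_id = cohort$info$eye_id, group = cohort$info$group,
                    sweep(acc, 1, cnt, "/"), n_trials_used = cnt,
                    stringsAsFactors = FALSE)
  attr(out, "inbag") <- inbag
  out
}
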