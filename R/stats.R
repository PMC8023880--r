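#' Fit an HKAA-prediction regression model
#'
#' Ordinary least squares of the gold-standard hip-knee-ankle angle on the
#' femoro-tibial angle. Three variants are supported: `simple`
#' (`hkaa ~ fta`), `quadratic` (`hkaa ~ fta + fta^2`) and `sex_adjusted`
#' (`hkaa ~ fta * sex`: sex main effect plus FTA-by-sex interaction).
#'
#' @param fta numeric vector of FTA measurements, degrees.
#' @param hkaa numeric vector of gold-standard HKAA, degrees.
#' @param sex factor/character (`male`/`female`); required (and complete)
#'   for the sex-adjusted variant.
#' @param variant model variant.
#' @return an object of class `hkaa_model` with elements `variant`,
#'   `coefficients`, `n_fit` and the underlying `lm` fit.
#' @export
fit_hkaa_model <- function(fta, hkaa, sex = NULL,
                           variant = c("simple", "quadratic", "sex_adjusted")) {
  variant <- match.arg(variant)
  stopifnot(length(fta) == length(hkaa))
  ok <- is.finite(fta) & is.finite(hkaa)
  need <- c(simple = 3L, quadratic = 4L, sex_adjusted = 5L)[[variant]]
  if (variant == "sex_adjusted") {
    if (is.null(sex)) stop("sex-adjusted model requires sex", call. = FALSE)
    if (any(ok & (is.na(sex) | !nzchar(as.character(sex))))) {
      stop("sex-adjusted model refuses cases with missing sex", call. = FALSE)
    }
  }
  if (sum(ok) < need) {
    stop(sprintf("%s model needs at least %d complete cases, got %d",
                 variant, need, sum(ok)), call. = FALSE)
  }
  df <- data.frame(fta = fta[ok], hkaa = hkaa[ok])
  if (!is.null(sex)) df$sex <- factor(as.character(sex)[ok])
  if (stats::sd(df$fta) < 1e-12) {
    stop("singular fit: FTA predictor is constant", call. = FALSE)
  }
  fml <- switch(variant,
                simple = hkaa ~ fta,
                quadratic = hkaa ~ fta + I(fta^2),
                sex_adjusted = hkaa ~ fta * sex)
  if (variant == "sex_adjusted" && nlevels(df$sex) < 2) {
    stop("sex-adjusted model requires both sexes in the fitting data", call. = FALSE)
  }
  fit <- stats::lm(fml, data = df)
  if (any(is.na(stats::coef(fit)))) {
    stop("singular fit: rank-deficient design", call. = FALSE)
  }
  structure(list(variant = variant, coefficients = stats::coef(fit),
                 n_fit = nrow(df), fit = fit),
            class = "hkaa_model")
}

#' @export
predict.hkaa_model <- function(object, newdata, ...) {
  if (is.numeric(newdata)) newdata <- data.frame(fta = newdata)
  if (object$variant == "sex_adjusted") {
    newdata$sex <- factor(as.character(newdata$sex),
                          levels = levels(object$fit$model$sex))
  }
  unname(stats::predict(object$fit, newdata = newdata))
}

#' @export
print.hkaa_model <- function(x, ...) {
  cat(sprintf("<hkaa_model> %s (n = %d)\n", x$variant, x$n_fit))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Random k-fold assignment
#'
#' Seeded uniform shuffle followed by a contiguous split: fold sizes differ
#' by at most one, and every case belongs to exactly one fold. No
#' stratification is applied.
#'
#' @param case_ids case identifiers (or an integer n).
#' @param k number of folds.
#' @param seed integer seed (required; logged by the pipeline manifest).
#' @return integer vector of fold indices (1..k), named by case id.
#' @export
kfold_assignment <- function(case_ids, k = 5, seed) {
  if (length(case_ids) == 1 && is.numeric(case_ids)) {
    case_ids <- as.character(seq_len(case_ids))
  }
  n <- length(case_ids)
  stopifnot(k >= 2, n >= k)
  sizes <- rep(n %/% k, k)
  if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  folds <- integer(n)
  folds[perm] <- rep(seq_len(k), times = sizes)
  stats::setNames(folds, case_ids)
}

#' Cross-validated HKAA prediction
#'
#' Splits the cases into `k` random folds ([kfold_assignment()]); each fold
#' is predicted by a model fitted on the other k-1 folds, so every case
#' receives exactly one out-of-fold prediction. Deterministic given `seed`.
#'
#' @inheritParams fit_hkaa_model
#' @param k number of folds (default 5); requires `n >= 2k`.
#' @param seed integer seed for the fold assignment.
#' @param case_ids optional case identifiers.
#' @return data frame with columns `case_id`, `fold`, `fta`, `hkaa`,
#'   `pred`.
#' @export
kfold_predict <- function(fta, hkaa, sex = NULL,
                          variant = c("simple", "quadratic", "sex_adjusted"),
                          k = 5, seed, case_ids = NULL) {
  variant <- match.arg(variant)
  n <- length(fta)
  stopifnot(length(hkaa) == n)
  if (is.null(case_ids)) case_ids <- sprintf("case%03d", seq_len(n))
  if (n < 2 * k) {
    stop(sprintf("cross-validation with k = %d requires at least %d cases, got %d",
                 k, 2 * k, n), call. = FALSE)
  }
  folds <- kfold_assignment(case_ids, k = k, seed = seed)
  need <- c(simple = 3L, quadratic = 4L, sex_adjusted = 5L)[[variant]]
  sizes <- tabulate(folds, k)
  if (any(n - sizes < need)) {
    stop(sprintf("fold too small: training sets of %s cases cannot fit the %s model",
                 paste(unique(n - sizes), collapse = "/"), variant), call. = FALSE)
  }
  if (variant == "sex_adjusted") {
    for (f in seq_len(k)) {
      if (length(unique(as.character(sex)[folds != f])) < 2) {
        stop("fold ", f, ": training data contain a single sex; ",
             "sex-adjusted model cannot be fit", call. = FALSE)
      }
    }
  }
  pred <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    test <- folds == f
    model <- fit_hkaa_model(fta[!test], hkaa[!test],
                            sex = if (is.null(sex)) NULL else sex[!test],
                            variant = variant)
    nd <- data.frame(fta = fta[test])
    if (!is.null(sex)) nd$sex <- as.character(sex)[test]
    pred[test] <- predict(model, nd)
  }
  data.frame(case_id = case_ids, fold = unname(folds),
             fta = fta, hkaa = hkaa, pred = pred,
             stringsAsFactors = FALSE)
}

#' Pearson product-moment correlation
#'
#' Thin wrapper around [stats::cor()] with the preconditions used
#' throughout the pipeline: at least 3 pairs and nonzero variance in both
#' arguments.
#'
#' @param x,y numeric vectors of equal length.
#' @return the correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("Pearson correlation needs at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x[ok]) < 1e-12 || stats::sd(y[ok]) < 1e-12) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  stats::cor(x[ok], y[ok])
}

#' Intraclass correlation for absolute agreement (two-way, single measures)
#'
#' ICC(A,1) in the McGraw & Wong (1996) nomenclature: a two-way model with
#' the two measurement methods as fixed raters and cases as random subjects,
#' single measures, absolute-agreement definition -- the form that penalises
#' both dispersion and systematic offset between the methods. From the
#' two-way ANOVA mean squares (MSR between subjects, MSC between raters,
#' MSE residual; n subjects, k = 2 raters):
#'
#' \deqn{ICC(A,1) = \frac{MSR - MSE}{MSR + (k-1) MSE + \frac{k}{n}(MSC - MSE)}}
#'
#' The confidence interval uses McGraw & Wong's exact F-distribution method
#' (their Table 7): with `a = k*icc/(n*(1-icc))`, `b = 1 + k*icc*(n-1)/(n*(1-icc))`
#' and Satterthwaite degrees of freedom
#' `v = (a*MSC + b*MSE)^2 / ((a*MSC)^2/(k-1) + (b*MSE)^2/((n-1)(k-1)))`,
#' the bounds are obtained from the `F(n-1, v)` and `F(v, n-1)` quantiles.
#'
#' @param obs,pred paired measurements (n >= 5 pairs).
#' @param conf_level confidence level of the interval.
#' @return an object of class `icc`: `value`, `lower`, `upper`, `n`, `k`
#'   and the ANOVA mean squares.
#' @export
icc_agreement <- function(obs, pred, conf_level = 0.95) {
  stopifnot(length(obs) == length(pred))
  ok <- is.finite(obs) & is.finite(pred)
  x <- cbind(obs[ok], pred[ok])
  n <- nrow(x); k <- 2L
  if (n < 5) stop("ICC needs at least 5 paired values", call. = FALSE)
  G <- mean(x)
  SSR <- k * sum((rowMeans(x) - G)^2)
  SSC <- n * sum((colMeans(x) - G)^2)
  SST <- sum((x - G)^2)
  SSE <- max(SST - SSR - SSC, 0)
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (MSR < 1e-12) {
    stop("degenerate ANOVA: no between-subject variance", call. = FALSE)
  }
  est <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  alpha <- 1 - conf_level
  if (abs(1 - est) < 1e-12) {
    lower <- upper <- 1
  } else {
    a <- (k * est) / (n * (1 - est))
    b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- stats::qf(1 - alpha / 2, n - 1, v)
    FU <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    upper <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  }
  structure(list(value = est, lower = lower, upper = upper,
                 n = n, k = k, ms = c(MSR = MSR, MSC = MSC, MSE = MSE),
                 conf_level = conf_level),
            class = "icc")
}

#' @export
print.icc <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f (%.0f%% CI %.3f-%.3f), n = %d\n",
              x$value, 100 * x$conf_level, x$lower, x$upper, x$n))
  invisible(x)
}

#' Bland-Altman statistics for predicted vs observed angles
#'
#' Differences are oriented observed minus predicted. Besides the mean
#' difference (bias) and the limits of agreement (bias +/- 1.96 sd of the
#' differences), two proportional-bias regressions are reported: the
#' difference against the pairwise mean (the classical Bland-Altman
#' abscissa) and against the predicted value. For a regression-calibrated
#' prediction the difference-vs-mean slope is positively biased by OLS
#' shrinkage -- cov(obs - pred, (obs + pred)/2) equals half the residual
#' variance -- so the vs-predicted slope is the appropriate test of residual
#' proportional bias; both are returned.
#'
#' @param obs,pred paired angles, degrees.
#' @return list with `bias`, `sd_diff`, `loa_lower`, `loa_upper`,
#'   `slope_vs_mean`, `p_vs_mean`, `slope_vs_pred`, `p_vs_pred` and the
#'   per-case `data` frame.
#' @export
bland_altman <- function(obs, pred) {
  stopifnot(length(obs) == length(pred))
  ok <- is.finite(obs) & is.finite(pred)
  obs <- obs[ok]; pred <- pred[ok]
  if (length(obs) < 5) stop("Bland-Altman needs at least 5 pairs", call. = FALSE)
  diff <- obs - pred
  mn <- (obs + pred) / 2
  bias <- mean(diff)
  s <- stats::sd(diff)
  slope_stats <- function(x) {
    if (stats::sd(x) < 1e-12 || s < 1e-12) return(c(slope = 0, p = 1))
    sm <- summary(stats::lm(diff ~ x))$coefficients
    c(slope = sm["x", "Estimate"], p = sm["x", "Pr(>|t|)"])
  }
  vm <- slope_stats(mn)
  vp <- slope_stats(pred)
  list(bias = bias, sd_diff = s,
       loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
       slope_vs_mean = unname(vm["slope"]), p_vs_mean = unname(vm["p"]),
       slope_vs_pred = unname(vp["slope"]), p_vs_pred = unname(vp["p"]),
       data = data.frame(mean = mn, pred = pred, diff = diff))
}

#' Agreement summary between observed and predicted HKAA
#'
#' Bundles the evaluation statistics used throughout the pipeline: Pearson
#' correlation, absolute-agreement ICC with confidence interval, the mean
#' absolute error (mean, sd, range of |observed - predicted|) and the
#' Bland-Altman summary ([bland_altman()]). When `sex` is supplied with
#' both levels present, the absolute errors are additionally compared
#' between sexes with a Welch two-sample t-test.
#'
#' @inheritParams bland_altman
#' @param sex optional per-case sex for the error comparison.
#' @param conf_level confidence level for the ICC interval.
#' @return an object of class `agreement_summary`.
#' @export
agreement_summary <- function(obs, pred, sex = NULL, conf_level = 0.95) {
  stopifnot(length(obs) == length(pred))
  ok <- is.finite(obs) & is.finite(pred)
  if (sum(ok) < 5) stop("agreement summary needs at least 5 complete pairs", call. = FALSE)
  obs_ok <- obs[ok]; pred_ok <- pred[ok]
  abs_err <- abs(obs_ok - pred_ok)
  ba <- bland_altman(obs_ok, pred_ok)
  sex_p <- NA_real_
  if (!is.null(sex)) {
    sx <- factor(as.character(sex)[ok])
    if (nlevels(droplevels(sx)) == 2 && all(table(droplevels(sx)) >= 2)) {
      sex_p <- stats::t.test(abs_err ~ droplevels(sx))$p.value
    }
  }
  structure(list(
    n = sum(ok),
    pearson = pearson_r(obs_ok, pred_ok),
    icc = icc_agreement(obs_ok, pred_ok, conf_level = conf_level),
    mae = mean(abs_err), mae_sd = stats::sd(abs_err),
    mae_range = range(abs_err),
    bland_altman = ba,
    sex_error_p = sex_p
  ), class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("<agreement_summary> n = %d\n", x$n))
  cat(sprintf("  Pearson r   %.3f\n", x$pearson))
  cat(sprintf("  ICC(A,1)    %.3f (%.3f-%.3f)\n",
              x$icc$value, x$icc$lower, x$icc$upper))
  cat(sprintf("  MAE         %.2f deg (SD %.2f, range %.2f-%.2f)\n",
              x$mae, x$mae_sd, x$mae_range[1], x$mae_range[2]))
  cat(sprintf("  Bland-Altman bias %.2f deg, LoA %.2f to %.2f\n",
              x$bland_altman$bias, x$bland_altman$loa_lower,
              x$bland_altman$loa_upper))
  if (is.finite(x$sex_error_p)) {
    cat(sprintf("  |error| by sex: Welch p = %.2f\n", x$sex_error_p))
  }
  invisible(x)
}
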