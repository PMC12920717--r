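#' Fit the exponential lambda-versus-age model
#'
#' The diversity-decay metric lambda grows exponentially with chronological
#' age in healthy cohorts, so log(lambda) = a + b * age.  The constants are
#' estimated by maximum likelihood under Gaussian errors on the log scale
#' (equivalent to least squares there), with the optimizer started from the
#' conventional initial values a = 1/1000 and b = 0.3; the closed-form OLS
#' solution is computed as an internal cross-check and stored in the fit
#' log.  The fitted model inverts to a physiological blood age via
#' [predict_phyloage()].
#'
#' Individuals with lambda equal to zero carry no retained variants and sit
#' outside the model's support; they are dropped with a warning naming them.
#' A negative lambda is an input error.
#'
#' @param training data.frame with columns `age` (years) and `lambda`
#'   (positive), optionally `sample_id`.
#' @param init_a,init_b optimizer starting values (defaults 0.001 and 0.3).
#' @param threshold,depth_profile,panel_tag provenance recorded on the
#'   model: the tip-variant threshold, mean read depth (`"full"` for
#'   unresampled data), and panel label the training lambdas were computed
#'   under.
#' @return An object of class `"phyloage_model"`: list with elements `a`,
#'   `b`, `sigma` (residual SD on the log scale), `se_a`, `se_b`,
#'   provenance fields, `n_training` and `fit_log`.
#' @examples
#' coh <- calibrated_cohort(-1.65, 0.084, ages = seq(20, 80, 10))
#' fit_age_model(coh)
#' @export
fit_age_model <- function(training, init_a = 0.001, init_b = 0.3,
                          threshold = 0.01, depth_profile = "full",
                          panel_tag = "all") {
  if (!is.data.frame(training) || !all(c("age", "lambda") %in% names(training)))
    stop_input("training must be a data.frame with columns age and lambda")
  ids <- training$sample_id %||% paste0("ind", seq_len(nrow(training)))
  neg <- training$lambda < 0
  if (any(neg))
    stop_input("negative lambda for sample(s): ", paste(ids[neg], collapse = ", "))
  zero <- training$lambda == 0
  if (any(zero)) {
    warning("excluding sample(s) with lambda = 0 (no retained variants): ",
            paste(ids[zero], collapse = ", "), call. = FALSE)
    training <- training[!zero, , drop = FALSE]
    ids <- ids[!zero]
  }
  n <- nrow(training)
  if (n < 3) stop_input("at least 3 individuals with lambda > 0 are required")
  age <- training$age
  if (length(unique(age)) < 2)
    stop_input("all ages equal: slope b is unidentifiable")
  y <- log(training$lambda)
  sse <- function(par) sum((y - par[1] - par[2] * age)^2)
  grad <- function(par) {
    r <- y - par[1] - par[2] * age
    c(-2 * sum(r), -2 * sum(r * age))
  }
  opt <- optim(c(init_a, init_b), sse, grad, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15))
  ols <- lm(y ~ age)
  ols_ab <- unname(coef(ols))
  # the SSE surface is quadratic; accept whichever solution is lower to guard
  # against a premature optimizer stop, and record both in the fit log
  ab <- if (sse(ols_ab) < opt$value) ols_ab else opt$par
  a <- ab[1]; b <- ab[2]
  if (b <= 0)
    stop_input("fitted slope b <= 0: lambda does not increase with age in ",
               "this cohort, model not usable")
  res <- y - a - b * age
  sm <- suppressWarnings(summary(ols))  # noiseless fits trip a precision warning
  structure(list(a = a, b = b,
                 sigma = sqrt(sum(res^2) / n),
                 se_a = sm$coefficients[1, 2],
                 se_b = sm$coefficients[2, 2],
                 threshold = threshold,
                 depth_profile = depth_profile,
                 panel_tag = panel_tag,
                 n_training = n,
                 fit_log = list(optim_a = opt$par[1], optim_b = opt$par[2],
                                optim_sse = opt$value, ols_a = ols_ab[1],
                                ols_b = ols_ab[2], ols_sse = sse(ols_ab),
                                convergence = opt$convergence,
                                init = c(a = init_a, b = init_b),
                                likelihood = "gaussian_log_scale_unweighted")),
            class = "phyloage_model")
}

#' @method print phyloage_model
#' @export
print.phyloage_model <- function(x, ...) {
  cat(sprintf(paste0("phyloAge* model: log(lambda) = %.4g + %.4g * age\n",
                     "  n = %d, sigma(log) = %.3g, threshold = %g, depth = %s, panel = %s\n"),
              x$a, x$b, x$n_training, x$sigma, x$threshold,
              as.character(x$depth_profile), x$panel_tag))
  invisible(x)
}

#' Predict physiological blood age (phyloAge*) from lambda
#'
#' Inverts the exponential age model: phyloAge* = (log(lambda) - a) / b.
#' Very small lambdas give predictions below zero; these are returned as-is
#' (not clipped) and flagged via the `"negative"` attribute.
#'
#' @param model a `"phyloage_model"`.
#' @param lambda_value positive lambda value(s).
#' @return Predicted age(s) in years, with attribute `negative` marking
#'   below-zero predictions.
#' @export
predict_phyloage <- function(model, lambda_value) {
  stopifnot(inherits(model, "phyloage_model"))
  if (!is.numeric(lambda_value) || any(!is.finite(lambda_value)))
    stop_input("lambda_value must be finite numeric")
  if (any(lambda_value <= 0))
    stop_input("lambda <= 0 is below model support: no retained variants, ",
               "phyloAge* undefined")
  out <- (log(lambda_value) - model$a) / model$b
  attr(out, "negative") <- out < 0
  out
}

#' @export
predict.phyloage_model <- function(object, lambda_value, ...) {
  predict_phyloage(object, lambda_value)
}

#' Residual age
#'
#' Difference between the model's phyloAge* estimate and the chronological
#' age; positive values indicate physiologically older blood.
#' @param model a `"phyloage_model"`.
#' @param lambda_value positive lambda value(s).
#' @param age chronological age(s), years.
#' @return phyloAge* minus age.
#' @export
residual_age <- function(model, lambda_value, age) {
  as.numeric(predict_phyloage(model, lambda_value)) - age
}

# contiguous breaks so arbitrary (non-integer) ages still partition
phyloage_bands <- data.frame(
  band = c("0-30", "31-45", "46-60", "61-75", "76-100"),
  lo = c(-Inf, 30, 45, 60, 75),
  hi = c(30, 45, 60, 75, Inf))

#' Leave-one-out evaluation of the age model
#'
#' For each individual, refits the model on the remaining cohort and
#' predicts the held-out lambda.  Reports per-individual residuals, overall
#' MAE and RMSE, errors stratified over the standard age bands (0-30,
#' 31-45, 46-60, 61-75, 76-100 years) plus an under/over `split_age`
#' split, and a calibration regression of predictions on ages.  A fold
#' whose fit fails or whose held-out lambda is non-positive is recorded
#' with status and an NA residual rather than aborting the evaluation.
#'
#' @param cohort data.frame with columns `age`, `lambda`, optional
#'   `sample_id`.
#' @param threshold,depth_profile,panel_tag provenance passed to the fits.
#' @param split_age boundary for the additional two-band split (default 65).
#' @param n_bootstrap,seed bootstrap settings for the calibration CIs.
#' @return Object of class `"phyloage_eval"`: list with `per_individual`,
#'   `mae_overall`, `rmse_overall`, `strata`, `calibration`.
#' @export
loo_evaluate <- function(cohort, threshold = 0.01, depth_profile = "full",
                         panel_tag = "all", split_age = 65,
                         n_bootstrap = 1000L, seed = 1L) {
  if (!is.data.frame(cohort) || !all(c("age", "lambda") %in% names(cohort)))
    stop_input("cohort must be a data.frame with columns age and lambda")
  n <- nrow(cohort)
  if (n < 4) stop_input("leave-one-out evaluation needs at least 4 individuals")
  ids <- cohort$sample_id %||% paste0("ind", seq_len(n))
  pred <- rep(NA_real_, n)
  status <- rep("ok", n)
  for (i in seq_len(n)) {
    fit_i <- tryCatch(
      suppressWarnings(fit_age_model(cohort[-i, , drop = FALSE],
                                     threshold = threshold,
                                     depth_profile = depth_profile,
                                     panel_tag = panel_tag)),
      error = function(e) e)
    if (inherits(fit_i, "error")) { status[i] <- conditionMessage(fit_i); next }
    if (cohort$lambda[i] <= 0) { status[i] <- "below model support"; next }
    pred[i] <- as.numeric(predict_phyloage(fit_i, cohort$lambda[i]))
  }
  resid <- pred - cohort$age
  per <- data.frame(sample_id = ids, age = cohort$age, lambda = cohort$lambda,
                    phyloage_star = pred, residual = resid, status = status,
                    stringsAsFactors = FALSE)
  ok <- !is.na(resid)
  strata <- do.call(rbind, lapply(seq_len(nrow(phyloage_bands)), function(j) {
    inb <- ok & cohort$age > phyloage_bands$lo[j] & cohort$age <= phyloage_bands$hi[j]
    data.frame(band = phyloage_bands$band[j], n = sum(inb),
               rmse = if (any(inb)) sqrt(mean(resid[inb]^2)) else NA_real_,
               mae = if (any(inb)) mean(abs(resid[inb])) else NA_real_)
  }))
  split <- do.call(rbind, lapply(list(
    list(band = sprintf("<%g", split_age), sel = ok & cohort$age < split_age),
    list(band = sprintf(">=%g", split_age), sel = ok & cohort$age >= split_age)),
    function(s) data.frame(band = s$band, n = sum(s$sel),
                           rmse = if (any(s$sel)) sqrt(mean(resid[s$sel]^2)) else NA_real_,
                           mae = if (any(s$sel)) mean(abs(resid[s$sel])) else NA_real_)))
  calib <- if (sum(ok) >= 3 && var(cohort$age[ok]) > 0)
    calibration_regression(cohort$age[ok], pred[ok],
                           n_bootstrap = n_bootstrap, seed = seed)
  else NULL
  structure(list(per_individual = per,
                 mae_overall = mean(abs(resid[ok])),
                 rmse_overall = sqrt(mean(resid[ok]^2)),
                 strata = rbind(strata, split),
                 calibration = calib),
            class = "phyloage_eval")
}

#' @method print phyloage_eval
#' @export
print.phyloage_eval <- function(x, ...) {
  cat(sprintf("Leave-one-out evaluation: n = %d, MAE = %.3g y, RMSE = %.3g y\n",
              nrow(x$per_individual), x$mae_overall, x$rmse_overall))
  print(x$strata, row.names = FALSE)
  if (!is.null(x$calibration))
    cat(sprintf("calibration: intercept %.3g (%.3g, %.3g), slope %.3g (%.3g, %.3g), R2 %.3g\n",
                x$calibration$intercept, x$calibration$ci_intercept[1],
                x$calibration$ci_intercept[2], x$calibration$slope,
                x$calibration$ci_slope[1], x$calibration$ci_slope[2],
                x$calibration$r_squared))
  invisible(x)
}

#' Calibration regression of predictions on chronological age
#'
#' OLS of phyloAge* predictions on ages; a well-calibrated model has
#' intercept 0 and slope 1.  Percentile confidence intervals come from a
#' seeded bootstrap over individuals.
#'
#' @param ages,predictions equal-length numeric vectors, n >= 3.
#' @param n_bootstrap bootstrap replicates (default 1000).
#' @param seed bootstrap seed.
#' @param conf confidence level (default 0.95).
#' @return List with `intercept`, `slope`, `r_squared` and percentile CIs
#'   `ci_intercept`, `ci_slope`, `ci_r_squared`.
#' @export
calibration_regression <- function(ages, predictions, n_bootstrap = 1000L,
                                   seed = 1L, conf = 0.95) {
  if (length(ages) != length(predictions))
    stop_input("ages and predictions must have equal length")
  n <- length(ages)
  if (n < 3) stop_input("calibration regression needs at least 3 individuals")
  if (var(ages) == 0) stop_input("zero variance in ages")
  fit <- lm(predictions ~ ages)
  boots <- with_seed(seed, {
    t(vapply(seq_len(n_bootstrap), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (var(ages[idx]) == 0) return(c(NA_real_, NA_real_, NA_real_))
      f <- lm(predictions[idx] ~ ages[idx])
      c(coef(f), suppressWarnings(summary(f))$r.squared)
    }, numeric(3)))
  })
  alpha <- (1 - conf) / 2
  ci <- function(col) unname(quantile(boots[, col], c(alpha, 1 - alpha), na.rm = TRUE))
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       r_squared = suppressWarnings(summary(fit))$r.squared,
       ci_intercept = ci(1), ci_slope = ci(2), ci_r_squared = ci(3),
       n = n, n_bootstrap = n_bootstrap, seed = seed)
}

#' Serialize an age model to JSON
#'
#' @param model a `"phyloage_model"`.
#' @param path output path.
#' @export
write_age_model <- function(model, path) {
  stopifnot(inherits(model, "phyloage_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_age_model
#' @export
read_age_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "phyloage_model")
}

#' Export an evaluation report as TSV
#' @param x a `"phyloage_eval"`.
#' @param path output file; strata go to `<path>` with a `.strata.tsv`
#'   sibling.
#' @export
write_evaluation_report <- function(x, path) {
  stopifnot(inherits(x, "phyloage_eval"))
  write.table(x$per_individual, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$strata, sub("(\\.tsv)?$", ".strata.tsv", path),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
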