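#' Stepwise linear model for an appraisal
#'
#' Fits the full main-effects linear model of an appraisal on the
#' screened eye-behavior features and reduces it by bidirectional
#' stepwise search minimizing AIC (via [MASS::stepAIC()]). The other
#' appraisal and any questionnaire item columns are barred from the
#' predictor set (a leakage guard), as are id columns.
#'
#' @param response name of the appraisal column to model
#'   (e.g. `"comprehensibility"`).
#' @param data the screened study table.
#' @param predictors names of candidate predictor columns; defaults to
#'   every numeric feature column (ids, appraisals and item responses
#'   excluded).
#' @param criterion penalty per parameter in the stepwise search
#'   (default `2`, i.e. AIC).
#' @return An object of class `appraisal_lm`: the reduced [stats::lm()]
#'   fit plus `response`, `predictors` (selected), `r_squared_pct`,
#'   `f_statistic`, `df`, `p_value`, `t_values` and the search settings.
#' @export
appraisal_lm <- function(response, data, predictors = NULL, criterion = 2) {
  if (!response %in% names(data)) stop("response column not found: ", response)
  barred <- c("participant", "article", "block", "order",
              "comprehensibility", "interest", "novelty_complexity",
              unlist(lapply(scale_definitions(), `[[`, "items"),
                     use.names = FALSE))
  if (is.null(predictors)) {
    predictors <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                          barred)
  } else {
    leak <- intersect(predictors, barred)
    if (length(leak)) {
      stop("predictors would leak appraisal information: ",
           paste(leak, collapse = ", "))
    }
  }
  if (!length(predictors)) stop("no candidate predictors")
  df <- data[, c(response, predictors), drop = FALSE]
  if (anyNA(df)) stop("screened data must not contain missing values")
  n <- nrow(df)
  if (n <= length(predictors) + 1) {
    stop("more predictors than observations; screen the table more aggressively")
  }
  full <- stats::lm(stats::reformulate(predictors, response = response),
                    data = df)
  reduced <- MASS::stepAIC(full, direction = "both", trace = 0, k = criterion)
  sm <- summary(reduced)
  sel <- attr(stats::terms(reduced), "term.labels")
  fstat <- sm$fstatistic
  if (is.null(fstat)) fstat <- c(NA_real_, 0, stats::df.residual(reduced))
  structure(
    list(fit = reduced, response = response, predictors = sel,
         r_squared_pct = 100 * sm$r.squared,
         f_statistic = unname(fstat[1]),
         df = unname(fstat[2:3]),
         p_value = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                    lower.tail = FALSE)),
         t_values = sm$coefficients[, "t value"],
         criterion = criterion, n = n),
    class = "appraisal_lm")
}

#' @export
print.appraisal_lm <- function(x, ...) {
  cat(sprintf("Stepwise linear model for %s\n", x$response))
  cat(sprintf("  %d predictors selected from the screened feature set (n = %d)\n",
              length(x$predictors), x$n))
  cat(sprintf("  R^2 = %.2f%%, F(%d, %d) = %.2f, p = %.3g\n",
              x$r_squared_pct, x$df[1], x$df[2], x$f_statistic, x$p_value))
  invisible(x)
}

#' @export
summary.appraisal_lm <- function(object, ...) summary(object$fit, ...)

#' @export
coef.appraisal_lm <- function(object, ...) stats::coef(object$fit)

#' @export
predict.appraisal_lm <- function(object, newdata = NULL, ...) {
  stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.appraisal_lm <- function(object, ...) stats::residuals(object$fit)

#' Leave-one-out cross-validation of a fixed predictor set
#'
#' Every observation is predicted by the linear model refit on the
#' remaining N - 1 observations, keeping the predictor set fixed (the
#' set is treated as optimal; only the coefficients are re-estimated).
#' For ordinary least squares the held-out prediction equals
#' `y_i - e_i / (1 - h_i)` (the PRESS identity, algebraically identical
#' to N explicit refits), which is how it is computed; folds with
#' leverage `h_i` at 1, where the refit would be singular, are flagged
#' and dropped from the error summaries.
#'
#' Performance is summarized by `nRMSE` (RMSE divided by the range of
#' the actual responses, i.e. min-max normalized) and Pearson's r
#' between predictions and actuals. Predictions are not clipped to the
#' 1-7 response scale.
#'
#' @param object an [appraisal_lm()] fit, or `NULL` when `data`,
#'   `predictors` and `response` are given directly.
#' @param data the screened table (defaults to the model frame).
#' @param predictors,response predictor/response column names.
#' @return An object of class `appraisal_cv`: data frame `folds`
#'   (actual, predicted, flagged) plus `nrmse`, `pearson_r`, `response`,
#'   `n`.
#' @export
loocv <- function(object = NULL, data = NULL, predictors = NULL,
                  response = NULL) {
  if (!is.null(object)) {
    stopifnot(inherits(object, "appraisal_lm"))
    if (is.null(data)) data <- stats::model.frame(object$fit)
    predictors <- object$predictors
    response <- object$response
  }
  if (!length(predictors)) stop("no predictors to cross-validate")
  fit <- stats::lm(stats::reformulate(predictors, response = response),
                   data = data)
  y <- stats::model.response(stats::model.frame(fit))
  h <- stats::lm.influence(fit, do.coef = FALSE)$hat
  singular <- h > 1 - 1e-8
  pred <- y - stats::residuals(fit) / (1 - h)
  pred[singular] <- NA_real_
  ok <- !singular
  rng <- diff(range(y[ok]))
  structure(
    list(folds = data.frame(actual = y, predicted = pred,
                            singular = singular),
         nrmse = sqrt(mean((pred[ok] - y[ok])^2)) / rng,
         pearson_r = stats::cor(pred[ok], y[ok]),
         n_singular = sum(singular),
         response = response, n = length(y)),
    class = "appraisal_cv")
}

#' @export
print.appraisal_cv <- function(x, ...) {
  cat(sprintf("Leave-one-out CV for %s (n = %d%s)\n", x$response, x$n,
              if (x$n_singular) sprintf(", %d singular folds", x$n_singular) else ""))
  cat(sprintf("  nRMSE = %.3f, Pearson r = %.3f\n", x$nrmse, x$pearson_r))
  invisible(x)
}

#' Feature-appraisal correlation table
#'
#' Pearson correlation of every feature with every appraisal, with
#' two-sided t-test p-values and the conventional significance stars
#' (.05 / .01 / .001). No multiple-testing correction is applied (the
#' table mirrors per-cell testing); the number of tests is recorded.
#' Constant features yield `NA`.
#'
#' @param table the (screened) study table.
#' @param appraisals appraisal column names (default comprehensibility
#'   and interest).
#' @param features feature column names; defaults to all numeric
#'   non-appraisal, non-id columns.
#' @return A data frame `feature, appraisal, r, p, stars` with
#'   attribute `n_tests`.
#' @export
correlation_table <- function(table,
                              appraisals = c("comprehensibility", "interest"),
                              features = NULL) {
  if (is.null(features)) {
    features <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                        c(appraisals, "order"))
  }
  out <- expand.grid(feature = features, appraisal = appraisals,
                     stringsAsFactors = FALSE)
  est <- mapply(function(f, a) {
    x <- table[[f]]; y <- table[[a]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(c(NA_real_, NA_real_))
    }
    r <- stats::cor(x[ok], y[ok])
    n <- sum(ok)
    tval <- r * sqrt((n - 2) / (1 - r^2))
    c(r, 2 * stats::pt(-abs(tval), n - 2))
  }, out$feature, out$appraisal)
  out$r <- est[1, ]
  out$p <- est[2, ]
  out$stars <- ifelse(is.na(out$p), "",
                      ifelse(out$p < .001, "***",
                             ifelse(out$p < .01, "**",
                                    ifelse(out$p < .05, "*", ""))))
  attr(out, "n_tests") <- sum(!is.na(out$p))
  out
}

#' Chance-level baseline of a rating scale
#'
#' The percent accuracy of guessing uniformly on a scale with
#' `n_levels` response options: 14.29% for a 7-point scale, 50% for a
#' binary one. Used as the reference line in prediction reports.
#'
#' @param n_levels number of response levels.
#' @return percent (scalar).
#' @export
chance_level <- function(n_levels) {
  stopifnot(n_levels >= 1)
  100 / n_levels
}

#' Predicted-vs-actual report data
#'
#' Builds plot-ready data for the cross-validation scatter: the point
#' pairs, a local-regression (loess) trend of actual on predicted with
#' 95% prediction intervals from the linear calibration fit
#' (`predict.lm`), and kernel density margins for both axes.
#'
#' @param cv an [loocv()] result.
#' @param span loess smoothing span (default 0.75).
#' @param grid_n number of grid points for trend and densities.
#' @return A list of data frames: `points`, `trend`
#'   (`predicted, actual_smooth, lower, upper`), `density_actual`,
#'   `density_predicted`; plus `nrmse`, `pearson_r`, `chance_pct`.
#' @export
cv_report <- function(cv, span = 0.75, grid_n = 101) {
  stopifnot(inherits(cv, "appraisal_cv"))
  pts <- cv$folds[!cv$folds$singular, c("actual", "predicted")]
  grid <- data.frame(predicted = seq(min(pts$predicted), max(pts$predicted),
                                     length.out = grid_n))
  lo <- stats::loess(actual ~ predicted, data = pts, span = span,
                     degree = 2, family = "gaussian")
  lin <- stats::lm(actual ~ predicted, data = pts)
  pi_band <- stats::predict(lin, newdata = grid, interval = "prediction",
                            level = 0.95)
  trend <- data.frame(predicted = grid$predicted,
                      actual_smooth = stats::predict(lo, newdata = grid),
                      lower = pi_band[, "lwr"], upper = pi_band[, "upr"])
  dens <- function(v) {
    d <- stats::density(v, n = grid_n)
    data.frame(value = d$x, density = d$y)
  }
  list(points = pts, trend = trend,
       density_actual = dens(pts$actual),
       density_predicted = dens(pts$predicted),
       nrmse = cv$nrmse, pearson_r = cv$pearson_r,
       chance_pct = chance_level(7))
}

#' Plot a cross-validation result
#'
#' Scatter of actual vs predicted appraisals with the loess trend, the
#' 95% prediction band and marginal densities, in base graphics.
#'
#' @param x an `appraisal_cv` object.
#' @param span loess span forwarded to [cv_report()].
#' @param ... ignored.
#' @return the report data, invisibly.
#' @export
plot.appraisal_cv <- function(x, span = 0.75, ...) {
  rep <- cv_report(x, span = span)
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op))
  layout_m <- matrix(c(2, 4, 1, 3), 2, 2, byrow = TRUE)
  graphics::layout(layout_m, widths = c(4, 1), heights = c(1, 4))
  graphics::par(mar = c(4, 4, 0.5, 0.5))
  graphics::plot(rep$points$predicted, rep$points$actual,
                 xlab = sprintf("Predicted %s", x$response),
                 ylab = sprintf("Actual %s", x$response),
                 pch = 16, col = grDevices::adjustcolor("grey30", 0.5))
  oo <- order(rep$trend$predicted)
  graphics::polygon(c(rep$trend$predicted[oo], rev(rep$trend$predicted[oo])),
                    c(rep$trend$lower[oo], rev(rep$trend$upper[oo])),
                    col = grDevices::adjustcolor("steelblue", 0.15),
                    border = NA)
  graphics::lines(rep$trend$predicted[oo], rep$trend$actual_smooth[oo],
                  col = "steelblue", lwd = 2)
  graphics::par(mar = c(0.5, 4, 0.5, 0.5))
  graphics::plot(rep$density_predicted$value, rep$density_predicted$density,
                 type = "l", axes = FALSE, xlab = "", ylab = "")
  graphics::par(mar = c(4, 0.5, 0.5, 0.5))
  graphics::plot(rep$density_actual$density, rep$density_actual$value,
                 type = "l", axes = FALSE, xlab = "", ylab = "")
  invisible(rep)
}
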