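sim_table <- function(n, p, beta = NULL, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  y <- rnorm(n)
  if (!is.null(beta)) y <- y + x %*% beta
  data.frame(comprehensibility = as.numeric(y), x)
}

test_that("the stepwise fit bars appraisal leakage and degenerate designs", {
  tab <- sim_table(50, 3)
  tab$interest <- rnorm(50)
  expect_error(appraisal_lm("comprehensibility", tab,
                            predictors = c("x1", "interest")), "leak")
  expect_error(appraisal_lm("comprehensibility", tab,
                            predictors = c("x1", "int_exciting")), "leak")
  m <- appraisal_lm("comprehensibility", tab)
  expect_false("interest" %in% m$predictors)
  wide <- sim_table(10, 20)
  expect_error(appraisal_lm("comprehensibility", wide), "screen")
  expect_error(appraisal_lm("nope", tab), "not found")
})

test_that("under pure noise the selected model cross-validates near zero while fitting above zero in-sample", {
  rs <- c(); r2 <- c()
  for (seed in 1:8) {
    tab <- sim_table(300, 10, seed = seed)
    m <- appraisal_lm("comprehensibility", tab)
    r2 <- c(r2, m$r_squared_pct)
    if (length(m$predictors)) rs <- c(rs, loocv(m, data = tab)$pearson_r)
  }
  expect_lt(abs(mean(rs)), 2 / sqrt(300))
  expect_gt(mean(r2), 0)  # selection bias shows up in-sample
})

test_that("a planted predictor with a standardized effect of 0.5 is selected almost always", {
  hits <- 0L
  for (seed in 1:12) {
    tab <- sim_table(400, 10, beta = c(0.5, rep(0, 9)), seed = 100 + seed)
    m <- appraisal_lm("comprehensibility", tab)
    hits <- hits + ("x1" %in% m$predictors)
  }
  expect_gte(hits, 11L)
})

test_that("model accessors report the fit consistently", {
  tab <- sim_table(200, 5, beta = c(0.8, 0.4, 0, 0, 0), seed = 3)
  m <- appraisal_lm("comprehensibility", tab)
  expect_s3_class(m, "appraisal_lm")
  expect_equal(m$df[2], m$n - m$df[1] - 1)
  expect_true(m$r_squared_pct > 0 && m$r_squared_pct < 100)
  expect_equal(length(predict(m)), 200L)
  expect_named(coef(m))
  expect_output(print(m), "Stepwise linear model")
})

test_that("leave-one-out predictions equal N explicit refits and recover a noiseless linear response", {
  set.seed(9)
  tab <- sim_table(40, 4, beta = c(1, -0.5, 0.25, 0), seed = 9)
  cv <- loocv(data = tab, predictors = paste0("x", 1:4),
              response = "comprehensibility")
  oracle <- loocv_oracle(tab, paste0("x", 1:4), "comprehensibility")
  expect_equal(cv$folds$predicted, oracle, tolerance = 1e-8)

  # exact linear response: r = 1, nRMSE ~ 0
  tab2 <- sim_table(30, 2, seed = 10)
  tab2$comprehensibility <- 2 + 3 * tab2$x1 - tab2$x2
  cv2 <- loocv(data = tab2, predictors = c("x1", "x2"),
               response = "comprehensibility")
  expect_equal(cv2$pearson_r, 1, tolerance = 1e-9)
  expect_lt(cv2$nrmse, 1e-9)
  expect_output(print(cv2), "Leave-one-out")
})

test_that("nRMSE divides the refit RMSE by the observed response range (hand-computed five-row table)", {
  tab <- data.frame(y = c(1, 3, 5, 7, 14), x = c(1.2, 2.9, 5.3, 6.8, 13.1))
  cv <- loocv(data = tab, predictors = "x", response = "y")
  pred <- loocv_oracle(tab, "x", "y")
  hand <- sqrt(mean((pred - tab$y)^2)) / (max(tab$y) - min(tab$y))
  expect_equal(cv$nrmse, hand, tolerance = 1e-12)
  expect_equal(cv$pearson_r, cor(pred, tab$y), tolerance = 1e-12)
})

test_that("the correlation table matches the covariance formula, stars p-values, and handles constants", {
  set.seed(12)
  tab <- data.frame(comprehensibility = rnorm(10), interest = rnorm(10),
                    f1 = rnorm(10), f2 = rnorm(10), const = rep(2, 10))
  tab$f3 <- tab$comprehensibility
  ct <- correlation_table(tab)
  row <- function(f, a) ct[ct$feature == f & ct$appraisal == a, ]
  # r = 1 when the feature is the appraisal itself
  expect_equal(row("f3", "comprehensibility")$r, 1)
  # brute-force covariance / (sd * sd)
  x <- tab$f1; y <- tab$interest
  brute <- sum((x - mean(x)) * (y - mean(y))) / (9 * sd(x) * sd(y))
  expect_equal(row("f1", "interest")$r, brute, tolerance = 1e-12)
  tv <- brute * sqrt(8 / (1 - brute^2))
  expect_equal(row("f1", "interest")$p, 2 * pt(-abs(tv), 8), tolerance = 1e-12)
  expect_true(is.na(row("const", "interest")$r))
  expect_equal(attr(ct, "n_tests"), sum(!is.na(ct$p)))
})

test_that("chance-level baselines are exact scale arithmetic", {
  expect_equal(chance_level(7), 100 / 7)
  expect_equal(chance_level(2), 50)
})

test_that("the CV report yields a diagonal trend for perfect predictions and a stable schema", {
  set.seed(15)
  y <- rnorm(200, 4, 1)
  cv <- structure(list(folds = data.frame(actual = y, predicted = y,
                                          singular = FALSE),
                       nrmse = 0, pearson_r = 1, n_singular = 0L,
                       response = "comprehensibility", n = 200L),
                  class = "appraisal_cv")
  rep <- cv_report(cv)
  expect_named(rep, c("points", "trend", "density_actual",
                      "density_predicted", "nrmse", "pearson_r", "chance_pct"))
  expect_named(rep$trend, c("predicted", "actual_smooth", "lower", "upper"))
  inner <- rep$trend$predicted > quantile(y, .1) & rep$trend$predicted < quantile(y, .9)
  expect_lt(max(abs(rep$trend$actual_smooth[inner] - rep$trend$predicted[inner])), 0.05)
  expect_equal(rep$chance_pct, 100 / 7)
})

test_that("95% prediction intervals cover about 95% of simulated linear data", {
  set.seed(16)
  n <- 1500
  x <- rnorm(n)
  tab <- data.frame(comprehensibility = 4 + 0.8 * x + rnorm(n, 0, 0.8), x = x)
  cv <- loocv(data = tab, predictors = "x", response = "comprehensibility")
  rep <- cv_report(cv)
  lo <- approx(rep$trend$predicted, rep$trend$lower, xout = cv$folds$predicted)$y
  hi <- approx(rep$trend$predicted, rep$trend$upper, xout = cv$folds$predicted)$y
  cover <- mean(cv$folds$actual >= lo & cv$folds$actual <= hi, na.rm = TRUE)
  expect_gt(cover, 0.92)
  expect_lt(cover, 0.98)
})

test_that("plotting the CV result draws without error and returns the report invisibly", {
  set.seed(17)
  tab <- sim_table(80, 2, beta = c(0.7, 0), seed = 17)
  cv <- loocv(data = tab, predictors = c("x1", "x2"),
              response = "comprehensibility")
  png_file <- tempfile(fileext = ".png")
  grDevices::png(png_file)
  out <- plot(cv)
  grDevices::dev.off()
  expect_true(file.exists(png_file))
  expect_named(out$trend, c("predicted", "actual_smooth", "lower", "upper"))
  unlink(png_file)
})
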