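# Independent brute-force oracles and small fixture builders.
# These deliberately re-derive every quantity from first principles,
# without reusing package internals beyond the exported px/deg mapping.

# build a gaze stream with both eyes on the same position (so the
# binocular mean is exactly x, y); blink rows are encoded by x = y = 0
make_stream <- function(t, x, y, pupil = 15) {
  n <- length(t)
  pupil <- rep_len(pupil, n)
  pupil[x == 0 & y == 0] <- 0
  data.frame(time_ms = t,
             left_x_px = x, left_y_px = y,
             right_x_px = x, right_y_px = y,
             left_pupil_px = pupil, right_pupil_px = pupil)
}

# O(n^2) greedy dispersion grouping: recomputes the bounding-box
# dispersion of every candidate run from scratch
idt_oracle <- function(stream, geometry = screen_geometry(),
                       min_duration_ms = 80, dispersion_deg = 1.0,
                       max_gap_intervals = 2) {
  t <- stream$time_ms
  x <- (stream$left_x_px + stream$right_x_px) / 2
  y <- (stream$left_y_px + stream$right_y_px) / 2
  blink <- (stream$left_x_px == 0 & stream$left_y_px == 0) |
    (stream$right_x_px == 0 & stream$right_y_px == 0)
  thr <- deg_to_px(dispersion_deg, geometry)
  n <- length(t)
  nominal <- if (n > 1) stats::median(diff(t)) else Inf
  res <- NULL
  i <- 1L
  while (i <= n) {
    if (blink[i]) { i <- i + 1L; next }
    j <- i
    while (j < n) {
      if (blink[j + 1L] || (t[j + 1L] - t[j]) > max_gap_intervals * nominal) break
      run <- i:(j + 1L)
      disp <- (max(x[run]) - min(x[run])) + (max(y[run]) - min(y[run]))
      if (disp > thr) break
      j <- j + 1L
    }
    if (t[j] - t[i] >= min_duration_ms) {
      run <- i:j
      res <- rbind(res, c(t[i], t[j], mean(x[run]), mean(y[run])))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (is.null(res)) {
    return(data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      centroid_x_px = numeric(0), centroid_y_px = numeric(0)))
  }
  data.frame(onset_ms = res[, 1], offset_ms = res[, 2],
             centroid_x_px = res[, 3], centroid_y_px = res[, 4])
}

# type-7 quantile written out longhand
quantile7_oracle <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- min(lo + 1, length(x))
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

iqr_oracle <- function(x, multiplier = 4) {
  fin <- x[is.finite(x)]
  if (length(fin) < 4) return(x)
  q1 <- quantile7_oracle(fin, 0.25)
  q2 <- quantile7_oracle(fin, 0.50)
  q3 <- quantile7_oracle(fin, 0.75)
  iqr <- q3 - q1
  x[x >= q2 - multiplier * iqr & x <= q3 + multiplier * iqr]
}

# leave-one-out by N explicit refits
loocv_oracle <- function(data, predictors, response) {
  f <- stats::reformulate(predictors, response)
  vapply(seq_len(nrow(data)), function(i) {
    fit <- stats::lm(f, data = data[-i, , drop = FALSE])
    unname(stats::predict(fit, newdata = data[i, , drop = FALSE]))
  }, numeric(1))
}

# exhaustive search over removal subsets: smallest sets that leave no
# pair above the threshold
dedup_oracle_sizes <- function(df, r_threshold) {
  cols <- names(df)
  cm <- abs(stats::cor(as.matrix(df)))
  diag(cm) <- 0
  best <- length(cols)
  for (size in 0:length(cols)) {
    combos <- utils::combn(cols, size, simplify = FALSE)
    ok <- vapply(combos, function(rm) {
      keep <- setdiff(cols, rm)
      length(keep) < 2 || max(cm[keep, keep]) <= r_threshold
    }, logical(1))
    if (any(ok)) return(size)
  }
  best
}

default_cfg_small <- function(seed = 1, n_participants = 4, n_articles = 4,
                              n_blocks = 2, dropout_rate = 0,
                              pupil_loss_sessions = 1, ...) {
  gaze_config(n_participants = n_participants, n_articles = n_articles,
              n_blocks = n_blocks, dropout_rate = dropout_rate,
              pupil_loss_sessions = pupil_loss_sessions, rng_seed = seed, ...)
}

null_directions <- function() {
  list(reading_time = 0, fixation_duration = 0, saccade_amplitude = 0,
       pupil_variance = 0, regression = 0)
}

# memoised full-scale pipeline runs shared across acceptance checks
.study_cache <- new.env(parent = emptyenv())
run_default_study <- function(seed, fit_models = TRUE, null_effects = FALSE) {
  key <- paste0("s", seed, if (fit_models) "_m", if (null_effects) "_null")
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  cfg <- if (null_effects) {
    gaze_config(effect_directions = null_directions(), rng_seed = seed)
  } else {
    gaze_config(rng_seed = seed)
  }
  res <- run_pipeline(cfg, fit_models = fit_models)
  res$study$streams <- NULL  # keep the cache light
  .study_cache[[key]] <- res
  res
}
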