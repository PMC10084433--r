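#' @title Per-session feature aggregation
#' @name session-features
#' @description Turns detected oculomotor events into one feature vector
#'   per reading session: counts, distribution moments, reading time,
#'   pupil features and Coefficient K, after pool-wide lenient IQR
#'   outlier removal and AOI filtering, with participant (`_a`) and
#'   participant-block (`_b`) median-baseline normalization.
NULL

#' Distribution moments of a feature series
#'
#' Count, mean, sample variance (n - 1 denominator), skewness `g1`
#' (third standardized moment) and excess kurtosis `g2` (fourth
#' standardized moment minus 3). Slots whose minimum sample size is not
#' met (variance 2, skewness 3, kurtosis 4) or whose spread is zero are
#' `NA`.
#'
#' @param x numeric vector; `NA`s are dropped.
#' @return named numeric vector `c(count, mean, var, skew, kurt)`.
#' @export
#' @examples
#' moments(c(-1, 0, 1)) # symmetric: skew 0
moments <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  out <- c(count = n, mean = NA_real_, var = NA_real_,
           skew = NA_real_, kurt = NA_real_)
  if (n >= 1) out["mean"] <- mean(x)
  if (n >= 2) out["var"] <- stats::var(x)
  m2 <- mean((x - mean(x))^2)
  if (n >= 3 && m2 > 0) out["skew"] <- mean((x - mean(x))^3) / m2^1.5
  if (n >= 4 && m2 > 0) out["kurt"] <- mean((x - mean(x))^4) / m2^2 - 3
  out
}

#' Lenient interquartile-range outlier bounds and filter
#'
#' `iqr_bounds()` returns the retention interval
#' `[Q2 - multiplier * IQR, Q3 + multiplier * IQR]` with
#' `IQR = Q3 - Q1`; note the asymmetric anchors (median below, third
#' quartile above). Quantiles use linear interpolation
#' (`stats::quantile` type 7). `iqr_keep()` returns a logical retention
#' mask (`NA` values are retained: they cannot be judged outliers) and
#' `iqr_filter()` the retained values. With fewer than 4 finite values
#' everything is retained.
#'
#' @param x numeric vector (the pooled feature series).
#' @param multiplier how many IQRs beyond the anchors to tolerate
#'   (default 4, a deliberately lenient limit accommodating skewed
#'   oculomotor distributions).
#' @param warn_fraction emit a warning when more than this fraction of
#'   finite values is removed (default 0.2).
#' @return `iqr_bounds()`: numeric `c(lower, upper)`; `iqr_keep()`:
#'   logical vector along `x`; `iqr_filter()`: the retained values.
#' @export
#' @examples
#' iqr_filter(c(1, 2, 3, 4, 100)) # 100 removed
iqr_bounds <- function(x, multiplier = 4) {
  x <- x[is.finite(x)]
  if (length(x) < 4) return(c(-Inf, Inf))
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  c(q[2] - multiplier * iqr, q[3] + multiplier * iqr)
}

#' @rdname iqr_bounds
#' @export
iqr_keep <- function(x, multiplier = 4, warn_fraction = 0.2) {
  b <- iqr_bounds(x, multiplier)
  keep <- is.na(x) | (x >= b[1] & x <= b[2])
  removed <- sum(!keep)
  n_finite <- sum(is.finite(x))
  if (n_finite > 0 && removed / n_finite > warn_fraction) {
    warning(sprintf("IQR filter removed %.1f%% of values (> %.0f%% alarm threshold)",
                    100 * removed / n_finite, 100 * warn_fraction))
  }
  keep
}

#' @rdname iqr_bounds
#' @export
iqr_filter <- function(x, multiplier = 4, warn_fraction = 0.2) {
  x[iqr_keep(x, multiplier, warn_fraction)]
}

#' Coefficient K: focal vs ambient attention
#'
#' For each fixation i followed by a (non-blink) saccade of amplitude
#' `a[i+1]`, `K[i] = (d[i] - mu_d) / sigma_d - (a[i+1] - mu_a) / sigma_a`,
#' where the means and standard deviations are the participant's over
#' their pool of such pairs. Positive values indicate focal processing
#' (long fixations, short saccades), negative ambient scanning.
#'
#' `k_context()` estimates the participant baselines from the pooled
#' pairs; its standard deviations must be positive, otherwise K is
#' undefined for that participant.
#'
#' @param durations_ms fixation durations of the pairs.
#' @param amplitudes_deg amplitudes of the following saccades (degrees).
#' @param ctx a context from [k_context()].
#' @return `coefficient_k()`: numeric vector of K values;
#'   `k_context()`: list `mu_d, sigma_d, mu_a, sigma_a`.
#' @export
#' @examples
#' ctx <- list(mu_d = 200, sigma_d = 50, mu_a = 2, sigma_a = 1)
#' coefficient_k(300, 1, ctx) # 2 - (-1) = 3
coefficient_k <- function(durations_ms, amplitudes_deg, ctx) {
  if (length(durations_ms) != length(amplitudes_deg)) {
    stop("durations and amplitudes must pair one-to-one")
  }
  if (!is.finite(ctx$sigma_d) || !is.finite(ctx$sigma_a) ||
      ctx$sigma_d <= 0 || ctx$sigma_a <= 0) {
    stop("K undefined: context standard deviations must be positive")
  }
  (durations_ms - ctx$mu_d) / ctx$sigma_d -
    (amplitudes_deg - ctx$mu_a) / ctx$sigma_a
}

#' @rdname coefficient_k
#' @export
k_context <- function(durations_ms, amplitudes_deg) {
  list(mu_d = mean(durations_ms), sigma_d = stats::sd(durations_ms),
       mu_a = mean(amplitudes_deg), sigma_a = stats::sd(amplitudes_deg))
}

#' Reading time of a session
#'
#' The span between the onset of the first and the offset of the last
#' fixation, in seconds.
#'
#' @param fixations fixation table of one session.
#' @return seconds, or `NA` with no fixations.
#' @export
reading_time <- function(fixations) {
  if (nrow(fixations) == 0) return(NA_real_)
  (max(fixations$offset_ms) - min(fixations$onset_ms)) / 1000
}

#' Median-baseline normalization across sessions
#'
#' Subtracts from each session's feature value the median of that value
#' over a baseline scope: all of the participant's sessions (the `_a`
#' variant) or the participant's sessions within the same experimental
#' block (`_b`). Centering on a personal baseline removes stable
#' inter-individual level differences.
#'
#' @param x numeric feature values, one per session.
#' @param participant participant id per session.
#' @param block optional block id per session; when given the baseline
#'   scope is participant x block.
#' @return numeric vector of baseline-subtracted values.
#' @export
normalize_baseline <- function(x, participant, block = NULL) {
  g <- if (is.null(block)) as.character(participant) else {
    paste(participant, block, sep = "\r")
  }
  x - stats::ave(x, g, FUN = function(v) stats::median(v, na.rm = TRUE))
}

stat_suffixes <- c("mean", "var", "skew", "kurt")

# named moment block feature_<stat>
stat_block <- function(x, prefix) {
  m <- moments(x)[stat_suffixes]
  names(m) <- paste(prefix, stat_suffixes, sep = "_")
  m
}

#' Assemble the study table from per-session events
#'
#' Applies the processing chain in pipeline order: pool-wide lenient IQR
#' outlier removal per event feature, AOI filtering, Coefficient K with
#' per-participant baselines, per-session aggregation into counts and
#' moments, and participant / participant-block median normalization.
#' Blink saccades are excluded throughout.
#'
#' @param sessions a list, one element per reading session, each a list
#'   with `participant`, `article`, `block`, `fixations` (from
#'   [detect_fixations()]) and `saccades` (from [derive_saccades()]).
#' @param aois named list of AOI definitions per article (names are
#'   article ids as character), each `list(title =, content =)`.
#' @param ratings optional data frame with columns `participant`,
#'   `article` and appraisal score columns to join onto the table.
#' @param iqr_multiplier IQR leniency multiplier (default 4).
#' @return A list: `table` (one row per session: ids, ~113 feature
#'   columns, any joined appraisals), `manifest` (data frame describing
#'   every feature column: family, statistic, normalization, units) and
#'   `counts` (events surviving each stage, for the run ledger).
#' @export
build_feature_table <- function(sessions, aois, ratings = NULL,
                                iqr_multiplier = 4) {
  if (!length(sessions)) stop("no sessions supplied")
  ns <- length(sessions)
  part <- vapply(sessions, function(s) as.character(s$participant), character(1))
  art <- vapply(sessions, function(s) as.character(s$article), character(1))
  blk <- vapply(sessions, function(s) as.character(s$block), character(1))

  fix_list <- lapply(sessions, `[[`, "fixations")
  sac_list <- lapply(sessions, function(s) {
    s$saccades[!s$saccades$is_blink, , drop = FALSE]
  })
  n_fix_raw <- sum(vapply(fix_list, nrow, integer(1)))
  n_sac_raw <- sum(vapply(sac_list, nrow, integer(1)))

  # ---- stage 1: pool-wide IQR bounds per event feature ----
  all_fix_dur <- unlist(lapply(fix_list, `[[`, "duration_ms"))
  fix_b <- iqr_bounds(all_fix_dur, iqr_multiplier)
  sac_pool <- do.call(rbind, lapply(sac_list, function(s) {
    s[, c("amplitude_deg", "duration_ms", "peak_speed_deg_s"), drop = FALSE]
  }))
  sac_b <- lapply(sac_pool, iqr_bounds, multiplier = iqr_multiplier)
  reg_flag_pool <- unlist(lapply(sac_list, `[[`, "is_regression"))
  reg_b <- lapply(sac_pool[reg_flag_pool, , drop = FALSE], iqr_bounds,
                  multiplier = iqr_multiplier)
  all_pupil <- unlist(lapply(fix_list, `[[`, "mean_pupil_px"))
  pup_b <- iqr_bounds(all_pupil, iqr_multiplier)

  within <- function(x, b) is.na(x) | (x >= b[1] & x <= b[2])

  per_session <- vector("list", ns)
  n_fix_iqr <- n_sac_iqr <- n_reg_iqr <- 0L
  n_fix_aoi <- n_sac_aoi <- n_reg_aoi <- 0L
  for (s in seq_len(ns)) {
    fx <- fix_list[[s]]
    sc <- sac_list[[s]]
    keep_f_iqr <- within(fx$duration_ms, fix_b)
    keep_s_iqr <- within(sc$amplitude_deg, sac_b$amplitude_deg) &
      within(sc$duration_ms, sac_b$duration_ms) &
      within(sc$peak_speed_deg_s, sac_b$peak_speed_deg_s)
    keep_r_iqr <- sc$is_regression &
      within(sc$amplitude_deg, reg_b$amplitude_deg) &
      within(sc$duration_ms, reg_b$duration_ms) &
      within(sc$peak_speed_deg_s, reg_b$peak_speed_deg_s)
    n_fix_iqr <- n_fix_iqr + sum(keep_f_iqr)
    n_sac_iqr <- n_sac_iqr + sum(keep_s_iqr)
    n_reg_iqr <- n_reg_iqr + sum(keep_r_iqr)

    # ---- stage 2: AOI membership on fixation centroids ----
    aoi <- aois[[art[s]]]
    if (is.null(aoi)) stop("missing AOI definition for article ", art[s])
    in_aoi <- in_rect(fx$centroid_x_px, fx$centroid_y_px, aoi$title) |
      in_rect(fx$centroid_x_px, fx$centroid_y_px, aoi$content)
    keep_f <- keep_f_iqr & in_aoi
    anchors <- keep_f[sc$from_fix] & keep_f[sc$to_fix]
    keep_s <- keep_s_iqr & anchors
    # regressions are their own event class: filtered against the
    # regression pools only, not the (tighter) overall saccade pools
    keep_r <- keep_r_iqr & anchors
    n_fix_aoi <- n_fix_aoi + sum(keep_f)
    n_sac_aoi <- n_sac_aoi + sum(keep_s)
    n_reg_aoi <- n_reg_aoi + sum(keep_r)

    fx_k <- fx[keep_f, , drop = FALSE]
    sc_k <- sc[keep_s, , drop = FALSE]
    # fixation-saccade adjacency for K: retained saccade leaving a retained fixation
    pair_dur <- fx$duration_ms[sc_k$from_fix]
    pair_amp <- sc_k$amplitude_deg
    keep_pup <- within(fx_k$mean_pupil_px, pup_b)
    per_session[[s]] <- list(
      fixations = fx_k, saccades = sc_k,
      regressions = sc[keep_r, , drop = FALSE],
      pupil = fx_k$mean_pupil_px[keep_pup],
      pair_dur = pair_dur, pair_amp = pair_amp
    )
  }

  # ---- stage 3: Coefficient K with participant baselines over the pair pool ----
  k_values <- vector("list", ns)
  for (p in unique(part)) {
    idx <- which(part == p)
    dpool <- unlist(lapply(per_session[idx], `[[`, "pair_dur"))
    apool <- unlist(lapply(per_session[idx], `[[`, "pair_amp"))
    ctx <- if (length(dpool) >= 2) k_context(dpool, apool) else NULL
    ok <- !is.null(ctx) && is.finite(ctx$sigma_d) && is.finite(ctx$sigma_a) &&
      ctx$sigma_d > 0 && ctx$sigma_a > 0
    if (!ok && length(dpool)) {
      warning("participant ", p, " excluded from K features (zero-variance pool)")
    }
    for (s in idx) {
      k_values[[s]] <- if (ok) {
        coefficient_k(per_session[[s]]$pair_dur, per_session[[s]]$pair_amp, ctx)
      } else numeric(0)
    }
  }
  n_k_raw <- sum(lengths(k_values))
  k_b <- iqr_bounds(unlist(k_values), iqr_multiplier)
  k_values <- lapply(k_values, function(k) k[within(k, k_b)])
  n_k_iqr <- sum(lengths(k_values))

  # ---- stage 4: per-session aggregation ----
  rows <- lapply(seq_len(ns), function(s) {
    ps <- per_session[[s]]
    c(reading_time = reading_time(ps$fixations),
      fix_count = nrow(ps$fixations),
      stat_block(ps$fixations$duration_ms, "fix_dur"),
      moments(ps$pupil)[c("mean", "var", "skew", "kurt")] |>
        stats::setNames(paste0("pupil_", c("mean", "var", "skew", "kurt"))),
      sac_count = nrow(ps$saccades),
      stat_block(ps$saccades$amplitude_deg, "sac_amp"),
      stat_block(ps$saccades$duration_ms, "sac_dur"),
      stat_block(ps$saccades$peak_speed_deg_s, "sac_speed"),
      reg_count = nrow(ps$regressions),
      stat_block(ps$regressions$amplitude_deg, "reg_amp"),
      stat_block(ps$regressions$duration_ms, "reg_dur"),
      stat_block(ps$regressions$peak_speed_deg_s, "reg_speed"),
      stat_block(k_values[[s]], "k") |>
        stats::setNames(paste0("k_", stat_suffixes)))
  })
  feat <- as.data.frame(do.call(rbind, rows))

  # ---- stage 5: baseline normalization ----
  base_families <- c("reading_time",
                     paste("fix_dur", stat_suffixes, sep = "_"),
                     paste("pupil", stat_suffixes, sep = "_"),
                     paste("sac_amp", stat_suffixes, sep = "_"),
                     paste("sac_dur", stat_suffixes, sep = "_"),
                     paste("sac_speed", stat_suffixes, sep = "_"),
                     paste("reg_amp", stat_suffixes, sep = "_"),
                     paste("reg_dur", stat_suffixes, sep = "_"),
                     paste("reg_speed", stat_suffixes, sep = "_"),
                     paste("k", stat_suffixes, sep = "_"))
  for (f in base_families) {
    feat[[paste0(f, "_a")]] <- normalize_baseline(feat[[f]], part)
    feat[[paste0(f, "_b")]] <- normalize_baseline(feat[[f]], part, blk)
  }
  # the raw pupil level reflects personal baselines, not processing:
  # only its normalized variants are kept
  feat$pupil_mean <- NULL

  table <- cbind(data.frame(participant = part, article = art, block = blk,
                            stringsAsFactors = FALSE), feat)
  if (!is.null(ratings)) {
    key_t <- paste(part, art, sep = "\r")
    key_r <- paste(as.character(ratings$participant),
                   as.character(ratings$article), sep = "\r")
    score_cols <- setdiff(names(ratings),
                          c("participant", "article", "block", "order"))
    for (col in score_cols) table[[col]] <- ratings[[col]][match(key_t, key_r)]
  }
  rownames(table) <- NULL

  list(table = table,
       manifest = feature_manifest(names(feat)),
       counts = data.frame(
         stage = c("detected", "iqr", "aoi"),
         fixations = c(n_fix_raw, n_fix_iqr, n_fix_aoi),
         saccades = c(n_sac_raw, n_sac_iqr, n_sac_aoi),
         regressions = c(sum(reg_flag_pool), n_reg_iqr, n_reg_aoi),
         k_samples = c(NA, n_k_raw, n_k_iqr)))
}

# describe each feature column: family, statistic, normalization, units
feature_manifest <- function(cols) {
  norm <- ifelse(grepl("_a$", cols), "participant",
                 ifelse(grepl("_b$", cols), "participant_block", "raw"))
  stem <- sub("_[ab]$", "", cols)
  stat <- ifelse(grepl("_count$", stem), "count",
                 ifelse(stem == "reading_time", "sum",
                        sub(".*_", "", stem)))
  family <- ifelse(stem == "reading_time", "reading_time",
                   sub("_(mean|var|skew|kurt|count)$", "", stem))
  units <- rep("unitless", length(cols))
  units[family == "reading_time"] <- "s"
  units[family %in% c("fix_dur", "sac_dur", "reg_dur")] <- "ms"
  units[family %in% c("sac_amp", "reg_amp")] <- "deg"
  units[family %in% c("sac_speed", "reg_speed")] <- "deg/s"
  units[family == "pupil"] <- "px"
  units[stat == "count"] <- "count"
  data.frame(name = cols, family = family, statistic = stat,
             normalization = norm, units = units, stringsAsFactors = FALSE)
}
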