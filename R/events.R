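#' @title Oculomotor event detection from raw gaze streams
#' @name gaze-events
#' @description Dispersion-based (I-DT) fixation detection, saccade
#'   derivation with blink exclusion, regression classification and
#'   saccade kinematics. Gaze streams are data frames with columns
#'   `time_ms, left_x_px, left_y_px, right_x_px, right_y_px,
#'   left_pupil_px, right_pupil_px`; blink samples carry a (0, 0)
#'   position for both eyes (the tracker's convention).
NULL

gaze_cols <- c("time_ms", "left_x_px", "left_y_px", "right_x_px", "right_y_px",
               "left_pupil_px", "right_pupil_px")

# binocular mean position + blink flag; (0,0) marks lid closure
stream_position <- function(stream) {
  x <- (stream$left_x_px + stream$right_x_px) / 2
  y <- (stream$left_y_px + stream$right_y_px) / 2
  blink <- (stream$left_x_px == 0 & stream$left_y_px == 0) |
    (stream$right_x_px == 0 & stream$right_y_px == 0)
  list(x = x, y = y, blink = blink,
       pupil = (stream$left_pupil_px + stream$right_pupil_px) / 2)
}

#' Detect fixations with the dispersion-threshold (I-DT) algorithm
#'
#' A fixation is a maximal run of consecutive samples whose bounding-box
#' dispersion, `(max(x) - min(x)) + (max(y) - min(y))` computed on the
#' binocular mean position, stays within the dispersion threshold, and
#' whose temporal span is at least `min_duration_ms`. Runs are grown
#' greedily left to right; a sample that cannot seed a fixation is skipped
#' and the search restarts at the next one. Blink samples (position
#' (0, 0)) never join a fixation and break any run, as do gaps longer
#' than `max_gap_intervals` nominal sample intervals.
#'
#' @param stream a gaze-sample data frame (see [gaze-events]).
#' @param geometry a [screen_geometry()]; used to convert the threshold.
#' @param min_duration_ms minimum fixation span in ms (default 80).
#' @param dispersion_deg dispersion threshold in visual degrees
#'   (default 1.0; converted to pixels via `geometry`).
#' @param max_gap_intervals maximum tolerated sample gap, in multiples of
#'   the nominal (median) sampling interval.
#' @return A data frame with one row per fixation: `onset_ms, offset_ms,
#'   duration_ms, centroid_x_px, centroid_y_px, mean_pupil_px, n_samples`.
#'   Pupil is averaged across both eyes over the fixation's samples.
#' @export
detect_fixations <- function(stream, geometry = screen_geometry(),
                             min_duration_ms = 80, dispersion_deg = 1.0,
                             max_gap_intervals = 2) {
  stopifnot(is.data.frame(stream))
  missing_cols <- setdiff(gaze_cols, names(stream))
  if (length(missing_cols)) {
    stop("gaze stream lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  empty <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      duration_ms = numeric(0), centroid_x_px = numeric(0),
                      centroid_y_px = numeric(0), mean_pupil_px = numeric(0),
                      n_samples = integer(0))
  n <- nrow(stream)
  if (n == 0L) return(empty)
  t <- stream$time_ms
  if (is.unsorted(t, strictly = TRUE)) {
    stop("gaze stream timestamps must be strictly increasing")
  }
  pos <- stream_position(stream)
  thr_px <- deg_to_px(dispersion_deg, geometry)

  # segment boundaries: blinks and oversized gaps
  nominal <- if (n > 1) stats::median(diff(t)) else Inf
  gap_after <- c(diff(t) > max_gap_intervals * nominal, TRUE)
  seg_id <- cumsum(c(TRUE, pos$blink[-n] | gap_after[-n] | pos$blink[-1]))
  seg_id[pos$blink] <- NA_integer_

  fixes <- vector("list", 64L); nf <- 0L
  for (seg in split(seq_len(n), seg_id)) {
    m <- length(seg)
    i <- 1L
    while (i <= m) {
      j <- idt_extend(pos$x[seg], pos$y[seg], i, thr_px)
      if (t[seg[j]] - t[seg[i]] >= min_duration_ms) {
        idx <- seg[i:j]
        nf <- nf + 1L
        if (nf > length(fixes)) fixes <- c(fixes, vector("list", length(fixes)))
        fixes[[nf]] <- c(t[seg[i]], t[seg[j]],
                         mean(pos$x[idx]), mean(pos$y[idx]),
                         mean(pos$pupil[idx]), length(idx))
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  if (nf == 0L) return(empty)
  m <- do.call(rbind, fixes[seq_len(nf)])
  out <- data.frame(onset_ms = m[, 1], offset_ms = m[, 2],
                    duration_ms = m[, 2] - m[, 1],
                    centroid_x_px = m[, 3], centroid_y_px = m[, 4],
                    mean_pupil_px = m[, 5], n_samples = as.integer(m[, 6]))
  out[order(out$onset_ms), , drop = FALSE]
}

# grow the window [i, j] while dispersion <= thr; returns the maximal j.
# cummax/cummin evaluated in blocks so long fixations stay vectorised.
idt_extend <- function(x, y, i, thr, block = 64L) {
  n <- length(x)
  j <- i
  xmax <- x[i]; xmin <- x[i]; ymax <- y[i]; ymin <- y[i]
  while (j < n) {
    hi <- min(n, j + block)
    idx <- (j + 1L):hi
    cxmax <- cummax(c(xmax, x[idx]))[-1L]
    cxmin <- cummin(c(xmin, x[idx]))[-1L]
    cymax <- cummax(c(ymax, y[idx]))[-1L]
    cymin <- cummin(c(ymin, y[idx]))[-1L]
    disp <- (cxmax - cxmin) + (cymax - cymin)
    bad <- which(disp > thr)
    if (length(bad)) return(j + bad[1L] - 1L)
    j <- hi
    xmax <- cxmax[length(cxmax)]; xmin <- cxmin[length(cxmin)]
    ymax <- cymax[length(cymax)]; ymin <- cymin[length(cymin)]
  }
  j
}

#' Derive saccades between consecutive fixations
#'
#' Each adjacent fixation pair contributes one saccade spanning
#' `[offset of the first, onset of the second]`. Displacements are taken
#' between the bounding fixation centroids (y positive downward). A
#' saccade whose interval contains a blink sample (position (0, 0)) is
#' flagged `is_blink`; blink saccades are excluded from feature
#' aggregation downstream. Regressions are flagged per
#' [classify_regression()].
#'
#' @param fixations output of [detect_fixations()].
#' @param stream the gaze stream the fixations came from.
#' @param geometry a [screen_geometry()].
#' @param regression_px backward-displacement threshold in px (default 20).
#' @return A data frame with one row per saccade: `onset_ms, offset_ms,
#'   duration_ms, dx_px, dy_px, amplitude_px, amplitude_deg,
#'   peak_speed_deg_s, is_blink, is_regression, from_fix, to_fix`.
#'   Fewer than two fixations yield zero rows.
#' @export
derive_saccades <- function(fixations, stream, geometry = screen_geometry(),
                            regression_px = 20) {
  empty <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      duration_ms = numeric(0), dx_px = numeric(0),
                      dy_px = numeric(0), amplitude_px = numeric(0),
                      amplitude_deg = numeric(0), peak_speed_deg_s = numeric(0),
                      is_blink = logical(0), is_regression = logical(0),
                      from_fix = integer(0), to_fix = integer(0))
  nf <- nrow(fixations)
  if (nf < 2L) return(empty)
  pos <- stream_position(stream)
  t <- stream$time_ms
  i <- seq_len(nf - 1L)
  onset <- fixations$offset_ms[i]
  offset <- fixations$onset_ms[i + 1L]
  dx <- fixations$centroid_x_px[i + 1L] - fixations$centroid_x_px[i]
  dy <- fixations$centroid_y_px[i + 1L] - fixations$centroid_y_px[i]
  amp_px <- sqrt(dx^2 + dy^2)
  amp_deg <- px_to_deg(amp_px, geometry)
  # index range of samples inside each interval; cumulated blink counts
  i1 <- findInterval(onset, t, left.open = TRUE) + 1L
  i2 <- findInterval(offset, t)
  blink_cum <- c(0L, cumsum(pos$blink))
  is_blink <- (blink_cum[i2 + 1L] - blink_cum[i1]) > 0
  step_deg <- px_to_deg(sqrt(diff(pos$x)^2 + diff(pos$y)^2), geometry)
  speed <- c(step_deg / (diff(t) / 1000), NA_real_)
  peak <- vapply(i, function(k) {
    if (i2[k] - i1[k] < 1L) {
      if (offset[k] <= onset[k]) return(NA_real_)
      return(amp_deg[k] / ((offset[k] - onset[k]) / 1000))
    }
    max(speed[i1[k]:(i2[k] - 1L)])
  }, numeric(1))
  out <- data.frame(onset_ms = onset, offset_ms = offset,
                    duration_ms = offset - onset,
                    dx_px = dx, dy_px = dy,
                    amplitude_px = amp_px, amplitude_deg = amp_deg,
                    peak_speed_deg_s = peak,
                    is_blink = is_blink,
                    is_regression = FALSE,
                    from_fix = i, to_fix = i + 1L)
  out$is_regression <- !out$is_blink &
    classify_regression(out$dx_px, out$dy_px, threshold_px = regression_px)
  out
}

#' Classify a saccade as a regression
#'
#' A regression is a backward saccade: its displacement moves at least
#' `threshold_px` upward on screen (`dy <= -threshold_px`; the screen
#' origin is top-left so "northwards" is negative dy) or at least
#' `threshold_px` against the left-to-right reading direction
#' (`dx <= -threshold_px`). The 20 px floor is about the width of a short
#' word and excludes both progressive saccades and corrective
#' microsaccades.
#'
#' @param dx_px,dy_px saccade displacement components in pixels
#'   (vectorised).
#' @param threshold_px minimal backward distance in pixels (default 20).
#' @return logical vector.
#' @export
classify_regression <- function(dx_px, dy_px, threshold_px = 20) {
  (dx_px <= -threshold_px) | (dy_px <= -threshold_px)
}

#' Peak angular speed within a saccade interval
#'
#' The maximum over consecutive sample pairs (samples with timestamps in
#' `[onset_ms, offset_ms]`) of angular displacement divided by the pair's
#' time difference. With fewer than two samples in the interval the speed
#' falls back to `fallback_deg` (the centroid-to-centroid amplitude)
#' divided by the interval duration.
#'
#' @param stream gaze-sample data frame.
#' @param onset_ms,offset_ms saccade interval bounds.
#' @param geometry a [screen_geometry()].
#' @param fallback_deg amplitude in degrees used by the single-sample
#'   fallback.
#' @return peak speed in degrees per second (non-negative scalar).
#' @export
peak_speed <- function(stream, onset_ms, offset_ms,
                       geometry = screen_geometry(), fallback_deg = NA_real_) {
  sel <- stream$time_ms >= onset_ms & stream$time_ms <= offset_ms
  if (sum(sel) < 2L) {
    if (is.na(fallback_deg) || offset_ms <= onset_ms) return(NA_real_)
    return(fallback_deg / ((offset_ms - onset_ms) / 1000))
  }
  pos <- stream_position(stream[sel, , drop = FALSE])
  t <- stream$time_ms[sel]
  step_px <- sqrt(diff(pos$x)^2 + diff(pos$y)^2)
  max(px_to_deg(step_px, geometry) / (diff(t) / 1000))
}

#' Restrict events to areas of interest
#'
#' Keeps fixations whose centroid lies in the title or content rectangle
#' and labels them with their AOI; keeps saccades only when both bounding
#' fixations are kept. Rectangles are half-open: a point on the max edge
#' is outside.
#'
#' @param fixations,saccades event tables from [detect_fixations()] /
#'   [derive_saccades()].
#' @param aoi a list with elements `title` and `content`, each a numeric
#'   `c(x0, y0, x1, y1)` rectangle in pixels, origin top-left.
#' @return A list with the filtered `fixations` (gaining an `aoi_label`
#'   column) and `saccades` (with `from_fix`/`to_fix` re-indexed into the
#'   filtered fixation table).
#' @export
filter_aoi <- function(fixations, saccades, aoi) {
  if (is.null(aoi$title) || is.null(aoi$content)) {
    stop("aoi must define both 'title' and 'content' rectangles")
  }
  lab <- rep(NA_character_, nrow(fixations))
  lab[in_rect(fixations$centroid_x_px, fixations$centroid_y_px, aoi$content)] <- "content"
  lab[in_rect(fixations$centroid_x_px, fixations$centroid_y_px, aoi$title)] <- "title"
  keep <- !is.na(lab)
  fix_kept <- fixations[keep, , drop = FALSE]
  fix_kept$aoi_label <- lab[keep]
  new_idx <- cumsum(keep)
  sac_keep <- keep[saccades$from_fix] & keep[saccades$to_fix]
  sac_kept <- saccades[sac_keep, , drop = FALSE]
  sac_kept$from_fix <- new_idx[saccades$from_fix[sac_keep]]
  sac_kept$to_fix <- new_idx[saccades$to_fix[sac_keep]]
  rownames(fix_kept) <- rownames(sac_kept) <- NULL
  list(fixations = fix_kept, saccades = sac_kept)
}

# half-open rectangle membership: [x0, x1) x [y0, y1)
in_rect <- function(x, y, rect) {
  x >= rect[1] & x < rect[3] & y >= rect[2] & y < rect[4]
}
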