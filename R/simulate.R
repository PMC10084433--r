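#' Configuration for the synthetic reading-gaze generator
#'
#' Describes the emulated study: a within-subjects design in which every
#' participant reads every article, articles are grouped into
#' counterbalanced blocks, one participant's gaze recording is lost, and
#' a handful of sessions lose their pupil channel. Latent
#' comprehensibility and interest appraisals are standardized bivariate
#' normal per session and drive eye behavior through session-level
#' multipliers whose signs are set by `effect_directions`.
#'
#' @param n_participants,n_articles,n_blocks study dimensions
#'   (defaults 30, 18, 3; articles divide evenly over blocks).
#' @param sample_rate tracker sampling rate in Hz (default 60).
#' @param latent_correlation correlation between the two latent
#'   appraisals (default 0.466, i.e. about 21.7% shared variance).
#' @param effect_directions named numeric signs (-1, 0 or +1) for the
#'   feature families `reading_time`, `fixation_duration`,
#'   `saccade_amplitude`, `pupil_variance`, `regression`; defaults all
#'   -1 (higher appraisals mean faster, more fluent reading).
#' @param effect_weights named list of `c(comp, int)` effect magnitudes
#'   per family; comprehensibility effects are stronger by default.
#' @param item_intercorrelation pairwise inter-item correlation of the
#'   two questionnaire scales (defaults 0.7356 and 0.7953).
#' @param blink_rate blink events per minute (default 6; readers blink
#'   sparsely).
#' @param dropout_rate fraction of participants whose gaze recording is
#'   lost entirely, questionnaires surviving (default 1/30).
#' @param pupil_loss_sessions number of sessions whose pupil channel
#'   fails (recorded as NA), yielding missing pupil features (default 5).
#' @param base_fixation_ms,skip_prob,refixation_prob,regression_prob
#'   scanpath mechanics: baseline fixation duration, per-word skip,
#'   refixation and backward-regression probabilities.
#' @param rng_seed integer seed making the whole study reproducible.
#' @return A validated list of class `gaze_config`.
#' @export
gaze_config <- function(n_participants = 30, n_articles = 18, n_blocks = 3,
                        sample_rate = 60, latent_correlation = 0.466,
                        effect_directions = NULL, effect_weights = NULL,
                        item_intercorrelation = c(comprehensibility = 0.7356,
                                                  interest = 0.7953),
                        blink_rate = 6, dropout_rate = 1 / 30,
                        pupil_loss_sessions = 5,
                        base_fixation_ms = 340, skip_prob = 0.25,
                        refixation_prob = 0.12, regression_prob = 0.08,
                        rng_seed = 1) {
  dirs <- list(reading_time = -1, fixation_duration = -1,
               saccade_amplitude = -1, pupil_variance = -1, regression = -1)
  if (!is.null(effect_directions)) {
    bad <- setdiff(names(effect_directions), names(dirs))
    if (length(bad)) stop("invalid config: unknown effect_directions field ",
                          paste(bad, collapse = ", "))
    dirs[names(effect_directions)] <- effect_directions
  }
  weights <- list(reading_time = c(0.08, 0.05),
                  fixation_duration = c(0.03, 0.015),
                  saccade_amplitude = c(0.30, 0.15),
                  pupil_variance = c(0.05, 0.025),
                  regression = c(0.15, 0.08))
  if (!is.null(effect_weights)) weights[names(effect_weights)] <- effect_weights

  cfg <- list(n_participants = n_participants, n_articles = n_articles,
              n_blocks = n_blocks, sample_rate = sample_rate,
              latent_correlation = latent_correlation,
              effect_directions = dirs, effect_weights = weights,
              item_intercorrelation = item_intercorrelation,
              blink_rate = blink_rate, dropout_rate = dropout_rate,
              pupil_loss_sessions = pupil_loss_sessions,
              base_fixation_ms = base_fixation_ms, skip_prob = skip_prob,
              refixation_prob = refixation_prob,
              regression_prob = regression_prob,
              rng_seed = rng_seed)
  for (f in c("n_participants", "n_articles", "n_blocks")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]])) {
      stop("invalid config: '", f, "' must be a positive integer")
    }
  }
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    stop("invalid config: 'sample_rate' must be positive")
  }
  if (abs(latent_correlation) > 1) {
    stop("invalid config: 'latent_correlation' must lie in [-1, 1]")
  }
  if (any(item_intercorrelation <= 0 | item_intercorrelation >= 1)) {
    stop("invalid config: 'item_intercorrelation' must lie in (0, 1)")
  }
  if (dropout_rate < 0 || dropout_rate > 1) {
    stop("invalid config: 'dropout_rate' must lie in [0, 1]")
  }
  if (blink_rate < 0) stop("invalid config: 'blink_rate' must be non-negative")
  structure(cfg, class = "gaze_config")
}

#' Generate article layouts
#'
#' Each article renders as a one-line title above a block of left-aligned
#' text lines on a 1280 x 1024 canvas (origin top-left, y downward).
#' Word counts vary mildly across articles, mimicking articles truncated
#' to a fixed character budget.
#'
#' @param n_articles number of articles.
#' @param words_per_line words per full text line (default 12).
#' @return A list of layouts, each with `title_rect`, `content_rect`,
#'   `lines` (data frame of line rectangles), `words` (data frame of
#'   word center positions and line indices) and `n_words`.
#' @export
article_layouts <- function(n_articles, words_per_line = 12) {
  lapply(seq_len(n_articles), function(a) {
    n_words <- round(min(240, max(190, stats::rnorm(1, 215, 12))))
    n_title <- 7
    x0 <- 140; x1 <- 1140
    title_rect <- c(x0, 80, x1, 130)
    n_lines <- ceiling((n_words - n_title) / words_per_line)
    line_y0 <- 170 + 40 * (seq_len(n_lines) - 1)
    content_rect <- c(x0, 170, x1, 170 + 40 * n_lines)
    pitch <- (x1 - x0) / words_per_line
    body <- n_words - n_title
    line_of <- rep(seq_len(n_lines), each = words_per_line)[seq_len(body)]
    pos_in_line <- rep(seq_len(words_per_line), n_lines)[seq_len(body)]
    words <- data.frame(
      line = c(rep(0L, n_title), line_of),
      x = c(x0 + (x1 - x0) * (seq_len(n_title) - 0.5) / n_title,
            x0 + pitch * (pos_in_line - 0.5)) + stats::rnorm(n_words, 0, 6),
      y = c(rep(105, n_title), 170 + 40 * (line_of - 1) + 14) +
        stats::rnorm(n_words, 0, 2))
    list(title_rect = title_rect, content_rect = content_rect,
         lines = data.frame(x0 = x0, y0 = line_y0, x1 = x1,
                            y1 = line_y0 + 28),
         words = words, n_words = n_words)
  })
}

# session-level multipliers: how the latent appraisals bend eye behavior
session_effects <- function(comp, int, cfg) {
  w <- cfg$effect_weights; d <- cfg$effect_directions
  shift <- function(fam, noise_sd) {
    d[[fam]] * (w[[fam]][1] * comp + w[[fam]][2] * int) +
      stats::rnorm(1, 0, noise_sd)
  }
  list(rt_mult = exp(shift("reading_time", 0.30)),
       fd_mult = exp(shift("fixation_duration", 0.06)),
       skip_shift = shift("saccade_amplitude", 0.20),
       pupil_mult = exp(shift("pupil_variance", 0.25)),
       reg_shift = shift("regression", 0.25))
}

#' Generate one synthetic reading session
#'
#' Simulates a word-by-word reading scanpath over the article layout
#' (progressive within-line saccades, line-return sweeps, per-word
#' skips, refixations and Bernoulli backward regressions, lognormal
#' fixation durations), renders it to gaze samples at the tracker rate
#' with positional jitter and a binocular disparity, overlays a pupil
#' signal (personal baseline + slow drift + noise) and inserts blinks as
#' runs of samples at position (0, 0).
#'
#' Higher latent appraisals shorten fixations (hence reading time),
#' lengthen saccades via word skipping, and damp pupil variability and
#' regression probability, with signs taken from the configuration's
#' `effect_directions`.
#'
#' @param latent list or one-row data frame with standardized
#'   `comprehensibility` and `interest`.
#' @param layout an element of [article_layouts()].
#' @param config a [gaze_config()].
#' @param participant list of stable participant traits: `speed_mult`,
#'   `pupil_base`, `fix_jitter` (defaults used when omitted).
#' @param pupil_loss when `TRUE` the pupil channel is recorded as `NA`.
#' @return A gaze-sample data frame (see [gaze-events]).
#' @export
generate_session <- function(latent, layout, config = gaze_config(),
                             participant = list(), pupil_loss = FALSE) {
  if (is.null(layout$words) || nrow(layout$words) == 0 ||
      nrow(layout$lines) == 0) {
    stop("layout must contain at least one text line")
  }
  speed <- participant$speed_mult %||% 1
  pupil_base <- participant$pupil_base %||% 17
  eff <- session_effects(latent$comprehensibility, latent$interest, config)

  words <- layout$words
  nw <- nrow(words)
  p_skip <- stats::plogis(stats::qlogis(config$skip_prob) + eff$skip_shift)
  p_reg <- stats::plogis(stats::qlogis(config$regression_prob) + eff$reg_shift)
  keep <- stats::runif(nw) > p_skip | words$line == 0  # titles read fully
  seq_idx <- which(keep)
  # interleave refixations and backward regressions into the word walk
  fix_words <- integer(0)
  for (j in seq_along(seq_idx)) {
    w <- seq_idx[j]
    fix_words <- c(fix_words, w)
    if (stats::runif(1) < config$refixation_prob) fix_words <- c(fix_words, w)
    if (words$line[w] > 0 && stats::runif(1) < p_reg) {
      back <- max(1L, w - sample(2:9, 1))
      fix_words <- c(fix_words, back, w)
    }
  }
  nf <- length(fix_words)
  fx <- words$x[fix_words] + stats::rnorm(nf, 0, 4)
  fy <- words$y[fix_words] + stats::rnorm(nf, 0, 3)
  dur <- stats::rlnorm(nf, log(config$base_fixation_ms * eff$rt_mult *
                                 eff$fd_mult * speed), 0.30)
  dur <- pmax(dur, 120)
  amp_px <- c(0, sqrt(diff(fx)^2 + diff(fy)^2))
  sac_dur <- c(0, 21 + 0.25 * sqrt(amp_px[-1]) * 8)  # main-sequence-like
  onset <- cumsum(sac_dur) + cumsum(c(0, dur[-nf]))
  offset <- onset + dur
  total_ms <- offset[nf]

  dt <- 1000 / config$sample_rate
  t_s <- seq(0, total_ms - dt / 2, by = dt)
  ns <- length(t_s)
  ev <- findInterval(t_s, onset)  # which fixation interval we are at/past
  ev[ev < 1] <- 1L
  in_fix <- t_s <= offset[ev]
  x <- numeric(ns); y <- numeric(ns)
  x[in_fix] <- fx[ev[in_fix]]
  y[in_fix] <- fy[ev[in_fix]]
  tr <- which(!in_fix)  # saccade transition samples: interpolate
  if (length(tr)) {
    frm <- ev[tr]; nxt <- pmin(frm + 1L, nf)
    frac <- (t_s[tr] - offset[frm]) / pmax(onset[nxt] - offset[frm], dt)
    x[tr] <- fx[frm] + frac * (fx[nxt] - fx[frm])
    y[tr] <- fy[frm] + frac * (fy[nxt] - fy[frm])
  }
  x <- x + stats::rnorm(ns, 0, 1.5)
  y <- y + stats::rnorm(ns, 0, 1.5)

  # pupil: personal baseline + slow drift + white noise, variance bent by latents
  drift <- 0.5 * eff$pupil_mult * sin(2 * pi * t_s / 45000 +
                                        stats::runif(1, 0, 2 * pi))
  pupil <- pupil_base + drift + stats::rnorm(ns, 0, 0.35 * eff$pupil_mult)

  # blinks: Poisson events, uniform 100-400 ms, (0,0) position convention
  n_blinks <- stats::rpois(1, config$blink_rate * total_ms / 60000)
  blink <- rep(FALSE, ns)
  if (n_blinks > 0) {
    b_on <- stats::runif(n_blinks, 0, max(total_ms - 400, 1))
    b_dur <- stats::runif(n_blinks, 100, 400)
    for (b in seq_len(n_blinks)) {
      blink[t_s >= b_on[b] & t_s <= b_on[b] + b_dur[b]] <- TRUE
    }
  }
  disp <- 1.5  # binocular disparity, px
  lx <- x - disp + stats::rnorm(ns, 0, 0.7)
  ly <- y + stats::rnorm(ns, 0, 0.7)
  rx <- x + disp + stats::rnorm(ns, 0, 0.7)
  ry <- y + stats::rnorm(ns, 0, 0.7)
  lp <- pupil + stats::rnorm(ns, 0, 0.1)
  rp <- pupil + stats::rnorm(ns, 0, 0.1)
  lx[blink] <- ly[blink] <- rx[blink] <- ry[blink] <- 0
  lp[blink] <- rp[blink] <- 0
  if (pupil_loss) lp <- rp <- rep(NA_real_, ns)
  data.frame(time_ms = t_s,
             left_x_px = lx, left_y_px = ly,
             right_x_px = rx, right_y_px = ry,
             left_pupil_px = lp, right_pupil_px = rp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate questionnaire responses from the latent appraisals
#'
#' Items are built from a common-factor model in which the latent
#' appraisal is the factor: each of the three items per construct loads
#' `sqrt(rho)` on it, giving pairwise inter-item correlation `rho` in
#' expectation, then is mapped onto the 1-7 response scale (rounded and
#' clamped). Reverse-coded items (see [scale_definitions()]) are stored
#' flipped (`x -> 8 - x`), exactly as a participant would answer them.
#'
#' @param latents data frame with one row per session:
#'   `participant, article, block, order, comprehensibility, interest`
#'   (latents standardized).
#' @param config a [gaze_config()]; supplies the inter-item
#'   correlations.
#' @return A ratings data frame: ids plus six item columns (values 1-7).
#' @export
generate_ratings <- function(latents, config = gaze_config()) {
  defs <- scale_definitions()
  n <- nrow(latents)
  # scale means/SDs chosen to emulate upper-mid appraisals on the 1-7 scale
  pars <- list(comprehensibility = c(mean = 5.35, sd = 1.23),
               interest = c(mean = 4.66, sd = 1.43))
  out <- latents[, c("participant", "article", "block", "order"), drop = FALSE]
  for (construct in names(defs)) {
    rho <- config$item_intercorrelation[[construct]]
    p <- pars[[construct]]
    item_sd <- p["sd"] / sqrt(rho + (1 - rho) / 3)
    items <- simulate_scale_items(n, rho, k = 3,
                                  factor_scores = latents[[construct]],
                                  item_mean = p["mean"], item_sd = item_sd,
                                  discretize = TRUE)
    rev <- defs[[construct]]$reverse
    items[, rev] <- 8 - items[, rev, drop = FALSE]
    colnames(items) <- defs[[construct]]$items
    out <- cbind(out, as.data.frame(items))
  }
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic reading study
#'
#' Draws standardized latent comprehensibility/interest pairs per
#' (participant, article) session, assigns articles to counterbalanced
#' blocks with randomized within-block presentation order, generates a
#' gaze stream per session (except for dropout participants, whose
#' recordings are lost while their questionnaires survive) and
#' questionnaire responses for every session. Deterministic given
#' `config$rng_seed`.
#'
#' @param config a [gaze_config()].
#' @return A list:
#'   `streams` -- named list of gaze-sample data frames, one per
#'     recorded session, named `P{pp}_A{aa}`;
#'   `ratings` -- item responses for all sessions;
#'   `latents` -- the latent appraisal pairs with design columns;
#'   `layouts` -- article layouts; `aois` -- per-article AOI rectangles
#'     (named by article id); `config` -- the configuration used.
#' @export
generate_study <- function(config = gaze_config()) {
  stopifnot(inherits(config, "gaze_config"))
  set.seed(config$rng_seed)
  np <- config$n_participants; na <- config$n_articles; nb <- config$n_blocks
  if (na %% nb != 0) stop("invalid config: 'n_articles' must divide evenly over 'n_blocks'")

  layouts <- article_layouts(na)
  aois <- lapply(layouts, function(l) list(title = l$title_rect,
                                           content = l$content_rect))
  names(aois) <- as.character(seq_len(na))

  # articles grouped into blocks by a familiarity score; block order
  # counterbalanced across participants, article order randomized within
  familiarity <- stats::runif(na)
  art_block <- rep(seq_len(nb), each = na / nb)[rank(familiarity,
                                                     ties.method = "first")]
  rho <- config$latent_correlation
  design <- do.call(rbind, lapply(seq_len(np), function(p) {
    block_order <- ((p - 1 + seq_len(nb) - 1) %% nb) + 1
    arts <- unlist(lapply(block_order, function(b) {
      a <- which(art_block == b)
      a[sample.int(length(a))]
    }))
    data.frame(participant = p, article = arts,
               block = art_block[arts], order = seq_len(na))
  }))
  nsess <- nrow(design)
  zc <- stats::rnorm(nsess)
  design$comprehensibility <- zc
  design$interest <- rho * zc + sqrt(1 - rho^2) * stats::rnorm(nsess)

  n_drop <- round(np * config$dropout_rate)
  dropped <- if (n_drop > 0) sample.int(np, n_drop) else integer(0)
  recorded <- which(!design$participant %in% dropped)
  loss_idx <- if (config$pupil_loss_sessions > 0 && length(recorded)) {
    sample(recorded, min(config$pupil_loss_sessions, length(recorded)))
  } else integer(0)

  traits <- lapply(seq_len(np), function(p) {
    list(speed_mult = exp(stats::rnorm(1, 0, 0.12)),
         pupil_base = stats::rnorm(1, 17, 1.2))
  })

  streams <- vector("list", length(recorded))
  nm <- character(length(recorded))
  for (k in seq_along(recorded)) {
    i <- recorded[k]
    p <- design$participant[i]; a <- design$article[i]
    streams[[k]] <- generate_session(
      list(comprehensibility = design$comprehensibility[i],
           interest = design$interest[i]),
      layouts[[a]], config, traits[[p]],
      pupil_loss = i %in% loss_idx)
    nm[k] <- sprintf("P%02d_A%02d", p, a)
  }
  names(streams) <- nm

  ratings <- generate_ratings(design, config)
  list(streams = streams, ratings = ratings, latents = design,
       layouts = layouts, aois = aois, config = config)
}
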