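#' Detect all oculomotor events of one session
#'
#' Convenience wrapper chaining [detect_fixations()] and
#' [derive_saccades()] for a single gaze stream.
#'
#' @param stream gaze-sample data frame.
#' @param geometry a [screen_geometry()].
#' @param min_fixation_ms,dispersion_deg,regression_px detection
#'   thresholds (defaults 80 ms, 1.0 degree, 20 px).
#' @return list with `fixations` and `saccades`.
#' @export
detect_session_events <- function(stream, geometry = screen_geometry(),
                                  min_fixation_ms = 80, dispersion_deg = 1.0,
                                  regression_px = 20) {
  fx <- detect_fixations(stream, geometry, min_duration_ms = min_fixation_ms,
                         dispersion_deg = dispersion_deg)
  sc <- derive_saccades(fx, stream, geometry, regression_px = regression_px)
  list(fixations = fx, saccades = sc)
}

#' Run the full gaze-to-appraisal pipeline
#'
#' Executes every stage on a (simulated) study: generate -> detect
#' events -> aggregate session features -> score scales -> screen ->
#' stepwise model per appraisal -> leave-one-out cross-validation ->
#' report data. A run manifest records the configuration hash, the seed
#' and the per-stage row/event counts, so shrinking event counts across
#' the filter stages are auditable.
#'
#' @param config a [gaze_config()]; its `rng_seed` drives everything.
#' @param geometry a [screen_geometry()].
#' @param study optionally a pre-generated study (from
#'   [generate_study()]); when `NULL` one is simulated from `config`.
#' @param fit_models fit the stepwise models and cross-validate
#'   (the slowest stage; disable for feature-level work).
#' @param out_dir optional directory: stage outputs are written as CSV /
#'   JSON files there.
#' @return A list with `study`, `events`, `features`
#'   (table + manifest + counts), `scores`, `screening`, `models`,
#'   `cv`, `reports` and `manifest`.
#' @export
run_pipeline <- function(config = gaze_config(), geometry = screen_geometry(),
                         study = NULL, fit_models = TRUE, out_dir = NULL) {
  if (is.null(study)) study <- generate_study(config)
  if (!identical(config_hash(study$config), config_hash(config))) {
    stop("pipeline stage refused: study was generated under a different configuration")
  }

  sess_keys <- names(study$streams)
  key <- do.call(rbind, regmatches(sess_keys,
                                   regexec("^P(\\d+)_A(\\d+)$", sess_keys)))
  participants <- as.integer(key[, 2]); articles <- as.integer(key[, 3])
  lat_key <- paste(study$latents$participant, study$latents$article)
  blocks <- study$latents$block[match(paste(participants, articles), lat_key)]

  events <- vector("list", length(sess_keys))
  for (k in seq_along(sess_keys)) {
    ev <- detect_session_events(study$streams[[k]], geometry)
    events[[k]] <- list(participant = participants[k], article = articles[k],
                        block = blocks[k], fixations = ev$fixations,
                        saccades = ev$saccades)
  }

  scored <- score_scales(study$ratings)
  features <- build_feature_table(events, study$aois, ratings = scored$scores)
  screening <- screen_features(features$table)

  models <- cv <- reports <- NULL
  if (fit_models) {
    models <- lapply(c(comprehensibility = "comprehensibility",
                       interest = "interest"),
                     appraisal_lm, data = screening$table)
    cv <- lapply(models, loocv, data = screening$table)
    reports <- lapply(cv, cv_report)
  }

  manifest <- list(
    config_hash = config_hash(config),
    seed = config$rng_seed,
    counts = list(
      appraisal_records = nrow(study$ratings),
      gaze_sessions = length(study$streams),
      events = features$counts,
      feature_columns = nrow(features$manifest),
      screened_rows = unname(screening$report$final_dims["rows"]),
      screened_removed_rows = screening$report$rows_removed$count,
      screened_removed_columns = length(screening$report$columns_removed)),
    alpha = scored$alpha,
    models = if (fit_models) lapply(models, function(m) {
      list(predictors = m$predictors, r_squared_pct = m$r_squared_pct,
           f = m$f_statistic, df = m$df, p = m$p_value)
    }),
    cv = if (fit_models) lapply(cv, function(v) {
      list(nrmse = v$nrmse, pearson_r = v$pearson_r)
    }))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    gaze_dir <- file.path(out_dir, "gaze")
    dir.create(gaze_dir, showWarnings = FALSE)
    for (k in seq_along(sess_keys)) {
      write_gaze_csv(study$streams[[k]],
                     file.path(gaze_dir, paste0(sess_keys[k], ".csv")))
    }
    aoi_dir <- file.path(out_dir, "aoi")
    dir.create(aoi_dir, showWarnings = FALSE)
    for (a in names(study$aois)) {
      write_aoi_json(study$aois[[a]],
                     file.path(aoi_dir, sprintf("A%02d.json", as.integer(a))))
    }
    write_ratings_csv(study$ratings, file.path(out_dir, "ratings.csv"))
    write_study_table(features, out_dir)
    utils::write.csv(screening$table, file.path(out_dir, "screened.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(study = study, events = events, features = features, scores = scored,
       screening = screening, models = models, cv = cv, reports = reports,
       manifest = manifest)
}
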