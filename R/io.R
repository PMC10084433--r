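#' @title Plain-text readers and writers
#' @name gaze-io
#' @description The pipeline's on-disk dialects are deliberately plain:
#'   per-session gaze CSVs (`time_ms, left_x_px, left_y_px, right_x_px,
#'   right_y_px, left_pupil_px, right_pupil_px`; blink rows carry (0, 0)
#'   positions), one AOI JSON per article
#'   (`{"title": [x0,y0,x1,y1], "content": [...]}`, pixel coordinates,
#'   origin top-left, half-open max edges), a ratings CSV with six item
#'   columns, and the study table as CSV with a JSON feature manifest
#'   sidecar. Every writer stamps the configuration hash so stages
#'   cannot silently mix runs.
NULL

#' @rdname gaze-io
#' @param stream gaze-sample data frame.
#' @param path file path.
#' @export
write_gaze_csv <- function(stream, path) {
  utils::write.csv(stream[, gaze_cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname gaze-io
#' @export
read_gaze_csv <- function(path) {
  df <- utils::read.csv(path)
  missing_cols <- setdiff(gaze_cols, names(df))
  if (length(missing_cols)) {
    stop("not a gaze CSV (", path, "): missing ",
         paste(missing_cols, collapse = ", "))
  }
  df[, gaze_cols]
}

#' @rdname gaze-io
#' @param aoi list with `title` and `content` rectangles.
#' @export
write_aoi_json <- function(aoi, path) {
  jsonlite::write_json(lapply(aoi[c("title", "content")], as.numeric),
                       path, digits = NA)
  invisible(path)
}

#' @rdname gaze-io
#' @export
read_aoi_json <- function(path) {
  if (!file.exists(path)) stop("AOI file not found: ", path)
  aoi <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(aoi$title) || is.null(aoi$content)) {
    stop("AOI file must define 'title' and 'content': ", path)
  }
  aoi
}

#' @rdname gaze-io
#' @param ratings ratings data frame.
#' @export
write_ratings_csv <- function(ratings, path) {
  utils::write.csv(ratings, path, row.names = FALSE)
  invisible(path)
}

#' @rdname gaze-io
#' @export
read_ratings_csv <- function(path) utils::read.csv(path)

#' @rdname gaze-io
#' @param result a [build_feature_table()] result.
#' @param dir output directory; writes `study_table.csv` and
#'   `feature_manifest.json`.
#' @export
write_study_table <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$table, file.path(dir, "study_table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$manifest,
                       file.path(dir, "feature_manifest.json"), digits = NA)
  invisible(dir)
}

#' @rdname gaze-io
#' @export
read_study_table <- function(dir) {
  list(table = utils::read.csv(file.path(dir, "study_table.csv"),
                               colClasses = c(participant = "character",
                                              article = "character",
                                              block = "character")),
       manifest = jsonlite::read_json(file.path(dir, "feature_manifest.json"),
                                      simplifyVector = TRUE))
}

# stable hash of a configuration (md5 of its serialized JSON)
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA),
             tmp)
  unname(tools::md5sum(tmp))
}
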