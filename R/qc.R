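#' Screen the study table before modeling
#'
#' Three checks secure the table for regression modeling:
#' rows with any missing feature value are removed; near-zero-variance
#' columns are flagged (frequency ratio of the two most common values
#' at least 95/5 and unique-value fraction under 10%) but retained
#' unless `drop_nzv = TRUE`; and highly correlated column pairs
#' (`|r| > r_threshold`) are de-duplicated by greedily removing, from
#' the worst offending pair, the member with the larger mean absolute
#' correlation against all remaining feature columns (ties broken by
#' name order). Columns are visited in sorted-name order so the result
#' is deterministic.
#'
#' @param table the study table from [build_feature_table()].
#' @param feature_cols names of the feature columns to screen; defaults
#'   to every numeric column except ids and appraisal scores.
#' @param r_threshold absolute Pearson correlation above which one of a
#'   pair is removed (default 0.95).
#' @param drop_nzv drop (not just flag) near-zero-variance columns.
#' @return A list: `table` (screened) and `report` with elements
#'   `rows_removed` (count + ids), `nzv_columns`, `correlated_pairs`
#'   (name, name, r), `columns_removed` and `final_dims`.
#' @export
screen_features <- function(table, feature_cols = NULL, r_threshold = 0.95,
                            drop_nzv = FALSE) {
  if (nrow(table) < 2) stop("screening needs at least two rows")
  if (is.null(feature_cols)) {
    id_cols <- c("participant", "article", "block", "order",
                 "comprehensibility", "interest", "novelty_complexity")
    feature_cols <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                            id_cols)
  }
  feature_cols <- sort(feature_cols)

  miss <- rowSums(is.na(table[, feature_cols, drop = FALSE])) > 0
  if (all(miss)) stop("every row has missing feature values")
  removed_ids <- rownames(table)[miss]
  if (!is.null(table$participant)) {
    removed_ids <- paste(table$participant[miss], table$article[miss], sep = ":")
  }
  tab <- table[!miss, , drop = FALSE]

  nzv <- feature_cols[vapply(feature_cols, function(cl) {
    near_zero_variance(tab[[cl]])
  }, logical(1))]
  if (drop_nzv && length(nzv)) {
    tab <- tab[, setdiff(names(tab), nzv), drop = FALSE]
    feature_cols <- setdiff(feature_cols, nzv)
  }

  dedup <- drop_correlated(tab[, feature_cols, drop = FALSE], r_threshold)
  tab <- tab[, setdiff(names(tab), dedup$removed), drop = FALSE]

  list(table = tab,
       report = list(
         rows_removed = list(count = sum(miss), ids = removed_ids),
         nzv_columns = nzv,
         correlated_pairs = dedup$pairs,
         columns_removed = dedup$removed,
         final_dims = c(rows = nrow(tab), columns = ncol(tab))))
}

# the 95/5 + 10% screening convention for near-zero variance
near_zero_variance <- function(x, freq_cut = 95 / 5, unique_cut = 0.1) {
  x <- x[!is.na(x)]
  if (!length(x)) return(TRUE)
  freq <- sort(table(x), decreasing = TRUE)
  ratio <- if (length(freq) < 2) Inf else freq[1] / freq[2]
  unique_frac <- length(freq) / length(x)
  ratio >= freq_cut && unique_frac < unique_cut
}

# greedy de-duplication of |r| > threshold pairs
drop_correlated <- function(df, r_threshold) {
  cols <- sort(names(df))
  # constant columns correlate as NA; treated as uncorrelated below
  cm <- abs(suppressWarnings(stats::cor(as.matrix(df[, cols, drop = FALSE]),
                                        use = "pairwise.complete.obs")))
  diag(cm) <- 0
  cm[is.na(cm)] <- 0
  pairs <- list()
  removed <- character(0)
  repeat {
    if (max(cm) <= r_threshold) break
    hit <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    a <- rownames(cm)[hit[1]]; b <- colnames(cm)[hit[2]]
    if (a > b) { tmp <- a; a <- b; b <- tmp }
    pairs[[length(pairs) + 1L]] <- data.frame(var1 = a, var2 = b,
                                              r = max(cm))
    mean_a <- mean(cm[a, setdiff(colnames(cm), a)])
    mean_b <- mean(cm[b, setdiff(colnames(cm), b)])
    drop <- if (mean_a > mean_b) a else if (mean_b > mean_a) b else max(a, b)
    removed <- c(removed, drop)
    keep <- setdiff(rownames(cm), drop)
    cm <- cm[keep, keep, drop = FALSE]
    if (length(keep) < 2) break
  }
  list(removed = removed,
       pairs = if (length(pairs)) do.call(rbind, pairs) else
         data.frame(var1 = character(0), var2 = character(0), r = numeric(0)))
}
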