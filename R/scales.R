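#' Questionnaire scale definitions
#'
#' Each appraisal construct is measured by three 7-point items
#' (semantic differentials or Likert). Reverse-coded items run against
#' the construct (a high raw value means less of it) and are flipped
#' (`x -> 8 - x`) before scoring so that higher scores always mean more
#' comprehensible / more interesting.
#'
#' @return A named list of constructs, each with `items` (column names)
#'   and `reverse` (logical flags, same length).
#' @export
scale_definitions <- function() {
  list(
    comprehensibility = list(
      items = c("comp_comprehensible", "comp_coherent", "comp_easy"),
      reverse = c(FALSE, FALSE, FALSE)),
    interest = list(
      items = c("int_interesting", "int_exciting", "int_read_more"),
      # boring-exciting is anchored opposite to interesting-uninteresting
      reverse = c(FALSE, TRUE, FALSE))
  )
}

#' Cronbach's alpha of a multi-item scale
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(item sum))` for k
#' items. For items with common pairwise correlation rho the population
#' value is `k * rho / (1 + (k - 1) * rho)`.
#'
#' @param items a numeric matrix or data frame, one column per item
#'   (already aligned: reverse-coded items flipped).
#' @return alpha (scalar).
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  k <- ncol(items)
  if (k < 2) stop("alpha needs at least two items")
  total <- rowSums(items)
  k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / stats::var(total))
}

#' Score appraisal scales from item responses
#'
#' Flips reverse-coded items (`x -> 8 - x`), averages the three aligned
#' items per construct into a scale score, and reports Cronbach's alpha
#' per scale.
#'
#' @param ratings data frame of item responses (values 1-7) with one
#'   row per session; must contain every item column named in
#'   `definitions`.
#' @param definitions scale definitions as from [scale_definitions()].
#' @return A list: `scores` (the input ids plus one score column per
#'   construct) and `alpha` (named numeric).
#' @export
score_scales <- function(ratings, definitions = scale_definitions()) {
  out <- ratings[, intersect(c("participant", "article", "block", "order"),
                             names(ratings)), drop = FALSE]
  alpha <- numeric(0)
  for (construct in names(definitions)) {
    def <- definitions[[construct]]
    missing_items <- setdiff(def$items, names(ratings))
    if (length(missing_items)) {
      stop("ratings lack item columns: ", paste(missing_items, collapse = ", "))
    }
    items <- as.matrix(ratings[, def$items, drop = FALSE])
    bad <- which(items < 1 | items > 7 | is.na(items), arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("item '%s' out of range 1-7 in row %d",
                   def$items[bad[1, 2]], bad[1, 1]))
    }
    items[, def$reverse] <- 8 - items[, def$reverse, drop = FALSE]
    out[[construct]] <- rowMeans(items)
    alpha[construct] <- cronbach_alpha(items)
  }
  list(scores = out, alpha = alpha)
}

#' Simulate correlated scale items from a common-factor model
#'
#' Draws `n` response triplets (or k-tuples) in which every item loads
#' on one latent factor so that the pairwise standardized inter-item
#' correlation equals `rho` in expectation:
#' `item_j = sqrt(rho) * F + sqrt(1 - rho) * e_j`. Used to study the
#' sampling behavior of Cronbach's alpha; responses are continuous and
#' standardized unless a mean/sd/discretization is requested.
#'
#' @param n number of response tuples.
#' @param rho common pairwise inter-item correlation, in (0, 1).
#' @param k number of items (default 3).
#' @param factor_scores optional length-`n` latent factor scores to use
#'   instead of fresh standard-normal draws.
#' @param item_mean,item_sd location/scale applied to each item.
#' @param discretize round and clamp responses to the 1-7 scale.
#' @return an `n x k` matrix of item responses.
#' @export
simulate_scale_items <- function(n, rho, k = 3, factor_scores = NULL,
                                 item_mean = 0, item_sd = 1,
                                 discretize = FALSE) {
  if (rho <= 0 || rho >= 1) stop("rho must lie strictly between 0 and 1")
  f <- if (is.null(factor_scores)) stats::rnorm(n) else factor_scores
  e <- matrix(stats::rnorm(n * k), n, k)
  items <- item_mean + item_sd * (sqrt(rho) * f + sqrt(1 - rho) * e)
  if (discretize) items <- pmax(pmin(round(items), 7), 1)
  items
}
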