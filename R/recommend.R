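#' Recommend the next feature to acquire for one patient
#'
#' The individualized recommender: cases in the pool are weighted by inverse
#' Euclidean distance to the patient over the features the patient already
#' has, a weighted logistic classifier is fit on *all* pool features, the
#' fit is attributed with closed-form linear Shapley values over the pool,
#' and features are ranked by mean absolute attribution. The recommendation
#' is the highest-ranked feature the patient is missing. The full ranking is
#' computed first and then filtered to the candidate set.
#'
#' @param table a [case_table()] (the pool of known cases).
#' @param query a [patient_query()] on the table's encoded scale (see
#'   [encode_query()] when loading raw patient values).
#' @param C inverse regularisation strength passed to the classifier.
#' @return An object of class `recommendation`: list with `ranking`
#'   (an `importance_ranking` over all features), `recommended` (a feature
#'   name, or `NA` when the patient already has every feature), `partition`
#'   and `mode`.
#' @seealso [global_recommend()] for the population-level selector.
#' @export
icare_recommend <- function(table, query, C = 1) {
  stopifnot(inherits(table, "case_table"))
  part <- identify_missing(query, table)
  w <- case_weights(query, table, subset = part$initial)
  fit <- fit_weighted_logistic(table$X, table$y, weights = w, C = C)
  .rank_and_pick(fit, table, part, mode = "icare")
}

#' Population-level (global) feature recommendation
#'
#' The non-personalised reference selector: an unweighted logistic
#' classifier is fit on the full pool, attributed with linear Shapley
#' values, and the highest-ranked candidate feature is recommended. Every
#' patient sharing the same partition receives the same recommendation.
#'
#' @param table a [case_table()].
#' @param partition a `feature_partition` (from [identify_missing()] or
#'   [select_initial_features()]).
#' @inheritParams icare_recommend
#' @return A `recommendation` object (see [icare_recommend()]).
#' @export
global_recommend <- function(table, partition, C = 1) {
  stopifnot(inherits(table, "case_table"), inherits(partition, "feature_partition"))
  fit <- fit_weighted_logistic(table$X, table$y, weights = NULL, C = C)
  .rank_and_pick(fit, table, partition, mode = "global")
}

.rank_and_pick <- function(fit, table, part, mode) {
  phi <- linear_shap(fit, table$X)
  rk <- mean_abs_importance(phi)
  hit <- rk$order[rk$order %in% part$candidate]
  structure(
    list(
      ranking = rk,
      recommended = if (length(hit)) hit[[1L]] else NA_character_,
      partition = part,
      mode = mode
    ),
    class = "recommendation"
  )
}

#' @export
print.recommendation <- function(x, ...) {
  cat(sprintf("recommendation (%s)\n", x$mode))
  if (is.na(x$recommended)) {
    cat("  no missing feature to recommend\n")
  } else {
    cat("  recommended:", x$recommended, "\n")
  }
  cands <- x$ranking$order[x$ranking$order %in% x$partition$candidate]
  if (length(cands)) {
    cat("  candidate ranking:\n")
    print(x$ranking$importance[cands])
  }
  invisible(x)
}

#' Tabulate a recommendation's candidate ranking
#'
#' @param x a `recommendation`.
#' @param ... unused.
#' @return data.frame with columns `feature`, `importance`, `recommended`,
#'   candidates only, ranked.
#' @export
as.data.frame.recommendation <- function(x, ...) {
  cands <- x$ranking$order[x$ranking$order %in% x$partition$candidate]
  data.frame(
    feature = cands,
    importance = as.numeric(x$ranking$importance[cands]),
    recommended = cands %in% x$recommended,
    row.names = NULL
  )
}
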