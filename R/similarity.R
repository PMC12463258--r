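#' Euclidean distance from a query to every case in the pool
#'
#' Distances are computed only over `subset` -- the features the patient
#' actually has. The outcome never enters the distance. No scaling happens
#' here; features are assumed to be on comparable scales already (see
#' [load_cases()]).
#'
#' @param query a [patient_query()] or named numeric vector on the table's
#'   encoded scale.
#' @param table a [case_table()].
#' @param subset feature names over which to compute the distance; defaults
#'   to every feature the query observes.
#' @return Numeric vector of length `table$n`, `d_i >= 0`.
#' @export
euclidean_distance <- function(query, table, subset = names(query)) {
  stopifnot(inherits(table, "case_table"))
  if (length(subset) == 0L) {
    stop("distance subset must be non-empty", call. = FALSE)
  }
  .check_known_features(subset, table)
  missing_in_query <- setdiff(subset, names(query))
  if (length(missing_in_query)) {
    stop("query does not observe: ", paste(missing_in_query, collapse = ", "),
      call. = FALSE
    )
  }
  q <- as.numeric(query)[match(subset, names(query))]
  diff <- sweep(table$X[, subset, drop = FALSE], 2, q, "-")
  sqrt(rowSums(diff^2))
}

#' Convert distances to inverse-distance sample weights
#'
#' Each case's weight is the reciprocal of its distance to the incoming
#' patient, floored by a small epsilon so identical cases get a large
#' finite weight: `w_i = 1 / (d_i + eps)`. Weights are deliberately not
#' normalised -- the weighted likelihood is used with the raw reciprocals,
#' and their overall scale interacts only with the fixed ridge penalty.
#'
#' @param d non-negative distance vector.
#' @param eps stabilising floor added to every distance (default `1e-9`).
#' @return Positive weight vector of the same length, anti-monotone in `d`.
#' @export
weights_from_distances <- function(d, eps = 1e-9) {
  d <- as.numeric(d)
  if (anyNA(d) || any(d < 0)) {
    stop("distances must be non-negative and non-missing", call. = FALSE)
  }
  1 / (d + eps)
}

#' @rdname weights_from_distances
#' @inheritParams euclidean_distance
#' @details `case_weights()` composes the two steps: distances from the
#'   query over `subset`, then inverse-distance weights.
#' @export
case_weights <- function(query, table, subset = names(query), eps = 1e-9) {
  weights_from_distances(euclidean_distance(query, table, subset), eps = eps)
}
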