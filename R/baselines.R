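#' Baseline next-feature selectors
#'
#' Reference selectors against which the individualized recommender is
#' compared: cross-validated sequential forward scoring
#' ([sfs_select()]), L1-penalised coefficient ranking ([lasso_select()])
#' and an imputation-based explanation-guided selector
#' ([eguided_select()]). Each returns a `selector_result`: the candidate
#' features ordered best-first with their scores.
#'
#' @name baselines
NULL

.selector_result <- function(feature, score, method) {
  structure(
    data.frame(feature = feature, score = as.numeric(score), row.names = NULL),
    method = method,
    class = c("selector_result", "data.frame")
  )
}

#' @export
print.selector_result <- function(x, ...) {
  cat("selector_result (", attr(x, "method"), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Sequential forward selection scoring of candidates
#'
#' One forward step from the initial set: each candidate feature is scored
#' by the k-fold cross-validated accuracy of a logistic classifier on
#' `initial + candidate`, and candidates are ordered by score (descending,
#' canonical-order tie-break). A fold whose training part is single-class
#' triggers one reshuffle before failing.
#'
#' @param table a [case_table()].
#' @param partition a `feature_partition`.
#' @param folds number of CV folds (default 5).
#' @param seed optional seed controlling the fold assignment.
#' @param C inverse regularisation strength.
#' @return A `selector_result` over the candidates.
#' @export
sfs_select <- function(table, partition, folds = 5, seed = NULL, C = 1) {
  stopifnot(inherits(table, "case_table"), inherits(partition, "feature_partition"))
  cands <- partition$candidate
  if (!length(cands)) stop("no candidate features to score", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  assign_folds <- function() sample(rep(seq_len(folds), length.out = table$n))
  fold_id <- assign_folds()
  for (try in 1:2) {
    ok <- all(vapply(seq_len(folds), function(f) {
      length(unique(table$y[fold_id != f])) == 2L
    }, logical(1)))
    if (ok) break
    if (try == 2) stop("single-class CV fold after reshuffle", call. = FALSE)
    fold_id <- assign_folds()
  }

  score_one <- function(cand) {
    cols <- c(partition$initial, cand)
    accs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fit <- fit_weighted_logistic(table$X[tr, cols, drop = FALSE],
        table$y[tr],
        weights = NULL, C = C
      )
      pr <- predict_prob(fit, table$X[!tr, cols, drop = FALSE])
      mean((pr > 0.5) == table$y[!tr])
    }, numeric(1))
    mean(accs)
  }
  scores <- vapply(cands, score_one, numeric(1))
  ord <- order(-scores) # stable: ties keep canonical order
  .selector_result(cands[ord], scores[ord], "sfs")
}

#' L1-penalised (lasso) candidate ranking
#'
#' Fits an L1-penalised logistic model on all pool features (glmnet,
#' unstandardised -- features are expected to be on comparable scales) and
#' orders the candidates by absolute coefficient at the chosen penalty.
#' When no penalty is given it is selected by 5-fold cross-validation.
#'
#' @inheritParams sfs_select
#' @param penalty lasso penalty (glmnet's `lambda`); `NULL` selects
#'   `lambda.min` by CV.
#' @return A `selector_result`; if every coefficient is zero at the chosen
#'   penalty the candidates are returned in canonical order with zero
#'   scores and a warning.
#' @export
lasso_select <- function(table, partition, penalty = NULL, seed = NULL) {
  stopifnot(inherits(table, "case_table"), inherits(partition, "feature_partition"))
  cands <- partition$candidate
  if (!length(cands)) stop("no candidate features to score", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(penalty)) {
    cv <- glmnet::cv.glmnet(table$X, table$y,
      family = "binomial", alpha = 1,
      nfolds = 5, standardize = FALSE
    )
    penalty <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    fit <- glmnet::glmnet(table$X, table$y,
      family = "binomial", alpha = 1,
      standardize = FALSE
    )
  }
  cf <- glmnet::coef.glmnet(fit,
    s = penalty, exact = TRUE,
    x = table$X, y = table$y
  )
  beta <- stats::setNames(as.numeric(cf)[-1L], rownames(cf)[-1L])
  scores <- abs(beta[cands])
  if (all(scores == 0)) {
    warning("all candidate coefficients are zero at penalty ", signif(penalty, 3),
      "; returning canonical order",
      call. = FALSE
    )
    return(.selector_result(cands, scores, "lasso"))
  }
  ord <- order(-scores)
  .selector_result(cands[ord], scores[ord], "lasso")
}

#' Imputation-based explanation-guided candidate ranking
#'
#' A simplified explanation-guided selector: the `k_similar` pool cases
#' nearest the patient (Euclidean distance over the observed features)
#' supply plausible values for the missing features; `n_imputations`
#' synthetic complete records are built by drawing each missing feature
#' independently from those neighbours; an ordinary unweighted classifier
#' fit on the full pool is attributed with linear Shapley values on the
#' imputed records; candidates are ranked by mean absolute attribution.
#' This follows the published mechanism (nearest cases, imputation,
#' attribution) with a logistic base model, intended for qualitative
#' comparison only.
#'
#' @inheritParams sfs_select
#' @param query a [patient_query()].
#' @param k_similar neighbourhood size (default 100).
#' @param n_imputations number of imputed records (must be >= 1).
#' @return A `selector_result` over the patient's missing features.
#' @export
eguided_select <- function(table, query, k_similar = 100, n_imputations = 10,
                           seed = NULL, C = 1) {
  stopifnot(inherits(table, "case_table"))
  if (n_imputations < 1) stop("`n_imputations` must be >= 1", call. = FALSE)
  if (k_similar < 1 || k_similar > table$n) {
    stop("`k_similar` must lie in [1, number of cases]", call. = FALSE)
  }
  part <- identify_missing(query, table)
  if (!length(part$candidate)) {
    stop("the patient already has every feature", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  d <- euclidean_distance(query, table, subset = part$initial)
  nbr <- order(d)[seq_len(k_similar)]

  imputed <- matrix(NA_real_, n_imputations, table$p,
    dimnames = list(NULL, table$feature_names)
  )
  for (f in part$initial) imputed[, f] <- query[[f]]
  for (f in part$candidate) {
    pool_vals <- sort(table$X[nbr, f]) # sorted: invariant to pool row order
    imputed[, f] <- pool_vals[sample.int(length(pool_vals), n_imputations,
      replace = TRUE
    )]
  }

  fit <- fit_weighted_logistic(table$X, table$y, weights = NULL, C = C)
  phi <- linear_shap(fit, imputed, background = colMeans(table$X))
  imp <- colMeans(abs(phi[, part$candidate, drop = FALSE]))
  ord <- order(-imp)
  .selector_result(part$candidate[ord], imp[ord], "eguided")
}
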