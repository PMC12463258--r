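#' Closed-form Shapley attribution of a linear classifier
#'
#' For a linear decision function \eqn{f(x) = b_0 + \beta^\top x} under the
#' feature-independence (interventional) assumption, the Shapley value of
#' feature \eqn{j} at instance \eqn{x} is exactly
#' \eqn{\phi_j = \beta_j (x_j - \mu_j)}, where \eqn{\mu} is the per-feature
#' mean of the background data. No sampling is involved; the result
#' coincides with the game-theoretic value computed over all feature
#' coalitions with mean-imputation of absent features. Attributions are on
#' the log-odds scale of the decision function.
#'
#' Every row satisfies local accuracy:
#' \eqn{\sum_j \phi_{ij} = f(x_i) - f(\mu)}.
#'
#' @param model a `linear_classifier` from [fit_weighted_logistic()].
#' @param X matrix of instances to attribute (typically the case pool).
#' @param background per-feature reference means; defaults to the unweighted
#'   column means of `X` itself.
#' @return An `n x p` matrix of attributions with the model's feature names
#'   as columns.
#' @export
linear_shap <- function(model, X, background = NULL) {
  stopifnot(inherits(model, "linear_classifier"))
  X <- .conform_columns(model, X)
  if (is.null(background)) background <- colMeans(X)
  if (length(background) != length(model$feature_names)) {
    stop("background must have one mean per model feature", call. = FALSE)
  }
  if (!is.null(names(background))) {
    background <- background[model$feature_names]
  }
  phi <- sweep(X, 2, as.numeric(background), "-")
  phi <- sweep(phi, 2, model$coefficients, "*")
  colnames(phi) <- model$feature_names
  phi
}

#' Mean-absolute-attribution feature importance
#'
#' Aggregates a Shapley attribution matrix to one importance score per
#' feature, \eqn{I_j = \frac{1}{N}\sum_i |\phi_{ij}|}, and the induced
#' descending ranking. Ties are broken by the canonical column order, so
#' the ranking is fully deterministic.
#'
#' @param phi attribution matrix from [linear_shap()] (instances x features).
#' @param feature_names feature names; defaults to `colnames(phi)`.
#' @return An object of class `importance_ranking`: list with `importance`
#'   (named vector, canonical order) and `order` (feature names, most to
#'   least important).
#' @export
mean_abs_importance <- function(phi, feature_names = colnames(phi)) {
  if (is.data.frame(phi)) phi <- as.matrix(phi)
  if (!is.matrix(phi) || nrow(phi) < 1L) {
    stop("`phi` must be a non-empty matrix", call. = FALSE)
  }
  imp <- colMeans(abs(phi))
  names(imp) <- feature_names
  # order() is stable, so equal scores keep canonical (column) order
  structure(
    list(importance = imp, order = feature_names[order(-imp)]),
    class = "importance_ranking"
  )
}

#' @export
print.importance_ranking <- function(x, ...) {
  cat("importance_ranking (mean |attribution|, descending)\n")
  print(x$importance[x$order])
  invisible(x)
}
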