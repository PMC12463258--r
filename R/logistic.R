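#' Fit an L2-regularised, optionally sample-weighted, logistic classifier
#'
#' Minimises the penalised weighted negative log-likelihood
#' \deqn{\frac{1}{2C}\lVert\beta\rVert^2 +
#'   \sum_i w_i\,\ell(y_i,\ b_0 + x_i^\top\beta)}
#' where \eqn{\ell} is the logistic loss and the intercept \eqn{b_0} is not
#' penalised. This is the classifier used everywhere in the package: with
#' inverse-distance weights it is the locally weighted model centred on one
#' patient; with unit weights it is the ordinary global fit. Optimisation is
#' a damped Newton iteration (step-halving on the objective), deterministic
#' given its inputs.
#'
#' @param X numeric feature matrix (cases x features) with column names.
#' @param y binary outcome vector (0/1).
#' @param weights positive per-case weights, or `NULL` for unit weights.
#'   Weights are used as given; they are not normalised.
#' @param C inverse regularisation strength (default 1): larger `C`, weaker
#'   ridge penalty.
#' @param tol convergence tolerance on the Newton step (default 1e-6).
#' @param max_iter iteration cap (default 1000).
#' @return An object of class `linear_classifier` with `coefficients`
#'   (named slope vector, log-odds per unit feature), `intercept`,
#'   `feature_names` and `converged`.
#' @export
fit_weighted_logistic <- function(X, y, weights = NULL, C = 1,
                                  tol = 1e-6, max_iter = 1000) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L, dimnames = list(NULL, "x"))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2L) stop("need at least two cases to fit", call. = FALSE)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (anyNA(X) || anyNA(y) || any(!is.finite(X))) {
    stop("non-finite values in training data", call. = FALSE)
  }
  if (!all(y %in% c(0, 1))) stop("`y` must be 0/1", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("degenerate training set: only one outcome class present",
      call. = FALSE
    )
  }
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be positive, finite, one per case", call. = FALSE)
  }
  if (!is.numeric(C) || length(C) != 1L || C <= 0) {
    stop("`C` must be a positive scalar", call. = FALSE)
  }

  theta <- numeric(p + 1L) # (intercept, beta)
  Xa <- cbind(1, X)
  pen <- c(0, rep(1 / C, p)) # ridge on slopes only
  obj <- function(th) {
    eta <- drop(Xa %*% th)
    sum(weights * (.log1pexp(eta) - y * eta)) + 0.5 * sum(pen * th^2)
  }
  f_cur <- obj(theta)
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    eta <- drop(Xa %*% theta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(Xa, weights * (mu - y))) + pen * theta
    s <- pmax(weights * mu * (1 - mu), .Machine$double.xmin)
    H <- crossprod(Xa, Xa * s) + diag(pen, p + 1L)
    step <- tryCatch(
      solve(H, grad),
      error = function(e) solve(H + diag(1e-8 * max(diag(H)), p + 1L), grad)
    )
    # damped update: halve until the objective does not increase
    alpha <- 1
    repeat {
      theta_new <- theta - alpha * step
      f_new <- obj(theta_new)
      if (is.finite(f_new) && f_new <= f_cur + 1e-12 * abs(f_cur)) break
      alpha <- alpha / 2
      if (alpha < 1e-12) {
        theta_new <- theta
        f_new <- f_cur
        break
      }
    }
    delta <- max(abs(theta_new - theta))
    theta <- theta_new
    f_cur <- f_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  structure(
    list(
      coefficients = stats::setNames(unname(theta[-1L]), colnames(X)),
      intercept = unname(theta[1L]),
      feature_names = colnames(X),
      C = C,
      converged = converged
    ),
    class = "linear_classifier"
  )
}

# numerically stable log(1 + exp(x))
.log1pexp <- function(x) {
  out <- x
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  hi <- x > 18 & x <= 33.3
  out[hi] <- x[hi] + exp(-x[hi])
  out
}

#' @export
print.linear_classifier <- function(x, ...) {
  cat(sprintf(
    "linear_classifier (logistic, ridge C = %g%s)\n",
    x$C, if (x$converged) "" else ", NOT converged"
  ))
  print(c("(intercept)" = x$intercept, x$coefficients))
  invisible(x)
}

#' Linear decision function and predicted probabilities
#'
#' `decision_function()` returns the log-odds `b0 + X beta`;
#' `predict_prob()` passes it through the logistic link.
#'
#' @param model a `linear_classifier`.
#' @param X matrix (or data.frame) whose columns cover the model's features.
#' @return Numeric vector, one value per row of `X`.
#' @export
predict_prob <- function(model, X) {
  stats::plogis(decision_function(model, X))
}

#' @rdname predict_prob
#' @export
decision_function <- function(model, X) {
  stopifnot(inherits(model, "linear_classifier"))
  X <- .conform_columns(model, X)
  drop(model$intercept + X %*% model$coefficients)
}

.conform_columns <- function(model, X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L, dimnames = list(NULL, model$feature_names))
  if (ncol(X) != length(model$feature_names)) {
    stop("expected ", length(model$feature_names), " feature column(s), got ",
      ncol(X),
      call. = FALSE
    )
  }
  if (!is.null(colnames(X))) X <- X[, model$feature_names, drop = FALSE]
  X
}
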