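# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Exact Shapley value of a linear decision function by enumeration of all
# feature coalitions, with mean-imputation of absent features.
brute_shapley <- function(beta, intercept, x, mu) {
  p <- length(beta)
  f_coal <- function(members) {
    z <- mu
    z[members] <- x[members]
    intercept + sum(beta * z)
  }
  phi <- numeric(p)
  idx <- seq_len(p)
  for (j in idx) {
    others <- setdiff(idx, j)
    for (size in 0:length(others)) {
      subsets <- if (size == 0) list(integer(0)) else {
        asplit(utils::combn(others, size), 2)
      }
      w <- factorial(size) * factorial(p - size - 1) / factorial(p)
      for (S in subsets) {
        phi[j] <- phi[j] + w * (f_coal(c(S, j)) - f_coal(S))
      }
    }
  }
  phi
}

# Direct numerical minimisation of the penalised weighted logistic objective
# (ridge on slopes, unpenalised intercept) with a general-purpose optimiser.
fit_by_optim <- function(X, y, w = NULL, C = 1) {
  if (is.null(w)) w <- rep(1, nrow(X))
  obj <- function(theta) {
    eta <- theta[1] + drop(X %*% theta[-1])
    sum(w * (log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta)) +
      sum(theta[-1]^2) / (2 * C)
  }
  fit <- stats::optim(rep(0, ncol(X) + 1), obj,
    method = "BFGS",
    control = list(maxit = 2000, reltol = 1e-14)
  )
  list(intercept = fit$par[1], beta = fit$par[-1])
}

# Holm step-down adjustment straight from its definition.
holm_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  run_max <- 0
  for (i in seq_len(m)) {
    run_max <- max(run_max, min(1, (m - i + 1) * p[o[i]]))
    adj_sorted[i] <- run_max
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# Tiny deterministic two-feature pool for unit tests.
tiny_table <- function() {
  X <- cbind(
    a = c(0.1, 0.3, 0.5, 0.7, 0.9, 0.2),
    b = c(0.9, 0.2, 0.6, 0.1, 0.8, 0.4)
  )
  case_table(X, c(0, 0, 1, 1, 1, 0))
}

write_csv_fixture <- function(df, file = tempfile(fileext = ".csv")) {
  utils::write.csv(df, file, row.names = FALSE)
  file
}
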