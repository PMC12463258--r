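test_that("symmetric balanced data yields a zero intercept", {
  x <- c(0.1, 0.2, 0.3, 0.9, 0.8, 0.7)
  X <- cbind(f = c(x, 1 - x))
  y <- c(rep(0, 6), rep(1, 6))
  fit <- fit_weighted_logistic(X, y)
  # mirrored design around 0.5 with flipped labels: decision f(0.5) = 0
  expect_equal(fit$intercept + 0.5 * fit$coefficients[["f"]], 0,
    tolerance = 1e-6
  )
})

test_that("unit weights reproduce the unweighted fit", {
  tab <- tiny_table()
  f0 <- fit_weighted_logistic(tab$X, tab$y)
  f1 <- fit_weighted_logistic(tab$X, tab$y, weights = rep(1, tab$n))
  expect_equal(f1$coefficients, f0$coefficients, tolerance = 1e-8)
  expect_equal(f1$intercept, f0$intercept, tolerance = 1e-8)
})

test_that("doubling weights while halving C leaves the argmin unchanged", {
  tab <- tiny_table()
  w <- seq(0.5, 3, length.out = tab$n)
  f1 <- fit_weighted_logistic(tab$X, tab$y, weights = w, C = 1)
  f2 <- fit_weighted_logistic(tab$X, tab$y, weights = 2 * w, C = 0.5)
  expect_equal(f2$coefficients, f1$coefficients, tolerance = 1e-5)
  expect_equal(f2$intercept, f1$intercept, tolerance = 1e-5)
})

test_that("fitted coefficients match direct minimisation of the objective", {
  set.seed(7)
  for (rep in 1:6) {
    n <- sample(8:20, 1)
    p <- sample(1:2, 1)
    X <- matrix(runif(n * p), n, dimnames = list(NULL, paste0("x", 1:p)))
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    w <- if (rep %% 2) runif(n, 0.1, 5) else NULL
    C <- sample(c(0.5, 1, 2), 1)
    fit <- fit_weighted_logistic(X, y, weights = w, C = C)
    ref <- fit_by_optim(X, y, w, C)
    expect_equal(unname(fit$coefficients), ref$beta, tolerance = 1e-4)
    expect_equal(fit$intercept, ref$intercept, tolerance = 1e-4)
  }
})

test_that("degenerate and invalid training inputs are rejected", {
  X <- matrix(runif(10), 5, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_weighted_logistic(X, rep(1, 5)), "degenerate")
  expect_error(fit_weighted_logistic(X, c(0, 1, 1, 0, NA)), "non-finite")
  expect_error(
    fit_weighted_logistic(X, c(0, 1, 1, 0, 1), weights = c(1, 1, 1, 1, -1)),
    "positive"
  )
})

test_that("linear attribution matches hand arithmetic and zeroes at the background", {
  model <- structure(
    list(
      coefficients = c(a = 2, b = -1), intercept = 0.3,
      feature_names = c("a", "b"), C = 1, converged = TRUE
    ),
    class = "linear_classifier"
  )
  phi <- linear_shap(model, rbind(c(a = 1, b = 0)), background = c(0.5, 0.5))
  expect_equal(unname(phi[1, ]), c(1.0, 0.5))
  phi0 <- linear_shap(model, rbind(c(a = 0.5, b = 0.5)), background = c(0.5, 0.5))
  expect_equal(unname(phi0[1, ]), c(0, 0))
})

test_that("linear attribution equals brute-force coalition Shapley values", {
  set.seed(21)
  X <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- as.integer(X[, 1] + rnorm(20, sd = 0.3) > 0.5)
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  fit <- fit_weighted_logistic(X, y)
  mu <- colMeans(X)
  phi <- linear_shap(fit, X)
  for (i in seq_len(nrow(X))) {
    oracle <- brute_shapley(unname(fit$coefficients), fit$intercept, X[i, ], mu)
    expect_equal(unname(phi[i, ]), oracle, tolerance = 1e-9)
  }
})

test_that("attributions satisfy local accuracy on every explained row", {
  set.seed(5)
  X <- matrix(runif(80), 16, 5, dimnames = list(NULL, paste0("v", 1:5)))
  y <- rbinom(16, 1, 0.5)
  y[1:2] <- c(0, 1)
  fit <- fit_weighted_logistic(X, y, weights = runif(16, 0.5, 2))
  phi <- linear_shap(fit, X)
  f_mu <- fit$intercept + sum(fit$coefficients * colMeans(X))
  expect_equal(rowSums(phi), decision_function(fit, X) - f_mu,
    tolerance = 1e-9
  )
})

test_that("mean-absolute importance aggregates and ranks deterministically", {
  phi <- cbind(a = c(1, -1, 3), b = c(0, 0, 0), c = c(1, 1, 1))
  rk <- mean_abs_importance(phi)
  expect_equal(rk$importance[["a"]], 5 / 3)
  expect_equal(rk$order, c("a", "c", "b"))
  expect_equal(rk$importance[["b"]], 0)

  tied <- cbind(p = c(1, 1), q = c(-1, -1), r = c(0.5, 0.5))
  expect_equal(mean_abs_importance(tied)$order, c("p", "q", "r"))
  expect_error(mean_abs_importance(matrix(numeric(0), 0, 2)), "non-empty")
})

test_that("importance equals |beta| times mean absolute deviation from the background", {
  set.seed(13)
  X <- matrix(runif(90), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(30, 1, 0.5)
  y[1:2] <- c(0, 1)
  fit <- fit_weighted_logistic(X, y)
  rk <- mean_abs_importance(linear_shap(fit, X))
  mu <- colMeans(X)
  closed <- abs(fit$coefficients) * colMeans(abs(sweep(X, 2, mu)))
  expect_equal(rk$importance, closed, tolerance = 1e-12)
})

test_that("predicted probabilities respect the logistic link and monotonicity", {
  model <- structure(
    list(
      coefficients = c(a = 0, b = 0), intercept = 0,
      feature_names = c("a", "b"), C = 1, converged = TRUE
    ),
    class = "linear_classifier"
  )
  X <- matrix(runif(10), 5, dimnames = list(NULL, c("a", "b")))
  expect_equal(predict_prob(model, X), rep(0.5, 5))

  set.seed(3)
  tab <- tiny_table()
  fit <- fit_weighted_logistic(tab$X, tab$y)
  j <- names(which(fit$coefficients > 0))[1]
  for (i in 1:10) {
    x0 <- matrix(runif(2), 1, dimnames = list(NULL, c("a", "b")))
    x1 <- x0
    x1[, j] <- x1[, j] + runif(1)
    expect_gte(predict_prob(fit, x1), predict_prob(fit, x0))
  }
  expect_error(predict_prob(fit, matrix(1, 1, 3)), "feature column")
})
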