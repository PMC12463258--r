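#' Synthetic benchmark scenarios with region-dependent informative features
#'
#' Generates tabular case pools in which the predictive power of each added
#' feature is confined to a stated interval of a single initial feature
#' `x ~ Uniform(0, 1)`. The outcome `y ~ Bernoulli(0.5)` is independent of
#' `x`. Inside a predictive region with association sign `+1`, the added
#' feature takes the value `0.5 + s * U(margin, 0.5)` with `s = +1` for
#' positive cases and `-1` for negative cases (a `-1` region sign flips
#' `s`), so classes are perfectly separable at 0.5 inside the region;
#' outside its regions a feature is pure `Uniform(0, 1)` noise.
#'
#' The five stock scenarios:
#' \describe{
#'   \item{1}{`A1` predictive on `[0, 0.5)`, `A2` on `(0.5, 1]` --
#'     complementary halves; the ideal case for individualized selection.}
#'   \item{2}{`A1` on `[0, 0.25)` with sign `+` and `[0.25, 0.5)` with sign
#'     `-`; `A2` mirrored on `(0.5, 0.75]` `-` and `(0.75, 1]` `+`. The
#'     association sign flips within each feature's half, so no single
#'     pooled linear fit can use either feature -- locally weighted
#'     inference is required.}
#'   \item{3}{`A1` on `[0, 0.7)`, `A2` on `(0.3, 1]` -- overlapping regions
#'     where both features are equally predictive for `0.3 < x < 0.7`.}
#'   \item{4}{`A1` and `A2` both predictive on all of `[0, 1]` -- identical
#'     regions, so personalisation cannot help.}
#'   \item{5}{`A1` predictive on `[0, 1]` plus two pure-noise features --
#'     one feature dominates everything.}
#' }
#'
#' @param scenario integer 1..5 selecting a stock geometry, or `NULL` to
#'   supply `regions` directly.
#' @param n_samples number of cases (default 1000).
#' @param margin half-gap of the class separation inside predictive regions,
#'   in feature units, `0 < margin < 0.5` (default 0.05).
#' @param seed optional integer seed for reproducible generation.
#' @param regions custom geometry: named list (one element per added
#'   feature) of lists of regions `list(interval = c(lo, hi), sign = +-1)`.
#'   Intervals are half-open `[lo, hi)` except that `hi = 1` is closed.
#' @param n_noise_features extra pure-noise columns appended after the added
#'   features.
#' @param outcome_column name for the outcome column in the generated table.
#' @return A [case_table()] with columns `x`, the added features, any noise
#'   features, in that canonical order.
#' @export
generate_scenario <- function(scenario = 1, n_samples = 1000, margin = 0.05,
                              seed = NULL, regions = NULL,
                              n_noise_features = 0,
                              outcome_column = "class") {
  if (is.null(regions)) {
    geo <- .scenario_geometry(scenario)
    regions <- geo$regions
    n_noise_features <- n_noise_features + geo$n_noise
  }
  .validate_regions(regions)
  if (!is.numeric(margin) || margin <= 0 || margin >= 0.5) {
    stop("`margin` must lie in (0, 0.5)", call. = FALSE)
  }
  if (n_samples < 50) stop("`n_samples` must be at least 50", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  x <- stats::runif(n_samples)
  y <- stats::rbinom(n_samples, 1, 0.5)
  cols <- list(x = x)
  for (feat in names(regions)) {
    a <- stats::runif(n_samples) # noise baseline outside all regions
    for (reg in regions[[feat]]) {
      lo <- reg$interval[1]
      hi <- reg$interval[2]
      inside <- if (hi >= 1) x >= lo & x <= 1 else x >= lo & x < hi
      s <- ifelse(y == 1, 1, -1) * reg$sign
      k <- sum(inside)
      a[inside] <- 0.5 + s[inside] * stats::runif(k, margin, 0.5)
    }
    cols[[feat]] <- a
  }
  if (n_noise_features > 0) {
    for (j in seq_len(n_noise_features)) {
      cols[[paste0("noise", j)]] <- stats::runif(n_samples)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  tab <- case_table(X, y)
  attr(tab, "outcome_column") <- outcome_column
  tab
}

.scenario_geometry <- function(scenario) {
  if (!scenario %in% 1:5) stop("`scenario` must be 1..5", call. = FALSE)
  reg <- function(lo, hi, sign) list(interval = c(lo, hi), sign = sign)
  switch(as.character(scenario),
    "1" = list(regions = list(
      A1 = list(reg(0, 0.5, +1)),
      A2 = list(reg(0.5, 1, +1))
    ), n_noise = 0),
    "2" = list(regions = list(
      A1 = list(reg(0, 0.25, +1), reg(0.25, 0.5, -1)),
      A2 = list(reg(0.5, 0.75, -1), reg(0.75, 1, +1))
    ), n_noise = 0),
    "3" = list(regions = list(
      A1 = list(reg(0, 0.7, +1)),
      A2 = list(reg(0.3, 1, +1))
    ), n_noise = 0),
    "4" = list(regions = list(
      A1 = list(reg(0, 1, +1)),
      A2 = list(reg(0, 1, +1))
    ), n_noise = 0),
    "5" = list(regions = list(
      A1 = list(reg(0, 1, +1))
    ), n_noise = 2)
  )
}

.validate_regions <- function(regions) {
  if (!is.list(regions) || is.null(names(regions)) || !length(regions)) {
    stop("`regions` must be a named list of region lists", call. = FALSE)
  }
  for (feat in names(regions)) {
    for (reg in regions[[feat]]) {
      iv <- reg$interval
      if (length(iv) != 2 || anyNA(iv) || iv[1] < 0 || iv[2] > 1 || iv[1] >= iv[2]) {
        stop("invalid interval for feature '", feat,
          "': intervals must be ordered and inside [0, 1]",
          call. = FALSE
        )
      }
      if (!reg$sign %in% c(-1, 1)) {
        stop("region sign must be +1 or -1", call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Uninformative timing benchmark dataset
#'
#' All features i.i.d. `Uniform(0, 1)` and a `Bernoulli(0.5)` label that is
#' independent of every feature -- a pool used only to measure how the
#' selectors' run time scales with feature count.
#'
#' @param n_samples cases (default 500).
#' @param n_features feature columns (default 100).
#' @param seed optional seed.
#' @return A [case_table()] with features `f1..f<n_features>`.
#' @export
generate_timing <- function(n_samples = 500, n_features = 100, seed = NULL) {
  if (n_features < 1) stop("`n_features` must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(stats::runif(n_samples * n_features),
    nrow = n_samples,
    dimnames = list(NULL, paste0("f", seq_len(n_features)))
  )
  y <- stats::rbinom(n_samples, 1, 0.5)
  case_table(X, y)
}
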