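#' Two-arm metric contrast
#'
#' Mean difference and two-sided t-test p-value between two per-iteration
#' metric vectors. Because arms within one experiment share split seeds,
#' the paired test is the default; `paired = FALSE` gives the two-sample
#' (Welch) test. Degenerate conventions: identical vectors give `p = 1`
#' (no signal); a constant non-zero paired difference gives `p = 0` (the
#' difference is certain under the pairing).
#'
#' @param a,b numeric metric vectors (equal length when `paired`).
#' @param paired use the paired t-test (default `TRUE`).
#' @return List with `difference` (`mean(a) - mean(b)`) and `p`.
#' @export
arm_contrast <- function(a, b, paired = TRUE) {
  if (length(a) < 2 || length(b) < 2) {
    stop("metric vectors must have length >= 2", call. = FALSE)
  }
  if (paired && length(a) != length(b)) {
    stop("paired contrast requires equal-length vectors", call. = FALSE)
  }
  diff <- mean(a) - mean(b)
  near0 <- function(s, scale) s <= 1e-12 * (abs(scale) + 1)
  if (paired) {
    d <- a - b
    if (near0(stats::sd(d), mean(d))) {
      return(list(difference = diff, p = if (abs(diff) < 1e-12) 1 else 0))
    }
    p <- stats::t.test(a, b, paired = TRUE)$p.value
  } else {
    if (near0(stats::sd(a), mean(a)) && near0(stats::sd(b), mean(b))) {
      return(list(difference = diff, p = if (abs(diff) < 1e-12) 1 else 0))
    }
    p <- stats::t.test(a, b, paired = FALSE)$p.value
  }
  list(difference = diff, p = p)
}

#' Holm step-down multiple-testing adjustment
#'
#' Step-down familywise-error control: with the raw p-values sorted
#' ascending, `adj_(i) = max_{j <= i} min(1, (m - j + 1) * p_(j))`,
#' returned in the original order.
#'
#' @param p vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "holm")
}

.star_code <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Pairwise arm contrast table with Holm adjustment
#'
#' Builds the standard four-contrast report for one experiment: iCARE vs
#' Global, iCARE+LW vs Global+LW, iCARE vs iCARE+LW and Global vs
#' Global+LW, on each requested metric. All raw p-values in the table form
#' one Holm family (4 contrasts x metrics), the conservative per-table
#' reading. Star codes: `*` adj-p < 0.05, `**` < 0.01, `***` < 0.001.
#'
#' @param result an `experiment_result` containing the arms involved.
#' @param metrics metric names, subset of `c("accuracy", "auc")`.
#' @param paired passed to [arm_contrast()].
#' @return data.frame of class `contrast_table` with columns `contrast`,
#'   `metric`, `difference`, `p`, `p_holm`, `stars`.
#' @export
contrast_table <- function(result, metrics = c("accuracy", "auc"),
                           paired = TRUE) {
  stopifnot(inherits(result, "experiment_result"))
  metrics <- match.arg(metrics, several.ok = TRUE)
  pairs <- list(
    c("icare", "global"),
    c("icare_lw", "global_lw"),
    c("icare", "icare_lw"),
    c("global", "global_lw")
  )
  have <- names(result$arms)
  rows <- list()
  for (pr in pairs) {
    if (!all(pr %in% have)) next
    for (m in metrics) {
      ct <- arm_contrast(result$arms[[pr[1]]][[m]],
        result$arms[[pr[2]]][[m]],
        paired = paired
      )
      rows[[length(rows) + 1L]] <- data.frame(
        contrast = paste(pr[1], "vs", pr[2]),
        metric = m,
        difference = ct$difference,
        p = ct$p
      )
    }
  }
  if (!length(rows)) {
    stop("no contrastable arm pairs present in `result`", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_holm <- holm_adjust(out$p)
  out$stars <- .star_code(out$p_holm)
  class(out) <- c("contrast_table", "data.frame")
  out
}

#' @export
print.contrast_table <- function(x, digits = 4, ...) {
  cat("contrast_table (paired t-tests, Holm-adjusted family of",
    nrow(x), "tests)\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
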