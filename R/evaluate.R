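#' Select the least-informative initial feature set
#'
#' Emulates the realistic intake situation in which an incoming patient
#' arrives with the *least* informative features: an unweighted classifier
#' is fit on all pool features, attributed with linear Shapley values, and
#' the `k` lowest-ranked features form the initial (observed) set; the rest
#' are the candidates available for recommendation.
#'
#' @param table a [case_table()].
#' @param k number of initial features, `1 <= k < p`.
#' @param C inverse regularisation strength for the ranking fit.
#' @return A `feature_partition` (both sets in canonical column order).
#' @export
select_initial_features <- function(table, k, C = 1) {
  stopifnot(inherits(table, "case_table"))
  if (k < 1 || k >= table$p) {
    stop("`k` must satisfy 1 <= k < number of features (", table$p, ")",
      call. = FALSE
    )
  }
  fit <- fit_weighted_logistic(table$X, table$y, weights = NULL, C = C)
  rk <- mean_abs_importance(linear_shap(fit, table$X))
  initial <- rev(rk$order)[seq_len(k)]
  feature_partition(
    initial = table$feature_names[table$feature_names %in% initial],
    candidate = table$feature_names[!table$feature_names %in% initial]
  )
}

.subset_cases <- function(table, idx) {
  case_table(table$X[idx, , drop = FALSE], table$y[idx],
    scaling = table$scaling
  )
}

.normalise_arms <- function(arms) {
  arms <- gsub("-", "_", tolower(arms))
  ok <- c("global", "global_lw", "icare", "icare_lw")
  bad <- setdiff(arms, ok)
  if (length(bad)) {
    stop("unknown arm(s): ", paste(bad, collapse = ", "),
      "; valid arms are ", paste(ok, collapse = ", "),
      call. = FALSE
    )
  }
  ok[ok %in% arms] # canonical order
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Area under the ROC curve computed as the normalised Mann-Whitney U
#' statistic with midranks for ties: the probability that a random positive
#' case receives a higher score than a random negative one.
#'
#' @param scores numeric prediction scores (e.g. predicted probabilities).
#' @param labels binary labels (0/1), both classes present.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute AUC", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Run one split-evaluate iteration of the recommendation experiment
#'
#' One iteration of the evaluation protocol: (a) a seeded 80/20 split of
#' the pool into training cases and test patients; (b) test patients are
#' stripped down to the initial features; (c) a recommendation is produced
#' -- once per iteration for the global arms, per patient for the
#' individualized arms; (d) the recommended feature's true value is
#' appended to each test patient from the held-out row; (e) an inference
#' classifier on `initial + recommended` predicts each patient -- an
#' ordinary pooled fit for the plain arms, a per-patient inverse-distance
#' weighted fit (weights over `initial + recommended`, since that value has
#' just been acquired) for the `_lw` arms; (f) accuracy at probability
#' threshold 0.5 and rank-based AUC over the whole test set.
#'
#' If a drawn test split contains a single outcome class it is redrawn
#' (deterministically, continuing the seeded RNG stream) and a message is
#' emitted; a single-class training split is an error.
#'
#' @param table a [case_table()].
#' @param partition `feature_partition` defining initial vs candidate
#'   features.
#' @param arms subset of `c("global", "global_lw", "icare", "icare_lw")`.
#' @param seed integer seed for the split.
#' @param test_fraction held-out fraction (default 0.2).
#' @param C inverse regularisation strength used by every fit.
#' @param max_resample redraw limit for single-class test splits.
#' @return List with per-arm `accuracy`, `auc` and recommendation `tally`,
#'   plus `ceiling` (all-features reference fit) and the realised `test_idx`.
#' @export
run_iteration <- function(table, partition, arms = c("global", "icare"),
                          seed = 1, test_fraction = 0.2, C = 1,
                          max_resample = 25) {
  stopifnot(inherits(table, "case_table"), inherits(partition, "feature_partition"))
  arms <- .normalise_arms(arms)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("`test_fraction` must lie in (0, 1)", call. = FALSE)
  }
  n_test <- max(1L, round(table$n * test_fraction))

  set.seed(seed)
  for (attempt in seq_len(max_resample)) {
    test_idx <- sort(sample.int(table$n, n_test))
    if (length(unique(table$y[test_idx])) == 2L) break
    message("single-class test split (seed ", seed, "); redrawing")
    if (attempt == max_resample) {
      stop("could not draw a two-class test split", call. = FALSE)
    }
  }
  train_idx <- setdiff(seq_len(table$n), test_idx)
  if (length(unique(table$y[train_idx])) < 2L) {
    stop("single-class training split for seed ", seed, call. = FALSE)
  }
  train <- .subset_cases(table, train_idx)
  y_test <- table$y[test_idx]
  initial <- partition$initial

  # recommendations ---------------------------------------------------------
  rec_for <- list()
  if (any(arms %in% c("global", "global_lw"))) {
    rec_g <- global_recommend(train, partition, C = C)$recommended
    rec_for$global <- rep(rec_g, n_test)
  }
  if (any(arms %in% c("icare", "icare_lw"))) {
    rec_for$icare <- vapply(test_idx, function(i) {
      q <- patient_query(stats::setNames(
        table$X[i, initial],
        initial
      ))
      icare_recommend(train, q, C = C)$recommended
    }, character(1))
  }

  # inference ----------------------------------------------------------------
  plain_cache <- new.env(parent = emptyenv())
  plain_fit <- function(cols) {
    key <- paste(cols, collapse = "\r")
    if (is.null(plain_cache[[key]])) {
      plain_cache[[key]] <- fit_weighted_logistic(
        train$X[, cols, drop = FALSE], train$y,
        weights = NULL, C = C
      )
    }
    plain_cache[[key]]
  }

  predict_arm <- function(recs, weighted) {
    probs <- numeric(n_test)
    for (j in seq_len(n_test)) {
      cols <- c(initial, recs[j][!is.na(recs[j])])
      xrow <- table$X[test_idx[j], cols, drop = FALSE]
      fit <- if (weighted) {
        q <- patient_query(stats::setNames(as.numeric(xrow), cols))
        w <- case_weights(q, train, subset = cols)
        fit_weighted_logistic(train$X[, cols, drop = FALSE], train$y,
          weights = w, C = C
        )
      } else {
        plain_fit(cols)
      }
      probs[j] <- predict_prob(fit, xrow)
    }
    probs
  }

  out <- list()
  for (arm in arms) {
    mode <- if (startsWith(arm, "global")) "global" else "icare"
    recs <- rec_for[[mode]]
    probs <- predict_arm(recs, weighted = endsWith(arm, "_lw"))
    tally_src <- if (mode == "global") recs[1L] else recs
    tally_src <- tally_src[!is.na(tally_src)]
    out[[arm]] <- list(
      accuracy = mean((probs > 0.5) == y_test),
      auc = rank_auc(probs, y_test),
      tally = if (length(tally_src)) table(tally_src) else table(character(0)),
      probs = probs
    )
  }

  ceiling_fit <- fit_weighted_logistic(train$X, train$y, weights = NULL, C = C)
  ceil_probs <- predict_prob(ceiling_fit, table$X[test_idx, , drop = FALSE])
  list(
    arms = out,
    ceiling = list(
      accuracy = mean((ceil_probs > 0.5) == y_test),
      auc = rank_auc(ceil_probs, y_test)
    ),
    test_idx = test_idx,
    seed = seed
  )
}

#' Run the full repeated-split recommendation experiment
#'
#' Repeats [run_iteration()] `n_iterations` times with seeds
#' `seed, seed + 1, ..., seed + n_iterations - 1` and aggregates
#' per-iteration accuracy and AUC for every arm, the recommendation
#' tallies, and the ceiling reference (an all-features classifier refit on
#' each split).
#'
#' @inheritParams run_iteration
#' @param k_initial number of (least informative) initial features; ignored
#'   when `partition` is supplied.
#' @param n_iterations number of repeated splits (default 100).
#' @param partition optional pre-computed `feature_partition`; by default
#'   [select_initial_features()] is applied to the full table.
#' @param verbose emit a progress message every 25 iterations.
#' @return An object of class `experiment_result`: per-arm per-iteration
#'   metric vectors and summed tallies, ceiling vectors, the partition and
#'   the configuration.
#' @export
run_experiment <- function(table, k_initial = 1,
                           arms = c("global", "global_lw", "icare", "icare_lw"),
                           n_iterations = 100, seed = 1, test_fraction = 0.2,
                           C = 1, partition = NULL, verbose = FALSE) {
  stopifnot(inherits(table, "case_table"))
  arms <- .normalise_arms(arms)
  if (n_iterations < 1) stop("`n_iterations` must be >= 1", call. = FALSE)
  if (is.null(partition)) {
    partition <- select_initial_features(table, k_initial, C = C)
  }

  acc <- matrix(NA_real_, n_iterations, length(arms), dimnames = list(NULL, arms))
  auc <- acc
  ceil_acc <- numeric(n_iterations)
  ceil_auc <- numeric(n_iterations)
  tallies <- stats::setNames(
    rep(list(numeric(0)), length(arms)), arms
  )

  for (i in seq_len(n_iterations)) {
    it <- run_iteration(table, partition, arms,
      seed = seed + i - 1L,
      test_fraction = test_fraction, C = C
    )
    for (arm in arms) {
      acc[i, arm] <- it$arms[[arm]]$accuracy
      auc[i, arm] <- it$arms[[arm]]$auc
      tl <- it$arms[[arm]]$tally
      merged <- tallies[[arm]]
      for (f in names(tl)) {
        merged[f] <- (if (f %in% names(merged)) merged[f] else 0) + tl[[f]]
      }
      tallies[[arm]] <- merged
    }
    ceil_acc[i] <- it$ceiling$accuracy
    ceil_auc[i] <- it$ceiling$auc
    if (verbose && i %% 25 == 0) {
      message("iteration ", i, "/", n_iterations)
    }
  }

  arms_out <- lapply(stats::setNames(arms, arms), function(arm) {
    list(
      accuracy = as.numeric(acc[, arm]), auc = as.numeric(auc[, arm]),
      tally = tallies[[arm]]
    )
  })
  structure(
    list(
      arms = arms_out,
      ceiling = list(accuracy = ceil_acc, auc = ceil_auc),
      partition = partition,
      config = list(
        k_initial = length(partition$initial), arms = arms,
        n_iterations = n_iterations, seed = seed,
        test_fraction = test_fraction, C = C
      )
    ),
    class = "experiment_result"
  )
}

#' @export
summary.experiment_result <- function(object, ...) {
  rows <- lapply(names(object$arms), function(arm) {
    a <- object$arms[[arm]]
    data.frame(
      arm = arm,
      mean_accuracy = mean(a$accuracy), sd_accuracy = stats::sd(a$accuracy),
      mean_auc = mean(a$auc), sd_auc = stats::sd(a$auc)
    )
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(
    arm = "ceiling",
    mean_accuracy = mean(object$ceiling$accuracy),
    sd_accuracy = stats::sd(object$ceiling$accuracy),
    mean_auc = mean(object$ceiling$auc),
    sd_auc = stats::sd(object$ceiling$auc)
  ))
  rownames(out) <- NULL
  out
}

#' @export
print.experiment_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "experiment_result: %d iterations, %d initial feature(s), arms: %s\n",
    cfg$n_iterations, cfg$k_initial, paste(cfg$arms, collapse = ", ")
  ))
  cat("initial features:", paste(x$partition$initial, collapse = ", "), "\n\n")
  print(summary(x), digits = 4)
  invisible(x)
}

#' Repeat the experiment over several initial-feature-set sizes
#'
#' Runs [run_experiment()] once per value of `k`, with identical seeds
#' across the sweep so that contrasts between sizes are paired.
#'
#' @inheritParams run_experiment
#' @param k_values integer vector of initial-set sizes (each `< p`).
#' @return Named list of `experiment_result`, one per `k`.
#' @export
sweep_initial_features <- function(table, k_values,
                                   arms = c("global", "global_lw", "icare", "icare_lw"),
                                   n_iterations = 100, seed = 1,
                                   test_fraction = 0.2, C = 1,
                                   verbose = FALSE) {
  out <- list()
  for (k in k_values) {
    out[[paste0("k", k)]] <- run_experiment(
      table,
      k_initial = k, arms = arms, n_iterations = n_iterations,
      seed = seed, test_fraction = test_fraction, C = C, verbose = verbose
    )
  }
  out
}
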