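test_that("forward selection scores the dominant feature first", {
  tab5 <- generate_scenario(5, n_samples = 300, seed = 15)
  part <- identify_missing("x", tab5) # candidates: A1, noise1, noise2
  sel <- sfs_select(tab5, part, seed = 1)
  expect_equal(sel$feature[1], "A1")
  expect_gt(sel$score[1], max(sel$score[-1]) + 0.2)

  one <- sfs_select(tab5, feature_partition(
    c("x", "noise1", "noise2"), "A1"
  ), seed = 1)
  expect_equal(one$feature, "A1")
})

test_that("duplicated candidate columns tie and break canonically in forward selection", {
  set.seed(8)
  a <- runif(150)
  y <- as.integer(a > 0.5)
  tab <- case_table(cbind(x = runif(150), A1 = a, A2 = a), y)
  part <- identify_missing("x", tab)
  sel <- sfs_select(tab, part, seed = 2)
  expect_equal(sel$score[1], sel$score[2]) # identical columns, identical CV
  expect_equal(sel$feature, c("A1", "A2")) # canonical tie-break
})

test_that("the lasso path shrinks noise before the dominant feature", {
  tab5 <- generate_scenario(5, n_samples = 500, seed = 25)
  part <- identify_missing(c("x", "noise1", "noise2"), tab5)
  sel <- lasso_select(tab5, part, seed = 3)
  expect_equal(sel$feature[1], "A1")

  full <- identify_missing("x", tab5)
  at_cv <- lasso_select(tab5, full, seed = 3)
  noise_scores <- at_cv$score[at_cv$feature %in% c("noise1", "noise2")]
  a1_score <- at_cv$score[at_cv$feature == "A1"]
  expect_true(all(noise_scores < 0.2 * a1_score))
})

test_that("a vanishing penalty recovers the unpenalised coefficient ordering", {
  tab <- generate_scenario(3, n_samples = 400, seed = 33)
  part <- identify_missing("x", tab)
  sel <- lasso_select(tab, part, penalty = 1e-6)
  ref <- fit_weighted_logistic(tab$X, tab$y, C = 1e6) # effectively unpenalised
  ref_order <- names(sort(-abs(ref$coefficients[part$candidate])))
  expect_equal(sel$feature, ref_order)
})

test_that("explanation-guided selection reduces to the pool case when the query matches it", {
  tab <- generate_scenario(1, n_samples = 100, seed = 12)
  i <- 17
  q <- patient_query(x = tab$X[i, "x"])
  sel <- eguided_select(tab, q, k_similar = 1, n_imputations = 1, seed = 5)
  # with one neighbour and one imputation, the imputed record IS that case,
  # so candidate scores equal |phi| of the global model at that case
  fit <- fit_weighted_logistic(tab$X, tab$y)
  nbr <- which.min(abs(tab$X[, "x"] - tab$X[i, "x"]))
  phi <- linear_shap(fit, tab$X[nbr, , drop = FALSE],
    background = colMeans(tab$X)
  )
  expect_equal(
    sort(sel$score),
    sort(unname(abs(phi[1, c("A1", "A2")]))),
    tolerance = 1e-12
  )
})

test_that("explanation-guided selection follows the local regime", {
  hits <- 0
  for (s in 1:10) {
    tab <- generate_scenario(1, n_samples = 500, margin = 0.05, seed = 200 + s)
    sel <- eguided_select(tab, patient_query(x = 0.25),
      k_similar = 100,
      n_imputations = 20, seed = s
    )
    hits <- hits + (sel$feature[1] == "A1")
  }
  expect_gte(hits, 9)
})

test_that("selector inputs are validated", {
  tab <- generate_scenario(1, n_samples = 100, seed = 1)
  q <- patient_query(x = 0.5)
  expect_error(eguided_select(tab, q, n_imputations = 0), "n_imputations")
  expect_error(eguided_select(tab, q, k_similar = 1000), "k_similar")
  expect_error(
    sfs_select(tab, feature_partition(tab$feature_names, character(0))),
    "candidate"
  )
})

test_that("selector rankings are stable under pool row shuffling", {
  tab5 <- generate_scenario(5, n_samples = 400, seed = 44)
  set.seed(99)
  perm <- sample(tab5$n)
  shuf <- case_table(tab5$X[perm, ], tab5$y[perm])
  part <- identify_missing(c("x", "noise1", "noise2"), tab5)
  q <- patient_query(x = 0.4)

  expect_equal(
    lasso_select(tab5, part, seed = 6)$feature,
    lasso_select(shuf, part, seed = 6)$feature
  )
  expect_equal(
    sfs_select(tab5, part, seed = 6)$feature,
    sfs_select(shuf, part, seed = 6)$feature
  )
  expect_equal(
    eguided_select(tab5, q, k_similar = 50, n_imputations = 15, seed = 6)$score,
    eguided_select(shuf, q, k_similar = 50, n_imputations = 15, seed = 6)$score,
    tolerance = 1e-10
  )
})

test_that("all selectors agree on the dominant feature", {
  tab5 <- generate_scenario(5, n_samples = 400, seed = 55)
  part <- identify_missing(c("x", "noise1", "noise2"), tab5)
  q <- patient_query(x = 0.6, noise1 = 0.2, noise2 = 0.8)
  picks <- c(
    global_recommend(tab5, part)$recommended,
    icare_recommend(tab5, q)$recommended,
    sfs_select(tab5, part, seed = 1)$feature[1],
    lasso_select(tab5, part, seed = 1)$feature[1],
    eguided_select(tab5, q, k_similar = 80, n_imputations = 20, seed = 1)$feature[1]
  )
  expect_true(all(picks == "A1"))
})
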