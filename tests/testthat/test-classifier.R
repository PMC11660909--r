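test_that("rank-based AUC matches pair counting and the Mann-Whitney U", {
  s <- c(0.9, 0.8, 0.3, 0.2); y <- c(1, 0, 1, 0)
  # pairs: (0.9 vs 0.8) win, (0.9 vs 0.2) win, (0.3 vs 0.8) loss,
  # (0.3 vs 0.2) win -> 3/4
  expect_equal(auc_roc(s, y), 0.75)
  expect_equal(auc_roc(y, y), 1)
  expect_equal(auc_roc(-y, y), 0)

  set.seed(2)
  s2 <- rnorm(60); y2 <- rbinom(60, 1, 0.4)
  mw <- mann_whitney(s2[y2 == 1], s2[y2 == 0])
  expect_equal(auc_roc(s2, y2), mw$U / (sum(y2) * sum(1 - y2)))
  expect_error(auc_roc(s2, rep(1, 60)), "single class")
})

test_that("precision-recall AUC integrates the step curve", {
  expect_equal(auc_pr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # hand case: order y = 1,0,1,0 -> precision at recalls .5 and 1:
  # 1 and 2/3 -> AUC = .5*1 + .5*2/3
  expect_equal(auc_pr(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)),
               0.5 + 0.5 * 2 / 3)
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(8)
    s <- rnorm(100); y <- rbinom(100, 1, 0.5)
    ref <- pROC::auc(pROC::roc(y, s, quiet = TRUE))
    expect_equal(auc_roc(s, y), as.numeric(ref), tolerance = 1e-10)
  }
})

test_that("nested CV scores separable data perfectly and permuted labels at chance", {
  set.seed(31)
  n <- 160
  X <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- as.integer(X$a > 0)
  cvc <- cv_config(outer_folds = 4, inner_folds = 3, repeats = 2,
                   search_budget = 3, seed = 5)
  rep_sep <- nested_cv(X, y, cvc)
  expect_equal(rep_sep$auc_roc_mean, 1, tolerance = 0.005)

  y_perm <- sample(y)
  rep_null <- nested_cv(X, y_perm, cvc)
  expect_lt(abs(rep_null$auc_roc_mean - 0.5), 0.12)
  expect_error(nested_cv(X[1:6, ], y[1:6], cvc), "per class")
})

test_that("baseline features at configured effect sizes give moderate discrimination", {
  sim <- simulate_cohort(cohort_config(n_patients = 400, seed = 42))
  lab <- as.integer(sim$cohort$truth$true_label == "fast")
  cvc <- cv_config(outer_folds = 4, inner_folds = 3, repeats = 2,
                   search_budget = 4, seed = 9)
  rep <- nested_cv(sim$baseline, lab, cvc)
  expect_gt(rep$auc_roc_mean, 0.6)
  expect_lt(rep$auc_roc_mean, 0.8)
  expect_equal(rep$prevalence, mean(lab))
})

test_that("label noise monotonically degrades cross-validated discrimination", {
  set.seed(77)
  n <- 200
  X <- tibble::tibble(a = rnorm(n), b = rnorm(n))
  y <- as.integer(X$a + 0.5 * rnorm(n) > 0)
  cvc <- cv_config(outer_folds = 3, inner_folds = 3, repeats = 2,
                   search_budget = 2, seed = 3)
  aucs <- vapply(c(0, 0.2, 0.4), function(noise) {
    yy <- y
    flip <- runif(n) < noise
    yy[flip] <- 1L - yy[flip]
    nested_cv(X, yy, cvc)$auc_roc_mean
  }, numeric(1))
  expect_true(all(diff(aucs) < 0))
})

test_that("final model training is deterministic and handles missing values", {
  sim <- simulate_cohort(cohort_config(n_patients = 150, seed = 51))
  lab <- as.integer(sim$cohort$truth$true_label == "fast")
  base <- sim$baseline
  base$mmse[1:10] <- NA  # missing at fit time is accepted

  m1 <- train_final(base, lab, seed = 4)
  m2 <- train_final(base, lab, seed = 4)
  expect_identical(predict_proba(m1, base), predict_proba(m2, base))

  p <- predict_proba(m1, base)
  expect_true(all(p >= 0 & p <= 1))

  # column reordering leaves predictions unchanged
  shuffled <- base[, c("patient_id", rev(setdiff(names(base), "patient_id")))]
  expect_equal(predict_proba(m1, shuffled), p)

  # an all-missing row still yields a valid probability
  row_na <- base[1, ]
  row_na[, setdiff(names(row_na), "patient_id")] <- NA
  p_na <- predict_proba(m1, row_na)
  expect_true(p_na >= 0 && p_na <= 1)

  extra <- base; extra$unknown_feature <- 1
  expect_error(predict_proba(m1, extra), "unknown feature")
  missing_col <- base; missing_col$age <- NULL
  expect_error(predict_proba(m1, missing_col), "missing feature")
})

test_that("a single perfectly predictive feature yields monotone probabilities", {
  set.seed(13)
  X <- tibble::tibble(a = sort(rnorm(100)))
  y <- as.integer(X$a > 0)
  m <- train_final(X, y, params = list(max_depth = 2, nrounds = 60), seed = 2)
  p <- predict_proba(m, X)
  expect_gt(auc_roc(p, y), 0.99)
  expect_true(all(diff(p) > -1e-6))
})

test_that("training-data optimism bounds CV performance from above", {
  sim <- simulate_cohort(cohort_config(n_patients = 300, seed = 61))
  lab <- as.integer(sim$cohort$truth$true_label == "fast")
  cvc <- cv_config(outer_folds = 4, inner_folds = 3, repeats = 1,
                   search_budget = 3, seed = 8)
  cv <- nested_cv(sim$baseline, lab, cvc)
  m <- train_final(sim$baseline, lab, seed = 8)
  train_auc <- auc_roc(predict_proba(m, sim$baseline), lab)
  expect_gte(train_auc, cv$auc_roc_mean)
  ev <- external_validate(m, sim$baseline, lab)
  expect_equal(ev$auc_roc, train_auc)
  expect_error(external_validate(m, sim$baseline, rep(1, 300)),
               "single class")
})
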