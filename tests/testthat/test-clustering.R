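# Model fitting, assignment, reconstruction and the cluster-evaluation
# machinery. Fits use the sharply separated planted cohort so that single
# runs are reliable at small n.

planted <- make_planted(120, seed = 101)
cfg_fit <- fast_training(seed = 7)
model <- fit_model(planted$tensor, cfg_fit)
assn <- assign_subgroups(model, planted$tensor)

test_that("planted well-separated clusters are recovered near-perfectly", {
  expect_gte(adjusted_rand_index(assn$label, planted$truth), 0.9)
  # responsibilities near-binary and a valid simplex
  expect_equal(rowSums(assn$responsibilities), rep(1, 120), tolerance = 1e-8)
  expect_gt(mean(apply(assn$responsibilities, 1, max) > 0.9), 0.9)
  expect_identical(assn$label, max.col(assn$responsibilities,
                                       ties.method = "first"))
  # semantic tag: fast component has the larger CDRSB worsening
  ch <- progenrich:::observed_change(planted$tensor, "cdrsb")
  expect_gt(mean(ch[assn$semantic_label == "fast"], na.rm = TRUE),
            mean(ch[assn$semantic_label == "slow"], na.rm = TRUE))
})

test_that("fitting is deterministic and assignment idempotent", {
  cfg1 <- fast_training(seed = 13, n_init = 1, epochs = 40,
                        pretrain_epochs = 40)
  m1 <- fit_model(planted$tensor, cfg1)
  m2 <- fit_model(planted$tensor, cfg1)
  expect_identical(m1$final_loss, m2$final_loss)
  expect_identical(m1$params, m2$params)
  a1 <- assign_subgroups(m1, planted$tensor)
  a2 <- assign_subgroups(m1, planted$tensor)
  expect_identical(a1$label, a2$label)
})

test_that("k = 1 reduces to a unimodal prior with a constant assignment", {
  cfg1 <- fast_training(seed = 5, k = 1, epochs = 30, pretrain_epochs = 30,
                        n_init = 1)
  m <- fit_model(planted$tensor, cfg1)
  a <- assign_subgroups(m, planted$tensor)
  expect_true(all(a$label == 1))
  expect_equal(m$mixture$pi, 1)
})

test_that("k > n and incompatible data are rejected", {
  small <- progenrich:::subset_tensor(planted$tensor, 1:3)
  expect_error(fit_model(small, training_config(k = 5)), "exceeds")
  bad <- planted$tensor
  bad$scores <- c("a", "b", "c")
  expect_error(assign_subgroups(model, bad), "score dimensions")
})

test_that("masked cells never influence training", {
  d <- make_planted(60, seed = 301, missing = 0.25)
  t1 <- d$tensor
  t2 <- t1
  t2$values[t2$mask == 0] <- 99  # garbage behind the mask
  cfg <- fast_training(seed = 3, epochs = 30, pretrain_epochs = 30,
                       n_init = 1)
  m1 <- fit_model(t1, cfg)
  m2 <- fit_model(t2, cfg)
  expect_identical(m1$final_loss, m2$final_loss)
  expect_identical(m1$params, m2$params)
})

test_that("reconstruction passes observed cells through and imputes the rest", {
  # fully observed: output equals input everywhere
  d0 <- make_planted(50, seed = 121, missing = 0)
  cfg <- fast_training(seed = 9, epochs = 30, pretrain_epochs = 30,
                       n_init = 1)
  m0 <- fit_model(d0$tensor, cfg)
  rec0 <- reconstruct(m0, d0$tensor)
  orig <- progenrich:::destandardize(d0$tensor, d0$tensor$values)
  expect_equal(unclass(rec0)[seq_along(orig)], as.vector(orig),
               tolerance = 1e-10)

  # hide 20% of cells of a noise-free cohort; imputation beats cohort SD
  specs <- sharp_specs()
  for (g in names(specs)) {
    specs[[g]]$traj_sd[] <- 1e-3
    specs[[g]]$visit_noise_sd[] <- 1e-3
  }
  d <- make_planted(100, seed = 122, specs = specs, missing = 0)
  full <- d$tensor
  set.seed(5)
  hide <- array(runif(length(full$mask)) < 0.2, dim = dim(full$mask))
  hide[, 1, ] <- FALSE
  masked <- full
  masked$mask[hide] <- 0
  masked$values[hide] <- 0
  m <- fit_model(masked, fast_training(seed = 10))
  rec <- reconstruct(m, masked)
  truth <- progenrich:::destandardize(full, full$values)
  for (dd in 1:3) {
    h <- hide[, , dd]
    rmse <- sqrt(mean((rec[, , dd][h] - truth[, , dd][h])^2))
    cohort_sd <- sd(truth[, , dd])
    expect_lt(rmse, cohort_sd)
  }
})

test_that("prediction strength is 1 at k = 1 and bounded in [0, 1]", {
  expect_equal(prediction_strength(planted$tensor, 1, cfg_fit, n_splits = 4),
               rep(1, 4))
  expect_equal(random_null(planted$tensor, 1, 5), rep(1, 5))
})

test_that("the pairwise co-assignment statistic matches hand enumeration", {
  ps <- progenrich:::ps_pairs
  # two tight pairs, deterministic assigner: perfect agreement
  expect_equal(ps(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(ps(c(2, 2, 1, 1), c(1, 1, 2, 2)), 1)  # label-permutation
  # one swapped point: cluster 1 of cl has pairs (1,2),(1,3),(2,3); ref
  # co-assigns only (1,2) -> 2/6 ordered; cluster 2 is a singleton -> 1
  expect_equal(ps(c(1, 1, 2, 2), c(1, 1, 1, 2)), 1 / 3)
  # singleton-only clusters contribute 1 by convention
  expect_equal(ps(c(1, 2, 3), c(1, 2, 3)), 1)
})

test_that("the random null matches exhaustive enumeration at n = 6, k = 2", {
  # all balanced labelings of 6 items into 3+3
  combs <- utils::combn(6, 3)
  labs <- apply(combs, 2, function(ix) {
    l <- rep(2L, 6); l[ix] <- 1L; l
  })
  ps <- progenrich:::ps_pairs
  vals <- c()
  for (i in seq_len(ncol(labs))) for (j in seq_len(ncol(labs))) {
    vals <- c(vals, ps(labs[, i], labs[, j]))
  }
  exact_mean <- mean(vals)
  t6 <- iso_tensor(12, 3)  # halves of size 6
  draws <- random_null(t6, 2, 4000, seed = 8)
  expect_lt(abs(mean(draws) - exact_mean), 3 * sd(draws) / sqrt(4000))
  expect_error(random_null(t6, 2, 0), "n_draws")
})

test_that("label alignment finds the optimal permutation", {
  ref <- c(1L, 1L, 2L, 2L)
  perm <- align_labels(ref, c(2L, 2L, 1L, 1L))
  expect_equal(as.integer(perm), c(2L, 1L))
  expect_equal(attr(perm, "agreement"), 1)
  expect_equal(as.integer(align_labels(ref, ref)), c(1L, 2L))
  # random case vs brute force over both permutations of k = 2
  set.seed(4)
  for (i in 1:20) {
    a <- sample(1:2, 4, replace = TRUE)
    b <- sample(1:2, 4, replace = TRUE)
    if (max(a) < 2 || max(b) < 2) next
    best <- max(mean(a == b), mean(a == c(2L, 1L)[b]))
    expect_equal(attr(align_labels(a, b), "agreement"), best)
  }
  expect_error(align_labels(assn, manual_assignment(assn$patient_id,
                                                    rep(1L, 120))),
               "different k|patients")
})

test_that("consensus reproduces unanimous input and outvotes noise", {
  mk <- function(lab) manual_assignment(planted$tensor$patient_id, lab)
  truth_int <- ifelse(planted$truth == "fast", 2L, 1L)
  unanimous <- replicate(10, mk(truth_int), simplify = FALSE)
  cons <- consensus(unanimous, 2, data = planted$tensor)
  expect_equal(cons$label, truth_int)

  # 9 identical + 1 label-permuted: consensus equals the majority
  flipped <- mk(3L - truth_int)
  cons2 <- consensus(c(unanimous[1:9], list(flipped)), 2,
                     data = planted$tensor)
  expect_gte(attr(align_labels(truth_int, cons2), "agreement"), 1)

  # independent 10% label noise per repeat: consensus beats single repeats
  set.seed(6)
  noisy <- lapply(1:15, function(r) {
    l <- truth_int
    flip <- runif(length(l)) < 0.1
    l[flip] <- 3L - l[flip]
    mk(l)
  })
  cons3 <- consensus(noisy, 2, data = planted$tensor)
  single_ari <- median(vapply(noisy, function(a) {
    adjusted_rand_index(a$label, truth_int)
  }, numeric(1)))
  expect_gt(adjusted_rand_index(cons3$label, truth_int), single_ari)

  bad <- mk(truth_int)
  bad$patient_id <- rev(bad$patient_id)
  expect_error(consensus(list(unanimous[[1]], bad), 2), "inconsistent")
})

test_that("select_k validates its inputs", {
  expect_error(select_k(planted$tensor, 1:2, cfg_fit), "start at 2")
  expect_error(select_k(planted$tensor, 2, cfg_fit, n_splits = 1),
               "at least 2")
})
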