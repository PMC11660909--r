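test_that("threshold retention follows the strict-inequality rule", {
  expect_equal(apply_threshold(c(0.6, 0.7, 0.66), 0.65), c(2, 3))
  expect_equal(apply_threshold(c(0.2, 0.8), 0), 1:2)
  expect_equal(length(apply_threshold(c(0.2, 0.8), 1)), 0)
  expect_error(apply_threshold(c(0.5), 1.2), "threshold")
  expect_error(apply_threshold(c(1.5), 0.5), "probabilities")
})

test_that("treatment emulation scales worseners only and exactly", {
  expect_equal(simulate_treatment(c(4, 0, -1), 0.27), c(2.92, 0, -1))
  ch <- c(3.5, -2, 0, 1.2)
  expect_identical(simulate_treatment(ch, 0), ch)
  e1 <- simulate_treatment(ch, 1)
  expect_equal(e1, c(0, -2, 0, 0))
  # non-worseners bit-identical, never increased
  set.seed(5)
  ch2 <- rnorm(200)
  out <- simulate_treatment(ch2, 0.27)
  expect_identical(out[ch2 <= 0], ch2[ch2 <= 0])
  expect_true(all(out <= ch2 + 1e-12))
  expect_error(effect_spec(relative_effect = 1.2), "relative_effect")
})

test_that("Cohen's d matches hand arithmetic and large-sample limits", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  x <- c(1, 2, 6); y <- c(2, 4, 9)
  sp <- sqrt((2 * var(x) + 2 * var(y)) / 4)
  expect_equal(cohens_d(x, y), (3 - 5) / sp)
  set.seed(9)
  big <- cohens_d(rnorm(1e5, 1), rnorm(1e5, 0.5))
  expect_equal(big, 0.5, tolerance = 0.02)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "zero pooled SD")
  expect_error(cohens_d(1, c(1, 2)), ">= 2")
})

test_that("required sample size solves the noncentral-t power condition", {
  expect_equal(required_n_per_arm(0.5), 86L)
  # closed-form normal approximation within +2 across the d grid
  for (d in seq(0.2, 1.0, by = 0.1)) {
    approx_n <- 2 * (qnorm(0.975) + qnorm(0.9))^2 / d^2
    exact_n <- required_n_per_arm(d)
    expect_gte(exact_n, floor(approx_n))
    expect_lte(exact_n, approx_n + 2)
  }
  # 1/d^2 scaling and monotonicity in power
  expect_lt(abs(required_n_per_arm(0.25) / required_n_per_arm(0.5) - 4), 0.2)
  expect_gt(required_n_per_arm(0.5, power_spec(power = 0.999)),
            required_n_per_arm(0.5, power_spec(power = 0.90)))
  expect_warning(n_inf <- required_n_per_arm(0), "infinite")
  expect_identical(n_inf, Inf)
  expect_error(power_spec(alpha = 0), "alpha")
})

test_that("enrichment curve reflects classifier quality", {
  set.seed(21)
  y <- rbinom(400, 1, 0.6)
  # oracle: p_fast equals the label
  ec <- enrichment_curve(as.numeric(y), y, thresholds = c(0.3, 0.65))
  expect_equal(ec$fast_fraction, c(1, 1))
  expect_equal(ec$retained_fraction, rep(mean(y), 2))
  # independent scores: fast fraction stays near prevalence
  p_ind <- runif(400)
  ec2 <- enrichment_curve(p_ind, y, thresholds = c(0.4, 0.6))
  expect_lt(max(abs(ec2$fast_fraction - mean(y))), 3 * sqrt(0.24 / 150))
  # repeats produce a CI
  pm <- cbind(p_ind, pmin(pmax(p_ind + rnorm(400, 0, 0.05), 0), 1))
  ec3 <- enrichment_curve(pm, y, thresholds = 0.5)
  expect_true(is.finite(ec3$fast_lo) && ec3$fast_lo <= ec3$fast_fraction)
})

test_that("horizon changes use the observed visit or the fitted slope", {
  cohort <- make_planted(80, seed = 71, missing = 0)$cohort
  ch <- horizon_changes(cohort, "cdrsb", 24)
  expect_true(all(ch$source == "observed"))
  v <- cohort$visits
  p1 <- v[v$patient_id == ch$patient_id[1], ]
  expect_equal(ch$change[1],
               p1$cdrsb[p1$month == 24] - p1$cdrsb[p1$month == 0])

  # remove the month-24 visit of one patient -> least-squares carry-forward
  v2 <- v[!(v$patient_id == ch$patient_id[1] & v$month == 24), ]
  cohort2 <- cohort
  cohort2$visits <- v2
  ch2 <- horizon_changes(cohort2, "cdrsb", 24)
  expect_equal(ch2$source[1], "interpolated")
  sub <- v2[v2$patient_id == ch$patient_id[1] & v2$month <= 24, ]
  slope <- unname(coef(lm(sub$cdrsb ~ sub$month))[2])
  expect_equal(ch2$change[1], slope * 24)
})

test_that("sample-size reduction behaves as the power analysis dictates", {
  set.seed(31)
  n <- 300
  truth <- rbinom(n, 1, 0.6)
  # cohort where only fast patients worsen
  months <- seq(0, 36, 6)
  visits <- tibble::tibble(
    patient_id = rep(sprintf("P%03d", 1:n), each = length(months)),
    month = rep(months, n),
    mmse = 25, faq = 10,
    cdrsb = 4 + rep(truth * 4, each = length(months)) *
      rep(months / 36, n) + rnorm(n * length(months), 0, 0.3)
  )
  visits$cdrsb <- pmin(pmax(visits$cdrsb, 0), 18)
  cohort <- progenrich:::new_longitudinal_cohort(
    visits, tibble::tibble(patient_id = sprintf("P%03d", 1:n),
                           true_label = ifelse(truth == 1, "fast", "slow")),
    months)

  # oracle classifier: strictly positive reduction at tau = 0.65
  p_oracle <- ifelse(truth == 1, 0.95, 0.05)
  rc <- reduction_curve(cohort, p_oracle, thresholds = c(0.65))
  expect_gt(rc$reduction_pct, 0)

  # direct power computation agrees with the curve's required n
  ch <- horizon_changes(cohort, "cdrsb", 24)
  keep <- which(p_oracle > 0.65 & !is.na(ch$change))
  d <- cohens_d(ch$change[keep], simulate_treatment(ch$change[keep], 0.27))
  expect_equal(rc$n_required_total, 2 * required_n_per_arm(d))

  # a threshold that changes nothing yields zero reduction
  rc0 <- reduction_curve(cohort, rep(0.9, n), thresholds = c(0.5))
  expect_equal(rc0$reduction_pct, 0)
})

test_that("effect size and reduction are invariant to affine outcome rescaling", {
  set.seed(41)
  ctrl <- rnorm(100, 3, 1.5)
  trt <- simulate_treatment(ctrl, 0.27)
  d1 <- cohens_d(ctrl, trt)
  d2 <- cohens_d(ctrl * 7, trt * 7)
  expect_equal(d1, d2)
})
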