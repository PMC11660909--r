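test_that("subgroup draw matches configured prevalence", {
  cfg <- cohort_config(n_patients = 283, seed = 11)
  out <- generate_cohort(cfg)
  frac <- mean(out$cohort$truth$true_label == "fast")
  se <- sqrt(0.63 * 0.37 / 283)
  expect_lt(abs(frac - 0.63), 3 * se)
})

test_that("noise-free slow-only cohort changes exactly by the configured delta", {
  traj <- c(mmse = 0, cdrsb = 0, faq = 0)
  specs <- list(slow = subgroup_spec(
    "slow", prevalence = 1,
    delta36 = c(mmse = -1.83, cdrsb = 1.85, faq = 5.59),
    baseline_mean = c(mmse = 24.21, cdrsb = 3.98, faq = 11.46),
    baseline_sd = c(mmse = 2.71, cdrsb = 1.36, faq = 5.90),
    traj_sd = traj, visit_noise_sd = traj
  ))
  cfg <- cohort_config(n_patients = 40, seed = 3, subgroups = specs,
                       apoe_rate = c(slow = 0.5))
  out <- generate_cohort(cfg)
  v <- out$cohort$visits
  ch <- tapply(v$cdrsb, v$patient_id, function(x) x[7] - x[1])
  expect_equal(as.numeric(ch), rep(1.85, 40), tolerance = 1e-12)
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- cohort_config(n_patients = 60, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
})

test_that("values respect score ranges and every patient has month 0", {
  cfg <- cohort_config(n_patients = 150, seed = 5)
  sim <- simulate_cohort(cfg)
  v <- sim$cohort$visits
  expect_true(all(v$mmse >= 0 & v$mmse <= 30, na.rm = TRUE))
  expect_true(all(v$cdrsb >= 0 & v$cdrsb <= 18, na.rm = TRUE))
  expect_true(all(v$faq >= 0 & v$faq <= 30, na.rm = TRUE))
  m0 <- tapply(v$month, v$patient_id, min)
  expect_true(all(m0 == 0))
})

test_that("invalid configurations are rejected", {
  specs <- default_subgroup_specs()
  specs$fast$prevalence <- 0.5
  expect_error(cohort_config(subgroups = specs), "sum to 1")
  expect_error(cohort_config(visit_grid = c(6, 12)), "start at 0")
  expect_error(cohort_config(visit_grid = numeric(0)), "non-empty")
  expect_error(cohort_config(missing_rate = 1), "missing_rate")
})

test_that("dropout hits the target median follow-up", {
  cfg <- cohort_config(n_patients = 2000, seed = 7)
  out <- generate_cohort(cfg)
  coh <- apply_dropout(out$cohort, 24, seed = 8)
  last <- tapply(coh$visits$month, coh$visits$patient_id, max)
  expect_equal(unname(median(last)), 24)
  # every patient keeps the diagnosis visit and one follow-up
  expect_true(all(last >= 6))
})

test_that("dropout edge cases: max-grid median and a single patient", {
  cfg <- cohort_config(n_patients = 600, seed = 17)
  out <- generate_cohort(cfg)
  coh36 <- apply_dropout(out$cohort, 36, seed = 2)
  last <- tapply(coh36$visits$month, coh36$visits$patient_id, max)
  expect_gte(mean(last == 36), 0.5)

  cfg1 <- cohort_config(n_patients = 1, seed = 1)
  one <- apply_dropout(generate_cohort(cfg1)$cohort, 24, seed = 3)
  expect_true(0 %in% one$visits$month)
})

test_that("missingness is binomial at the configured rate and spares month 0", {
  cfg <- cohort_config(n_patients = 600, seed = 21)
  out <- generate_cohort(cfg)
  expect_identical(inject_missingness(out$cohort, 0, seed = 1), out$cohort)

  coh <- inject_missingness(out$cohort, 0.2, seed = 22)
  v <- coh$visits
  eligible <- v$month > 0
  n_cells <- 3 * sum(eligible)
  rate <- (sum(is.na(v$mmse[eligible])) + sum(is.na(v$cdrsb[eligible])) +
             sum(is.na(v$faq[eligible]))) / n_cells
  expect_lt(abs(rate - 0.2), 3 * sqrt(0.2 * 0.8 / n_cells))
  expect_false(anyNA(v[v$month == 0, c("mmse", "cdrsb", "faq")]))
  expect_error(inject_missingness(out$cohort, 1, seed = 1), "rate")
})

test_that("subgroup mean changes and the APOE gap converge to the configuration", {
  cfg <- cohort_config(n_patients = 2000, seed = 31)
  out <- generate_cohort(cfg)
  v <- out$cohort$visits
  lab <- setNames(out$cohort$truth$true_label, out$cohort$truth$patient_id)
  ch <- tapply(v$cdrsb, v$patient_id, function(x) x[7] - x[1])
  for (g in c("slow", "fast")) {
    target <- default_subgroup_specs()[[g]]$delta36[["cdrsb"]]
    got <- ch[names(ch)[lab[names(ch)] == g]]
    expect_lt(abs(mean(got) - target), 2 * sd(got) / sqrt(length(got)) + 0.05)
  }
  apoe <- tapply(out$baseline$apoe_e4, lab[out$baseline$patient_id], mean)
  gap <- apoe[["fast"]] - apoe[["slow"]]
  expect_lt(abs(gap - 0.0933), 2 * sqrt(2 * 0.25 / 1000))
})

test_that("trajectory tensor mask is consistent with the long table", {
  d <- make_planted(80, seed = 41)
  t <- d$tensor
  expect_true(all(t$mask %in% c(0, 1)))
  expect_true(all(t$mask[, 1, ] == 1))
  # standardized observed cells invert to the original values
  raw <- progenrich:::destandardize(t, t$values)
  v <- d$cohort$visits
  i <- match(v$patient_id, t$patient_id)
  j <- match(v$month, t$month_grid)
  for (s in c("mmse", "cdrsb", "faq")) {
    dd <- match(s, t$scores)
    obs <- !is.na(v[[s]])
    expect_equal(raw[cbind(i[obs], j[obs], dd)], v[[s]][obs],
                 tolerance = 1e-10)
    expect_true(all(t$mask[cbind(i[!obs], j[!obs], dd)] == 0))
  }
})
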