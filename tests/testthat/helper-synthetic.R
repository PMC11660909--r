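# Shared synthetic fixtures, generated in code at load time.

# cohort with sharply separated planted subgroups: low slope heterogeneity
# and visit noise so single fits recover the structure reliably
sharp_specs <- function() {
  traj <- c(mmse = 0.3, cdrsb = 0.25, faq = 0.3)
  noise <- c(mmse = 0.3, cdrsb = 0.25, faq = 0.4)
  list(
    slow = subgroup_spec(
      "slow", prevalence = 0.37,
      delta36 = c(mmse = -1.83, cdrsb = 1.85, faq = 5.59),
      baseline_mean = c(mmse = 24.21, cdrsb = 3.98, faq = 11.46),
      baseline_sd = c(mmse = 2.71, cdrsb = 1.36, faq = 5.90),
      traj_sd = traj, visit_noise_sd = noise
    ),
    fast = subgroup_spec(
      "fast", prevalence = 0.63,
      delta36 = c(mmse = -9.24, cdrsb = 6.38, faq = 13.19),
      baseline_mean = c(mmse = 23.55, cdrsb = 4.48, faq = 12.79),
      baseline_sd = c(mmse = 3.33, cdrsb = 1.81, faq = 5.62),
      traj_sd = traj, visit_noise_sd = noise
    )
  )
}

# single-population cohort: no subgroup structure at all
flat_specs <- function() {
  list(slow = subgroup_spec(
    "slow", prevalence = 1,
    delta36 = c(mmse = -4, cdrsb = 3, faq = 8),
    baseline_mean = c(mmse = 24, cdrsb = 4, faq = 12),
    baseline_sd = c(mmse = 3, cdrsb = 1.5, faq = 5.5),
    traj_sd = c(mmse = 1.5, cdrsb = 1, faq = 1.5),
    visit_noise_sd = c(mmse = 1, cdrsb = 0.75, faq = 1.25)
  ))
}

make_planted <- function(n, seed, specs = sharp_specs(), missing = 0.1) {
  apoe <- if (length(specs) == 1) c(slow = 0.5) else NULL
  cfg <- if (is.null(apoe)) {
    cohort_config(n_patients = n, seed = seed, subgroups = specs)
  } else {
    cohort_config(n_patients = n, seed = seed, subgroups = specs,
                  apoe_rate = apoe,
                  demo_params = default_demo_params()["slow"])
  }
  out <- generate_cohort(cfg)
  coh <- if (missing > 0) {
    inject_missingness(out$cohort, missing, seed = seed + 1)
  } else {
    out$cohort
  }
  list(cohort = coh, baseline = out$baseline,
       tensor = as_trajectory_tensor(coh),
       truth = out$cohort$truth$true_label)
}

# isotropic standard-normal tensor: the structureless null
iso_tensor <- function(n, seed) {
  set.seed(seed)
  structure(
    list(values = array(rnorm(n * 7 * 3), dim = c(n, 7, 3)),
         mask = array(1, dim = c(n, 7, 3)),
         month_grid = seq(0, 36, 6),
         patient_id = sprintf("P%05d", seq_len(n)),
         scores = c("mmse", "cdrsb", "faq"),
         scaler = list(center = c(mmse = 0, cdrsb = 0, faq = 0),
                       scale = c(mmse = 1, cdrsb = 1, faq = 1))),
    class = "trajectory_tensor"
  )
}

fast_training <- function(...) {
  defaults <- list(epochs = 120, pretrain_epochs = 80, n_init = 2)
  do.call(training_config, utils::modifyList(defaults, list(...)))
}
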