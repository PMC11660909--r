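# Synthetic longitudinal dementia cohorts
#
# The generator plants two latent progression subgroups ("slow"/"fast") with
# linear mean trajectories on a fixed month grid, patient-level slope
# heterogeneity, bounded visit noise, and Table-1-style baseline feature
# shifts (clinical scores, demographics, APOE e4 carrier enrichment in fast
# progressors). It is the ground-truth oracle for every downstream stage.

#' Specification of one progression subgroup
#'
#' @param label `"slow"` or `"fast"`.
#' @param prevalence fraction of the cohort in this subgroup, in (0, 1).
#' @param delta36 named numeric (`mmse`, `cdrsb`, `faq`): mean score change
#'   over 36 months. MMSE worsening is stored as a negative change (the
#'   score decreases with decline); CDRSB/FAQ worsening is positive.
#' @param baseline_mean,baseline_sd named numerics: score distribution at
#'   diagnosis (month 0), truncated to the valid score range when drawn.
#' @param traj_sd named numeric: between-patient SD of the total 36-month
#'   change (slope heterogeneity), in score units.
#' @param visit_noise_sd named numeric: within-visit measurement noise SD.
#' @return an object of class `subgroup_spec`.
#' @export
subgroup_spec <- function(label, prevalence, delta36, baseline_mean,
                          baseline_sd, traj_sd, visit_noise_sd) {
  label <- match.arg(label, c("slow", "fast"))
  sc <- score_names()
  for (v in list(delta36, baseline_mean, baseline_sd, traj_sd, visit_noise_sd)) {
    if (!all(sc %in% names(v))) {
      stopf("subgroup_spec: per-score vectors need names %s",
            paste(sc, collapse = ", "))
    }
  }
  if (prevalence <= 0 || prevalence > 1) {
    stopf("prevalence must lie in (0, 1], got %g", prevalence)
  }
  info <- score_info()
  for (s in sc) {
    lo <- info$min[info$score == s]; hi <- info$max[info$score == s]
    if (baseline_mean[[s]] < lo || baseline_mean[[s]] > hi) {
      stopf("baseline mean for %s (%g) outside [%g, %g]",
            s, baseline_mean[[s]], lo, hi)
    }
  }
  structure(
    list(label = label, prevalence = prevalence,
         delta36 = delta36[sc], baseline_mean = baseline_mean[sc],
         baseline_sd = baseline_sd[sc], traj_sd = traj_sd[sc],
         visit_noise_sd = visit_noise_sd[sc]),
    class = "subgroup_spec"
  )
}

#' Default subgroup specifications
#'
#' Two subgroups at 37%/63% prevalence whose 36-month mean changes and
#' baseline score distributions follow the published ADNI subgroup
#' characterisation (slow: CDRSB +1.85, MMSE -1.83, FAQ +5.59; fast:
#' CDRSB +6.38, MMSE -9.24, FAQ +13.19). Slope heterogeneity and visit
#' noise are set to values under which the planted structure is recoverable
#' at a few hundred patients; see the methods vignette for the rationale.
#'
#' @return list of two `subgroup_spec` objects named `slow`, `fast`.
#' @export
default_subgroup_specs <- function() {
  traj_sd <- c(mmse = 1.5, cdrsb = 1.0, faq = 1.5)
  noise <- c(mmse = 1.0, cdrsb = 0.75, faq = 1.25)
  list(
    slow = subgroup_spec(
      "slow", prevalence = 0.37,
      delta36 = c(mmse = -1.83, cdrsb = 1.85, faq = 5.59),
      baseline_mean = c(mmse = 24.21, cdrsb = 3.98, faq = 11.46),
      baseline_sd = c(mmse = 2.71, cdrsb = 1.36, faq = 5.90),
      traj_sd = traj_sd, visit_noise_sd = noise
    ),
    fast = subgroup_spec(
      "fast", prevalence = 0.63,
      delta36 = c(mmse = -9.24, cdrsb = 6.38, faq = 13.19),
      baseline_mean = c(mmse = 23.55, cdrsb = 4.48, faq = 12.79),
      baseline_sd = c(mmse = 3.33, cdrsb = 1.81, faq = 5.62),
      traj_sd = traj_sd, visit_noise_sd = noise
    )
  )
}

#' Cohort generation configuration
#'
#' @param n_patients number of patients to simulate.
#' @param subgroups list of [subgroup_spec()] objects; prevalences must sum
#'   to 1.
#' @param visit_grid months since diagnosis at which visits are scheduled;
#'   strictly increasing, starting at 0.
#' @param dropout_median_months target median follow-up duration used by
#'   [apply_dropout()] (months; must be a grid point).
#' @param missing_rate probability that an attended non-baseline visit is
#'   missing a given score, used by [inject_missingness()]; in [0, 1).
#' @param apoe_rate named numeric: APOE e4 carrier probability per subgroup
#'   label. The default 0.4842/0.5775 reproduces the published 9.33
#'   percentage-point carrier enrichment among fast progressors.
#' @param demo_params per-subgroup demographic distributions (age and
#'   education means/SDs in years, probability of female sex).
#' @param n_noise_features count of uninformative standard-normal baseline
#'   features (stand-ins for unrelated screening variables).
#' @param n_subscores count of standardized clinical subscore features with
#'   a fast-vs-slow mean shift of `subscore_d` (emulating CDR/MMSE/FAQ
#'   item-level subscores, which carry prognostic signal beyond the summary
#'   scores).
#' @param subscore_d standardized shift of each subscore in fast
#'   progressors.
#' @param curvature exponent of the mean trajectory in scaled time,
#'   `(month/36)^curvature`; 1 = linear.
#' @param seed integer seed controlling all randomness.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 300,
                          subgroups = default_subgroup_specs(),
                          visit_grid = seq(0, 36, by = 6),
                          dropout_median_months = 24,
                          missing_rate = 0.1,
                          apoe_rate = c(slow = 0.4842, fast = 0.5775),
                          demo_params = default_demo_params(),
                          n_noise_features = 10,
                          n_subscores = 6,
                          subscore_d = 0.25,
                          curvature = 1,
                          seed = 1) {
  if (length(visit_grid) == 0) stopf("visit_grid must be non-empty")
  if (visit_grid[1] != 0 || any(diff(visit_grid) <= 0)) {
    stopf("visit_grid must start at 0 and be strictly increasing")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stopf("missing_rate must lie in [0, 1), got %g", missing_rate)
  }
  prev <- vapply(subgroups, function(s) s$prevalence, numeric(1))
  if (abs(sum(prev) - 1) > 1e-8) {
    stopf("subgroup prevalences must sum to 1 (got %g)", sum(prev))
  }
  labels <- vapply(subgroups, function(s) s$label, character(1))
  if (anyDuplicated(labels)) stopf("duplicate subgroup labels")
  names(subgroups) <- labels
  if (!all(labels %in% names(apoe_rate))) {
    stopf("apoe_rate must be named by subgroup label")
  }
  structure(
    list(n_patients = as.integer(n_patients), subgroups = subgroups,
         visit_grid = as.numeric(visit_grid),
         dropout_median_months = dropout_median_months,
         missing_rate = missing_rate, apoe_rate = apoe_rate,
         demo_params = demo_params,
         n_noise_features = as.integer(n_noise_features),
         n_subscores = as.integer(n_subscores), subscore_d = subscore_d,
         curvature = curvature, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' @rdname cohort_config
#' @export
default_demo_params <- function() {
  list(
    slow = list(age_mean = 75.32, age_sd = 6.95,
                edu_mean = 15.91, edu_sd = 2.73, female = 0.2547),
    fast = list(age_mean = 75.53, age_sd = 7.04,
                edu_mean = 15.90, edu_sd = 2.88, female = 0.3616)
  )
}

new_longitudinal_cohort <- function(visits, truth, visit_grid) {
  structure(list(visits = visits, truth = truth, visit_grid = visit_grid),
            class = "longitudinal_cohort")
}

#' @export
print.longitudinal_cohort <- function(x, ...) {
  cat(sprintf("<longitudinal_cohort> %d patients, %d visit rows, grid %s\n",
              nrow(x$truth), nrow(x$visits),
              paste(x$visit_grid, collapse = ",")))
  invisible(x)
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws each patient's subgroup by prevalence, a truncated-Gaussian
#' baseline per score, a patient-level total 36-month change
#' `delta36 + N(0, traj_sd)`, then evaluates the mean trajectory
#' `baseline + change * (month/36)^curvature` on the full visit grid, adds
#' visit noise and clamps to the valid score range. Baseline features
#' (demographics, APOE e4, subscores, noise features) are drawn per
#' subgroup. The returned cohort covers the complete grid; follow-up
#' truncation and item missingness are separate operations
#' ([apply_dropout()], [inject_missingness()]); [simulate_cohort()] chains
#' all three.
#'
#' @param config a [cohort_config()].
#' @return list with elements `cohort` (a `longitudinal_cohort`: tidy visit
#'   table + withheld `truth` labels) and `baseline` (one row per patient of
#'   cross-sectional features at diagnosis; month-0 scores duplicate the
#'   trajectory baseline).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_patients
    grid <- config$visit_grid
    info <- score_info()
    labels <- vapply(config$subgroups, function(s) s$label, character(1))
    prev <- vapply(config$subgroups, function(s) s$prevalence, numeric(1))
    lab <- sample(unname(labels), n, replace = TRUE, prob = unname(prev))
    pid <- sprintf("P%05d", seq_len(n))

    tmax <- 36
    frac <- (grid / tmax)^config$curvature

    vals <- array(NA_real_, dim = c(n, length(grid), nrow(info)))
    for (g in labels) {
      idx <- which(lab == g)
      if (length(idx) == 0) next
      sg <- config$subgroups[[g]]
      for (d in seq_len(nrow(info))) {
        s <- info$score[d]
        base <- rtruncnorm(length(idx), sg$baseline_mean[[s]],
                           sg$baseline_sd[[s]], info$min[d], info$max[d])
        change <- sg$delta36[[s]] + rnorm(length(idx), 0, sg$traj_sd[[s]])
        mu <- outer(base, rep(1, length(grid))) + outer(change, frac)
        noise <- matrix(rnorm(length(idx) * length(grid), 0,
                              sg$visit_noise_sd[[s]]),
                        nrow = length(idx))
        noise[, 1] <- 0  # month-0 value IS the drawn baseline
        vals[idx, , d] <- clamp(mu + noise, info$min[d], info$max[d])
      }
    }

    visits <- tibble::tibble(
      patient_id = rep(pid, each = length(grid)),
      month = rep(grid, times = n),
      mmse = as.vector(t(vals[, , which(info$score == "mmse")])),
      cdrsb = as.vector(t(vals[, , which(info$score == "cdrsb")])),
      faq = as.vector(t(vals[, , which(info$score == "faq")]))
    )
    truth <- tibble::tibble(patient_id = pid, true_label = lab)
    cohort <- new_longitudinal_cohort(visits, truth, grid)

    dp <- config$demo_params
    age <- edu <- female <- apoe <- numeric(n)
    for (g in labels) {
      idx <- which(lab == g)
      age[idx] <- rnorm(length(idx), dp[[g]]$age_mean, dp[[g]]$age_sd)
      edu[idx] <- rnorm(length(idx), dp[[g]]$edu_mean, dp[[g]]$edu_sd)
      female[idx] <- rbinom(length(idx), 1, dp[[g]]$female)
      apoe[idx] <- rbinom(length(idx), 1, config$apoe_rate[[g]])
    }
    baseline <- tibble::tibble(
      patient_id = pid,
      age = round(age, 1),
      education = round(clamp(edu, 6, 24)),
      sex = ifelse(female == 1, "F", "M"),
      apoe_e4 = as.integer(apoe),
      mmse = vals[, 1, which(info$score == "mmse")],
      cdrsb = vals[, 1, which(info$score == "cdrsb")],
      faq = vals[, 1, which(info$score == "faq")]
    )
    if (config$n_subscores > 0) {
      shift <- ifelse(lab == "fast", config$subscore_d, 0)
      for (j in seq_len(config$n_subscores)) {
        baseline[[sprintf("subscore_%02d", j)]] <- rnorm(n, shift, 1)
      }
    }
    if (config$n_noise_features > 0) {
      for (j in seq_len(config$n_noise_features)) {
        baseline[[sprintf("noise_%02d", j)]] <- rnorm(n, 0, 1)
      }
    }
    list(cohort = cohort, baseline = baseline)
  })
}

#' Truncate follow-up to a target median duration
#'
#' Each patient's last attended visit index follows a truncated geometric
#' distribution over grid indices: the month-0 (diagnosis) visit and the
#' first follow-up visit are always retained (mirroring the inclusion
#' criterion of at least one follow-up assessment), and the patient
#' continues past each later grid step independently with probability `c`
#' calibrated so that the distribution's median last-visit month equals
#' `median_months`. Dropout is independent of subgroup unless
#' `subgroup_hazard` supplies a per-label multiplier on the per-step log
#' continuation probability (values > 1 mean earlier dropout for that
#' subgroup).
#'
#' @param cohort a `longitudinal_cohort`.
#' @param median_months target median follow-up; must be a visit-grid month
#'   after 0.
#' @param seed integer seed.
#' @param subgroup_hazard optional named numeric (by subgroup label).
#' @return the cohort with post-dropout visit rows removed.
#' @export
apply_dropout <- function(cohort, median_months, seed,
                          subgroup_hazard = NULL) {
  stopifnot(inherits(cohort, "longitudinal_cohort"))
  grid <- cohort$visit_grid
  j_m <- match(median_months, grid) - 1
  if (is.na(j_m) || j_m < 1) {
    stopf("median_months must be a visit-grid month after 0")
  }
  # last index >= 1 always; continuation probability set at the half-step
  # so that P(last >= median) and P(last <= median) both exceed 1/2 and
  # the sample median concentrates on the target month
  cont <- 0.5^(1 / (j_m - 0.5))
  with_seed(seed, {
    pid <- cohort$truth$patient_id
    n <- length(pid)
    logc <- rep(log(cont), n)
    if (!is.null(subgroup_hazard)) {
      h <- subgroup_hazard[cohort$truth$true_label]
      logc <- logc * as.numeric(h)
    }
    steps <- length(grid) - 2  # steps beyond the guaranteed first follow-up
    last_idx <- if (steps > 0) {
      u <- matrix(runif(n * steps), nrow = n)
      go <- u < exp(logc)  # continue past step j?
      1 + rowSums(matrixStats_cumall(go))
    } else {
      rep(length(grid) - 1, n)
    }
    last_month <- grid[last_idx + 1]
    cutoff <- setNames(last_month, pid)
    visits <- cohort$visits
    visits <- visits[visits$month <= cutoff[visits$patient_id], , drop = FALSE]
    new_longitudinal_cohort(visits, cohort$truth, grid)
  })
}

# row-wise cumulative AND (leading-run indicator)
matrixStats_cumall <- function(m) {
  out <- m
  if (ncol(m) > 1) {
    for (j in 2:ncol(m)) out[, j] <- out[, j - 1] & m[, j]
  }
  out
}

#' Remove individual score values at random
#'
#' Every non-baseline (patient, month, score) cell is set missing
#' independently with probability `rate`; month-0 cells are never removed.
#'
#' @param cohort a `longitudinal_cohort`.
#' @param rate missingness probability in [0, 1).
#' @param seed integer seed.
#' @return the cohort with NA-ed score cells.
#' @export
inject_missingness <- function(cohort, rate, seed) {
  stopifnot(inherits(cohort, "longitudinal_cohort"))
  if (rate < 0 || rate >= 1) stopf("rate must lie in [0, 1), got %g", rate)
  if (rate == 0) return(cohort)
  with_seed(seed, {
    visits <- cohort$visits
    eligible <- visits$month > 0
    for (s in score_names()) {
      drop <- eligible & runif(nrow(visits)) < rate
      visits[[s]][drop] <- NA_real_
    }
    new_longitudinal_cohort(visits, cohort$truth, cohort$visit_grid)
  })
}

#' Generate, truncate and perturb a cohort in one call
#'
#' Chains [generate_cohort()], [apply_dropout()] (at the config's
#' `dropout_median_months`) and [inject_missingness()] (at the config's
#' `missing_rate`), deriving the two stage seeds from the config seed.
#'
#' @param config a [cohort_config()].
#' @return list(cohort, baseline) as in [generate_cohort()].
#' @export
simulate_cohort <- function(config) {
  out <- generate_cohort(config)
  cohort <- apply_dropout(out$cohort, config$dropout_median_months,
                          seed = config$seed + 1L)
  cohort <- inject_missingness(cohort, config$missing_rate,
                               seed = config$seed + 2L)
  list(cohort = cohort, baseline = out$baseline)
}
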