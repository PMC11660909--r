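# Prognostic enrichment: threshold sweeps over classifier probabilities,
# emulated treatment effects on the 24-month CDRSB change, Cohen's d, and
# required sample sizes at fixed power.

#' Power analysis specification
#'
#' @param alpha two-sided type-I error level.
#' @param power required statistical power.
#' @return object of class `power_spec` (test: two-sample two-sided t).
#' @export
power_spec <- function(alpha = 0.05, power = 0.90) {
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stopf("alpha and power must lie in (0, 1)")
  }
  structure(list(alpha = alpha, power = power, test = "two-sample t"),
            class = "power_spec")
}

#' Treatment-effect specification
#'
#' @param relative_effect relative reduction of the outcome change in
#'   treated worseners (0.27 emulates the lecanemab effect size).
#' @param outcome outcome score (change from baseline).
#' @param horizon_months trial runtime.
#' @param apply_only_to_worseners if `TRUE` (default), patients whose
#'   change is <= 0 (improvement or no change) are left untouched.
#' @return object of class `effect_spec`.
#' @export
effect_spec <- function(relative_effect = 0.27, outcome = "cdrsb",
                        horizon_months = 24,
                        apply_only_to_worseners = TRUE) {
  if (relative_effect < 0 || relative_effect > 1) {
    stopf("relative_effect must lie in [0, 1]")
  }
  structure(list(relative_effect = relative_effect, outcome = outcome,
                 horizon_months = horizon_months,
                 apply_only_to_worseners = apply_only_to_worseners),
            class = "effect_spec")
}

#' Retain patients above a probability threshold
#'
#' @param p_fast per-patient predicted probabilities in [0, 1].
#' @param tau threshold in [0, 1]; patients with `p_fast > tau` are kept.
#' @return integer indices of retained patients.
#' @export
apply_threshold <- function(p_fast, tau) {
  if (tau < 0 || tau > 1) stopf("threshold must lie in [0, 1]")
  if (any(p_fast < 0 | p_fast > 1, na.rm = TRUE)) {
    stopf("probabilities must lie in [0, 1]")
  }
  which(p_fast > tau)
}

#' Emulate a uniform relative treatment effect
#'
#' Worsening changes (`> 0`) are scaled by `1 - relative_effect`;
#' improvements and no-change values are returned bit-identical.
#'
#' @param changes per-patient outcome changes from baseline.
#' @param effect an [effect_spec()] or a bare relative effect in [0, 1].
#' @return treated change vector.
#' @export
simulate_treatment <- function(changes, effect = effect_spec()) {
  if (is.numeric(effect)) effect <- effect_spec(relative_effect = effect)
  stopifnot(all(is.finite(changes)))
  out <- changes
  target <- if (effect$apply_only_to_worseners) changes > 0 else rep(TRUE, length(changes))
  out[target] <- changes[target] * (1 - effect$relative_effect)
  out
}

#' Cohen's d between control and treated samples
#'
#' `(mean(control) - mean(treated)) / pooled SD`, pooled with (n-1)
#' weighting.
#'
#' @param control,treated numeric samples of size >= 2.
#' @return standardized mean difference.
#' @export
cohens_d <- function(control, treated) {
  n1 <- length(control); n2 <- length(treated)
  if (n1 < 2 || n2 < 2) stopf("each sample needs >= 2 values")
  sp2 <- ((n1 - 1) * var(control) + (n2 - 1) * var(treated)) / (n1 + n2 - 2)
  if (sp2 == 0) stopf("zero pooled SD; effect size undefined")
  (mean(control) - mean(treated)) / sqrt(sp2)
}

#' Required sample size per arm for a two-sided t-test
#'
#' Smallest integer n per arm achieving the specified power at the
#' specified alpha for standardized effect `d`, from the noncentral-t
#' power function (via [stats::power.t.test]).
#'
#' @param d standardized effect size (> 0).
#' @param spec a [power_spec()].
#' @return integer patients per arm; `Inf` (with a warning) when `d <= 0`.
#' @export
required_n_per_arm <- function(d, spec = power_spec()) {
  if (!is.finite(d) || d <= 0) {
    warning("non-positive effect size: required sample size is infinite")
    return(Inf)
  }
  n <- power.t.test(delta = d, sd = 1, sig.level = spec$alpha,
                    power = spec$power, type = "two.sample",
                    alternative = "two.sided")$n
  as.integer(ceiling(n - 1e-9))
}

summarize_repeats <- function(m) {
  # m: thresholds x repeats; normal-approximation 95% CI across repeats
  mean_v <- rowMeans(m, na.rm = TRUE)
  if (ncol(m) > 1) {
    sd_v <- apply(m, 1, sd, na.rm = TRUE)
    nn <- rowSums(!is.na(m))
    se <- sd_v / sqrt(pmax(nn, 1))
    list(mean = mean_v, lo = mean_v - 1.96 * se, hi = mean_v + 1.96 * se)
  } else {
    list(mean = mean_v, lo = rep(NA_real_, nrow(m)),
         hi = rep(NA_real_, nrow(m)))
  }
}

as_prob_matrix <- function(p_fast) {
  if (is.matrix(p_fast)) p_fast else matrix(p_fast, ncol = 1)
}

#' Enrichment curve: retention and fast-progressor fraction by threshold
#'
#' @param p_fast probabilities; a vector, or a matrix with one column per
#'   classifier-retraining repeat (repeats give the 95% CI).
#' @param true_labels binary subgroup labels (1/`"fast"` = fast).
#' @param thresholds threshold grid (default 0.50-0.90 by 0.01).
#' @return tibble per threshold: retained fraction and fast fraction among
#'   the retained (means with normal-approximation CIs across repeats);
#'   empty retained sets yield `NA` fast fractions.
#' @export
enrichment_curve <- function(p_fast, true_labels,
                             thresholds = seq(0.5, 0.9, by = 0.01)) {
  pm <- as_prob_matrix(p_fast)
  y <- as_binary_labels(true_labels)
  stopifnot(nrow(pm) == length(y))
  ret <- fast <- matrix(NA_real_, length(thresholds), ncol(pm))
  for (r in seq_len(ncol(pm))) {
    for (i in seq_along(thresholds)) {
      keep <- apply_threshold(pm[, r], thresholds[i])
      ret[i, r] <- length(keep) / length(y)
      fast[i, r] <- if (length(keep) > 0) mean(y[keep]) else NA_real_
    }
  }
  rs <- summarize_repeats(ret); fs <- summarize_repeats(fast)
  tibble::tibble(
    tau = thresholds,
    retained_fraction = rs$mean, retained_lo = rs$lo, retained_hi = rs$hi,
    fast_fraction = fs$mean, fast_lo = fs$lo, fast_hi = fs$hi
  )
}

#' Outcome change from baseline to the trial horizon
#'
#' Uses the observed visit at the horizon when present (change = value at
#' horizon minus value at month 0). Patients without that visit but with
#' at least two observed values at months <= horizon get a least-squares
#' linear fit of their observed trajectory carried to the horizon; the
#' per-patient source is recorded. Others are `NA` (`"unavailable"`).
#'
#' @param cohort a `longitudinal_cohort`.
#' @param score outcome score column.
#' @param horizon_months trial horizon.
#' @return tibble: `patient_id`, `change`, `source`.
#' @export
horizon_changes <- function(cohort, score = "cdrsb", horizon_months = 24) {
  stopifnot(inherits(cohort, "longitudinal_cohort"))
  v <- cohort$visits
  pid <- cohort$truth$patient_id
  change <- rep(NA_real_, length(pid))
  source <- rep("unavailable", length(pid))
  sp <- split(v[, c("month", score)], v$patient_id)
  for (i in seq_along(pid)) {
    tab <- sp[[pid[i]]]
    if (is.null(tab)) next
    tab <- tab[!is.na(tab[[score]]) & tab$month <= horizon_months, ,
               drop = FALSE]
    base <- tab[[score]][tab$month == 0]
    if (length(base) == 0) next
    at_h <- tab[[score]][tab$month == horizon_months]
    if (length(at_h) == 1) {
      change[i] <- at_h - base
      source[i] <- "observed"
    } else if (nrow(tab) >= 2) {
      slope <- coef(lm(tab[[score]] ~ tab$month))[2]
      change[i] <- unname(slope) * horizon_months
      source[i] <- "interpolated"
    }
  }
  tibble::tibble(patient_id = pid, change = change, source = source)
}

#' Sample-size reduction achievable by threshold-based enrichment
#'
#' Per threshold, the retained patients' horizon changes form the control
#' arm; [simulate_treatment()] on the same changes forms the treatment
#' arm (the theoretical control arm consists of the same patients without
#' the effect). Cohen's d between the two arms feeds
#' [required_n_per_arm()], and the reduction is relative to the
#' unselected cohort: `1 - n(tau)/n(unselected)`. Thresholds retaining
#' fewer than 4 evaluable patients are dropped (`NA`).
#'
#' @param cohort a `longitudinal_cohort`.
#' @param p_fast probabilities (vector, or matrix with one column per
#'   classifier retraining).
#' @param thresholds threshold grid.
#' @param effect an [effect_spec()].
#' @param spec a [power_spec()].
#' @return tibble per threshold: mean Cohen's d, required total sample
#'   size (both arms), and percent reduction with CI across repeats.
#' @export
reduction_curve <- function(cohort, p_fast,
                            thresholds = seq(0.5, 0.9, by = 0.01),
                            effect = effect_spec(), spec = power_spec()) {
  pm <- as_prob_matrix(p_fast)
  ch <- horizon_changes(cohort, effect$outcome, effect$horizon_months)
  ok <- !is.na(ch$change)
  stopifnot(nrow(pm) == nrow(ch))
  dmat <- nmat <- red <- matrix(NA_real_, length(thresholds), ncol(pm))
  for (r in seq_len(ncol(pm))) {
    ctrl_all <- ch$change[ok]
    d0 <- cohens_d(ctrl_all, simulate_treatment(ctrl_all, effect))
    n0 <- required_n_per_arm(d0, spec)
    for (i in seq_along(thresholds)) {
      keep <- intersect(apply_threshold(pm[, r], thresholds[i]), which(ok))
      if (length(keep) < 4) next
      ctrl <- ch$change[keep]
      trt <- simulate_treatment(ctrl, effect)
      d <- tryCatch(cohens_d(ctrl, trt), error = function(e) NA_real_)
      if (!is.finite(d) || d <= 0) next
      n <- required_n_per_arm(d, spec)
      dmat[i, r] <- d
      nmat[i, r] <- 2 * n
      red[i, r] <- (1 - n / n0) * 100
    }
  }
  ds <- summarize_repeats(dmat); ns <- summarize_repeats(nmat)
  rs <- summarize_repeats(red)
  tibble::tibble(
    tau = thresholds,
    cohens_d = ds$mean,
    n_required_total = ns$mean,
    reduction_pct = rs$mean, reduction_lo = rs$lo, reduction_hi = rs$hi
  )
}
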