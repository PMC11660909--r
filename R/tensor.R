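# Trajectory tensor: patients x grid timepoints x scores, with an observed
# mask. The clustering substrate; missing visits/values carry mask 0 and a
# zero-filled standardized value so they cannot influence any masked loss.

#' Build a trajectory tensor from a longitudinal cohort
#'
#' Arranges the tidy visit table on a fixed month grid as an
#' n x T x D array (patients x timepoints x scores) with an observation
#' mask, and z-standardizes each score on its observed cells. An external
#' cohort is standardized with the scaler of the training cohort by passing
#' `scaler` (required for model transfer); months absent from the cohort
#' are padded with mask 0.
#'
#' @param cohort a `longitudinal_cohort`.
#' @param month_grid months to arrange on; defaults to the cohort's grid.
#' @param scaler optional scaler (`list(center, scale)` per score) to
#'   reuse; when `NULL`, computed from this cohort's observed cells.
#' @return object of class `trajectory_tensor`: `values` (standardized,
#'   masked cells zero), `mask`, `month_grid`, `patient_id`, `scores`,
#'   `scaler`.
#' @export
as_trajectory_tensor <- function(cohort, month_grid = NULL, scaler = NULL) {
  stopifnot(inherits(cohort, "longitudinal_cohort"))
  grid <- month_grid %||% cohort$visit_grid
  pid <- cohort$truth$patient_id
  scores <- score_names()
  n <- length(pid); T <- length(grid); D <- length(scores)
  vals <- array(NA_real_, dim = c(n, T, D),
                dimnames = list(pid, NULL, scores))
  v <- cohort$visits
  v <- v[v$month %in% grid, , drop = FALSE]
  i <- match(v$patient_id, pid)
  j <- match(v$month, grid)
  for (d in seq_len(D)) {
    vals[cbind(i, j, d)] <- v[[scores[d]]]
  }
  mask <- 1 - is.na(vals)
  if (any(mask[, 1, ] == 0 & rowSums(mask, dims = 1) == 0)) {
    warning("patients with no observed cell at all; they will be assigned from the prior")
  }
  if (is.null(scaler)) {
    center <- scale <- setNames(numeric(D), scores)
    for (d in seq_len(D)) {
      obs <- vals[, , d][mask[, , d] == 1]
      center[d] <- mean(obs)
      scale[d] <- sd(obs)
      if (!is.finite(scale[d]) || scale[d] == 0) scale[d] <- 1
    }
    scaler <- list(center = center, scale = scale)
  }
  z <- vals
  for (d in seq_len(D)) {
    z[, , d] <- (vals[, , d] - scaler$center[d]) / scaler$scale[d]
  }
  z[mask == 0] <- 0
  structure(
    list(values = z, mask = mask, month_grid = grid, patient_id = pid,
         scores = scores, scaler = scaler),
    class = "trajectory_tensor"
  )
}

# undo the per-score standardization; x is n x T x D on the z scale
destandardize <- function(tensor, x) {
  for (d in seq_along(tensor$scores)) {
    x[, , d] <- x[, , d] * tensor$scaler$scale[d] + tensor$scaler$center[d]
  }
  x
}

# flatten to the model's input layout. The loss target `x` carries the
# standardized values with masked cells zeroed (they contribute nothing to
# any masked loss, whatever sits behind the mask). The encoder input
# presents masked cells as the patient's own linear interpolation /
# constant extrapolation over observed visits instead: with ragged
# follow-up, zero-filling makes the missingness pattern the dominant
# direction of variation and drowns the progression signal.
flatten_tensor <- function(tensor) {
  dims <- dim(tensor$values)
  n <- dims[1]
  xm <- matrix(tensor$mask, nrow = n)
  xv <- matrix(tensor$values, nrow = n) * xm
  filled <- tensor$values
  g <- tensor$month_grid
  for (i in seq_len(n)) {
    for (d in seq_len(dims[3])) {
      obs <- which(tensor$mask[i, , d] == 1)
      if (length(obs) == dims[2]) next
      if (length(obs) == 0) {
        filled[i, , d] <- 0
      } else if (length(obs) == 1) {
        filled[i, , d] <- tensor$values[i, obs, d]
      } else {
        filled[i, , d] <- approx(g[obs], tensor$values[i, obs, d],
                                 xout = g, rule = 2)$y
      }
    }
  }
  list(x = xv, m = xm, xin = cbind(matrix(filled, nrow = n), xm))
}

# per-patient observed change in one score: last observed value minus
# month-0 value (original scale); NA when fewer than two observations
observed_change <- function(tensor, score = "cdrsb") {
  d <- match(score, tensor$scores)
  vals <- destandardize(tensor, tensor$values)[, , d]
  mask <- tensor$mask[, , d]
  n <- nrow(mask)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    obs <- which(mask[i, ] == 1)
    if (length(obs) >= 2) out[i] <- vals[i, max(obs)] - vals[i, min(obs)]
  }
  out
}
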