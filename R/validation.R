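# External validation: transferring a trained clustering model to an
# independent cohort and quantifying assignment concordance.

#' Apply a trained clustering model to an external cohort
#'
#' Builds the external cohort's trajectory tensor on the model's month
#' grid, reusing the model's standardization scaler (required for
#' transfer), and assigns subgroups. Patients with no observed
#' post-baseline visit are still assigned (prior-driven) and flagged in
#' the `prior_only` attribute.
#'
#' @param model a fitted `cluster_model`.
#' @param cohort a `longitudinal_cohort` whose scores map to the model's.
#' @return an `assignment` with attribute `prior_only` (logical vector).
#' @export
apply_external <- function(model, cohort) {
  stopifnot(inherits(model, "cluster_model"),
            inherits(cohort, "longitudinal_cohort"))
  missing_scores <- setdiff(model$scores, names(cohort$visits))
  if (length(missing_scores) > 0) {
    stopf("cohort lacks required score column(s): %s",
          paste(missing_scores, collapse = ", "))
  }
  tensor <- as_trajectory_tensor(cohort, month_grid = model$month_grid,
                                 scaler = model$scaler)
  a <- assign_subgroups(model, tensor)
  post <- apply(tensor$mask[, -1, , drop = FALSE], 1, sum)
  attr(a, "prior_only") <- post == 0
  a
}

#' Concordance between two subgroup assignments
#'
#' Agreement is the percentage of patients assigned identically. When both
#' assignments carry a slow/fast semantic map the semantic labels are
#' compared directly; otherwise agreement is maximized over label
#' permutations (component indices are arbitrary across trainings).
#'
#' @param a,b `assignment` objects over the same patients.
#' @return object of class `concordance_report`: `n_common`, `agreement`
#'   (percent), `confusion` (k x k counts, rows = `a`).
#' @export
concordance <- function(a, b) {
  stopifnot(inherits(a, "assignment"), inherits(b, "assignment"))
  if (!identical(a$patient_id, b$patient_id)) {
    stopf("assignments cover different patient sets")
  }
  n <- length(a$label)
  semantic_ok <- !anyNA(a$semantic_label) && !anyNA(b$semantic_label)
  if (semantic_ok) {
    agreement <- mean(a$semantic_label == b$semantic_label) * 100
    confusion <- table(a = a$semantic_label, b = b$semantic_label)
  } else {
    perm <- align_labels(a, b)
    agreement <- attr(perm, "agreement") * 100
    confusion <- table(a = a$label, b = perm[b$label])
  }
  structure(list(n_common = n, agreement = agreement,
                 confusion = as.matrix(confusion)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> n = %d, agreement = %.1f%%\n",
              x$n_common, x$agreement))
  print(x$confusion)
  invisible(x)
}
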