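# Cluster-number selection by prediction strength against a random null,
# and consensus aggregation of repeated clustering runs.

# take a subset of patients from a trajectory tensor
subset_tensor <- function(tensor, idx) {
  structure(
    list(values = tensor$values[idx, , , drop = FALSE],
         mask = tensor$mask[idx, , , drop = FALSE],
         month_grid = tensor$month_grid,
         patient_id = tensor$patient_id[idx],
         scores = tensor$scores, scaler = tensor$scaler),
    class = "trajectory_tensor"
  )
}

# prediction-strength statistic for one (reference rule, clustering) pair:
# min over clusters of `cl` of the fraction of ordered within-cluster
# pairs that `ref` co-assigns; clusters with < 2 members contribute 1
ps_pairs <- function(ref, cl) {
  ps <- 1
  for (j in unique(cl)) {
    members <- which(cl == j)
    nj <- length(members)
    if (nj < 2) next
    counts <- table(ref[members])
    co <- sum(counts * (counts - 1))
    ps <- min(ps, co / (nj * (nj - 1)))
  }
  ps
}

#' Prediction strength of the model-induced clustering
#'
#' For each split the patients are halved at random, a model is fitted on
#' each half, and the held-out half is clustered by both. The prediction
#' strength is the minimum over the test-half model's clusters of the
#' fraction of ordered co-clustered pairs that the train-half model also
#' co-assigns. `k = 1` returns 1 for every split by definition.
#'
#' @param data a `trajectory_tensor`.
#' @param k number of clusters.
#' @param cfg a [training_config()] (its `k` is overridden by `k`).
#' @param n_splits number of random half-splits.
#' @param seed integer seed.
#' @param detail if `TRUE`, also return the per-split cluster-size
#'   profiles of the two assignments of the held-out half (used to match
#'   the random null to the observed profiles).
#' @return numeric vector of length `n_splits` with values in [0, 1], or
#'   a list with `ps` and `profiles` when `detail = TRUE`.
#' @export
prediction_strength <- function(data, k, cfg, n_splits = 20,
                                seed = cfg$seed, detail = FALSE) {
  stopifnot(k >= 1, n_splits >= 1)
  n <- dim(data$values)[1]
  if (k == 1) {
    ps <- rep(1, n_splits)
    if (!detail) return(ps)
    return(list(ps = ps, profiles = replicate(n_splits, list(
      a = floor(n / 2), b = floor(n / 2)), simplify = FALSE)))
  }
  profiles <- vector("list", n_splits)
  ps <- vapply(seq_len(n_splits), function(s) {
    base <- seed + 7919L * s
    perm <- with_seed(base, sample.int(n))
    half <- floor(n / 2)
    ia <- perm[seq_len(half)]; ib <- perm[(half + 1):n]
    cfg_a <- cfg; cfg_a$k <- as.integer(k); cfg_a$seed <- base + 1L
    cfg_b <- cfg_a; cfg_b$seed <- base + 2L
    ma <- fit_model(subset_tensor(data, ia), cfg_a)
    mb <- fit_model(subset_tensor(data, ib), cfg_b)
    tb <- subset_tensor(data, ib)
    la <- assign_subgroups(ma, tb)$label
    lb <- assign_subgroups(mb, tb)$label
    profiles[[s]] <<- list(
      a = as.integer(table(factor(la, levels = seq_len(k)))),
      b = as.integer(table(factor(lb, levels = seq_len(k)))))
    ps_pairs(la, lb)
  }, numeric(1))
  if (detail) list(ps = ps, profiles = profiles) else ps
}

labels_from_profile <- function(sizes) {
  k <- length(sizes)
  sample(rep.int(seq_len(k), sizes))
}

balanced_profile <- function(n, k) {
  rep(floor(n / k), k) + as.integer(seq_len(k) <= n %% k)
}

#' Prediction strength under random clustering
#'
#' The null distribution the model-induced prediction strength is compared
#' against: the same statistic computed between two independent uniformly
#' random label assignments of the held-out half. By default the
#' cluster-size profile is balanced; [select_k()] passes the profiles
#' observed in the model arm so that the null matches the clustering's
#' actual size profile (a degenerate, heavily unbalanced partition scores
#' high prediction strength under any labelling, and only a
#' profile-matched null accounts for that).
#'
#' @param data a `trajectory_tensor` (only its patient count is used: the
#'   null does not look at the values).
#' @param k number of clusters.
#' @param n_draws number of random draws (>= 1).
#' @param seed integer seed.
#' @param profiles optional list of `list(a = sizes, b = sizes)`
#'   cluster-size profiles (as returned by
#'   `prediction_strength(..., detail = TRUE)`), recycled across draws.
#' @return numeric vector of `n_draws` null prediction-strength values.
#' @export
random_null <- function(data, k, n_draws, seed = 1, profiles = NULL) {
  if (n_draws < 1) stopf("n_draws must be >= 1")
  stopifnot(k >= 1)
  n <- dim(data$values)[1]
  if (k == 1) return(rep(1, n_draws))
  half <- floor(n / 2)
  if (is.null(profiles)) {
    profiles <- list(list(a = balanced_profile(half, k),
                          b = balanced_profile(half, k)))
  }
  with_seed(seed, {
    vapply(seq_len(n_draws), function(i) {
      pr <- profiles[[(i - 1) %% length(profiles) + 1]]
      ps_pairs(labels_from_profile(pr$a), labels_from_profile(pr$b))
    }, numeric(1))
  })
}

#' Select the number of progression subgroups
#'
#' For each candidate `k` in ascending order, the model prediction-strength
#' values are compared with the random-clustering null by a one-sided
#' Mann-Whitney U test; the smallest `k` whose clustering is significantly
#' stronger than random (p < `alpha`) is selected. If no candidate passes,
#' the selection is `NA` ("no structure").
#'
#' @param data a `trajectory_tensor`.
#' @param k_range integer candidates, starting at 2.
#' @param cfg a [training_config()].
#' @param n_splits half-splits per candidate (model arm).
#' @param n_null null draws per candidate.
#' @param alpha significance level.
#' @param seed integer seed.
#' @return object of class `k_selection`: `k` (integer or `NA`), `table`
#'   (per-candidate mean prediction strength, null mean and p-value),
#'   `alpha`.
#' @export
select_k <- function(data, k_range = 2:3, cfg = training_config(),
                     n_splits = 20, n_null = 20, alpha = 0.05,
                     seed = cfg$seed) {
  k_range <- sort(as.integer(k_range))
  if (k_range[1] < 2) stopf("k_range must start at 2")
  if (n_splits < 2 || n_null < 2) {
    stopf("need at least 2 prediction-strength values per arm")
  }
  rows <- list(); selected <- NA_integer_
  for (k in k_range) {
    det <- prediction_strength(data, k, cfg, n_splits,
                               seed = seed + 101L * k, detail = TRUE)
    ps_m <- det$ps
    ps_0 <- random_null(data, k, n_null, seed = seed + 211L * k,
                        profiles = det$profiles)
    p <- suppressWarnings(
      wilcox.test(ps_m, ps_0, alternative = "greater")$p.value
    )
    rows[[length(rows) + 1]] <- tibble::tibble(
      k = k, mean_ps = mean(ps_m), mean_null = mean(ps_0), p_value = p
    )
    if (is.na(selected) && p < alpha) {
      selected <- k
      break  # smallest significant k; larger candidates not needed
    }
  }
  structure(list(k = selected, table = dplyr::bind_rows(rows),
                 alpha = alpha),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  if (is.na(x$k)) {
    cat("<k_selection> no structure detected\n")
  } else {
    cat(sprintf("<k_selection> selected k = %d (alpha = %g)\n", x$k, x$alpha))
  }
  print(x$table)
  invisible(x)
}

perms <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- perms(k - 1L)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}

as_hard_labels <- function(x) {
  if (inherits(x, "assignment")) x$label else as.integer(x)
}

#' Optimal label alignment between two assignments
#'
#' Finds the permutation of `other`'s component labels that maximizes
#' agreement with `reference` (exhaustive search over the k x k confusion
#' matrix; component indices are arbitrary across trainings).
#'
#' @param reference,other `assignment` objects or integer label vectors
#'   over the same patients with the same number of components.
#' @return integer permutation `perm` such that `perm[other_label]` is the
#'   aligned label, with attribute `"agreement"` (fraction identical).
#' @export
align_labels <- function(reference, other) {
  ref <- as_hard_labels(reference); oth <- as_hard_labels(other)
  if (length(ref) != length(oth)) stopf("assignments cover different patients")
  k_ref <- if (inherits(reference, "assignment")) {
    ncol(reference$responsibilities)
  } else max(ref)
  k_oth <- if (inherits(other, "assignment")) {
    ncol(other$responsibilities)
  } else max(oth)
  k <- max(k_ref, k_oth)
  if (k_ref != k_oth && inherits(reference, "assignment") &&
      inherits(other, "assignment")) {
    stopf("assignments have different k (%d vs %d)", k_ref, k_oth)
  }
  pm <- perms(k)
  agree <- apply(pm, 1, function(p) sum(p[oth] == ref))
  best <- pm[which.max(agree), ]
  attr(best, "agreement") <- max(agree) / length(ref)
  best
}

#' Consensus over repeated cluster assignments
#'
#' Builds the n x n co-assignment frequency matrix across repeats, cuts the
#' average-linkage hierarchical clustering of (1 - frequency) into `k`
#' groups to anchor component identities, aligns every repeat to that cut,
#' and reports per-patient responsibilities as the fraction of aligned
#' repeats voting for each component (hard label = argmax, ties to the
#' lowest index). Invariant to label permutations of individual repeats.
#'
#' @param assignments list of >= 2 `assignment` objects over identical
#'   patients.
#' @param k number of consensus groups.
#' @param data optional `trajectory_tensor` used to recompute the
#'   slow/fast semantic map from observed CDRSB changes.
#' @return an `assignment`.
#' @export
consensus <- function(assignments, k, data = NULL) {
  stopifnot(length(assignments) >= 2)
  pid <- assignments[[1]]$patient_id
  for (a in assignments) {
    if (!identical(a$patient_id, pid)) {
      stopf("assignments cover inconsistent patient sets")
    }
  }
  n <- length(pid); R <- length(assignments)
  labmat <- vapply(assignments, function(a) a$label, integer(n))
  co <- matrix(0, n, n)
  for (r in seq_len(R)) {
    L <- labmat[, r]
    co <- co + outer(L, L, "==")
  }
  co <- co / R
  hc <- hclust(stats::as.dist(1 - co), method = "average")
  ref <- cutree(hc, k = k)
  # anchor component identities to the first repeat so that unanimous
  # inputs come back unchanged (cutree numbers clusters arbitrarily)
  if (max(labmat[, 1]) <= k) {
    perm0 <- align_labels(labmat[, 1], ref)
    ref <- as.integer(perm0)[ref]
  }
  resp <- matrix(0, n, k)
  for (r in seq_len(R)) {
    perm <- align_labels(ref, labmat[, r])
    aligned <- perm[labmat[, r]]
    resp[cbind(seq_len(n), aligned)] <- resp[cbind(seq_len(n), aligned)] + 1
  }
  resp <- resp / R
  hard <- max.col(resp, ties.method = "first")
  sem <- if (!is.null(data)) {
    semantic_from_data(hard, k, data)
  } else {
    setNames(rep(NA_character_, k), NULL)
  }
  new_assignment(pid, resp, sem)
}

#' Repeated clustering with consensus aggregation
#'
#' Fits the model `repeats` times with seeds `cfg$seed + repeat index`,
#' assigns each run, and aggregates with [consensus()].
#'
#' @param data a `trajectory_tensor`.
#' @param k number of subgroups.
#' @param cfg a [training_config()].
#' @param repeats number of independent runs (the analysis default is 40).
#' @return list: `assignment` (consensus), `assignments` (per repeat),
#'   `models` (per repeat).
#' @export
consensus_cluster <- function(data, k, cfg = training_config(),
                              repeats = 40) {
  models <- vector("list", repeats)
  assignments <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    cfg_r <- cfg
    cfg_r$k <- as.integer(k)
    cfg_r$seed <- cfg$seed + r
    models[[r]] <- fit_model(data, cfg_r)
    assignments[[r]] <- assign_subgroups(models[[r]], data)
  }
  cons <- consensus(assignments, k, data = data)
  list(assignment = cons, assignments = assignments, models = models)
}
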