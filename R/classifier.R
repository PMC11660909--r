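# Baseline subgroup classifier: gradient-boosted trees under repeated
# nested stratified cross-validation, with rank-based AUC-ROC and
# step-interpolated AUC-PR.

#' Area under the ROC curve by the rank statistic
#'
#' Equivalent to the Mann-Whitney U statistic normalized by the number of
#' positive-negative pairs (midranks handle score ties).
#'
#' @param scores numeric predictions (higher = more positive).
#' @param labels binary labels (1/`TRUE`/`"fast"` = positive).
#' @return AUC in [0, 1].
#' @export
auc_roc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  npos <- sum(y == 1); nneg <- sum(y == 0)
  if (npos == 0 || nneg == 0) stopf("labels contain a single class")
  r <- rank(scores)
  (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve
#'
#' Step-interpolated integration: walking thresholds from the highest
#' score down (tied scores grouped), the area accumulates
#' `precision * delta-recall` at each step. The chance baseline equals the
#' positive-class prevalence.
#'
#' @inheritParams auc_roc
#' @return AUC-PR in [0, 1].
#' @export
auc_pr <- function(scores, labels) {
  y <- as_binary_labels(labels)
  npos <- sum(y == 1)
  if (npos == 0 || npos == length(y)) stopf("labels contain a single class")
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)  # end of each tied block
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / npos
  sum(diff(c(0, rec)) * prec)
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    as.integer(as.character(labels) == "fast")
  } else {
    y <- as.integer(labels)
    if (!all(y %in% c(0, 1))) stopf("labels must be binary (0/1 or slow/fast)")
    y
  }
}

# numeric design matrix with native NA routing; character/factor columns
# are integer-coded with the level map stored for prediction time
encode_features <- function(df, spec = NULL) {
  df <- df[, setdiff(names(df), "patient_id"), drop = FALSE]
  if (is.null(spec)) {
    spec <- list(features = names(df), levels = list())
    for (v in names(df)) {
      if (is.character(df[[v]]) || is.factor(df[[v]])) {
        spec$levels[[v]] <- sort(unique(as.character(stats::na.omit(df[[v]]))))
      }
    }
  } else {
    unknown <- setdiff(names(df), spec$features)
    if (length(unknown) > 0) {
      stopf("unknown feature name(s): %s", paste(unknown, collapse = ", "))
    }
    miss <- setdiff(spec$features, names(df))
    if (length(miss) > 0) {
      stopf("missing feature column(s): %s", paste(miss, collapse = ", "))
    }
    df <- df[, spec$features, drop = FALSE]
  }
  m <- matrix(NA_real_, nrow(df), length(spec$features),
              dimnames = list(NULL, spec$features))
  for (v in spec$features) {
    if (!is.null(spec$levels[[v]])) {
      m[, v] <- as.numeric(match(as.character(df[[v]]), spec$levels[[v]]))
    } else {
      m[, v] <- as.numeric(df[[v]])
    }
  }
  list(matrix = m, spec = spec)
}

#' Cross-validation configuration
#'
#' @param outer_folds,inner_folds stratified fold counts (>= 2).
#' @param repeats whole-CV repetitions (>= 1); repeat r uses seed
#'   `seed + r`.
#' @param search_budget random-search candidates per outer fold.
#' @param param_space named list of `c(lo, hi)` ranges for `max_depth`,
#'   `eta` (log-uniform), `nrounds`, `subsample`, `colsample_bytree`,
#'   `min_child_weight`.
#' @param seed integer seed.
#' @return object of class `cv_config`.
#' @export
cv_config <- function(outer_folds = 8, inner_folds = 8, repeats = 10,
                      search_budget = 25, param_space = default_param_space(),
                      seed = 1) {
  if (outer_folds < 2 || inner_folds < 2) stopf("folds must be >= 2")
  if (repeats < 1) stopf("repeats must be >= 1")
  structure(
    list(outer_folds = as.integer(outer_folds),
         inner_folds = as.integer(inner_folds),
         repeats = as.integer(repeats),
         search_budget = as.integer(search_budget),
         param_space = param_space, seed = as.integer(seed)),
    class = "cv_config"
  )
}

#' @rdname cv_config
#' @export
default_param_space <- function() {
  list(max_depth = c(2, 6), eta = c(0.03, 0.3), nrounds = c(50, 300),
       subsample = c(0.6, 1), colsample_bytree = c(0.6, 1),
       min_child_weight = c(1, 10))
}

sample_params <- function(space, budget) {
  lapply(seq_len(budget), function(i) {
    list(
      max_depth = sample(space$max_depth[1]:space$max_depth[2], 1),
      eta = exp(runif(1, log(space$eta[1]), log(space$eta[2]))),
      nrounds = sample(space$nrounds[1]:space$nrounds[2], 1),
      subsample = runif(1, space$subsample[1], space$subsample[2]),
      colsample_bytree = runif(1, space$colsample_bytree[1],
                               space$colsample_bytree[2]),
      min_child_weight = runif(1, space$min_child_weight[1],
                               space$min_child_weight[2])
    )
  })
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(sample.int(k), length(idx))
  }
  if (any(vapply(split(y, fold), function(v) length(unique(v)), 1L) < 2)) {
    stopf("a fold received a single class; reduce fold count")
  }
  fold
}

xgb_fit <- function(x, y, params, seed) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = params$max_depth, eta = params$eta,
                  subsample = params$subsample,
                  colsample_bytree = params$colsample_bytree,
                  min_child_weight = params$min_child_weight,
                  nthread = 1, seed = as.integer(seed)),
    data = dtrain, nrounds = params$nrounds, verbose = 0
  )
}

xgb_predict <- function(booster, x) {
  predict(booster, xgboost::xgb.DMatrix(x, nthread = 1))
}

#' Repeated nested cross-validation of the subgroup classifier
#'
#' Stratified outer folds; hyperparameters are picked per outer fold by
#' random search evaluated in an inner stratified CV restricted to the
#' outer-training rows; the winning configuration is refit on the full
#' outer-training set and scored on the held-out fold. Outer-fold
#' predictions are pooled per repeat into one AUC-ROC/AUC-PR pair, then
#' summarized as mean +/- sd across repeats.
#'
#' @param features baseline feature table (may include `patient_id`).
#' @param labels binary subgroup labels (1/`"fast"` = positive).
#' @param cfg a [cv_config()].
#' @return object of class `cv_report`: AUC summaries, per-repeat values,
#'   chosen hyperparameters per outer fold, and the positive-class
#'   prevalence (the AUC-PR chance baseline).
#' @export
nested_cv <- function(features, labels, cfg = cv_config()) {
  y <- as_binary_labels(labels)
  if (min(table(y)) < cfg$outer_folds) {
    stopf("need at least outer_folds (%d) patients per class", cfg$outer_folds)
  }
  enc <- encode_features(features)
  x <- enc$matrix
  auc_reps <- pr_reps <- numeric(cfg$repeats)
  chosen <- list()
  for (r in seq_len(cfg$repeats)) {
    with_seed(cfg$seed + r, {
      fold <- stratified_folds(y, cfg$outer_folds)
      pred <- rep(NA_real_, length(y))
      for (f in seq_len(cfg$outer_folds)) {
        tr <- which(fold != f); te <- which(fold == f)
        cand <- sample_params(cfg$param_space, cfg$search_budget)
        inner_fold <- stratified_folds(y[tr], cfg$inner_folds)
        scores <- vapply(cand, function(pp) {
          ip <- rep(NA_real_, length(tr))
          for (g in seq_len(cfg$inner_folds)) {
            itr <- tr[inner_fold != g]; ite_rel <- which(inner_fold == g)
            b <- xgb_fit(x[itr, , drop = FALSE], y[itr], pp,
                         seed = cfg$seed + r)
            ip[ite_rel] <- xgb_predict(b, x[tr[ite_rel], , drop = FALSE])
          }
          auc_roc(ip, y[tr])
        }, numeric(1))
        best <- cand[[which.max(scores)]]
        chosen[[sprintf("rep%d_fold%d", r, f)]] <- best
        b <- xgb_fit(x[tr, , drop = FALSE], y[tr], best, seed = cfg$seed + r)
        pred[te] <- xgb_predict(b, x[te, , drop = FALSE])
      }
      auc_reps[r] <- auc_roc(pred, y)
      pr_reps[r] <- auc_pr(pred, y)
    })
  }
  structure(
    list(auc_roc_mean = mean(auc_reps), auc_roc_sd = sd(auc_reps),
         auc_pr_mean = mean(pr_reps), auc_pr_sd = sd(pr_reps),
         auc_roc_per_repeat = auc_reps, auc_pr_per_repeat = pr_reps,
         chosen_params = chosen, prevalence = mean(y), config = cfg),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report> AUC-ROC %.3f +/- %.3f, AUC-PR %.3f +/- %.3f (prevalence %.2f)\n",
    x$auc_roc_mean, x$auc_roc_sd %||% NA, x$auc_pr_mean, x$auc_pr_sd %||% NA,
    x$prevalence))
  invisible(x)
}

#' Train a final classifier on all rows
#'
#' @param features baseline feature table.
#' @param labels binary subgroup labels.
#' @param params hyperparameter list as produced by the CV search (any
#'   subset; unspecified entries take moderate defaults).
#' @param seed integer seed (deterministic fit).
#' @return object of class `classifier_model`.
#' @export
train_final <- function(features, labels, params = list(), seed = 1) {
  y <- as_binary_labels(labels)
  enc <- encode_features(features)
  if (ncol(enc$matrix) == 0) stopf("empty feature set")
  defaults <- list(max_depth = 3, eta = 0.1, nrounds = 150, subsample = 0.9,
                   colsample_bytree = 0.9, min_child_weight = 2)
  params <- utils::modifyList(defaults, params)
  booster <- xgb_fit(enc$matrix, y, params, seed = seed)
  structure(
    list(booster = booster, feature_spec = enc$spec, params = params,
         seed = as.integer(seed)),
    class = "classifier_model"
  )
}

#' Predict the probability of fast progression
#'
#' Missing feature values are routed natively by the trees, never imputed;
#' feature columns may arrive in any order but must match the training
#' list.
#'
#' @param model a `classifier_model`.
#' @param features baseline feature table.
#' @return numeric vector of probabilities in [0, 1].
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "classifier_model"))
  enc <- encode_features(features, spec = model$feature_spec)
  xgb_predict(model$booster, enc$matrix)
}

#' External validation of a trained classifier
#'
#' @param model a `classifier_model`.
#' @param features external baseline feature table.
#' @param labels binary subgroup labels of the external cohort.
#' @return list with `auc_roc` and `auc_pr`.
#' @export
external_validate <- function(model, features, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stopf("labels contain a single class")
  p <- predict_proba(model, features)
  list(auc_roc = auc_roc(p, y), auc_pr = auc_pr(p, y))
}
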