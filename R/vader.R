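# Variational deep embedding for multivariate trajectory clustering.
#
# A single-hidden-layer dense encoder maps the flattened (timepoint x
# score) grid plus its observation mask to a diagonal-Gaussian posterior
# over a low-dimensional latent code; a mirror-image decoder reconstructs
# the grid. The latent prior is a mixture of diagonal Gaussians whose
# responsibilities define the cluster assignment. Training is two-phase:
# deterministic autoencoder pretraining on the masked reconstruction
# error, then the variational phase minimising masked Gaussian
# reconstruction NLL plus the mixture KL, with the mixture parameters
# updated by closed-form EM steps on the full batch of latent means and
# the network weights by Adam on minibatches. Missing cells carry mask 0
# and contribute exactly zero to every loss term, which is what lets the
# model impute them implicitly.

#' Training configuration for the trajectory clustering model
#'
#' @param latent_dim latent code dimension.
#' @param hidden_size hidden layer width of encoder and decoder.
#' @param k number of mixture components (sought subgroups).
#' @param epochs variational-phase epochs.
#' @param pretrain_epochs autoencoder pretraining epochs.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param weight_decay L2 penalty on the weight matrices (not biases).
#' @param n_init independent restarts; the run with the lowest final
#'   objective is kept (restart r uses seed `seed + 1000 * (r - 1)`).
#' @param seed integer seed; all model randomness derives from it.
#' @return object of class `training_config`.
#' @export
training_config <- function(latent_dim = 4, hidden_size = 32, k = 2,
                            epochs = 200, pretrain_epochs = 100,
                            learning_rate = 5e-3, batch_size = 64,
                            weight_decay = 0, n_init = 3,
                            seed = 1) {
  vals <- c(latent_dim, hidden_size, k, epochs, pretrain_epochs,
            learning_rate, batch_size, n_init)
  if (any(!is.finite(vals)) || any(vals <= 0) || weight_decay < 0) {
    stopf("all training_config fields must be positive")
  }
  structure(
    list(latent_dim = as.integer(latent_dim),
         hidden_size = as.integer(hidden_size), k = as.integer(k),
         epochs = as.integer(epochs),
         pretrain_epochs = as.integer(pretrain_epochs),
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         weight_decay = weight_decay, n_init = as.integer(n_init),
         seed = as.integer(seed)),
    class = "training_config"
  )
}

glorot <- function(nin, nout) {
  matrix(runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)), nin, nout)
}

init_params <- function(d_in, h, L, d_out) {
  list(W1 = glorot(d_in, h), b1 = numeric(h),
       Wmu = glorot(h, L), bmu = numeric(L),
       Wlv = glorot(h, L), blv = rep(-2, L),
       V1 = glorot(L, h), c1 = numeric(h),
       V2 = glorot(h, d_out), c2 = numeric(d_out))
}

addb <- function(A, b) sweep(A, 2, b, "+")

enc_forward <- function(p, xin) {
  h1 <- tanh(addb(xin %*% p$W1, p$b1))
  mu <- addb(h1 %*% p$Wmu, p$bmu)
  lv <- clamp(addb(h1 %*% p$Wlv, p$blv), -8, 8)
  list(h1 = h1, mu = mu, lv = lv)
}

dec_forward <- function(p, z) {
  h2 <- tanh(addb(z %*% p$V1, p$c1))
  xhat <- addb(h2 %*% p$V2, p$c2)
  list(h2 = h2, xhat = xhat)
}

# log pi_c + log N(mu | mu_c, sigma2_c) for every component; n x k
gmm_logdens <- function(z, mix) {
  k <- length(mix$pi)
  out <- matrix(0, nrow(z), k)
  for (c in seq_len(k)) {
    d <- sweep(z, 2, mix$mu[c, ], "-")
    out[, c] <- log(mix$pi[c]) -
      0.5 * sum(log(2 * pi * mix$sigma2[c, ])) -
      0.5 * rowSums(sweep(d^2, 2, mix$sigma2[c, ], "/"))
  }
  out
}

softmax_rows <- function(lp) {
  m <- apply(lp, 1, max)
  e <- exp(lp - m)
  e / rowSums(e)
}

responsibilities_of <- function(z, mix) softmax_rows(gmm_logdens(z, mix))

# closed-form mixture M-step from latent means/variances and resp
mixture_mstep <- function(mu, sz, gamma) {
  k <- ncol(gamma); L <- ncol(mu)
  Nc <- pmax(colSums(gamma), 1e-8)
  piv <- pmax(Nc / nrow(mu), 1e-6); piv <- piv / sum(piv)
  muc <- crossprod(gamma, mu) / Nc
  s2 <- matrix(0, k, L)
  for (c in seq_len(k)) {
    d <- sweep(mu, 2, muc[c, ], "-")
    s2[c, ] <- colSums(gamma[, c] * (sz + d^2)) / Nc[c]
  }
  s2 <- pmax(s2, 1e-4)
  list(pi = piv, mu = muc, sigma2 = s2)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

decayed <- c("W1", "Wmu", "Wlv", "V1", "V2")

adam_step <- function(params, grads, st, lr, wd = 0, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (wd > 0 && nm %in% decayed) g <- g + wd * params[[nm]]
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g^2
    mhat <- st$m[[nm]] / (1 - b1^st$t)
    vhat <- st$v[[nm]] / (1 - b2^st$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = st)
}

# backprop through the decoder; returns parameter grads and dL/dz
dec_backward <- function(p, z, fw, dxhat) {
  dh2 <- (dxhat %*% t(p$V2)) * (1 - fw$h2^2)
  list(grads = list(V2 = crossprod(fw$h2, dxhat), c2 = colSums(dxhat),
                    V1 = crossprod(z, dh2), c1 = colSums(dh2)),
       dz = dh2 %*% t(p$V1))
}

# backprop through the encoder given grads on mu and lv
enc_backward <- function(p, xin, fw, dmu, dlv) {
  in_range <- (fw$lv > -8 & fw$lv < 8)  # clamp gradient gate
  dlv <- dlv * in_range
  dh1 <- (dmu %*% t(p$Wmu) + dlv %*% t(p$Wlv)) * (1 - fw$h1^2)
  list(W1 = crossprod(xin, dh1), b1 = colSums(dh1),
       Wmu = crossprod(fw$h1, dmu), bmu = colSums(dmu),
       Wlv = crossprod(fw$h1, dlv), blv = colSums(dlv))
}

# full VaDE objective on one batch (for monitoring and the final report);
# s2x is the per-dimension observation variance of the Gaussian likelihood
vade_loss <- function(p, mix, x, m, xin, eps_z, s2x = NULL) {
  if (is.null(s2x)) s2x <- rep(1, ncol(x))
  fw <- enc_forward(p, xin)
  sz <- exp(fw$lv)
  z <- fw$mu + sqrt(sz) * eps_z
  dec <- dec_forward(p, z)
  n <- nrow(x)
  recon <- 0.5 * sum(m * (sweep((dec$xhat - x)^2, 2, s2x, "/") +
                            matrix(log(2 * pi * s2x), n, ncol(x),
                                   byrow = TRUE))) / n
  gamma <- responsibilities_of(fw$mu, mix)
  k <- length(mix$pi)
  klz <- 0
  for (c in seq_len(k)) {
    d <- sweep(fw$mu, 2, mix$mu[c, ], "-")
    term <- sweep(
      sweep(sz, 2, mix$sigma2[c, ], "/") +
        sweep(d^2, 2, mix$sigma2[c, ], "/"), 2,
      log(mix$sigma2[c, ]), "+")
    klz <- klz + sum(gamma[, c] * 0.5 * rowSums(term))
  }
  klz <- klz - 0.5 * sum(1 + fw$lv)
  klc <- sum(gamma * (log(pmax(gamma, 1e-12)) -
                        matrix(log(mix$pi), nrow(x), k, byrow = TRUE)))
  recon + (klz + klc) / n
}

#' Fit the trajectory clustering model
#'
#' Two-phase training as described in the package vignette: masked
#' autoencoder pretraining, Gaussian-mixture initialisation of the latent
#' prior on the pretrained codes (via [mclust::Mclust]), then the
#' variational phase. Deterministic for a fixed `cfg$seed`.
#'
#' @param data a [as_trajectory_tensor()] object, standardized.
#' @param cfg a [training_config()].
#' @return object of class `cluster_model` with the network weights,
#'   mixture parameters, scaler and configuration.
#' @export
fit_model <- function(data, cfg) {
  stopifnot(inherits(data, "trajectory_tensor"),
            inherits(cfg, "training_config"))
  best <- NULL
  for (r in seq_len(cfg$n_init)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + 1000L * (r - 1L)
    m <- fit_model_once(data, cfg_r)
    if (is.null(best) || m$final_loss < best$final_loss) best <- m
  }
  best$config <- cfg
  best
}

fit_model_once <- function(data, cfg) {
  n <- dim(data$values)[1]
  if (cfg$k > n) stopf("k (%d) exceeds the number of patients (%d)", cfg$k, n)
  if (n < 10 * cfg$k) {
    warning(sprintf("only %d patients for k=%d; fit may be unstable", n, cfg$k))
  }
  fl <- flatten_tensor(data)
  d_out <- ncol(fl$x); d_in <- 2 * d_out
  L <- cfg$latent_dim; h <- cfg$hidden_size; k <- cfg$k

  with_seed(cfg$seed, {
    p <- init_params(d_in, h, L, d_out)
    st <- adam_init(p)
    lr <- cfg$learning_rate

    run_epochs <- function(p, st, epochs, step_fn) {
      for (ep in seq_len(epochs)) {
        ord <- sample.int(n)
        starts <- seq(1, n, by = cfg$batch_size)
        for (s0 in starts) {
          idx <- ord[s0:min(s0 + cfg$batch_size - 1, n)]
          upd <- step_fn(p, st, idx)
          p <- upd$params; st <- upd$state
        }
      }
      list(p = p, st = st)
    }

    # phase 1: deterministic AE on masked reconstruction error
    pre_step <- function(p, st, idx) {
      x <- fl$x[idx, , drop = FALSE]; m <- fl$m[idx, , drop = FALSE]
      xin <- fl$xin[idx, , drop = FALSE]
      fw <- enc_forward(p, xin)
      dec <- dec_forward(p, fw$mu)
      nb <- length(idx)
      dxhat <- m * (dec$xhat - x) / nb
      db <- dec_backward(p, fw$mu, dec, dxhat)
      ge <- enc_backward(p, xin, fw, db$dz, fw$lv * 0)
      adam_step(p, c(db$grads, ge), st, lr, cfg$weight_decay)
    }
    out <- run_epochs(p, st, cfg$pretrain_epochs, pre_step)
    p <- out$p; st <- out$st

    # mixture init: GMM on pretrained latent codes
    mu_all <- enc_forward(p, fl$xin)$mu
    mix <- init_mixture(mu_all, k)

    # observation variance of the Gaussian likelihood, per output dim:
    # closed-form (masked residual variance), refreshed every epoch
    s2x <- rep(1, d_out)
    update_s2x <- function(p) {
      dec <- dec_forward(p, enc_forward(p, fl$xin)$mu)
      num <- colSums(fl$m * (dec$xhat - fl$x)^2)
      pmax(num / pmax(colSums(fl$m), 1), 0.01)
    }

    # phase 2: variational with EM mixture updates per epoch
    st <- adam_init(p)
    for (ep in seq_len(cfg$epochs)) {
      s2x <- update_s2x(p)
      fwall <- enc_forward(p, fl$xin)
      gam_all <- responsibilities_of(fwall$mu, mix)
      mix <- mixture_mstep(fwall$mu, exp(fwall$lv), gam_all)
      ord <- sample.int(n)
      starts <- seq(1, n, by = cfg$batch_size)
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + cfg$batch_size - 1, n)]
        x <- fl$x[idx, , drop = FALSE]; m <- fl$m[idx, , drop = FALSE]
        xin <- fl$xin[idx, , drop = FALSE]
        nb <- length(idx)
        fw <- enc_forward(p, xin)
        sz <- exp(fw$lv)
        eps_z <- matrix(rnorm(nb * L), nb, L)
        z <- fw$mu + sqrt(sz) * eps_z
        dec <- dec_forward(p, z)
        dxhat <- sweep(m * (dec$xhat - x), 2, s2x, "/") / nb
        db <- dec_backward(p, z, dec, dxhat)
        gamma <- responsibilities_of(fw$mu, mix)
        A <- gamma %*% (1 / mix$sigma2)            # nb x L
        B <- gamma %*% (mix$mu / mix$sigma2)
        dmu <- db$dz + (fw$mu * A - B) / nb
        dlv <- db$dz * (0.5 * sqrt(sz) * eps_z) +
          0.5 * (sz * A - 1) / nb
        ge <- enc_backward(p, xin, fw, dmu, dlv)
        upd <- adam_step(p, c(db$grads, ge), st, lr, cfg$weight_decay)
        p <- upd$params; st <- upd$state
      }
    }
    s2x <- update_s2x(p)

    eps_fin <- matrix(0, n, L)
    final_loss <- vade_loss(p, mix, fl$x, fl$m, fl$xin, eps_fin, s2x)
    if (!is.finite(final_loss)) {
      stopf("training diverged: non-finite loss (k=%d, lr=%g)", k, lr)
    }
    structure(
      list(params = p, mixture = mix, k = k, config = cfg,
           out_sigma2 = s2x, scaler = data$scaler,
           month_grid = data$month_grid, scores = data$scores,
           final_loss = final_loss),
      class = "cluster_model"
    )
  })
}

init_mixture <- function(z, k) {
  L <- ncol(z)
  if (k == 1) {
    return(list(pi = 1, mu = matrix(colMeans(z), 1),
                sigma2 = matrix(pmax(apply(z, 2, var), 1e-4), 1)))
  }
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(z, G = k, modelNames = "VVI",
                                    verbose = FALSE)),
    error = function(e) NULL
  )
  if (!is.null(fit) && !is.null(fit$parameters)) {
    pr <- fit$parameters
    s2 <- matrix(0, k, L)
    for (c in seq_len(k)) s2[c, ] <- diag(as.matrix(pr$variance$sigma[, , c]))
    return(list(pi = pr$pro, mu = t(pr$mean), sigma2 = pmax(s2, 1e-4)))
  }
  # fallback: k-means moments
  km <- stats::kmeans(z, centers = k, nstart = 5)
  s2 <- matrix(0, k, L)
  for (c in seq_len(k)) {
    zz <- z[km$cluster == c, , drop = FALSE]
    s2[c, ] <- pmax(apply(zz, 2, var), 1e-4)
  }
  s2[!is.finite(s2)] <- 1e-2
  list(pi = as.numeric(table(factor(km$cluster, levels = seq_len(k)))) /
         nrow(z),
       mu = km$centers, sigma2 = s2)
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k=%d, latent_dim=%d, final loss %.4f\n",
              x$k, x$config$latent_dim, x$final_loss))
  invisible(x)
}

check_compatible <- function(model, data) {
  if (!identical(model$scores, data$scores)) {
    stopf("score dimensions of data (%s) do not match the model (%s)",
          paste(data$scores, collapse = ","),
          paste(model$scores, collapse = ","))
  }
  if (length(model$month_grid) != length(data$month_grid)) {
    stopf("month grid length mismatch: model %d vs data %d",
          length(model$month_grid), length(data$month_grid))
  }
}

new_assignment <- function(patient_id, resp, semantic) {
  hard <- max.col(resp, ties.method = "first")
  structure(
    list(patient_id = patient_id, label = hard, responsibilities = resp,
         semantic = semantic,
         semantic_label = unname(semantic[hard])),
    class = "assignment"
  )
}

#' @export
print.assignment <- function(x, ...) {
  tb <- table(x$semantic_label)
  cat(sprintf("<assignment> %d patients, k=%d (%s)\n", length(x$label),
              ncol(x$responsibilities),
              paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
  invisible(x)
}

# label each mixture component slow/fast by the mean observed CDRSB change
# of its members (largest mean change -> fast)
semantic_from_data <- function(hard, k, tensor) {
  ch <- observed_change(tensor, "cdrsb")
  means <- vapply(seq_len(k), function(c) {
    v <- ch[hard == c]
    if (all(is.na(v)) || length(v) == 0) -Inf else mean(v, na.rm = TRUE)
  }, numeric(1))
  sem <- rep("slow", k)
  sem[which.max(means)] <- "fast"
  sem
}

#' Build an assignment from plain labels
#'
#' Wraps hard labels (integers, or `"slow"`/`"fast"` strings) as an
#' `assignment` object with one-hot responsibilities, e.g. to compare a
#' model assignment against generator ground truth or to characterise
#' subgroups defined externally.
#'
#' @param patient_id patient identifiers.
#' @param labels integer component labels or `"slow"`/`"fast"` strings.
#' @return an `assignment`.
#' @export
manual_assignment <- function(patient_id, labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    stopifnot(all(labels %in% c("slow", "fast")))
    hard <- ifelse(labels == "slow", 1L, 2L)
    semantic <- c("slow", "fast")
  } else {
    hard <- as.integer(labels)
    stopifnot(all(hard >= 1))
    semantic <- rep(NA_character_, max(hard))
  }
  k <- max(hard, length(semantic))
  resp <- matrix(0, length(hard), k)
  resp[cbind(seq_along(hard), hard)] <- 1
  new_assignment(patient_id, resp, semantic)
}

#' Assign patients to progression subgroups
#'
#' Responsibilities are the mixture posterior of the encoded latent means;
#' the hard label is the argmax (ties to the lowest component index). The
#' component whose members show the largest mean observed CDRSB change is
#' tagged `"fast"`, the rest `"slow"`.
#'
#' @param model a fitted `cluster_model`.
#' @param data a `trajectory_tensor` on the model's grid (use the model's
#'   scaler when building it for an external cohort).
#' @return object of class `assignment`.
#' @export
assign_subgroups <- function(model, data) {
  stopifnot(inherits(model, "cluster_model"))
  check_compatible(model, data)
  fl <- flatten_tensor(data)
  mu <- enc_forward(model$params, fl$xin)$mu
  resp <- responsibilities_of(mu, model$mixture)
  hard <- max.col(resp, ties.method = "first")
  sem <- semantic_from_data(hard, model$k, data)
  new_assignment(data$patient_id, resp, sem)
}

#' Reconstruct trajectories, imputing masked cells
#'
#' Observed cells are returned unchanged; masked cells take the decoder
#' output at the encoded latent mean (the model's implicit imputation).
#'
#' @param model a fitted `cluster_model`.
#' @param data a `trajectory_tensor`.
#' @return n x T x D array on the original score scale, with attribute
#'   `"imputed"` marking the cells that were filled in.
#' @export
reconstruct <- function(model, data) {
  stopifnot(inherits(model, "cluster_model"))
  check_compatible(model, data)
  fl <- flatten_tensor(data)
  fw <- enc_forward(model$params, fl$xin)
  dec <- dec_forward(model$params, fw$mu)
  xhat <- array(dec$xhat, dim = dim(data$values))
  out <- data$values
  out[data$mask == 0] <- xhat[data$mask == 0]
  out <- destandardize(data, out)
  info <- score_info()
  for (d in seq_along(data$scores)) {
    i <- match(data$scores[d], info$score)
    out[, , d] <- clamp(out[, , d], info$min[i], info$max[i])
  }
  dimnames(out) <- list(data$patient_id, NULL, data$scores)
  attr(out, "imputed") <- data$mask == 0
  out
}
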