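#' Network and optimizer configuration
#'
#' A small VGG-style backbone: five 3x3 convolution layers with 16 feature
#' channels each, ReLU after every convolution and 2x2 max-pooling after
#' the first four (a 51x51 input shrinks 51 -> 25 -> 12 -> 6 -> 3; the 3x3
#' map of the fifth convolution flattens to 16 * 3 * 3 = 144). Three fully
#' connected ReLU layers of sizes 144, 144 and 12 follow, each with
#' dropout, then a final linear layer with `n_k` output activations. The
#' treatment indicator is concatenated to these activations by an affine
#' head, `y_hat = beta0 + beta_t * t + sum_j beta_j * a_j`, so `beta_t`
#' plays the role of the treatment effect during training. Activation 1 is
#' the reserved collider slot; activations `2..n_k` are constrained by the
#' independence regularizer.
#'
#' @param n_k number of last-layer activations (default 6).
#' @param conv_channels feature channels per convolution (default 16).
#' @param fc_sizes sizes of the fully connected layers.
#' @param dropout dropout rate on the fully connected layers.
#' @param input_dim input patch side in pixels (default 51).
#' @param batch_size minibatch size (default 40; must exceed `n_k + 1` so
#'   the in-batch regression is well-posed).
#' @param lr,beta1,beta2,eps Adam optimizer settings (default learning
#'   rate 0.001, no weight decay).
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience, in epochs without improvement
#'   of the validation total loss.
#' @param ridge jitter for the in-batch OLS of the regularizer.
#' @param reg_gradient `"full"` to differentiate through the in-batch OLS
#'   solution (default) or `"stop"` to treat its coefficients as constants.
#' @param reg_backprop `"last_layer"` (default) applies the independence
#'   regularizer's gradient to the final linear layer only, so the
#'   constrained slots are rotated orthogonal to the collider within the
#'   learned feature space while the shared trunk keeps learning content
#'   under the outcome and collider losses; `"full"` propagates it through
#'   the whole network. Full propagation lets the purge reach features the
#'   collider and prognostic signals still share early in training, which
#'   can collapse the constrained slots before they differentiate.
#' @param head_refit recalibrate the affine head at the end of every epoch
#'   by least squares of the target on `(t, a)` over clean training
#'   activations (default `TRUE`). Applies to the causal and ground-truth
#'   modes; the biased contrast always trains its head by Adam alone — it
#'   is the deliberate "plain curve fitting" reference. The head is the linear-regression part
#'   of the model; keeping it at its least-squares optimum makes the
#'   outcome loss depend on the activations only through their span, so
#'   the independence regularizer can remove collider-aligned components
#'   without competing against a stale head. With `FALSE` the head is
#'   trained by Adam alone.
#' @param slot_projection at each head refit, first re-express the final
#'   linear layer so that every constrained activation is empirically
#'   orthogonal to the reserved collider slot over the refit subsample (a
#'   pure linear reparameterization of the layer — the span of the
#'   activations, and hence the model's predictions after refit, are
#'   unchanged). This enforces the last-layer linear-independence
#'   constraint directly; the in-batch hinge still measures and penalizes
#'   any dependence that regrows between refits.
#' @param head_refit_after number of burn-in epochs before the first head
#'   refit. During burn-in the head keeps its (stale) stochastic values,
#'   which act as exploration pressure: the trunk is pulled toward every
#'   outcome-correlated feature, including the prognostic ones the
#'   constrained slots must eventually carry. Refitting from the first
#'   epoch would zero the coefficients of still-uninformative slots and
#'   cut off that discovery.
#' @return A list of class `net_config`.
#' @export
net_config <- function(n_k = 6L, conv_channels = 16L,
                       fc_sizes = c(144L, 144L, 12L), dropout = 0.25,
                       input_dim = 51L, batch_size = 40L, lr = 0.001,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       max_epochs = 200L, patience = 10L, ridge = 1e-6,
                       reg_gradient = c("full", "stop"),
                       reg_backprop = c("last_layer", "full"),
                       head_refit = TRUE, head_refit_after = 5L,
                       slot_projection = TRUE,
                       weight_x = 1, weight_reg = 1) {
  reg_gradient <- match.arg(reg_gradient)
  reg_backprop <- match.arg(reg_backprop)
  if (n_k < 2L) stop("'n_k' must be at least 2")
  if (batch_size <= n_k + 1L)
    stop("'batch_size' must exceed n_k + 1 for the in-batch regression")
  structure(list(n_k = as.integer(n_k),
                 conv_channels = as.integer(conv_channels),
                 fc_sizes = as.integer(fc_sizes), dropout = dropout,
                 input_dim = as.integer(input_dim),
                 batch_size = as.integer(batch_size), lr = lr,
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), ridge = ridge,
                 reg_gradient = reg_gradient,
                 reg_backprop = reg_backprop,
                 head_refit = isTRUE(head_refit),
                 head_refit_after = as.integer(head_refit_after),
                 slot_projection = isTRUE(slot_projection),
                 weight_x = weight_x, weight_reg = weight_reg),
            class = "net_config")
}

# spatial sizes of the five conv stages for a given input side
conv_stage_dims <- function(d) {
  dims <- integer(5)
  for (k in 1:5) {
    dims[k] <- d
    if (k <= 4) d <- d %/% 2L
  }
  dims
}

#' Initialize network parameters
#'
#' He-scaled Gaussian initialization for the ReLU layers, Xavier scaling
#' for the linear output layer and the affine head.
#'
#' @param config a [net_config()].
#' @param seed integer seed.
#' @return Named list of parameter arrays (class `net_params`).
#' @export
init_network <- function(config = net_config(), seed = 1L) {
  set.seed(seed)
  ch <- config$conv_channels
  flat <- ch * 9L
  he <- function(nr, nc, fan) matrix(rnorm(nr * nc, 0, sqrt(2 / fan)), nr, nc)
  p <- list(k1 = he(9L, ch, 9L), cb1 = numeric(ch))
  for (k in 2:5) {
    p[[paste0("k", k)]] <- he(9L * ch, ch, 9L * ch)
    p[[paste0("cb", k)]] <- numeric(ch)
  }
  fc <- config$fc_sizes
  sz <- c(flat, fc)
  for (k in seq_along(fc)) {
    p[[paste0("w", k)]] <- he(sz[k], sz[k + 1L], sz[k])
    p[[paste0("fb", k)]] <- numeric(sz[k + 1L])
  }
  p$w4 <- matrix(rnorm(fc[3] * config$n_k, 0, sqrt(1 / fc[3])),
                 fc[3], config$n_k)
  p$fb4 <- numeric(config$n_k)
  p$beta0 <- 0
  p$beta_t <- 0
  p$beta <- rnorm(config$n_k, 0, sqrt(1 / config$n_k))
  class(p) <- "net_params"
  p
}

#' Number of trainable parameters
#' @param params a `net_params` list.
#' @return Integer parameter count.
#' @export
n_parameters <- function(params) {
  sum(vapply(unclass(params), length, integer(1)))
}

#' Forward pass of the multi-task network
#'
#' @param params a `net_params` list from [init_network()].
#' @param images numeric array `input_dim x input_dim x m` (a batch of
#'   augmented patches).
#' @param t binary treatment vector of length `m`.
#' @param config the [net_config()].
#' @param training logical: apply dropout (inverted scaling) and keep the
#'   caches needed for the backward pass.
#' @param drop_masks optional list of pre-drawn dropout masks (used for
#'   gradient checking); when `NULL` and `training`, masks are drawn from
#'   the R random stream.
#' @return A list with `y_hat` (length m), `a` (`m x n_k` last-layer
#'   activations) and, when `training`, a `cache` for
#'   [backward_network()].
#' @export
forward_network <- function(params, images, t, config = net_config(),
                            training = FALSE, drop_masks = NULL) {
  m <- dim(images)[3]
  if (length(t) != m) stop("shape mismatch between images and t")
  cache <- list(m = m, t = t)
  Ks <- lapply(1:5, function(k) params[[paste0("k", k)]])
  bs <- lapply(1:5, function(k) params[[paste0("cb", k)]])
  Xf <- cnn_forward_stack(images, Ks, bs, m, keep_cache = training)
  keep <- 1 - config$dropout
  H <- Xf
  for (k in 1:3) {
    H <- H %*% params[[paste0("w", k)]]
    H <- sweep(H, 2, params[[paste0("fb", k)]], "+")
    H[H < 0] <- 0
    if (training) cache[[paste0("h", k)]] <- H
    if (training && config$dropout > 0) {
      msk <- if (!is.null(drop_masks)) drop_masks[[k]] else
        matrix(rbinom(length(H), 1L, keep) / keep, nrow(H), ncol(H))
      H <- H * msk
      cache[[paste0("mask", k)]] <- msk
    }
    if (training) cache[[paste0("d", k)]] <- H
  }
  a <- sweep(H %*% params$w4, 2, params$fb4, "+")
  y_hat <- drop(params$beta0 + params$beta_t * t + a %*% params$beta)
  if (training) {
    cache$xf <- Xf
    cache$a <- a
  }
  list(y_hat = y_hat, a = a, cache = if (training) cache else NULL)
}

#' Backward pass
#'
#' Back-propagates gradients supplied at the prediction (`d_yhat`) and at
#' the last-layer activations (`d_a`, e.g. from the collider loss and the
#' independence regularizer) to all parameters.
#'
#' @param params a `net_params` list.
#' @param cache the cache from [forward_network()] with `training = TRUE`.
#' @param d_yhat gradient of the loss w.r.t. `y_hat` (length m).
#' @param d_a gradient of the loss w.r.t. the activations (`m x n_k`),
#'   excluding the contribution through the head (added internally).
#' @param config the [net_config()].
#' @param d_a_local optional `m x n_k` part of the activation gradient
#'   whose influence stops at the final linear layer: it contributes to
#'   the last layer's weight and bias gradients but is not propagated
#'   into the shared trunk. Used for the independence regularizer under
#'   the default `reg_backprop = "last_layer"` routing.
#' @return Named list of gradients matching the parameter list.
#' @export
backward_network <- function(params, cache, d_yhat, d_a,
                             config = net_config(), d_a_local = NULL) {
  m <- cache$m
  a <- cache$a
  g <- list()
  g$beta0 <- sum(d_yhat)
  g$beta_t <- sum(d_yhat * cache$t)
  g$beta <- drop(crossprod(a, d_yhat))
  da <- d_a + tcrossprod(d_yhat, params$beta)
  da_full <- if (is.null(d_a_local)) da else da + d_a_local
  g$w4 <- crossprod(cache$d3, da_full)
  g$fb4 <- colSums(da_full)
  dH <- tcrossprod(da, params$w4)
  for (k in 3:1) {
    if (config$dropout > 0) dH <- dH * cache[[paste0("mask", k)]]
    dH <- dH * (cache[[paste0("h", k)]] > 0)
    g[[paste0("w", k)]] <- crossprod(
      if (k == 1) cache$xf else cache[[paste0("d", k - 1)]], dH)
    g[[paste0("fb", k)]] <- colSums(dH)
    dH <- tcrossprod(dH, params[[paste0("w", k)]])
  }
  Ks <- lapply(1:5, function(k) params[[paste0("k", k)]])
  bw <- cnn_backward_stack(dH, Ks)
  for (k in 1:5) {
    g[[paste0("k", k)]] <- bw$dk[[k]]
    g[[paste0("cb", k)]] <- drop(bw$db[[k]])
  }
  g
}

# one Adam step; state holds first/second moment lists and step counter
adam_step <- function(params, grads, state, config) {
  state$t <- state$t + 1L
  b1 <- config$beta1; b2 <- config$beta2
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * gr
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * gr^2
    params[[nm]] <- params[[nm]] - config$lr *
      (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + config$eps)
  }
  list(params = params, state = state)
}

# gather an augmented image batch from the pool
gather_batch <- function(pool, patch_idx, mode, crop = 51L) {
  m <- length(patch_idx)
  out <- array(0, c(crop, crop, m))
  for (j in seq_len(m))
    out[, , j] <- augment_patch(pool$pixels[, , patch_idx[j]], mode, crop)
  out
}

# losses + activation gradients for one batch, by training mode
batch_losses <- function(fw, yb, xb, target_b, mode, config,
                         with_grad = FALSE) {
  m <- length(yb)
  a <- fw$a
  if (mode == "ground_truth") {
    ly <- loss_y(fw$y_hat, target_b)
    lx <- loss_x(a[, 1L], xb)
    lr <- loss_reg(a[, -1L, drop = FALSE], xb, config$ridge)
    out <- list(l_y = ly, l_x = lx, l_reg = lr, l_opt = ly)
    if (with_grad) {
      out$d_yhat <- 2 * (fw$y_hat - target_b) / m
      out$d_a <- matrix(0, m, config$n_k)
    }
    return(out)
  }
  ly <- loss_y(fw$y_hat, yb)
  if (mode == "biased") {
    lx <- loss_x(a[, 1L], xb)
    lr <- loss_reg(a[, -1L, drop = FALSE], xb, config$ridge)
    out <- list(l_y = ly, l_x = lx, l_reg = lr, l_opt = ly)
    if (with_grad) {
      out$d_yhat <- 2 * (fw$y_hat - yb) / m
      out$d_a <- matrix(0, m, config$n_k)
    }
    return(out)
  }
  # causal mode: L = L_y + w_x * L_x + w_reg * L_reg
  lx <- loss_x(a[, 1L], xb)
  lr <- loss_reg(a[, -1L, drop = FALSE], xb, config$ridge,
                 gradient = if (with_grad) config$reg_gradient else "none")
  out <- list(l_y = ly, l_x = lx, l_reg = as.numeric(lr),
              l_opt = ly + config$weight_x * lx +
                config$weight_reg * as.numeric(lr))
  if (with_grad) {
    out$d_yhat <- 2 * (fw$y_hat - yb) / m
    d_a <- matrix(0, m, config$n_k)
    d_a[, 1L] <- config$weight_x * 2 * (a[, 1L] - xb) / m
    d_reg <- matrix(0, m, config$n_k)
    d_reg[, -1L] <- config$weight_reg * attr(lr, "grad")
    if (config$reg_backprop == "last_layer") {
      out$d_a <- d_a
      out$d_a_local <- d_reg
    } else {
      out$d_a <- d_a + d_reg
      out$d_a_local <- NULL
    }
  }
  out
}

#' Train the multi-task network
#'
#' Optimizes the network with Adam under one of three modes:
#' `"causal"` minimizes the full loss `L_y + L_x + L_reg` (outcome MSE,
#' collider MSE on the reserved activation, independence hinge on the
#' remaining activations); `"biased"` minimizes `L_y` only (the
#' unconstrained contrast that conditions on the whole image); and
#' `"ground_truth"` replaces the outcome with a ground-truth label (the
#' subject's simulated `x` or `z`) and minimizes its MSE, which is used to
#' quantify the inherent measurement error of the image pipeline. Training
#' stops early when the validation total loss has not improved for
#' `patience` epochs, and the parameters of the best validation epoch are
#' restored. Final minibatches too small for the in-batch regression are
#' dropped.
#'
#' @param matched_train,matched_val `matched_cohort` data.frames from
#'   [match_images()].
#' @param pool the `image_pool` the matches refer to.
#' @param mode `"causal"`, `"biased"` or `"ground_truth"`.
#' @param config a [net_config()].
#' @param seed integer seed controlling initialization, shuffling,
#'   augmentation and dropout.
#' @param target for `"ground_truth"` mode, the cohort column to predict
#'   (`"x"` or `"z"`).
#' @param verbose print per-epoch validation losses.
#' @return An object of class `collider_net`: the trained parameters, the
#'   config, the training mode, a per-epoch log (`epoch`, `split`, `l_y`,
#'   `l_x`, `l_reg`, `l_total`) and the selected epoch.
#' @export
train_network <- function(matched_train, matched_val, pool,
                          mode = c("causal", "biased", "ground_truth"),
                          config = net_config(), seed = 1L,
                          target = c("x", "z"), verbose = FALSE) {
  mode <- match.arg(mode)
  target <- match.arg(target)
  set.seed(seed)
  params <- init_network(config, seed = sample.int(.Machine$integer.max, 1))
  state <- list(t = 0L,
                m = lapply(unclass(params), function(p) p * 0),
                v = lapply(unclass(params), function(p) p * 0))
  n_tr <- nrow(matched_train)
  tgt_tr <- if (mode == "ground_truth") matched_train[[target]] else NULL
  tgt_va <- if (mode == "ground_truth") matched_val[[target]] else NULL
  min_batch <- config$n_k + 2L
  log_rows <- list()
  best <- list(loss = Inf, epoch = 0L, params = params)
  wait <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n_tr)
    starts <- seq(1L, n_tr, by = config$batch_size)
    tr_acc <- c(l_y = 0, l_x = 0, l_reg = 0)
    tr_n <- 0L
    for (s in starts) {
      bi <- ord[s:min(s + config$batch_size - 1L, n_tr)]
      if (length(bi) < min_batch) next
      Xb <- gather_batch(pool, matched_train$patch[bi], "train",
                         config$input_dim)
      fw <- forward_network(params, Xb, matched_train$t[bi], config,
                            training = TRUE)
      bl <- batch_losses(fw, matched_train$y[bi], matched_train$x_prime[bi],
                         tgt_tr[bi], mode, config, with_grad = TRUE)
      if (!is.finite(bl$l_opt))
        stop(sprintf("training diverged at epoch %d (non-finite loss)", epoch))
      gr <- backward_network(params, fw$cache, bl$d_yhat, bl$d_a, config,
                             d_a_local = bl$d_a_local)
      up <- adam_step(params, gr, state, config)
      params <- up$params
      state <- up$state
      w <- length(bi)
      tr_acc <- tr_acc + w * c(bl$l_y, bl$l_x, bl$l_reg)
      tr_n <- tr_n + w
    }
    if (config$head_refit && mode != "biased" &&
        epoch > config$head_refit_after) {
      sub <- ord[seq_len(min(n_tr, 1000L))]
      tgt <- if (mode == "ground_truth") tgt_tr[sub] else
        matched_train$y[sub]
      params <- refit_head(params, matched_train[sub, , drop = FALSE],
                           pool, tgt, config,
                           project = (mode == "causal"))
    }
    va <- evaluate_split(params, matched_val, pool, mode, config, tgt_va)
    tr <- tr_acc / max(tr_n, 1L)
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      epoch = epoch, split = c("train", "validation"),
      l_y = c(tr["l_y"], va["l_y"]), l_x = c(tr["l_x"], va["l_x"]),
      l_reg = c(tr["l_reg"], va["l_reg"]),
      l_total = c(sum(tr), sum(va[c("l_y", "l_x", "l_reg")])))
    val_opt <- va[["l_opt"]]
    if (verbose)
      message(sprintf("epoch %3d  val L_y %.4f L_x %.4f L_reg %.4f (monitor %.4f)",
                      epoch, va[["l_y"]], va[["l_x"]], va[["l_reg"]], val_opt))
    if (val_opt < best$loss - 1e-6) {
      best <- list(loss = val_opt, epoch = epoch, params = params)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  structure(list(params = best$params, config = config, mode = mode,
                 target = if (mode == "ground_truth") target else NULL,
                 log = do.call(rbind, log_rows), best_epoch = best$epoch,
                 n_epochs = epoch, best_val_loss = best$loss),
            class = "collider_net")
}

# least-squares recalibration of the affine head on (t, a) -> target,
# using clean eval-path activations of a training subsample. The solve is
# guarded against degenerate activation columns: near-constant columns are
# excluded (coefficient 0) and the remaining columns are standardized
# before a lightly ridged solve, so a collapsed column can never inject
# exploding coefficients (and hence exploding activation gradients).
refit_head <- function(params, matched_sub, pool, target, config,
                       project = TRUE, fit_beta = TRUE) {
  n <- nrow(matched_sub)
  a <- matrix(0, n, config$n_k)
  for (s in seq(1L, n, by = config$batch_size)) {
    bi <- s:min(s + config$batch_size - 1L, n)
    Xb <- gather_batch(pool, matched_sub$patch[bi], "eval",
                       config$input_dim)
    fw <- forward_network(params, Xb, matched_sub$t[bi], config,
                          training = FALSE)
    a[bi, ] <- fw$a
  }
  # Enforce last-layer linear independence directly: subtract from each
  # constrained column the multiple of the collider slot that zeroes its
  # sample covariance with the measured collider. With every covariance
  # zero, the OLS of x' on the constrained activations is identically
  # zero over the calibration sample — the stated independence property.
  # A pure linear reparameterization of the final layer; the activation
  # span (hence the refit head's predictions) is unchanged.
  if (project && config$slot_projection) {
    xs <- matched_sub$x_prime
    c1 <- stats::cov(a[, 1L], xs)
    if (abs(c1) > 0.2 * sd(xs) * max(sd(a[, 1L]), 1e-12)) {
      for (j in 2:config$n_k) {
        del <- stats::cov(a[, j], xs) / c1
        a[, j] <- a[, j] - del * a[, 1L]
        params$w4[, j] <- params$w4[, j] - del * params$w4[, 1L]
        params$fb4[j] <- params$fb4[j] - del * params$fb4[1L]
      }
    }
  }
  if (!fit_beta) return(params)
  mu <- colMeans(a)
  sds <- apply(a, 2, sd)
  keep <- which(sds > 1e-3)
  As <- sweep(sweep(a[, keep, drop = FALSE], 2, mu[keep]), 2, sds[keep], "/")
  X <- cbind(1, matched_sub$t, As)
  M <- crossprod(X) + 1e-4 * n * diag(ncol(X))
  M[1L, 1L] <- M[1L, 1L] - 1e-4 * n          # do not shrink the intercept
  cf <- drop(solve(M, crossprod(X, target)))
  beta <- numeric(config$n_k)
  beta[keep] <- cf[-(1:2)] / sds[keep]
  params$beta <- beta
  params$beta_t <- cf[2L]
  params$beta0 <- cf[1L] - sum(beta[keep] * mu[keep])
  params
}

# validation losses (eval augmentation, no dropout), weighted by batch size
evaluate_split <- function(params, matched, pool, mode, config, tgt = NULL) {
  n <- nrow(matched)
  starts <- seq(1L, n, by = config$batch_size)
  acc <- c(l_y = 0, l_x = 0, l_reg = 0, l_opt = 0)
  wt <- c(0, 0, 0, 0)
  for (s in starts) {
    bi <- s:min(s + config$batch_size - 1L, n)
    Xb <- gather_batch(pool, matched$patch[bi], "eval", config$input_dim)
    fw <- forward_network(params, Xb, matched$t[bi], config, training = FALSE)
    degenerate <- length(bi) < config$n_k + 2L
    a_rest <- fw$a[, -1L, drop = FALSE]
    lr <- if (degenerate) NA_real_ else
      loss_reg(a_rest, matched$x_prime[bi], config$ridge)
    ly <- if (mode == "ground_truth") loss_y(fw$y_hat, tgt[bi]) else
      loss_y(fw$y_hat, matched$y[bi])
    lx <- loss_x(fw$a[, 1L], matched$x_prime[bi])
    lo <- if (mode == "causal")
      ly + config$weight_x * lx +
        config$weight_reg * ifelse(degenerate, 0, lr)
    else ly
    w <- length(bi)
    vals <- c(ly, lx, lr, lo)
    ok <- !is.na(vals)
    acc[ok] <- acc[ok] + w * vals[ok]
    wt[ok] <- wt[ok] + w
  }
  out <- acc / pmax(wt, 1)
  names(out) <- c("l_y", "l_x", "l_reg", "l_opt")
  out
}

#' @export
print.collider_net <- function(x, ...) {
  cat(sprintf("<collider_net mode=%s%s: %d parameters, best epoch %d/%d, val loss %.4f>\n",
              x$mode, if (!is.null(x$target)) paste0("(", x$target, ")") else "",
              n_parameters(x$params), x$best_epoch, x$n_epochs,
              x$best_val_loss))
  invisible(x)
}

#' Inherent measurement error of the image pipeline
#'
#' Trains the same architecture twice in ground-truth mode, predicting the
#' subjects' simulated `x` (size collider) and `z` (heterogeneity) from
#' the matched images, and returns the validation MSEs. These quantify the
#' error floor induced by the feature matching and the network, and are
#' used to calibrate the measurement noise added to `x, z` in the
#' regression baselines.
#'
#' @param matched_train,matched_val matched cohorts.
#' @param pool the image pool.
#' @param config a [net_config()].
#' @param seed integer seed.
#' @return Named numeric vector `c(mse_x =, mse_z =)`.
#' @export
ground_truth_measurement_error <- function(matched_train, matched_val, pool,
                                           config = net_config(),
                                           seed = 1L) {
  out <- numeric(2)
  names(out) <- c("mse_x", "mse_z")
  for (tg in c("x", "z")) {
    net <- train_network(matched_train, matched_val, pool,
                         mode = "ground_truth", config = config,
                         seed = seed + match(tg, c("x", "z")), target = tg)
    pred <- predict_network(net, matched_val, pool)
    out[paste0("mse_", tg)] <- mean((pred$y_hat - matched_val[[tg]])^2)
  }
  out
}

#' Deterministic eval-mode predictions and activations
#'
#' Runs the trained network over a matched cohort using the evaluation
#' augmentation path (center crop, no flips, dropout disabled), in
#' batches.
#'
#' @param net a trained `collider_net`.
#' @param matched a `matched_cohort`.
#' @param pool the image pool.
#' @return A list with `y_hat` (length n) and `a` (`n x n_k`).
#' @export
predict_network <- function(net, matched, pool) {
  if (!inherits(net, "collider_net")) stop("'net' must be a trained collider_net")
  n <- nrow(matched)
  cfg <- net$config
  y_hat <- numeric(n)
  a <- matrix(0, n, cfg$n_k)
  for (s in seq(1L, n, by = cfg$batch_size)) {
    bi <- s:min(s + cfg$batch_size - 1L, n)
    Xb <- gather_batch(pool, matched$patch[bi], "eval", cfg$input_dim)
    fw <- forward_network(net$params, Xb, matched$t[bi], cfg,
                          training = FALSE)
    y_hat[bi] <- fw$y_hat
    a[bi, ] <- fw$a
  }
  list(y_hat = y_hat, a = a)
}

#' Save / load model parameters as a flat named archive
#'
#' Checkpoints are written as one tab-delimited table of named flat
#' parameter values plus the config as YAML.
#'
#' @param net a `collider_net`.
#' @param path file path for the parameter table (the config is written
#'   alongside with extension `.config.yaml`).
#' @return `save_checkpoint` returns `path` invisibly.
#' @export
save_checkpoint <- function(net, path) {
  rows <- do.call(rbind, lapply(names(unclass(net$params)), function(nm) {
    v <- net$params[[nm]]
    data.frame(param = nm, index = seq_along(v), value = as.numeric(v))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  yaml::write_yaml(c(unclass(net$config), mode = net$mode),
                   paste0(path, ".config.yaml"))
  invisible(path)
}
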