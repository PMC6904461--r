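#' Extract last-layer activations for a matched cohort
#'
#' After training, all network parameters are fixed and the final-layer
#' activations are computed for every subject's matched image along the
#' deterministic evaluation path (center crop, no flips, dropout off).
#'
#' @param net a trained `collider_net`.
#' @param matched a `matched_cohort`.
#' @param pool the image pool.
#' @return Numeric matrix `n x n_k`; column 1 is the reserved collider
#'   slot.
#' @export
extract_activations <- function(net, matched, pool) {
  predict_network(net, matched, pool)$a
}

# OLS fit + validation metrics shared by all model variants.
# design: data.frame with column t plus regressors; y: outcome.
# Near-constant regressors (training sd below `sd_tol`) are excluded up
# front: their coefficients are unidentified at the training scale and can
# produce arbitrarily bad out-of-sample predictions.
fit_and_score <- function(model_name, variables, design, y, train_index,
                          diagnostics = NULL, sd_tol = 1e-3) {
  sds <- vapply(design, function(v) sd(v[train_index]), numeric(1))
  degen <- names(design) != "t" & !(sds > sd_tol)
  if (any(degen)) {
    warning(sprintf("%s: dropping %d near-constant activation column(s)",
                    model_name, sum(degen)))
    design <- design[, !degen, drop = FALSE]
  }
  df <- cbind(y = y, design)
  fit <- stats::lm(y ~ ., data = df[train_index, , drop = FALSE])
  cf <- coef(fit)
  if (anyNA(cf)) {
    warning(sprintf("%s: rank-deficient design; dropping %d collinear column(s)",
                    model_name, sum(is.na(cf))))
    cf[is.na(cf)] <- 0
  }
  val <- setdiff(seq_len(nrow(df)), train_index)
  Xv <- cbind(1, as.matrix(design[val, , drop = FALSE]))
  pred <- drop(Xv %*% cf[c("(Intercept)", colnames(design))])
  structure(list(model = model_name, variables = variables,
                 ate = unname(cf["t"]),
                 mse_y = mean((y[val] - pred)^2),
                 coefficients = cf,
                 diagnostics = diagnostics),
            class = "fit_summary")
}

#' @export
print.fit_summary <- function(x, ...) {
  cat(sprintf("%-12s %-18s MSE_y %.3f  ATE %.3f\n", x$model, x$variables,
              x$mse_y, x$ate))
  invisible(x)
}

#' Collect fit summaries into a report table
#' @param fits a list of `fit_summary` objects.
#' @return A data.frame with columns `model`, `variables`, `mse_y`, `ate`.
#' @export
summary_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f)
    data.frame(model = f$model, variables = f$variables,
               mse_y = f$mse_y, ate = f$ate)))
}

#' Post-hoc constrained ("CausalNet") treatment-effect estimate
#'
#' Ordinary least squares of the outcome on the treatment indicator and
#' the constrained activations (columns `2..n_k`; the reserved collider
#' slot is excluded), fitted on the training subjects. The resulting `t`
#' coefficient is the estimated average treatment effect; the outcome MSE
#' is evaluated on the validation subjects. The independence diagnostic
#' (R-squared of the measured collider regressed on the constrained
#' activations over the validation set) is attached.
#'
#' @param activations `n x n_k` activation matrix from
#'   [extract_activations()].
#' @param t,y treatment and outcome vectors (length n).
#' @param train_index integer indices of the training subjects; all others
#'   are validation.
#' @param x_prime optional standardized measured collider for the
#'   independence diagnostic.
#' @return A `fit_summary` with fields `ate`, `mse_y`, `diagnostics`.
#' @export
causalnet_fit <- function(activations, t, y, train_index, x_prime = NULL) {
  a_rest <- as.data.frame(activations[, -1L, drop = FALSE])
  names(a_rest) <- paste0("a", seq_len(ncol(a_rest)) + 1L)
  diag <- NULL
  if (!is.null(x_prime)) {
    val <- setdiff(seq_along(t), train_index)
    diag <- list(independence_r2 = r_squared(
      x_prime[val], as.matrix(a_rest)[val, , drop = FALSE]))
  }
  fit_and_score("CausalNet", "t, a_j (j > 1)",
                cbind(data.frame(t = t), a_rest), y, train_index, diag)
}

#' Unconstrained ("BiasedNet") treatment-effect estimate
#'
#' Ordinary least squares of the outcome on the treatment indicator and
#' all `n_k` activations of an unconstrained (outcome-loss-only) network,
#' i.e. conditioning on the entire image. Both network variants are scored
#' under the same post-hoc estimation procedure for comparability.
#'
#' @inheritParams causalnet_fit
#' @return A `fit_summary`.
#' @export
biasednet_fit <- function(activations, t, y, train_index, x_prime = NULL) {
  a_all <- as.data.frame(activations)
  names(a_all) <- paste0("a", seq_len(ncol(a_all)))
  diag <- NULL
  if (!is.null(x_prime)) {
    val <- setdiff(seq_along(t), train_index)
    diag <- list(collider_r2 = r_squared(
      x_prime[val], as.matrix(a_all)[val, , drop = FALSE]))
  }
  fit_and_score("BiasedNet", "t, image",
                cbind(data.frame(t = t), a_all), y, train_index, diag)
}

# R-squared of OLS of target on columns of X (with intercept)
r_squared <- function(target, X) {
  fit <- stats::lm.fit(cbind(1, X), target)
  1 - mean(fit$residuals^2) / mean((target - mean(target))^2)
}

#' Regression baselines on (noisy) tabular features
#'
#' The three tabular reference models: (1) treatment only, (2) treatment
#' plus noisy size and heterogeneity (conditions on the collider), (3)
#' treatment plus noisy heterogeneity only (the optimum for this setup:
#' prognostic image information without the collider). Measured features
#' are emulated as `x' = x + N(0, sqrt(mse_x))` and
#' `z' = z + N(0, sqrt(mse_z))`, with the noise calibrated from the
#' ground-truth network run ([ground_truth_measurement_error()]) or
#' supplied explicitly. Models are fitted on the training cohort and
#' scored on the validation cohort.
#'
#' @param cohort_train,cohort_val cohorts from [sample_cohort()].
#' @param noise_mse named vector `c(mse_x =, mse_z =)` of measurement-error
#'   variances. The defaults are the validation MSEs of the ground-truth
#'   network runs on the reference synthetic pipeline (3000/1000 matched
#'   subjects, default pool): the packaged calibration of the pipeline's
#'   inherent feature error.
#' @param seed integer seed for the added measurement noise.
#' @return List of three `fit_summary` objects, names `t`, `t_xp_zp`,
#'   `t_zp`.
#' @export
regression_baselines <- function(cohort_train, cohort_val,
                                 noise_mse = c(mse_x = 0.126, mse_z = 0.171),
                                 seed = 1L) {
  set.seed(seed)
  co <- rbind(as.data.frame(cohort_train), as.data.frame(cohort_val))
  n <- nrow(co)
  tr <- seq_len(nrow(cohort_train))
  xp <- co$x + rnorm(n, 0, sqrt(noise_mse[["mse_x"]]))
  zp <- co$z + rnorm(n, 0, sqrt(noise_mse[["mse_z"]]))
  list(
    t = fit_and_score("Regression", "t", data.frame(t = co$t), co$y, tr),
    t_xp_zp = fit_and_score("Regression", "t, x', z'",
                            data.frame(t = co$t, xp = xp, zp = zp),
                            co$y, tr),
    t_zp = fit_and_score("Regression*", "t, z'",
                         data.frame(t = co$t, zp = zp), co$y, tr))
}
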