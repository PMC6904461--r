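#' Outcome loss: minibatch mean squared error
#'
#' @param y_hat predicted outcomes.
#' @param y observed outcomes, same length.
#' @return Mean of squared residuals.
#' @export
loss_y <- function(y_hat, y) {
  if (length(y_hat) == 0L) stop("empty batch")
  if (length(y_hat) != length(y)) stop("'y_hat' and 'y' lengths differ")
  mean((y_hat - y)^2)
}

#' Collider loss: mean squared error of the reserved activation
#'
#' Penalizes the distance between the reserved first last-layer activation
#' and the measured (standardized) collider, so that a single activation
#' learns to approximate the collider.
#'
#' @param a1 first last-layer activation, one value per subject.
#' @param x_prime standardized measured collider, same length.
#' @return Mean of squared differences.
#' @export
loss_x <- function(a1, x_prime) {
  if (length(a1) == 0L) stop("empty batch")
  if (length(a1) != length(x_prime)) stop("'a1' and 'x_prime' lengths differ")
  mean((a1 - x_prime)^2)
}

#' Independence regularizer
#'
#' Within a minibatch, the measured collider is regressed by ordinary least
#' squares (with intercept) on the constrained last-layer activations. The
#' loss is the hinge `max(0, MSE(batch mean) - MSE(OLS fit))`: it is zero
#' exactly when the activations predict the collider no better than the
#' batch mean, and otherwise equals the linear-predictability gain. A small
#' ridge jitter on the normal equations keeps the in-batch solve stable.
#'
#' @param a_rest numeric matrix, `m x (N_k - 1)` constrained activations.
#' @param x_prime standardized measured collider, length `m`.
#' @param ridge jitter added to the diagonal of the normal equations.
#' @param gradient `"none"` (value only), `"full"` (differentiate through
#'   the closed-form OLS solution) or `"stop"` (treat the fitted
#'   coefficients as constants). With `"full"` or `"stop"` the gradient
#'   with respect to `a_rest` is attached as attribute `"grad"`.
#' @return The loss value (>= 0), optionally with a `"grad"` attribute.
#' @export
loss_reg <- function(a_rest, x_prime, ridge = 1e-6,
                     gradient = c("none", "full", "stop")) {
  gradient <- match.arg(gradient)
  a_rest <- as.matrix(a_rest)
  m <- nrow(a_rest)
  if (m == 0L || length(x_prime) != m)
    stop("'a_rest' rows and 'x_prime' length must match and be positive")
  if (m <= ncol(a_rest) + 1L)
    stop("degenerate batch: need more observations than regressors + 1")
  A <- cbind(1, a_rest)
  M <- crossprod(A) + ridge * diag(ncol(A))
  bh <- solve(M, crossprod(A, x_prime))
  r <- x_prime - drop(A %*% bh)
  mse_fit <- mean(r^2)
  mse_mean <- mean((x_prime - mean(x_prime))^2)
  val <- max(0, mse_mean - mse_fit)
  if (gradient == "none") return(val)
  if (val <= 0) {
    g <- matrix(0, m, ncol(a_rest))
  } else if (gradient == "stop") {
    g <- (2 / m) * tcrossprod(r, drop(bh))[, -1L, drop = FALSE]
  } else {
    s <- drop(solve(M, crossprod(A, r)))
    g <- (2 / m) * (tcrossprod(r, drop(bh)) + tcrossprod(r, s) -
                      tcrossprod(drop(A %*% s), drop(bh)))
    g <- g[, -1L, drop = FALSE]
  }
  attr(val, "grad") <- g
  val
}

#' Total loss breakdown
#'
#' The total training loss is the direct, unweighted sum of the outcome
#' loss, the collider loss and the independence regularizer. In the
#' unconstrained ("biased") training mode only the outcome loss is
#' optimized, in which case the total equals `l_y`.
#'
#' @param l_y,l_x,l_reg the three loss components.
#' @return An object of class `loss_breakdown` with fields `l_y`, `l_x`,
#'   `l_reg`, `l_total`.
#' @export
total_loss <- function(l_y, l_x = 0, l_reg = 0) {
  stopifnot(is.finite(l_y), is.finite(l_x), is.finite(l_reg))
  structure(list(l_y = as.numeric(l_y), l_x = as.numeric(l_x),
                 l_reg = as.numeric(l_reg),
                 l_total = as.numeric(l_y) + as.numeric(l_x) +
                   as.numeric(l_reg)),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("L_y = %.4f  L_x = %.4f  L_reg = %.4f  total = %.4f\n",
              x$l_y, x$l_x, x$l_reg, x$l_total))
  invisible(x)
}
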