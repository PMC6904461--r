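test_that("outcome and collider losses are minibatch mean squared errors", {
  expect_equal(loss_y(c(1, 2), c(1, 2)), 0)
  expect_equal(loss_y(c(2, 4), c(1, 1)), 5)          # residuals 1, 3
  y <- rnorm(20); yh <- rnorm(20)
  expect_equal(loss_y(yh + 3, y + 3), loss_y(yh, y)) # translation invariant
  expect_error(loss_y(numeric(0), numeric(0)), "empty")
  expect_error(loss_y(1:3, 1:2), "differ")

  expect_equal(loss_x(c(0.3, -1), c(0.3, -1)), 0)
  expect_equal(loss_x(c(3, 5), c(1, 3)), 4)          # constant offset 2
  a1 <- rnorm(15); xp <- rnorm(15)
  p <- sample(15)
  expect_equal(loss_x(a1[p], xp[p]), loss_x(a1, xp)) # permutation invariant
})

test_that("total loss is the exact unweighted sum", {
  expect_equal(total_loss(0, 0, 0)$l_total, 0)
  lb <- total_loss(1.0, 2.0, 0.5)
  expect_s3_class(lb, "loss_breakdown")
  expect_equal(lb$l_total, 3.5)
  expect_identical(lb$l_total, lb$l_y + lb$l_x + lb$l_reg)
  # outcome-only ("biased") training: total reduces to l_y
  expect_equal(total_loss(1.7)$l_total, 1.7)
})

# independent normal-equations oracle for the regularizer
oracle_reg <- function(A, x) {
  X <- cbind(1, A)
  beta <- solve(t(X) %*% X, t(X) %*% x)
  mse_fit <- mean((x - X %*% beta)^2)
  max(0, mean((x - mean(x))^2) - mse_fit)
}

test_that("regularizer matches the normal-equations oracle on random batches", {
  set.seed(31)
  for (rep in 1:8) {
    m <- sample(10:60, 1)
    k <- sample(1:5, 1)
    A <- matrix(rnorm(m * k), m, k)
    x <- rnorm(m) + A %*% rnorm(k) * runif(1, 0, 1.5)
    expect_equal(as.numeric(loss_reg(A, x, ridge = 0)), oracle_reg(A, x),
                 tolerance = 1e-8)
  }
})

test_that("regularizer hinge and degenerate cases behave as specified", {
  set.seed(32)
  x <- rnorm(40)
  # constant activation columns: OLS reduces to the batch mean, hinge at 0
  A0 <- matrix(2.5, 40, 5)
  expect_equal(as.numeric(loss_reg(A0, x)), 0)
  # one column equal to x: perfect fit, loss is the population variance
  A1 <- cbind(x, matrix(1.3, 40, 4))
  expect_equal(as.numeric(loss_reg(A1, x)), mean((x - mean(x))^2),
               tolerance = 1e-6)
  # independent activations at large m: loss small, bounded by the
  # overfitting gain of OLS with k regressors
  m <- 5000
  Abig <- matrix(rnorm(m * 5), m, 5)
  xb <- rnorm(m)
  v <- as.numeric(loss_reg(Abig, xb))
  expect_gte(v, 0)
  expect_lt(v, 10 * 5 / m * var(xb))
  expect_error(loss_reg(matrix(rnorm(12), 4, 3), rnorm(4)), "degenerate")
})

test_that("regularizer is invariant to affine reparameterization of a column", {
  set.seed(33)
  A <- matrix(rnorm(40 * 5), 40, 5)
  x <- rnorm(40) + 0.5 * A[, 2]
  base <- as.numeric(loss_reg(A, x, ridge = 0))
  A2 <- A
  A2[, 3] <- -4 * A[, 3] + 7
  expect_equal(as.numeric(loss_reg(A2, x, ridge = 0)), base,
               tolerance = 1e-8)
})

test_that("replacing a column by the collider itself never lowers the hinge", {
  set.seed(34)
  for (rep in 1:5) {
    A <- matrix(rnorm(40 * 5), 40, 5)
    x <- rnorm(40) + 0.3 * A[, 1]
    base <- as.numeric(loss_reg(A, x, ridge = 0))
    A2 <- A
    A2[, sample(5, 1)] <- x
    expect_gte(as.numeric(loss_reg(A2, x, ridge = 0)) + 1e-10, base)
  }
})

test_that("regularizer gradients match finite differences", {
  set.seed(35)
  m <- 25
  A <- cbind(0.8 * rnorm(m), matrix(rnorm(m * 3), m, 3))
  x <- 0.7 * A[, 1] + rnorm(m, 0, 0.4)
  for (mode in c("full", "stop")) {
    lr <- loss_reg(A, x, 1e-6, gradient = mode)
    g <- attr(lr, "grad")
    eps <- 1e-6
    num <- matrix(0, m, 4)
    for (j in 1:4) for (i in 1:m) {
      Ap <- A; Ap[i, j] <- Ap[i, j] + eps
      Am <- A; Am[i, j] <- Am[i, j] - eps
      num[i, j] <- (loss_reg(Ap, x, 1e-6) - loss_reg(Am, x, 1e-6)) / (2 * eps)
    }
    tol <- if (mode == "full") 1e-6 else 0.05
    expect_equal(g, num, tolerance = tol)
  }
  # inactive hinge: zero gradient
  Az <- matrix(0.1, m, 4)
  lr0 <- loss_reg(Az, x, gradient = "full")
  expect_equal(attr(lr0, "grad"), matrix(0, m, 4))
})
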