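test_that("architecture shapes and parameter count match the design", {
  cfg <- net_config()
  p <- init_network(cfg, seed = 1)
  # conv: 9*16+16 + 4*(144*16+16); fc: 144^2+144 twice, 144*12+12,
  # 12*6+6; head: 1+1+6
  expect_equal(n_parameters(p), 160 + 4 * 2320 + 20880 + 20880 + 1740 +
                 78 + 8)
  expect_equal(dim(p$k1), c(9L, 16L))
  expect_equal(dim(p$w1), c(144L, 144L))
  expect_equal(length(p$beta), 6L)
  imgs <- array(rnorm(51 * 51 * 3), c(51, 51, 3))
  fw <- forward_network(p, imgs, c(0, 1, 0), cfg)
  expect_equal(dim(fw$a), c(3L, 6L))
  expect_length(fw$y_hat, 3L)
  # the five conv stages shrink 51 -> 25 -> 12 -> 6 -> 3 and flatten to 144
  expect_equal(colliderfree:::conv_stage_dims(51L), c(51L, 25L, 12L, 6L, 3L))
  expect_error(forward_network(p, imgs, c(0, 1)), "shape mismatch")
  expect_error(net_config(batch_size = 6), "batch_size")
})

test_that("the head is affine in treatment and activations", {
  cfg <- net_config()
  p <- init_network(cfg, seed = 2)
  # zero the last linear layer: all activations become the bias fb4 = 0
  p$w4[] <- 0; p$fb4[] <- 0
  p$beta0 <- 1.25; p$beta_t <- 0.75
  imgs <- array(rnorm(51 * 51 * 4), c(51, 51, 4))
  fw0 <- forward_network(p, imgs, rep(0, 4), cfg)
  fw1 <- forward_network(p, imgs, rep(1, 4), cfg)
  expect_equal(unname(fw0$y_hat), rep(1.25, 4))
  expect_equal(unname(fw1$y_hat), rep(2.0, 4))
  # flipping t changes the prediction by exactly beta_t, any image
  p2 <- init_network(cfg, seed = 3)
  fA <- forward_network(p2, imgs, c(0, 1, 0, 1), cfg)
  fB <- forward_network(p2, imgs, c(1, 0, 1, 0), cfg)
  expect_equal(fB$y_hat - fA$y_hat, p2$beta_t * c(1, -1, 1, -1))
  expect_equal(fA$a, fB$a)
})

test_that("eval-mode forward passes are deterministic", {
  cfg <- net_config()
  p <- init_network(cfg, seed = 4)
  imgs <- array(rnorm(51 * 51 * 2), c(51, 51, 2))
  f1 <- forward_network(p, imgs, c(0, 1), cfg)
  f2 <- forward_network(p, imgs, c(0, 1), cfg)
  expect_identical(f1$y_hat, f2$y_hat)
  expect_identical(f1$a, f2$a)
})

test_that("backpropagated gradients match finite differences", {
  cfg <- net_config()
  set.seed(6)
  p <- init_network(cfg, seed = 6)
  m <- 9
  imgs <- array(rnorm(51 * 51 * m), c(51, 51, m))
  tt <- rbinom(m, 1, 0.5); y <- rnorm(m); xp <- rnorm(m)
  keep <- 1 - cfg$dropout
  masks <- list(matrix(rbinom(m * 144, 1, keep) / keep, m, 144),
                matrix(rbinom(m * 144, 1, keep) / keep, m, 144),
                matrix(rbinom(m * 12, 1, keep) / keep, m, 12))
  lossfun <- function(p) {
    fw <- forward_network(p, imgs, tt, cfg, training = TRUE,
                          drop_masks = masks)
    loss_y(fw$y_hat, y) + loss_x(fw$a[, 1], xp) +
      as.numeric(loss_reg(fw$a[, -1, drop = FALSE], xp, cfg$ridge))
  }
  fw <- forward_network(p, imgs, tt, cfg, training = TRUE,
                        drop_masks = masks)
  lr <- loss_reg(fw$a[, -1, drop = FALSE], xp, cfg$ridge, gradient = "full")
  d_a <- matrix(0, m, 6)
  d_a[, 1] <- 2 * (fw$a[, 1] - xp) / m
  d_a[, -1] <- attr(lr, "grad")
  g <- backward_network(p, fw$cache, 2 * (fw$y_hat - y) / m, d_a, cfg)
  eps <- 1e-5
  # a spread of parameters across head, fully connected and conv layers
  set.seed(7)
  for (nm in c("beta_t", "beta", "w4", "fb2", "w2", "k5", "cb3", "k2")) {
    for (i in sample(length(p[[nm]]), min(3, length(p[[nm]])))) {
      p2 <- p; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- p; p3[[nm]][i] <- p3[[nm]][i] - eps
      num <- (lossfun(p2) - lossfun(p3)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("single-layer conv and pooling primitives match naive oracles", {
  set.seed(8)
  X <- array(rnorm(6 * 6 * 2), c(6, 6, 2))   # two samples, one channel
  K <- matrix(rnorm(9 * 2), 9, 2)
  b <- rnorm(2)
  Y <- colliderfree:::conv3_forward(X, K, b, 2L)
  expect_equal(dim(Y), c(6L, 6L, 4L))
  naive <- function(img, k9, bb, i, j) {
    pad <- matrix(0, 8, 8); pad[2:7, 2:7] <- img
    sum(pad[i:(i + 2), j:(j + 2)] * matrix(k9, 3, 3)) + bb
  }
  for (i in c(1, 3, 6)) for (j in c(1, 4, 6))
    expect_equal(Y[i, j, 2], naive(X[, , 1], K[, 2], b[2], i, j))
  mp <- colliderfree:::maxpool2_forward(Y)
  expect_equal(dim(mp$out), c(3L, 3L, 4L))
  expect_equal(mp$out[2, 2, 1], max(Y[3:4, 3:4, 1]))
  # pooling backward routes gradient mass to the argmax positions only
  dX <- colliderfree:::maxpool2_backward(mp$out, mp$idx, 6L, 6L)
  expect_equal(sum(dX), sum(mp$out))
  expect_equal(sum(dX != 0), sum(mp$out != 0))
})

test_that("training is reproducible and obeys its mode contracts", {
  fx <- fixture_matched()
  cfg <- net_config(max_epochs = 2L, patience = 2L)
  n1 <- train_network(fx$train, fx$val, fx$pool, "causal", cfg, seed = 5)
  n2 <- train_network(fx$train, fx$val, fx$pool, "causal", cfg, seed = 5)
  expect_identical(n1$log, n2$log)
  expect_identical(n1$params$w4, n2$params$w4)
  expect_s3_class(n1, "collider_net")
  expect_true(all(c("epoch", "split", "l_y", "l_x", "l_reg", "l_total")
                  %in% names(n1$log)))
  expect_equal(n1$log$l_total,
               n1$log$l_y + n1$log$l_x + n1$log$l_reg)
  # predictions are deterministic after training
  p1 <- predict_network(n1, fx$val, fx$pool)
  p2 <- predict_network(n1, fx$val, fx$pool)
  expect_identical(p1$a, p2$a)
  expect_equal(nrow(p1$a), nrow(fx$val))
})

test_that("ground-truth mode learns heterogeneity beyond the mean predictor", {
  fx <- fixture_matched()
  cfg <- net_config(max_epochs = 8L, patience = 8L)
  net <- train_network(fx$train, fx$val, fx$pool, "ground_truth", cfg,
                       seed = 9, target = "z")
  pred <- predict_network(net, fx$val, fx$pool)
  mse <- mean((pred$y_hat - fx$val$z)^2)
  expect_lt(mse, mean((fx$val$z - mean(fx$val$z))^2))
})

test_that("noise calibrated from a measurement MSE attenuates as predicted", {
  set.seed(10)
  n <- 60000
  x <- rnorm(n)
  mse <- 0.35
  xp <- x + rnorm(n, 0, sqrt(mse))
  r2 <- summary(lm(xp ~ x))$r.squared
  expect_equal(r2, var(x) / (var(x) + mse), tolerance = 0.02)
})
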