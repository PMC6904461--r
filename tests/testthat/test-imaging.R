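test_that("size measurement is pixel count times pixel area", {
  expect_equal(measure_size(tiny_patch(dim = 10L, spacing = 0.7)), 49)
  one <- image_patch(matrix(0, 5, 5),
                     matrix(seq_len(25) == 13, 5, 5), 1)
  expect_equal(measure_size(one), 1)
  # mirroring the mask leaves the size unchanged
  m <- matrix(FALSE, 8, 8); m[2:5, 3:7] <- TRUE
  p1 <- image_patch(matrix(0, 8, 8), m, 0.7)
  p2 <- image_patch(matrix(0, 8, 8), m[, 8:1], 0.7)
  expect_equal(measure_size(p1), measure_size(p2))
})

test_that("heterogeneity is the population variance inside the mask", {
  expect_equal(measure_heterogeneity(tiny_patch(3.7)), 0)
  px <- matrix(99, 4, 4); px[1, 1] <- 0; px[1, 2] <- 2
  m <- matrix(FALSE, 4, 4); m[1, 1:2] <- TRUE
  expect_equal(measure_heterogeneity(image_patch(px, m, 1)), 1)
  # background intensities are irrelevant
  px2 <- px; px2[!m] <- rnorm(14)
  expect_equal(measure_heterogeneity(image_patch(px2, m, 1)), 1)
  expect_error(measure_heterogeneity(image_patch(px, m & (px == 0), 1)),
               "2 foreground")
})

test_that("patch constructor enforces its invariants", {
  expect_error(image_patch(matrix(0, 4, 4), matrix(TRUE, 5, 5), 1),
               "identical shapes")
  expect_error(image_patch(matrix(0, 4, 4), matrix(FALSE, 4, 4), 1),
               "foreground")
  expect_error(image_patch(matrix(0, 4, 4), matrix(TRUE, 4, 4), 0),
               "positive")
})

test_that("pool filtering keeps the 20 mm^2 boundary and is idempotent", {
  mk <- function(n_px, n_ann = 4L) {
    m <- matrix(FALSE, 30, 30); m[seq_len(n_px)] <- TRUE
    image_patch(matrix(0, 30, 30), m, 1, n_annotations = n_ann,
                n_annotators = 4L)
  }
  pool <- list(mk(19), mk(20), mk(25))  # sizes 19.9-ish: spacing 1 -> mm2 = px
  sizes <- sapply(filter_pool(pool, min_size_mm2 = 20), measure_size)
  expect_equal(sizes, c(20, 25))
  expect_length(filter_pool(pool, min_size_mm2 = 100), 0)
  f1 <- filter_pool(pool)
  expect_identical(filter_pool(f1), f1)
  # annotator agreement filter
  pool2 <- list(mk(30, 4L), mk(30, 3L))
  expect_length(filter_pool(pool2), 1)
  expect_length(filter_pool(pool2, require_all_annotators = FALSE), 2)
})

test_that("preprocessing yields a centred, standardized 100-pixel patch", {
  # 7 cm field of view at 0.7 mm is 100 pixels per side
  expect_equal(0.07 / 0.0007, 100)
  set.seed(5)
  px <- matrix(rnorm(150 * 150), 150, 150)
  m <- matrix(FALSE, 150, 150); m[70:80, 60:75] <- TRUE
  out <- preprocess_patch(px, m, spacing_mm = 0.7)
  expect_equal(dim(out$pixels), c(100L, 100L))
  expect_false(attr(out, "padded"))
  # already-isotropic input: resampling is the identity on the pixel grid
  cr <- round(mean(which(m, arr.ind = TRUE)[, 1]))
  cc <- round(mean(which(m, arr.ind = TRUE)[, 2]))
  expect_equal(out$pixels, px[(cr - 49):(cr + 50), (cc - 49):(cc + 50)])
  # standardization constants are applied
  out2 <- preprocess_patch(px, m, 0.7, norm_mean = 2, norm_sd = 4)
  expect_equal(out2$pixels, (out$pixels - 2) / 4)
  # nodule near the border: edge replication plus a flag
  m2 <- matrix(FALSE, 150, 150); m2[2:6, 2:6] <- TRUE
  out3 <- preprocess_patch(px, m2, 0.7)
  expect_true(attr(out3, "padded"))
  expect_equal(dim(out3$pixels), c(100L, 100L))
})

test_that("training-pool intensities are standardized to zero mean, unit sd", {
  pool <- fixture_pool()
  tr <- pool$split == "train"
  expect_equal(mean(pool$pixels[, , tr]), 0, tolerance = 0.01)
  expect_equal(sd(as.numeric(pool$pixels[, , tr])), 1, tolerance = 0.01)
})

test_that("augmentation crops and flips as specified", {
  set.seed(9)
  px <- matrix(rnorm(100 * 100), 100, 100)
  e1 <- augment_patch(px, "eval")
  e2 <- augment_patch(px, "eval")
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(51L, 51L))
  # center crop is the 0-based half-open window [25, 76)
  expect_equal(e1, px[26:76, 26:76])
  t1 <- augment_patch(px, "train")
  expect_equal(dim(t1), c(51L, 51L))
  expect_equal(augment_patch(matrix(7, 100, 100), "train"),
               matrix(7, 51, 51))
  expect_error(augment_patch(matrix(0, 40, 40), "train"), "smaller")
})

test_that("cropping and mirroring do not change mask-restricted features", {
  pool <- fixture_pool()
  p <- pool_patch(pool, which(pool$features$x_prime < 100)[1])
  inside <- which(p$mask, arr.ind = TRUE)
  # this small fixture nodule lies inside the center crop
  expect_true(all(inside[, 1] >= 26 & inside[, 1] <= 76 &
                    inside[, 2] >= 26 & inside[, 2] <= 76))
  crop_px <- p$pixels[26:76, 26:76]
  crop_mask <- p$mask[26:76, 26:76]
  cp <- image_patch(crop_px, crop_mask, p$spacing_mm)
  expect_equal(measure_size(cp), measure_size(p))
  expect_equal(measure_heterogeneity(cp), measure_heterogeneity(p))
  fp <- image_patch(crop_px[51:1, ], crop_mask[51:1, ], p$spacing_mm)
  expect_equal(measure_heterogeneity(fp), measure_heterogeneity(cp))
})
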