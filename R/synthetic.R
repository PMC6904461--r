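#' Generate a synthetic nodule-image pool
#'
#' Renders elliptical "nodules" on cluttered, CT-like backgrounds so that
#' the two image features the pipeline relies on — size (segmented area in
#' mm^2) and heterogeneity (intensity variance within the segmentation) —
#' span controllable ranges and are recoverable by measurement. Target
#' areas are drawn log-uniformly over `size_range_mm2`; intra-nodule
#' texture is a smoothed Gaussian random field rescaled so its within-mask
#' variance equals a target drawn uniformly over `hetero_range`.
#'
#' The background emulates the visual difficulty of real chest CT: a
#' smooth parenchyma-scale intensity field, fine acquisition noise, and
#' sparse blob- and vessel-like structures whose intensities overlap the
#' nodule's. The nodule's mean contrast varies from patch to patch and its
#' rim is blended over about one pixel. Mask-based measurement is exact,
#' but visually recovering size or heterogeneity from a cropped patch
#' without the mask is realistically imperfect — the property that gives
#' the image pipeline an inherent measurement error, quantified post hoc
#' by the ground-truth network run.
#'
#' After rendering, intensities are standardized with a global mean and
#' standard deviation computed from the training split only, and per-split
#' feature standardization constants are recorded (log-area z-scores for
#' size, raw z-scores for heterogeneity).
#'
#' @param n_patches number of patches (default 6543; with the default
#'   `train_frac` this gives 5015 training and 1528 validation patches).
#' @param size_range_mm2 target area interval in mm^2 (default 20 to 600).
#' @param hetero_range target intensity-variance interval (default 0.05 to
#'   4, on the raw rendering scale).
#' @param seed integer seed; pools are bit-identical for a fixed seed.
#' @param spacing_mm pixel spacing (default 0.7).
#' @param dim patch side length in pixels (default 100).
#' @param train_frac fraction of nodules assigned to the training split.
#' @param bg_sd fine background noise standard deviation (raw scale).
#' @param nodule_level centre of the per-patch nodule contrast range; the
#'   rendered mean contrast is drawn uniformly within +/- 35% of it.
#' @param clutter_amp amplitude of the blob/vessel-like background
#'   structures relative to the nodule contrast (0 disables clutter).
#' @return An object of class `image_pool`: pixel and mask arrays of shape
#'   `dim x dim x n_patches`, per-patch metadata, a feature table with
#'   measured `x_prime` (mm^2) and `z_prime` (variance), and the
#'   training-split standardization constants.
#' @export
#' @examples
#' pool <- generate_synthetic_pool(20, seed = 1)
#' pool$features[1:3, ]
generate_synthetic_pool <- function(n_patches = 6543L,
                                    size_range_mm2 = c(20, 600),
                                    hetero_range = c(0.05, 4),
                                    seed = 1L,
                                    spacing_mm = 0.7,
                                    dim = 100L,
                                    train_frac = 5015 / 6543,
                                    bg_sd = 0.2,
                                    nodule_level = 1,
                                    clutter_amp = 1) {
  if (n_patches < 1L) stop("'n_patches' must be at least 1")
  if (any(size_range_mm2 <= 0) || diff(size_range_mm2) < 0)
    stop("'size_range_mm2' must be a positive non-decreasing interval")
  if (any(hetero_range <= 0) || diff(hetero_range) < 0)
    stop("'hetero_range' must be a positive non-decreasing interval")
  # the most elongated ellipse drawn (aspect ratio 0.6) must fit the patch
  max_semi <- 0.45 * dim
  capacity_mm2 <- pi * 0.6 * max_semi^2 * spacing_mm^2
  if (size_range_mm2[2] > capacity_mm2)
    stop(sprintf("size_range_mm2 upper bound %.0f exceeds patch capacity %.0f mm^2",
                 size_range_mm2[2], capacity_mm2))
  set.seed(seed)
  n <- as.integer(n_patches)
  pixels <- array(0, c(dim, dim, n))
  masks <- array(FALSE, c(dim, dim, n))
  target_area <- exp(runif(n, log(size_range_mm2[1]), log(size_range_mm2[2])))
  target_het <- runif(n, hetero_range[1], hetero_range[2])
  ratio <- runif(n, 0.6, 1)
  theta <- runif(n, 0, pi)
  jit_r <- round(runif(n, -2, 2))
  jit_c <- round(runif(n, -2, 2))
  ctr <- (dim + 1) / 2
  gr <- matrix(seq_len(dim), dim, dim)         # row coordinate
  gc <- matrix(seq_len(dim), dim, dim, byrow = TRUE)
  level <- runif(n, 0.65, 1.35) * nodule_level
  for (i in seq_len(n)) {
    area_px <- target_area[i] / spacing_mm^2
    a <- sqrt(area_px / (pi * ratio[i]))       # semi-major (pixels)
    b <- a * ratio[i]
    dr <- gr - (ctr + jit_r[i]); dc <- gc - (ctr + jit_c[i])
    u <- dr * cos(theta[i]) + dc * sin(theta[i])
    v <- -dr * sin(theta[i]) + dc * cos(theta[i])
    mask <- (u / a)^2 + (v / b)^2 <= 1
    # background: parenchyma-scale field + fine noise + sparse structures
    img <- smooth121(matrix(rnorm(dim * dim, 0, bg_sd), dim, dim), 1L)
    par_f <- smooth121(matrix(rnorm(dim * dim), dim, dim), 8L)
    img <- img + par_f / max(sd(par_f), 1e-12) * 0.25
    if (clutter_amp > 0) {
      f1 <- smooth121(matrix(rnorm(dim * dim), dim, dim), 3L)
      f2 <- smooth121(matrix(rnorm(dim * dim), dim, dim), 6L)
      img <- img +
        clutter_amp * runif(1, 0.6, 1.4) * pmax(f1 / sd(f1) - 1, 0) +
        clutter_amp * runif(1, 0.5, 1.2) * pmax(f2 / sd(f2) - 1.2, 0)
    }
    field <- smooth121(matrix(rnorm(dim * dim), dim, dim), 2L)
    fm <- field[mask]
    s <- sqrt(mean((fm - mean(fm))^2))
    field <- (field - mean(fm)) / max(s, 1e-12) * sqrt(target_het[i])
    nod <- level[i] + field
    alpha <- smooth121(mask + 0, 1L)           # ~1 px rim blend
    img <- img * (1 - alpha) + nod * alpha
    pixels[, , i] <- img
    masks[, , i] <- mask
  }
  split <- rep("validation", n)
  split[sample.int(n, round(train_frac * n))] <- "train"
  train <- split == "train"
  if (!any(train)) train <- rep(TRUE, n)       # degenerate tiny pools
  gm <- mean(pixels[, , train])
  gs <- sd(as.numeric(pixels[, , train]))
  if (!is.finite(gs) || gs == 0) gs <- 1
  pixels <- (pixels - gm) / gs
  x_prime <- apply(masks, 3, sum) * spacing_mm^2
  z_prime <- vapply(seq_len(n), function(i) {
    v <- pixels[, , i][masks[, , i]]
    mean((v - mean(v))^2)
  }, numeric(1))
  lx <- log(x_prime)
  std <- list(
    x_meanlog = mean(lx[train]),
    x_sdlog = max(sd(lx[train]), 1e-12),
    z_mean = mean(z_prime[train]),
    z_sd = max(sd(z_prime[train]), 1e-12),
    intensity_mean = gm, intensity_sd = gs)
  pool <- list(
    pixels = pixels, masks = masks, spacing_mm = spacing_mm,
    source_id = sprintf("synth-%05d", seq_len(n)),
    n_annotations = rep(4L, n), n_annotators = rep(4L, n),
    split = split,
    features = data.frame(source_id = sprintf("synth-%05d", seq_len(n)),
                          split = split, x_prime = x_prime,
                          z_prime = z_prime,
                          target_area = target_area,
                          target_het = target_het),
    standardization = std,
    generator = list(size_range_mm2 = size_range_mm2,
                     hetero_range = hetero_range, seed = seed,
                     dim = dim, train_frac = train_frac))
  class(pool) <- "image_pool"
  pool
}

#' @export
print.image_pool <- function(x, ...) {
  cat(sprintf("<image_pool: %d patches (%d train / %d validation), %dx%d px @ %.2f mm>\n",
              length(x$source_id), sum(x$split == "train"),
              sum(x$split == "validation"), nrow(x$pixels), ncol(x$pixels),
              x$spacing_mm))
  invisible(x)
}

#' Extract one patch from a pool
#'
#' @param pool an `image_pool`.
#' @param i patch index.
#' @return An [image_patch()].
#' @export
pool_patch <- function(pool, i) {
  image_patch(pool$pixels[, , i], pool$masks[, , i], pool$spacing_mm,
              n_annotations = pool$n_annotations[i],
              n_annotators = pool$n_annotators[i],
              source_id = pool$source_id[i])
}

#' Standardized pool features
#'
#' Size is standardized as a z-score of log-area and heterogeneity as a
#' raw z-score, both using training-split constants, so that pool features
#' live on the same scale as the simulated `(x, z)` (standard normal by
#' construction).
#'
#' @param pool an `image_pool`.
#' @param idx patch indices (default all).
#' @return A data.frame with columns `xs` and `zs`.
#' @export
pool_standardized_features <- function(pool, idx = seq_along(pool$source_id)) {
  s <- pool$standardization
  data.frame(
    xs = (log(pool$features$x_prime[idx]) - s$x_meanlog) / s$x_sdlog,
    zs = (pool$features$z_prime[idx] - s$z_mean) / s$z_sd)
}

#' Match simulated subjects to pool images
#'
#' For each subject, draws (with replacement) the patch of the requested
#' split that minimizes the Euclidean distance between the subject's
#' `(x, z)` and the patch's standardized measured features `(x', z')`.
#' Ties are broken by the lowest pool index. Matching is deterministic.
#'
#' @param cohort a cohort from [sample_cohort()].
#' @param pool an `image_pool`.
#' @param split `"train"` or `"validation"`: which pool split to draw from
#'   (validation subjects must use only validation images).
#' @param seed unused; accepted for interface symmetry with the other
#'   samplers (nearest-neighbour matching has no randomness).
#' @return A `matched_cohort` data.frame: the cohort columns plus `patch`
#'   (global pool index), `x_prime` and `z_prime` (the matched patch's
#'   standardized features).
#' @export
match_images <- function(cohort, pool, split = c("train", "validation"),
                         seed = NULL) {
  split <- match.arg(split)
  cand <- which(pool$split == split)
  if (length(cand) == 0L) stop("empty image pool for split ", split)
  f <- pool_standardized_features(pool, cand)
  n <- nrow(cohort)
  sel <- integer(n)
  chunk <- 512L
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    d2 <- outer(cohort$x[lo:hi], f$xs, "-")^2 +
      outer(cohort$z[lo:hi], f$zs, "-")^2
    sel[lo:hi] <- cand[max.col(-d2, ties.method = "first")]
  }
  out <- cbind(as.data.frame(cohort), patch = sel,
               x_prime = pool_standardized_features(pool, sel)$xs,
               z_prime = pool_standardized_features(pool, sel)$zs)
  class(out) <- c("matched_cohort", "data.frame")
  out
}

#' Serialize / load an image pool
#'
#' Pools are written as a directory holding a tab-delimited feature index
#' (`features.tsv`), a YAML metadata file and flat binary grids
#' (`pixels.bin` as doubles, `masks.bin` as raw 0/1), a compact run-time
#' interchange format.
#'
#' @param pool an `image_pool`.
#' @param dir directory (created if missing).
#' @return `save_pool` returns `dir` invisibly; `load_pool` the pool.
#' @export
save_pool <- function(pool, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(pool$features, file.path(dir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(spacing_mm = pool$spacing_mm, dim = dim(pool$pixels)[1],
               n = dim(pool$pixels)[3], split = pool$split,
               source_id = pool$source_id,
               n_annotations = pool$n_annotations,
               n_annotators = pool$n_annotators,
               standardization = pool$standardization,
               generator = pool$generator)
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  con <- file(file.path(dir, "pixels.bin"), "wb")
  writeBin(as.numeric(pool$pixels), con); close(con)
  con <- file(file.path(dir, "masks.bin"), "wb")
  writeBin(as.raw(as.integer(pool$masks)), con); close(con)
  invisible(dir)
}

#' @rdname save_pool
#' @export
load_pool <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  d <- meta$dim; n <- meta$n
  con <- file(file.path(dir, "pixels.bin"), "rb")
  px <- readBin(con, "numeric", d * d * n); close(con)
  con <- file(file.path(dir, "masks.bin"), "rb")
  mk <- readBin(con, "raw", d * d * n); close(con)
  pool <- list(pixels = array(px, c(d, d, n)),
               masks = array(as.logical(as.integer(mk)), c(d, d, n)),
               spacing_mm = meta$spacing_mm,
               source_id = unlist(meta$source_id),
               n_annotations = unlist(meta$n_annotations),
               n_annotators = unlist(meta$n_annotators),
               split = unlist(meta$split),
               features = utils::read.table(file.path(dir, "features.tsv"),
                                            header = TRUE, sep = "\t"),
               standardization = meta$standardization,
               generator = meta$generator)
  class(pool) <- "image_pool"
  pool
}
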