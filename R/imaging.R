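#' Construct an image patch
#'
#' A patch is a 2-D grayscale pixel grid plus a binary segmentation mask of
#' the same shape, with isotropic pixel spacing in mm. `n_annotations`
#' records how many readers marked a nodule on the slice, out of
#' `n_annotators` readers in total.
#'
#' @param pixels numeric matrix of intensities.
#' @param mask logical (or 0/1) matrix, same shape; at least one foreground
#'   pixel.
#' @param spacing_mm pixel edge length in mm (> 0).
#' @param n_annotations readers marking a nodule on this slice.
#' @param n_annotators total readers for this slice.
#' @param source_id opaque provenance string.
#' @return An object of class `image_patch`.
#' @export
image_patch <- function(pixels, mask, spacing_mm,
                        n_annotations = 1L, n_annotators = n_annotations,
                        source_id = "patch") {
  pixels <- as.matrix(pixels)
  if (!identical(dim(pixels), dim(as.matrix(mask))))
    stop("'pixels' and 'mask' must have identical shapes")
  mask <- matrix(as.logical(mask), nrow(pixels), ncol(pixels))
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L || spacing_mm <= 0)
    stop("'spacing_mm' must be a single positive number")
  if (!any(mask)) stop("mask must contain at least one foreground pixel")
  structure(list(pixels = pixels, mask = mask, spacing_mm = spacing_mm,
                 n_annotations = as.integer(n_annotations),
                 n_annotators = as.integer(n_annotators),
                 source_id = as.character(source_id)),
            class = "image_patch")
}

#' @export
print.image_patch <- function(x, ...) {
  cat(sprintf("<image_patch %s: %dx%d px @ %.2f mm, %d fg px>\n",
              x$source_id, nrow(x$pixels), ncol(x$pixels), x$spacing_mm,
              sum(x$mask)))
  invisible(x)
}

#' Measure nodule size from a patch
#'
#' Size is the segmented pixel count times the pixel area, in mm^2.
#'
#' @param patch an [image_patch()].
#' @return Size in mm^2.
#' @export
#' @examples
#' p <- image_patch(matrix(0, 10, 10), matrix(TRUE, 10, 10), 0.7)
#' measure_size(p)  # 100 * 0.49 = 49
measure_size <- function(patch) {
  stopifnot(inherits(patch, "image_patch"))
  n_fg <- sum(patch$mask)
  if (n_fg == 0L) stop("empty segmentation mask")
  n_fg * patch$spacing_mm^2
}

#' Measure nodule heterogeneity from a patch
#'
#' Heterogeneity is the variance of pixel intensities over the foreground
#' pixels only. The population convention (divide by N) is used: the pixel
#' set is a complete enumeration of the segmented region, not a sample.
#'
#' @param patch an [image_patch()].
#' @return Intensity variance (>= 0).
#' @export
measure_heterogeneity <- function(patch) {
  stopifnot(inherits(patch, "image_patch"))
  v <- patch$pixels[patch$mask]
  if (length(v) < 2L) stop("need at least 2 foreground pixels")
  mean((v - mean(v))^2)
}

#' Filter a pool of patches
#'
#' Removes patches whose measured size is strictly below `min_size_mm2`
#' and, when `require_all_annotators` is set, patches for which not every
#' reader marked a nodule on the slice. Patches are returned unmodified;
#' the output is always a subset of the input, so filtering is idempotent.
#'
#' @param patches list of [image_patch()] objects.
#' @param min_size_mm2 minimum retained size in mm^2 (default 20; a patch
#'   of exactly 20 mm^2 is kept).
#' @param require_all_annotators require `n_annotations == n_annotators`.
#' @return Filtered list (possibly empty).
#' @export
filter_pool <- function(patches, min_size_mm2 = 20,
                        require_all_annotators = TRUE) {
  keep <- vapply(patches, function(p) {
    measure_size(p) >= min_size_mm2 &&
      (!require_all_annotators || p$n_annotations == p$n_annotators)
  }, logical(1))
  patches[keep]
}

#' Preprocess a raw slice into a standard patch
#'
#' Resamples a raw image and its mask to isotropic `out_spacing` mm (7 x 7
#' cm field of view at 0.7 mm gives 100 x 100 pixels), recenters on the
#' mask centroid (rounded to the nearest native pixel), and standardizes
#' intensities with the supplied global mean and standard deviation
#' (computed once from the training pool). Image values are interpolated
#' bilinearly, the mask by nearest neighbour. If the nodule lies closer
#' than half a patch to the image border the patch is padded by edge
#' replication and flagged via the attribute `padded`.
#'
#' @param pixels raw intensity matrix.
#' @param mask binary matrix, same shape.
#' @param spacing_mm native isotropic pixel spacing.
#' @param out_dim output side length in pixels (default 100).
#' @param out_spacing output spacing in mm (default 0.7).
#' @param norm_mean,norm_sd global intensity standardization constants.
#' @param ... passed to [image_patch()] (`source_id`, annotator counts).
#' @return An [image_patch()] with attribute `padded` (logical).
#' @export
preprocess_patch <- function(pixels, mask, spacing_mm, out_dim = 100L,
                             out_spacing = 0.7, norm_mean = 0, norm_sd = 1,
                             ...) {
  pixels <- as.matrix(pixels)
  mask <- matrix(as.logical(mask), nrow(pixels), ncol(pixels))
  if (!any(mask)) stop("cannot compute nodule centroid: empty mask")
  H <- nrow(pixels); W <- ncol(pixels)
  idx <- which(mask, arr.ind = TRUE)
  cr <- round(mean(idx[, 1])); cc <- round(mean(idx[, 2]))
  step <- out_spacing / spacing_mm
  half <- out_dim %/% 2L
  # source coordinates of output pixel centres (native pixel units)
  src_r <- cr + (seq_len(out_dim) - half) * step
  src_c <- cc + (seq_len(out_dim) - half) * step
  padded <- any(src_r < 1 | src_r > H) || any(src_c < 1 | src_c > W)
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)  # edge replication
  # bilinear interpolation on the (clamped) source grid
  r0 <- clamp(floor(src_r), 1, H); r1 <- clamp(r0 + 1, 1, H)
  c0 <- clamp(floor(src_c), 1, W); c1 <- clamp(c0 + 1, 1, W)
  fr <- clamp(src_r, 1, H) - r0; fc <- clamp(src_c, 1, W) - c0
  out <- (1 - fr) %o% (1 - fc) * pixels[r0, c0, drop = FALSE] +
    fr %o% (1 - fc) * pixels[r1, c0, drop = FALSE] +
    (1 - fr) %o% fc * pixels[r0, c1, drop = FALSE] +
    fr %o% fc * pixels[r1, c1, drop = FALSE]
  rn <- clamp(round(src_r), 1, H); cn <- clamp(round(src_c), 1, W)
  mout <- mask[rn, cn, drop = FALSE]
  p <- image_patch((out - norm_mean) / norm_sd, mout, out_spacing, ...)
  attr(p, "padded") <- padded
  p
}

#' Crop-and-flip augmentation
#'
#' In training mode a uniformly random 51 x 51 crop is taken and the crop
#' is mirrored vertically and horizontally, each independently with
#' probability one half. In eval mode a deterministic center crop is taken
#' (rows and columns 26..76 of a 100-grid, the 0-based half-open window
#' \[25, 76)) and no flips are applied.
#'
#' @param pixels numeric matrix, at least `crop` pixels per side.
#' @param mode `"train"` or `"eval"`.
#' @param crop output side length (default 51).
#' @return A `crop` x `crop` numeric matrix. Training mode consumes the R
#'   random number stream; seed it with `set.seed()` for reproducibility.
#' @export
augment_patch <- function(pixels, mode = c("train", "eval"), crop = 51L) {
  mode <- match.arg(mode)
  H <- nrow(pixels); W <- ncol(pixels)
  if (H < crop || W < crop) stop("patch smaller than the crop size")
  if (mode == "eval") {
    r0 <- (H - crop + 1L) %/% 2L + 1L
    c0 <- (W - crop + 1L) %/% 2L + 1L
    return(pixels[r0:(r0 + crop - 1L), c0:(c0 + crop - 1L)])
  }
  r0 <- sample.int(H - crop + 1L, 1L)
  c0 <- sample.int(W - crop + 1L, 1L)
  out <- pixels[r0:(r0 + crop - 1L), c0:(c0 + crop - 1L)]
  if (runif(1) < 0.5) out <- out[rev(seq_len(crop)), , drop = FALSE]
  if (runif(1) < 0.5) out <- out[, rev(seq_len(crop)), drop = FALSE]
  out
}
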