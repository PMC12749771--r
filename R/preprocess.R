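# Tissue segmentation, grid patching and patch quality filtering.
#
# Segmentation follows the standard contour-based WSI pipeline: downscale,
# RGB -> HSV, threshold the saturation channel, median-blur the binary mask,
# morphological closing, then drop small regions. Patches are extracted on a
# non-overlapping grid at level 0 and kept iff their centre falls in a
# retained tissue region; a final RGB filter drops blank and contaminated
# (black marker / dust) patches.

#' Tissue segmentation parameters
#'
#' Defaults follow the "biopsy"-style preset used for small cryosection
#' specimens; all values are exposed because presets differ between scanners.
#'
#' @param downscale_factor Integer downscale applied before segmentation
#'   (area averaging over factor x factor blocks).
#' @param saturation_threshold HSV saturation threshold on the 0-255 scale;
#'   pixels strictly above it are tissue candidates.
#' @param median_blur_kernel Odd kernel width of the median blur.
#' @param closing_kernel Diameter of the disc structuring element for
#'   morphological closing.
#' @param min_region_area Minimum connected-region area, in pixels at the
#'   downscaled resolution.
#' @return An object of class `seg_params`.
#' @export
seg_params <- function(downscale_factor = 20L, saturation_threshold = 8,
                       median_blur_kernel = 7L, closing_kernel = 4L,
                       min_region_area = 100) {
  if (downscale_factor < 1) stop("configuration error: 'downscale_factor' must be >= 1", call. = FALSE)
  if (saturation_threshold < 0 || saturation_threshold > 255)
    stop("configuration error: 'saturation_threshold' must be in [0, 255]", call. = FALSE)
  if (median_blur_kernel < 1 || median_blur_kernel %% 2 == 0)
    stop("configuration error: 'median_blur_kernel' must be a positive odd integer", call. = FALSE)
  if (closing_kernel < 1) stop("configuration error: 'closing_kernel' must be >= 1", call. = FALSE)
  if (min_region_area < 0) stop("configuration error: 'min_region_area' must be >= 0", call. = FALSE)
  structure(list(downscale_factor = as.integer(downscale_factor),
                 saturation_threshold = saturation_threshold,
                 median_blur_kernel = as.integer(median_blur_kernel),
                 closing_kernel = as.integer(closing_kernel),
                 min_region_area = min_region_area),
            class = "seg_params")
}

#' Patch extraction parameters
#'
#' @param patch_size Patch side length in level-0 pixels.
#' @param stride Grid stride in pixels; equal to `patch_size` for
#'   non-overlapping tiling.
#' @param magnification Magnification tag recorded with the coordinates.
#' @return An object of class `patch_params`.
#' @export
patch_params <- function(patch_size = 224L, stride = patch_size,
                         magnification = "20x") {
  if (patch_size < 1) stop("configuration error: 'patch_size' must be >= 1", call. = FALSE)
  if (stride < 1) stop("configuration error: 'stride' must be >= 1", call. = FALSE)
  structure(list(patch_size = as.integer(patch_size), stride = as.integer(stride),
                 magnification = magnification),
            class = "patch_params")
}

#' Patch quality filter parameters
#'
#' All intensities are on the 0-255 scale.
#'
#' @param blank_mean_threshold Mean RGB intensity strictly above which a
#'   patch is considered blank (no tissue).
#' @param dark_pixel_value Per-channel value strictly below which a pixel
#'   counts as near-black.
#' @param dark_fraction_threshold Fraction of near-black pixels strictly
#'   above which a patch is contaminated (marker, dust, black regions).
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(blank_mean_threshold = 230, dark_pixel_value = 40,
                          dark_fraction_threshold = 0.3) {
  if (blank_mean_threshold < 0 || blank_mean_threshold > 255)
    stop("configuration error: 'blank_mean_threshold' must be in [0, 255]", call. = FALSE)
  if (dark_pixel_value < 0 || dark_pixel_value > 255)
    stop("configuration error: 'dark_pixel_value' must be in [0, 255]", call. = FALSE)
  if (dark_fraction_threshold < 0 || dark_fraction_threshold > 1)
    stop("configuration error: 'dark_fraction_threshold' must be in [0, 1]", call. = FALSE)
  structure(list(blank_mean_threshold = blank_mean_threshold,
                 dark_pixel_value = dark_pixel_value,
                 dark_fraction_threshold = dark_fraction_threshold),
            class = "filter_params")
}

# Integer-factor area-average downscaling of one channel plane.
downscale_plane <- function(plane, f) {
  if (f == 1) return(plane)
  h <- (nrow(plane) %/% f) * f
  w <- (ncol(plane) %/% f) * f
  p <- plane[seq_len(h), seq_len(w), drop = FALSE]
  # average f x f blocks: collapse rows, then columns
  rows <- rowsum(p, rep(seq_len(h %/% f), each = f)) / f
  t(rowsum(t(rows), rep(seq_len(w %/% f), each = f)) / f)
}

check_rgb_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("format error: expected an RGB image array (height x width x 3)", call. = FALSE)
  invisible(image)
}

#' Segment tissue in a slide image
#'
#' Fixed pipeline: integer-factor area-average downscale, RGB to HSV,
#' threshold on the saturation channel, median blur, morphological closing
#' with a disc, then removal of connected regions below `min_region_area`.
#'
#' @param image RGB array (height x width x 3, values in \[0, 1\]).
#' @param params A [seg_params()].
#' @return An object of class `tissue_mask`: `mask` (logical matrix at the
#'   downscaled resolution, retained regions only), `labels` (integer region
#'   label matrix), `regions` (data.frame of label and area), `outlines`
#'   (list of region outline coordinate matrices), `downscale_factor`, and
#'   `dim_level0` (the segmented image's height/width).
#' @export
segment_tissue <- function(image, params = seg_params()) {
  check_rgb_image(image)
  if (min(dim(image)[1:2]) < params$downscale_factor)
    stop("image dimensions must be at least the downscale factor", call. = FALSE)
  f <- params$downscale_factor
  r <- downscale_plane(image[, , 1], f)
  g <- downscale_plane(image[, , 2], f)
  b <- downscale_plane(image[, , 3], f)
  hsv <- grDevices::rgb2hsv(as.vector(r), as.vector(g), as.vector(b), maxColorValue = 1)
  sat <- matrix(hsv["s", ] * 255, nrow(r), ncol(r))
  mask <- sat > params$saturation_threshold

  blur_radius <- params$median_blur_kernel %/% 2L
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (blur_radius >= 1) m <- EBImage::medianFilter(m, blur_radius)
  brush_size <- params$closing_kernel + (params$closing_kernel %% 2L == 0L)
  if (brush_size >= 3) {
    m <- EBImage::closing(m > 0.5, EBImage::makeBrush(brush_size, shape = "disc"))
  }
  m <- matrix(as.numeric(m) > 0.5, nrow(mask), ncol(mask))

  labels <- EBImage::bwlabel(matrix(as.numeric(m), nrow(m), ncol(m)))
  labels <- matrix(as.integer(labels), nrow(m), ncol(m))
  areas <- if (max(labels) > 0) tabulate(labels[labels > 0], nbins = max(labels)) else integer(0)
  keep <- which(areas >= params$min_region_area)
  retained <- matrix(labels %in% keep & labels > 0, nrow(m), ncol(m))
  relabel <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_along(keep)) relabel[labels == keep[i]] <- i
  outlines <- if (length(keep))
    EBImage::ocontour(EBImage::Image(relabel)) else list()

  structure(list(mask = retained, labels = relabel,
                 regions = data.frame(label = seq_along(keep), area = areas[keep]),
                 outlines = outlines,
                 downscale_factor = f, dim_level0 = dim(image)[1:2]),
            class = "tissue_mask")
}

#' Extract grid patches whose centres fall in tissue
#'
#' Coordinates are 0-based level-0 pixels of patch top-left corners
#' (x = column, y = row), on the stride grid, with the half-open patch extent
#' fully inside the image. A patch is kept iff its centre pixel maps into a
#' retained tissue region of `mask`.
#'
#' @param image The RGB array `mask` was computed from.
#' @param mask A [segment_tissue()] result for `image`.
#' @param params A [patch_params()].
#' @param return_blocks If TRUE, also return the pixel block of each kept
#'   patch.
#' @return A list with `coords` (data.frame: x, y, level, magnification) and,
#'   if requested, `blocks` (list of patch_size^2 RGB arrays, parallel to
#'   `coords`).
#' @export
extract_patches <- function(image, mask, params = patch_params(),
                            return_blocks = FALSE) {
  check_rgb_image(image)
  if (!inherits(mask, "tissue_mask")) stop("mask must be a tissue_mask", call. = FALSE)
  if (!identical(as.integer(mask$dim_level0), as.integer(dim(image)[1:2])))
    stop("consistency error: mask was not produced from this image", call. = FALSE)
  ps <- params$patch_size; st <- params$stride
  h <- dim(image)[1]; w <- dim(image)[2]; f <- mask$downscale_factor
  xs <- seq(0L, w - ps, by = st)
  ys <- seq(0L, h - ps, by = st)
  grid <- expand.grid(x = xs, y = ys)
  cx <- grid$x + ps %/% 2L
  cy <- grid$y + ps %/% 2L
  # map level-0 centre pixel to downscaled mask cell (1-based indices)
  col_idx <- pmin(cx %/% f + 1L, ncol(mask$mask))
  row_idx <- pmin(cy %/% f + 1L, nrow(mask$mask))
  kept <- mask$mask[cbind(row_idx, col_idx)]
  n_kept <- sum(kept)
  coords <- data.frame(x = grid$x[kept], y = grid$y[kept],
                       level = rep(0L, n_kept),
                       magnification = rep(params$magnification, n_kept),
                       stringsAsFactors = FALSE)
  out <- list(coords = coords)
  if (return_blocks) {
    out$blocks <- lapply(seq_len(nrow(coords)), function(i) {
      image[coords$y[i] + seq_len(ps), coords$x[i] + seq_len(ps), , drop = FALSE]
    })
  }
  out
}

#' Filter patches for blank and contaminated content
#'
#' A patch is rejected as `blank` when its mean RGB intensity exceeds
#' `blank_mean_threshold`, and as `contaminated` when the fraction of pixels
#' with all channels below `dark_pixel_value` exceeds
#' `dark_fraction_threshold`. Kept and rejected sets partition the input in
#' order.
#'
#' @param blocks List of RGB patch arrays (values in \[0, 1\], equal square
#'   dimensions).
#' @param params A [filter_params()].
#' @return A list with `kept` (integer indices into `blocks`) and `rejected`
#'   (data.frame: index, reason in `blank`/`contaminated`).
#' @export
filter_patches <- function(blocks, params = filter_params()) {
  if (length(blocks) == 0)
    return(list(kept = integer(0),
                rejected = data.frame(index = integer(0), reason = character(0))))
  dims <- dim(blocks[[1]])
  reasons <- vapply(blocks, function(p) {
    if (!is.array(p) || length(dim(p)) != 3 || dim(p)[3] != 3 ||
        dim(p)[1] != dim(p)[2] || !identical(dim(p), dims))
      stop("format error: patches must be equal-sized square RGB blocks", call. = FALSE)
    v <- p * 255
    if (mean(v) > params$blank_mean_threshold) return("blank")
    dark <- v[, , 1] < params$dark_pixel_value &
            v[, , 2] < params$dark_pixel_value &
            v[, , 3] < params$dark_pixel_value
    if (mean(dark) > params$dark_fraction_threshold) return("contaminated")
    ""
  }, character(1))
  kept <- which(reasons == "")
  rejected <- data.frame(index = which(reasons != ""),
                         reason = reasons[reasons != ""],
                         stringsAsFactors = FALSE)
  list(kept = kept, rejected = rejected)
}
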