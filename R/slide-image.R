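# Synthetic slide images: white background, saturated elliptical tissue
# blobs, optional artefacts (black marker strokes, near-white blank holes,
# dust specks), plus the ground-truth tissue mask. These are fixtures for the
# preprocessing stage, not attempts at realistic histology texture.

#' Configuration for a synthetic slide image
#'
#' @param width,height Image dimensions in pixels (level 0).
#' @param n_blobs Number of elliptical tissue blobs.
#' @param blob_axis_range Range of ellipse semi-axes, as fractions of the
#'   shorter image side.
#' @param tissue_colour RGB triple in \[0, 1\] for tissue (eosin-like pink by
#'   default; saturated so HSV segmentation can find it).
#' @param colour_jitter SD of per-pixel Gaussian colour noise on tissue.
#' @param n_markers Number of black marker strokes.
#' @param n_holes Number of near-white blank holes punched into tissue.
#' @param n_dust Number of small dark dust specks.
#' @param patch_size Patch size the image is meant to be tiled with; width
#'   and height must be at least this.
#' @return An object of class `slide_image_config`.
#' @export
slide_image_config <- function(width = 896L, height = 896L, n_blobs = 1L,
                               blob_axis_range = c(0.18, 0.32),
                               tissue_colour = c(0.85, 0.45, 0.65),
                               colour_jitter = 0.02,
                               n_markers = 0L, n_holes = 0L, n_dust = 0L,
                               patch_size = 224L) {
  if (width < patch_size || height < patch_size)
    stop("configuration error: image dimensions must be at least one patch (",
         patch_size, " px)", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_blobs = as.integer(n_blobs), blob_axis_range = blob_axis_range,
                 tissue_colour = tissue_colour, colour_jitter = colour_jitter,
                 n_markers = as.integer(n_markers), n_holes = as.integer(n_holes),
                 n_dust = as.integer(n_dust), patch_size = as.integer(patch_size)),
            class = "slide_image_config")
}

# Logical H x W mask of a rotated ellipse. cx, cy in 0-based pixel
# coordinates (x = column, y = row).
rasterize_ellipse <- function(width, height, cx, cy, a, b, theta = 0) {
  xs <- matrix(rep(seq_len(width) - 1, each = height), height, width)
  ys <- matrix(rep(seq_len(height) - 1, times = width), height, width)
  dx <- xs - cx; dy <- ys - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  u * u + v * v <= 1
}

#' Generate a synthetic slide image and its ground-truth tissue mask
#'
#' @param config A [slide_image_config()].
#' @param seed Seed for the image's private RNG stream.
#' @return A list with `image` (height x width x 3 array in \[0, 1\],
#'   quantised to 8-bit so PNG round trips are exact) and `mask` (logical
#'   height x width, TRUE on tissue pixels; holes and marker strokes are not
#'   tissue).
#' @export
generate_slide_image <- function(config, seed = 1L) {
  stopifnot(inherits(config, "slide_image_config"))
  h <- config$height; w <- config$width
  short <- min(h, w)
  with_seed(seed, {
    img <- array(1, dim = c(h, w, 3))
    mask <- matrix(FALSE, h, w)

    for (b in seq_len(config$n_blobs)) {
      ax <- runif(1, config$blob_axis_range[1], config$blob_axis_range[2]) * short
      bx <- runif(1, config$blob_axis_range[1], config$blob_axis_range[2]) * short
      cx <- runif(1, ax, w - 1 - ax)
      cy <- runif(1, bx, h - 1 - bx)
      blob <- rasterize_ellipse(w, h, cx, cy, ax, bx, runif(1, 0, pi))
      mask <- mask | blob
      idx <- which(blob)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[idx] <- pmin(1, pmax(0, config$tissue_colour[ch] +
                                        rnorm(length(idx), sd = config$colour_jitter)))
        img[, , ch] <- plane
      }
    }

    # near-white holes: blank regions inside (or overlapping) tissue
    for (k in seq_len(config$n_holes)) {
      r <- runif(1, 0.02, 0.05) * short
      cx <- runif(1, r, w - 1 - r); cy <- runif(1, r, h - 1 - r)
      hole <- rasterize_ellipse(w, h, cx, cy, r, r)
      mask[hole] <- FALSE
      idx <- which(hole)
      for (ch in 1:3) { plane <- img[, , ch]; plane[idx] <- 0.98; img[, , ch] <- plane }
    }

    # black marker strokes: thick line segments; they obscure tissue
    for (k in seq_len(config$n_markers)) {
      x0 <- runif(1, 0, w - 1); y0 <- runif(1, 0, h - 1)
      ang <- runif(1, 0, pi); len <- runif(1, 0.2, 0.5) * short
      x1 <- min(max(x0 + len * cos(ang), 0), w - 1)
      y1 <- min(max(y0 + len * sin(ang), 0), h - 1)
      half_w <- runif(1, 3, 8)
      xs <- matrix(rep(seq_len(w) - 1, each = h), h, w)
      ys <- matrix(rep(seq_len(h) - 1, times = w), h, w)
      vx <- x1 - x0; vy <- y1 - y0
      seg_len2 <- max(vx * vx + vy * vy, 1e-9)
      t <- pmin(pmax(((xs - x0) * vx + (ys - y0) * vy) / seg_len2, 0), 1)
      d2 <- (xs - (x0 + t * vx))^2 + (ys - (y0 + t * vy))^2
      stroke <- d2 <= half_w^2
      mask[stroke] <- FALSE
      idx <- which(stroke)
      for (ch in 1:3) { plane <- img[, , ch]; plane[idx] <- 0.05; img[, , ch] <- plane }
    }

    # dust: small dark specks, too small to pass the area filter
    for (k in seq_len(config$n_dust)) {
      r <- runif(1, 1, 3)
      cx <- runif(1, r, w - 1 - r); cy <- runif(1, r, h - 1 - r)
      speck <- rasterize_ellipse(w, h, cx, cy, r, r)
      idx <- which(speck)
      for (ch in 1:3) { plane <- img[, , ch]; plane[idx] <- 0.15; img[, , ch] <- plane }
    }

    img <- round(img * 255) / 255
    list(image = img, mask = mask)
  })
}

#' Write a synthetic slide image as PNG
#'
#' @param image Height x width x 3 array in \[0, 1\].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_slide_png <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}
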