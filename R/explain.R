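# Attention-based patch explanation.
#
# Patch importance is the averaged logarithm of the attention weights
# involving patch i:
#
#   W_i = (1/N_x) * sum_j log(A_ij)
#
# Two axis conventions are provided because the attention matrix is not
# symmetric: "literal" sums over the second index (the attention patch i
# pays out), "received" sums over the first index (the attention patch i
# receives from the other patches). "literal" is the default. Entries are
# clamped at a small floor before the logarithm, since softmax can underflow
# to zero in finite precision. Since every log A_ij <= 0, importances are
# non-positive, with 0 attained only by a 1-patch bag.

ATTENTION_FLOOR <- 1e-12

#' Per-patch importance from an attention matrix
#'
#' @param A Square attention matrix with rows summing to 1.
#' @param convention `"literal"` (row-average of log A, the printed formula)
#'   or `"received"` (column-average: attention received by each patch).
#' @return An object of class `patch_importance`: `W` (length-N_x numeric,
#'   all entries <= 0) and `axis_convention`.
#' @export
patch_importance <- function(A, convention = c("literal", "received")) {
  convention <- match.arg(convention)
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("shape error: A must be square", call. = FALSE)
  logA <- log(pmax(A, ATTENTION_FLOOR))
  W <- if (convention == "literal") rowMeans(logA) else colMeans(logA)
  structure(list(W = as.vector(W), axis_convention = convention),
            class = "patch_importance")
}

#' Indices of the k most important patches
#'
#' @param W A [patch_importance()] (or plain numeric vector of weights).
#' @param k Number of patches; values above N_x return all patches.
#' @return Integer indices of the k largest weights, in descending weight
#'   order; ties broken by ascending index.
#' @export
top_patches <- function(W, k) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  w <- if (inherits(W, "patch_importance")) W$W else as.numeric(W)
  ord <- order(-w, seq_along(w))
  head(ord, min(k, length(w)))
}

#' Map patch importances back onto the slide grid
#'
#' Builds an importance grid at patch-stride resolution: each kept patch's
#' weight is placed at its grid cell; cells with no patch are NA.
#'
#' @param W A [patch_importance()] or numeric vector, one weight per patch.
#' @param patch_coords Matrix/data.frame of 0-based level-0 top-left patch
#'   coordinates (columns x, y), parallel to `W`.
#' @param slide_extent Length-2 integer vector c(width, height) of the slide
#'   in level-0 pixels.
#' @param stride Grid stride in pixels.
#' @param normalise If TRUE, min-max rescale filled cells to \[0, 1\] (a
#'   constant field maps to 0); the flag is recorded in the result.
#' @return A list with `grid` (rows = y cells, cols = x cells; NA where no
#'   patch), `stride` and `normalised`.
#' @export
attention_heatmap <- function(W, patch_coords, slide_extent, stride = 224L,
                              normalise = FALSE) {
  w <- if (inherits(W, "patch_importance")) W$W else as.numeric(W)
  patch_coords <- as.matrix(patch_coords)
  n_cells_x <- max(1L, ceiling(slide_extent[1] / stride))
  n_cells_y <- max(1L, ceiling(slide_extent[2] / stride))
  grid <- matrix(NA_real_, n_cells_y, n_cells_x)
  if (length(w) > 0) {
    if (nrow(patch_coords) != length(w))
      stop("consistency error: one coordinate pair per weight is required", call. = FALSE)
    if (any(patch_coords[, 1] < 0) || any(patch_coords[, 2] < 0) ||
        any(patch_coords[, 1] >= slide_extent[1]) ||
        any(patch_coords[, 2] >= slide_extent[2]))
      stop("consistency error: patch coordinate outside the slide extent", call. = FALSE)
    cx <- patch_coords[, 1] %/% stride + 1L
    cy <- patch_coords[, 2] %/% stride + 1L
    vals <- w
    if (normalise) {
      rng <- range(w)
      vals <- if (diff(rng) > 0) (w - rng[1]) / diff(rng) else rep(0, length(w))
    }
    grid[cbind(cy, cx)] <- vals
  }
  list(grid = grid, stride = as.integer(stride), normalised = isTRUE(normalise))
}

#' Top-patch report for one slide
#'
#' Convenience wrapper combining [patch_importance()] and [top_patches()]
#' into the tabular report used for pathologist review.
#'
#' @param A Attention matrix of the slide.
#' @param patch_coords Patch coordinates parallel to the bag rows.
#' @param slide_id Slide identifier for the report.
#' @param k Number of top patches to report.
#' @param convention Importance axis convention, see [patch_importance()].
#' @return data.frame: slide_id, rank, patch index, x, y, W.
#' @export
top_patch_report <- function(A, patch_coords, slide_id, k = 10L,
                             convention = "literal") {
  imp <- patch_importance(A, convention)
  idx <- top_patches(imp, k)
  patch_coords <- as.matrix(patch_coords)
  data.frame(slide_id = slide_id, rank = seq_along(idx), patch = idx,
             x = patch_coords[idx, 1], y = patch_coords[idx, 2],
             W = imp$W[idx], stringsAsFactors = FALSE)
}
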