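# Tissue segmentation, grid patching, patch filtering.

make_tissue_image <- function(h, w, colour = c(0.85, 0.45, 0.65)) {
  img <- array(1, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- colour[ch]
  img
}

test_that("an all-white image segments to nothing", {
  img <- array(1, dim = c(128, 128, 3))
  tm <- segment_tissue(img, seg_params(downscale_factor = 4, min_region_area = 1))
  expect_false(any(tm$mask))
  expect_equal(nrow(tm$regions), 0)
})

test_that("segmentation recovers a synthetic blob with IoU >= 0.90", {
  cfg <- slide_image_config(width = 448, height = 448, n_blobs = 1, patch_size = 224)
  out <- generate_slide_image(cfg, seed = 13)
  f <- 4
  tm <- segment_tissue(out$image, seg_params(downscale_factor = f, min_region_area = 20))
  gt <- cryomil:::downscale_plane(out$mask * 1, f) > 0.5
  iou <- sum(tm$mask & gt) / sum(tm$mask | gt)
  expect_gte(iou, 0.90)
})

test_that("the area filter removes small regions and is monotone", {
  cfg <- slide_image_config(width = 320, height = 320, n_blobs = 1, patch_size = 160)
  out <- generate_slide_image(cfg, seed = 2)
  sp <- function(area) seg_params(downscale_factor = 4, min_region_area = area)
  blob_area <- sum(cryomil:::downscale_plane(out$mask * 1, 4) > 0.5)
  expect_equal(nrow(segment_tissue(out$image, sp(blob_area * 10))$regions), 0)
  n_regions <- vapply(c(1, 50, blob_area * 10),
                      function(a) nrow(segment_tissue(out$image, sp(a))$regions),
                      numeric(1))
  expect_true(all(diff(n_regions) <= 0))
})

test_that("segmentation is idempotent on the background-whitened image", {
  cfg <- slide_image_config(width = 320, height = 320, n_blobs = 2, patch_size = 160)
  out <- generate_slide_image(cfg, seed = 8)
  sp <- seg_params(downscale_factor = 4, min_region_area = 20)
  tm1 <- segment_tissue(out$image, sp)
  # whiten everything outside the retained regions (at level 0)
  big <- tm1$mask[rep(seq_len(nrow(tm1$mask)), each = 4),
                  rep(seq_len(ncol(tm1$mask)), each = 4)]
  img2 <- out$image
  for (ch in 1:3) { pl <- img2[, , ch]; pl[!big] <- 1; img2[, , ch] <- pl }
  tm2 <- segment_tissue(img2, sp)
  # same region structure; boundary cells may shift by a blur radius
  expect_equal(nrow(tm2$regions), nrow(tm1$regions))
  iou <- sum(tm2$mask & tm1$mask) / sum(tm2$mask | tm1$mask)
  expect_gte(iou, 0.98)
})

test_that("a fully-tissue 448x448 image yields exactly the 4 grid patches", {
  img <- make_tissue_image(448, 448)
  tm <- segment_tissue(img, seg_params(downscale_factor = 4, min_region_area = 1))
  res <- extract_patches(img, tm, patch_params(patch_size = 224))
  expect_equal(nrow(res$coords), 4)
  expect_setequal(paste(res$coords$x, res$coords$y),
                  c("0 0", "224 0", "0 224", "224 224"))
  expect_true(all(res$coords$x %% 224 == 0))
  expect_true(all(res$coords$y %% 224 == 0))
})

test_that("an empty mask yields no patches and mismatches are caught", {
  img <- array(1, dim = c(448, 448, 3))
  tm <- segment_tissue(img, seg_params(downscale_factor = 4))
  expect_equal(nrow(extract_patches(img, tm, patch_params(patch_size = 224))$coords), 0)
  other <- array(1, dim = c(224, 224, 3))
  expect_error(extract_patches(other, tm, patch_params(patch_size = 224)),
               "consistency error")
  expect_error(segment_tissue(matrix(1, 10, 10)), "format error")
})

test_that("blank and contaminated patches are rejected with reasons", {
  white <- array(1, dim = c(32, 32, 3))
  tissue <- array(0.6, dim = c(32, 32, 3)); tissue[, , 1] <- 0.85
  half_black <- tissue
  half_black[1:16, , ] <- 0.02  # 50% near-black
  res <- filter_patches(list(white, tissue, half_black),
                        filter_params(dark_fraction_threshold = 0.3))
  expect_equal(res$kept, 2L)
  expect_equal(res$rejected$index, c(1L, 3L))
  expect_equal(res$rejected$reason, c("blank", "contaminated"))
  expect_error(filter_patches(list(matrix(1, 4, 4))), "format error")
})

test_that("filter survivors equal an independent pixelwise oracle on a mixed set", {
  set.seed(404)
  fp <- filter_params(blank_mean_threshold = 230, dark_pixel_value = 40,
                      dark_fraction_threshold = 0.3)
  patches <- lapply(1:50, function(i) {
    base <- runif(1, 0.3, 1)
    p <- array(base + runif(16 * 16 * 3, -0.05, 0.05), dim = c(16, 16, 3))
    if (i %% 3 == 0) p[seq_len(sample(4:14, 1)), , ] <- runif(1, 0, 0.1)
    pmin(pmax(p, 0), 1)
  })
  res <- filter_patches(patches, fp)
  # brute-force oracle over every pixel
  oracle_keep <- vapply(patches, function(p) {
    v <- p * 255
    if (mean(v) > 230) return(FALSE)
    dark <- 0
    for (i in 1:16) for (j in 1:16)
      if (v[i, j, 1] < 40 && v[i, j, 2] < 40 && v[i, j, 3] < 40) dark <- dark + 1
    dark / 256 <= 0.3
  }, logical(1))
  expect_equal(res$kept, which(oracle_keep))
  expect_equal(sort(c(res$kept, res$rejected$index)), 1:50)

  # raising the blank threshold never loses survivors
  res_hi <- filter_patches(patches, filter_params(blank_mean_threshold = 250,
                                                  dark_pixel_value = 40,
                                                  dark_fraction_threshold = 0.3))
  expect_true(all(res$kept %in% res_hi$kept))
})
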