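#' @title Retinal-layer extraction
#' @description Five-step preprocessing that isolates the bright retinal-layer
#'   region of a B-scan: bilateral filtering (edge-preserving denoising),
#'   contrast-limited adaptive histogram equalization, Otsu thresholding,
#'   morphological opening-then-closing of the binary mask, and masking of the
#'   original image. The filtered/equalized image is used only to build the
#'   mask; the mask multiplies the original intensities.
#' @name preprocess
NULL

#' Preprocessing parameters
#'
#' @param bilateral_diameter Odd neighbourhood diameter of the bilateral
#'   filter, pixels.
#' @param bilateral_sigma_color Range (intensity) sigma of the bilateral
#'   filter.
#' @param bilateral_sigma_space Spatial sigma of the bilateral filter, pixels.
#' @param clahe_clip_limit Contrast limit as a multiple of the uniform
#'   per-bin histogram height (> 0).
#' @param clahe_tile_grid Integer `c(rows, cols)` tile grid.
#' @param morph_kernel_shape `"ellipse"`, `"rect"` or `"cross"`.
#' @param morph_kernel_size Odd structuring-element size, pixels.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(bilateral_diameter = 9,
                              bilateral_sigma_color = 75,
                              bilateral_sigma_space = 75,
                              clahe_clip_limit = 2,
                              clahe_tile_grid = c(8, 8),
                              morph_kernel_shape = "ellipse",
                              morph_kernel_size = 5) {
  if (bilateral_diameter < 1 || bilateral_sigma_color <= 0 ||
      bilateral_sigma_space <= 0)
    stop("bilateral parameters must be positive")
  if (clahe_clip_limit <= 0) stop("clahe_clip_limit must be > 0")
  if (length(clahe_tile_grid) != 2 || any(clahe_tile_grid < 1))
    stop("clahe_tile_grid must be two positive integers")
  morph_kernel_shape <- match.arg(morph_kernel_shape, c("ellipse", "rect", "cross"))
  structure(list(bilateral_diameter = bilateral_diameter,
                 bilateral_sigma_color = bilateral_sigma_color,
                 bilateral_sigma_space = bilateral_sigma_space,
                 clahe_clip_limit = clahe_clip_limit,
                 clahe_tile_grid = as.integer(clahe_tile_grid),
                 morph_kernel_shape = morph_kernel_shape,
                 morph_kernel_size = as.integer(morph_kernel_size)),
            class = "preprocess_config")
}

#' Edge-preserving bilateral filter
#'
#' Weighted neighbourhood average where each neighbour's weight is the product
#' of a spatial Gaussian in pixel distance and a range Gaussian in intensity
#' difference, so strong edges are preserved while flat regions are smoothed.
#' Borders are reflect-padded.
#'
#' @param img Grayscale intensity matrix in \[0, 255\].
#' @param diameter Neighbourhood diameter in pixels (window is
#'   `diameter x diameter`).
#' @param sigma_color Range sigma (intensity units).
#' @param sigma_space Spatial sigma (pixels).
#' @return Filtered image, same shape, values within the input range.
#' @export
bilateral_filter <- function(img, diameter = 9, sigma_color = 75,
                             sigma_space = 75) {
  assert_gray_image(img)
  if (diameter < 1 || sigma_color <= 0 || sigma_space <= 0)
    stop("diameter, sigma_color and sigma_space must be positive")
  r <- floor(diameter / 2)
  if (r == 0) return(img)
  padded <- pad_reflect(img, r)
  nr <- nrow(img); nc <- ncol(img)
  num <- matrix(0, nr, nc); den <- matrix(0, nr, nc)
  inv2ss <- 1 / (2 * sigma_space^2); inv2sc <- 1 / (2 * sigma_color^2)
  for (dy in -r:r) for (dx in -r:r) {
    shifted <- padded[(1 + r + dy):(nr + r + dy), (1 + r + dx):(nc + r + dx)]
    w <- exp(-(dy * dy + dx * dx) * inv2ss - (shifted - img)^2 * inv2sc)
    num <- num + w * shifted
    den <- den + w
  }
  round(num / den)
}

# Per-tile CLAHE mapping: clipped histogram, uniform redistribution, cdf
# remap m(v) = round((cdf(v) - cdf_min) / (n - cdf_min) * 255). Degenerate
# tiles (single occupied bin) map identically.
clahe_tile_map <- function(values, clip_limit) {
  n <- length(values)
  h <- tabulate(values + 1L, nbins = 256)
  climit <- max(1, clip_limit * n / 256)
  excess <- sum(pmax(h - climit, 0))
  h <- pmin(h, climit) + excess / 256
  cdf <- cumsum(h)
  cdf_min <- min(cdf[cdf > 0])
  if (cdf[256] - cdf_min <= 0) return(0:255)  # degenerate: identity
  pmin(pmax(round((cdf - cdf_min) / (cdf[256] - cdf_min) * 255), 0), 255)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Splits the image into a grid of tiles, computes a clipped-histogram
#' equalization mapping per tile (excess mass redistributed uniformly over
#' all bins), and remaps every pixel by bilinear interpolation between the
#' mappings of the four nearest tile centres. The remap is monotone
#' non-decreasing within each tile neighbourhood. The image is reflect-padded
#' when the grid does not divide it evenly.
#'
#' @param img Grayscale intensity matrix in \[0, 255\].
#' @param clip_limit Contrast limit as a multiple of the uniform bin height.
#' @param tile_grid Integer `c(rows, cols)`.
#' @return Equalized image, same shape, integer intensities in \[0, 255\].
#' @export
clahe <- function(img, clip_limit = 2, tile_grid = c(8, 8)) {
  assert_gray_image(img)
  if (clip_limit <= 0) stop("clip_limit must be > 0")
  tg <- as.integer(tile_grid)
  nr0 <- nrow(img); nc0 <- ncol(img)
  v <- round(img)
  th <- ceiling(nr0 / tg[1]); tw <- ceiling(nc0 / tg[2])
  nr <- th * tg[1]; nc <- tw * tg[2]
  if (nr != nr0 || nc != nc0) {
    # reflect-pad bottom/right up to the tiled size
    ridx <- c(seq_len(nr0), nr0 - seq_len(nr - nr0))
    cidx <- c(seq_len(nc0), nc0 - seq_len(nc - nc0))
    if (any(ridx < 1) || any(cidx < 1)) stop("tile grid too fine for image")
    v <- v[ridx, cidx, drop = FALSE]
  }
  # 256-entry mapping per tile
  maps <- array(0L, c(tg[1], tg[2], 256))
  for (i in seq_len(tg[1])) for (j in seq_len(tg[2])) {
    tile <- v[((i - 1) * th + 1):(i * th), ((j - 1) * tw + 1):(j * tw)]
    maps[i, j, ] <- clahe_tile_map(as.integer(tile), clip_limit)
  }
  # bilinear interpolation between tile-centre mappings
  yi <- (seq_len(nr) - 0.5) / th + 0.5
  xi <- (seq_len(nc) - 0.5) / tw + 0.5
  i0 <- pmin(pmax(floor(yi), 1), tg[1]); i1 <- pmin(i0 + 1, tg[1])
  j0 <- pmin(pmax(floor(xi), 1), tg[2]); j1 <- pmin(j0 + 1, tg[2])
  fy <- pmin(pmax(yi - i0, 0), 1); fx <- pmin(pmax(xi - j0, 0), 1)
  vi <- v + 1L
  lookup <- function(ti, tj) {
    # maps is [tile_i, tile_j, value]; build per-pixel flat indices
    ti_m <- matrix(ti, nr, nc); tj_m <- matrix(tj, nr, nc, byrow = TRUE)
    matrix(maps[cbind(as.vector(ti_m), as.vector(tj_m), as.vector(vi))], nr, nc)
  }
  wy <- matrix(fy, nr, nc); wx <- matrix(fx, nr, nc, byrow = TRUE)
  out <- (1 - wy) * (1 - wx) * lookup(i0, j0) +
         (1 - wy) * wx       * lookup(i0, j1) +
         wy       * (1 - wx) * lookup(i1, j0) +
         wy       * wx       * lookup(i1, j1)
  round(out)[seq_len(nr0), seq_len(nc0), drop = FALSE]
}

#' Otsu threshold and binary mask
#'
#' Chooses the intensity cut that maximizes the between-class variance over
#' all 256 candidate thresholds; the mask marks pixels with intensity greater
#' than or equal to the threshold. Ties are broken by the smallest threshold.
#' A constant image is flagged degenerate and yields an all-zero mask with
#' the constant value as the threshold.
#'
#' @param img Grayscale intensity matrix in \[0, 255\].
#' @return List with `threshold` (intensity), `mask` (0/1 matrix) and
#'   `degenerate` (logical).
#' @export
otsu_threshold <- function(img) {
  assert_gray_image(img)
  v <- round(img)
  if (length(unique(as.vector(v))) < 2) {
    return(list(threshold = v[1], mask = matrix(0, nrow(v), ncol(v)),
                degenerate = TRUE))
  }
  h <- tabulate(as.integer(v) + 1L, nbins = 256)
  n <- sum(h)
  lv <- 0:255
  # class 0 = {value < t}, class 1 = {value >= t}, for t = 0..255
  cum_n <- c(0, cumsum(h))[1:256]        # pixels below t
  cum_s <- c(0, cumsum(h * lv))[1:256]   # intensity sum below t
  w0 <- cum_n / n; w1 <- 1 - w0
  mu0 <- ifelse(cum_n > 0, cum_s / cum_n, 0)
  mu1 <- ifelse(n - cum_n > 0, (sum(h * lv) - cum_s) / (n - cum_n), 0)
  sigma_b <- ifelse(cum_n > 0 & cum_n < n, w0 * w1 * (mu0 - mu1)^2, 0)
  t <- lv[which.max(sigma_b)]  # which.max takes the first (smallest) maximizer
  list(threshold = t, mask = (v >= t) * 1, degenerate = FALSE)
}

morph_kernel <- function(shape, size) {
  if (size %% 2 == 0) stop("morph kernel size must be odd")
  r <- (size - 1) / 2
  d <- outer(-r:r, -r:r, function(y, x) y^2 + x^2)
  switch(shape,
    rect = matrix(1, size, size),
    ellipse = (d <= r^2 + 1e-9) * 1,
    cross = outer(-r:r, -r:r, function(y, x) (y == 0 | x == 0) * 1),
    stop("unknown kernel shape: ", shape))
}

# Min/max filters over the kernel support. Erosion treats out-of-frame as
# foreground, dilation as background: the adjoint pair on the finite frame,
# which makes open-then-close exactly idempotent.
erode_mask <- function(mask, kern) {
  r <- (nrow(kern) - 1) / 2
  out <- matrix(1, nrow(mask), ncol(mask))
  for (dy in -r:r) for (dx in -r:r) if (kern[dy + r + 1, dx + r + 1] == 1)
    out <- pmin(out, shift_matrix(mask, -dy, -dx, fill = 1))
  out
}

dilate_mask <- function(mask, kern) {
  r <- (nrow(kern) - 1) / 2
  out <- matrix(0, nrow(mask), ncol(mask))
  for (dy in -r:r) for (dx in -r:r) if (kern[dy + r + 1, dx + r + 1] == 1)
    out <- pmax(out, shift_matrix(mask, dy, dx, fill = 0))
  out
}

#' Morphological cleaning of a binary mask
#'
#' Opening (erosion then dilation) followed by closing (dilation then
#' erosion) with the same structuring element: the opening removes specks
#' smaller than the kernel, the closing fills the pits the opening leaves.
#' The composite filter is idempotent.
#'
#' @param mask Binary 0/1 matrix.
#' @param kernel_shape `"ellipse"`, `"rect"` or `"cross"`.
#' @param kernel_size Odd structuring-element size in pixels.
#' @return Cleaned binary mask, same shape.
#' @export
morph_clean <- function(mask, kernel_shape = "ellipse", kernel_size = 5) {
  assert_binary_mask(mask)
  kern <- morph_kernel(kernel_shape, kernel_size)
  opened <- dilate_mask(erode_mask(mask, kern), kern)
  erode_mask(dilate_mask(opened, kern), kern)
}

#' Mask an image
#'
#' Element-wise product of image and binary mask: original values inside the
#' mask, zero outside.
#'
#' @param img Grayscale intensity matrix.
#' @param mask Binary 0/1 matrix of the same shape.
#' @return Masked image.
#' @export
apply_mask <- function(img, mask) {
  assert_gray_image(img)
  assert_binary_mask(mask)
  if (!all(dim(img) == dim(mask))) stop("image and mask shapes differ")
  img * mask
}

#' Extract the retinal-layer region
#'
#' The composed five-step pipeline: bilateral filter, CLAHE, Otsu
#' thresholding, morphological opening-then-closing, and masking. The
#' threshold is computed on the equalized image; the final mask multiplies
#' the *original* image.
#'
#' @param img Grayscale intensity matrix in \[0, 255\].
#' @param cfg A [preprocess_config()].
#' @param verbose Emit a per-image log line with the threshold and mask area
#'   fraction.
#' @return List with `image` (masked original), `mask` (0/1), `threshold`,
#'   `degenerate` flag and `mask_area` (fraction of pixels kept).
#' @export
extract_retina <- function(img, cfg = preprocess_config(), verbose = FALSE) {
  assert_gray_image(img)
  filtered <- bilateral_filter(img, cfg$bilateral_diameter,
                               cfg$bilateral_sigma_color,
                               cfg$bilateral_sigma_space)
  equalized <- clahe(filtered, cfg$clahe_clip_limit, cfg$clahe_tile_grid)
  ot <- otsu_threshold(equalized)
  mask <- morph_clean(ot$mask, cfg$morph_kernel_shape, cfg$morph_kernel_size)
  masked <- apply_mask(img, mask)
  if (verbose)
    message(sprintf("extract_retina: threshold=%d mask_area=%.3f%s",
                    ot$threshold, mean(mask),
                    if (ot$degenerate) " (degenerate)" else ""))
  list(image = masked, mask = mask, threshold = ot$threshold,
       degenerate = ot$degenerate, mask_area = mean(mask))
}
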