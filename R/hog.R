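#' Histogram-of-oriented-gradients configuration
#'
#' @param cell_size Cell side in pixels.
#' @param block_cells Cells per block side (blocks are
#'   `block_cells x block_cells` cells).
#' @param n_bins Orientation bins over the unsigned range \[0, 180) degrees.
#' @param block_stride Block stride in cells.
#' @param vote_mode `"hard"` (all magnitude to the bin containing the angle)
#'   or `"bilinear"` (magnitude split between the two nearest bin centres).
#' @return An object of class `hog_config`.
#' @export
hog_config <- function(cell_size = 8, block_cells = 2, n_bins = 9,
                       block_stride = 1, vote_mode = "hard") {
  vote_mode <- match.arg(vote_mode, c("hard", "bilinear"))
  if (cell_size < 1 || block_cells < 1 || n_bins < 1 || block_stride < 1)
    stop("hog parameters must be positive")
  structure(list(cell_size = as.integer(cell_size),
                 block_cells = as.integer(block_cells),
                 n_bins = as.integer(n_bins),
                 block_stride = as.integer(block_stride),
                 vote_mode = vote_mode), class = "hog_config")
}

#' Number of HOG features for a given image size
#'
#' Closed-form block count: with `ncr = floor(height / cell_size)` cells per
#' column and stride `s`, there are `floor((ncr - block_cells) / s) + 1`
#' block rows (similarly for columns), each block contributing
#' `block_cells^2 * n_bins` values.
#'
#' @param height,width Image size in pixels.
#' @param cfg A [hog_config()].
#' @return Integer feature count (0 if the image holds no complete block).
#' @export
hog_length <- function(height, width, cfg = hog_config()) {
  ncr <- floor(height / cfg$cell_size); ncc <- floor(width / cfg$cell_size)
  br <- floor((ncr - cfg$block_cells) / cfg$block_stride) + 1
  bc <- floor((ncc - cfg$block_cells) / cfg$block_stride) + 1
  if (br < 1 || bc < 1) return(0L)
  as.integer(br * bc * cfg$block_cells^2 * cfg$n_bins)
}

#' HOG descriptor
#'
#' Gradients are computed with centred `[-1, 0, 1]` differences (replicate
#' borders); orientation is folded to the unsigned range \[0, 180) degrees
#' and the gradient magnitude votes into a per-cell orientation histogram
#' (hard assignment to the bin containing the angle by default, bilinear
#' splitting optionally). Cells are grouped into overlapping blocks, each
#' block vector is L2-normalized (zero-norm blocks stay zero), and the block
#' vectors are concatenated row-major.
#'
#' @param img Grayscale intensity matrix in \[0, 255\].
#' @param cfg A [hog_config()].
#' @return Named numeric vector (names prefixed `"hog:"`) of length
#'   [hog_length()].
#' @export
hog_features <- function(img, cfg = hog_config()) {
  assert_gray_image(img)
  len <- hog_length(nrow(img), ncol(img), cfg)
  if (len < 1)
    stop(sprintf("image %dx%d holds no complete HOG block: need at least %d pixels per side",
                 nrow(img), ncol(img), cfg$cell_size * cfg$block_cells))
  nr <- nrow(img); nc <- ncol(img)
  # centred differences with replicate borders
  left  <- img[, c(1, seq_len(nc - 1)), drop = FALSE]
  right <- img[, c(2:nc, nc), drop = FALSE]
  up    <- img[c(1, seq_len(nr - 1)), , drop = FALSE]
  down  <- img[c(2:nr, nr), , drop = FALSE]
  gx <- right - left
  gy <- down - up
  mag <- sqrt(gx^2 + gy^2)
  ang <- (atan2(gy, gx) * 180 / pi) %% 180   # unsigned, [0, 180)
  cs <- cfg$cell_size
  ncr <- floor(nr / cs); ncc <- floor(nc / cs)
  keep_r <- seq_len(ncr * cs); keep_c <- seq_len(ncc * cs)
  mag <- mag[keep_r, keep_c]; ang <- ang[keep_r, keep_c]
  cell_r <- (row(mag) - 1) %/% cs; cell_c <- (col(mag) - 1) %/% cs
  cell_id <- cell_r * ncc + cell_c              # 0-based, row-major
  bw <- 180 / cfg$n_bins
  hist_len <- ncr * ncc * cfg$n_bins
  hist <- numeric(hist_len)
  accumulate <- function(bin, weight) {
    idx <- cell_id * cfg$n_bins + bin + 1L
    agg <- rowsum(as.vector(weight), group = as.vector(idx))
    hist[as.integer(rownames(agg))] <<- hist[as.integer(rownames(agg))] + agg[, 1]
    invisible(NULL)
  }
  if (cfg$vote_mode == "hard") {
    bin <- pmin(floor(ang / bw), cfg$n_bins - 1)
    accumulate(bin, mag)
  } else {
    t <- ang / bw - 0.5
    b0 <- floor(t)
    f <- t - b0
    accumulate(b0 %% cfg$n_bins, mag * (1 - f))
    accumulate((b0 + 1) %% cfg$n_bins, mag * f)
  }
  # hist indexed as [bin, cell_c, cell_r] flattened with bin fastest
  H <- array(hist, c(cfg$n_bins, ncc, ncr))
  bcs <- cfg$block_cells; stride <- cfg$block_stride
  out <- numeric(0)
  for (br in seq(1, ncr - bcs + 1, by = stride)) {
    for (bc in seq(1, ncc - bcs + 1, by = stride)) {
      block <- numeric(0)
      for (rr in br:(br + bcs - 1)) for (cc in bc:(bc + bcs - 1))
        block <- c(block, H[, cc, rr])
      nrm <- sqrt(sum(block^2))
      if (nrm > 0) block <- block / nrm
      out <- c(out, block)
    }
  }
  names(out) <- paste0("hog:", seq_along(out))
  out
}
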