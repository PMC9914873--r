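#' Gray-level co-occurrence configuration
#'
#' @param distances Integer pixel offsets (>= 1).
#' @param angles Subset of `c(0, 45, 90, 135)` degrees.
#' @param levels Gray-level quantization count in \[2, 256\]. Intensities are
#'   binned uniformly over \[0, 255\].
#' @param symmetric Count each pair in both directions.
#' @param normalize Normalize the matrix to sum 1 before computing statistics.
#' @return An object of class `glcm_config`.
#' @export
glcm_config <- function(distances = c(1, 2), angles = c(0, 45, 90, 135),
                        levels = 32, symmetric = FALSE, normalize = TRUE) {
  if (any(distances < 1)) stop("distances must be >= 1")
  if (!all(angles %in% c(0, 45, 90, 135)))
    stop("angles must be a subset of 0, 45, 90, 135")
  if (levels < 2 || levels > 256) stop("levels must lie in [2, 256]")
  structure(list(distances = as.integer(distances), angles = angles,
                 levels = as.integer(levels), symmetric = symmetric,
                 normalize = normalize), class = "glcm_config")
}

glcm_offset <- function(angle, distance) {
  switch(as.character(angle),
    "0"   = c(0L, distance),
    "45"  = c(-distance, distance),
    "90"  = c(-distance, 0L),
    "135" = c(-distance, -distance),
    stop("unsupported angle: ", angle))
}

#' Gray-level co-occurrence matrix
#'
#' Quantizes intensities to `levels` uniform bins of \[0, 255\] and counts,
#' for every pixel with an in-bounds neighbour at the given distance and
#' angle, the pair (source level, target level). Entry (i, j) of the result
#' is the count (or probability, when normalized) of level i co-occurring
#' with level j at that offset. Angles follow the convention 0 deg = east,
#' 45 deg = north-east, 90 deg = north, 135 deg = north-west (rows grow
#' downwards).
#'
#' @param img Grayscale intensity matrix in \[0, 255\].
#' @param distance Pixel offset (>= 1).
#' @param angle One of 0, 45, 90, 135 (degrees).
#' @param levels Quantization level count.
#' @param symmetric Also count each pair in the reverse direction.
#' @param normalize Divide by the total pair count.
#' @return A `levels x levels` matrix; attribute `n_pairs` holds the
#'   in-bounds pair count, and attribute `empty` is TRUE when the offset
#'   does not fit in the image.
#' @export
glcm_matrix <- function(img, distance, angle, levels = 32,
                        symmetric = FALSE, normalize = FALSE) {
  assert_gray_image(img)
  q <- pmin(floor(round(img) * levels / 256), levels - 1)
  nr <- nrow(q); nc <- ncol(q)
  off <- glcm_offset(angle, distance)
  rs <- seq_len(nr); cs <- seq_len(nc)
  src_r <- rs[rs + off[1] >= 1 & rs + off[1] <= nr]
  src_c <- cs[cs + off[2] >= 1 & cs + off[2] <= nc]
  m <- matrix(0, levels, levels)
  if (!length(src_r) || !length(src_c)) {
    attr(m, "empty") <- TRUE; attr(m, "n_pairs") <- 0L
    return(m)
  }
  i <- as.vector(q[src_r, src_c, drop = FALSE])
  j <- as.vector(q[src_r + off[1], src_c + off[2], drop = FALSE])
  counts <- tabulate(i * levels + j + 1L, nbins = levels * levels)
  m <- matrix(counts, levels, levels, byrow = TRUE)  # m[i+1, j+1]
  if (symmetric) m <- m + t(m)
  attr(m, "n_pairs") <- sum(m)
  attr(m, "empty") <- FALSE
  if (normalize && sum(m) > 0) {
    np <- attr(m, "n_pairs")
    m <- m / sum(m)
    attr(m, "n_pairs") <- np; attr(m, "empty") <- FALSE
  }
  m
}

glcm_stats <- function(p) {
  levels <- nrow(p)
  idx <- 0:(levels - 1)
  dif <- outer(idx, idx, `-`)
  contrast <- sum(p * dif^2)
  energy <- sum(p^2)
  homogeneity <- sum(p / (1 + dif^2))
  pi_ <- rowSums(p); pj <- colSums(p)
  mu_i <- sum(idx * pi_); mu_j <- sum(idx * pj)
  sd_i <- sqrt(sum((idx - mu_i)^2 * pi_)); sd_j <- sqrt(sum((idx - mu_j)^2 * pj))
  correlation <- if (sd_i == 0 || sd_j == 0) 1 else
    sum(outer(idx - mu_i, idx - mu_j) * p) / (sd_i * sd_j)
  c(energy = energy, correlation = correlation,
    homogeneity = homogeneity, contrast = contrast)
}

#' GLCM texture features
#'
#' For every (distance, angle) pair of the configuration, computes energy,
#' correlation, homogeneity and contrast from the normalized co-occurrence
#' matrix:
#' contrast = sum P(i,j) (i-j)^2; energy = sum P(i,j)^2;
#' homogeneity = sum P(i,j) / (1 + (i-j)^2);
#' correlation = sum (i - mu_i)(j - mu_j) P(i,j) / (sigma_i sigma_j),
#' with correlation defined as 1 when either marginal is degenerate
#' (sigma = 0).
#'
#' @param img Grayscale intensity matrix in \[0, 255\].
#' @param cfg A [glcm_config()].
#' @return Named numeric vector of length
#'   `4 * length(distances) * length(angles)`, names prefixed `"glcm:"`.
#' @export
glcm_features <- function(img, cfg = glcm_config()) {
  out <- numeric(0)
  for (d in cfg$distances) for (a in cfg$angles) {
    p <- glcm_matrix(img, d, a, cfg$levels, cfg$symmetric, normalize = TRUE)
    s <- glcm_stats(p)
    names(s) <- sprintf("glcm:d%d.a%d.%s", d, a, names(s))
    out <- c(out, s)
  }
  out
}
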