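# Independent brute-force oracles used to validate the implementation.
# These deliberately use naive double loops, not the package's code paths.

# Exhaustive Otsu: for every candidate threshold t, split pixels into
# {v < t} and {v >= t} and compute the between-class variance directly.
oracle_otsu <- function(img) {
  v <- as.vector(round(img))
  n <- length(v)
  best_t <- NA_integer_; best_var <- -1
  for (t in 0:255) {
    lo <- v[v < t]; hi <- v[v >= t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / n; w1 <- length(hi) / n
    var_b <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (var_b > best_var + 1e-12) { best_var <- var_b; best_t <- t }
  }
  best_t
}

# Pair enumeration GLCM + direct statistic sums.
oracle_glcm_stats <- function(img, distance, angle, levels) {
  q <- pmin(floor(round(img) * levels / 256), levels - 1)
  off <- switch(as.character(angle),
    "0" = c(0, distance), "45" = c(-distance, distance),
    "90" = c(-distance, 0), "135" = c(-distance, -distance))
  p <- matrix(0, levels, levels)
  for (r in seq_len(nrow(q))) for (cc in seq_len(ncol(q))) {
    r2 <- r + off[1]; c2 <- cc + off[2]
    if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q))
      p[q[r, cc] + 1, q[r2, c2] + 1] <- p[q[r, cc] + 1, q[r2, c2] + 1] + 1
  }
  if (sum(p) > 0) p <- p / sum(p)
  contrast <- 0; energy <- 0; homogeneity <- 0
  for (i in 0:(levels - 1)) for (j in 0:(levels - 1)) {
    pij <- p[i + 1, j + 1]
    contrast <- contrast + pij * (i - j)^2
    energy <- energy + pij^2
    homogeneity <- homogeneity + pij / (1 + (i - j)^2)
  }
  mu_i <- 0; mu_j <- 0
  for (i in 0:(levels - 1)) { mu_i <- mu_i + i * sum(p[i + 1, ]); mu_j <- mu_j + i * sum(p[, i + 1]) }
  var_i <- 0; var_j <- 0
  for (i in 0:(levels - 1)) {
    var_i <- var_i + (i - mu_i)^2 * sum(p[i + 1, ])
    var_j <- var_j + (i - mu_j)^2 * sum(p[, i + 1])
  }
  correlation <- if (var_i <= 0 || var_j <= 0) 1 else {
    s <- 0
    for (i in 0:(levels - 1)) for (j in 0:(levels - 1))
      s <- s + (i - mu_i) * (j - mu_j) * p[i + 1, j + 1]
    s / sqrt(var_i * var_j)
  }
  c(energy = energy, correlation = correlation,
    homogeneity = homogeneity, contrast = contrast)
}

# Direct spatial-Gaussian weighted average with reflected borders (the
# sigma_color -> Inf limit of the bilateral filter).
oracle_gaussian_blur <- function(img, radius, sigma_space) {
  nr <- nrow(img); nc <- ncol(img)
  reflect <- function(i, n) { i <- ifelse(i < 1, 1 - i, i); ifelse(i > n, 2 * n + 1 - i, i) }
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    num <- 0; den <- 0
    for (dy in -radius:radius) for (dx in -radius:radius) {
      w <- exp(-(dy^2 + dx^2) / (2 * sigma_space^2))
      v <- img[reflect(r + dy, nr), reflect(cc + dx, nc)]
      num <- num + w * v; den <- den + w
    }
    out[r, cc] <- num / den
  }
  out
}

# Plain histogram equalization by the cdf formula:
# m(v) = round((cdf(v) - cdf_min) / (n - cdf_min) * 255).
oracle_hist_eq <- function(img) {
  v <- round(img)
  h <- tabulate(as.integer(v) + 1L, nbins = 256)
  cdf <- cumsum(h)
  cdf_min <- min(cdf[cdf > 0])
  map <- round((cdf - cdf_min) / (length(v) - cdf_min) * 255)
  matrix(map[as.integer(v) + 1L], nrow(v), ncol(v))
}

# Exhaustive nearest-neighbour classification with explicit distance
# enumeration; same tie conventions as the spec (smallest fit index,
# smallest class label).
oracle_knn <- function(selection, fit_x, fit_y, eval_x, eval_y, k) {
  mu <- colMeans(fit_x)
  sdv <- apply(fit_x, 2, sd); sdv[sdv == 0] <- 1
  fs <- sweep(sweep(fit_x, 2, mu), 2, sdv, `/`)
  es <- sweep(sweep(eval_x, 2, mu), 2, sdv, `/`)
  sel <- which(selection == 1)
  lev <- levels(factor(fit_y))
  correct <- 0
  for (r in seq_len(nrow(es))) {
    d <- numeric(nrow(fs))
    for (q in seq_len(nrow(fs)))
      d[q] <- sqrt(sum((es[r, sel] - fs[q, sel])^2))
    nn <- order(d)[seq_len(k)]
    votes <- table(factor(fit_y[nn], levels = lev))
    pred <- names(votes)[which.max(votes)]
    if (pred == as.character(eval_y[r])) correct <- correct + 1
  }
  correct / nrow(es)
}

random_image <- function(nr, nc, seed) {
  set.seed(seed)
  matrix(as.double(sample(0:255, nr * nc, replace = TRUE)), nr, nc)
}

# step edge: left half `lo`, right half `hi`
step_edge_image <- function(nr, nc, lo = 0, hi = 200) {
  cbind(matrix(lo, nr, floor(nc / 2)), matrix(hi, nr, ncol = nc - floor(nc / 2)))
}
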