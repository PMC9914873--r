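## Internal helpers shared across modules.

# Run `expr` under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit sub-seed from a base seed and arbitrary string tokens.
# Keeps derived seeds below 2^31 so they are valid R integers.
derive_seed <- function(base_seed, ...) {
  tokens <- paste(c(base_seed, ...), collapse = "/")
  h <- 0
  for (b in utf8ToInt(tokens)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

clip8 <- function(x) pmin(pmax(x, 0), 255)

is_gray_image <- function(img) {
  is.matrix(img) && is.numeric(img) && all(is.finite(img)) &&
    min(img) >= 0 && max(img) <= 255
}

assert_gray_image <- function(img, arg = deparse(substitute(img))) {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("`%s` must be a numeric matrix of grayscale intensities", arg))
  if (any(!is.finite(img)) || min(img) < 0 || max(img) > 255)
    stop(sprintf("`%s` must hold finite intensities in [0, 255]", arg))
  invisible(img)
}

assert_binary_mask <- function(mask, arg = deparse(substitute(mask))) {
  if (!is.matrix(mask) || !all(mask %in% c(0, 1)))
    stop(sprintf("`%s` must be a strictly binary (0/1) matrix", arg))
  invisible(mask)
}

# Shift a matrix by (dr, dc), filling vacated entries with `fill`.
shift_matrix <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dr; src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1 & src_r <= nr; ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# Reflect-pad a matrix by `k` pixels on every side (edge pixel not repeated
# beyond what reflection gives; standard "symmetric" padding).
pad_reflect <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  idx <- function(n) {
    i <- c(rev(seq_len(min(k, n))), seq_len(n), n + 1 - seq_len(min(k, n)))
    if (k > n) stop("padding exceeds image size")
    i
  }
  m[idx(nr), idx(nc), drop = FALSE]
}

# Bilinear resize of an intensity matrix to (out_h, out_w).
resize_bilinear <- function(img, out_h, out_w) {
  nr <- nrow(img); nc <- ncol(img)
  if (nr == out_h && nc == out_w) return(img)
  # map output pixel centres into input coordinates
  ys <- (seq_len(out_h) - 0.5) * nr / out_h + 0.5
  xs <- (seq_len(out_w) - 0.5) * nc / out_w + 0.5
  y0 <- pmin(pmax(floor(ys), 1), nr); y1 <- pmin(y0 + 1, nr)
  x0 <- pmin(pmax(floor(xs), 1), nc); x1 <- pmin(x0 + 1, nc)
  wy <- pmin(pmax(ys - y0, 0), 1); wx <- pmin(pmax(xs - x0, 0), 1)
  a <- img[y0, x0, drop = FALSE]; b <- img[y0, x1, drop = FALSE]
  c_ <- img[y1, x0, drop = FALSE]; d <- img[y1, x1, drop = FALSE]
  top <- a * outer(1 - wy, 1 - wx) + b * outer(1 - wy, wx) +
    c_ * outer(wy, 1 - wx) + d * outer(wy, wx)
  top
}
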