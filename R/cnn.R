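#' Headless CNN backbone specification
#'
#' Describes a convolutional trunk used purely as a feature extractor (the
#' classification head is removed). The built-in `"stub"` architecture is a
#' small bias-free two-stage trunk (3x3 convolutions, ReLU, 2x2 average
#' pooling) with seed-deterministic random weights, so embeddings are
#' reproducible without downloading any pretrained model. Named backbones
#' such as `"vgg16"`/`"densenet121"` may be declared with
#' `weights_source = "random"`, which runs the stub trunk under that name;
#' `weights_source = "pretrained"` is an explicit error because no weights
#' ship with the package.
#'
#' @param name Backbone identifier (used as the feature-name prefix).
#' @param weights_source `"random"` (seeded stub weights) or `"pretrained"`.
#' @param pooling `"global_average"` (one value per output map) or
#'   `"flatten"` (all spatial activations).
#' @param input_size Side length images are resized to before the forward
#'   pass (bilinear).
#' @param seed Integer seed for the random weights.
#' @param n_filters Output maps of the two convolution stages.
#' @return An object of class `backbone_spec`.
#' @export
backbone_spec <- function(name = "stub", weights_source = "random",
                          pooling = "global_average", input_size = 64,
                          seed = 1L, n_filters = c(8, 16)) {
  weights_source <- match.arg(weights_source, c("random", "pretrained"))
  pooling <- match.arg(pooling, c("global_average", "flatten"))
  if (input_size < 8) stop("input_size must be >= 8")
  structure(list(name = name, weights_source = weights_source,
                 pooling = pooling, input_size = as.integer(input_size),
                 seed = as.integer(seed), n_filters = as.integer(n_filters)),
            class = "backbone_spec")
}

# 'same' zero-padded 3x3 convolution of a list of channel matrices with a
# weight array w[3, 3, n_in, n_out]; bias-free.
conv3x3 <- function(channels, w) {
  n_out <- dim(w)[4]
  out <- vector("list", n_out)
  zero <- channels[[1]] * 0
  for (f in seq_len(n_out)) {
    acc <- zero
    for (ci in seq_along(channels)) for (dy in -1:1) for (dx in -1:1) {
      wv <- w[dy + 2, dx + 2, ci, f]
      if (wv != 0) acc <- acc + wv * shift_matrix(channels[[ci]], dy, dx, fill = 0)
    }
    out[[f]] <- acc
  }
  out
}

avg_pool2 <- function(m) {
  nr <- 2 * (nrow(m) %/% 2); nc <- 2 * (ncol(m) %/% 2)
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  (m[seq(1, nr, 2), seq(1, nc, 2), drop = FALSE] +
   m[seq(2, nr, 2), seq(1, nc, 2), drop = FALSE] +
   m[seq(1, nr, 2), seq(2, nc, 2), drop = FALSE] +
   m[seq(2, nr, 2), seq(2, nc, 2), drop = FALSE]) / 4
}

stub_weights <- function(spec) {
  with_seed(spec$seed, {
    f1 <- spec$n_filters[1]; f2 <- spec$n_filters[2]
    list(w1 = array(stats::rnorm(3 * 3 * 3 * f1, sd = sqrt(2 / (9 * 3))),
                    c(3, 3, 3, f1)),
         w2 = array(stats::rnorm(3 * 3 * f1 * f2, sd = sqrt(2 / (9 * f1))),
                    c(3, 3, f1, f2)))
  })
}

#' Headless CNN embedding of an image
#'
#' Resizes the image to the backbone's input size, replicates the grayscale
#' channel to the trunk's three input channels, runs the convolutional trunk
#' (no classification head), and pools per the spec. Deterministic for a
#' fixed spec and input.
#'
#' @param img Grayscale intensity matrix in \[0, 255\].
#' @param spec A [backbone_spec()].
#' @return Named numeric vector, names prefixed with the backbone name.
#' @export
cnn_features <- function(img, spec = backbone_spec()) {
  assert_gray_image(img)
  if (spec$weights_source == "pretrained")
    stop("pretrained weights for backbone '", spec$name, "' are not bundled; ",
         "install/export them yourself or use weights_source = \"random\" ",
         "for the seed-deterministic stub trunk")
  x <- resize_bilinear(img, spec$input_size, spec$input_size) / 255
  channels <- list(x, x, x)
  w <- stub_weights(spec)
  a1 <- lapply(conv3x3(channels, w$w1), function(m) pmax(m, 0))
  a1 <- lapply(a1, avg_pool2)
  a2 <- lapply(conv3x3(a1, w$w2), function(m) pmax(m, 0))
  a2 <- lapply(a2, avg_pool2)
  out <- if (spec$pooling == "global_average") {
    vapply(a2, mean, numeric(1))
  } else {
    unlist(lapply(a2, as.vector), use.names = FALSE)
  }
  names(out) <- paste0(spec$name, ":", seq_along(out))
  out
}
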