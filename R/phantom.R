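#' @title Synthetic OCT phantom generator
#' @description Seeded generators for OCT-like B-scan phantoms with known
#'   lesion ground truth, phantom datasets on disk, and synthetic feature
#'   tables with known informative columns. These drive every downstream
#'   stage of the pipeline without any external image data.
#' @name phantom
NULL

PHANTOM_CLASSES <- c("NORMAL", "CNV", "DME", "DRUSEN")
PHANTOM_BACKGROUND <- 10   # background mean on the 8-bit scale
PHANTOM_RPE <- 200         # bottom (RPE-analogue) band intensity
PHANTOM_POCKET <- 30       # fluid-pocket target intensity

#' Configuration for a single OCT phantom
#'
#' @param height,width Image size in pixels (both >= 64).
#' @param class_label One of `"NORMAL"`, `"CNV"`, `"DME"`, `"DRUSEN"`.
#' @param n_layers Number of retinal bands including the bright bottom
#'   (RPE-analogue) band.
#' @param noise_sigma Standard deviation of additive i.i.d. Gaussian noise,
#'   in 8-bit intensity units (>= 0).
#' @param lesion_intensity Dimensionless lesion contrast in \[0, 1\]: 1 pulls
#'   pockets fully to the fluid intensity and bumps fully to the RPE
#'   intensity; 0 removes the lesion contrast entirely.
#' @param seed Integer seed; fully determines the generated sample.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(height = 128, width = 128, class_label = "NORMAL",
                           n_layers = 5, noise_sigma = 5,
                           lesion_intensity = 1, seed = 1L) {
  if (!is.character(class_label) || length(class_label) != 1 ||
      !(class_label %in% PHANTOM_CLASSES))
    stop("class_label must be one of: ", paste(PHANTOM_CLASSES, collapse = ", "))
  if (height < 64 || width < 64) stop("height and width must be >= 64")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (n_layers < 2) stop("n_layers must be >= 2")
  if (lesion_intensity < 0 || lesion_intensity > 1)
    stop("lesion_intensity must lie in [0, 1]")
  structure(list(height = as.integer(height), width = as.integer(width),
                 class_label = class_label, n_layers = as.integer(n_layers),
                 noise_sigma = noise_sigma,
                 lesion_intensity = lesion_intensity, seed = as.integer(seed)),
            class = "phantom_config")
}

# Deterministic band geometry shared by all classes: the banded region spans
# rows [top, bot]; the bottom band is the bright RPE analogue.
phantom_geometry <- function(cfg) {
  top <- round(0.30 * cfg$height)
  bot <- round(0.78 * cfg$height)
  edges <- round(seq(top, bot + 1, length.out = cfg$n_layers + 1))
  rpe_top <- edges[cfg$n_layers]
  list(top = top, bot = bot, edges = edges, rpe_top = rpe_top)
}

# Noiseless NORMAL base: dark background, alternating inner bands, bright RPE.
phantom_base <- function(cfg, geom) {
  img <- matrix(PHANTOM_BACKGROUND, cfg$height, cfg$width)
  for (k in seq_len(cfg$n_layers)) {
    rows <- geom$edges[k]:(geom$edges[k + 1] - 1)
    val <- if (k == cfg$n_layers) PHANTOM_RPE else 110 + 50 * (k %% 2)
    img[rows, ] <- val
  }
  img
}

# Raise the RPE top boundary by a smooth Gaussian bump; returns the modified
# image and the bounding box of changed pixels (NULL if nothing changed).
add_bump <- function(img, geom, centre, width_px, amp, strength) {
  cols <- seq_len(ncol(img))
  lift <- round(amp * exp(-(cols - centre)^2 / (2 * width_px^2)))
  lift <- pmin(lift, geom$rpe_top - geom$top - 1)
  changed_cols <- which(lift >= 1)
  if (!length(changed_cols)) return(list(img = img, box = NULL))
  min_row <- geom$rpe_top
  for (cc in changed_cols) {
    rows <- (geom$rpe_top - lift[cc]):(geom$rpe_top - 1)
    img[rows, cc] <- img[rows, cc] + strength * (PHANTOM_RPE - img[rows, cc])
    min_row <- min(min_row, rows[1])
  }
  box <- c(row_min = min_row, row_max = geom$rpe_top - 1,
           col_min = min(changed_cols), col_max = max(changed_cols))
  list(img = img, box = box)
}

# Carve a dark elliptical fluid pocket inside the banded region (above the
# RPE band) centred at (r0, c0) with semi-axes (a, b) in pixels.
add_pocket <- function(img, geom, r0, c0, a, b, strength) {
  rr <- pmax(geom$top, floor(r0 - a)):pmin(geom$rpe_top - 1, ceiling(r0 + a))
  cc <- pmax(1, floor(c0 - b)):pmin(ncol(img), ceiling(c0 + b))
  if (!length(rr) || !length(cc)) return(list(img = img, box = NULL))
  inside <- outer((rr - r0)^2 / a^2, (cc - c0)^2 / b^2, `+`) <= 1
  if (!any(inside)) return(list(img = img, box = NULL))
  sub <- img[rr, cc, drop = FALSE]
  sub[inside] <- sub[inside] + strength * (PHANTOM_POCKET - sub[inside])
  img[rr, cc] <- sub
  hit_r <- rr[apply(inside, 1, any)]; hit_c <- cc[apply(inside, 2, any)]
  box <- c(row_min = min(hit_r), row_max = max(hit_r),
           col_min = min(hit_c), col_max = max(hit_c))
  list(img = img, box = box)
}

#' Generate one synthetic OCT phantom
#'
#' Builds a dark-background image with a banded bright retinal region whose
#' bottom band (the RPE analogue) is brightest, then adds class-specific
#' lesions: smooth bumps deforming the bottom band for DRUSEN, dark fluid
#' pockets for DME (large, mid-retina) and CNV (small, sub-retinal, plus a
#' broad RPE elevation), nothing for NORMAL. Additive Gaussian noise of scale
#' `noise_sigma` is applied last and intensities are clipped to \[0, 255\].
#' The ground-truth retina mask marks every pixel whose noiseless intensity
#' exceeds the background level.
#'
#' @param config A [phantom_config()].
#' @return An object of class `phantom_sample`: a list with elements
#'   `image` (intensity matrix), `retina_mask_truth` (0/1 matrix),
#'   `label`, `noiseless` (pre-noise image), `lesion_boxes` (list of
#'   changed-pixel bounding boxes) and `config`.
#' @export
generate_phantom <- function(config) {
  if (!inherits(config, "phantom_config")) config <- do.call(phantom_config, config)
  geom <- phantom_geometry(config)
  base <- phantom_base(config, geom)
  s <- config$lesion_intensity
  boxes <- list()
  img <- with_seed(config$seed, {
    out <- base
    if (config$class_label == "DRUSEN") {
      n_bumps <- sample(2:4, 1)
      for (i in seq_len(n_bumps)) {
        res <- add_bump(out, geom,
                        centre = runif(1, 0.15, 0.85) * config$width,
                        width_px = runif(1, 3, 6),
                        amp = runif(1, 5, 10), strength = s)
        out <- res$img; if (!is.null(res$box)) boxes[[length(boxes) + 1]] <- res$box
      }
    } else if (config$class_label == "CNV") {
      # broad dome-like RPE elevation with small sub-retinal pockets beneath it
      res <- add_bump(out, geom, centre = runif(1, 0.3, 0.7) * config$width,
                      width_px = runif(1, 10, 16), amp = runif(1, 6, 10),
                      strength = s)
      out <- res$img; if (!is.null(res$box)) boxes[[length(boxes) + 1]] <- res$box
      n_p <- sample(2:3, 1)
      lower <- geom$rpe_top - 0.3 * (geom$rpe_top - geom$top)
      for (i in seq_len(n_p)) {
        res <- add_pocket(out, geom,
                          r0 = runif(1, lower, geom$rpe_top - 2),
                          c0 = runif(1, 0.1, 0.9) * config$width,
                          a = runif(1, 2, 4), b = runif(1, 4, 8), strength = s)
        out <- res$img; if (!is.null(res$box)) boxes[[length(boxes) + 1]] <- res$box
      }
    } else if (config$class_label == "DME") {
      n_p <- sample(1:2, 1)
      mid <- (geom$top + geom$rpe_top) / 2
      for (i in seq_len(n_p)) {
        res <- add_pocket(out, geom,
                          r0 = runif(1, mid - 5, mid + 5),
                          c0 = runif(1, 0.25, 0.75) * config$width,
                          a = runif(1, 6, 10), b = runif(1, 9, 14), strength = s)
        out <- res$img; if (!is.null(res$box)) boxes[[length(boxes) + 1]] <- res$box
      }
    }
    noiseless <- out
    noisy <- if (config$noise_sigma > 0) {
      clip8(round(out + stats::rnorm(length(out), sd = config$noise_sigma)))
    } else out
    list(noiseless = noiseless, noisy = noisy)
  })
  structure(list(image = img$noisy,
                 retina_mask_truth = (img$noiseless > PHANTOM_BACKGROUND) * 1,
                 label = config$class_label,
                 noiseless = img$noiseless,
                 lesion_boxes = boxes,
                 config = config),
            class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %s %dx%d, %d lesion(s), noise_sigma=%g, seed=%d\n",
              x$label, nrow(x$image), ncol(x$image), length(x$lesion_boxes),
              x$config$noise_sigma, x$config$seed))
  invisible(x)
}

#' Generate a phantom dataset on disk
#'
#' Writes 8-bit grayscale PNGs into a `split/class/` directory tree and a
#' `manifest.csv`. Per-sample seeds are derived deterministically from the
#' base seed, the split, the class and the sample index, so a dataset can be
#' extended without reshuffling existing samples.
#'
#' @param class_counts Named list: one element per split (e.g. `train`,
#'   `val`, `test`), each a named integer vector mapping class to count.
#' @param out_dir Output directory (created if needed).
#' @param base_config A [phantom_config()] supplying size, layers, noise and
#'   the base seed; its `class_label` is ignored.
#' @return A data.frame manifest with columns `path`, `split`, `label`
#'   (also written to `out_dir/manifest.csv`).
#' @export
generate_dataset <- function(class_counts, out_dir, base_config = phantom_config()) {
  if (!is.list(class_counts) || is.null(names(class_counts)))
    stop("class_counts must be a named list: split -> c(class = count)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  rows <- list()
  for (split in names(class_counts)) {
    counts <- class_counts[[split]]
    for (cls in names(counts)) {
      cls_dir <- file.path(out_dir, split, cls)
      dir.create(cls_dir, recursive = TRUE, showWarnings = FALSE)
      n <- counts[[cls]]
      for (i in seq_len(n)) {
        cfg <- base_config
        cfg$class_label <- cls
        cfg$seed <- derive_seed(base_config$seed, split, cls, i)
        sample_i <- generate_phantom(cfg)
        path <- file.path(cls_dir, sprintf("%s_%s_%04d.png", tolower(cls), split, i))
        write_gray_image(sample_i$image, path)
        rows[[length(rows) + 1]] <- data.frame(path = path, split = split,
                                               label = cls, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(path = character(), split = character(), label = character())
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Synthetic two-class feature table with known informative columns
#'
#' Draws a balanced two-class table: `n_informative` randomly placed columns
#' carry a between-class mean difference of `class_sep` (in units of the
#' within-class standard deviation, which is 1); the remaining columns are
#' class-independent standard normal noise.
#'
#' @param n_samples Total number of rows (split evenly between classes
#'   `"A"` and `"B"`).
#' @param n_features Number of feature columns (`F1` ... `Fp`).
#' @param n_informative Number of informative columns (0 <= k <= p).
#' @param class_sep Between-class mean difference of informative columns.
#' @param seed Integer seed.
#' @return A list with `features` (matrix with named columns), `labels`
#'   (factor with levels A/B) and `informative` (sorted indices of the
#'   informative columns).
#' @export
make_feature_table <- function(n_samples, n_features, n_informative,
                               class_sep = 2, seed = 1L) {
  if (n_informative > n_features) stop("n_informative must be <= n_features")
  if (n_informative < 0) stop("n_informative must be >= 0")
  # labels alternate so any prefix split stays (near-)balanced
  labels <- factor(rep(c("A", "B"), length.out = n_samples))
  with_seed(seed, {
    x <- matrix(stats::rnorm(n_samples * n_features), n_samples, n_features)
    informative <- sort(sample.int(n_features, n_informative))
    if (n_informative > 0) {
      shift <- ifelse(labels == "A", -class_sep / 2, class_sep / 2)
      x[, informative] <- x[, informative] + shift
    }
    colnames(x) <- paste0("F", seq_len(n_features))
    list(features = x, labels = labels, informative = informative)
  })
}
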