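#' Hybrid feature extractor configuration
#'
#' Bundles the enabled extractor configurations. The assembled vector always
#' concatenates groups in the fixed canonical order GLCM, HOG, then each
#' backbone in its registered order, so the feature layout is a pure function
#' of the configuration, never of image content.
#'
#' @param glcm A [glcm_config()], or NULL to disable.
#' @param hog A [hog_config()], or NULL to disable.
#' @param backbones List of [backbone_spec()]s (possibly empty).
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(glcm = glcm_config(), hog = hog_config(),
                           backbones = list(backbone_spec())) {
  if (is.null(glcm) && is.null(hog) && !length(backbones))
    stop("at least one extractor must be enabled")
  if (!is.null(glcm) && !inherits(glcm, "glcm_config"))
    stop("glcm must be a glcm_config or NULL")
  if (!is.null(hog) && !inherits(hog, "hog_config"))
    stop("hog must be a hog_config or NULL")
  for (b in backbones) if (!inherits(b, "backbone_spec"))
    stop("backbones must be a list of backbone_spec objects")
  structure(list(glcm = glcm, hog = hog, backbones = backbones),
            class = "feature_config")
}

#' Assemble the hybrid feature vector of one image
#'
#' Runs every enabled extractor and concatenates the results in the fixed
#' canonical order (GLCM, HOG, backbones). Feature names carry their
#' extractor provenance as a `"prefix:"`.
#'
#' @param img Grayscale intensity matrix in \[0, 255\].
#' @param cfg A [feature_config()].
#' @return Named numeric vector; all values finite, names unique.
#' @export
assemble_features <- function(img, cfg = feature_config()) {
  out <- numeric(0)
  if (!is.null(cfg$glcm)) out <- c(out, glcm_features(img, cfg$glcm))
  if (!is.null(cfg$hog)) out <- c(out, hog_features(img, cfg$hog))
  for (b in cfg$backbones) out <- c(out, cnn_features(img, b))
  if (anyDuplicated(names(out)))
    stop("duplicate feature names (backbone names must be distinct)")
  if (any(!is.finite(out))) stop("non-finite feature value produced")
  out
}

#' Extract a feature table from a set of images
#'
#' @param images List of grayscale intensity matrices (optionally named).
#' @param cfg A [feature_config()].
#' @param resize_to Optional side length; images are bilinearly resized to
#'   `resize_to x resize_to` before extraction so the layout is constant.
#' @return Matrix, one row per image, columns named by feature provenance.
#' @export
extract_feature_table <- function(images, cfg = feature_config(),
                                  resize_to = NULL) {
  rows <- lapply(images, function(im) {
    if (!is.null(resize_to)) im <- clip8(resize_bilinear(im, resize_to, resize_to))
    assemble_features(im, cfg)
  })
  lens <- vapply(rows, length, integer(1))
  if (length(unique(lens)) > 1)
    stop("inconsistent feature layout across images; pass resize_to to fix the size")
  x <- do.call(rbind, rows)
  colnames(x) <- names(rows[[1]])
  rownames(x) <- names(images)
  x
}

#' Write a feature table with labels as CSV
#'
#' @param x Feature matrix (rows = samples).
#' @param labels Character/factor vector of leaf labels.
#' @param path Output CSV path.
#' @param paths Optional per-sample source paths.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, labels, path, paths = NULL) {
  df <- as.data.frame(x, check.names = FALSE)
  df$label <- as.character(labels)
  if (!is.null(paths)) df$path <- paths
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table CSV written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return List with `features` (matrix), `labels` (factor) and `paths`
#'   (or NULL).
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  labels <- factor(df$label)
  paths <- if ("path" %in% names(df)) df$path else NULL
  keep <- setdiff(names(df), c("label", "path"))
  list(features = as.matrix(df[, keep, drop = FALSE]), labels = labels,
       paths = paths)
}
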