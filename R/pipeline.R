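#' @title Pipeline orchestration
#' @description Ties the stages together: data (phantoms or an image tree),
#'   retinal-layer preprocessing, hybrid feature extraction, per-stage
#'   firefly feature selection, per-stage classifier training and
#'   evaluation, and consolidated reporting. One global seed derives every
#'   module seed deterministically and the fully resolved configuration is
#'   serialized next to the outputs, so reruns are bit-reproducible.
#' @name pipeline
NULL

pipeline_defaults <- function() {
  list(
    seed = 1L,
    input_dir = NULL,
    out_dir = NULL,
    phantom = list(
      height = 128, width = 128, n_layers = 5, noise_sigma = 5,
      lesion_intensity = 1,
      counts = list(
        train = list(CNV = 50, DME = 50, DRUSEN = 50, NORMAL = 50),
        val   = list(CNV = 15, DME = 15, DRUSEN = 15, NORMAL = 15),
        test  = list(CNV = 15, DME = 15, DRUSEN = 15, NORMAL = 15))),
    preprocess = list(
      enabled = TRUE,
      bilateral_diameter = 9, bilateral_sigma_color = 75,
      bilateral_sigma_space = 75, clahe_clip_limit = 2,
      clahe_tile_grid = c(8, 8), morph_kernel_shape = "ellipse",
      morph_kernel_size = 5),
    features = list(
      resize_to = 64,
      glcm = list(enabled = TRUE, distances = c(1, 2),
                  angles = c(0, 45, 90, 135), levels = 32),
      hog = list(enabled = TRUE, cell_size = 8, block_cells = 2, n_bins = 9),
      backbones = list(list(name = "stub", pooling = "global_average",
                            input_size = 64, n_filters = c(8, 16)))),
    firefly = list(
      enabled = TRUE, n_fireflies = 10, max_iter = 3, w = 0.9, alpha = 0.5,
      beta0 = 1, gamma = 1, knn_k = 5, parsimony_mode = "penalize",
      movement_variant = "standard", fit_on_validation = FALSE),
    hierarchy = "dataset1",
    classifiers = list("logistic_regression"),
    cascade = TRUE)
}

merge_config <- function(defaults, override) {
  if (is.null(override)) return(defaults)
  for (nm in names(override)) {
    if (is.list(defaults[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(defaults[[nm]])) && nm != "counts" &&
        nm != "backbones" && nm != "classifiers") {
      defaults[[nm]] <- merge_config(defaults[[nm]], override[[nm]])
    } else {
      defaults[[nm]] <- override[[nm]]
    }
  }
  defaults
}

#' Build a fully resolved pipeline configuration
#'
#' Merges overrides into the defaults. The defaults describe a four-class
#' phantom study (50 train / 15 validation / 15 test images per class,
#' 128x128, noise sigma 5) analysed at a 64x64 working size with GLCM + HOG
#' + a stub backbone, a per-stage firefly selector and a ridge logistic
#' classifier.
#'
#' @param ... Named overrides of the default sections (`seed`, `input_dir`,
#'   `out_dir`, `phantom`, `preprocess`, `features`, `firefly`,
#'   `hierarchy`, `classifiers`, `cascade`). Nested lists are merged
#'   recursively.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- merge_config(pipeline_defaults(), list(...))
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param cfg A `pipeline_config`.
#' @param path YAML file path.
#' @return The path (write) or a resolved `pipeline_config` (read).
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  structure(merge_config(pipeline_defaults(), yaml::read_yaml(path)),
            class = "pipeline_config")
}

#' Load a split/class image directory tree
#'
#' Expects `root/split/class/image files`; labels come from the class
#' directory names. PNG, TIFF and JPEG files are read as 8-bit grayscale;
#' files with other extensions are skipped with a warning.
#'
#' @param root Dataset root directory.
#' @return Named list per split, each with `images` (list of intensity
#'   matrices), `labels` (character) and `paths`.
#' @export
load_image_dataset <- function(root) {
  if (!dir.exists(root)) stop("dataset root not found: ", root)
  splits <- list.dirs(root, recursive = FALSE, full.names = FALSE)
  splits <- splits[vapply(splits, function(s)
    length(list.dirs(file.path(root, s), recursive = FALSE)) > 0, logical(1))]
  if (!length(splits)) stop("no split/class directories under ", root)
  out <- list()
  for (split in splits) {
    classes <- list.dirs(file.path(root, split), recursive = FALSE,
                         full.names = FALSE)
    images <- list(); labels <- character(); paths <- character()
    for (cls in classes) {
      files <- sort(list.files(file.path(root, split, cls), full.names = TRUE))
      if (!length(files)) { warning("empty class directory: ", split, "/", cls); next }
      for (f in files) {
        ext <- tolower(tools::file_ext(f))
        if (!ext %in% c("png", "tif", "tiff", "jpg", "jpeg")) {
          warning("skipping unsupported file: ", f); next
        }
        images[[length(images) + 1]] <- read_gray_image(f)
        labels <- c(labels, cls); paths <- c(paths, f)
      }
    }
    out[[split]] <- list(images = images, labels = labels, paths = paths)
  }
  out
}

# In-memory phantom dataset with the same per-sample seed scheme as
# generate_dataset().
phantom_splits <- function(ph, seed) {
  base <- phantom_config(height = ph$height, width = ph$width,
                         n_layers = ph$n_layers, noise_sigma = ph$noise_sigma,
                         lesion_intensity = ph$lesion_intensity, seed = seed)
  out <- list()
  for (split in names(ph$counts)) {
    images <- list(); labels <- character()
    counts <- ph$counts[[split]]
    for (cls in names(counts)) {
      for (i in seq_len(counts[[cls]])) {
        cfg <- base
        cfg$class_label <- cls
        cfg$seed <- derive_seed(seed, split, cls, i)
        images[[length(images) + 1]] <- generate_phantom(cfg)$image
        labels <- c(labels, cls)
      }
    }
    out[[split]] <- list(images = images, labels = labels, paths = NULL)
  }
  out
}

resolve_feature_config <- function(fc, seed) {
  glcm <- if (isTRUE(fc$glcm$enabled))
    glcm_config(distances = fc$glcm$distances, angles = fc$glcm$angles,
                levels = fc$glcm$levels) else NULL
  hog <- if (isTRUE(fc$hog$enabled))
    hog_config(cell_size = fc$hog$cell_size, block_cells = fc$hog$block_cells,
               n_bins = fc$hog$n_bins) else NULL
  backbones <- lapply(fc$backbones, function(b)
    backbone_spec(name = b$name,
                  weights_source = if (is.null(b$weights_source)) "random" else b$weights_source,
                  pooling = if (is.null(b$pooling)) "global_average" else b$pooling,
                  input_size = if (is.null(b$input_size)) 64 else b$input_size,
                  seed = derive_seed(seed, "backbone", b$name),
                  n_filters = if (is.null(b$n_filters)) c(8, 16) else b$n_filters))
  feature_config(glcm = glcm, hog = hog, backbones = backbones)
}

#' Run the full hierarchical classification pipeline
#'
#' Executes, in order: data acquisition (phantoms or `input_dir`), optional
#' retinal-layer preprocessing, hybrid feature extraction, per-stage firefly
#' feature selection (optional; all-ones selection when disabled), per-stage
#' training of each requested classifier, per-stage evaluation on the test
#' split, and (optionally) cascade evaluation of the composed stages.
#'
#' @param cfg A [pipeline_config()].
#' @return An object of class `pipeline_report`; when `cfg$out_dir` is set,
#'   the report JSON, the resolved config YAML, per-stage selection JSONs,
#'   feature-table CSVs and confusion CSVs are written there.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  if (!inherits(cfg, "pipeline_config")) cfg <- do.call(pipeline_config, cfg)
  seed <- as.integer(cfg$seed)
  seeds <- list(phantom = derive_seed(seed, "phantom"))

  data <- if (!is.null(cfg$input_dir)) load_image_dataset(cfg$input_dir)
          else phantom_splits(cfg$phantom, seeds$phantom)
  for (need in c("train", "test")) if (is.null(data[[need]]))
    stop("pipeline needs a '", need, "' split; found: ",
         paste(names(data), collapse = ", "))

  # preprocessing
  pp <- cfg$preprocess
  if (isTRUE(pp$enabled)) {
    pcfg <- preprocess_config(
      bilateral_diameter = pp$bilateral_diameter,
      bilateral_sigma_color = pp$bilateral_sigma_color,
      bilateral_sigma_space = pp$bilateral_sigma_space,
      clahe_clip_limit = pp$clahe_clip_limit,
      clahe_tile_grid = pp$clahe_tile_grid,
      morph_kernel_shape = pp$morph_kernel_shape,
      morph_kernel_size = pp$morph_kernel_size)
    for (split in names(data))
      data[[split]]$images <- lapply(data[[split]]$images, function(im)
        extract_retina(im, pcfg)$image)
  }

  # features
  fcfg <- resolve_feature_config(cfg$features, seed)
  tables <- lapply(data, function(d)
    list(x = extract_feature_table(d$images, fcfg,
                                   resize_to = cfg$features$resize_to),
         y = d$labels))
  n_features <- ncol(tables$train$x)

  # hierarchy stages per split
  spec <- if (identical(cfg$hierarchy, "dataset2")) hierarchy_dataset2()
          else if (identical(cfg$hierarchy, "dataset1")) hierarchy_dataset1()
          else cfg$hierarchy
  stage_data <- lapply(tables, function(tb)
    build_stage_datasets(tb$x, tb$y, spec))

  ff <- cfg$firefly
  classifiers <- cfg$classifiers
  stages_out <- list()
  models <- lapply(classifiers, function(k) list())
  names(models) <- unlist(classifiers)

  for (s in spec$stages) {
    sname <- s$name
    train_d <- stage_data$train[[sname]]
    test_d <- stage_data$test[[sname]]
    selection <- rep(1L, n_features)
    sel_info <- list(n_selected = n_features, fitness = NA_real_)
    sel_res <- NULL
    if (isTRUE(ff$enabled)) {
      params <- firefly_params(
        n_fireflies = ff$n_fireflies, max_iter = ff$max_iter, w = ff$w,
        alpha = ff$alpha, beta0 = ff$beta0, gamma = ff$gamma,
        knn_k = ff$knn_k, seed = derive_seed(seed, "firefly", sname),
        parsimony_mode = ff$parsimony_mode,
        movement_variant = ff$movement_variant)
      if (isTRUE(ff$fit_on_validation)) {
        if (is.null(stage_data$val))
          stop("fit_on_validation selection needs a 'val' split")
        fit_tab <- stage_data$val[[sname]]; eval_tab <- test_d
      } else {
        fit_tab <- train_d
        eval_tab <- if (!is.null(stage_data$val)) stage_data$val[[sname]] else test_d
      }
      sel_res <- run_selection(list(x = fit_tab$x, y = fit_tab$y),
                               list(x = eval_tab$x, y = eval_tab$y), params)
      selection <- unname(sel_res$best_selection)
      sel_info <- list(n_selected = sel_res$n_selected,
                       fitness = sel_res$best_fitness)
    }
    per_classifier <- list()
    for (kind in unlist(classifiers)) {
      cs <- classifier_spec(kind, seed = derive_seed(seed, "classifier", sname, kind))
      model <- train_stage(train_d, selection, cs)
      models[[kind]][[sname]] <- model
      per_classifier[[kind]] <- evaluate_stage(model, test_d)
    }
    stages_out[[sname]] <- list(
      name = sname,
      counts_train = as.list(train_d$counts),
      counts_test = as.list(test_d$counts),
      n_features_total = n_features,
      n_selected = sel_info$n_selected,
      selection_fitness = sel_info$fitness,
      selection = selection,
      selection_result = sel_res,
      results = per_classifier)
  }

  mean_acc <- lapply(unlist(classifiers), function(kind)
    mean_accuracy(lapply(stages_out, function(st) st$results[[kind]])))
  names(mean_acc) <- unlist(classifiers)

  cascade <- NULL
  if (isTRUE(cfg$cascade)) {
    # composed-cascade leaf accuracy on the test split: an extra report on
    # top of the per-stage protocol
    cascade <- lapply(unlist(classifiers), function(kind) {
      leaf <- cascade_predict(models[[kind]], tables$test$x, spec)
      mean(leaf == tables$test$y)
    })
    names(cascade) <- unlist(classifiers)
  }

  report <- structure(list(
    config = unclass(cfg), seeds = seeds, n_features = n_features,
    stages = stages_out, mean_accuracy = mean_acc,
    cascade_accuracy = cascade, hierarchy = spec), class = "pipeline_report")

  if (!is.null(cfg$out_dir)) write_pipeline_report(report, cfg$out_dir, tables)
  report
}

# Serialize the report (JSON), resolved config (YAML), selections and
# confusion matrices under out_dir.
write_pipeline_report <- function(report, out_dir, tables = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_pipeline_config(structure(report$config, class = "pipeline_config"),
                        file.path(out_dir, "config.yaml"))
  json_stages <- lapply(report$stages, function(st) {
    res <- lapply(st$results, function(r)
      list(accuracy = r$accuracy,
           confusion = as.list(r$confusion),
           per_class = r$per_class))
    list(counts_train = st$counts_train, counts_test = st$counts_test,
         n_features_total = st$n_features_total, n_selected = st$n_selected,
         selection_fitness = st$selection_fitness, classifiers = res)
  })
  jsonlite::write_json(
    list(n_features = report$n_features, stages = json_stages,
         mean_accuracy = report$mean_accuracy,
         cascade_accuracy = report$cascade_accuracy,
         seeds = report$seeds),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
  for (sname in names(report$stages)) {
    st <- report$stages[[sname]]
    if (!is.null(st$selection_result))
      write_selection_result(st$selection_result,
                             file.path(out_dir, paste0("selection_", sname, ".json")))
    for (kind in names(st$results)) {
      conf <- st$results[[kind]]$confusion
      utils::write.csv(data.frame(t(conf)),
                       file.path(out_dir, sprintf("confusion_%s_%s.csv", sname, kind)),
                       row.names = FALSE)
    }
  }
  if (!is.null(tables))
    for (split in names(tables))
      write_feature_table(tables[[split]]$x, tables[[split]]$y,
                          file.path(out_dir, paste0("features_", split, ".csv")))
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  features: %d\n", x$n_features))
  for (st in x$stages) {
    cat(sprintf("  stage %-20s selected %d/%d\n", st$name, st$n_selected,
                st$n_features_total))
    for (kind in names(st$results))
      cat(sprintf("    %-20s acc %.3f\n", kind, st$results[[kind]]$accuracy))
  }
  for (kind in names(x$mean_accuracy))
    cat(sprintf("  mean accuracy [%s]: %.3f\n", kind, x$mean_accuracy[[kind]]))
  if (!is.null(x$cascade_accuracy))
    for (kind in names(x$cascade_accuracy))
      cat(sprintf("  cascade leaf accuracy [%s]: %.3f (composed stages)\n",
                  kind, x$cascade_accuracy[[kind]]))
  invisible(x)
}
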