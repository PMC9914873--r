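#' @title Hierarchical binary classification
#' @description Instead of one multiclass decision, an ordered cascade of
#'   binary stages: abnormal vs normal, then AMD vs DME among the abnormal,
#'   then CNV vs DRUSEN among the AMD cases. Each stage trains its own
#'   binary classifier on relabeled data and is evaluated with full
#'   confusion-matrix metrics; stages can also be chained into a single
#'   leaf prediction.
#' @name hierarchy
NULL

hier_stage <- function(name, positive_group, negative_group,
                       pos_label, neg_label) {
  list(name = name, positive_group = positive_group,
       negative_group = negative_group,
       pos_label = pos_label, neg_label = neg_label)
}

#' Hierarchy specification
#'
#' @param stages List of stages as built by the preset constructors; each
#'   stage holds a name, a positive and a negative leaf-class group, and the
#'   two stage labels.
#' @return An object of class `hierarchy_spec`.
#' @seealso [hierarchy_dataset1()], [hierarchy_dataset2()]
#' @export
hierarchy_spec <- function(stages) {
  for (s in stages)
    if (length(intersect(s$positive_group, s$negative_group)))
      stop("stage groups must be disjoint: ", s$name)
  structure(list(stages = stages), class = "hierarchy_spec")
}

#' Four-class hierarchy: CNV/DME/DRUSEN/NORMAL
#'
#' Stage 1 separates abnormal (CNV + DRUSEN + DME) from NORMAL; stage 2
#' separates AMD (CNV + DRUSEN) from DME; stage 3 separates CNV from DRUSEN.
#'
#' @return A `hierarchy_spec` with three stages.
#' @export
hierarchy_dataset1 <- function() {
  hierarchy_spec(list(
    hier_stage("abnormal_vs_normal", c("CNV", "DRUSEN", "DME"), "NORMAL",
               "ABNORMAL", "NORMAL"),
    hier_stage("amd_vs_dme", c("CNV", "DRUSEN"), "DME", "AMD", "DME"),
    hier_stage("cnv_vs_drusen", "CNV", "DRUSEN", "CNV", "DRUSEN")))
}

#' Three-class hierarchy: AMD/DME/NORMAL
#'
#' Stage 1 separates abnormal (AMD + DME) from NORMAL; stage 2 separates
#' AMD from DME.
#'
#' @return A `hierarchy_spec` with two stages.
#' @export
hierarchy_dataset2 <- function() {
  hierarchy_spec(list(
    hier_stage("abnormal_vs_normal", c("AMD", "DME"), "NORMAL",
               "ABNORMAL", "NORMAL"),
    hier_stage("amd_vs_dme", "AMD", "DME", "AMD", "DME")))
}

#' Build per-stage relabeled datasets
#'
#' For each stage, samples whose leaf label is in the positive group get the
#' stage-positive label, those in the negative group the stage-negative
#' label; all other samples are excluded from that stage.
#'
#' @param x Feature matrix (rows = samples).
#' @param labels Leaf class labels, one per row.
#' @param spec A `hierarchy_spec`.
#' @return Named list (one element per stage) of lists with `x`, `y`
#'   (factor with levels `c(pos_label, neg_label)`), `counts` (per stage
#'   label) and `degenerate` (TRUE when a stage has fewer than two classes).
#' @export
build_stage_datasets <- function(x, labels, spec) {
  labels <- as.character(labels)
  known <- unique(unlist(lapply(spec$stages, function(s)
    c(s$positive_group, s$negative_group))))
  bad <- setdiff(unique(labels), known)
  if (length(bad))
    stop("unknown leaf label(s) not covered by the hierarchy: ",
         paste(bad, collapse = ", "))
  out <- lapply(spec$stages, function(s) {
    keep_pos <- labels %in% s$positive_group
    keep_neg <- labels %in% s$negative_group
    keep <- keep_pos | keep_neg
    y <- factor(ifelse(keep_pos[keep], s$pos_label, s$neg_label),
                levels = c(s$pos_label, s$neg_label))
    counts <- table(y)
    degenerate <- sum(counts > 0) < 2
    if (degenerate)
      warning("stage '", s$name, "' has fewer than two represented classes")
    list(x = x[keep, , drop = FALSE], y = y, stage = s,
         counts = counts, degenerate = degenerate)
  })
  names(out) <- vapply(spec$stages, `[[`, character(1), "name")
  out
}

#' Binary classifier specification
#'
#' @param kind `"logistic_regression"`, `"svm"` or `"random_forest"`.
#' @param hyperparameters Named list of overrides: `C` (SVM cost /
#'   inverse-regularization of the ridge logistic model, default 1),
#'   `ntree` (random forest trees, default 100).
#' @param seed Integer seed controlling any stochastic training component.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = "logistic_regression",
                            hyperparameters = list(), seed = 1L) {
  kind <- match.arg(kind, c("logistic_regression", "svm", "random_forest"))
  structure(list(kind = kind, hyperparameters = hyperparameters,
                 seed = as.integer(seed)), class = "classifier_spec")
}

#' Train one hierarchy stage
#'
#' Standardizes features on the stage's training split, restricts them to
#' the selected columns, and fits the requested binary classifier. The
#' returned bundle carries the classifier, the selection and the
#' standardization statistics, so prediction is a pure function of the
#' bundle and the input.
#'
#' @param stage_data One element of [build_stage_datasets()] (or any list
#'   with `x`, `y` and optionally `stage`).
#' @param selection 0/1 vector over all features, or NULL for all-ones.
#' @param cls A [classifier_spec()].
#' @return An object of class `stage_model`.
#' @export
train_stage <- function(stage_data, selection = NULL, cls = classifier_spec()) {
  x <- as.matrix(stage_data$x); y <- droplevels(factor(stage_data$y))
  if (nlevels(y) < 2) stop("stage training data must contain both classes")
  if (is.null(selection)) selection <- rep(1L, ncol(x))
  if (length(selection) != ncol(x))
    stop("selection length must equal the feature count")
  if (sum(selection) < 1) stop("selection must keep at least one feature")
  st <- standardize_stats(x)
  sel_idx <- which(selection == 1)
  xs <- standardize_apply(x, st)[, sel_idx, drop = FALSE]
  hp <- cls$hyperparameters
  cost <- if (!is.null(hp$C)) hp$C else 1
  fit <- with_seed(cls$seed, switch(cls$kind,
    svm = e1071::svm(x = xs, y = y, kernel = "radial", cost = cost,
                     scale = FALSE),
    logistic_regression = {
      # ridge-penalized logistic regression; glmnet needs >= 2 columns,
      # a zero column is padded (and padded again at prediction time)
      xg <- if (ncol(xs) < 2) cbind(xs, 0) else xs
      glmnet::glmnet(xg, y, family = "binomial", alpha = 0,
                     lambda = 1 / (nrow(xg) * cost), standardize = FALSE,
                     maxit = 1e5)
    },
    random_forest = {
      ntree <- if (!is.null(hp$ntree)) hp$ntree else 100
      randomForest::randomForest(x = xs, y = y, ntree = ntree)
    }))
  stage <- stage_data$stage
  structure(list(fit = fit, kind = cls$kind, cls = cls,
                 selection = as.integer(selection), sel_idx = sel_idx,
                 standardize = st, levels = levels(y),
                 pos_label = if (!is.null(stage)) stage$pos_label else levels(y)[1],
                 stage_name = if (!is.null(stage)) stage$name else "stage"),
            class = "stage_model")
}

#' Predict stage labels for new samples
#'
#' @param object A `stage_model`.
#' @param newdata Feature matrix over the *full* feature layout the model
#'   was trained on (the model applies its own selection and
#'   standardization).
#' @param ... Unused.
#' @return Character vector of stage labels.
#' @export
predict.stage_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  xs <- standardize_apply(x, object$standardize)[, object$sel_idx, drop = FALSE]
  out <- switch(object$kind,
    svm = as.character(predict(object$fit, xs)),
    logistic_regression = {
      xg <- if (ncol(xs) < 2) cbind(xs, 0) else xs
      as.character(predict(object$fit, newx = xg, type = "class")[, 1])
    },
    random_forest = as.character(predict(object$fit, xs)))
  out
}

#' Evaluate a stage model on its test split
#'
#' Confusion counts take the stage-positive label as positive. Accuracy is
#' `(TP + TN) / (TP + TN + FP + FN)`; precision, recall and F1 are computed
#' class by class (each stage class in turn treated as positive).
#' Zero-denominator metrics are defined as 0 and flagged.
#'
#' @param model A `stage_model`.
#' @param test_data List with `x` and `y` (stage labels).
#' @return An object of class `stage_result`: `confusion`
#'   (`TP`, `FP`, `FN`, `TN`), `accuracy`, `per_class` (data.frame with
#'   precision/recall/f1 per class), `classifier`, `n`,
#'   `zero_division_flagged`.
#' @export
evaluate_stage <- function(model, test_data) {
  x <- as.matrix(test_data$x)
  if (!nrow(x)) stop("test set must be nonempty")
  stage_metrics(predict(model, x), as.character(test_data$y),
                pos_label = model$pos_label, levels = model$levels,
                classifier = model$kind, stage = model$stage_name)
}

#' Confusion-matrix metrics for stage predictions
#'
#' The arithmetic behind [evaluate_stage()], usable directly on label
#' vectors: confusion counts with `pos_label` as positive, accuracy
#' `(TP + TN) / n`, and precision/recall/F1 computed class by class with the
#' zero-denominator convention of 0 (flagged).
#'
#' @param pred,truth Character vectors of predicted and true stage labels.
#' @param pos_label The stage-positive label.
#' @param levels The two stage labels (defaults to `pos_label` plus the
#'   other label seen in `truth`).
#' @param classifier,stage Optional names echoed into the result.
#' @return An object of class `stage_result`.
#' @export
stage_metrics <- function(pred, truth, pos_label,
                          levels = union(pos_label, unique(truth)),
                          classifier = "manual", stage = "stage") {
  pos <- pos_label
  tp <- sum(pred == pos & truth == pos)
  fp <- sum(pred == pos & truth != pos)
  fn <- sum(pred != pos & truth == pos)
  tn <- sum(pred != pos & truth != pos)
  n <- length(truth)
  flagged <- FALSE
  per_class <- do.call(rbind, lapply(levels, function(cl) {
    tpc <- sum(pred == cl & truth == cl)
    fpc <- sum(pred == cl & truth != cl)
    fnc <- sum(pred != cl & truth == cl)
    prec <- if (tpc + fpc == 0) { flagged <<- TRUE; 0 } else tpc / (tpc + fpc)
    rec <- if (tpc + fnc == 0) { flagged <<- TRUE; 0 } else tpc / (tpc + fnc)
    f1 <- f1_score(prec, rec)
    if (prec + rec == 0) flagged <<- TRUE
    data.frame(class = cl, precision = prec, recall = rec, f1 = f1)
  }))
  structure(list(confusion = c(TP = tp, FP = fp, FN = fn, TN = tn),
                 accuracy = (tp + tn) / n, per_class = per_class,
                 classifier = classifier, stage = stage, n = n,
                 zero_division_flagged = flagged),
            class = "stage_result")
}

#' @export
print.stage_result <- function(x, ...) {
  cat(sprintf("<stage_result> %s [%s]: acc %.3f (TP %d FP %d FN %d TN %d)\n",
              x$stage, x$classifier, x$accuracy,
              x$confusion["TP"], x$confusion["FP"],
              x$confusion["FN"], x$confusion["TN"]))
  invisible(x)
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 * P * R / (P + R)`, defined as 0 when `P + R = 0`.
#'
#' @param precision,recall Values in \[0, 1\].
#' @return F1 in \[0, 1\].
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Mean accuracy over hierarchy stages
#'
#' Unweighted arithmetic mean of the per-stage accuracies.
#'
#' @param stage_results List of `stage_result`s, or a numeric vector of
#'   accuracies.
#' @return Mean accuracy.
#' @export
mean_accuracy <- function(stage_results) {
  acc <- if (is.numeric(stage_results)) stage_results else
    vapply(stage_results, function(s) s$accuracy, numeric(1))
  if (!length(acc)) stop("at least one stage accuracy is required")
  mean(acc)
}

#' Cascade stage models into leaf predictions
#'
#' Routes each sample through the ordered stages: a stage-negative
#' prediction terminates at that stage's (single-leaf) negative group, a
#' stage-positive prediction moves on; the final stage's positive prediction
#' yields its (single-leaf) positive group. Each stage applies its own
#' selection and standardization.
#'
#' @param models Named list of `stage_model`s, one per stage of `spec`, in
#'   stage order.
#' @param newdata Feature matrix over the full feature layout.
#' @param spec The `hierarchy_spec` the models were trained for.
#' @return Character vector of leaf classes, one per row of `newdata`.
#' @export
cascade_predict <- function(models, newdata, spec) {
  x <- as.matrix(newdata)
  n <- nrow(x)
  out <- rep(NA_character_, n)
  active <- seq_len(n)
  n_stages <- length(spec$stages)
  for (s_i in seq_len(n_stages)) {
    if (!length(active)) break
    s <- spec$stages[[s_i]]
    model <- models[[s$name]]
    if (is.null(model)) stop("missing stage model on the routing path: ", s$name)
    pred <- predict(model, x[active, , drop = FALSE])
    neg <- pred == s$neg_label
    if (any(neg)) {
      if (length(s$negative_group) != 1)
        stop("cannot resolve a leaf: stage '", s$name,
             "' has a multi-class negative group")
      out[active[neg]] <- s$negative_group
    }
    if (s_i == n_stages) {
      if (length(s$positive_group) != 1)
        stop("cannot resolve a leaf: final stage '", s$name,
             "' has a multi-class positive group")
      out[active[!neg]] <- s$positive_group
    }
    active <- active[!neg]
  }
  out
}
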