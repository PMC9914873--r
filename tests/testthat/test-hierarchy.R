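# small 4-class Gaussian-cluster feature sets for cascade/stage tests
make_leaf_data <- function(n_per_class, seed, classes = c("CNV", "DME", "DRUSEN", "NORMAL"),
                           sep = 6) {
  set.seed(seed)
  centers <- diag(length(classes)) * sep
  x <- do.call(rbind, lapply(seq_along(classes), function(i)
    sweep(matrix(rnorm(n_per_class * length(classes)), n_per_class), 2,
          centers[i, ], `+`)))
  colnames(x) <- paste0("F", seq_len(ncol(x)))
  list(x = x, y = rep(classes, each = n_per_class))
}

test_that("stage datasets relabel, exclude and conserve samples", {
  x <- matrix(seq_len(8), 4, 2)
  labels <- c("CNV", "DME", "DRUSEN", "NORMAL")
  sd1 <- build_stage_datasets(x, labels, hierarchy_dataset1())
  expect_named(sd1, c("abnormal_vs_normal", "amd_vs_dme", "cnv_vs_drusen"))
  expect_equal(nrow(sd1$abnormal_vs_normal$x), 4)
  expect_equal(as.vector(sd1$abnormal_vs_normal$counts), c(3, 1))
  expect_equal(nrow(sd1$amd_vs_dme$x), 3)
  expect_equal(as.vector(sd1$amd_vs_dme$counts), c(2, 1))
  expect_equal(nrow(sd1$cnv_vs_drusen$x), 2)

  # conservation: kept + excluded = input, per stage
  for (st in sd1) expect_equal(nrow(st$x) + (4 - nrow(st$x)), 4)

  warns <- capture_warnings(
    sdn <- build_stage_datasets(x, rep("NORMAL", 4), hierarchy_dataset1()))
  expect_true(all(grepl("fewer than two", warns)))
  expect_length(warns, 3)  # all three stages lack a class
  expect_true(sdn$amd_vs_dme$degenerate)
  expect_equal(nrow(sdn$amd_vs_dme$x), 0)

  expect_error(build_stage_datasets(x, c("CNV", "DME", "PET", "NORMAL"),
                                    hierarchy_dataset1()), "PET")
})

test_that("stage counts reproduce the published split arithmetic", {
  # first classification: 1200 + 1200 + 1200 abnormal vs 3600 normal
  lab1 <- c(rep("CNV", 1200), rep("DRUSEN", 1200), rep("DME", 1200),
            rep("NORMAL", 3600))
  sd <- build_stage_datasets(matrix(0, length(lab1), 1), lab1, hierarchy_dataset1())
  expect_equal(as.vector(sd$abnormal_vs_normal$counts), c(3600, 3600))
  # second classification drawn with its own counts: 2000 + 2000 vs 4000
  lab2 <- c(rep("CNV", 2000), rep("DRUSEN", 2000), rep("DME", 4000))
  # no NORMAL samples here, so the first stage warns as degenerate
  sd2 <- suppressWarnings(
    build_stage_datasets(matrix(0, length(lab2), 1), lab2, hierarchy_dataset1()))
  expect_equal(as.vector(sd2$amd_vs_dme$counts), c(4000, 4000))
})

test_that("stage training is deterministic and honours the selection", {
  set.seed(1)
  x <- rbind(matrix(rnorm(40, mean = 0), 20), matrix(rnorm(40, mean = 5), 20))
  colnames(x) <- c("F1", "F2")
  y <- factor(rep(c("ABNORMAL", "NORMAL"), each = 20),
              levels = c("ABNORMAL", "NORMAL"))
  sdat <- list(x = x, y = y,
               stage = list(name = "abnormal_vs_normal",
                            pos_label = "ABNORMAL", neg_label = "NORMAL"))
  m <- train_stage(sdat, cls = classifier_spec("logistic_regression"))
  expect_equal(mean(predict(m, x) == as.character(y)), 1.0)

  for (kind in c("svm", "random_forest")) {
    ma <- train_stage(sdat, cls = classifier_spec(kind, seed = 3))
    mb <- train_stage(sdat, cls = classifier_spec(kind, seed = 3))
    expect_identical(predict(ma, x), predict(mb, x))
  }

  expect_error(train_stage(list(x = x, y = factor(rep("A", 40))),
                           cls = classifier_spec()), "both classes")
  expect_error(train_stage(sdat, selection = c(1, 0, 1)), "length")

  # restricting to a label-independent noise column gives chance accuracy
  accs <- vapply(1:20, function(s) {
    set.seed(s)
    xn <- cbind(c(rnorm(15, 0), rnorm(15, 8)), rnorm(30))
    colnames(xn) <- c("signal", "noise")
    yn <- factor(rep(c("A", "B"), each = 15))
    tr <- list(x = xn[c(1:10, 16:25), ], y = yn[c(1:10, 16:25)],
               stage = list(name = "s", pos_label = "A", neg_label = "B"))
    te <- list(x = xn[c(11:15, 26:30), ], y = yn[c(11:15, 26:30)])
    mm <- train_stage(tr, selection = c(0, 1), cls = classifier_spec(seed = s))
    evaluate_stage(mm, te)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.18)
})

test_that("stage metrics implement the confusion-matrix formulas", {
  # perfect predictions
  perfect <- stage_metrics(rep(c("P", "N"), 5), rep(c("P", "N"), 5), "P",
                           levels = c("P", "N"))
  expect_equal(perfect$accuracy, 1)
  expect_true(all(perfect$per_class$precision == 1))
  expect_true(all(perfect$per_class$f1 == 1))

  # TP=8, FN=1, FP=2, TN=9
  truth <- c(rep("P", 9), rep("N", 11))
  pred <- c(rep("P", 8), "N", rep("P", 2), rep("N", 9))
  r <- stage_metrics(pred, truth, "P", levels = c("P", "N"))
  expect_equal(unname(r$confusion), c(8, 2, 1, 9))
  expect_equal(r$accuracy, 0.85)
  pc <- r$per_class[r$per_class$class == "P", ]
  expect_equal(pc$precision, 0.8)
  expect_equal(pc$recall, 8 / 9)
  expect_equal(pc$f1, 2 * 0.8 * (8 / 9) / (0.8 + 8 / 9))
  expect_equal(sum(r$confusion), r$n)

  # degenerate always-negative predictor: zero-division convention
  r0 <- stage_metrics(rep("N", 5), c("P", "P", "N", "N", "N"), "P",
                      levels = c("P", "N"))
  expect_true(r0$zero_division_flagged)
  expect_equal(r0$per_class[r0$per_class$class == "P", "precision"], 0)

  # F1 equals the harmonic-mean identity on random confusions
  for (s in 1:10) {
    set.seed(s)
    pred <- sample(c("P", "N"), 30, replace = TRUE)
    truth <- sample(c("P", "N"), 30, replace = TRUE)
    rr <- stage_metrics(pred, truth, "P", levels = c("P", "N"))
    for (i in 1:2) {
      p <- rr$per_class$precision[i]; q <- rr$per_class$recall[i]
      expect_equal(rr$per_class$f1[i], f1_score(p, q))
    }
  }
})

test_that("mean accuracy is the unweighted stage average", {
  expect_equal(mean_accuracy(c(0.969, 0.925, 0.977)), 0.957)
  expect_equal(mean_accuracy(0.42), 0.42)
  expect_equal(mean_accuracy(c(1.0, 0.5)), 0.75)
  expect_error(mean_accuracy(numeric(0)), "at least one")
})

test_that("the cascade routes through the hierarchy consistently", {
  spec <- hierarchy_dataset1()
  train <- make_leaf_data(30, seed = 1)
  test <- make_leaf_data(10, seed = 2)
  sd_train <- build_stage_datasets(train$x, train$y, spec)
  models <- lapply(sd_train, train_stage, cls = classifier_spec("logistic_regression"))

  leaf <- cascade_predict(models, test$x, spec)
  expect_true(all(leaf %in% c("CNV", "DME", "DRUSEN", "NORMAL")))
  expect_gt(mean(leaf == test$y), 0.9)

  # routing consistency: a CNV/DRUSEN leaf was ABNORMAL at stage 1, AMD at 2
  p1 <- predict(models$abnormal_vs_normal, test$x)
  p2 <- predict(models$amd_vs_dme, test$x)
  deep <- leaf %in% c("CNV", "DRUSEN")
  expect_true(all(p1[deep] == "ABNORMAL"))
  expect_true(all(p2[deep] == "AMD"))

  # samples the first stage calls NORMAL never touch later stages
  only_stage1 <- list(abnormal_vs_normal = models$abnormal_vs_normal)
  normal_only <- test$x[test$y == "NORMAL", , drop = FALSE]
  expect_true(all(cascade_predict(only_stage1, normal_only, spec) == "NORMAL"))

  # missing stage model on an exercised path is an explicit error
  expect_error(cascade_predict(only_stage1, test$x, spec), "amd_vs_dme")

  # three-class hierarchy yields three leaves
  spec2 <- hierarchy_dataset2()
  tr2 <- make_leaf_data(30, seed = 3, classes = c("AMD", "DME", "NORMAL"))
  te2 <- make_leaf_data(10, seed = 4, classes = c("AMD", "DME", "NORMAL"))
  m2 <- lapply(build_stage_datasets(tr2$x, tr2$y, spec2), train_stage,
               cls = classifier_spec("svm"))
  leaf2 <- cascade_predict(m2, te2$x, spec2)
  expect_true(all(leaf2 %in% c("AMD", "DME", "NORMAL")))
})
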