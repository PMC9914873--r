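make_split_tables <- function(n, p, k, sep, seed, n_fit) {
  tab <- make_feature_table(n, p, k, class_sep = sep, seed = seed)
  list(fit = list(x = tab$features[seq_len(n_fit), , drop = FALSE],
                  y = tab$labels[seq_len(n_fit)]),
       eval = list(x = tab$features[(n_fit + 1):n, , drop = FALSE],
                   y = tab$labels[(n_fit + 1):n]),
       informative = tab$informative)
}

test_that("KNN fitness accuracy matches a brute-force oracle and its edge cases", {
  st <- make_split_tables(60, 8, 3, 3, seed = 2, n_fit = 40)
  # evaluating on the fit set itself with k = 1 is a perfect self-match
  expect_equal(knn_accuracy(rep(1, 8), st$fit, st$fit, k = 1), 1.0)

  # a single perfectly separating column
  x <- matrix(c(rep(0, 10), rep(10, 10), rnorm(20)), ncol = 2)
  y <- factor(rep(c("A", "B"), each = 10))
  toy <- list(x = x, y = y)
  expect_equal(knn_accuracy(c(1, 0), toy, toy, k = 1), 1.0)

  for (s in 1:5) {
    st <- make_split_tables(38, 8, 2, 1.5, seed = 10 + s, n_fit = 30)
    sel <- as.integer(runif(8) < 0.6); if (sum(sel) == 0) sel[1] <- 1L
    for (k in c(1, 3, 5)) {
      expect_equal(knn_accuracy(sel, st$fit, st$eval, k),
                   oracle_knn(sel, st$fit$x, st$fit$y, st$eval$x, st$eval$y, k))
    }
  }
  expect_error(knn_accuracy(rep(0, 8), st$fit, st$eval, 1), "at least one bit")
})

test_that("fitness combines accuracy and subset size in both parsimony modes", {
  # self-evaluation with k = 1 forces accuracy 1, isolating the size term
  x <- matrix(rnorm(200), 20, 10); y <- factor(rep(c("A", "B"), 10))
  toy <- list(x = x, y = y)
  sel <- c(1, rep(0, 9))  # 1 of 10 selected
  lit <- firefly_fitness(sel, toy, toy, firefly_params(w = 0.9, knn_k = 1,
                                                       parsimony_mode = "literal"))
  pen <- firefly_fitness(sel, toy, toy, firefly_params(w = 0.9, knn_k = 1,
                                                       parsimony_mode = "penalize"))
  expect_equal(lit, 0.9 * 1 + 0.1 * 0.1)
  expect_equal(pen, 0.9 * 1 + 0.1 * 0.9)

  # w = 1: fitness is the accuracy regardless of mode
  st <- make_split_tables(60, 6, 2, 2, seed = 5, n_fit = 40)
  sel6 <- c(1, 1, 0, 1, 0, 0)
  acc <- knn_accuracy(sel6, st$fit, st$eval, 5)
  for (mode in c("literal", "penalize"))
    expect_equal(firefly_fitness(sel6, st$fit, st$eval,
                                 firefly_params(w = 1, parsimony_mode = mode)), acc)

  # direct arithmetic of the printed form: acc 0.8, w 0.9, 10 of 100
  expect_equal(0.9 * 0.8 + (1 - 0.9) * (10 / 100), 0.73)
  expect_equal(0.9 * 0.8 + (1 - 0.9) * (1 - 10 / 100), 0.81)
})

test_that("bitstring distance follows the normalized Hamming form", {
  a <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  b <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  expect_equal(pairwise_distance(a, a), 0)
  expect_equal(pairwise_distance(a, b), 2 / (2 * 10 - (5 + 3)))
  expect_equal(pairwise_distance(rep(1, 4), rep(1, 4)), 0)  # zero denominator
  for (s in 1:10) {
    set.seed(s)
    u <- rbinom(12, 1, 0.5); w <- rbinom(12, 1, 0.5)
    expect_equal(pairwise_distance(u, w), pairwise_distance(w, u))
  }
  expect_error(pairwise_distance(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("attractiveness decays exponentially with distance", {
  p <- firefly_params(beta0 = 1, gamma = 1)
  expect_equal(attractiveness(0, p), 1)
  expect_equal(attractiveness(1, p), exp(-1))
  p2 <- firefly_params(beta0 = 2.5, gamma = 0)
  expect_equal(attractiveness(c(0, 1, 7), p2), c(2.5, 2.5, 2.5))
  rs <- seq(0, 3, by = 0.25)
  expect_true(all(diff(attractiveness(rs, p)) < 0))
})

test_that("tanh binarization thresholds at atanh(0.5) and fixes bits", {
  expect_equal(binarize_positions(-2), 0L)
  expect_equal(binarize_positions(0.55), 1L)
  expect_equal(binarize_positions(0.54), 0L)
  # crossing at atanh(0.5), tested one ulp either side of the boundary
  expect_equal(binarize_positions(atanh(0.5) + 1e-12), 1L)
  bits <- c(0L, 1L, 1L, 0L, 1L)
  expect_identical(binarize_positions(bits), bits)
})

test_that("movement steps follow the attraction and random-walk forms", {
  p_std <- firefly_params(alpha = 0, gamma = 0, beta0 = 1)
  # dim firefly pulled onto a brighter one's set bit
  st <- move_towards(xi = c(0, 1), xj = c(1, 1), fit_i = 0.2, fit_j = 0.9, p_std)
  expect_equal(st$proposal, c(1, 1))
  expect_equal(st$bits, c(1L, 1L))
  expect_equal(st$beta, 1)

  # literal variant: agreeing coordinates collapse to 0
  p_lit <- firefly_params(alpha = 0, gamma = 0, beta0 = 1,
                          movement_variant = "literal")
  st_lit <- move_towards(c(1, 1), c(1, 1), 0.2, 0.9, p_lit)
  expect_equal(st_lit$proposal, c(0, 0))
  expect_equal(st_lit$bits, c(0L, 0L))

  expect_error(move_towards(c(0, 1), c(1, 1), 0.9, 0.2, p_std), "fitness")

  # random move with alpha = 0 keeps the bits
  st_r <- move_random(c(1, 0, 1), firefly_params(alpha = 0))
  expect_equal(st_r$proposal, c(1, 0, 1))
  expect_equal(st_r$bits, c(1L, 0L, 1L))

  # alpha = 1 from a 0 bit can never reach the selection threshold
  set.seed(3)
  for (i in 1:100)
    expect_equal(move_random(0, firefly_params(alpha = 1))$bits, 0L)

  # seeded streams reproduce proposals
  s1 <- withr::with_seed(9, move_random(rep(0, 5), firefly_params(alpha = 1)))
  s2 <- withr::with_seed(9, move_random(rep(0, 5), firefly_params(alpha = 1)))
  expect_identical(s1$proposal, s2$proposal)
})

test_that("empty selections are repaired to a single random bit", {
  set.seed(1)
  r <- repair_empty(rep(0L, 10))
  expect_equal(sum(r), 1)
  nz <- c(0L, 1L, 0L)
  expect_identical(repair_empty(nz), nz)
  b1 <- withr::with_seed(4, repair_empty(rep(0L, 10)))
  b2 <- withr::with_seed(4, repair_empty(rep(0L, 10)))
  expect_identical(b1, b2)
})

test_that("the full selection run is reproducible, elitist and degenerate-safe", {
  st <- make_split_tables(60, 12, 3, 2.5, seed = 7, n_fit = 40)
  params <- firefly_params(n_fireflies = 6, max_iter = 4, seed = 21)
  r1 <- run_selection(st$fit, st$eval, params)
  r2 <- run_selection(st$fit, st$eval, params)
  expect_identical(r1$best_selection, r2$best_selection)
  expect_identical(r1$history, r2$history)
  expect_true(all(diff(r1$history) >= 0))
  expect_equal(r1$n_selected, sum(r1$best_selection))
  expect_gte(r1$n_selected, 1)

  r0 <- run_selection(st$fit, st$eval,
                      firefly_params(n_fireflies = 6, max_iter = 0, seed = 21))
  expect_length(r0$history, 0)
  expect_gte(r1$best_fitness, r0$best_fitness)

  one_class <- list(x = st$fit$x, y = factor(rep("A", nrow(st$fit$x))))
  expect_error(run_selection(one_class, st$eval, params), "2 classes")
})
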