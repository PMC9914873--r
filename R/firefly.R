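#' @title Binary firefly wrapper feature selection
#' @description A population of candidate feature subsets ("fireflies",
#'   bitstrings with one bit per feature) is evolved by attraction: a dimmer
#'   (less fit) firefly moves towards each brighter one with a distance-
#'   decaying attractiveness, the brightest move randomly, and real-valued
#'   position proposals are squashed through tanh and thresholded at 0.5
#'   back into bits. Fitness is a weighted combination of the KNN accuracy
#'   of the subset and a parsimony term. The best subset ever evaluated is
#'   retained (elitism).
#' @name firefly
NULL

#' Firefly selector parameters
#'
#' @param n_fireflies Population size (>= 2).
#' @param max_iter Outer sweeps of the population.
#' @param w Fitness weight on KNN accuracy, in \[0, 1\]; `1 - w` weighs the
#'   subset-size term.
#' @param alpha Randomization scale of the per-coordinate uniform kick
#'   (constant over iterations).
#' @param beta0 Attractiveness at zero distance (> 0).
#' @param gamma Light-absorption coefficient (>= 0); larger values make
#'   attractiveness decay faster with distance.
#' @param knn_k Neighbour count of the KNN fitness classifier.
#' @param seed Integer seed; one stream drives initialization, moves and
#'   repair in a fixed order.
#' @param parsimony_mode `"penalize"` (default; the size term is
#'   `1 - selected/total`, rewarding small subsets) or `"literal"` (the size
#'   term is `selected/total`, rewarding large subsets).
#' @param movement_variant `"standard"` (default; attraction step adds the
#'   incumbent position) or `"literal"` (no incumbent term, so agreeing
#'   coordinates collapse towards 0).
#' @return An object of class `firefly_params`.
#' @export
firefly_params <- function(n_fireflies = 20, max_iter = 30, w = 0.9,
                           alpha = 0.5, beta0 = 1, gamma = 1, knn_k = 5,
                           seed = 1L, parsimony_mode = "penalize",
                           movement_variant = "standard") {
  if (n_fireflies < 2) stop("n_fireflies must be >= 2")
  if (w < 0 || w > 1) stop("w must lie in [0, 1]")
  if (beta0 <= 0) stop("beta0 must be > 0")
  if (gamma < 0) stop("gamma must be >= 0")
  if (knn_k < 1) stop("knn_k must be >= 1")
  parsimony_mode <- match.arg(parsimony_mode, c("penalize", "literal"))
  movement_variant <- match.arg(movement_variant, c("standard", "literal"))
  structure(list(n_fireflies = as.integer(n_fireflies),
                 max_iter = as.integer(max_iter), w = w, alpha = alpha,
                 beta0 = beta0, gamma = gamma, knn_k = as.integer(knn_k),
                 seed = as.integer(seed), parsimony_mode = parsimony_mode,
                 movement_variant = movement_variant),
            class = "firefly_params")
}

# Normalize a table argument to list(x = matrix, y = factor).
as_ff_table <- function(tab) {
  if (is.list(tab) && !is.null(tab$features)) tab <- list(x = tab$features, y = tab$labels)
  if (is.null(tab$x) || is.null(tab$y))
    stop("tables must be lists with elements x/features and y/labels")
  list(x = as.matrix(tab$x), y = factor(tab$y))
}

# Standardization statistics from the fit table; constant columns get SD 1.
standardize_stats <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mu = mu, sd = sd)
}

standardize_apply <- function(x, st) sweep(sweep(x, 2, st$mu), 2, st$sd, `/`)

# Fast KNN accuracy on pre-standardized matrices. Deterministic tie-breaks:
# equidistant neighbours by smallest fit-row index (stable order()), vote
# ties by smallest class label (factor level order).
knn_accuracy_core <- function(sel_idx, fx, fy, ex, ey, k) {
  a <- ex[, sel_idx, drop = FALSE]
  b <- fx[, sel_idx, drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  k <- min(k, nrow(b))
  nl <- nlevels(fy)
  fyi <- as.integer(fy)
  correct <- 0L
  eyi <- as.integer(factor(ey, levels = levels(fy)))
  for (r in seq_len(nrow(a))) {
    nn <- order(d2[r, ])[seq_len(k)]
    counts <- tabulate(fyi[nn], nbins = nl)
    if (!is.na(eyi[r]) && which.max(counts) == eyi[r]) correct <- correct + 1L
  }
  correct / nrow(a)
}

#' KNN accuracy of a feature subset
#'
#' Fraction of evaluation rows whose majority label among the `k` nearest
#' fit rows (Euclidean distance over the selected columns only) matches the
#' truth. Features are standardized by fit-table statistics. Distance ties
#' are broken by the smallest fit-row index and vote ties by the smallest
#' class label.
#'
#' @param selection 0/1 vector, one bit per feature (at least one bit set).
#' @param fit_table,eval_table Lists with `x`/`features` (matrix) and
#'   `y`/`labels`; both share the same feature layout.
#' @param k Neighbour count.
#' @return Accuracy in \[0, 1\].
#' @export
knn_accuracy <- function(selection, fit_table, eval_table, k = 5) {
  fit <- as_ff_table(fit_table); ev <- as_ff_table(eval_table)
  if (length(selection) != ncol(fit$x))
    stop("selection length must equal the feature count")
  if (sum(selection) < 1) stop("selection must have at least one bit set")
  st <- standardize_stats(fit$x)
  knn_accuracy_core(which(selection == 1), standardize_apply(fit$x, st),
                    fit$y, standardize_apply(ev$x, st), ev$y, k)
}

#' Firefly fitness of a feature subset
#'
#' `w * acc + (1 - w) * size_term` where `acc` is the subset's KNN accuracy
#' and the size term depends on the parsimony mode: `"literal"` uses the
#' selected fraction `selected / total` (rewarding large subsets, the printed
#' form), `"penalize"` (default) uses `1 - selected / total`, consistent with
#' seeking the highest accuracy with the fewest features.
#'
#' @param selection 0/1 vector.
#' @inheritParams knn_accuracy
#' @param params A [firefly_params()].
#' @return Fitness in \[0, 1\].
#' @export
firefly_fitness <- function(selection, fit_table, eval_table, params = firefly_params()) {
  acc <- knn_accuracy(selection, fit_table, eval_table, params$knn_k)
  frac <- sum(selection) / length(selection)
  size_term <- if (params$parsimony_mode == "literal") frac else 1 - frac
  params$w * acc + (1 - params$w) * size_term
}

#' Distance between two firefly bitstrings
#'
#' `r = Hamming(a, b) / (2N - |a| - |b|)` where `|.|` counts set bits and `N`
#' is the bitstring length. When both strings are all-ones the denominator is
#' zero and the distance is defined as 0 (the strings are then identical).
#'
#' @param a,b 0/1 vectors of equal length.
#' @return Non-negative distance.
#' @export
pairwise_distance <- function(a, b) {
  if (length(a) != length(b)) stop("bitstrings must have equal length")
  num <- sum((a - b)^2)
  den <- 2 * length(a) - (sum(a) + sum(b))
  if (den == 0) return(0)
  num / den
}

#' Attractiveness at a given distance
#'
#' `beta = beta0 * exp(-gamma * r)`: equals `beta0` at zero distance and is
#' strictly decreasing in `r` for positive `gamma`.
#'
#' @param r Non-negative distance.
#' @param params A [firefly_params()] supplying `beta0` and `gamma`.
#' @return Attractiveness in `(0, beta0]`.
#' @export
attractiveness <- function(r, params = firefly_params()) {
  if (any(r < 0)) stop("r must be >= 0")
  params$beta0 * exp(-params$gamma * r)
}

#' Binarize real position proposals
#'
#' Squashes each coordinate through `tanh` and selects the bit when the
#' squashed value is at least 0.5 (so the crossing sits at
#' `atanh(0.5) ~= 0.5493`; negative proposals always give 0).
#'
#' @param proposal Numeric vector of position proposals.
#' @return Integer 0/1 vector.
#' @export
binarize_positions <- function(proposal) {
  as.integer(tanh(proposal) >= 0.5)
}

#' Repair an empty selection
#'
#' An all-zero bitstring gets one uniformly random bit set (the accuracy of
#' an empty subset is undefined); any nonempty selection is returned
#' unchanged. Consumes the current RNG stream.
#'
#' @param selection 0/1 vector.
#' @return 0/1 vector with at least one bit set.
#' @export
repair_empty <- function(selection) {
  if (sum(selection) == 0)
    selection[sample.int(length(selection), 1)] <- 1L
  selection
}

#' Move a dim firefly towards a brighter one
#'
#' Attraction step for a firefly `i` with lower fitness than `j`:
#' the proposal is `beta * (xj - xi) + alpha * (R - 0.5)` under the
#' `"literal"` movement variant (as printed) and additionally adds the
#' incumbent `xi` under the default `"standard"` variant. `beta` is computed
#' once per pair from the bitstring distance; `R` is a fresh uniform draw
#' per coordinate from the current RNG stream.
#'
#' @param xi,xj Current 0/1 positions of the dim and bright firefly.
#' @param fit_i,fit_j Their fitness values (`fit_i < fit_j` required).
#' @param params A [firefly_params()].
#' @return List (`move_step`): `r`, `beta`, `proposal`, `normalized`
#'   (tanh of the proposal) and `bits` (binarized, not yet repaired).
#' @export
move_towards <- function(xi, xj, fit_i, fit_j, params = firefly_params()) {
  if (!(fit_i < fit_j))
    stop("move_towards requires fitness(i) < fitness(j); use move_random")
  r <- pairwise_distance(xi, xj)
  beta <- attractiveness(r, params)
  kick <- params$alpha * (stats::runif(length(xi)) - 0.5)
  proposal <- beta * (xj - xi) + kick
  if (params$movement_variant == "standard") proposal <- proposal + xi
  list(r = r, beta = beta, proposal = proposal,
       normalized = tanh(proposal), bits = binarize_positions(proposal))
}

#' Random move of a firefly at least as bright as its partner
#'
#' `proposal = xi + alpha * (R - 0.5)` with a fresh uniform `R` per
#' coordinate, so each coordinate stays within `xi +/- alpha / 2`.
#'
#' @param xi Current 0/1 position.
#' @param params A [firefly_params()].
#' @return List (`move_step`) as in [move_towards()] (`r`, `beta` are NA).
#' @export
move_random <- function(xi, params = firefly_params()) {
  proposal <- xi + params$alpha * (stats::runif(length(xi)) - 0.5)
  list(r = NA_real_, beta = NA_real_, proposal = proposal,
       normalized = tanh(proposal), bits = binarize_positions(proposal))
}

#' Run the binary firefly feature selection
#'
#' Initializes `n_fireflies` selections as independent fair coin flips per
#' bit (repaired if empty) with real positions equal to the bits, then runs
#' the doubly nested comparison loop with asynchronous updates: firefly `i`
#' is moved (towards each brighter `j`, or randomly otherwise), binarized,
#' repaired and re-evaluated after every comparison, so later comparisons in
#' the same sweep see the update and positions always hold 0/1 values. At
#' the end of each sweep the population is ranked by fitness (reporting
#' only). The best (selection, fitness) over all evaluations — including
#' initialization — is recorded elitistically.
#'
#' @param fit_table,eval_table Lists with `x`/`features` and `y`/`labels`;
#'   the KNN fitness is trained on `fit_table` and scored on `eval_table`.
#' @param params A [firefly_params()].
#' @return An object of class `selection_result`: `best_selection` (0/1
#'   vector named by feature), `best_fitness`, `n_selected`, `history`
#'   (best-so-far fitness after each sweep), `params`, `feature_names`.
#' @export
run_selection <- function(fit_table, eval_table, params = firefly_params()) {
  fit <- as_ff_table(fit_table); ev <- as_ff_table(eval_table)
  if (!nrow(fit$x) || !nrow(ev$x)) stop("tables must be nonempty")
  if (ncol(fit$x) != ncol(ev$x)) stop("tables must share the feature layout")
  if (nlevels(droplevels(fit$y)) < 2)
    stop("fit table must contain at least 2 classes")
  p <- ncol(fit$x)
  st <- standardize_stats(fit$x)
  fx <- standardize_apply(fit$x, st); ex <- standardize_apply(ev$x, st)
  fy <- fit$y; ey <- ev$y
  eval_fitness <- function(bits) {
    acc <- knn_accuracy_core(which(bits == 1), fx, fy, ex, ey, params$knn_k)
    frac <- sum(bits) / p
    size_term <- if (params$parsimony_mode == "literal") frac else 1 - frac
    params$w * acc + (1 - params$w) * size_term
  }
  with_seed(params$seed, {
    n <- params$n_fireflies
    sel <- matrix(0L, n, p)
    for (i in seq_len(n))
      sel[i, ] <- repair_empty(as.integer(stats::runif(p) < 0.5))
    fitv <- apply(sel, 1, eval_fitness)
    best_i <- which.max(fitv)
    best_sel <- sel[best_i, ]; best_fit <- fitv[best_i]
    history <- numeric(params$max_iter)
    if (params$max_iter > 0) for (iter in seq_len(params$max_iter)) {
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          step <- if (fitv[i] < fitv[j])
            move_towards(sel[i, ], sel[j, ], fitv[i], fitv[j], params)
          else
            move_random(sel[i, ], params)
          bits <- repair_empty(step$bits)
          sel[i, ] <- bits
          fitv[i] <- eval_fitness(bits)
          if (fitv[i] > best_fit) { best_fit <- fitv[i]; best_sel <- bits }
        }
      }
      # rank the population at sweep end: reporting only, the population
      # order used for the next sweep's comparisons is left untouched
      rank_order <- order(-fitv, seq_len(n))
      history[iter] <- best_fit
    }
    names(best_sel) <- colnames(fit$x)
    structure(list(best_selection = best_sel, best_fitness = best_fit,
                   n_selected = sum(best_sel), history = history,
                   params = params, feature_names = colnames(fit$x)),
              class = "selection_result")
  })
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d/%d features selected, best fitness %.4f (%d sweeps)\n",
              x$n_selected, length(x$best_selection), x$best_fitness,
              length(x$history)))
  invisible(x)
}

#' Serialize a selection result to JSON
#'
#' @param res A `selection_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_selection_result <- function(res, path) {
  out <- list(bitstring = paste(res$best_selection, collapse = ""),
              selected_features = res$feature_names[res$best_selection == 1],
              best_fitness = res$best_fitness,
              n_selected = res$n_selected,
              history = res$history,
              params = unclass(res$params))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
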