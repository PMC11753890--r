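#' Binary tree-growth configuration
#'
#' Parameters of the binary tree-growth (BTG) feature-selection
#' metaheuristic. The population is partitioned by fitness rank into four
#' groups per iteration: the best trees (local refinement), a competition
#' group (moves toward nearby good solutions), a removal group (worst
#' trees, re-initialized) and a reproduction group (recombined offspring
#' of the best trees). Continuous tree positions are binarized by an
#' S-shaped transfer function to obtain candidate feature masks.
#'
#' @param population Number of trees.
#' @param iterations Number of iterations.
#' @param groups Named integer vector `best`, `competition`, `removal`,
#'   `reproduction` summing to `population`.
#' @param theta Reduction rate of the best-group refinement
#'   (`x <- x / theta + r x`); in (0, 1).
#' @param lambda Mixing weight of the two nearest good solutions in the
#'   competition move; in \[0, 1\].
#' @param alpha Fitness trade-off between classification quality and
#'   subset size, in (0, 1\]: fitness = alpha (1 - metric) +
#'   (1 - alpha) |mask| / D, minimized.
#' @param transfer `"s"` (logistic, default) or `"v"` (V-shaped).
#' @param folds Inner cross-validation folds of the 1-nearest-neighbor
#'   evaluator.
#' @param seed Integer seed for all randomness (including k-NN tie
#'   breaking).
#' @return List of class `btg_config`.
#' @export
btg_config <- function(population = 30L, iterations = 100L,
                       groups = c(best = 6L, competition = 12L,
                                  removal = 6L, reproduction = 6L),
                       theta = 0.8, lambda = 0.5, alpha = 0.99,
                       transfer = c("s", "v"), folds = 5L, seed = 1L) {
  transfer <- match.arg(transfer)
  groups <- vapply(groups, as.integer, integer(1))
  stopifnot(setequal(names(groups),
                     c("best", "competition", "removal", "reproduction")),
            sum(groups) == population, all(groups >= 1L),
            theta > 0, theta < 1, lambda >= 0, lambda <= 1,
            alpha > 0, alpha <= 1)
  structure(list(population = as.integer(population),
                 iterations = as.integer(iterations),
                 groups = groups[c("best", "competition", "removal",
                                   "reproduction")],
                 theta = theta, lambda = lambda, alpha = alpha,
                 transfer = transfer, folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "btg_config")
}

# 1-nearest-neighbor stratified CV accuracy of a column subset
.btg_cv_accuracy <- function(x, y, mask, fold) {
  xs <- x[, mask, drop = FALSE]
  correct <- 0L
  for (f in sort(unique(fold))) {
    tr <- fold != f
    pred <- class::knn(xs[tr, , drop = FALSE], xs[!tr, , drop = FALSE],
                       factor(y[tr]), k = 1L)
    correct <- correct + sum(pred == factor(y[!tr], levels = levels(pred)))
  }
  correct / length(y)
}

#' Select features with the binary tree-growth algorithm
#'
#' Wrapper feature selection over the columns of a labelled feature
#' table. Candidate masks are scored by a size-penalized inner
#' cross-validation criterion (1-nearest-neighbor accuracy by default)
#' and the best mask ever seen is returned, so the reported fitness trace
#' is non-increasing. All randomness is driven by `cfg$seed`; identical
#' configurations reproduce identical masks.
#'
#' @param table A labelled [feature_table()] with at least 2 columns.
#' @param cfg A [btg_config()].
#' @return List with `mask` (logical vector over columns, never empty),
#'   `fitness` (the best mask's fitness), `metric` (its inner CV
#'   accuracy), `trace` (best-ever fitness per iteration), `config`.
#' @export
btg_select <- function(table, cfg = btg_config()) {
  stopifnot(inherits(table, "feature_table"), !is.null(table$labels))
  x <- table$matrix
  y <- table$labels
  D <- ncol(x)
  if (D < 2L) stop("need at least 2 features to select from")
  fold <- stratified_kfold(y, k = cfg$folds, seed = cfg$seed)
  fitness_of <- function(mask) {
    acc <- .btg_cv_accuracy(x, y, mask, fold)
    cfg$alpha * (1 - acc) + (1 - cfg$alpha) * sum(mask) / D
  }
  .with_seed(cfg$seed, function() {
    np <- cfg$population
    pos <- matrix(stats::runif(np * D, -2, 2), nrow = np)
    binarize <- function(p) {
      prob <- if (cfg$transfer == "s") sigmoid(p) else abs(tanh(p))
      b <- prob > stats::runif(length(p))
      if (!any(b)) b[sample.int(length(b), 1L)] <- TRUE  # repair empty mask
      b
    }
    best_mask <- NULL
    best_fit <- Inf
    trace <- numeric(cfg$iterations)
    g <- cfg$groups
    i_best <- seq_len(g["best"])
    i_comp <- g["best"] + seq_len(g["competition"])
    i_rem <- g["best"] + g["competition"] + seq_len(g["removal"])
    i_rep <- g["best"] + g["competition"] + g["removal"] +
      seq_len(g["reproduction"])
    for (it in seq_len(cfg$iterations)) {
      masks <- lapply(seq_len(np), function(i) binarize(pos[i, ]))
      fit <- vapply(masks, fitness_of, numeric(1))
      if (min(fit) < best_fit) {
        best_fit <- min(fit)
        best_mask <- masks[[which.min(fit)]]
      }
      trace[it] <- best_fit
      ord <- order(fit)
      pos <- pos[ord, , drop = FALSE]
      # best trees: local refinement around their current position
      for (i in i_best) {
        pos[i, ] <- pos[i, ] / cfg$theta + stats::runif(1) * pos[i, ]
      }
      # competition trees: move toward a lambda-mix of the two nearest
      # solutions among the best and competition groups
      pool <- pos[c(i_best, i_comp), , drop = FALSE]
      for (i in i_comp) {
        d2 <- rowSums(sweep(pool, 2L, pos[i, ], "-")^2)
        d2[i] <- Inf
        nn <- order(d2)[1:2]
        target <- cfg$lambda * pool[nn[1L], ] + (1 - cfg$lambda) * pool[nn[2L], ]
        pos[i, ] <- pos[i, ] + stats::runif(1) * (target - pos[i, ])
      }
      # removal trees: worst solutions are replaced by fresh random ones
      pos[i_rem, ] <- matrix(stats::runif(length(i_rem) * D, -2, 2),
                             nrow = length(i_rem))
      # reproduction trees: noisy copies of random best trees
      for (i in i_rep) {
        parent <- pos[sample(i_best, 1L), ]
        pos[i, ] <- parent + stats::rnorm(D, sd = 0.5)
      }
      pos <- pmin(pmax(pos, -6), 6)  # keep transfer probabilities responsive
    }
    list(mask = best_mask, fitness = best_fit,
         metric = .btg_cv_accuracy(x, y, best_mask, fold),
         trace = trace, config = cfg)
  })
}

#' Column-subset a feature table by a mask
#'
#' Keeps the selected columns in their original order and recomputes the
#' per-block widths; blocks whose every column is dropped disappear.
#'
#' @param table A [feature_table()].
#' @param mask Logical vector over columns (at least one `TRUE`).
#' @return A [feature_table()] of the selected columns.
#' @export
apply_mask <- function(table, mask) {
  stopifnot(inherits(table, "feature_table"),
            length(mask) == ncol(table$matrix))
  mask <- as.logical(mask)
  if (!any(mask)) stop("mask selects no features")
  blk <- rep(names(table$blocks), times = table$blocks)
  kept <- table(factor(blk[mask], levels = unique(blk)))
  blocks <- stats::setNames(as.integer(kept), names(kept))
  blocks <- blocks[blocks > 0L]
  feature_table(table$matrix[, mask, drop = FALSE], table$ids, blocks,
                table$labels)
}
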