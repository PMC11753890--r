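#' Weighted serial concatenation of feature views
#'
#' Scales each feature block of a multi-view table by its scalar weight
#' and keeps the blocks concatenated in their fixed order. With unit
#' weights this is plain serial integration; learned weights rebalance
#' the relative influence of the views for scale-sensitive classifiers.
#'
#' @param table A [feature_table()].
#' @param w Numeric weight vector, one weight per block in block order.
#' @return A [feature_table()] of the same shape with scaled blocks.
#' @export
weighted_concat <- function(table, w) {
  stopifnot(inherits(table, "feature_table"))
  if (length(w) != length(table$blocks)) {
    stop(sprintf("need %d weights (one per view), got %d",
                 length(table$blocks), length(w)))
  }
  x <- table$matrix * rep(as.numeric(w), times = table$blocks)[col(table$matrix)]
  feature_table(x, table$ids, table$blocks, table$labels)
}

#' Closed-form ridge classifier (dual form)
#'
#' A fast deterministic linear classifier used inside metaheuristic
#' fitness loops: ridge regression of the 0/1 labels, solved in the dual
#' so cost scales with the number of training rows rather than features.
#' Scores approximate class probabilities around 0.5 and the classifier
#' is sensitive to per-block feature scaling, which is what makes view
#' weights identifiable.
#'
#' @param x Numeric training matrix.
#' @param y 0/1 labels.
#' @param lambda Ridge penalty.
#' @return Model list for [ridge_predict()].
#' @export
ridge_train <- function(x, y, lambda = 1) {
  y <- as.numeric(y)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu, "-")
  K <- tcrossprod(xc)
  alpha <- solve(K + diag(lambda, nrow(K)), y - mean(y))
  list(beta = crossprod(xc, alpha), intercept = mean(y), center = mu)
}

#' Predict scores from a ridge classifier
#'
#' @param model Output of [ridge_train()].
#' @param x Numeric matrix of rows to score.
#' @return Numeric scores (around \[0, 1\]; threshold at 0.5).
#' @export
ridge_predict <- function(model, x) {
  drop(sweep(x, 2L, model$center, "-") %*% model$beta) + model$intercept
}

#' Cross-validated MCC fitness of a view-weight vector
#'
#' The objective maximized by the weight-learning step: the mean Matthews
#' correlation coefficient of a classifier over stratified k-fold
#' cross-validation on the weighted concatenated features. The per-view
#' features are fixed; only the block scaling changes between calls, so
#' evaluation is cheap. Deterministic given (w, seed).
#'
#' @param table A labelled [feature_table()].
#' @param w Weight vector, one per view.
#' @param k Number of folds.
#' @param seed Fold seed.
#' @param classifier `"ridge"` (default, closed form) or `"snbilstm"`.
#' @param classifier_config Optional [snbilstm_config()] when
#'   `classifier = "snbilstm"`.
#' @return Mean cross-validated MCC.
#' @export
cv_mcc_fitness <- function(table, w, k = 5L, seed = 1L,
                           classifier = c("ridge", "snbilstm"),
                           classifier_config = NULL) {
  classifier <- match.arg(classifier)
  wt <- weighted_concat(table, w)
  if (classifier == "ridge") {
    cv <- cross_validate(wt, ridge_train, ridge_predict, k = k, seed = seed)
  } else {
    cfg <- if (is.null(classifier_config)) snbilstm_config() else classifier_config
    cv <- cross_validate(
      wt,
      function(x, y) snbilstm_train_xy(x, y, cfg),
      function(m, x) snbilstm_predict(m, x)$probability,
      k = k, seed = seed, threshold = cfg$threshold)
  }
  unname(cv$mean["MCC"])
}

#' Differential-evolution configuration
#'
#' Defaults follow the published optimizer settings: population 100,
#' 50 generations, crossover rate 0.5, scaling factor 0.5, weights
#' bounded in \[-2, 2\].
#'
#' @param N Population size (>= 4; mutation needs three distinct others).
#' @param G_max Maximum number of generations.
#' @param CR Crossover rate in \[0, 1\].
#' @param F Mutation scaling factor (> 0).
#' @param lower,upper Box bounds applied to every coordinate.
#' @param dim Problem dimension (4 views by default).
#' @param seed Integer seed driving all optimizer randomness.
#' @return List of class `de_config`.
#' @export
de_config <- function(N = 100L, G_max = 50L, CR = 0.5, F = 0.5,
                      lower = -2, upper = 2, dim = 4L, seed = 1L) {
  stopifnot(N >= 4L, CR >= 0, CR <= 1, F > 0, lower < upper, dim >= 1L)
  structure(list(N = as.integer(N), G_max = as.integer(G_max), CR = CR, F = F,
                 lower = lower, upper = upper, dim = as.integer(dim),
                 seed = as.integer(seed), bound_handling = "clip"),
            class = "de_config")
}

#' Differential evolution over a box (maximization)
#'
#' Classic DE/rand/1/bin: the population starts uniform in the box; each
#' target j is challenged by a trial vector built from the mutant
#' \eqn{v = w_{r1} + F (w_{r2} - w_{r3})} (three distinct others),
#' binomial crossover with a guaranteed coordinate \eqn{k_{rand}}, and
#' strictly-greater greedy selection. Out-of-bounds mutant coordinates
#' are clipped to the box. All randomness comes from the seeded
#' generator, so runs are bit-reproducible.
#'
#' @param fitness `function(w) -> finite numeric` to maximize.
#' @param cfg A [de_config()].
#' @return List with `w_best`, `best_fitness`, per-generation `trace`
#'   (best fitness, non-decreasing), `evaluations`, `seed`, `config`.
#' @export
de_optimize <- function(fitness, cfg = de_config()) {
  stopifnot(inherits(cfg, "de_config"))
  rng <- .seeded_rng(cfg$seed)
  N <- cfg$N; d <- cfg$dim
  P <- matrix(rng$unif(N * d, cfg$lower, cfg$upper), nrow = N)
  eval1 <- function(w) {
    f <- fitness(w)
    if (!is.finite(f)) {
      stop(sprintf("non-finite fitness at w = (%s)",
                   paste(format(w), collapse = ", ")))
    }
    f
  }
  f <- apply(P, 1L, eval1)
  evals <- N
  trace <- numeric(cfg$G_max)
  for (g in seq_len(cfg$G_max)) {
    for (j in seq_len(N)) {
      r <- rng$pick(setdiff(seq_len(N), j), 3L)
      v <- P[r[1L], ] + cfg$F * (P[r[2L], ] - P[r[3L], ])
      v <- pmin(pmax(v, cfg$lower), cfg$upper)
      k_rand <- rng$int(1L, d)
      cross <- rng$unif(d) < cfg$CR | seq_len(d) == k_rand
      u <- ifelse(cross, v, P[j, ])
      fu <- eval1(u)
      evals <- evals + 1L
      if (fu > f[j]) {   # strict: ties keep the target
        P[j, ] <- u
        f[j] <- fu
      }
    }
    trace[g] <- max(f)
  }
  best <- which.max(f)
  list(w_best = P[best, ], best_fitness = f[best], trace = trace,
       evaluations = evals, seed = cfg$seed, config = cfg)
}

#' Learn view-integration weights by differential evolution
#'
#' Convenience wrapper: maximizes [cv_mcc_fitness()] over the weight box
#' and returns the optimizer result together with the weighted table.
#'
#' @param table A labelled multi-view [feature_table()].
#' @param cfg A [de_config()] (its `dim` is forced to the number of views).
#' @param k,classifier,classifier_config Passed to [cv_mcc_fitness()].
#' @return List with the [de_optimize()] result (`de`), the learned
#'   weights (`w`) and the weighted table (`table`).
#' @export
de_integrate <- function(table, cfg = de_config(), k = 5L,
                         classifier = "ridge", classifier_config = NULL) {
  cfg$dim <- length(table$blocks)
  res <- de_optimize(function(w) {
    cv_mcc_fitness(table, w, k = k, seed = cfg$seed,
                   classifier = classifier,
                   classifier_config = classifier_config)
  }, cfg)
  list(de = res, w = res$w_best, table = weighted_concat(table, res$w_best))
}
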