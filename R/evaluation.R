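#' Classification metrics from a confusion table
#'
#' Computes accuracy, sensitivity, specificity and the Matthews
#' correlation coefficient from TP/TN/FP/FN counts:
#' \deqn{MCC = (TP\,TN - FP\,FN) / \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' When any factor of the MCC denominator is zero the coefficient is
#' reported as 0 (with a flag), the usual convention for degenerate
#' tables.
#'
#' @param TP,TN,FP,FN Non-negative integer counts.
#' @return Named list `Acc`, `Sen`, `Spe`, `MCC`, plus
#'   `mcc_degenerate` flag.
#' @export
confusion_metrics <- function(TP, TN, FP, FN) {
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0)
  n <- TP + TN + FP + FN
  denom2 <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  degenerate <- denom2 == 0
  mcc <- if (degenerate) 0 else (TP * TN - FP * FN) / sqrt(denom2)
  list(Acc = (TP + TN) / n,
       Sen = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
       Spe = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
       MCC = mcc, mcc_degenerate = degenerate)
}

#' Count a confusion table from labels and predictions
#'
#' @param labels True 0/1 labels.
#' @param predicted Predicted 0/1 labels.
#' @return Named list TP, TN, FP, FN.
#' @export
confusion_counts <- function(labels, predicted) {
  stopifnot(length(labels) == length(predicted))
  list(TP = sum(labels == 1 & predicted == 1),
       TN = sum(labels == 0 & predicted == 0),
       FP = sum(labels == 0 & predicted == 1),
       FN = sum(labels == 1 & predicted == 0))
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation with midrank tie handling: the
#' probability that a random positive scores above a random negative,
#' counting ties as one half.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels 0/1 labels.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L) stop("both classes required for AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average-precision integration over score thresholds:
#' \eqn{AP = \sum_i (R_i - R_{i-1}) P_i} with one step per distinct
#' score, which avoids the optimism of trapezoidal PR interpolation.
#' Tied scores fall into one threshold step. With all scores equal the
#' result is the positive-class prevalence.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels 0/1 labels.
#' @return AUPR in \[0, 1\].
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  npos <- sum(labels == 1L)
  if (npos == 0L) stop("at least one positive required for AUPR")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y); fp <- cumsum(1L - y)
  # evaluate at the last index of each distinct-score block
  last <- which(s != c(s[-1L], NA) | seq_along(s) == length(s))
  prec <- tp[last] / (tp[last] + fp[last])
  rec <- tp[last] / npos
  sum(diff(c(0, rec)) * prec)
}

#' Stratified k-fold assignment
#'
#' Splits rows into k disjoint, covering folds such that each class is
#' spread as evenly as possible (per-class fold counts differ by at most
#' one). The within-class ordering is a seeded shuffle, so the same seed
#' reproduces the same folds.
#'
#' @param labels 0/1 labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold assignment in 1..k, one per row.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  labels <- as.integer(labels)
  counts <- table(factor(labels, levels = c(0L, 1L)))
  if (any(counts < k)) {
    stop(sprintf("each class needs >= k members (have %s, k = %d)",
                 paste(counts, collapse = "/"), k))
  }
  rng <- .seeded_rng(seed)
  folds <- integer(length(labels))
  for (cl in c(0L, 1L)) {
    idx <- which(labels == cl)
    idx <- rng$shuffle(idx)
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# local RNG helper: isolates package randomness from the global stream
.seeded_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    s
  })
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    f()
  }
  list(
    unif = function(n, min = 0, max = 1) with_state(function() stats::runif(n, min, max)),
    norm = function(n, mean = 0, sd = 1) with_state(function() stats::rnorm(n, mean, sd)),
    int = function(n, max) with_state(function() sample.int(max, n, replace = TRUE)),
    pick = function(x, size) with_state(function() sample(x, size)),
    shuffle = function(x) with_state(function() if (length(x) == 1L) x else sample(x))
  )
}

#' Stratified cross-validated evaluation of a classifier
#'
#' Trains and tests a classifier over seeded stratified k folds and
#' reports the standard metric panel per fold and on average.
#'
#' @param table A labelled [feature_table()].
#' @param train_fun `function(x, y)` returning a fitted model.
#' @param predict_fun `function(model, x)` returning scores in \[0, 1\].
#' @param k Number of folds.
#' @param seed Fold seed.
#' @param threshold Decision threshold; positive iff score > threshold.
#' @return List with per-fold metric data frame (`folds`), the metric
#'   means (`mean`), the fold assignment and the seed.
#' @export
cross_validate <- function(table, train_fun, predict_fun, k = 5L, seed = 1L,
                           threshold = 0.5) {
  stopifnot(inherits(table, "feature_table"), !is.null(table$labels))
  fold <- stratified_kfold(table$labels, k = k, seed = seed)
  rows <- lapply(seq_len(k), function(f) {
    tr <- fold != f
    model <- train_fun(table$matrix[tr, , drop = FALSE], table$labels[tr])
    sc <- predict_fun(model, table$matrix[!tr, , drop = FALSE])
    y <- table$labels[!tr]
    cc <- confusion_counts(y, as.integer(sc > threshold))
    m <- confusion_metrics(cc$TP, cc$TN, cc$FP, cc$FN)
    data.frame(fold = f, Acc = m$Acc, Sen = m$Sen, Spe = m$Spe, MCC = m$MCC,
               AUC = roc_auc(sc, y), AUPR = pr_auc(sc, y))
  })
  folds <- do.call(rbind, rows)
  list(folds = folds,
       mean = colMeans(folds[, -1L, drop = FALSE]),
       assignment = fold, seed = seed, threshold = threshold,
       aupr_method = "average_precision_step")
}
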