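#' Reshape a feature vector into a timestep matrix
#'
#' Recurrent classifiers consume the fixed-length feature vector as a
#' short sequence: the vector is chunked into `ceil(D / width)` timesteps
#' of `width` values each, zero-padding the tail chunk.
#'
#' @param v Numeric vector of length D.
#' @param width Timestep width.
#' @return T x width numeric matrix with attribute `n_pad` (number of
#'   padding zeros).
#' @export
reshape_to_sequence <- function(v, width) {
  width <- as.integer(width)
  stopifnot(width >= 1L)
  D <- length(v)
  T <- as.integer(ceiling(D / width))
  out <- matrix(c(v, numeric(T * width - D)), T, width, byrow = TRUE)
  attr(out, "n_pad") <- T * width - D
  out
}

# batch version: n x D matrix -> list of T matrices (n x width)
.make_xlist <- function(x, width) {
  D <- ncol(x)
  T <- as.integer(ceiling(D / width))
  pad <- T * width - D
  if (pad > 0L) x <- cbind(x, matrix(0, nrow(x), pad))
  lapply(seq_len(T), function(t) {
    x[, (t - 1L) * width + seq_len(width), drop = FALSE]
  })
}

#' SnBiLSTM classifier configuration
#'
#' Architecture and training settings of the self-normalizing
#' bidirectional LSTM. The feature vector is chunked into timesteps
#' (`width`), encoded by an LSTM in each direction (`hidden` units per
#' direction), the two final states are concatenated and passed through a
#' dense head with SELU activation, its paired alpha-dropout and LeCun
#' initialization (the self-normalizing recipe), then a sigmoid output
#' trained with binary cross-entropy and Adam.
#'
#' @param width Timestep width of the feature-vector chunking.
#' @param hidden Recurrent units per direction.
#' @param dense Integer vector of dense-layer widths.
#' @param dropout Alpha-dropout rate on dense layers.
#' @param variant `"snbilstm"` (default), `"bilstm"` (ReLU head, plain
#'   dropout) or `"lstm"` (single direction, ReLU head).
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without training-loss
#'   improvement).
#' @param class_weights If `TRUE`, weight the loss inversely to class
#'   frequencies.
#' @param threshold Decision threshold Th; positive iff probability > Th.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return List of class `snbilstm_config`.
#' @export
snbilstm_config <- function(width = 64L, hidden = 128L, dense = 64L,
                            dropout = 0.05,
                            variant = c("snbilstm", "bilstm", "lstm"),
                            lr = 1e-3, batch_size = 32L, epochs = 100L,
                            patience = 10L, class_weights = FALSE,
                            threshold = 0.5, seed = 7L) {
  variant <- match.arg(variant)
  stopifnot(width >= 1L, hidden >= 1L, all(dense >= 1L),
            dropout >= 0, dropout < 1, threshold > 0, threshold < 1)
  structure(list(width = as.integer(width), hidden = as.integer(hidden),
                 dense = as.integer(dense), dropout = dropout,
                 variant = variant, lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 class_weights = class_weights, threshold = threshold,
                 seed = as.integer(seed)),
            class = "snbilstm_config")
}

# ---- parameter initialization -------------------------------------------

.selu_lambda <- 1.0507009873554805
.selu_alpha <- 1.6732632423543772

.init_lstm <- function(input, H) {
  glorot <- function(nin, nout) {
    matrix(stats::runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)), nin, nout)
  }
  b <- numeric(4L * H)
  b[H + seq_len(H)] <- 1  # forget-gate bias
  list(W = glorot(input, 4L * H), U = glorot(H, 4L * H), b = b)
}

.init_dense <- function(nin, nout, selu) {
  sd <- if (selu) 1 / sqrt(nin) else sqrt(2 / nin)  # LeCun / He
  list(W = matrix(stats::rnorm(nin * nout, sd = sd), nin, nout),
       b = numeric(nout))
}

# ---- LSTM forward / backward --------------------------------------------

.lstm_forward <- function(xlist, p, H, keep_cache = FALSE) {
  n <- nrow(xlist[[1L]])
  T <- length(xlist)
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  cache <- if (keep_cache) vector("list", T)
  for (t in seq_len(T)) {
    a <- xlist[[t]] %*% p$W + h %*% p$U +
      matrix(p$b, n, 4L * H, byrow = TRUE)
    i <- sigmoid(a[, seq_len(H), drop = FALSE])
    f <- sigmoid(a[, H + seq_len(H), drop = FALSE])
    g <- tanh(a[, 2L * H + seq_len(H), drop = FALSE])
    o <- sigmoid(a[, 3L * H + seq_len(H), drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    if (keep_cache) {
      cache[[t]] <- list(x = xlist[[t]], h_prev = h, c_prev = cc,
                         i = i, f = f, g = g, o = o, tc = tc)
    }
    h <- o * tc
    cc <- c_new
  }
  list(h = h, cache = cache)
}

.lstm_backward <- function(dh_final, cache, p, H) {
  T <- length(cache)
  dW <- p$W * 0; dU <- p$U * 0; db <- p$b * 0
  dh <- dh_final
  dc <- dh_final * 0
  for (t in rev(seq_len(T))) {
    s <- cache[[t]]
    do <- dh * s$tc
    dc <- dc + dh * s$o * (1 - s$tc^2)
    di <- dc * s$g
    df <- dc * s$c_prev
    dg <- dc * s$i
    da <- cbind(di * s$i * (1 - s$i), df * s$f * (1 - s$f),
                dg * (1 - s$g^2), do * s$o * (1 - s$o))
    dW <- dW + crossprod(s$x, da)
    dU <- dU + crossprod(s$h_prev, da)
    db <- db + colSums(da)
    dh <- da %*% t(p$U)
    dc <- dc * s$f
  }
  list(W = dW, U = dU, b = db)
}

# ---- dense head with SELU / alpha-dropout -------------------------------

.head_forward <- function(z, params, cfg, train = FALSE) {
  selu <- cfg$variant == "snbilstm"
  caches <- vector("list", length(params$dense))
  for (l in seq_along(params$dense)) {
    p <- params$dense[[l]]
    pre <- z %*% p$W + matrix(p$b, nrow(z), length(p$b), byrow = TRUE)
    if (selu) {
      act <- .selu_lambda * ifelse(pre > 0, pre, .selu_alpha * (exp(pre) - 1))
      dact <- .selu_lambda * ifelse(pre > 0, 1, .selu_alpha * exp(pre))
    } else {
      act <- pmax(pre, 0)
      dact <- (pre > 0) + 0
    }
    drop_scale <- NULL
    if (train && cfg$dropout > 0) {
      q <- 1 - cfg$dropout
      m <- matrix(stats::runif(length(act)) < q, nrow(act), ncol(act))
      if (selu) {
        # alpha dropout: dropped units go to the SELU negative saturation
        # value, then an affine correction restores mean and variance
        ap <- -.selu_lambda * .selu_alpha
        a_corr <- (q * (1 + cfg$dropout * ap^2))^(-0.5)
        b_corr <- -a_corr * cfg$dropout * ap
        out <- a_corr * (act * m + ap * (1 - m)) + b_corr
        drop_scale <- a_corr * m
      } else {
        out <- act * m / q
        drop_scale <- m / q
      }
    } else {
      out <- act
    }
    caches[[l]] <- list(input = z, dact = dact, drop_scale = drop_scale)
    z <- out
  }
  logits <- drop(z %*% params$out$W) + params$out$b
  list(p = sigmoid(logits), z_last = z, caches = caches)
}

.head_backward <- function(dlogit, fw, params) {
  nlayers <- length(params$dense)
  grads <- list(dense = vector("list", nlayers))
  grads$out <- list(W = crossprod(fw$z_last, dlogit),
                    b = sum(dlogit))
  dz <- dlogit %*% t(params$out$W)
  for (l in rev(seq_len(nlayers))) {
    cc <- fw$caches[[l]]
    if (!is.null(cc$drop_scale)) dz <- dz * cc$drop_scale
    dpre <- dz * cc$dact
    grads$dense[[l]] <- list(W = crossprod(cc$input, dpre),
                             b = colSums(dpre))
    dz <- dpre %*% t(params$dense[[l]]$W)
  }
  grads$dz_input <- dz
  grads
}

# ---- full loss + gradients (one minibatch) ------------------------------

.snbilstm_loss_grad <- function(params, xlist, y, cfg, sample_w = NULL,
                                train = FALSE) {
  H <- cfg$hidden
  bidir <- cfg$variant != "lstm"
  fwd <- .lstm_forward(xlist, params$fwd, H, keep_cache = TRUE)
  z <- fwd$h
  if (bidir) {
    bwd <- .lstm_forward(rev(xlist), params$bwd, H, keep_cache = TRUE)
    z <- cbind(fwd$h, bwd$h)
  }
  head <- .head_forward(z, params, cfg, train = train)
  p <- head$p
  n <- length(y)
  w <- if (is.null(sample_w)) rep(1, n) else sample_w
  eps <- 1e-12
  loss <- -mean(w * (y * log(pmax(p, eps)) +
                       (1 - y) * log(pmax(1 - p, eps))))
  dlogit <- matrix(w * (p - y) / n, n, 1L)
  hgrads <- .head_backward(dlogit, head, params)
  dz <- hgrads$dz_input
  grads <- list(dense = .name_dense(hgrads$dense), out = hgrads$out)
  if (bidir) {
    grads$fwd <- .lstm_backward(dz[, seq_len(H), drop = FALSE],
                                fwd$cache, params$fwd, H)
    grads$bwd <- .lstm_backward(dz[, H + seq_len(H), drop = FALSE],
                                bwd$cache, params$bwd, H)
  } else {
    grads$fwd <- .lstm_backward(dz, fwd$cache, params$fwd, H)
  }
  list(loss = loss, grads = grads, p = p)
}

# ---- Adam over a nested parameter list ----------------------------------

.flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    v <- p[[nm]]
    key <- paste0(prefix, nm)
    if (is.list(v) && is.null(dim(v))) {
      out <- c(out, .flatten_params(v, paste0(key, ".")))
    } else {
      out[[key]] <- v
    }
  }
  out
}

.adam_step <- function(params, grads, state, lr, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  fp <- .flatten_params(params)
  fg <- .flatten_params(grads)
  for (k in names(fp)) {
    g <- fg[[k]]
    if (is.null(state$m[[k]])) {
      state$m[[k]] <- g * 0
      state$v[[k]] <- g * 0
    }
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / (1 - beta1^t)
    vhat <- state$v[[k]] / (1 - beta2^t)
    fp[[k]] <- fp[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  # unflatten back into the nested structure
  assign_back <- function(p, prefix = "") {
    for (nm in names(p)) {
      key <- paste0(prefix, nm)
      v <- p[[nm]]
      if (is.list(v) && is.null(dim(v))) {
        p[[nm]] <- assign_back(v, paste0(key, "."))
      } else {
        p[[nm]] <- fp[[key]]
      }
    }
    p
  }
  list(params = assign_back(params), state = state)
}

# dense-list wrapper so .flatten_params recurses it by numeric name
.name_dense <- function(dense) stats::setNames(dense, paste0("L", seq_along(dense)))

#' Train the SnBiLSTM classifier on a feature matrix
#'
#' Lower-level entry point taking a plain matrix and 0/1 labels (see
#' [snbilstm_train()] for the feature-table interface). Training is fully
#' seeded: initialization, minibatch shuffling and dropout all derive
#' from `cfg$seed`, so identical inputs reproduce identical models.
#' Early stopping keeps the best parameters seen by training loss.
#'
#' @param x Numeric n x D matrix.
#' @param y 0/1 labels, both classes present.
#' @param cfg An [snbilstm_config()].
#' @return An object of class `snbilstm_model`.
#' @export
snbilstm_train_xy <- function(x, y, cfg = snbilstm_config()) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  stopifnot(nrow(x) == length(y))
  D <- ncol(x)
  xlist <- .make_xlist(x, cfg$width)
  H <- cfg$hidden
  bidir <- cfg$variant != "lstm"
  zdim <- if (bidir) 2L * H else H
  sample_w <- NULL
  if (cfg$class_weights) {
    tab <- table(factor(y, levels = c(0L, 1L)))
    cw <- length(y) / (2 * as.numeric(tab))
    sample_w <- cw[y + 1L]
  }
  .with_seed(cfg$seed, function() {
    selu <- cfg$variant == "snbilstm"
    params <- list(fwd = .init_lstm(cfg$width, H))
    if (bidir) params$bwd <- .init_lstm(cfg$width, H)
    sizes <- c(zdim, cfg$dense)
    params$dense <- .name_dense(lapply(seq_along(cfg$dense), function(l) {
      .init_dense(sizes[l], sizes[l + 1L], selu)
    }))
    params$out <- .init_dense(utils::tail(sizes, 1L), 1L, selu)
    state <- new.env(parent = emptyenv())
    state$m <- list(); state$v <- list()
    n <- length(y)
    step <- 0L
    history <- numeric(0)
    best_loss <- Inf
    best_params <- params
    stall <- 0L
    for (epoch in seq_len(cfg$epochs)) {
      idx <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        b <- idx[s:min(s + cfg$batch_size - 1L, n)]
        xb <- lapply(xlist, function(m) m[b, , drop = FALSE])
        lg <- .snbilstm_loss_grad(params, xb, y[b], cfg,
                                  sample_w = sample_w[b], train = TRUE)
        step <- step + 1L
        upd <- .adam_step(params, lg$grads, state, cfg$lr, step)
        params <- upd$params
        epoch_loss <- epoch_loss + lg$loss * length(b)
      }
      epoch_loss <- epoch_loss / n
      history <- c(history, epoch_loss)
      if (epoch_loss < best_loss - 1e-5) {
        best_loss <- epoch_loss
        best_params <- params
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    }
    structure(list(params = best_params, config = cfg, D = D,
                   history = history, best_loss = best_loss),
              class = "snbilstm_model")
  })
}

#' Train the SnBiLSTM classifier on a feature table
#'
#' @param table A labelled [feature_table()].
#' @param cfg An [snbilstm_config()].
#' @return An `snbilstm_model`.
#' @export
snbilstm_train <- function(table, cfg = snbilstm_config()) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$labels)) stop("training requires labels")
  snbilstm_train_xy(table$matrix, table$labels, cfg)
}

#' Predict class probabilities and labels
#'
#' Deterministic forward pass (no dropout). The decision rule is exactly
#' `probability > Th`: a probability equal to the threshold is negative.
#'
#' @param model An `snbilstm_model`.
#' @param x Numeric matrix or [feature_table()] with the training width.
#' @param threshold Optional override of the configured threshold.
#' @return List with `probability` (in \[0, 1\]) and `label` (0/1).
#' @export
snbilstm_predict <- function(model, x, threshold = NULL) {
  stopifnot(inherits(model, "snbilstm_model"))
  if (inherits(x, "feature_table")) x <- x$matrix
  if (ncol(x) != model$D) {
    stop(sprintf("model expects %d features, got %d", model$D, ncol(x)))
  }
  th <- if (is.null(threshold)) model$config$threshold else threshold
  cfg <- model$config
  xlist <- .make_xlist(x, cfg$width)
  H <- cfg$hidden
  fwd <- .lstm_forward(xlist, model$params$fwd, H)
  z <- fwd$h
  if (cfg$variant != "lstm") {
    z <- cbind(z, .lstm_forward(rev(xlist), model$params$bwd, H)$h)
  }
  p <- .head_forward(z, model$params, cfg, train = FALSE)$p
  list(probability = as.numeric(p), label = as.integer(p > th))
}
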