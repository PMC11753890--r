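test_that("feature vectors chunk into zero-padded timestep matrices", {
  m <- reshape_to_sequence(1:6, 3L)
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(attr(m, "n_pad"), 0L)
  expect_equal(m[1, ], c(1, 2, 3))

  m2 <- reshape_to_sequence(1:7, 3L)
  expect_equal(dim(m2), c(3L, 3L))
  expect_equal(attr(m2, "n_pad"), 2L)
  expect_equal(m2[3, ], c(7, 0, 0))

  m3 <- reshape_to_sequence(rep(0, 969), 64L)
  expect_equal(dim(m3), c(16L, 64L))
  expect_equal(attr(m3, "n_pad"), 16L * 64L - 969L)
})

test_that("analytic gradients match finite differences", {
  set.seed(13)
  n <- 6L; D <- 10L
  x <- matrix(rnorm(n * D), n, D)
  y <- rep(c(0L, 1L), 3L)
  for (variant in c("snbilstm", "lstm")) {
    cfg <- snbilstm_config(width = 4L, hidden = 3L, dense = 3L,
                           variant = variant, epochs = 1L, batch_size = 6L,
                           dropout = 0, seed = 2L)
    model <- snbilstm_train_xy(x, y, cfg)
    params <- model$params
    xlist <- targetclp:::.make_xlist(x, cfg$width)
    lg <- targetclp:::.snbilstm_loss_grad(params, xlist, y, cfg)
    eps <- 1e-6
    flat <- targetclp:::.flatten_params(params)
    gflat <- targetclp:::.flatten_params(lg$grads)
    set.seed(7)
    for (k in names(flat)) {
      for (probe in seq_len(min(3L, length(flat[[k]])))) {
        i <- sample(length(flat[[k]]), 1L)
        pp <- params
        bump <- function(delta) {
          fp <- flat; fp[[k]][i] <- fp[[k]][i] + delta
          # rebuild nested params from the flat copy
          rebuild <- function(p, prefix = "") {
            for (nm in names(p)) {
              key <- paste0(prefix, nm)
              if (is.list(p[[nm]]) && is.null(dim(p[[nm]]))) {
                p[[nm]] <- rebuild(p[[nm]], paste0(key, "."))
              } else {
                p[[nm]] <- fp[[key]]
              }
            }
            p
          }
          rebuild(pp)
        }
        up <- targetclp:::.snbilstm_loss_grad(bump(eps), xlist, y, cfg)$loss
        dn <- targetclp:::.snbilstm_loss_grad(bump(-eps), xlist, y, cfg)$loss
        expect_equal(gflat[[k]][i], (up - dn) / (2 * eps), tolerance = 1e-4)
      }
    }
  }
})

test_that("training is seeded-deterministic and rejects single-class labels", {
  ft <- gen_multiview_dataset(n = 30L, blocks = c(A = 12L),
                              informative = list(A = 1:3), shift = 3,
                              seed = 4)
  cfg <- snbilstm_config(width = 6L, hidden = 8L, dense = 6L, epochs = 5L,
                         seed = 11L)
  m1 <- snbilstm_train(ft, cfg)
  m2 <- snbilstm_train(ft, cfg)
  p1 <- snbilstm_predict(m1, ft)
  p2 <- snbilstm_predict(m2, ft)
  expect_identical(p1, p2)
  expect_true(all(p1$probability >= 0 & p1$probability <= 1))

  onecls <- ft
  onecls$labels <- rep(1L, 30L)
  expect_error(snbilstm_train(onecls, cfg), "single class")
})

test_that("the decision rule is strictly greater-than the threshold", {
  ft <- gen_multiview_dataset(n = 20L, blocks = c(A = 6L),
                              informative = list(A = 1:2), shift = 3,
                              seed = 6)
  model <- snbilstm_train(ft, snbilstm_config(width = 3L, hidden = 4L,
                                              dense = 3L, epochs = 3L))
  pred <- snbilstm_predict(model, ft)
  # a probability exactly equal to the threshold is classified negative
  th <- pred$probability[1]
  at_th <- snbilstm_predict(model, ft, threshold = th)
  expect_equal(at_th$label[1], 0L)
  expect_identical(at_th$label, as.integer(pred$probability > th))

  # raising the threshold never increases the positive count
  counts <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(t) {
    sum(snbilstm_predict(model, ft, threshold = t)$label)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("baseline variants share the train/predict contract", {
  ft <- gen_multiview_dataset(n = 24L, blocks = c(A = 8L),
                              informative = list(A = 1:3), shift = 4,
                              seed = 9)
  for (variant in c("snbilstm", "bilstm", "lstm")) {
    cfg <- snbilstm_config(width = 4L, hidden = 5L, dense = 4L,
                           variant = variant, epochs = 8L, seed = 1L)
    model <- snbilstm_train(ft, cfg)
    pred <- snbilstm_predict(model, ft)
    expect_length(pred$probability, 24L)
    expect_true(all(pred$label %in% c(0L, 1L)))
  }
})
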