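test_that("group encoding matches table lookup and excludes X", {
  g <- ctd_groupings()
  expect_length(g, 7L)
  expect_named(g, c("hydrophobicity", "normwaalsvolume", "polarity",
                    "polarizability", "charge", "secondarystruct",
                    "solventaccess"))

  charge <- g$charge
  enc <- encode_groups(protein_record("p", "AR"), charge)
  expect_equal(enc, c(2L, 1L))  # A neutral, R positive

  expect_equal(encode_groups(protein_record("p", "AAAA"), charge),
               rep(2L, 4))

  # X positions are dropped: effective length shrinks
  expect_equal(encode_groups(protein_record("p", "AXR"), charge), c(2L, 1L))
  expect_error(encode_groups(protein_record("p", "XXX"), charge),
               "no resolvable")

  rec <- random_record(25, seed = 3)
  chars <- strsplit(rec$sequence, "")[[1]]
  enc <- encode_groups(rec, g$polarity)
  for (i in seq_along(chars)) {
    expected <- which(vapply(1:3, function(k) {
      chars[i] %in% strsplit(g$polarity[k], "")[[1]]
    }, logical(1)))
    expect_equal(enc[i], expected)
  }
})

test_that("composition percentages are counts over L'", {
  expect_equal(ctd_composition(c(1L, 1L, 1L)), c(100, 0, 0))
  expect_equal(ctd_composition(c(1L, 2L, 1L, 2L)), c(50, 50, 0))
  set.seed(9)
  for (i in 1:5) {
    gs <- sample(1:3, 40, replace = TRUE)
    expect_equal(sum(ctd_composition(gs)), 100, tolerance = 1e-9)
  }
})

test_that("transition percentages count unordered boundary pairs", {
  expect_equal(ctd_transition(c(1L, 2L, 1L, 2L)), c(100, 0, 0))
  expect_equal(ctd_transition(rep(1L, 4)), c(0, 0, 0))
  expect_warning(t1 <- ctd_transition(1L), "too short")
  expect_equal(t1, c(0, 0, 0))
  set.seed(4)
  for (i in 1:5) {
    gs <- sample(1:3, 30, replace = TRUE)
    tr <- ctd_transition(gs)
    # boundary-count oracle
    manual <- c(0, 0, 0)
    for (j in 1:29) {
      p <- sort(c(gs[j], gs[j + 1]))
      if (all(p == c(1, 2))) manual[1] <- manual[1] + 1
      if (all(p == c(1, 3))) manual[2] <- manual[2] + 1
      if (all(p == c(2, 3))) manual[3] <- manual[3] + 1
    }
    expect_equal(tr, manual / 29 * 100)
    expect_lte(sum(tr), 100 + 1e-9)
  }
})

test_that("distribution quantile slots follow the ceil rule", {
  d <- ctd_distribution(rep(1L, 4))
  expect_equal(d[1:5], c(25, 25, 50, 75, 100))
  expect_equal(d[6:15], rep(0, 10))  # absent groups

  set.seed(6)
  for (i in 1:5) {
    gs <- sample(1:3, 35, replace = TRUE)
    d <- ctd_distribution(gs)
    expect_true(all(d >= 0 & d <= 100))
    for (g in 1:3) {
      slot <- d[(g - 1) * 5 + 1:5]
      if (any(gs == g)) expect_true(all(diff(slot) >= 0))
    }
  }
})

test_that("qlc_vector is 147-long and matches the per-index oracle", {
  rec <- random_record(30, seed = 21)
  v <- qlc_vector(rec)
  expect_length(v, 147L)

  groupings <- ctd_groupings()
  chars <- strsplit(rec$sequence, "")[[1]]
  expected <- unlist(lapply(groupings, function(g) oracle_ctd(chars, g)))
  expect_equal(as.numeric(v), as.numeric(expected))

  homo <- qlc_vector(protein_record("h", strrep("L", 12)))
  t_idx <- as.vector(outer(4:6, 21 * (0:6), "+"))
  expect_equal(as.numeric(homo[t_idx]), rep(0, 21))
})

test_that("composition survives sequence reversal but distribution does not", {
  rec <- random_record(40, seed = 31)
  revseq <- paste(rev(strsplit(rec$sequence, "")[[1]]), collapse = "")
  v1 <- qlc_vector(rec)
  v2 <- qlc_vector(protein_record("rev", revseq))
  c_idx <- as.vector(outer(1:3, 21 * (0:6), "+"))
  d_idx <- as.vector(outer(7:21, 21 * (0:6), "+"))
  expect_equal(as.numeric(v1[c_idx]), as.numeric(v2[c_idx]))
  expect_false(isTRUE(all.equal(as.numeric(v1[d_idx]),
                                as.numeric(v2[d_idx]))))
})

test_that("z-score normalization fits on training rows and recenters them", {
  x <- matrix(c(0, 10, 5, 5), 2, 2)  # second column constant
  ft <- feature_table(x, c("a", "b"), c(B = 2L))
  st <- fit_normalization(ft)
  out <- apply_normalization(ft, st)
  expect_equal(out$matrix[, 1], c(-0.7071068, 0.7071068),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(out$matrix[, 2], c(0, 0), ignore_attr = TRUE)
  expect_true(st$constant[2])

  set.seed(7)
  big <- feature_table(matrix(rnorm(80), 10, 8), paste0("r", 1:10),
                       c(B = 8L))
  st2 <- fit_normalization(big)
  norm <- apply_normalization(big, st2)
  expect_equal(colMeans(norm$matrix), rep(0, 8), tolerance = 1e-9,
               ignore_attr = TRUE)

  # min-max option maps onto [0, 1]
  mm <- apply_normalization(big, fit_normalization(big, method = "minmax"))
  expect_true(all(mm$matrix >= -1e-12 & mm$matrix <= 1 + 1e-12))

  expect_error(apply_normalization(big, list()), "fitted")
})
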