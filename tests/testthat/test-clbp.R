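test_that("scale_to_image maps endpoints, degenerates safely, ignores affine shifts", {
  m <- profile_matrix(matrix(c(-7, 9, rep(0, 58)), 3, 20))
  img <- scale_to_image(m)
  expect_equal(img[1, 1], 0L)
  expect_equal(img[2, 1], 255L)
  expect_true(all(img >= 0L & img <= 255L))

  const <- scale_to_image(profile_matrix(matrix(3.7, 4, 20)))
  expect_true(all(const == 0L))

  set.seed(8)
  x <- matrix(rnorm(200), 10, 20)
  expect_identical(unclass(scale_to_image(x)),
                   unclass(scale_to_image(2.5 * x + 11)))
})

test_that("code maps on a constant image take every >= branch", {
  img <- structure(matrix(100L, 5, 20), class = "matrix_image")
  maps <- clbp_code_maps(img)
  expect_true(all(maps$c_map == 1L))   # center == global mean
  expect_true(all(maps$s_map == 255L)) # all differences 0 >= 0
  expect_true(all(maps$m_map == 255L)) # |0| >= T_m = 0
  expect_equal(maps$n_centers, 3L * 18L)
  expect_equal(dim(maps$s_map), c(3L, 18L))
})

test_that("interior-center count and short-sequence error", {
  for (L in c(3L, 7L, 31L)) {
    maps <- clbp_code_maps(scale_to_image(random_profile(L, seed = L)))
    expect_equal(maps$n_centers, (L - 2L) * 18L)
  }
  expect_error(clbp_code_maps(scale_to_image(random_profile(2, seed = 1))),
               "too short")
})

test_that("code maps match a per-pixel brute-force computation", {
  m <- random_profile(6, seed = 11)
  img <- scale_to_image(m)
  maps <- clbp_code_maps(img)
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
               c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  Tg <- mean(unclass(img))
  diffs <- c()
  for (i in 2:5) for (j in 2:19) for (n in 1:8) {
    diffs <- c(diffs, img[i + offs[[n]][1], j + offs[[n]][2]] - img[i, j])
  }
  Tm <- mean(abs(diffs))
  expect_equal(maps$T_m, Tm)
  for (i in 2:5) for (j in 2:19) {
    s <- 0L; mc <- 0L
    for (n in 1:8) {
      d <- img[i + offs[[n]][1], j + offs[[n]][2]] - img[i, j]
      if (d >= 0) s <- s + 2L^(n - 1L)
      if (abs(d) >= Tm) mc <- mc + 2L^(n - 1L)
    }
    expect_equal(maps$s_map[i - 1, j - 1], s)
    expect_equal(maps$m_map[i - 1, j - 1], mc)
    expect_equal(maps$c_map[i - 1, j - 1], as.integer(img[i, j] >= Tg))
  }
})

test_that("uniform-pattern binning has 58 uniform codes plus a catch-all", {
  bins <- u2_bin(0:255)
  expect_equal(sum(bins < 59L), 58L)
  expect_equal(u2_bin(0L), 1L)      # 00000000: zero transitions
  expect_equal(u2_bin(255L), 58L)   # 11111111: zero transitions, largest code
  expect_equal(u2_bin(85L), 59L)    # 01010101: eight transitions
})

test_that("histogram of a constant image concentrates in the all-ones bin", {
  img <- structure(matrix(7L, 6, 20), class = "matrix_image")
  d <- clbp_histogram(clbp_code_maps(img))
  expect_length(d, 236L)
  bin255 <- u2_bin(255L)
  expect_equal(d[bin255], 4 * 18)           # S part
  expect_equal(sum(d[1:59]), 4 * 18)
  expect_equal(d[59 + bin255], 4 * 18)      # M part
  # all centers have c-bit 1, so the joint mass sits in the c=1 half
  expect_equal(sum(d[119:177]), 0)
  expect_equal(d[177 + bin255], 4 * 18)
})

test_that("pssm_clbp is deterministic, 236-long for any L, affine invariant", {
  for (L in c(3L, 10L, 500L)) {
    d <- pssm_clbp(random_profile(L, seed = 100 + L))
    expect_length(d, 236L)
    expect_true(all(d >= 0))
  }
  rec <- random_record(50, seed = 1)
  pm <- gen_profile(rec, seed = 1)
  d1 <- pssm_clbp(pm)
  d2 <- pssm_clbp(pm)
  expect_identical(d1, d2)
  d3 <- pssm_clbp(profile_matrix(2 * unclass(pm)[, ] + 5))
  expect_equal(as.numeric(d3), as.numeric(d1))
  expect_equal(attr(d1, "scheme"), "S_u2(59)+M_u2(59)+M_u2xC(2x59)")
})

test_that("build_recm_t looks rows up by residue", {
  e <- gen_energy_matrix(seed = 3)
  aa_rec <- protein_record("aa", "AA")
  rt <- build_recm_t(aa_rec, e)
  expect_equal(unclass(rt)[1, ], e["A", ])
  expect_equal(unclass(rt)[2, ], e["A", ])

  arn <- build_recm_t(protein_record("arn", "ARN"), e)
  expect_equal(unclass(arn)[1, ], e["A", ])
  expect_equal(unclass(arn)[2, ], e["R", ])
  expect_equal(unclass(arn)[3, ], e["N", ])

  rec <- random_record(30, seed = 12)
  rt2 <- unclass(build_recm_t(rec, e))
  chars <- strsplit(rec$sequence, "")[[1]]
  set.seed(5)
  for (probe in 1:50) {
    j <- sample(30, 1); l <- sample(20, 1)
    expect_equal(unname(rt2[j, l]),
                 unname(unclass(e)[chars[j], aa_alphabet()[l]]))
  }

  # policy-mapped X gets the column-wise mean energy row
  xrec <- protein_record("x", "AXA")
  rtx <- unclass(build_recm_t(xrec, e))
  expect_equal(rtx[2, ], colMeans(unclass(e)), ignore_attr = TRUE)
})

test_that("recm_clbp handles homopolymers and matches the brute-force oracle", {
  e <- gen_energy_matrix(seed = 3)
  homo <- protein_record("h", strrep("A", 20))
  d <- recm_clbp(homo, e)
  expect_length(d, 236L)
  expect_equal(as.numeric(d),
               oracle_clbp_descriptor(build_recm_t(homo, e)))
  rec <- random_record(40, seed = 6)
  expect_identical(recm_clbp(rec, e), recm_clbp(rec, e))
  expect_length(recm_clbp(rec, e), 236L)
})
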