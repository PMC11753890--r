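# Independent brute-force reference implementations used as oracles.
# Deliberately written with explicit per-pixel / per-residue loops and
# their own uniform-code bookkeeping, sharing no code with the package.

oracle_clbp_descriptor <- function(m) {
  m <- unclass(as.matrix(m))
  mn <- min(m); mx <- max(m)
  img <- if (mx == mn) {
    matrix(0L, nrow(m), ncol(m))
  } else {
    matrix(as.integer(round((m - mn) / (mx - mn) * 255)), nrow(m), ncol(m))
  }
  L <- nrow(img); W <- ncol(img)
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
               c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  Tg <- mean(img)
  n_centers <- (L - 2) * (W - 2)
  abs_diffs <- numeric(n_centers * 8)
  idx <- 0
  for (i in 2:(L - 1)) for (j in 2:(W - 1)) for (n in 1:8) {
    idx <- idx + 1
    abs_diffs[idx] <- abs(img[i + offs[[n]][1], j + offs[[n]][2]] - img[i, j])
  }
  Tm <- mean(abs_diffs)
  is_uniform <- function(code) {
    bits <- as.integer(intToBits(code))[1:8]
    sum(abs(diff(c(bits, bits[1])))) <= 2
  }
  unicodes <- Filter(is_uniform, 0:255)
  bin_of <- function(code) {
    k <- match(code, unicodes)
    if (is.na(k)) 59L else k
  }
  hs <- numeric(59); hm <- numeric(59); hmc <- numeric(118)
  for (i in 2:(L - 1)) for (j in 2:(W - 1)) {
    ctr <- img[i, j]
    s <- 0L; mc <- 0L
    for (n in 1:8) {
      d <- img[i + offs[[n]][1], j + offs[[n]][2]] - ctr
      if (d >= 0) s <- s + 2L^(n - 1L)
      if (abs(d) >= Tm) mc <- mc + 2L^(n - 1L)
    }
    cbit <- if (ctr >= Tg) 1L else 0L
    hs[bin_of(s)] <- hs[bin_of(s)] + 1
    hm[bin_of(mc)] <- hm[bin_of(mc)] + 1
    hmc[cbit * 59L + bin_of(mc)] <- hmc[cbit * 59L + bin_of(mc)] + 1
  }
  c(hs, hm, hmc)
}

oracle_ctd <- function(chars, grouping) {
  grp <- integer(length(chars))
  for (g in 1:3) {
    grp[chars %in% strsplit(grouping[g], "")[[1]]] <- g
  }
  n <- length(grp)
  comp <- sapply(1:3, function(g) sum(grp == g) / n * 100)
  trans <- c(0, 0, 0)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      pair <- sort(c(grp[i], grp[i + 1]))
      if (identical(pair, c(1L, 2L))) trans[1] <- trans[1] + 1
      if (identical(pair, c(1L, 3L))) trans[2] <- trans[2] + 1
      if (identical(pair, c(2L, 3L))) trans[3] <- trans[3] + 1
    }
    trans <- trans / (n - 1) * 100
  }
  dist <- numeric(15)
  for (g in 1:3) {
    pos <- which(grp == g)
    if (length(pos) > 0) {
      ng <- length(pos)
      occ <- c(1, ceiling(0.25 * ng), ceiling(0.5 * ng), ceiling(0.75 * ng), ng)
      dist[(g - 1) * 5 + 1:5] <- pos[occ] / n * 100
    }
  }
  c(comp, trans, dist)
}

random_profile <- function(L, seed) {
  set.seed(seed)
  profile_matrix(matrix(round(rnorm(L * 20, sd = 5)), L, 20))
}

random_record <- function(L, seed, id = "r") {
  set.seed(seed)
  protein_record(id, paste(sample(aa_alphabet(), L, replace = TRUE),
                           collapse = ""))
}
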