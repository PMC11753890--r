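#' Generate random protein sequences
#'
#' Draws i.i.d. residues from a stated composition (uniform over the 20
#' standard amino acids by default) with lengths uniform in a range.
#' Pure function of its arguments: the same seed reproduces the same
#' records.
#'
#' @param n Number of sequences.
#' @param length_range Length bounds (inclusive); minimum 3 so the CLBP
#'   window fits.
#' @param composition Optional length-20 probability vector over
#'   [aa_alphabet()].
#' @param seed Integer seed.
#' @return List of [protein_record()] objects with ids `synth_1`, ...
#' @export
gen_sequences <- function(n, length_range = c(50L, 200L),
                          composition = NULL, seed = 1L) {
  stopifnot(length_range[1] >= 3L, length_range[1] <= length_range[2])
  if (is.null(composition)) composition <- rep(1 / 20, 20L)
  stopifnot(length(composition) == 20L)
  .with_seed(seed, function() {
    lens <- length_range[1]:length_range[2]
    lapply(seq_len(n), function(i) {
      L <- if (length(lens) == 1L) lens else sample(lens, 1L)
      protein_record(paste0("synth_", i),
                     paste(sample(aa_alphabet(), L, replace = TRUE,
                                  prob = composition), collapse = ""))
    })
  })
}

#' Generate a plausible synthetic PSSM for a sequence
#'
#' A stand-in for an iterative-search profile: each row carries a base
#' log-odds of +4 on the observed residue's own column and -1 elsewhere,
#' plus integer-rounded Gaussian noise (sd = 2), clamped to \[-15, 15\]
#' to mimic the ASCII PSSM value range. Intentionally non-biological: it
#' only needs realistic range and texture for the downstream image
#' transform.
#'
#' @param record A [protein_record()].
#' @param seed Integer seed.
#' @return An integer-valued [profile_matrix()] of shape L x 20.
#' @export
gen_profile <- function(record, seed = 1L) {
  chars <- strsplit(record$sequence, "")[[1]]
  idx <- match(chars, aa_alphabet())
  L <- length(chars)
  .with_seed(seed, function() {
    base <- matrix(-1, L, 20L)
    own <- !is.na(idx)
    base[cbind(which(own), idx[own])] <- 4
    noisy <- base + round(matrix(stats::rnorm(L * 20L, sd = 2), L, 20L))
    profile_matrix(pmin(pmax(noisy, -15), 15), record$sequence)
  })
}

#' Generate a synthetic residue-wise energy contact matrix
#'
#' A symmetric 20 x 20 matrix of contact-energy-like values in
#' \[-8, 2\] (negative-dominated, as physical contact potentials are).
#' This is a clearly synthetic placeholder for a published energy table,
#' suitable for exercising the RECM-T transform, not for biology.
#'
#' @param seed Integer seed.
#' @return A 20 x 20 `energy_contact_matrix` with canonical dimnames.
#' @export
gen_energy_matrix <- function(seed = 1L) {
  .with_seed(seed, function() {
    m <- matrix(stats::runif(400L, -8, 2), 20L, 20L)
    m <- (m + t(m)) / 2
    dimnames(m) <- list(aa_alphabet(), aa_alphabet())
    structure(m, class = c("energy_contact_matrix", class(m)))
  })
}

#' Generate a two-class multi-view feature dataset
#'
#' Gaussian feature blocks with planted class signal: every view is unit
#' noise except at the stated informative dimensions, whose class-1 mean
#' is shifted by the effect size. Used to exercise weight learning
#' (views without informative dimensions are pure noise) and feature
#' selection (recovery of the planted columns).
#'
#' @param n Number of records (balanced classes: first half negative).
#' @param blocks Named integer vector of view widths.
#' @param informative Named list: for each view, integer indices (within
#'   the view) of informative dimensions. Views absent from the list get
#'   none.
#' @param shift Class-mean shift of informative dimensions (effect size).
#' @param noise_sd Noise standard deviation.
#' @param seed Integer seed.
#' @return A labelled [feature_table()].
#' @export
gen_multiview_dataset <- function(n = 100L,
                                  blocks = c(ESM = 32L, `PSSM-CLBP` = 16L,
                                             QLC = 8L, `RECM-CLBP` = 16L),
                                  informative = list(ESM = 1:4),
                                  shift = 2, noise_sd = 1, seed = 1L) {
  stopifnot(shift >= 0, n >= 4L)
  .with_seed(seed, function() {
    y <- rep(c(0L, 1L), length.out = n)
    D <- sum(blocks)
    x <- matrix(stats::rnorm(n * D, sd = noise_sd), n, D)
    ends <- cumsum(blocks)
    starts <- ends - blocks + 1L
    for (v in names(informative)) {
      if (!v %in% names(blocks)) stop(sprintf("unknown view '%s'", v))
      cols <- starts[[v]] + informative[[v]] - 1L
      stopifnot(all(cols <= ends[[v]]))
      x[y == 1L, cols] <- x[y == 1L, cols] + shift
    }
    feature_table(x, paste0("rec_", seq_len(n)), blocks, y)
  })
}

#' Write a complete synthetic input set to disk
#'
#' Materializes everything the end-to-end pipeline reads: a FASTA file,
#' one ASCII PSSM per record, the energy-matrix TSV and a labels TSV.
#' Labels are assigned alternately (deterministic).
#'
#' @param dir Output directory (created if needed).
#' @param n Number of sequences.
#' @param length_range Sequence length bounds.
#' @param seed Integer seed.
#' @return Invisible list of the written paths.
#' @export
synth_write_inputs <- function(dir, n = 10L, length_range = c(30L, 60L),
                               seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pssm_dir <- file.path(dir, "pssm")
  dir.create(pssm_dir, showWarnings = FALSE)
  records <- gen_sequences(n, length_range, seed = seed)
  fasta <- file.path(dir, "sequences.fasta")
  write_fasta(records, fasta)
  for (i in seq_along(records)) {
    pm <- gen_profile(records[[i]], seed = seed + i)
    write_pssm_ascii(pm, records[[i]]$sequence,
                     file.path(pssm_dir, paste0(records[[i]]$id, ".pssm")))
  }
  recm <- file.path(dir, "recm.tsv")
  write_energy_matrix(gen_energy_matrix(seed), recm)
  labels <- file.path(dir, "labels.tsv")
  utils::write.table(
    data.frame(id = vapply(records, `[[`, character(1), "id"),
               label = rep(c(0L, 1L), length.out = n)),
    labels, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fasta = fasta, pssm_dir = pssm_dir, recm = recm,
                 labels = labels))
}
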