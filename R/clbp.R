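#' Scale a profile matrix to an 8-bit image
#'
#' Min-max scales an L x 20 profile matrix (PSSM or RECM-T) to integer
#' pixel intensities in \[0, 255\]:
#' \deqn{x' = round(255 (x - min) / (max - min))}
#' A constant matrix maps to the all-zero image. Rounding is R's
#' round-half-to-even, which is platform stable. Because min-max scaling
#' is invariant to positive affine maps of the input, so is every CLBP
#' descriptor computed from the image.
#'
#' @param m A [profile_matrix()] (or any finite numeric matrix).
#' @return Integer matrix of the same shape with entries in \[0, 255\],
#'   class `matrix_image`.
#' @export
scale_to_image <- function(m) {
  m <- unclass(as.matrix(m))
  if (!all(is.finite(m))) stop("matrix contains non-finite entries")
  rng <- range(m)
  img <- if (rng[1] == rng[2]) {
    matrix(0L, nrow(m), ncol(m))
  } else {
    matrix(as.integer(round(255 * (m - rng[1]) / (rng[2] - rng[1]))),
           nrow(m), ncol(m))
  }
  structure(img, class = c("matrix_image", class(img)))
}

# neighbor offsets for R=1, N=8: n = 0 at the east neighbor, proceeding
# counter-clockwise (row index grows downward, so north is row - 1)
.clbp_offsets <- cbind(
  dr = c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L),
  dc = c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
)

#' Compute CLBP code maps of a matrix image
#'
#' For every interior pixel (all rows 2..L-1 crossed with columns 2..19;
#' each interior pixel is the center of one 3 x 3 window) three codes are
#' computed:
#' \itemize{
#'   \item the center code \code{c}: 1 iff the center intensity is >= the
#'     global image mean \code{T};
#'   \item the sign code \code{s}: an 8-bit code whose n-th bit is 1 iff
#'     \code{neighbor - center >= 0};
#'   \item the magnitude code \code{m}: an 8-bit code whose n-th bit is 1
#'     iff \code{|neighbor - center| >= T_m}, where \code{T_m} is the mean
#'     absolute center/neighbor difference over the whole image.
#' }
#' Neighbors are indexed n = 0 at the east pixel and proceed
#' counter-clockwise. Only interior centers are used (no padding), so all
#' three maps have shape (L-2) x 18.
#'
#' @param img A `matrix_image` from [scale_to_image()].
#' @param R Neighborhood radius; only 1 is supported.
#' @param N Number of neighbors; only 8 is supported.
#' @return List with integer matrices `c_map` (0/1), `s_map`, `m_map`
#'   (codes in \[0, 255\]), plus `n_centers`, `T`, `T_m`.
#' @export
clbp_code_maps <- function(img, R = 1L, N = 8L) {
  if (R != 1L || N != 8L) stop("only R = 1, N = 8 is supported")
  img <- unclass(img)
  L <- nrow(img); W <- ncol(img)
  if (L < 3L) stop("sequence too short for CLBP window (need L >= 3)")
  if (W < 3L) stop("image too narrow for CLBP window")
  ri <- 2:(L - 1L); ci <- 2:(W - 1L)
  center <- img[ri, ci, drop = FALSE]
  Tg <- mean(img)
  diffs <- lapply(seq_len(N), function(n) {
    img[ri + .clbp_offsets[n, "dr"], ci + .clbp_offsets[n, "dc"], drop = FALSE] - center
  })
  Tm <- mean(abs(unlist(diffs)))
  s_map <- matrix(0L, length(ri), length(ci))
  m_map <- matrix(0L, length(ri), length(ci))
  for (n in seq_len(N)) {
    w <- 2L^(n - 1L)
    s_map <- s_map + w * (diffs[[n]] >= 0)
    m_map <- m_map + w * (abs(diffs[[n]]) >= Tm)
  }
  list(c_map = (center >= Tg) + 0L,
       s_map = s_map, m_map = m_map,
       n_centers = length(ri) * length(ci), T = Tg, T_m = Tm)
}

#' Uniform-pattern (u2) bin index of 8-bit codes
#'
#' A circular 8-bit code is "uniform" when it has at most two 0/1
#' transitions; there are 58 such codes for N = 8. Uniform codes map to
#' bins 1..58 in ascending code order; every non-uniform code falls into
#' the catch-all bin 59.
#'
#' @param codes Integer vector/matrix of codes in \[0, 255\].
#' @return Integer bin indices in 1..59, same shape as `codes`.
#' @export
u2_bin <- function(codes) {
  map <- .u2_map()
  out <- map[as.integer(codes) + 1L]
  if (anyNA(out)) stop("codes must be integers in [0, 255]")
  if (is.matrix(codes)) dim(out) <- dim(codes)
  out
}

.u2_cache <- new.env(parent = emptyenv())
.u2_map <- function() {
  if (!is.null(.u2_cache$map)) return(.u2_cache$map)
  transitions <- vapply(0:255, function(code) {
    bits <- as.integer(intToBits(code))[1:8]
    sum(bits != bits[c(2:8, 1)])
  }, integer(1))
  uniform <- which(transitions <= 2L)  # ascending code order
  map <- rep(59L, 256L)
  map[uniform] <- seq_along(uniform)
  .u2_cache$map <- map
  map
}

#' Build the 236-dimensional CLBP descriptor from code maps
#'
#' Combines the three code maps into one histogram feature vector:
#' the u2 histogram of the sign map (59 bins), the u2 histogram of the
#' magnitude map (59 bins), and the joint magnitude/center histogram
#' (the magnitude u2 histogram split by the binary center code, 2 x 59 =
#' 118 bins), concatenated to 59 + 59 + 118 = 236 values. Bins hold raw
#' counts by default, so the sign and magnitude parts each sum to the
#' number of interior centers.
#'
#' @param maps Output of [clbp_code_maps()].
#' @param normalize If `TRUE`, divide by the number of centers.
#' @return Numeric vector of length 236 with attribute `scheme`
#'   identifying the decomposition, class `clbp_descriptor`.
#' @export
clbp_histogram <- function(maps, normalize = FALSE) {
  s_bins <- u2_bin(maps$s_map)
  m_bins <- u2_bin(maps$m_map)
  h_s <- tabulate(s_bins, nbins = 59L)
  h_m <- tabulate(m_bins, nbins = 59L)
  h_mc0 <- tabulate(m_bins[maps$c_map == 0L], nbins = 59L)
  h_mc1 <- tabulate(m_bins[maps$c_map == 1L], nbins = 59L)
  v <- as.numeric(c(h_s, h_m, h_mc0, h_mc1))
  if (normalize) v <- v / maps$n_centers
  structure(v, scheme = "S_u2(59)+M_u2(59)+M_u2xC(2x59)",
            class = "clbp_descriptor")
}

#' PSSM-CLBP: texture descriptor of a PSSM
#'
#' The full transform: min-max scale the L x 20 PSSM to an 8-bit image,
#' compute the CLBP center/sign/magnitude code maps over all 3 x 3
#' interior windows (R = 1, N = 8), and bin them into the 236-dimensional
#' histogram descriptor. Deterministic, and invariant under positive
#' affine rescaling of the input profile.
#'
#' @param m A [profile_matrix()] holding the PSSM.
#' @param normalize Passed to [clbp_histogram()].
#' @return A length-236 `clbp_descriptor`.
#' @export
pssm_clbp <- function(m, normalize = FALSE) {
  clbp_histogram(clbp_code_maps(scale_to_image(m)), normalize = normalize)
}

#' Build the RECM-T matrix of a sequence
#'
#' Expands a sequence into an L x 20 matrix whose row j is the
#' energy-contact vector of residue j against the 20 standard amino acids
#' (self-contact energy on the residue's own column, pairwise contact
#' energies elsewhere). Columns follow [aa_alphabet()]. A policy-mapped
#' `"X"` residue receives the column-wise mean of the 20 energy rows.
#'
#' @param record A [protein_record()].
#' @param e An `energy_contact_matrix` from [read_energy_matrix()] or
#'   [gen_energy_matrix()].
#' @return A [profile_matrix()] of shape L x 20.
#' @export
build_recm_t <- function(record, e) {
  stopifnot(inherits(record, "protein_record"))
  e <- unclass(e)
  stopifnot(all(dim(e) == c(20L, 20L)))
  chars <- strsplit(record$sequence, "")[[1]]
  idx <- match(chars, aa_alphabet())
  rows <- matrix(NA_real_, length(chars), 20L)
  known <- !is.na(idx)
  rows[known, ] <- e[idx[known], , drop = FALSE]
  if (any(!known)) {
    if (!all(chars[!known] == "X")) {
      stop(sprintf("record '%s': unresolvable residue(s) %s", record$id,
                   paste(unique(chars[!known & chars != "X"]), collapse = ", ")))
    }
    rows[!known, ] <- matrix(colMeans(e), sum(!known), 20L, byrow = TRUE)
  }
  profile_matrix(rows, record$sequence)
}

#' RECM-CLBP: texture descriptor of a sequence's energy-contact profile
#'
#' Builds the RECM-T matrix with [build_recm_t()] and applies the same
#' CLBP transform as [pssm_clbp()].
#'
#' @param record A [protein_record()].
#' @param e An `energy_contact_matrix`.
#' @param normalize Passed to [clbp_histogram()].
#' @return A length-236 `clbp_descriptor`.
#' @export
recm_clbp <- function(record, e, normalize = FALSE) {
  pssm_clbp(build_recm_t(record, e), normalize = normalize)
}
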