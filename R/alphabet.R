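#' Canonical amino-acid order
#'
#' The package's fixed column order for all 20-column profile matrices:
#' the PSI-BLAST header order \code{A R N D C Q E G H I L K M F P S T W Y V}.
#' Every matrix read from disk is reordered to this order on load, so
#' PSSM and energy-contact columns can never be silently misaligned.
#'
#' @return Character vector of the 20 standard amino-acid one-letter codes.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# letters accepted in input sequences beyond the standard 20
.nonstandard_aa <- c("B", "Z", "X", "U", "O", "J")

#' Map nonstandard residues according to the configured policy
#'
#' Ambiguous or rare residue codes (B, Z, X, U, O, J) are mapped to
#' \code{"X"} under the default \code{"map"} policy; under \code{"strict"}
#' any such residue is an error naming the record and the offending
#' character. Downstream consumers define what \code{"X"} means for them
#' (the energy-contact row of X is the mean of the 20 standard rows; the
#' CTD descriptors exclude X positions).
#'
#' @param seq Character scalar, an upper-case amino-acid sequence.
#' @param policy `"map"` (default) or `"strict"`.
#' @param id Record identifier used in error messages.
#' @return The sequence with nonstandard residues replaced by `"X"`.
#' @export
map_residues <- function(seq, policy = c("map", "strict"), id = "<unnamed>") {
  policy <- match.arg(policy)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  standard <- chars %in% aa_alphabet()
  nonstd <- chars %in% .nonstandard_aa
  illegal <- !standard & !nonstd
  if (any(illegal)) {
    stop(sprintf("record '%s': illegal residue character(s): %s",
                 id, paste(unique(chars[illegal]), collapse = ", ")))
  }
  if (policy == "strict" && any(nonstd)) {
    stop(sprintf("record '%s': nonstandard residue(s) %s not allowed under strict policy",
                 id, paste(unique(chars[nonstd]), collapse = ", ")))
  }
  chars[nonstd] <- "X"
  paste(chars, collapse = "")
}

#' Construct a protein record
#'
#' @param id Record identifier (non-empty string).
#' @param sequence Amino-acid sequence; upper-cased and policy-mapped.
#' @param policy Nonstandard-residue policy passed to [map_residues()].
#' @return An object of class `protein_record` with elements `id` and
#'   `sequence`.
#' @export
protein_record <- function(id, sequence, policy = "map") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) stop(sprintf("record '%s': empty sequence", id))
  sequence <- map_residues(sequence, policy = policy, id = id)
  structure(list(id = id, sequence = sequence), class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa)\n", x$id, nchar(x$sequence)))
  invisible(x)
}
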