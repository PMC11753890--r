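#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] that enforces the
#' package's record contract: unique ids, non-empty upper-case sequences,
#' and the configured nonstandard-residue policy.
#'
#' @param path Path to a FASTA file.
#' @param policy Nonstandard-residue policy, `"map"` or `"strict"`.
#' @return List of [protein_record()] objects.
#' @export
read_fasta <- function(path, policy = "map") {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) stop(sprintf("FASTA file is empty: %s", path))
  ids <- vapply(strsplit(names(aas), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate FASTA ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  mapply(function(id, s) protein_record(id, s, policy = policy),
         ids, as.character(aas), SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write protein records to a FASTA file
#'
#' @param records List of [protein_record()] objects.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(paste0(">", r$id), con)
    s <- r$sequence
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a profile matrix
#'
#' An L x 20 real matrix paired with a sequence: either a PSSM (log-odds
#' profile from iterative database search) or an RECM-T (per-residue
#' energy-contact rows). Columns always follow [aa_alphabet()].
#'
#' @param values Numeric L x 20 matrix.
#' @param sequence Optional sequence of length L for consistency checks.
#' @return A `profile_matrix` (numeric matrix with canonical colnames).
#' @export
profile_matrix <- function(values, sequence = NULL) {
  values <- as.matrix(values)
  if (ncol(values) != 20L) {
    stop(sprintf("profile matrix must have 20 columns, got %d", ncol(values)))
  }
  if (!all(is.finite(values))) stop("profile matrix contains non-finite entries")
  if (!is.null(sequence) && nchar(sequence) != nrow(values)) {
    stop(sprintf("profile has %d rows but sequence length is %d",
                 nrow(values), nchar(sequence)))
  }
  colnames(values) <- aa_alphabet()
  rownames(values) <- NULL
  class(values) <- c("profile_matrix", class(values))
  values
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the `-out_ascii_pssm` dialect: header lines, then one row per
#' residue holding the position, the residue letter, 20 log-odds integers
#' and 20 weighted-percentage columns, followed by per-row statistics and
#' a footer. The L x 20 log-odds block is returned by default; the
#' percentage block is available via `block = "percent"`.
#'
#' @param path Path to the ASCII PSSM file.
#' @param sequence Optional sequence; its residues are checked against the
#'   file's residue column (an error on mismatch).
#' @param block `"logodds"` (default) or `"percent"`.
#' @return A [profile_matrix()] with an attribute `residues` holding the
#'   file's residue-letter column.
#' @export
read_pssm_ascii <- function(path, sequence = NULL, block = c("logodds", "percent")) {
  block <- match.arg(block)
  if (!file.exists(path)) stop(sprintf("PSSM file not found: %s", path))
  lines <- readLines(path)
  # data rows start with an integer position followed by a residue letter
  is_data <- grepl("^\\s*\\d+\\s+[A-Z]\\s", lines)
  if (!any(is_data)) stop(sprintf("no PSSM data rows found in %s", path))
  rows <- which(is_data)
  vals <- matrix(NA_real_, nrow = length(rows), ncol = 20L)
  residues <- character(length(rows))
  for (i in seq_along(rows)) {
    tok <- strsplit(trimws(lines[rows[i]]), "\\s+")[[1]]
    if (length(tok) < 22L) {
      stop(sprintf("%s line %d: expected >= 22 fields, got %d",
                   path, rows[i], length(tok)))
    }
    residues[i] <- tok[2L]
    sel <- if (block == "logodds") 3:22 else {
      if (length(tok) < 42L) {
        stop(sprintf("%s line %d: no percentage block (%d fields)",
                     path, rows[i], length(tok)))
      }
      23:42
    }
    v <- suppressWarnings(as.numeric(tok[sel]))
    if (anyNA(v)) {
      stop(sprintf("%s line %d: fewer than 20 parsable values", path, rows[i]))
    }
    vals[i, ] <- v
  }
  # column order from the header line when present, else canonical
  hdr <- grep("^\\s*(?:[A-Z]\\s+){19}[A-Z]", lines[seq_len(rows[1] - 1L)],
              value = TRUE, perl = TRUE)
  if (length(hdr) > 0L) {
    cols <- strsplit(trimws(hdr[1L]), "\\s+")[[1]][1:20]
    if (!setequal(cols, aa_alphabet())) {
      stop(sprintf("%s: unrecognized PSSM column header", path))
    }
    vals <- vals[, match(aa_alphabet(), cols), drop = FALSE]
  }
  if (!is.null(sequence)) {
    if (nchar(sequence) != length(residues)) {
      stop(sprintf("%s: PSSM has %d rows but sequence length is %d",
                   path, length(residues), nchar(sequence)))
    }
    seq_chars <- strsplit(toupper(sequence), "")[[1]]
    bad <- which(seq_chars != residues & seq_chars != "X")
    if (length(bad) > 0L) {
      stop(sprintf("%s: residue column disagrees with sequence at position(s) %s",
                   path, paste(utils::head(bad, 5L), collapse = ", ")))
    }
  }
  pm <- profile_matrix(vals, sequence)
  attr(pm, "residues") <- residues
  pm
}

#' Write a profile matrix in PSI-BLAST ASCII PSSM layout
#'
#' Emits a file that [read_pssm_ascii()] parses back bit-exactly: two
#' header lines, one data row per residue with the 20 log-odds integers
#' and a zero percentage block, and a blank footer.
#'
#' @param pm A [profile_matrix()] of integers.
#' @param sequence The paired sequence (supplies the residue column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm_ascii <- function(pm, sequence, path) {
  stopifnot(nrow(pm) == nchar(sequence))
  aa <- aa_alphabet()
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", "Last position-specific scoring matrix computed",
               paste0("            ", paste(sprintf("%3s", aa), collapse = ""),
                      "   ", paste(sprintf("%3s", aa), collapse = ""))), con)
  chars <- strsplit(toupper(sequence), "")[[1]]
  for (i in seq_len(nrow(pm))) {
    writeLines(sprintf("%5d %s %s   %s  0.00 0.00", i, chars[i],
                       paste(sprintf("%3d", as.integer(pm[i, ])), collapse = " "),
                       paste(rep("  0", 20L), collapse = " ")), con)
  }
  writeLines("", con)
  invisible(path)
}

#' Read a residue-wise energy contact matrix (RECM)
#'
#' A labelled tab-separated 20 x 20 table of pairwise (off-diagonal) and
#' self (diagonal) contact energies between the standard amino acids.
#' Rows and columns are reordered to [aa_alphabet()] on load, so shuffled
#' input label orders are harmless.
#'
#' @param path Path to the TSV file (first column and header row are
#'   amino-acid labels).
#' @param asymmetry `"warn"` (default) or `"error"`: what to do when the
#'   matrix is asymmetric beyond `tol`.
#' @param tol Symmetry tolerance.
#' @return A 20 x 20 numeric matrix with canonical dimnames, class
#'   `energy_contact_matrix`.
#' @export
read_energy_matrix <- function(path, asymmetry = c("warn", "error"), tol = 1e-9) {
  asymmetry <- match.arg(asymmetry)
  if (!file.exists(path)) stop(sprintf("energy matrix file not found: %s", path))
  df <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  if (!all(dim(m) == c(20L, 20L))) {
    stop(sprintf("energy matrix must be 20x20, got %dx%d", nrow(m), ncol(m)))
  }
  if (!setequal(rownames(m), aa_alphabet()) || !setequal(colnames(m), aa_alphabet())) {
    stop("energy matrix labels must be the 20 standard amino acids")
  }
  m <- m[aa_alphabet(), aa_alphabet()]
  storage.mode(m) <- "double"
  dev <- max(abs(m - t(m)))
  if (dev > tol) {
    msg <- sprintf("energy matrix asymmetric (max |e[i,j]-e[j,i]| = %g)", dev)
    if (asymmetry == "error") stop(msg) else warning(msg)
  }
  structure(m, class = c("energy_contact_matrix", class(m)))
}

#' Write an energy contact matrix as labelled TSV
#'
#' @param e 20 x 20 matrix with amino-acid dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_energy_matrix <- function(e, path) {
  df <- as.data.frame(unclass(e))
  utils::write.table(df, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Construct a multi-view feature table
#'
#' The package's container for per-protein feature matrices: an n x D
#' matrix partitioned into named contiguous blocks (views), with optional
#' 0/1 class labels.
#'
#' @param matrix Numeric n x D matrix.
#' @param ids Character vector of n unique record ids.
#' @param blocks Named integer vector of block widths summing to D, in
#'   column order.
#' @param labels Optional 0/1 vector of length n.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(matrix, ids, blocks, labels = NULL) {
  matrix <- as.matrix(matrix)
  blocks <- vapply(blocks, as.integer, integer(1))
  if (is.null(names(blocks)) || any(!nzchar(names(blocks)))) {
    stop("blocks must be a named vector of widths")
  }
  if (sum(blocks) != ncol(matrix)) {
    stop(sprintf("block widths sum to %d but matrix has %d columns",
                 sum(blocks), ncol(matrix)))
  }
  if (length(ids) != nrow(matrix)) stop("one id per row required")
  if (anyDuplicated(ids)) stop("feature table ids must be unique")
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(matrix) || !all(labels %in% c(0L, 1L))) {
      stop("labels must be 0/1, one per row")
    }
  }
  rownames(matrix) <- ids
  colnames(matrix) <- unlist(lapply(names(blocks), function(b) {
    paste0(b, ".", seq_len(blocks[[b]]))
  }))
  structure(list(matrix = matrix, ids = as.character(ids),
                 blocks = blocks, labels = labels),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d records x %d features\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat("  blocks:", paste(sprintf("%s(%d)", names(x$blocks), x$blocks),
                         collapse = " + "), "\n")
  if (!is.null(x$labels)) {
    cat(sprintf("  labels: %d positive / %d negative\n",
                sum(x$labels == 1L), sum(x$labels == 0L)))
  }
  invisible(x)
}

#' Extract one view (block) of a feature table
#'
#' @param table A [feature_table()].
#' @param name Block name.
#' @return Numeric sub-matrix of the block's columns.
#' @export
get_block <- function(table, name) {
  stopifnot(inherits(table, "feature_table"))
  if (!name %in% names(table$blocks)) {
    stop(sprintf("no block named '%s' (have: %s)", name,
                 paste(names(table$blocks), collapse = ", ")))
  }
  ends <- cumsum(table$blocks)
  starts <- ends - table$blocks + 1L
  i <- match(name, names(table$blocks))
  table$matrix[, starts[i]:ends[i], drop = FALSE]
}

#' Write a feature table as TSV with a two-row header
#'
#' Row 1 carries the block name of each column, row 2 the within-block
#' column index; data rows start with the record id and optional label.
#'
#' @param table A [feature_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  blk <- rep(names(table$blocks), times = table$blocks)
  idx <- unlist(lapply(table$blocks, seq_len), use.names = FALSE)
  has_lab <- !is.null(table$labels)
  writeLines(paste(c("id", if (has_lab) "label", blk), collapse = "\t"), con)
  writeLines(paste(c("", if (has_lab) "", idx), collapse = "\t"), con)
  for (i in seq_len(nrow(table$matrix))) {
    writeLines(paste(c(table$ids[i], if (has_lab) table$labels[i],
                       format(table$matrix[i, ], digits = 17, trim = TRUE,
                              scientific = FALSE)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path Path to the TSV file.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop(sprintf("feature table file too short: %s", path))
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1]]
  has_lab <- length(hdr) >= 2L && hdr[2L] == "label"
  off <- if (has_lab) 2L else 1L
  blk <- hdr[-seq_len(off)]
  widths <- rle(blk)
  blocks <- stats::setNames(widths$lengths, widths$values)
  body <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  ids <- vapply(body, `[[`, character(1), 1L)
  labels <- if (has_lab) as.integer(vapply(body, `[[`, character(1), 2L)) else NULL
  mat <- do.call(rbind, lapply(body, function(f) as.numeric(f[-seq_len(off)])))
  feature_table(mat, ids, blocks, labels)
}
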