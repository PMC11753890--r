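#' Three-group physicochemical partitions of the amino acids
#'
#' Loads the grouping table used by the CTD descriptors: for each of the
#' seven physicochemical properties (hydrophobicity, normalized van der
#' Waals volume, polarity, polarizability, charge, secondary-structure
#' propensity, solvent accessibility) a partition of the 20 standard
#' amino acids into three groups. The shipped table is the canonical
#' three-group CTD scheme from the descriptor literature; a different
#' table may be supplied as a TSV with columns
#' `property`, `group1`, `group2`, `group3`.
#'
#' @param path Optional path to an alternative grouping TSV.
#' @return Named list (one element per property, in fixed order) of
#'   3-element character vectors of residue groups.
#' @export
ctd_groupings <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ctd_groups.tsv", package = "targetclp")
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("property", "group1", "group2", "group3") %in% names(df)))
  out <- lapply(seq_len(nrow(df)), function(i) {
    g <- toupper(c(df$group1[i], df$group2[i], df$group3[i]))
    all_res <- unlist(strsplit(g, ""))
    if (anyDuplicated(all_res) || !setequal(all_res, aa_alphabet())) {
      stop(sprintf("grouping '%s' is not a partition of the 20 amino acids",
                   df$property[i]))
    }
    g
  })
  stats::setNames(out, df$property)
}

#' Encode a sequence as a group string under one property partition
#'
#' Maps each resolvable residue to its group label 1/2/3. Policy-mapped
#' `"X"` positions are excluded, so the effective length L' is the number
#' of standard residues.
#'
#' @param record A [protein_record()].
#' @param grouping 3-element character vector of residue groups (one
#'   element of [ctd_groupings()]).
#' @return Integer vector over \{1, 2, 3\} of length L'.
#' @export
encode_groups <- function(record, grouping) {
  chars <- strsplit(record$sequence, "")[[1]]
  chars <- chars[chars != "X"]
  if (length(chars) == 0L) {
    stop(sprintf("record '%s': no resolvable residues", record$id))
  }
  lab <- integer(length(chars))
  for (g in 1:3) lab[chars %in% strsplit(grouping[g], "")[[1]]] <- g
  if (any(lab == 0L)) {
    stop(sprintf("record '%s': residue(s) missing from grouping", record$id))
  }
  lab
}

#' Composition index: percentage of each group
#'
#' @param groups Integer group string from [encode_groups()].
#' @return Numeric length-3 vector of percentages summing to 100.
#' @export
ctd_composition <- function(groups) {
  100 * tabulate(groups, nbins = 3L) / length(groups)
}

#' Transition index: percentage of adjacent dissimilar-group pairs
#'
#' For the unordered group pairs (1,2), (1,3), (2,3): the number of
#' adjacent positions where the two groups meet in either order, divided
#' by L' - 1, as a percentage.
#'
#' @param groups Integer group string from [encode_groups()].
#' @return Numeric length-3 vector in \[0, 100\] (pair order 12, 13, 23).
#' @export
ctd_transition <- function(groups) {
  n <- length(groups)
  if (n < 2L) {
    warning("sequence too short for transitions; returning zeros")
    return(c(0, 0, 0))
  }
  a <- groups[-n]; b <- groups[-1L]
  pair <- paste0(pmin(a, b), pmax(a, b))
  100 * c(sum(pair == "12"), sum(pair == "13"), sum(pair == "23")) / (n - 1L)
}

#' Distribution index: positional quantiles of each group
#'
#' For each group: the 1-based positions (within the resolvable sequence)
#' of its first occurrence and of occurrence number ceil(q * n_g) for
#' q = 0.25, 0.5, 0.75, plus the last occurrence, each expressed as a
#' percentage of L'. A group absent from the sequence contributes five
#' zeros.
#'
#' @param groups Integer group string from [encode_groups()].
#' @return Numeric length-15 vector (5 slots per group, groups in order).
#' @export
ctd_distribution <- function(groups) {
  n <- length(groups)
  out <- numeric(15L)
  for (g in 1:3) {
    pos <- which(groups == g)
    ng <- length(pos)
    if (ng > 0L) {
      occ <- c(1L, ceiling(c(0.25, 0.5, 0.75) * ng), ng)
      out[(g - 1L) * 5L + 1:5] <- 100 * pos[occ] / n
    }
  }
  out
}

#' QLC descriptor: the 147-dimensional CTD feature vector
#'
#' Concatenates, for each of the seven physicochemical properties in
#' fixed order, the composition (3), transition (3) and distribution (15)
#' indices, yielding 7 x 21 = 147 features.
#'
#' @param record A [protein_record()].
#' @param groupings Output of [ctd_groupings()] (defaults to the shipped
#'   table).
#' @return Named numeric vector of length 147.
#' @export
qlc_vector <- function(record, groupings = ctd_groupings()) {
  parts <- lapply(names(groupings), function(p) {
    g <- encode_groups(record, groupings[[p]])
    v <- c(ctd_composition(g), ctd_transition(g), ctd_distribution(g))
    names(v) <- paste0(p, ".", c(paste0("C", 1:3), c("T12", "T13", "T23"),
                                 paste0("D", rep(1:3, each = 5), ".",
                                        rep(c(0, 25, 50, 75, 100), 3))))
    v
  })
  unlist(parts)
}

#' Fit per-feature normalization statistics on training rows
#'
#' Learns a column-wise mean and standard deviation (z-score, the
#' default) or min/max range, to be applied identically at training and
#' prediction time. Zero-variance columns get a unit divisor and are
#' flagged.
#'
#' @param table A [feature_table()] of training rows.
#' @param method `"zscore"` (default) or `"minmax"`.
#' @return List with `method`, `center`, `scale`, `constant` (logical
#'   flags), class `normalization_stats`.
#' @export
fit_normalization <- function(table, method = c("zscore", "minmax")) {
  method <- match.arg(method)
  x <- table$matrix
  if (method == "zscore") {
    center <- colMeans(x)
    scale <- apply(x, 2L, stats::sd)
  } else {
    center <- apply(x, 2L, min)
    scale <- apply(x, 2L, max) - center
  }
  constant <- !is.finite(scale) | scale == 0
  scale[constant] <- 1
  structure(list(method = method, center = center, scale = scale,
                 constant = constant),
            class = "normalization_stats")
}

#' Apply fitted normalization statistics to a feature table
#'
#' @param table A [feature_table()].
#' @param stats A `normalization_stats` object from [fit_normalization()].
#' @return A [feature_table()] with the transformed matrix.
#' @export
apply_normalization <- function(table, stats) {
  if (!inherits(stats, "normalization_stats")) {
    stop("normalization statistics must be fitted before applying")
  }
  if (length(stats$center) != ncol(table$matrix)) {
    stop("normalization stats do not match table width")
  }
  x <- sweep(sweep(table$matrix, 2L, stats$center, "-"), 2L, stats$scale, "/")
  feature_table(x, table$ids, table$blocks, table$labels)
}
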