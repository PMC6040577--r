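## Pairwise residue contact-energy matrices versus inclusion-rank
## differences.  A contact matrix is a labelled symmetric 20x20 table of
## energy-like values (sign convention is dialect-dependent and
## irrelevant to the correlations, which are scale- and shift-invariant).

#' Construct and validate a contact-energy matrix
#'
#' Checks that the input is a 20x20 numeric matrix labelled with the 20
#' standard amino acids on both margins, reorders rows and columns to the
#' canonical alphabetical order, and enforces symmetry: asymmetries up to
#' `tol` are averaged away with a warning, larger ones are rejected.
#'
#' @param energies Numeric 20x20 matrix with row and column names.
#' @param name Label for the matrix.
#' @param tol Largest tolerated absolute row/column asymmetry.
#' @return Symmetric matrix of class `"contact_matrix"` with a `name`
#'   attribute.
#' @export
contact_matrix <- function(energies, name = "matrix", tol = 1e-9) {
  if (!is.matrix(energies) || !is.numeric(energies) ||
      nrow(energies) != 20L || ncol(energies) != 20L) {
    stop("contact matrix must be a numeric 20x20 matrix")
  }
  rn <- toupper(rownames(energies)); cn <- toupper(colnames(energies))
  if (is.null(rn) || is.null(cn) || !setequal(rn, AA20) || !setequal(cn, AA20) ||
      anyDuplicated(rn) || anyDuplicated(cn)) {
    stop("contact matrix must be labelled with each of the 20 standard amino acids exactly once")
  }
  rownames(energies) <- rn; colnames(energies) <- cn
  m <- energies[AA20, AA20]
  asym <- max(abs(m - t(m)))
  if (asym > tol) {
    stop(sprintf("contact matrix '%s' is asymmetric (max |e(a,b) - e(b,a)| = %.3g > tol = %.3g)",
                 name, asym, tol))
  }
  if (asym > 0) {
    warning(sprintf("contact matrix '%s': symmetrized small asymmetry (max %.3g) by averaging",
                    name, asym))
    m <- (m + t(m)) / 2
  }
  structure(m, name = as.character(name)[1], class = c("contact_matrix", "matrix", "array"))
}

#' Read a contact matrix from a labelled TSV
#'
#' Expects a header row of amino-acid labels and one labelled row per
#' amino acid, tab- or whitespace-separated.
#'
#' @param path File path.
#' @param name Matrix label (defaults to the file base name).
#' @param tol Passed to [contact_matrix()].
#' @return A [contact_matrix()].
#' @export
read_contact_matrix <- function(path, name = NULL, tol = 1e-9) {
  if (!file.exists(path)) stop("contact matrix file not found: ", path)
  tab <- read.table(path, header = TRUE, row.names = 1L, sep = "",
                    check.names = FALSE, comment.char = "#")
  contact_matrix(as.matrix(tab),
                 name = if (is.null(name)) sub("\\.[^.]*$", "", basename(path)) else name,
                 tol = tol)
}

#' Write a contact matrix to a labelled TSV
#'
#' @param m A [contact_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_contact_matrix <- function(m, path) {
  stopifnot(inherits(m, "contact_matrix"))
  df <- data.frame(aa = rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Absolute inclusion-rank difference matrix
#'
#' The 20x20 matrix `d(a, b) = |rank(a) - rank(b)|` of absolute
#' differences between the inclusion-order ranks of every amino-acid
#' pair.  Invariant to shifting all ranks by a constant; tied species
#' (consensus Q and I) have difference 0.
#'
#' @param ranks A [rank_table()].
#' @return Symmetric non-negative integer matrix with zero diagonal.
#' @export
#' @examples
#' rank_diff_matrix(consensus_ranks())["G", "A"]  # |1 - 2| = 1
rank_diff_matrix <- function(ranks) {
  stopifnot(inherits(ranks, "rank_table"))
  r <- as.integer(ranks[AA20])
  d <- abs(outer(r, r, "-"))
  dimnames(d) <- list(AA20, AA20)
  d
}

#' Per-amino-acid correlations of contact energy with rank difference
#'
#' For each focal species, the Pearson correlation over its 19 pairs with
#' the other species between contact energy `e(focal, other)` and
#' rank difference `d(focal, other)` (the self pair is excluded).  A
#' negative r means the focal species forms its most stabilising
#' contacts with species of very different inclusion rank.  P values are
#' two-tailed.
#'
#' @param m A [contact_matrix()].
#' @param ranks A [rank_table()], or a precomputed [rank_diff_matrix()].
#' @return Data frame with one row per focal species: `species`, `r`,
#'   `p_two_tailed`, `n` (= 19); attribute `n_negative` counts negative
#'   correlations.
#' @export
focal_correlations <- function(m, ranks) {
  stopifnot(inherits(m, "contact_matrix"))
  d <- if (inherits(ranks, "rank_table")) rank_diff_matrix(ranks) else ranks
  if (!is.matrix(d) || !identical(dim(d), c(20L, 20L)) ||
      !identical(rownames(d), AA20)) {
    stop("ranks must be a rank_table or a 20x20 rank-difference matrix in standard order")
  }
  rows <- lapply(AA20, function(a) {
    others <- setdiff(AA20, a)
    res <- pearson_test(d[a, others], unclass(m)[a, others], alternative = "two.sided")
    data.frame(species = a, r = res$r, p_two_tailed = res$p_two_tailed,
               n = res$n, row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_negative") <- sum(out$r < 0, na.rm = TRUE)
  attr(out, "matrix") <- attr(m, "name")
  out
}

#' Intra-minus-inter delta contact matrix
#'
#' Entrywise difference between two contact matrices sharing labels,
#' typically contact energies inside the hydrophobic protein core minus
#' those for the same residue pair exposed to the polar surface
#' environment.
#'
#' @param intra,inter [contact_matrix()] objects.
#' @param name Label for the result.
#' @return A [contact_matrix()].
#' @export
delta_matrix <- function(intra, inter,
                         name = paste0(attr(intra, "name"), "-", attr(inter, "name"))) {
  stopifnot(inherits(intra, "contact_matrix"), inherits(inter, "contact_matrix"))
  contact_matrix(unclass(intra) - unclass(inter), name = name)
}

#' Correlation between two contact matrices
#'
#' Pearson correlation over matching entries of two matrices.  Because
#' the matrices are symmetric, only one copy of each pair is used by
#' default: the upper triangle plus the diagonal (210 entries).  The
#' entry set is configurable since published matrix-to-matrix
#' correlations do not always state their choice.
#'
#' @param m1,m2 [contact_matrix()] objects.
#' @param entries `"upper_diag"` (210 entries, default), `"upper"` (190,
#'   off-diagonal pairs only), or `"all"` (400, counts each pair twice).
#' @return List as from [pearson_test()] (two-tailed), plus `entries`
#'   and `n_entries`.
#' @export
matrix_correlation <- function(m1, m2, entries = c("upper_diag", "upper", "all")) {
  entries <- match.arg(entries)
  stopifnot(inherits(m1, "contact_matrix"), inherits(m2, "contact_matrix"))
  idx <- switch(entries,
                upper_diag = upper.tri(unclass(m1), diag = TRUE),
                upper = upper.tri(unclass(m1), diag = FALSE),
                all = matrix(TRUE, 20L, 20L))
  res <- pearson_test(unclass(m1)[idx], unclass(m2)[idx], alternative = "two.sided")
  res$entries <- entries
  res$n_entries <- sum(idx)
  res
}
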