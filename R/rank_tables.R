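## Inclusion-order rank tables: one positive integer rank per standard
## amino acid, ties allowed.  The built-in "consensus" table is the
## average rank over 40 published chronologies of amino-acid recruitment
## into the genetic code (Trifonov's compilation).

.CONSENSUS_RANKS <- c(
  A = 2L,  C = 16L, D = 3L,  E = 7L,  F = 17L,
  G = 1L,  H = 14L, I = 11L, K = 15L, L = 8L,
  M = 19L, N = 12L, P = 5L,  Q = 11L, R = 10L,
  S = 6L,  T = 8L,  V = 4L,  W = 20L, Y = 18L
)

#' Construct an inclusion-order rank table
#'
#' A rank table maps each of the 20 standard amino acids to a positive
#' integer giving its hypothesised chronological rank of inclusion in the
#' genetic code (1 = earliest).  Ties are allowed: distinct species may
#' share a rank.
#'
#' @param ranks Named numeric vector: names must cover the 20 standard
#'   one-letter codes exactly once; values must be positive integers.
#' @param name Label for the hypothesis the table encodes.
#' @return Integer vector of length 20 in [standard_amino_acids()] order,
#'   class `"rank_table"`, with a `name` attribute.
#' @seealso [consensus_ranks()], [load_rank_table()], [epoch_of()]
#' @export
#' @examples
#' rank_table(setNames(1:20, standard_amino_acids()), name = "bijective")
rank_table <- function(ranks, name = "user") {
  if (is.null(names(ranks))) {
    stop("rank table must be a named vector (names = one-letter amino-acid codes)")
  }
  nm <- toupper(names(ranks))
  unknown <- setdiff(nm, AA20)
  if (length(unknown) > 0L) {
    stop("unknown amino-acid code(s) in rank table: ", paste(unknown, collapse = ", "))
  }
  dup <- unique(nm[duplicated(nm)])
  if (length(dup) > 0L) {
    stop("duplicated amino-acid code(s) in rank table: ", paste(dup, collapse = ", "))
  }
  missing <- setdiff(AA20, nm)
  if (length(missing) > 0L) {
    stop("rank table is missing amino acid(s): ", paste(missing, collapse = ", "))
  }
  vals <- as.numeric(ranks)
  if (anyNA(vals) || any(vals < 1) || any(vals != round(vals))) {
    stop("ranks must be positive integers (ties allowed)")
  }
  out <- as.integer(vals)[match(AA20, nm)]
  names(out) <- AA20
  structure(out, name = as.character(name)[1], class = "rank_table")
}

#' Consensus inclusion-order ranks
#'
#' The built-in consensus chronology of amino-acid inclusion in the
#' genetic code, averaged over 40 published hypotheses: G is earliest
#' (rank 1), then A, D, V, P, S, E; W is most recent (rank 20).  Q and I
#' are tied at rank 11.
#'
#' @return A [rank_table()] named `"consensus"`.
#' @export
#' @examples
#' consensus_ranks()
consensus_ranks <- function() {
  rank_table(.CONSENSUS_RANKS, name = "consensus")
}

#' Load a rank table from file or from the built-in registry
#'
#' Reads a two-column table (amino acid, integer rank), tab- or
#' whitespace-separated, with or without a header line.  The single
#' registry name `"consensus"` returns the built-in consensus table.
#'
#' @param path Path to a two-column TSV, or the name `"consensus"`.
#' @param name Optional label; defaults to the file base name.
#' @return A validated [rank_table()].
#' @export
load_rank_table <- function(path, name = NULL) {
  if (identical(path, "consensus")) return(consensus_ranks())
  if (!file.exists(path)) stop("rank table file not found: ", path)
  tab <- read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE,
                    colClasses = "character", comment.char = "#")
  if (ncol(tab) < 2L) stop("rank table must have two columns (amino acid, rank): ", path)
  ## tolerate a header line such as "aa<TAB>rank"
  if (nrow(tab) > 0L && is.na(suppressWarnings(as.numeric(tab[1L, 2L])))) {
    tab <- tab[-1L, , drop = FALSE]
  }
  vals <- suppressWarnings(as.numeric(tab[[2L]]))
  if (anyNA(vals)) {
    bad <- tab[[1L]][is.na(vals)]
    stop("non-numeric rank for amino acid(s): ", paste(bad, collapse = ", "))
  }
  rank_table(setNames(vals, tab[[1L]]),
             name = if (is.null(name)) sub("\\.[^.]*$", "", basename(path)) else name)
}

#' Write a rank table to a two-column TSV
#'
#' @param ranks A [rank_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_rank_table <- function(ranks, path) {
  stopifnot(inherits(ranks, "rank_table"))
  write.table(data.frame(aa = names(ranks), rank = as.integer(ranks)),
              path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.rank_table <- function(x, ...) {
  cat("Inclusion-order rank table:", attr(x, "name"), "\n")
  print(setNames(as.integer(x), names(x)))
  invisible(x)
}

#' Early/recent dichotomy of a rank table
#'
#' Splits the 20 species into "early" (rank < 11) and "recent"
#' (rank > 10) epochs.  With the consensus table this is an exact 10/10
#' split; the tied species Q and I (rank 11) fall on the recent side.
#'
#' @param ranks A [rank_table()].
#' @return Named factor over the 20 species with levels
#'   `c("early", "recent")`.
#' @export
#' @examples
#' table(epoch_of(consensus_ranks()))
epoch_of <- function(ranks) {
  stopifnot(inherits(ranks, "rank_table"))
  factor(ifelse(as.integer(ranks) < 11L, "early", "recent"),
         levels = c("early", "recent")) |>
    setNames(names(ranks))
}
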