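## Per-protein positional statistics.
##
## A protein is an ordered string of one-letter residue codes; position 1
## is the residue encoded at the 5' initiation codon and position k the
## last residue before the stop signal.  Every residue of a species
## contributes its 1-based position; the species mean position divided by
## k ("std_mean") is comparable across proteins of different lengths.
## Residues outside the 20 standard codes (X, U, O, B, Z, ...) occupy
## positions and count toward k but are profiled in a separate
## nonstandard bucket, never in the 20 species columns.

.split_residues <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence)) {
    stop("expected a single protein sequence string")
  }
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  if (length(chars) == 0L) stop("empty protein sequence")
  chars
}

#' Residue positions by amino-acid species
#'
#' Assigns every residue its 1-based rank from the 5' end (1..k) and
#' groups ranks by species.  Nonstandard residues are collected under the
#' key `"other"`.
#'
#' @param sequence Protein sequence as a single character string.
#' @return Named list of integer vectors; the union of all vectors is
#'   `1:k`.
#' @export
#' @examples
#' residue_ranks("MAGHLMVTYRGTG")$M   # 1, 6
residue_ranks <- function(sequence) {
  chars <- .split_residues(sequence)
  species <- ifelse(chars %in% AA20, chars, "other")
  split(seq_along(chars), species)
}

#' Mean residue positions of a protein
#'
#' For each of the 20 standard species: the number of residues, the mean
#' of their 1-based positions (`mean_rank`), and the size-standardised
#' mean position `std_mean = mean_rank / k`.  Species absent from the
#' protein carry `NA`, never 0.  A `std_mean` below 0.5 means the species
#' sits, on average, in the 5' half of the gene.
#'
#' @param sequence Protein sequence string.
#' @param id Protein identifier stored in the result.
#' @return A `data.frame` (class `"position_profile"`) with columns
#'   `species`, `count`, `mean_rank`, `std_mean` and attributes
#'   `protein_id`, `k`, `other_count`, `other_mean_rank` (the nonstandard
#'   bucket).
#' @export
#' @examples
#' p <- mean_positions("MAGHLMVTYRGTG")
#' p[p$species == "M", ]   # mean_rank 3.5, std_mean 3.5/13
mean_positions <- function(sequence, id = "protein") {
  ranks <- residue_ranks(sequence)
  k <- sum(lengths(ranks))
  std <- ranks[names(ranks) %in% AA20]
  count <- setNames(integer(20L), AA20)
  count[names(std)] <- lengths(std)
  mean_rank <- setNames(rep(NA_real_, 20L), AA20)
  mean_rank[names(std)] <- vapply(std, mean, numeric(1))
  out <- data.frame(species = AA20, count = as.integer(count),
                    mean_rank = as.numeric(mean_rank),
                    std_mean = as.numeric(mean_rank) / k,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "protein_id") <- as.character(id)[1]
  attr(out, "k") <- k
  attr(out, "other_count") <- if (is.null(ranks$other)) 0L else length(ranks$other)
  attr(out, "other_mean_rank") <- if (is.null(ranks$other)) NA_real_ else mean(ranks$other)
  class(out) <- c("position_profile", "data.frame")
  out
}

#' Position profiles for a set of proteins
#'
#' Applies [mean_positions()] to every sequence and stacks the results in
#' long form, one row per protein and species.
#'
#' @param proteins Named character vector of protein sequences (names are
#'   protein identifiers).
#' @return `data.frame` with columns `protein_id`, `k`, `species`,
#'   `count`, `mean_rank`, `std_mean` (20 rows per protein).
#' @export
position_profiles <- function(proteins) {
  if (length(proteins) == 0L) stop("no protein sequences supplied")
  ids <- names(proteins)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("protein sequences must be named by identifier")
  }
  if (anyDuplicated(ids)) {
    stop("duplicated protein identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  rows <- lapply(ids, function(i) {
    p <- mean_positions(proteins[[i]], id = i)
    data.frame(protein_id = i, k = attr(p, "k"), p,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-protein correlation between inclusion rank and mean position
#'
#' Pearson correlation, over the species present in the protein, between
#' the species' inclusion-order rank and its size-standardised mean
#' position.  A negative r means recently included amino acids sit
#' 5'-ward of early ones.  The one-tailed P is for the negative
#' direction.  Degenerate inputs (fewer than 3 species present, or a
#' constant vector) return a flagged-missing result rather than an error.
#'
#' @param profile A [mean_positions()] profile, or one protein's rows
#'   from [position_profiles()].
#' @param ranks A [rank_table()].
#' @return List as from [pearson_test()], plus `n` = species used.
#' @export
#' @examples
#' protein_rank_correlation(mean_positions("MAGHLMVTYRGTG"), consensus_ranks())
protein_rank_correlation <- function(profile, ranks) {
  stopifnot(inherits(ranks, "rank_table"))
  if (!is.data.frame(profile) || !all(c("species", "count", "std_mean") %in% names(profile))) {
    stop("profile must be a position profile data frame")
  }
  if ("protein_id" %in% names(profile) && length(unique(profile$protein_id)) > 1L) {
    stop("profile contains more than one protein; correlate one protein at a time")
  }
  keep <- profile$count >= 1L & profile$species %in% AA20
  pearson_test(as.numeric(ranks[profile$species[keep]]),
               profile$std_mean[keep], alternative = "less")
}
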