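## Readers and writers: protein FASTA, profile tables, group manifests
## and covariate tables.  All computation stays at full precision; the
## x100 integer presentation used in report tables is applied only at
## write time, on request.

#' Read protein sequences from FASTA
#'
#' Identifiers are the first whitespace-delimited token of each header.
#' Trailing `*` stop symbols are stripped before the length k is
#' computed.  Duplicate identifiers and empty records are rejected;
#' content that looks like nucleotides (>= 95% A/C/G/T/N) triggers a
#' warning.
#'
#' @param path FASTA file path.
#' @return Named character vector of protein sequences.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("no records in FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) {
    stop("duplicated record identifier(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*+$", "", seqs)
  if (any(!nzchar(seqs))) {
    stop("empty record(s) after stop stripping: ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  chars <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1L]]
  if (mean(chars %in% c("A", "C", "G", "T", "N")) >= 0.95) {
    warning("sequences in ", path, " look like nucleotides (>= 95% A/C/G/T/N); ",
            "expected protein sequences")
  }
  setNames(seqs, ids)
}

#' Write protein sequences to FASTA
#'
#' @param proteins Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_protein_fasta <- function(proteins, path) {
  if (is.null(names(proteins))) stop("sequences must be named")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteins), path)
  invisible(path)
}

#' Write position profiles to a wide TSV
#'
#' One row per protein: identifier, length k, the 20 `std_mean` columns
#' and the 20 count columns.  With `times100 = TRUE` the `std_mean`
#' columns are multiplied by 100 and rounded to integers (presentation
#' format); the default writes full precision so that profiles round-trip
#' through [read_profiles()] exactly.
#'
#' @param profiles Long table from [position_profiles()].
#' @param path Output path.
#' @param times100 Apply the x100 integer presentation.
#' @return Invisibly, `path`.
#' @export
write_profiles <- function(profiles, path, times100 = FALSE) {
  ids <- unique(profiles$protein_id)
  std <- matrix(NA_real_, length(ids), 20L, dimnames = list(ids, AA20))
  cnt <- matrix(0L, length(ids), 20L, dimnames = list(ids, AA20))
  std[cbind(profiles$protein_id, profiles$species)] <- profiles$std_mean
  cnt[cbind(profiles$protein_id, profiles$species)] <- profiles$count
  kk <- profiles$k[match(ids, profiles$protein_id)]
  if (times100) std <- round(100 * std)
  out <- data.frame(protein_id = ids, k = kk, std,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[-(1:2)] <- paste0("std_", AA20)
  cntdf <- as.data.frame(cnt)
  names(cntdf) <- paste0("count_", AA20)
  out <- cbind(out, cntdf)
  write.table(format(out, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a wide profile TSV back into long form
#'
#' Inverse of [write_profiles()] (full-precision files only).
#'
#' @param path Profile TSV path.
#' @return Long `data.frame` as from [position_profiles()].
#' @export
read_profiles <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    count <- as.integer(tab[i, paste0("count_", AA20)])
    std <- as.numeric(tab[i, paste0("std_", AA20)])
    data.frame(protein_id = tab$protein_id[i], k = tab$k[i], species = AA20,
               count = count, mean_rank = std * tab$k[i], std_mean = std,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## two-column TSV with optional header; returns character matrix of 2 cols
.read_two_col <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  tab <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character", comment.char = "#")
  if (ncol(tab) < 2L) stop(what, " file must have two tab-separated columns: ", path)
  if (nrow(tab) > 1L && tolower(tab[1L, 1L]) %in% c("protein_id", "id", "protein")) {
    tab <- tab[-1L, , drop = FALSE]
  }
  tab
}

#' Read a group manifest
#'
#' Two-column TSV of (protein identifier, group name).
#'
#' @param path Manifest path.
#' @return Named character vector: protein identifier -> group name.
#' @export
read_group_table <- function(path) {
  tab <- .read_two_col(path, "group manifest")
  if (anyDuplicated(tab[[1L]])) {
    stop("protein(s) listed in more than one group: ",
         paste(unique(tab[[1L]][duplicated(tab[[1L]])]), collapse = ", "))
  }
  setNames(tab[[2L]], tab[[1L]])
}

#' Read a per-protein covariate table
#'
#' Two-column TSV of (protein identifier, numeric value).
#'
#' @param path Covariate file path.
#' @return Named numeric vector.
#' @export
read_covariate <- function(path) {
  tab <- .read_two_col(path, "covariate")
  vals <- suppressWarnings(as.numeric(tab[[2L]]))
  if (anyNA(vals)) {
    stop("non-numeric covariate value for: ",
         paste(tab[[1L]][is.na(vals)], collapse = ", "))
  }
  setNames(vals, tab[[1L]])
}
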