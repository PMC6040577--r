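## Group-level aggregation of position profiles: per-species counts of
## proteins with std_mean below the midpoint, sign tests, the R_n / R_m
## rank correlations, per-protein gradient correlations ("ro"), cross-
## group averaging and the early/recent majority test.

#' Summarise position profiles over a protein group
#'
#' For each of the 20 species, counts the proteins containing it
#' (`n_present`), those where its size-standardised mean position falls
#' strictly below 0.5 (`n_below`) or strictly above (`n_above`; a value
#' of exactly 0.5 counts for neither side), the group mean of `std_mean`,
#' and a two-tailed exact sign test of `n_below` against a fair split.
#' Two group-level correlations against inclusion rank are computed:
#' `R_n` (rank vs fraction of proteins below 0.5, one-tailed positive)
#' and `R_m` (rank vs group-mean `std_mean`, one-tailed negative).
#' Per-protein rank-vs-position correlations ("ro") use all species
#' present in that protein.
#'
#' @param profiles Long profile table from [position_profiles()]
#'   containing at least two proteins.
#' @param ranks A [rank_table()].
#' @param group Group label stored in the result.
#' @return List of class `"group_summary"`: `group`, `n_proteins`,
#'   `species` (per-species data frame), `R_n`, `R_m` (see
#'   [pearson_test()]), and `ro` (per-protein data frame with `r`,
#'   `p_one_tailed`, `n_species`).
#' @export
summarize_group <- function(profiles, ranks, group = "group") {
  stopifnot(inherits(ranks, "rank_table"))
  if (!is.data.frame(profiles) ||
      !all(c("protein_id", "species", "count", "std_mean") %in% names(profiles))) {
    stop("profiles must come from position_profiles()")
  }
  ids <- unique(profiles$protein_id)
  if (length(ids) < 2L) stop("a group needs at least 2 proteins")
  present <- profiles[profiles$count >= 1L, ]
  agg <- function(f) {
    v <- setNames(rep(NA_real_, 20L), AA20)
    got <- tapply(present$std_mean, factor(present$species, levels = AA20), f)
    v[names(got)] <- got
    v
  }
  n_present <- setNames(integer(20L), AA20)
  tab <- table(factor(present$species, levels = AA20))
  n_present[names(tab)] <- as.integer(tab)
  n_below <- agg(function(v) sum(v < 0.5))
  n_above <- agg(function(v) sum(v > 0.5))
  n_below[is.na(n_below)] <- 0; n_above[is.na(n_above)] <- 0
  mean_std <- agg(mean)
  p_two <- vapply(AA20, function(a) {
    if (n_present[a] == 0L) NA_real_
    else sign_test(n_below[a], n_present[a])$p_two_tailed
  }, numeric(1))
  species <- data.frame(
    species = AA20,
    n_present = as.integer(n_present),
    n_below = as.integer(n_below),
    n_above = as.integer(n_above),
    frac_below = ifelse(n_present > 0L, n_below / n_present, NA_real_),
    mean_std = as.numeric(mean_std),
    p_two_tailed = p_two,
    row.names = NULL, stringsAsFactors = FALSE
  )
  rk <- as.numeric(ranks[AA20])
  R_n <- pearson_test(rk, species$frac_below, alternative = "greater")
  R_m <- pearson_test(rk, species$mean_std, alternative = "less")
  ro <- do.call(rbind, lapply(ids, function(i) {
    res <- protein_rank_correlation(profiles[profiles$protein_id == i, ], ranks)
    data.frame(protein_id = i, r = res$r, p_one_tailed = res$p_one_tailed,
               n_species = res$n, row.names = NULL, stringsAsFactors = FALSE)
  }))
  structure(list(group = as.character(group)[1], n_proteins = length(ids),
                 species = species, R_n = R_n, R_m = R_m, ro = ro),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("Group '%s': %d proteins\n", x$group, x$n_proteins))
  cat(sprintf("  R_n = %.3f (one-tailed P = %.3g), R_m = %.3f (one-tailed P = %.3g)\n",
              x$R_n$r, x$R_n$p_one_tailed, x$R_m$r, x$R_m$p_one_tailed))
  cat(sprintf("  per-protein r ('ro'): %d of %d negative\n",
              sum(x$ro$r < 0, na.rm = TRUE), sum(!is.na(x$ro$r))))
  invisible(x)
}

#' Cross-group grand means of standardised positions
#'
#' Averages each species' group-mean `std_mean` over groups (unweighted
#' by default, so small groups count as much as large ones) and
#' correlates the grand means against inclusion rank.  One or more
#' species can be excluded from the correlation to probe the influence of
#' extreme points (e.g. methionine, which is dragged 5'-ward by the
#' initiator).
#'
#' @param summaries List of [summarize_group()] results.
#' @param ranks A [rank_table()].
#' @param exclude Optional species to drop from the correlation (the
#'   grand means themselves are always reported for all 20).
#' @param weights `"equal"` (default) averages group means without
#'   weighting; `"size"` weights each group mean by the number of
#'   proteins in which the species occurs.
#' @return List: `species` (data frame `species`, `grand_mean`), `test`
#'   (rank correlation, one-tailed negative), `excluded`, `weights`.
#' @export
cross_group_mean <- function(summaries, ranks, exclude = NULL,
                             weights = c("equal", "size")) {
  weights <- match.arg(weights)
  stopifnot(inherits(ranks, "rank_table"))
  if (length(summaries) < 1L || !all(vapply(summaries, inherits, logical(1), "group_summary"))) {
    stop("summaries must be a list of group_summary objects")
  }
  m <- vapply(summaries, function(s) s$species$mean_std, numeric(20L))
  w <- vapply(summaries, function(s) as.numeric(s$species$n_present), numeric(20L))
  m <- matrix(m, nrow = 20L); w <- matrix(w, nrow = 20L)
  grand <- if (weights == "equal") {
    rowMeans(m, na.rm = TRUE)
  } else {
    rowSums(m * w, na.rm = TRUE) / rowSums(w * !is.na(m))
  }
  grand[is.nan(grand)] <- NA_real_
  names(grand) <- AA20
  keep <- !(AA20 %in% exclude)
  test <- pearson_test(as.numeric(ranks[AA20][keep]), grand[keep], alternative = "less")
  list(species = data.frame(species = AA20, grand_mean = as.numeric(grand),
                            row.names = NULL, stringsAsFactors = FALSE),
       test = test, excluded = exclude, weights = weights)
}

#' Majority test of the early/recent positional prediction
#'
#' The positional prediction: species included early in the genetic code
#' (rank < 11) should have cross-group grand mean positions above 0.5
#' (3'-ward), recently included ones (rank > 10) below 0.5 (5'-ward).
#' Counts the conforming species (strict inequalities; a grand mean of
#' exactly 0.5 conforms for neither epoch) and applies the exact
#' one-tailed sign test on 20 trials.  Separately, per-species sign tests
#' on the pooled protein counts (one-tailed in each species' predicted
#' direction) are Fisher-combined within the early and the recent set.
#'
#' @param summaries List of [summarize_group()] results.
#' @param ranks A [rank_table()].
#' @param weights Passed to [cross_group_mean()].
#' @return List: `conforming` (named logical over species),
#'   `n_conforming`, `sign_test` (a [sign_test()] result),
#'   `fisher_early`, `fisher_recent` (see [fisher_combine()]), and
#'   `grand_mean`.
#' @export
epoch_majority_test <- function(summaries, ranks, weights = "equal") {
  stopifnot(inherits(ranks, "rank_table"))
  epoch <- epoch_of(ranks)
  cg <- cross_group_mean(summaries, ranks, weights = weights)
  grand <- setNames(cg$species$grand_mean, cg$species$species)
  if (anyNA(grand)) {
    stop("grand means unavailable for species: ",
         paste(names(grand)[is.na(grand)], collapse = ", "))
  }
  conforming <- (epoch == "early" & grand > 0.5) | (epoch == "recent" & grand < 0.5)
  st <- sign_test(sum(conforming), 20L)
  ## pooled per-species sign tests, one-tailed in the predicted direction
  pool <- Reduce(function(a, b) a + b,
                 lapply(summaries, function(s)
                   as.matrix(s$species[, c("n_present", "n_below", "n_above")])))
  rownames(pool) <- AA20
  p_species <- vapply(AA20, function(a) {
    succ <- if (epoch[a] == "early") pool[a, "n_above"] else pool[a, "n_below"]
    sign_test(succ, pool[a, "n_present"])$p_one_tailed
  }, numeric(1))
  list(conforming = conforming, n_conforming = st$s, sign_test = st,
       p_species = p_species,
       fisher_early = fisher_combine(p_species[epoch == "early"]),
       fisher_recent = fisher_combine(p_species[epoch == "recent"]),
       grand_mean = grand)
}

#' Correlate per-protein gradient strength with a covariate
#'
#' Pairs each protein's rank-vs-position correlation ("ro") with an
#' external per-protein covariate (e.g. ranked time spent single-stranded
#' as a mutation-rate proxy) and reports Pearson and Spearman
#' correlations, one-tailed in the negative direction (stronger gradients
#' — more negative ro — at higher covariate values).  Proteins lacking
#' either value are dropped and counted.
#'
#' @param per_protein_r Named numeric vector of per-protein correlations.
#' @param covariate Named numeric vector, names matched to
#'   `per_protein_r` by protein identifier.
#' @param name Covariate label.
#' @return List of class `"covariate_result"`: `covariate`, `n_used`,
#'   `n_dropped`, `pairs` (data frame), `pearson`, `spearman`.
#' @export
covariate_correlation <- function(per_protein_r, covariate, name = "covariate") {
  if (is.null(names(per_protein_r)) || is.null(names(covariate))) {
    stop("both vectors must be named by protein identifier")
  }
  ids <- intersect(names(per_protein_r), names(covariate))
  x <- per_protein_r[ids]; y <- covariate[ids]
  ok <- is.finite(x) & is.finite(y)
  n_dropped <- length(union(names(per_protein_r), names(covariate))) - sum(ok)
  pairs <- data.frame(protein_id = ids[ok], r = as.numeric(x[ok]),
                      covariate = as.numeric(y[ok]),
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(covariate = name, n_used = sum(ok), n_dropped = n_dropped,
                 pairs = pairs,
                 pearson = pearson_test(pairs$covariate, pairs$r, alternative = "less"),
                 spearman = spearman_test(pairs$covariate, pairs$r, alternative = "less")),
            class = "covariate_result")
}

#' @export
print.covariate_result <- function(x, ...) {
  cat(sprintf("Covariate '%s': %d proteins used, %d dropped\n",
              x$covariate, x$n_used, x$n_dropped))
  cat(sprintf("  Pearson r = %.3f (one-tailed P = %.3g); Spearman rs = %.3f (one-tailed P = %.3g)\n",
              x$pearson$r, x$pearson$p_one_tailed, x$spearman$r, x$spearman$p_one_tailed))
  invisible(x)
}
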