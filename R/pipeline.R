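## End-to-end pipeline: read inputs, profile proteins, aggregate groups,
## run the epoch majority test, optional covariate and contact-matrix
## analyses, and write report files plus a full-precision JSON summary.

#' Pipeline run configuration
#'
#' Validates input paths at construction time and creates the output
#' directory if absent.
#'
#' @param fasta Protein FASTA path (required).
#' @param outdir Output directory (required; created if absent).
#' @param groups Optional group-manifest TSV (protein id, group name).
#' @param ranks Rank-table path or `"consensus"` (default).
#' @param covariate Optional per-protein covariate TSV.
#' @param matrix,matrix2 Optional contact-matrix TSV paths; when both are
#'   given their delta matrix and mutual correlation are also analysed.
#' @param times100 Write presentation report tables with x100 rounding
#'   (full-precision companions are always written).
#' @param seed Integer seed recorded in the summary (the analysis itself
#'   is deterministic; the seed matters only if synthetic stages are
#'   added upstream).
#' @return List of class `"run_config"`.
#' @export
run_config <- function(fasta, outdir, groups = NULL, ranks = "consensus",
                       covariate = NULL, matrix = NULL, matrix2 = NULL,
                       times100 = TRUE, seed = 1L) {
  for (p in c(fasta, groups, covariate, matrix, matrix2)) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  if (!identical(ranks, "consensus") && !file.exists(ranks)) {
    stop("rank table not found: ", ranks)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  structure(list(fasta = fasta, outdir = outdir, groups = groups,
                 ranks = ranks, covariate = covariate, matrix = matrix,
                 matrix2 = matrix2, times100 = isTRUE(times100),
                 seed = as.integer(seed)),
            class = "run_config")
}

.cor_summary <- function(res) {
  res[intersect(names(res), c("r", "n", "p_one_tailed", "p_two_tailed",
                              "flagged", "reason", "entries", "n_entries"))]
}

## per-protein wide table of std_mean (x100 presentation) plus the "ro"
## rank-vs-position correlation, one group block per call
.write_group_report <- function(summary, profiles, path, times100) {
  ids <- summary$ro$protein_id
  std <- matrix(NA_real_, length(ids), 20L, dimnames = list(ids, AA20))
  sub <- profiles[profiles$protein_id %in% ids, ]
  std[cbind(sub$protein_id, sub$species)] <- sub$std_mean
  ro <- summary$ro$r
  if (times100) { std <- round(100 * std); ro <- round(100 * ro) }
  out <- data.frame(protein_id = ids, std, ro = ro,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[2:21] <- AA20
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

## species x group table of below-midpoint counts, reduced denominators,
## sign-test Ps and the R_n / R_m footer rows
.write_counts_report <- function(summaries, path, times100) {
  blocks <- lapply(summaries, function(s) {
    sp <- s$species
    p <- if (times100) round(100 * sp$p_two_tailed, 1) else sp$p_two_tailed
    b <- data.frame(n_below = sp$n_below, n_present = sp$n_present, p = p)
    names(b) <- paste0(s$group, c("_below", "_n", "_P"))
    b
  })
  out <- cbind(data.frame(species = AA20), do.call(cbind, blocks))
  footer <- do.call(cbind, lapply(summaries, function(s) {
    f <- function(v) if (times100) round(100 * v) else v
    data.frame(a = c(f(s$R_n$r), f(s$R_m$r)),
               b = NA, c = round(c(s$R_n$p_one_tailed, s$R_m$p_one_tailed), 4))
  }))
  footer <- cbind(data.frame(species = c("R_n", "R_m")), setNames(footer, names(out)[-1]))
  write.table(rbind(out, footer), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full positional-gradient pipeline
#'
#' Stages (in order, later stages only when configured): read FASTA and
#' rank table; per-protein profiles (full-precision TSV, plus a x100
#' presentation copy); per-group summaries with report tables in the
#' per-protein and count styles; cross-group grand means and the
#' early/recent majority test; covariate correlation of per-protein
#' gradients; contact-matrix focal correlations, delta matrix and
#' matrix-matrix correlation.  All numeric results are also written to
#' `summary.json` at full precision.  Progress and every dropped or
#' flagged record are reported via `message()`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all computed objects (`profiles`,
#'   `summaries`, `cross_group`, `epoch_test`, `covariate`, `contacts`,
#'   `files`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ranks <- load_rank_table(config$ranks)
  proteins <- read_protein_fasta(config$fasta)
  message("profile: ", length(proteins), " proteins from ", config$fasta)
  profiles <- position_profiles(proteins)
  files <- c(profiles = file.path(config$outdir, "profiles.tsv"))
  write_profiles(profiles, files[["profiles"]])
  if (config$times100) {
    files[["profiles_x100"]] <- file.path(config$outdir, "profiles_x100.tsv")
    write_profiles(profiles, files[["profiles_x100"]], times100 = TRUE)
  }
  results <- list(profiles = profiles, files = files)
  summary_json <- list(n_proteins = length(proteins),
                       ranks = attr(ranks, "name"), seed = config$seed)

  if (!is.null(config$groups)) {
    membership <- read_group_table(config$groups)
    unmatched <- setdiff(names(proteins), names(membership))
    if (length(unmatched)) {
      message("group: dropped ", length(unmatched),
              " protein(s) absent from the manifest: ",
              paste(unmatched, collapse = ", "))
    }
    missing <- setdiff(names(membership), names(proteins))
    if (length(missing)) {
      message("group: manifest entries with no sequence: ",
              paste(missing, collapse = ", "))
    }
    keep <- profiles$protein_id %in% names(membership)
    grp <- split(profiles[keep, ],
                 membership[profiles$protein_id[keep]])
    summaries <- list()
    for (g in names(grp)) {
      if (length(unique(grp[[g]]$protein_id)) < 2L) {
        message("group: skipping '", g, "' (fewer than 2 proteins)")
        next
      }
      s <- summarize_group(grp[[g]], ranks, group = g)
      message(sprintf("group '%s': %d proteins, R_m = %.3f", g, s$n_proteins, s$R_m$r))
      summaries[[g]] <- s
      f <- file.path(config$outdir, paste0("group_", g, "_proteins.tsv"))
      .write_group_report(s, profiles, f, config$times100)
      files[[paste0("group_", g)]] <- f
    }
    results$summaries <- summaries
    if (length(summaries) >= 1L) {
      files[["counts"]] <- file.path(config$outdir, "group_counts.tsv")
      .write_counts_report(summaries, files[["counts"]], config$times100)
      cg <- cross_group_mean(summaries, ranks)
      et <- epoch_majority_test(summaries, ranks)
      results$cross_group <- cg
      results$epoch_test <- et
      summary_json$groups <- lapply(summaries, function(s)
        list(n_proteins = s$n_proteins, R_n = .cor_summary(s$R_n),
             R_m = .cor_summary(s$R_m),
             ro = setNames(as.list(s$ro$r), s$ro$protein_id)))
      summary_json$cross_group <- list(
        grand_mean = setNames(as.list(cg$species$grand_mean), cg$species$species),
        test = .cor_summary(cg$test))
      summary_json$epoch_test <- list(
        n_conforming = et$n_conforming,
        p_one_tailed = et$sign_test$p_one_tailed,
        fisher_early = et$fisher_early, fisher_recent = et$fisher_recent)
    }
  }

  if (!is.null(config$covariate)) {
    if (is.null(results$summaries)) {
      stop("covariate analysis requires a group manifest (per-protein r values)")
    }
    ro_all <- do.call(rbind, lapply(results$summaries, `[[`, "ro"))
    cov <- read_covariate(config$covariate)
    cv <- covariate_correlation(setNames(ro_all$r, ro_all$protein_id), cov,
                                name = basename(config$covariate))
    message(sprintf("covariate: n = %d used, %d dropped, Pearson r = %.3f",
                    cv$n_used, cv$n_dropped, cv$pearson$r))
    results$covariate <- cv
    summary_json$covariate <- list(name = cv$covariate, n_used = cv$n_used,
                                   n_dropped = cv$n_dropped,
                                   pearson = .cor_summary(cv$pearson),
                                   spearman = .cor_summary(cv$spearman))
  }

  if (!is.null(config$matrix)) {
    m1 <- read_contact_matrix(config$matrix)
    fc1 <- focal_correlations(m1, ranks)
    files[["focal"]] <- file.path(config$outdir, "contact_focal.tsv")
    write.table(fc1, files[["focal"]], sep = "\t", quote = FALSE, row.names = FALSE)
    contacts <- list(focal = fc1)
    summary_json$contacts <- list(
      matrix = attr(m1, "name"),
      focal_r = setNames(as.list(fc1$r), fc1$species),
      n_negative = attr(fc1, "n_negative"))
    if (!is.null(config$matrix2)) {
      m2 <- read_contact_matrix(config$matrix2)
      contacts$focal2 <- focal_correlations(m2, ranks)
      contacts$delta <- delta_matrix(m1, m2)
      contacts$focal_delta <- focal_correlations(contacts$delta, ranks)
      contacts$correlation <- matrix_correlation(m1, m2)
      files[["delta"]] <- file.path(config$outdir, "contact_delta.tsv")
      write_contact_matrix(contacts$delta, files[["delta"]])
      summary_json$contacts$matrix2 <- attr(m2, "name")
      summary_json$contacts$delta_focal_r <-
        setNames(as.list(contacts$focal_delta$r), contacts$focal_delta$species)
      summary_json$contacts$matrix_correlation <- .cor_summary(contacts$correlation)
    }
    results$contacts <- contacts
  }

  files[["summary"]] <- file.path(config$outdir, "summary.json")
  jsonlite::write_json(summary_json, files[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  results$files <- files
  invisible(results)
}
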