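make_group <- function(n, k, beta, seed, mu = 0) {
  position_profiles(generate_proteins(gradient_config(n, k, beta = beta,
                                                      mu = mu, seed = seed)))
}

test_that("group summary counts use strict < 0.5 and per-protein presence", {
  rk <- consensus_ranks()
  prof <- position_profiles(c(p1 = WORKED_SEQ, p2 = WORKED_SEQ, p3 = WORKED_SEQ))
  s <- summarize_group(prof, rk, group = "worked")
  sp <- s$species
  # identical proteins: every species is below in all or none
  expect_true(all(sp$n_below %in% c(0L, s$n_proteins)))
  # M std_mean = 0.269 < 0.5 in every protein
  expect_equal(sp$n_below[sp$species == "M"], 3L)
  expect_equal(sp$n_present[sp$species == "M"], 3L)
  # species absent from the sequence contribute nothing
  expect_equal(sp$n_present[sp$species == "W"], 0L)
  expect_true(is.na(sp$mean_std[sp$species == "W"]))
  # a std_mean of exactly 0.5 counts for neither tail
  prof2 <- position_profiles(c(a = "CA", b = "CA"))  # A at 2/2 = 1, C at 1/2 = 0.5
  s2 <- summarize_group(prof2, rk)
  expect_equal(s2$species$n_below[s2$species$species == "C"], 0L)
  expect_equal(s2$species$n_above[s2$species$species == "C"], 0L)

  expect_error(summarize_group(prof[prof$protein_id == "p1", ], rk), "at least 2")
})

test_that("with identical proteins R_m equals the single-profile correlation", {
  rk <- consensus_ranks()
  prof <- position_profiles(c(p1 = WORKED_SEQ, p2 = WORKED_SEQ))
  s <- summarize_group(prof, rk)
  single <- protein_rank_correlation(mean_positions(WORKED_SEQ), rk)
  expect_equal(s$R_m$r, single$r, tolerance = 1e-12)
  expect_equal(s$ro$r, rep(single$r, 2), tolerance = 1e-12)
})

test_that("group summary is invariant to protein order", {
  rk <- consensus_ranks()
  prof <- make_group(8, 80, beta = 0.5, seed = 31)
  ids <- unique(prof$protein_id)
  shuffled <- do.call(rbind, lapply(rev(ids), function(i) prof[prof$protein_id == i, ]))
  s1 <- summarize_group(prof, rk)
  s2 <- summarize_group(shuffled, rk)
  expect_equal(s1$species, s2$species)
  expect_equal(s1$R_m$r, s2$R_m$r)
  expect_setequal(s1$ro$r, s2$ro$r)
})

test_that("null compositions give calibrated per-species sign tests", {
  rk <- consensus_ranks()
  set.seed(55)
  n_sig <- replicate(20, {
    base <- strsplit(random_protein(60), "")[[1]]
    seqs <- replicate(30, paste(sample(base), collapse = ""))
    names(seqs) <- sprintf("p%02d", 1:30)
    s <- summarize_group(position_profiles(seqs), rk)
    sum(s$species$p_two_tailed < 0.05, na.rm = TRUE)
  })
  # under the null roughly alpha of the 20 species tests reject
  expect_lt(mean(n_sig) / 20, 0.12)
})

test_that("n_below never exceeds presence and sums stay bounded", {
  rk <- consensus_ranks()
  prof <- make_group(10, 50, beta = 1, seed = 17)
  s <- summarize_group(prof, rk)
  expect_true(all(s$species$n_below <= s$species$n_present))
  expect_true(all(s$species$n_present <= s$n_proteins))
  expect_lte(sum(s$species$n_below), 20 * s$n_proteins)
})

test_that("cross-group means average groups and recover trivial correlations", {
  rk <- consensus_ranks()
  prof <- make_group(10, 100, beta = 0.8, seed = 5)
  s <- summarize_group(prof, rk, "g")
  cg <- cross_group_mean(list(s, s, s), rk)
  expect_equal(cg$species$grand_mean, s$species$mean_std)

  # grand means strictly decreasing in rank -> r = -1: fabricate summaries
  s2 <- s
  s2$species$mean_std <- 1 - 0.02 * as.numeric(rk)
  cg2 <- cross_group_mean(list(s2, s2), rk)
  expect_equal(cg2$test$r, -1)

  # leave-one-species-out drops the point from the correlation
  cg3 <- cross_group_mean(list(s, s), rk, exclude = "M")
  expect_equal(cg3$test$n, sum(!is.na(s$species$mean_std)) - 1L)
})

test_that("gradient groups yield negative cross-group correlation", {
  rk <- consensus_ranks()
  summaries <- lapply(1:4, function(i)
    summarize_group(make_group(30, 150, beta = 1, seed = 100 + i), rk,
                    group = paste0("g", i)))
  cg <- cross_group_mean(summaries, rk)
  expect_lt(cg$test$r, -0.5)
  expect_lt(cg$test$p_one_tailed, 0.01)
})

test_that("epoch majority test counts conformers and combines tails", {
  rk <- consensus_ranks()
  summaries <- lapply(1:2, function(i)
    summarize_group(make_group(40, 150, beta = 1, seed = 200 + i), rk,
                    group = paste0("g", i)))
  et <- epoch_majority_test(summaries, rk)
  # strong gradient: clear majority conforms, early/recent tails both extreme
  expect_gte(et$n_conforming, 15L)
  expect_equal(et$sign_test$p_one_tailed,
               sign_test(et$n_conforming, 20)$p_one_tailed)
  expect_lt(et$fisher_early$p, 1e-6)
  expect_lt(et$fisher_recent$p, 1e-6)
  expect_equal(et$fisher_early$df, 20L)

  # flipping epochs complements the count when no grand mean is exactly 0.5
  flipped <- rank_table(setNames(21L - as.integer(rk), names(rk)), "flipped")
  et_f <- epoch_majority_test(summaries, flipped)
  if (!any(et$grand_mean == 0.5)) {
    # flipped table also reverses which species are early, so conformity
    # inverts except for species whose epoch is unchanged (none here: the
    # consensus 10/10 split maps ranks 1..10 <-> 11..20)
    expect_equal(et_f$n_conforming, 20L - et$n_conforming)
  }
})

test_that("covariate correlation pairs by id, flags degeneracies, finds attenuation", {
  r_vals <- c(a = -0.5, b = -0.2, c = 0.1, d = 0.4)
  cv <- covariate_correlation(r_vals, c(d = 0.4, c = 0.1, b = -0.2, a = -0.5))
  expect_equal(cv$pearson$r, 1)
  expect_equal(cv$n_used, 4L)

  cv2 <- covariate_correlation(r_vals, c(a = 1, b = 1, c = 1, d = 1))
  expect_true(cv2$pearson$flagged)

  cv3 <- covariate_correlation(r_vals, c(a = 1, b = 2))
  expect_true(cv3$pearson$flagged)
  expect_equal(cv3$n_used, 2L)
  expect_equal(cv3$n_dropped, 2L)

  # 13 proteins whose substitution load mu decreases with the covariate:
  # high-covariate proteins keep their gradient, low-covariate ones lose
  # it, so per-protein r decreases (more negative) with the covariate
  rk <- consensus_ranks()
  cov <- setNames(1:13, sprintf("m%02d", 1:13))
  mu <- 0.9 * (13 - (1:13)) / 12
  ro <- vapply(1:13, function(i) {
    p <- generate_proteins(gradient_config(1, 400, beta = 1.5, mu = mu[i],
                                           seed = 300 + i))
    protein_rank_correlation(mean_positions(p[[1]]), rk)$r
  }, numeric(1))
  cv4 <- covariate_correlation(setNames(ro, names(cov)), cov)
  expect_lt(cv4$pearson$r, 0)
  expect_lt(cv4$spearman$r, 0)
  expect_lt(cv4$pearson$p_one_tailed, 0.05)
})
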