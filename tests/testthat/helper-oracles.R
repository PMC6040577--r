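# Independent oracles and small generators shared across test files.

AA <- standard_amino_acids()
WORKED_SEQ <- "MAGHLMVTYRGTG"  # 13-mer worked example: M@1,6; T@8,12; G@3,11,13

# direct covariance-formula Pearson r, independent of pearson_test()
brute_pearson <- function(x, y) {
  n <- length(x)
  sum((x - sum(x) / n) * (y - sum(y) / n)) /
    sqrt(sum((x - sum(x) / n)^2) * sum((y - sum(y) / n)^2))
}

# definitional recomputation of per-species mean positions: loop over
# positions, accumulate, divide -- no shared code with mean_positions()
oracle_mean_positions <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  k <- length(chars)
  out <- list()
  for (a in unique(chars[chars %in% AA])) {
    pos <- which(chars == a)
    out[[a]] <- list(count = length(pos), mean_rank = sum(pos) / length(pos),
                     std_mean = (sum(pos) / length(pos)) / k)
  }
  out
}

random_protein <- function(len, p_nonstandard = 0) {
  pool <- AA
  chars <- sample(pool, len, replace = TRUE)
  if (p_nonstandard > 0) {
    hit <- runif(len) < p_nonstandard
    chars[hit] <- sample(c("X", "U", "B", "Z"), sum(hit), replace = TRUE)
  }
  paste(chars, collapse = "")
}

reverse_seq <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
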