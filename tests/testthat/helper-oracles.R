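suppressPackageStartupMessages(library(SummarizedExperiment))

# Independent oracles used across the suite. Each is written from the
# textbook definition, deliberately naive, and never shares code with the
# package implementation it checks.

# Step-up Benjamini-Hochberg, naive O(n^2): adjusted p of item i is the
# smallest n*p_j/rank_j over all j with p_j >= p_i, capped at 1.
naive_bh <- function(p) {
  n <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(n), function(i) {
    cand <- n * p[p >= p[i]] / r[p >= p[i]]
    min(1, min(cand))
  }, numeric(1))
}

# Pooled two-sample t-test (equal variances), textbook formulas.
pooled_t_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), df = n1 + n2 - 2))
}

# Welch t-test from the Welch-Satterthwaite formulas.
welch_oracle <- function(a, b) {
  v1 <- var(a) / length(a); v2 <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(a) - 1) + v2^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Two-proportion chi-square with Yates correction on the 2x2 table.
prop_chisq_oracle <- function(x1, n1, x2, n2) {
  a <- x1; b <- n1 - x1; c <- x2; d <- n2 - x2
  N <- n1 + n2
  num <- N * (abs(a * d - b * c) - N / 2)^2
  den <- as.numeric(n1) * n2 * (a + c) * (b + d)
  stat <- num / den
  if (abs(a * d - b * c) <= N / 2) stat <- 0   # correction cannot overshoot
  pchisq(stat, df = 1, lower.tail = FALSE)
}

# Brute-force agglomerative clustering with complete linkage: clusters as
# index sets, inter-cluster distance = max pairwise, O(n^3).
complete_linkage_oracle <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      d <- max(D[clusters[[i]], clusters[[j]]])
      if (d < bestd) { bestd <- d; best <- c(i, j) }
    }
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Exhaustive-enumeration analogue of the family-wise permutation FDR on a
# tiny universe: the permutation distribution is replaced by ALL lists of
# the same size, then the same ratio and monotone step are applied.
exhaustive_family_fdr <- function(genes, sets, universe) {
  n <- length(genes); N <- length(universe)
  K <- vapply(sets, length, integer(1))
  ratio <- function(lst) {
    k <- vapply(sets, function(s) length(intersect(s, lst)), integer(1))
    (k / n) / (K / N)
  }
  E_obs <- ratio(genes)
  combos <- utils::combn(universe, n, simplify = FALSE)
  allE <- vapply(combos, ratio, numeric(length(sets)))
  allE <- matrix(allE, nrow = length(sets))
  fdr <- vapply(E_obs, function(e) {
    num <- mean(colSums(allE >= e))
    den <- sum(E_obs >= e)
    min(1, num / den)
  }, numeric(1))
  ord <- order(E_obs, decreasing = TRUE)
  fdr[ord] <- cummax(fdr[ord])
  list(E = E_obs, fdr = fdr)
}

# Small ResponseExperiment built directly from a matrix of condition
# means, bypassing the simulator.
tiny_experiment <- function(means, n_rep = 4, sd = 0.2, seed = 99,
                            strains = c("HW", "LnA", "LE", "LnC")) {
  set.seed(seed)
  cols <- expand.grid(rep = seq_len(n_rep),
                      treatment = c("control", "exposed"),
                      strain = strains, stringsAsFactors = FALSE)
  cond <- paste(cols$strain, cols$treatment, sep = ".")
  mat <- means[, cond, drop = FALSE] +
    matrix(rnorm(nrow(means) * nrow(cols), sd = sd), nrow(means))
  colnames(mat) <- sprintf("%s_%s_%d", cols$strain, cols$treatment, cols$rep)
  rownames(mat) <- rownames(means)
  ResponseExperiment(mat, strain = cols$strain, treatment = cols$treatment,
                     collectives = c(HW = "resistant", LnA = "resistant",
                                     LE = "sensitive", LnC = "sensitive"),
                     replicate = cols$rep)
}
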