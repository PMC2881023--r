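test_that("tri-state scoring follows sign and significance", {
  # induced Type-I gene, above-threshold repression, significant repression
  expect_identical(scoreGene(c(1.3e-4, 0.02, 3.0e-3), c(6.4, -3, -0.3)),
                   c(1L, 0L, -1L))
  expect_error(scoreGene(c(0.1, NA), c(1, 1)), "incomplete record")
  expect_error(scoreGene(0.1, c(1, 2)), "incomplete record")
  expect_error(scoreGene(0.1, 1, alpha = 1.5), "alpha")
  expect_warning(s <- scoreGene(1e-5, 0), "zero fold change")
  expect_identical(s, 0L)
})

test_that("the seven labels partition the 25-cell score grid", {
  grid <- expand.grid(R = -2:2, S = -2:2)
  lab <- classifyScores(grid$R, grid$S)
  expect_setequal(unique(lab), scoreClassLabels())
  tally <- table(lab)
  expect_equal(tally[["TYPE_I_UP"]], 1L)        # (2, 2)
  expect_equal(tally[["TYPE_I_DOWN"]], 1L)      # (-2, -2)
  expect_equal(tally[["TYPE_I_DISCORDANT"]], 2L)
  expect_equal(tally[["TYPE_II_RESISTANT"]], 2L)
  expect_equal(tally[["TYPE_II_SENSITIVE"]], 2L)
  expect_equal(tally[["UNRESPONSIVE"]], 1L)
  expect_equal(tally[["PARTIAL"]], 16L)

  expect_identical(classifyScores(2, 2), "TYPE_I_UP")
  expect_identical(classifyScores(0, 0), "UNRESPONSIVE")
  expect_identical(classifyScores(0, -2), "TYPE_II_SENSITIVE")
  expect_identical(classifyScores(2, -2), "TYPE_I_DISCORDANT")
  expect_error(classifyScores(3, 0), "contract violation")
})

test_that("two-way table counting equals a brute-force tally", {
  set.seed(51)
  df <- data.frame(R = sample(-2:2, 500, TRUE), S = sample(-2:2, 500, TRUE))
  tab <- as.matrix(buildTwoWayTable(df))
  for (r in -2:2) for (s in -2:2)
    expect_equal(tab[as.character(r), as.character(s)],
                 sum(df$R == r & df$S == s))
})

test_that("the published two-way table reproduces every derived count", {
  ov <- summarizeOverlap(publishedTwoWayCounts())
  expect_equal(ov$total, 8605L)
  expect_equal(ov$responsive_any, 452L)
  expect_equal(ov$responsive_sensitive, 412L)
  expect_equal(ov$responsive_resistant, 138L)
  expect_equal(ov$multi_strain, 144L)
  expect_equal(ov$type_I, 25L)
  expect_equal(ov$type_I_up, 20L)
  expect_equal(ov$type_I_down, 5L)
  expect_equal(ov$type_I_discordant, 0L)
  expect_equal(ov$type_II, 46L)
  expect_equal(ov$type_II_sensitive_only, 43L)
  expect_equal(ov$type_II_resistant_only, 3L)
  expect_equal(ov$overlap_within_resistant, 31L)
  expect_equal(ov$overlap_within_sensitive, 108L)
  expect_equal(round(100 * ov$overlap_resistant_frac, 1), 22.5)
  expect_equal(round(100 * ov$overlap_sensitive_frac, 1), 26.2)
})

test_that("overlap summary equals a brute-force recount of raw scores", {
  set.seed(61)
  strs <- c("HW", "LnA", "LE", "LnC")
  cm <- c(HW = "resistant", LnA = "resistant",
          LE = "sensitive", LnC = "sensitive")
  sc <- matrix(sample(c(-1L, 0L, 0L, 0L, 1L), 400 * 4, TRUE), 400, 4,
               dimnames = list(NULL, strs))
  R <- as.integer(rowSums(sc[, 1:2])); S <- as.integer(rowSums(sc[, 3:4]))
  gst <- new("GeneScoreTable",
             scores = data.frame(gene = paste0("g", 1:400), sc, R = R, S = S,
                                 T = R + S, label = classifyScores(R, S),
                                 check.names = FALSE),
             strains = strs, collectives = cm, alpha = 0.01)
  ov <- summarizeOverlap(gst)
  nz <- sc != 0L
  expect_equal(ov$responsive_any, sum(rowSums(nz) > 0))
  expect_equal(ov$multi_strain, sum(rowSums(nz) >= 2))
  expect_equal(ov$responsive_sensitive, sum(nz[, "LE"] | nz[, "LnC"]))
  expect_equal(ov$responsive_resistant, sum(nz[, "HW"] | nz[, "LnA"]))
  expect_equal(ov$overlap_within_sensitive, sum(nz[, "LE"] & nz[, "LnC"]))
  expect_equal(ov$overlap_within_resistant, sum(nz[, "HW"] & nz[, "LnA"]))
  expect_equal(ov$type_I, sum(abs(R + S) == 4))
  expect_equal(ov$type_II,
               sum((abs(R) == 2 & S == 0) | (R == 0 & abs(S) == 2)))
  expect_equal(ov$unresponsive, sum(R == 0 & S == 0))
})

test_that("collective score sums agree with per-strain scores end to end", {
  re <- generateDataset(simConfig(n_genes = 300, seed = 71))
  gs <- scoreGenes(runStrainContrasts(re))
  df <- as.data.frame(gs)
  expect_true(all(df$R == df$HW + df$LnA))
  expect_true(all(df$S == df$LE + df$LnC))
  expect_true(all(df$T == df$R + df$S))
  expect_identical(df$label, classifyScores(df$R, df$S))
})

test_that("proportion test matches the published value and the oracle", {
  pt1 <- proportionTest(31, 138, 108, 412)
  expect_equal(round(100 * pt1$p1, 1), 22.5)
  expect_equal(round(100 * pt1$p2, 1), 26.2)
  expect_gt(pt1$p_value, 0.42)
  expect_lt(pt1$p_value, 0.46)

  expect_equal(proportionTest(5, 10, 5, 10)$p_value, 1)
  expect_equal(proportionTest(5, 10, 9, 10)$p_value,
               prop_chisq_oracle(5, 10, 9, 10), tolerance = 1e-10)
  expect_error(proportionTest(-1, 10, 5, 10), "contract violation")
  expect_error(proportionTest(11, 10, 5, 10), "contract violation")

  # without continuity correction the p-value is noticeably smaller
  expect_lt(proportionTest(31, 138, 108, 412, correct = FALSE)$p_value,
            pt1$p_value)
})

test_that("threshold sweep is monotone and counts everything at alpha = 1", {
  re <- generateDataset(simConfig(n_genes = 250, seed = 81))
  sc <- runStrainContrasts(re)
  sw <- thresholdSweep(sc)
  expect_equal(sw$alpha[1], 1)
  for (s in c("HW", "LnA", "LE", "LnC")) {
    expect_equal(sw[[s]][1], 250L)           # alpha = 1 counts all genes
    expect_true(all(diff(sw[[s]]) <= 0L))    # tightening never adds genes
  }
})

test_that("extra sensitive-collective effects order the strain counts", {
  re <- generateDataset(simConfig(n_genes = 1500, seed = 91,
    class_counts = c(TYPE_I_UP = 20L, TYPE_I_DOWN = 5L,
                     TYPE_II_SENS_UP = 17L, TYPE_II_SENS_DOWN = 26L,
                     TYPE_II_RES_UP = 2L, TYPE_II_RES_DOWN = 1L,
                     SINGLE_STRAIN = 308L)))
  sw <- thresholdSweep(runStrainContrasts(re), neg_log10_grid = 2)
  expect_true(all(!is.null(sw$LE), !is.null(sw$HW)))
  expect_gt(min(sw$LE, sw$LnC), max(sw$HW, sw$LnA))
})
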