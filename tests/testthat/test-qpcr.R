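make_ct <- function(ct_target, ct_ref, groups) {
  n <- length(ct_target)
  data.frame(
    animal = rep(seq_len(n), 2),
    group = rep(groups, 2),
    gene = rep(c("Tgt", "Ref"), each = n),
    ct = c(ct_target, ct_ref))
}

test_that("delta-delta-Ct reproduces the textbook examples", {
  # equal target and reference in every animal: expression 1 everywhere
  tab <- make_ct(rep(22, 6), rep(22, 6), rep(c("control", "treated"), 3))
  out <- ddct(tab, "Tgt", "Ref", calibrator = "control")
  expect_true(all(out$expression == 1))

  # control (25, 20) vs treated (22, 20): treated expression 2^3 = 8
  tab2 <- make_ct(c(25, 25, 22, 22), c(20, 20, 20, 20),
                  c("control", "control", "treated", "treated"))
  out2 <- ddct(tab2, "Tgt", "Ref", calibrator = "control")
  expect_equal(out2$expression[out2$group == "treated"], c(8, 8))
  expect_equal(out2$expression[out2$group == "control"], c(1, 1))
})

test_that("expression matches a log-space oracle on random tables", {
  set.seed(151)
  for (i in 1:10) {
    n <- 8
    tab <- make_ct(runif(n, 18, 32), runif(n, 17, 22),
                   rep(c("control", "treated"), each = n / 2))
    out <- ddct(tab, "Tgt", "Ref", calibrator = "control")
    dct <- tab$ct[tab$gene == "Tgt"] - tab$ct[tab$gene == "Ref"]
    oracle <- exp(-log(2) * (dct - mean(dct[tab$group[1:n] == "control"])))
    expect_equal(out$expression, oracle, tolerance = 1e-12)
  }
})

test_that("ddct is invariant to per-animal Ct shifts and propagates ND", {
  set.seed(161)
  tab <- make_ct(runif(6, 20, 30), runif(6, 18, 20),
                 rep(c("control", "treated"), 3))
  base <- ddct(tab, "Tgt", "Ref", calibrator = "control")
  shift <- runif(6, -3, 3)                  # same shift hits both genes
  tab2 <- tab
  tab2$ct <- tab$ct + rep(shift, 2)
  expect_equal(ddct(tab2, "Tgt", "Ref", "control")$expression,
               base$expression, tolerance = 1e-12)

  nd <- tab
  nd$ct[1] <- NA                            # target below detection
  out <- ddct(nd, "Tgt", "Ref", "control")
  expect_true(is.na(out$expression[1]) && !out$detected[1])
  expect_false(anyNA(out$expression[-1]))

  miss <- tab
  miss$ct[7] <- NA                          # reference missing for animal 1
  expect_error(ddct(miss, "Tgt", "Ref", "control"), "record error")
})

test_that("percent-of-max scaling is anchored and ratio-preserving", {
  expect_equal(percentOfMax(c(3, 3), c("only", "only"))$mean_pct, 100)
  out <- percentOfMax(c(2, 2, 8, 8), c("lo", "lo", "hi", "hi"))
  expect_equal(out$mean_pct[out$group == "lo"], 25)
  expect_equal(out$mean_pct[out$group == "hi"], 100)

  set.seed(171)
  vals <- rlnorm(12); grp <- rep(c("a", "b", "c"), each = 4)
  out2 <- percentOfMax(vals, grp)
  mu <- tapply(vals, factor(grp, unique(grp)), mean)
  expect_equal(out2$mean_pct[1] / out2$mean_pct[2],
               unname(mu["a"] / mu["b"]), tolerance = 1e-12)
  expect_true(all(out2$mean_pct > 0 & out2$mean_pct <= 100))
  expect_equal(sum(out2$mean_pct == 100), 1L)
  expect_error(percentOfMax(c(NA_real_, NA_real_), c("a", "b")),
               "below detection")
})

test_that("Welch tests agree with the Welch-Satterthwaite oracle", {
  set.seed(181)
  for (i in 1:10) {
    a <- rnorm(4, sd = runif(1, 0.5, 2)); b <- rnorm(5, 1, runif(1, 0.5, 2))
    got <- groupTests(c(a, b), rep(c("g1", "g2"), c(4, 5)), mode = "rat")
    ora <- welch_oracle(a, b)
    expect_equal(got$p_value, ora$p, tolerance = 1e-10)
    expect_equal(abs(got$t), abs(ora$t), tolerance = 1e-10)
  }
  # symmetry in group order
  x <- c(1, 2, 3, 7, 8, 10); g <- rep(c("a", "b"), each = 3)
  expect_equal(groupTests(x, g)$p_value,
               groupTests(rev(x), rev(g))$p_value, tolerance = 1e-12)
  # identical constant groups: no evidence of difference
  expect_equal(groupTests(rep(2, 6), g)$p_value, 1)
  expect_error(groupTests(c(1, 2), c("a", "b")), "insufficient data")
})

test_that("significance tiers follow the 0.05/0.01/0.001 convention", {
  expect_identical(significanceTier(c(0.2, 0.03, 0.004, 2e-4)),
                   c("", "*", "**", "***"))
})

test_that("mouse-mode ANOVA is calibrated under the null and finds real differences", {
  set.seed(191)
  null_p <- vapply(1:500, function(i) {
    groupTests(rnorm(12), rep(c("a", "b", "c"), each = 4),
               mode = "mouse")$anova_p
  }, numeric(1))
  expect_gte(mean(null_p > 0.05), 0.92)

  real <- groupTests(c(rnorm(4), rnorm(4, 5), rnorm(4, 5)),
                     rep(c("ko_ctl", "wt_tcdd", "wt_ctl"), each = 4),
                     mode = "mouse")
  expect_lt(real$anova_p, 0.01)
  expect_equal(nrow(real$pairwise), 3L)
  expect_true(all(real$pairwise$tier[real$pairwise$p_adj < 0.05] != ""))
})

test_that("amplification efficiency comes from the dilution slope", {
  # slope of exactly -1/log10(2): perfect doubling, 100%
  perfect <- efficiencyCheck(c(30, 30 - log2(10), 30 - 2 * log2(10)),
                             c(0, 1, 2))
  expect_equal(perfect$efficiency_pct, 100, tolerance = 1e-9)
  expect_true(perfect$ok)

  # slope -3.6 gives 89.6%, outside the 90-110% window
  sl <- efficiencyCheck(c(30, 26.4, 22.8), c(0, 1, 2))
  expect_equal(sl$slope, -3.6, tolerance = 1e-9)
  expect_equal(sl$efficiency_pct, (10^(1 / 3.6) - 1) * 100, tolerance = 1e-9)
  expect_false(sl$ok)

  expect_error(efficiencyCheck(c(30, 27), c(0, 1)), "insufficient data")
})
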