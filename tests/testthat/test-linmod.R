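test_that("condition-means fit matches hand computation and least squares", {
  # 2 conditions x 2 samples, values {0,0} and {1,3}: means 0 and 2,
  # residual SS = 0+0+1+1 = 2 on 2 df, s2 = 1
  m <- matrix(c(0, 0, 1, 3), nrow = 1,
              dimnames = list("g1", paste0("s", 1:4)))
  re <- ResponseExperiment(m, strain = rep("HW", 4),
                           treatment = rep(c("control", "exposed"), each = 2),
                           collectives = c(HW = "resistant"))
  fit <- fitConditionModel(re)
  expect_equal(unname(fit$means[1, ]), c(0, 2))
  expect_equal(unname(fit$s2), 1)
  expect_equal(fit$df, 2)

  # against an lm() least-squares oracle on a random 8-condition design
  re2 <- tiny_experiment(matrix(rnorm(5 * 8), 5, 8,
    dimnames = list(paste0("g", 1:5),
                    as.vector(outer(c("HW", "LnA", "LE", "LnC"),
                                    c("control", "exposed"),
                                    function(a, b) paste(a, b, sep = "."))))),
    n_rep = 3, sd = 0.5, seed = 17)
  fit2 <- fitConditionModel(re2)
  cond <- paste(colData(re2)$strain, colData(re2)$treatment, sep = ".")
  for (g in 1:5) {
    lmfit <- lm(assay(re2)[g, ] ~ 0 + factor(cond))
    expect_equal(sort(unname(fit2$means[g, ])), sort(unname(coef(lmfit))),
                 tolerance = 1e-12)
    expect_equal(unname(fit2$s2[g]), summary(lmfit)$sigma^2,
                 tolerance = 1e-12)
  }
  expect_equal(fit2$df, ncol(re2) - 8)
})

test_that("a constant gene has equal means and zero residual variance", {
  m <- matrix(5, nrow = 2, ncol = 32)
  rownames(m) <- c("g1", "g2"); colnames(m) <- paste0("s", 1:32)
  cols <- expand.grid(rep = 1:4, treatment = c("control", "exposed"),
                      strain = c("HW", "LnA", "LE", "LnC"),
                      stringsAsFactors = FALSE)
  re <- ResponseExperiment(m, strain = cols$strain,
                           treatment = cols$treatment,
                           collectives = c(HW = "resistant", LnA = "resistant",
                                           LE = "sensitive", LnC = "sensitive"))
  fit <- fitConditionModel(re)
  expect_true(all(fit$means == 5))
  expect_equal(unname(fit$s2), c(0, 0))
})

test_that("moderation recovers the generating prior and obeys its limits", {
  set.seed(31)
  n <- 10000; d0 <- 4; s0 <- 0.05; df <- 24
  s2 <- (s0 * d0 / rchisq(n, d0)) * rchisq(n, df) / df
  fit <- moderateVariances(s2, df)
  expect_lt(abs(fit$d0 - d0) / d0, 0.10)
  expect_lt(abs(fit$s0_sq - s0) / s0, 0.10)

  # shrinkage direction: posterior moves toward s0_sq, never past it
  expect_true(all(sign(fit$s2_post - s2) == sign(fit$s0_sq - s2) |
                  s2 == fit$s0_sq))
  expect_true(all(fit$s2_post >= pmin(s2, fit$s0_sq) - 1e-12))
  expect_true(all(fit$s2_post <= pmax(s2, fit$s0_sq) + 1e-12))

  # homoskedastic input: infinite d0, all posteriors equal s0_sq
  hom <- moderateVariances(rep(0.3, 50), df = 10)
  expect_identical(hom$d0, Inf)
  expect_equal(hom$s2_post, rep(hom$s0_sq, 50))
  # the log-scale moment estimate of s0_sq, bias-corrected for chi-square
  # sampling: exp(log(0.3) - digamma(df/2) + log(df/2))
  expect_equal(hom$s0_sq, 0.3 * exp(log(5) - digamma(5)), tolerance = 1e-12)

  # forced d0 = 0: no moderation
  off <- moderateVariances(s2[1:100], df, d0 = 0)
  expect_identical(off$s2_post, s2[1:100])
  # forced d0 = Inf: all pinned at s0_sq
  pin <- moderateVariances(s2[1:100], df, d0 = Inf)
  expect_true(all(pin$s2_post == pin$s0_sq))

  expect_error(moderateVariances(rep(0, 50), df), "degenerate")
  expect_error(moderateVariances(s2[1:5], df), "at least 10")
})

test_that("moderation agrees with the established empirical-Bayes tool", {
  skip_if_not_installed("limma")
  set.seed(8)
  s2 <- (0.04 * 5 / rchisq(3000, 5)) * rchisq(3000, 24) / 24
  ours <- moderateVariances(s2, 24)
  ref <- limma::squeezeVar(s2, df = 24)
  expect_equal(ours$d0, ref$df.prior, tolerance = 1e-6)
  expect_equal(ours$s0_sq, ref$var.prior, tolerance = 1e-6)
  expect_equal(ours$s2_post, ref$var.post, tolerance = 1e-6)
})

test_that("moderated t has the stated null behaviour and monotonicity", {
  expect_equal(moderatedT(0, 0.1, 0.5, 4, 24)$p, 1)
  expect_equal(moderatedT(0, 0.1, 0.5, 4, 24)$t, 0)
  expect_error(moderatedT(1, 0.1, -0.5, 4, 24), "v must be > 0")

  # decreasing |beta| at fixed variance never decreases p
  betas <- seq(5, 0, by = -0.25)
  ps <- moderatedT(betas, 0.05, 0.5, 4, 24)$p
  expect_true(all(diff(ps) >= 0))

  # infinite d0 uses the Normal limit
  inf <- moderatedT(2, 0.05, 0.5, Inf, 24)
  expect_equal(inf$p, 2 * pnorm(-abs(inf$t)), tolerance = 1e-12)
})

test_that("with d0 = 0 the chain equals the ordinary pooled t-test", {
  re <- generateDataset(simConfig(n_genes = 60, seed = 19))
  sc <- runStrainContrasts(re, per_strain_fit = TRUE, d0 = 0)
  mat <- assay(re, "log2")
  cd <- colData(re)
  for (s in c("HW", "LE")) {
    res <- contrastResults(sc, s)
    ctl <- mat[, cd$strain == s & cd$treatment == "control", drop = FALSE]
    exp_ <- mat[, cd$strain == s & cd$treatment == "exposed", drop = FALSE]
    for (g in c(1, 17, 60)) {
      ora <- pooled_t_oracle(ctl[g, ], exp_[g, ])
      expect_equal(res$t[g], ora$t, tolerance = 1e-10)
      expect_equal(res$p[g], ora$p, tolerance = 1e-10)
    }
  }
})

test_that("moderated pipeline matches limma end to end on one strain", {
  skip_if_not_installed("limma")
  re <- generateDataset(simConfig(n_genes = 400, seed = 23))
  sc <- runStrainContrasts(re, per_strain_fit = TRUE)
  cd <- colData(re)
  s <- "LnC"
  sub <- assay(re, "log2")[, cd$strain == s]
  tr <- cd$treatment[cd$strain == s]
  design <- cbind(1, tr == "exposed")
  efit <- limma::eBayes(limma::lmFit(sub, design))
  expect_equal(unname(priorDf(sc)[s]), efit$df.prior, tolerance = 1e-6)
  expect_equal(contrastResults(sc, s)$t, unname(efit$t[, 2]),
               tolerance = 1e-6)
  expect_equal(contrastResults(sc, s)$p, unname(efit$p.value[, 2]),
               tolerance = 1e-6)
})

test_that("BH adjustment reproduces the worked example and the oracle", {
  expect_equal(adjustBH(0.05), 0.05)
  expect_equal(adjustBH(rep(0.03, 7)), rep(0.03, 7))
  expect_equal(adjustBH(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_error(adjustBH(c(0.5, 1.2)), "contract violation")

  set.seed(41)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(adjustBH(p), naive_bh(p), tolerance = 1e-14)
  }
})

test_that("null p-values are uniform and adjusted calls are controlled", {
  cfg <- simConfig(n_genes = 5000, seed = 29,
                   class_counts = c(SINGLE_STRAIN = 0L))
  sc <- runStrainContrasts(generateDataset(cfg))
  for (s in c("HW", "LnA", "LE", "LnC")) {
    res <- contrastResults(sc, s)
    expect_gt(suppressWarnings(ks.test(res$p, "punif"))$p.value, 0.01)
    bound <- 0.01 + 3 * sqrt(0.01 * 0.99 / 5000)
    expect_lte(mean(res$p_adj < 0.01), bound)
  }
})

test_that("a large planted effect is detected in all strains nearly always", {
  hits <- 0L; runs <- 100L
  for (i in seq_len(runs)) {
    cfg <- simConfig(n_genes = 200, seed = 1000L + i,
                     class_counts = c(TYPE_I_UP = 1L, SINGLE_STRAIN = 0L),
                     effect_size = c(TYPE_I = 6.4, TYPE_II = 1.4,
                                     SINGLE_STRAIN = 1.5))
    sc <- runStrainContrasts(generateDataset(cfg))
    sig <- vapply(contrastResults(sc),
                  function(df) df$p_adj[1] < 0.01, logical(1))
    hits <- hits + as.integer(all(sig))
  }
  expect_gte(hits, 99L)
})

test_that("contrasts refuse designs with missing groups", {
  m <- matrix(rnorm(16 * 12), 12, 16)
  rownames(m) <- paste0("g", 1:12); colnames(m) <- paste0("s", 1:16)
  # a strain whose exposed group is entirely absent must error
  re <- ResponseExperiment(m, strain = rep(c("HW", "LnA"), each = 8),
                           treatment = c(rep("control", 8),
                                         rep(c("control", "exposed"), 4)),
                           collectives = c(HW = "resistant",
                                           LnA = "resistant"))
  expect_error(runStrainContrasts(re), "design error")
})
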