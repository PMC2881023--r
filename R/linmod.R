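#' @importFrom stats p.adjust pt
NULL

#' Fit the condition-means linear model
#'
#' Fits one cell-means linear model over every (strain, treatment)
#' condition of the experiment: the fitted value for each sample is its
#' condition mean, and the residual variance of a gene pools squared
#' deviations across all conditions with `n_samples - n_conditions`
#' degrees of freedom (24 for the full 32-sample, 8-condition design).
#' With `per_strain = TRUE` the model is instead fitted inside each strain
#' separately (2 conditions, `2 * n_rep - 2` df per strain).
#'
#' @param x a [ResponseExperiment-class].
#' @param per_strain fit each strain's samples as its own model instead of
#'   pooling residual variance across all conditions.
#' @return For the pooled fit, a list with `means` (genes x conditions
#'   matrix, columns `strain.treatment`), `s2` (pooled residual variance),
#'   `df` (residual df), `n_per_condition`. For `per_strain = TRUE`, a
#'   named list of such fits, one per strain.
#' @examples
#' re <- generateDataset(simConfig(n_genes = 50, seed = 1))
#' fit <- fitConditionModel(re)
#' fit$df
#' @export
fitConditionModel <- function(x, per_strain = FALSE) {
  stopifnot(is(x, "ResponseExperiment"))
  if (per_strain) {
    out <- lapply(strains(x), function(s)
      condition_fit(x[, colData(x)$strain == s]))
    names(out) <- strains(x)
    return(out)
  }
  condition_fit(x)
}

condition_fit <- function(x) {
  cd <- colData(x)
  cond <- paste(cd$strain, cd$treatment, sep = ".")
  n_per <- table(cond)
  if (any(n_per < 2))
    stop("design error: condition(s) with < 2 samples: ",
         paste(names(n_per)[n_per < 2], collapse = ", "))
  mat <- assay(x, "log2")
  df <- ncol(mat) - length(n_per)
  if (df < 1)
    stop("design error: zero residual degrees of freedom")
  grp <- factor(cond, levels = names(n_per))
  means <- t(rowsum(t(mat), grp) / as.vector(n_per))
  resid <- mat - means[, as.character(grp), drop = FALSE]
  s2 <- rowSums(resid^2) / df
  list(means = means, s2 = s2, df = df, n_per_condition = n_per)
}

# Newton inversion of the trigamma function, y = trigamma(x) solved for x.
trigamma_inverse <- function(y, tol = 1e-8, maxit = 50L) {
  out <- y
  lo <- y < 1e-7           # trigamma(x) ~ 1/x for large x
  out[lo] <- 1 / y[lo]
  hi <- y > 1e7            # trigamma(x) ~ 1/x^2 + ... for small x
  out[hi] <- 1 / sqrt(y[hi])
  mid <- !lo & !hi
  x <- 0.5 + 1 / y[mid]
  if (any(mid)) {
    for (i in seq_len(maxit)) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (max(-dif / x) < tol) break
    }
    out[mid] <- x
  }
  out
}

#' Empirical-Bayes moderation of gene-wise variances
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0_sq`
#' of a scaled inverse-chi-square variance prior by moment matching on
#' `log(s2)` (the digamma/trigamma estimating equations of the standard
#' moderated-t methodology), then shrinks each gene's variance to the
#' posterior `s2_post = (d0 * s0_sq + df * s2) / (d0 + df)`.
#'
#' Zero sample variances are admitted through a documented offset: before
#' taking logs they are floored at `1e-10` times the mean positive
#' variance. If the trigamma equation has no positive solution (the
#' observed spread of `log(s2)` is no larger than chi-square sampling
#' noise alone), `d0` is infinite and every posterior variance equals
#' `s0_sq`. Forcing `d0 = 0` disables moderation (`s2_post = s2`);
#' forcing `d0 = Inf` pins all posterior variances at `s0_sq`.
#'
#' @param s2 numeric vector of residual variances (>= 10 finite values).
#' @param df residual degrees of freedom (scalar or per-gene).
#' @param d0 optional forced prior df, bypassing estimation.
#' @return list with `d0`, `s0_sq` and `s2_post`.
#' @examples
#' set.seed(1)
#' s2 <- 0.05 * 4 / rchisq(2000, 4) * rchisq(2000, 24) / 24
#' fit <- moderateVariances(s2, df = 24)
#' c(fit$d0, fit$s0_sq)
#' @export
moderateVariances <- function(s2, df, d0 = NULL) {
  s2 <- as.numeric(s2)
  if (sum(is.finite(s2) & s2 >= 0) < 10L)
    stop("need at least 10 finite non-negative variances")
  if (all(s2 == 0))
    stop("degenerate data: all variances are zero")
  df <- rep_len(as.numeric(df), length(s2))
  eps <- 1e-10 * mean(s2[s2 > 0])
  z <- log(pmax(s2, eps))
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  n <- length(e)
  rhs <- mean((e - ebar)^2 * n / (n - 1) - trigamma(df / 2))

  if (!is.null(d0)) {
    d0 <- as.numeric(d0)
    s0_sq <- if (is.finite(d0) && d0 > 0)
      exp(ebar + digamma(d0 / 2) - log(d0 / 2))
    else exp(ebar)
    post <- if (d0 == 0) s2
      else if (is.infinite(d0)) rep(s0_sq, length(s2))
      else (d0 * s0_sq + df * s2) / (d0 + df)
    return(list(d0 = d0, s0_sq = s0_sq, s2_post = post))
  }

  if (rhs > 0) {
    d0 <- 2 * trigamma_inverse(rhs)
    s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
    post <- (d0 * s0_sq + df * s2) / (d0 + df)
  } else {
    d0 <- Inf
    s0_sq <- exp(ebar)
    post <- rep(s0_sq, length(s2))
  }
  list(d0 = d0, s0_sq = s0_sq, s2_post = post)
}

#' Moderated t-statistic and two-sided p-value
#'
#' `t = beta / sqrt(s2_post * v)` referred to a Student t distribution
#' with `d0 + df` degrees of freedom (the ordinary `df` when `d0 = 0`;
#' the Normal limit when `d0` is infinite). P-values are two-sided and
#' clipped to `[1e-300, 1]`.
#'
#' @param beta estimated log2 fold changes.
#' @param s2_post posterior (moderated) variances, > 0.
#' @param v unscaled variance factor of the contrast (e.g. `1/n1 + 1/n2`),
#'   > 0.
#' @param d0 prior degrees of freedom (0, finite, or Inf).
#' @param df residual degrees of freedom of the fit.
#' @return list with `t` and `p`.
#' @examples
#' moderatedT(beta = 1, s2_post = 0.05, v = 0.5, d0 = 4, df = 24)
#' @export
moderatedT <- function(beta, s2_post, v, d0, df) {
  if (any(v <= 0)) stop("contract violation: v must be > 0")
  if (any(s2_post <= 0)) stop("contract violation: s2_post must be > 0")
  t <- beta / sqrt(s2_post * v)
  df_total <- if (is.infinite(d0)) Inf else d0 + df
  p <- 2 * pt(-abs(t), df = df_total)
  p <- pmin(pmax(p, 1e-300), 1)
  list(t = t, p = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with the usual cumulative-
#' minimum monotonicity enforcement, preserving the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @examples
#' adjustBH(c(0.005, 0.01, 0.03, 0.04))
#' @export
adjustBH <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("contract violation: p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Per-strain moderated contrasts of exposed vs control
#'
#' The full differential-expression chain: condition-means fit (pooled
#' residual variance by default), empirical-Bayes variance moderation,
#' moderated t for the within-strain exposed-minus-control contrast, and
#' Benjamini-Hochberg adjustment applied within each strain's contrast
#' separately (each strain is its own testing family, as the per-strain
#' gene lists are interpreted separately).
#'
#' @param x a [ResponseExperiment-class] containing all four strains.
#' @param alpha adjusted-p significance threshold recorded for downstream
#'   scoring (default 0.01).
#' @param per_strain_fit restrict the linear model (and the moderation) to
#'   each strain's own samples instead of pooling residual variance across
#'   all conditions.
#' @param d0 optional forced prior df passed to [moderateVariances()]
#'   (0 = no moderation).
#' @return A [StrainContrasts-class] object.
#' @examples
#' re <- generateDataset(simConfig(n_genes = 100, seed = 1))
#' sc <- runStrainContrasts(re)
#' head(contrastResults(sc, "LE"))
#' @export
runStrainContrasts <- function(x, alpha = 0.01, per_strain_fit = FALSE,
                               d0 = NULL) {
  stopifnot(is(x, "ResponseExperiment"))
  strs <- strains(x)
  cm <- collectiveMap(x)
  gene <- rownames(x)

  strain_result <- function(fit, s) {
    mexp <- paste(s, "exposed", sep = ".")
    mcon <- paste(s, "control", sep = ".")
    if (!all(c(mexp, mcon) %in% colnames(fit$means)))
      stop("design error: strain '", s, "' lacks a control or exposed group")
    beta <- fit$means[, mexp] - fit$means[, mcon]
    v <- 1 / fit$n_per_condition[[mexp]] + 1 / fit$n_per_condition[[mcon]]
    mt <- moderatedT(beta, pmax(fit$mod$s2_post, 1e-300), v,
                     fit$mod$d0, fit$df)
    data.frame(gene = gene, log2FC = unname(beta), t = unname(mt$t),
               p = unname(mt$p), p_adj = adjustBH(mt$p),
               s2 = unname(fit$s2), s2_post = unname(fit$mod$s2_post),
               row.names = NULL)
  }

  if (per_strain_fit) {
    fits <- fitConditionModel(x, per_strain = TRUE)
    fits <- lapply(fits, function(f) {
      f$mod <- moderateVariances(f$s2, f$df, d0 = d0); f
    })
    results <- lapply(strs, function(s) strain_result(fits[[s]], s))
    d0v <- vapply(fits, function(f) f$mod$d0, numeric(1))
    s0v <- vapply(fits, function(f) f$mod$s0_sq, numeric(1))
    dfv <- vapply(fits, function(f) f$df, numeric(1))
  } else {
    fit <- fitConditionModel(x)
    fit$mod <- moderateVariances(fit$s2, fit$df, d0 = d0)
    results <- lapply(strs, function(s) strain_result(fit, s))
    d0v <- fit$mod$d0; s0v <- fit$mod$s0_sq; dfv <- fit$df
  }
  names(results) <- strs
  new("StrainContrasts", results = results, d0 = d0v, s0_sq = s0v,
      df_residual = dfv, alpha = alpha, collectives = cm[strs])
}

#' Access per-strain contrast results
#'
#' @param x a [StrainContrasts-class].
#' @param strain a strain label, or `NULL` for the full named list.
#' @return data.frame (single strain) or named list of data.frames.
#' @name contrastResults
#' @aliases contrastResults,StrainContrasts-method
#' @export
setMethod("contrastResults", "StrainContrasts", function(x, strain = NULL) {
  if (is.null(strain)) return(x@results)
  if (!strain %in% names(x@results))
    stop("unknown strain: ", strain)
  x@results[[strain]]
})

#' Variance-prior accessors
#'
#' @param x a [StrainContrasts-class].
#' @return `priorDf()` the estimated/forced prior degrees of freedom,
#'   `priorVar()` the prior variance `s0_sq` (named per strain when the
#'   model was fitted per strain).
#' @name priorAccessors
#' @aliases priorDf,StrainContrasts-method priorVar,StrainContrasts-method
NULL

#' @rdname priorAccessors
#' @export
setMethod("priorDf", "StrainContrasts", function(x) x@d0)

#' @rdname priorAccessors
#' @export
setMethod("priorVar", "StrainContrasts", function(x) x@s0_sq)

setMethod("show", "StrainContrasts", function(object) {
  cat("StrainContrasts over", length(object@results), "strains,",
      nrow(object@results[[1]]), "genes\n")
  cat(sprintf("prior: d0 = %s, s0_sq = %s; residual df = %s\n",
              paste(signif(object@d0, 4), collapse = "/"),
              paste(signif(object@s0_sq, 4), collapse = "/"),
              paste(object@df_residual, collapse = "/")))
  nsig <- vapply(object@results,
                 function(df) sum(df$p_adj < object@alpha), integer(1))
  cat(sprintf("genes at p_adj < %g: %s\n", object@alpha,
              paste(names(nsig), nsig, sep = "=", collapse = ", ")))
  invisible(NULL)
})

#' Write per-strain contrast tables as TSV
#'
#' One file per strain (`contrast_<strain>.tsv`) with columns gene,
#' log2FC, t, p, p_adj, mirroring the fold-change / adjusted-p layout of
#' per-strain gene lists.
#'
#' @param x a [StrainContrasts-class].
#' @param dir output directory.
#' @return Invisibly, the paths written.
#' @export
writeContrasts <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(x@results), function(s) {
    p <- file.path(dir, paste0("contrast_", s, ".tsv"))
    utils::write.table(x@results[[s]][, c("gene", "log2FC", "t", "p", "p_adj")],
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}
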