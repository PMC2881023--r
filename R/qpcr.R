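#' @importFrom stats t.test aov lm coef pairwise.t.test
NULL

# Long-format Ct table: one row per (animal, gene) with columns animal,
# group, gene, ct; ct = NA means below detection (ND).
check_ct_table <- function(ct) {
  need <- c("animal", "group", "gene", "ct")
  if (!is.data.frame(ct) || !all(need %in% colnames(ct)))
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  if (any(ct$ct <= 0, na.rm = TRUE))
    stop("Ct values must be positive cycles (NA = below detection)")
  invisible(ct)
}

#' Delta-delta-Ct relative quantification
#'
#' Per animal: `dCt = Ct_target - Ct_reference`; `ddCt = dCt - mean(dCt)`
#' over the calibrator group; normalised expression `2^-ddCt`. Targets
#' below detection (NA Ct) propagate as NA and are never imputed; a
#' missing reference Ct for any animal carrying the target is an error.
#'
#' @param ct long-format data.frame with columns `animal`, `group`,
#'   `gene`, `ct` (NA = below detection).
#' @param target target gene ID.
#' @param reference reference (normalisation) gene ID, e.g. Actb or
#'   Gapdh.
#' @param calibrator group label whose mean dCt anchors the scale
#'   (typically the control group).
#' @return data.frame per animal: `animal`, `group`, `delta_ct`,
#'   `ddct`, `expression`, `detected`.
#' @examples
#' ct <- data.frame(
#'   animal = rep(1:4, each = 2), group = rep(c("control", "treated"), each = 4),
#'   gene = rep(c("Cyp1a1", "Actb"), 4),
#'   ct = c(25, 20, 25, 20, 22, 20, 22, 20))
#' ddct(ct, "Cyp1a1", "Actb", calibrator = "control")
#' @export
ddct <- function(ct, target, reference, calibrator) {
  check_ct_table(ct)
  tgt <- ct[ct$gene == target, ]
  ref <- ct[ct$gene == reference, ]
  if (!nrow(tgt)) stop("no rows for target gene '", target, "'")
  miss <- setdiff(tgt$animal, ref$animal[!is.na(ref$ct)])
  if (length(miss))
    stop("record error: no reference Ct for animal(s): ",
         paste(miss, collapse = ", "))
  ref_ct <- ref$ct[match(tgt$animal, ref$animal)]
  dct <- tgt$ct - ref_ct
  cal <- dct[tgt$group == calibrator & !is.na(dct)]
  if (!length(cal))
    stop("calibrator group '", calibrator, "' has no detected values")
  dd <- dct - mean(cal)
  data.frame(animal = tgt$animal, group = tgt$group,
             delta_ct = dct, ddct = dd, expression = 2^(-dd),
             detected = !is.na(tgt$ct), row.names = NULL)
}

#' Scale group means to percent of the maximum group
#'
#' Group means (below-detection values excluded) are rescaled so the
#' largest group mean is 100%; group SDs are rescaled by the same factor,
#' as in bar plots where the highest condition is set to 100%. Ties for
#' the maximum resolve to the first group in input order.
#'
#' @param expression numeric vector of per-animal normalised expression
#'   values (NA = below detection).
#' @param group group label per value.
#' @return data.frame per group: `group`, `n`, `mean_pct`, `sd_pct`.
#' @examples
#' percentOfMax(c(2, 2, 8, 8), c("a", "a", "b", "b"))
#' @export
percentOfMax <- function(expression, group) {
  stopifnot(length(expression) == length(group))
  keep <- !is.na(expression)
  if (!any(keep)) stop("all values below detection")
  group <- factor(group, levels = unique(group))
  mu <- tapply(expression[keep], group[keep], mean)
  sdv <- tapply(expression[keep], group[keep], sd)
  n <- tapply(expression[keep], group[keep], length)
  top <- mu[which.max(mu)]
  data.frame(group = names(mu), n = as.integer(n),
             mean_pct = as.numeric(100 * mu / top),
             sd_pct = as.numeric(100 * sdv / top), row.names = NULL)
}

#' Significance tier symbols
#'
#' @param p numeric p-values.
#' @return `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for
#'   p < 0.05, `""` otherwise.
#' @examples
#' significanceTier(c(0.2, 0.03, 0.004, 2e-4))
#' @export
significanceTier <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Group comparisons for qPCR expression values
#'
#' `mode = "rat"`: Welch's unequal-variance two-tailed t-test between
#' exactly two groups (control vs TCDD-treated within a strain). Two
#' groups that are both constant and equal yield t = 0, p = 1. `mode =
#' "mouse"`: one-way ANOVA over all groups followed by Bonferroni-
#' adjusted pairwise t-tests (pooled SD). Significance tiers at
#' 0.05 / 0.01 / 0.001 accompany every p-value.
#'
#' @param expression numeric vector of values (NA dropped).
#' @param group group label per value; exactly 2 groups in rat mode.
#' @param mode `"rat"` or `"mouse"`.
#' @return rat mode: list with `t`, `df`, `p_value`, `tier`. mouse mode:
#'   list with `anova_p`, `pairwise` (data.frame of Bonferroni-adjusted
#'   pairwise p-values with tiers).
#' @examples
#' groupTests(c(1, 2, 1.5, 5, 6, 7), rep(c("ctl", "tcdd"), each = 3))
#' @export
groupTests <- function(expression, group, mode = c("rat", "mouse")) {
  mode <- match.arg(mode)
  keep <- !is.na(expression)
  expression <- expression[keep]
  group <- factor(as.character(group)[keep])
  sizes <- table(group)
  if (length(sizes) < 2L || any(sizes < 2L))
    stop("insufficient data: need >= 2 groups with >= 2 values each")
  if (mode == "rat") {
    if (length(sizes) != 2L)
      stop("rat mode compares exactly 2 groups")
    a <- expression[group == levels(group)[1]]
    b <- expression[group == levels(group)[2]]
    if (sd(a) == 0 && sd(b) == 0) {
      p <- if (mean(a) == mean(b)) 1 else 0
      return(list(t = if (p == 1) 0 else Inf, df = NA_real_, p_value = p,
                  tier = significanceTier(p)))
    }
    ht <- t.test(a, b, var.equal = FALSE)
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, tier = significanceTier(ht$p.value))
  } else {
    fit <- aov(expression ~ group)
    pan <- summary(fit)[[1]][["Pr(>F)"]][1]
    pw <- pairwise.t.test(expression, group, p.adjust.method = "bonferroni",
                          pool.sd = TRUE)
    m <- pw$p.value
    idx <- which(!is.na(m), arr.ind = TRUE)
    pairwise <- data.frame(group1 = rownames(m)[idx[, 1]],
                           group2 = colnames(m)[idx[, 2]],
                           p_adj = m[idx],
                           tier = significanceTier(m[idx]),
                           row.names = NULL)
    list(anova_p = pan, pairwise = pairwise)
  }
}

#' Amplification efficiency from a serial dilution
#'
#' Least-squares slope of Ct against log10 input amount over a 10-fold
#' dilution series; efficiency is `(10^(-1/slope) - 1) * 100` percent
#' (slope -3.3219 is exactly 100%: a perfect doubling per cycle). Values
#' outside the conventional 90-110% window are flagged.
#'
#' @param ct Ct values of the dilution series (>= 3 points).
#' @param log10_input log10 template amounts, same length.
#' @return list with `slope`, `efficiency_pct` and `ok` (inside
#'   90-110%).
#' @examples
#' efficiencyCheck(c(30, 26.68, 23.36), c(0, 1, 2))
#' @export
efficiencyCheck <- function(ct, log10_input) {
  if (length(ct) < 3L || length(log10_input) != length(ct))
    stop("insufficient data: need >= 3 dilution points")
  slope <- unname(coef(lm(ct ~ log10_input))[2])
  eff <- (10^(-1 / slope) - 1) * 100
  list(slope = slope, efficiency_pct = eff, ok = eff >= 90 && eff <= 110)
}
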