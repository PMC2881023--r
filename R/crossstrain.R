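#' @importFrom stats prop.test
NULL

#' Tri-state score of a gene in one or more strains
#'
#' A gene scores +1 in a strain when significantly induced (adjusted
#' p < alpha and positive log2 fold change), -1 when significantly
#' repressed, and 0 otherwise. A fold change of exactly zero with a
#' significant adjusted p has no defined sign and scores 0 with a warning
#' (unreachable in practice with continuous data).
#'
#' @param p_adj adjusted p-values.
#' @param log2FC log2 fold changes, same length.
#' @param alpha significance threshold in (0, 1), default 0.01.
#' @return integer vector of scores in `{-1, 0, +1}`.
#' @examples
#' scoreGene(c(0.005, 0.02, 3e-3), c(6.4, -3, -0.3), alpha = 0.01)
#' @export
scoreGene <- function(p_adj, log2FC, alpha = 0.01) {
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single value in (0, 1)")
  if (length(p_adj) != length(log2FC))
    stop("incomplete record: p_adj and log2FC lengths differ")
  if (any(is.na(p_adj)) || any(is.na(log2FC)))
    stop("incomplete record: missing p_adj or log2FC value")
  sig <- p_adj < alpha
  if (any(sig & log2FC == 0))
    warning("significant gene(s) with exactly zero fold change scored 0")
  as.integer(sign(log2FC) * sig)
}

#' Classify genes from their collective score pair
#'
#' Pure function of the resistant-collective score R and sensitive-
#' collective score S (each in -2..2): total T = R + S of +4 is Type-I up,
#' -4 Type-I down; both collectives at full magnitude but opposite sign
#' (|R| = |S| = 2, T = 0) is the discordant Type-I corner; full response
#' in exactly one collective with silence in the other (|R| = 2, S = 0 or
#' R = 0, |S| = 2) is Type-II (resistant-only or sensitive-only); R = S =
#' 0 is unresponsive; everything else is a partial response. The seven
#' labels partition the 25-cell grid.
#'
#' @param R resistant-collective scores in -2..2 (vectorised).
#' @param S sensitive-collective scores in -2..2.
#' @return character vector of labels, see [scoreClassLabels()].
#' @examples
#' classifyScores(2, 2)    # TYPE_I_UP
#' classifyScores(0, -2)   # TYPE_II_SENSITIVE
#' @export
classifyScores <- function(R, S) {
  R <- as.integer(R); S <- as.integer(S)
  if (any(is.na(R)) || any(is.na(S)) || any(abs(R) > 2) || any(abs(S) > 2))
    stop("contract violation: collective scores must be integers in -2..2")
  T <- R + S
  out <- rep("PARTIAL", length(R))
  out[T == 4L] <- "TYPE_I_UP"
  out[T == -4L] <- "TYPE_I_DOWN"
  out[abs(R) == 2L & abs(S) == 2L & T == 0L] <- "TYPE_I_DISCORDANT"
  out[abs(R) == 2L & S == 0L] <- "TYPE_II_RESISTANT"
  out[R == 0L & abs(S) == 2L] <- "TYPE_II_SENSITIVE"
  out[R == 0L & S == 0L] <- "UNRESPONSIVE"
  out
}

#' Score every gene of a contrast set and classify it
#'
#' Applies [scoreGene()] per strain, sums scores within the resistant and
#' sensitive collectives, and attaches the [classifyScores()] label.
#'
#' @param x a [StrainContrasts-class].
#' @param alpha significance threshold; defaults to the one stored in `x`.
#' @return A [GeneScoreTable-class].
#' @examples
#' re <- generateDataset(simConfig(n_genes = 100, seed = 1))
#' gs <- scoreGenes(runStrainContrasts(re))
#' table(as.data.frame(gs)$label)
#' @export
scoreGenes <- function(x, alpha = NULL) {
  stopifnot(is(x, "StrainContrasts"))
  if (is.null(alpha)) alpha <- x@alpha
  strs <- names(x@results)
  gene <- x@results[[1]]$gene
  sc <- vapply(strs, function(s) {
    df <- x@results[[s]]
    if (!identical(df$gene, gene))
      stop("incomplete record: strains disagree on the gene universe")
    scoreGene(df$p_adj, df$log2FC, alpha)
  }, integer(length(gene)))
  res <- strs[x@collectives == "resistant"]
  sen <- strs[x@collectives == "sensitive"]
  R <- as.integer(rowSums(sc[, res, drop = FALSE]))
  S <- as.integer(rowSums(sc[, sen, drop = FALSE]))
  scores <- data.frame(gene = gene, sc, R = R, S = S, T = R + S,
                       label = classifyScores(R, S), row.names = NULL,
                       check.names = FALSE)
  new("GeneScoreTable", scores = scores, strains = strs,
      collectives = x@collectives, alpha = alpha)
}

#' @describeIn GeneScoreTable-class the underlying per-gene data.frame.
#' @param x a `GeneScoreTable`.
#' @param row.names,optional,... ignored, present for generic consistency.
#' @export
as.data.frame.GeneScoreTable <- function(x, row.names = NULL,
                                         optional = FALSE, ...) x@scores

setMethod("show", "GeneScoreTable", function(object) {
  cat("GeneScoreTable:", nrow(object@scores), "genes at alpha =",
      object@alpha, "\n")
  print(table(object@scores$label))
  invisible(NULL)
})

#' Build the 5 x 5 two-way table of collective scores
#'
#' Cross-classifies the gene universe by (resistant score, sensitive
#' score); rows are the resistant collective score -2..2, columns the
#' sensitive collective score.
#'
#' @param x a [GeneScoreTable-class], or a data.frame with columns `R`
#'   and `S`.
#' @return A [CrossTable-class].
#' @export
buildTwoWayTable <- function(x) {
  df <- if (is(x, "GeneScoreTable")) x@scores else x
  if (!all(c("R", "S") %in% colnames(df)))
    stop("need columns R and S")
  lv <- -2:2
  counts <- table(factor(df$R, levels = lv), factor(df$S, levels = lv))
  m <- matrix(as.integer(counts), 5L, 5L,
              dimnames = list(as.character(lv), as.character(lv)))
  new("CrossTable", counts = m)
}

#' Construct a CrossTable from a plain 5 x 5 count matrix
#'
#' @param counts 5 x 5 matrix of gene counts, rows = resistant score
#'   -2..2, columns = sensitive score -2..2.
#' @return A [CrossTable-class].
#' @export
crossTable <- function(counts) {
  m <- as.matrix(counts)
  dimnames(m) <- list(as.character(-2:2), as.character(-2:2))
  storage.mode(m) <- "integer"
  new("CrossTable", counts = m)
}

#' @describeIn CrossTable-class the 5 x 5 count matrix.
#' @param x a `CrossTable`.
#' @param ... ignored.
#' @export
as.matrix.CrossTable <- function(x, ...) x@counts

setMethod("show", "CrossTable", function(object) {
  cat("CrossTable (rows: resistant score, columns: sensitive score),",
      sum(object@counts), "genes\n")
  print(object@counts)
  invisible(NULL)
})

#' The published four-strain two-way score table
#'
#' The 5 x 5 cross-classification of the 8605-gene universe by collective
#' scores reported for the original four-strain hepatic TCDD study, as a
#' [CrossTable-class]; used to reproduce the derived overlap counts (452
#' responsive genes, 25 Type-I, 46 Type-II, ...).
#'
#' @return A [CrossTable-class] with 8605 genes.
#' @examples
#' summarizeOverlap(publishedTwoWayCounts())$responsive_any
#' @export
publishedTwoWayCounts <- function() {
  path <- system.file("extdata", "published_twoway_counts.tsv",
                      package = "DioxinScore", mustWork = TRUE)
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  crossTable(m)
}

#' Overlap and classification summary of a score table
#'
#' Derives from the two-way table (or, preferably, from the raw per-gene
#' scores) every headline count of the cross-strain comparison: genes
#' responsive in at least one strain, responsive within each collective,
#' genes altered in more than one strain, the within-collective overlap
#' counts and fractions, and the Type-I / Type-II breakdown with
#' direction splits.
#'
#' Counts that mean "the gene responded in a strain" (`responsive_*`,
#' `multi_strain`, `overlap_within_*`) are exact when computed from a
#' [GeneScoreTable-class], where the per-strain scores are available;
#' from a bare [CrossTable-class] they are inferred from the collective
#' sums (`S != 0`, `|S| = 2`, `|R| + |S| >= 2`, ...), which is identical
#' unless opposite-signed responses cancelled inside one collective.
#' Type-I/Type-II counts are functions of (R, S) in either case.
#'
#' @param x a [GeneScoreTable-class] or [CrossTable-class].
#' @return named list of counts and fractions.
#' @examples
#' ov <- summarizeOverlap(publishedTwoWayCounts())
#' c(ov$responsive_any, ov$type_I, ov$type_II)
#' @export
summarizeOverlap <- function(x) {
  raw <- NULL
  if (is(x, "GeneScoreTable")) {
    tab <- buildTwoWayTable(x)@counts
    raw <- as.matrix(x@scores[, x@strains, drop = FALSE]) != 0L
    res_cols <- x@collectives[x@strains] == "resistant"
  } else if (is(x, "CrossTable")) {
    tab <- x@counts
  } else stop("need a GeneScoreTable or CrossTable")

  Rv <- matrix(-2:2, 5, 5, byrow = FALSE)
  Sv <- matrix(-2:2, 5, 5, byrow = TRUE)
  total <- sum(tab)
  if (is.null(raw)) {
    grid <- expand.grid(R = -2:2, S = -2:2)
    multi <- sum(tab[abs(grid$R) + abs(grid$S) >= 2L])
    resp_any <- total - tab["0", "0"]
    resp_sens <- sum(tab[Sv != 0])
    resp_res <- sum(tab[Rv != 0])
    ov_sens <- sum(tab[abs(Sv) == 2])
    ov_res <- sum(tab[abs(Rv) == 2])
  } else {
    nres <- rowSums(raw[, res_cols, drop = FALSE])
    nsen <- rowSums(raw[, !res_cols, drop = FALSE])
    multi <- sum(nres + nsen >= 2L)
    resp_any <- sum(nres + nsen > 0L)
    resp_sens <- sum(nsen > 0L)
    resp_res <- sum(nres > 0L)
    ov_sens <- sum(nsen == 2L)
    ov_res <- sum(nres == 2L)
  }
  lab <- matrix(classifyScores(Rv, Sv), 5, 5)
  cnt <- function(l) sum(tab[lab == l])
  list(
    total = total,
    responsive_any = resp_any,
    responsive_sensitive = resp_sens,
    responsive_resistant = resp_res,
    multi_strain = multi,
    overlap_within_sensitive = ov_sens,
    overlap_within_resistant = ov_res,
    overlap_sensitive_frac = ov_sens / resp_sens,
    overlap_resistant_frac = ov_res / resp_res,
    type_I = cnt("TYPE_I_UP") + cnt("TYPE_I_DOWN"),
    type_I_up = cnt("TYPE_I_UP"),
    type_I_down = cnt("TYPE_I_DOWN"),
    type_I_discordant = cnt("TYPE_I_DISCORDANT"),
    type_II = cnt("TYPE_II_SENSITIVE") + cnt("TYPE_II_RESISTANT"),
    type_II_sensitive_only = cnt("TYPE_II_SENSITIVE"),
    type_II_resistant_only = cnt("TYPE_II_RESISTANT"),
    type_II_up = sum(tab[(lab == "TYPE_II_SENSITIVE" & Sv == 2) |
                         (lab == "TYPE_II_RESISTANT" & Rv == 2)]),
    type_II_down = sum(tab[(lab == "TYPE_II_SENSITIVE" & Sv == -2) |
                           (lab == "TYPE_II_RESISTANT" & Rv == -2)]),
    partial = cnt("PARTIAL"),
    unresponsive = cnt("UNRESPONSIVE")
  )
}

#' Two-proportion test with continuity correction
#'
#' Two-sided comparison of two binomial proportions by the chi-square
#' test with Yates continuity correction (the conventional "proportion
#' test"); the correction can be disabled.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @param correct apply the Yates continuity correction (default TRUE).
#' @return list with `p1`, `p2`, `statistic` and `p_value`.
#' @examples
#' proportionTest(31, 138, 108, 412)$p_value  # ~0.44
#' @export
proportionTest <- function(x1, n1, x2, n2, correct = TRUE) {
  if (n1 <= 0 || n2 <= 0 || x1 < 0 || x2 < 0 || x1 > n1 || x2 > n2)
    stop("contract violation: need 0 <= x_i <= n_i and n_i > 0")
  ht <- suppressWarnings(
    prop.test(c(x1, x2), c(n1, n2), correct = correct))
  list(p1 = x1 / n1, p2 = x2 / n2,
       statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Responsive-gene counts across a significance sweep
#'
#' Counts, per strain, the genes with adjusted p at or below each
#' threshold of a grid spanning `-log10(alpha)` from 0 to 5 (inclusive
#' comparison, so `alpha = 1` counts every gene). Counts are monotone
#' non-increasing as alpha decreases.
#'
#' @param x a [StrainContrasts-class].
#' @param neg_log10_grid grid of `-log10(alpha)` values, default
#'   `seq(0, 5, by = 0.25)`.
#' @return data.frame with columns `neg_log10_alpha`, `alpha`, one count
#'   column per strain.
#' @export
thresholdSweep <- function(x, neg_log10_grid = seq(0, 5, by = 0.25)) {
  stopifnot(is(x, "StrainContrasts"))
  alpha <- 10^(-neg_log10_grid)
  if (any(alpha <= 0 | alpha > 1))
    stop("alpha grid must lie in (0, 1]")
  counts <- vapply(names(x@results), function(s) {
    pa <- x@results[[s]]$p_adj
    vapply(alpha, function(a) sum(pa <= a), integer(1))
  }, integer(length(alpha)))
  counts <- matrix(counts, nrow = length(alpha),
                   dimnames = list(NULL, names(x@results)))
  data.frame(neg_log10_alpha = neg_log10_grid, alpha = alpha, counts,
             check.names = FALSE)
}

#' Write scoring outputs as plain-text files
#'
#' `scores.tsv` (gene, per-strain scores, R, S, T, label), the 5 x 5
#' `twoway_table.tsv` in published orientation, and `overlap.json` with
#' the [summarizeOverlap()] counts.
#'
#' @param x a [GeneScoreTable-class].
#' @param dir output directory.
#' @return Invisibly, the paths written.
#' @export
writeScores <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(scores = file.path(dir, "scores.tsv"),
             twoway = file.path(dir, "twoway_table.tsv"),
             overlap = file.path(dir, "overlap.json"))
  utils::write.table(x@scores, paths["scores"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tab <- buildTwoWayTable(x)@counts
  utils::write.table(data.frame(resistant_score = rownames(tab), tab,
                                check.names = FALSE),
                     paths["twoway"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(summarizeOverlap(x), paths["overlap"],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
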