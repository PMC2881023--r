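#' @importFrom stats hclust as.dist cor cutree as.hclust
#' @importFrom cluster diana
NULL

#' Variance filter and within-row standardisation
#'
#' Drops genes whose variance (sample convention, denominator n-1) does
#' not exceed `var_threshold`, then z-scores each retained row to mean 0
#' and SD 1 — the within-row scaling applied before expression heatmaps.
#'
#' @param x numeric matrix (genes x samples) or a
#'   [ResponseExperiment-class].
#' @param var_threshold variance threshold, strict `>` (default 0.1; the
#'   laxer 0.01 used in parts of the original analysis is accepted too).
#' @return A [ScaledMatrix-class].
#' @examples
#' m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
#' filterAndScale(m, var_threshold = 0)
#' @export
filterAndScale <- function(x, var_threshold = 0.1) {
  m <- if (is(x, "ResponseExperiment")) assay(x, "log2") else as.matrix(x)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need at least 2 genes and 2 samples")
  v <- apply(m, 1L, var)
  kept <- v > var_threshold
  if (!any(kept))
    stop("empty selection: no gene exceeds the variance threshold")
  sub <- m[kept, , drop = FALSE]
  scaled <- (sub - rowMeans(sub)) / apply(sub, 1L, sd)
  new("ScaledMatrix", scaled = scaled, kept = unname(kept),
      var_threshold = var_threshold)
}

setMethod("show", "ScaledMatrix", function(object) {
  cat("ScaledMatrix:", nrow(object@scaled), "of", length(object@kept),
      "genes retained (variance >", object@var_threshold, "),",
      ncol(object@scaled), "samples\n")
  invisible(NULL)
})

correlation_distance <- function(m) {
  if (ncol(m) < 2L) stop("need at least 2 samples")
  sdv <- apply(m, 2L, sd)
  if (any(sdv == 0))
    stop("distance undefined: zero-variance sample column(s): ",
         paste(colnames(m)[sdv == 0], collapse = ", "))
  d <- 1 - cor(m)
  d[d < 0] <- 0     # guard tiny negative rounding at perfect correlation
  diag(d) <- 0
  d
}

#' Hierarchical clustering of samples under 1 - Pearson r
#'
#' Pairwise sample distance is one minus the Pearson correlation of the
#' retained (scaled) gene profiles, so identical samples sit at distance
#' 0 and perfectly anticorrelated ones at 2. Agglomeration uses complete
#' linkage by default; a divisive (DIANA-style) mode is available since
#' the original description of the analysis mixes the two vocabularies.
#' Leaf order follows [stats::hclust]'s deterministic convention (ties
#' broken by the order of the distance matrix entries).
#'
#' @param x a [ScaledMatrix-class], [ResponseExperiment-class] (scaled
#'   with defaults first) or plain matrix of already-scaled values.
#' @param linkage agglomeration method for [stats::hclust]
#'   (default `"complete"`).
#' @param divisive use divisive clustering ([cluster::diana]) instead of
#'   agglomerative linkage.
#' @return A [SampleClustering-class]; its `hclust` slot holds merge
#'   heights and leaf order.
#' @examples
#' re <- generateDataset(simConfig(n_genes = 200, seed = 1))
#' hc <- hierarchicalCluster(filterAndScale(re, 0.01))
#' hc
#' @export
hierarchicalCluster <- function(x, linkage = "complete", divisive = FALSE) {
  m <- if (is(x, "ScaledMatrix")) x@scaled
       else if (is(x, "ResponseExperiment")) filterAndScale(x)@scaled
       else as.matrix(x)
  d <- correlation_distance(m)
  hc <- if (divisive) as.hclust(diana(as.dist(d), diss = TRUE))
        else hclust(as.dist(d), method = linkage)
  new("SampleClustering", hclust = hc, dist = d,
      method = if (divisive) "divisive" else linkage)
}

setMethod("show", "SampleClustering", function(object) {
  hc <- object@hclust
  cat("SampleClustering (", object@method, " linkage, 1 - Pearson r): ",
      nrow(object@dist), " samples\n", sep = "")
  cat("merge heights:", paste(signif(hc$height, 4), collapse = ", "), "\n")
  invisible(NULL)
})

#' Treatment separation at the root bipartition
#'
#' Cuts the tree into its two top-level clusters and scores how well that
#' bipartition separates the two treatment groups: the proportion of
#' samples on the majority-treatment side of their cluster, maximised
#' over the two cluster-to-treatment assignments. 1 means the root split
#' is exactly the treatment split; around 0.5 is chance for balanced
#' groups.
#'
#' @param clustering a [SampleClustering-class] (or hclust).
#' @param treatment character/factor of treatment labels, in the sample
#'   order of the clustered matrix.
#' @return numeric score in `[0, 1]`, or `NA` when fewer than two
#'   treatment groups are present.
#' @export
treatmentSeparationScore <- function(clustering, treatment) {
  hc <- if (is(clustering, "SampleClustering")) clustering@hclust
        else clustering
  treatment <- as.character(treatment)
  lv <- unique(treatment)
  if (length(lv) < 2L) return(NA_real_)
  if (length(lv) > 2L)
    stop("separation score is defined for two treatment groups")
  cl <- cutree(as.hclust(hc), k = 2L)
  acc <- mean((cl == 1L) == (treatment == lv[1]))
  max(acc, 1 - acc)
}

#' Export a clustering as plain-text tables
#'
#' Writes the merge table (`linkage.tsv`: merge index, children, height)
#' and the leaf order (`leaf_order.tsv`).
#'
#' @param clustering a [SampleClustering-class].
#' @param dir output directory.
#' @return Invisibly, the paths written.
#' @export
writeClustering <- function(clustering, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hc <- as.hclust(clustering@hclust)
  paths <- c(linkage = file.path(dir, "linkage.tsv"),
             order = file.path(dir, "leaf_order.tsv"))
  utils::write.table(
    data.frame(merge = seq_along(hc$height), left = hc$merge[, 1],
               right = hc$merge[, 2], height = hc$height),
    paths["linkage"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(position = seq_along(hc$order), sample = hc$labels[hc$order]),
    paths["order"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
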