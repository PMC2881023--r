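#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
NULL

GENE_CLASSES <- c("TYPE_I_UP", "TYPE_I_DOWN",
                  "TYPE_II_SENS_UP", "TYPE_II_SENS_DOWN",
                  "TYPE_II_RES_UP", "TYPE_II_RES_DOWN",
                  "SINGLE_STRAIN", "NULL")

SCORE_LABELS <- c("TYPE_I_UP", "TYPE_I_DOWN", "TYPE_I_DISCORDANT",
                  "TYPE_II_SENSITIVE", "TYPE_II_RESISTANT",
                  "PARTIAL", "UNRESPONSIVE")

#' Configuration for the synthetic four-strain dioxin experiment
#'
#' A `SimConfig` holds every knob of the synthetic-data generator: the size
#' of the gene universe, the replication of the 4-strain x 2-treatment
#' design, the number of genes planted in each response class, the log2
#' fold-change magnitude per class, and the scaled inverse-chi-square prior
#' from which gene-wise variances are drawn.
#'
#' @slot n_genes number of genes in the simulated universe.
#' @slot n_replicates animals per (strain, treatment) condition.
#' @slot strains four strain labels, ordered.
#' @slot collectives named character mapping each strain to `"resistant"`
#'   or `"sensitive"`; exactly two strains per collective.
#' @slot class_counts named integer vector of planted gene counts per
#'   response class (see [geneClassLabels()]); classes not listed default
#'   to zero and the remainder of the universe is `NULL` (unresponsive).
#' @slot effect_size named numeric: |log2 fold change| planted for
#'   `TYPE_I`, `TYPE_II` and `SINGLE_STRAIN` genes.
#' @slot d0 prior degrees of freedom of the variance prior.
#' @slot s0_sq prior variance (log2-intensity squared).
#' @slot baseline_mean_range interval from which gene baseline means are
#'   drawn uniformly (log2 intensity).
#' @slot strain_shift_sd SD of Normal gene-by-strain baseline offsets.
#' @slot seed integer RNG seed.
#' @seealso [simConfig()], [generateDataset()]
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    n_genes = "integer",
    n_replicates = "integer",
    strains = "character",
    collectives = "character",
    class_counts = "integer",
    effect_size = "numeric",
    d0 = "numeric",
    s0_sq = "numeric",
    baseline_mean_range = "numeric",
    strain_shift_sd = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- NULL
  bad <- function(field, why) sprintf("configuration error in '%s': %s", field, why)
  if (length(object@n_genes) != 1L || is.na(object@n_genes) || object@n_genes < 1L)
    msg <- c(msg, bad("n_genes", "must be a single positive integer"))
  if (length(object@n_replicates) != 1L || is.na(object@n_replicates) ||
      object@n_replicates < 2L)
    msg <- c(msg, bad("n_replicates", "must be >= 2"))
  if (length(object@strains) != 4L || anyDuplicated(object@strains))
    msg <- c(msg, bad("strains", "exactly 4 distinct strain labels required"))
  if (!setequal(names(object@collectives), object@strains) ||
      !all(object@collectives %in% c("resistant", "sensitive")) ||
      sum(object@collectives == "resistant") != 2L)
    msg <- c(msg, bad("collectives",
      "must map the 4 strains to 'resistant'/'sensitive', 2 strains each"))
  if (!all(names(object@class_counts) %in% GENE_CLASSES))
    msg <- c(msg, bad("class_counts", paste("unknown class label(s):",
      paste(setdiff(names(object@class_counts), GENE_CLASSES), collapse = ", "))))
  if (any(object@class_counts < 0L))
    msg <- c(msg, bad("class_counts", "counts must be non-negative"))
  planted <- sum(object@class_counts[setdiff(names(object@class_counts), "NULL")])
  if (!is.na(object@n_genes) && planted > object@n_genes)
    msg <- c(msg, bad("class_counts", "planted classes exceed n_genes"))
  if (!all(c("TYPE_I", "TYPE_II", "SINGLE_STRAIN") %in% names(object@effect_size)) ||
      any(object@effect_size < 0))
    msg <- c(msg, bad("effect_size",
      "needs non-negative entries TYPE_I, TYPE_II, SINGLE_STRAIN"))
  if (length(object@d0) != 1L || is.na(object@d0) || object@d0 <= 0)
    msg <- c(msg, bad("d0", "must be > 0"))
  if (length(object@s0_sq) != 1L || is.na(object@s0_sq) || object@s0_sq <= 0)
    msg <- c(msg, bad("s0_sq", "must be > 0"))
  if (length(object@baseline_mean_range) != 2L ||
      diff(object@baseline_mean_range) < 0)
    msg <- c(msg, bad("baseline_mean_range", "must be an increasing interval"))
  if (length(object@strain_shift_sd) != 1L || object@strain_shift_sd < 0)
    msg <- c(msg, bad("strain_shift_sd", "must be >= 0"))
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, bad("seed", "must be a single integer"))
  if (is.null(msg)) TRUE else msg
})

#' Per-strain moderated differential-expression contrasts
#'
#' Container for the exposed-vs-control contrast of every gene in every
#' strain: log2 fold change, moderated t, raw and Benjamini-Hochberg
#' adjusted p-values, together with the empirical-Bayes variance prior
#' estimated from the data.
#'
#' @slot results named list (one element per strain) of data.frames with
#'   columns `gene`, `log2FC`, `t`, `p`, `p_adj`, `s2`, `s2_post`.
#' @slot d0 estimated (or forced) prior degrees of freedom; named vector
#'   when the model was fitted per strain.
#' @slot s0_sq estimated prior variance, same shape as `d0`.
#' @slot df_residual residual degrees of freedom of the linear model.
#' @slot alpha adjusted-p significance threshold carried for scoring.
#' @slot collectives named character, strain -> collective.
#' @exportClass StrainContrasts
setClass("StrainContrasts",
  representation(
    results = "list",
    d0 = "numeric",
    s0_sq = "numeric",
    df_residual = "numeric",
    alpha = "numeric",
    collectives = "character"
  )
)

setValidity("StrainContrasts", function(object) {
  msg <- NULL
  if (length(object@results) < 1L || is.null(names(object@results)))
    msg <- c(msg, "results must be a named per-strain list")
  need <- c("gene", "log2FC", "t", "p", "p_adj")
  for (nm in names(object@results)) {
    df <- object@results[[nm]]
    if (!is.data.frame(df) || !all(need %in% colnames(df)))
      msg <- c(msg, sprintf("results[['%s']] lacks columns %s", nm,
                            paste(need, collapse = ", ")))
  }
  if (is.null(msg)) TRUE else msg
})

#' Tri-state gene scores and Type-I/Type-II classification
#'
#' One row per gene: the four per-strain tri-state scores (-1 repressed, 0
#' unaltered, +1 induced at the adjusted-p threshold), the two collective
#' sums R (resistant) and S (sensitive), their total T, and the response
#' class label derived from (R, S).
#'
#' @slot scores data.frame with columns `gene`, one score column per
#'   strain, `R`, `S`, `T`, `label`.
#' @slot strains the four strain labels (column names of the score block).
#' @slot collectives named character, strain -> collective.
#' @slot alpha the adjusted-p threshold used.
#' @exportClass GeneScoreTable
setClass("GeneScoreTable",
  representation(
    scores = "data.frame",
    strains = "character",
    collectives = "character",
    alpha = "numeric"
  )
)

setValidity("GeneScoreTable", function(object) {
  msg <- NULL
  need <- c("gene", object@strains, "R", "S", "T", "label")
  if (!all(need %in% colnames(object@scores)))
    msg <- c(msg, "scores must contain gene, per-strain, R, S, T, label columns")
  else {
    sc <- as.matrix(object@scores[, object@strains, drop = FALSE])
    if (!all(sc %in% c(-1L, 0L, 1L)))
      msg <- c(msg, "per-strain scores must be in {-1, 0, +1}")
    res <- names(object@collectives)[object@collectives == "resistant"]
    sen <- names(object@collectives)[object@collectives == "sensitive"]
    if (!isTRUE(all(object@scores$R == rowSums(sc[, res, drop = FALSE]))) ||
        !isTRUE(all(object@scores$S == rowSums(sc[, sen, drop = FALSE]))))
      msg <- c(msg, "R/S must equal the within-collective score sums")
  }
  if (is.null(msg)) TRUE else msg
})

#' Two-way table of genes by collective scores
#'
#' The 5 x 5 cross-classification of the gene universe by (resistant
#' collective score, sensitive collective score), each in -2..2. Rows are
#' the resistant score, columns the sensitive score.
#'
#' @slot counts 5 x 5 integer matrix with dimnames "-2".."2".
#' @exportClass CrossTable
setClass("CrossTable", representation(counts = "matrix"))

setValidity("CrossTable", function(object) {
  m <- object@counts
  lv <- as.character(-2:2)
  if (!all(dim(m) == c(5L, 5L)))
    return("counts must be 5 x 5")
  if (!identical(rownames(m), lv) || !identical(colnames(m), lv))
    return("dimnames must be -2..2 (rows resistant, columns sensitive)")
  if (any(m < 0) || any(m != round(m)))
    return("counts must be non-negative integers")
  TRUE
})

#' Gene-category annotation map for enrichment analysis
#'
#' Categories (e.g. GO terms) restricted to a gene universe; categories
#' with fewer than `min_size` member genes in the universe are dropped at
#' construction.
#'
#' @slot sets named list of character vectors of gene IDs (already
#'   intersected with the universe).
#' @slot universe character vector of eligible gene IDs.
#' @slot min_size minimum category size applied at construction.
#' @exportClass AnnotationMap
setClass("AnnotationMap",
  representation(sets = "list", universe = "character", min_size = "integer"))

setValidity("AnnotationMap", function(object) {
  msg <- NULL
  if (anyDuplicated(object@universe))
    msg <- c(msg, "universe contains duplicated gene IDs")
  if (length(object@sets) && is.null(names(object@sets)))
    msg <- c(msg, "sets must be named by category ID")
  for (nm in names(object@sets)) {
    s <- object@sets[[nm]]
    if (!all(s %in% object@universe))
      msg <- c(msg, sprintf("category '%s' has genes outside the universe", nm))
    if (length(s) < object@min_size)
      msg <- c(msg, sprintf("category '%s' smaller than min_size", nm))
  }
  if (is.null(msg)) TRUE else msg
})

#' Variance-filtered, row-standardised expression matrix
#'
#' Result of the pre-clustering filter: genes whose variance exceeds the
#' threshold, each row centred to mean 0 and scaled to SD 1.
#'
#' @slot scaled numeric matrix of z-scored retained genes x samples.
#' @slot kept logical mask over the input genes (TRUE = retained).
#' @slot var_threshold the variance threshold applied (strict >).
#' @exportClass ScaledMatrix
setClass("ScaledMatrix",
  representation(scaled = "matrix", kept = "logical", var_threshold = "numeric"))

setValidity("ScaledMatrix", function(object) {
  m <- object@scaled
  if (nrow(m) && ncol(m) >= 2) {
    mu <- rowMeans(m)
    sdv <- apply(m, 1, stats::sd)
    if (max(abs(mu)) > 1e-9 || max(abs(sdv - 1)) > 1e-9)
      return("retained rows must have mean 0 and SD 1 (tolerance 1e-9)")
  }
  TRUE
})

#' Hierarchical clustering of samples under correlation distance
#'
#' Wraps the merge tree produced by complete-linkage (or divisive)
#' clustering of samples with distance 1 - Pearson r, together with the
#' distance matrix it was built from.
#'
#' @slot hclust an object coercible to [stats::hclust] (merge heights,
#'   leaf order).
#' @slot dist the symmetric sample-by-sample distance matrix in [0, 2].
#' @slot method linkage / algorithm label.
#' @exportClass SampleClustering
setClass("SampleClustering",
  representation(hclust = "ANY", dist = "matrix", method = "character"))

#' Labels of the planted gene response classes
#'
#' @return Character vector of the class labels understood by
#'   [simConfig()]'s `class_counts`: Type-I up/down (concordant in all
#'   four strains), Type-II up/down within the sensitive or resistant
#'   collective, single-strain responders, and `"NULL"` for unresponsive
#'   filler genes.
#' @examples geneClassLabels()
#' @export
geneClassLabels <- function() GENE_CLASSES

#' Labels assigned by the (R, S) score classification
#'
#' @return Character vector of the seven labels [classifyScores()] can
#'   produce.
#' @examples scoreClassLabels()
#' @export
scoreClassLabels <- function() SCORE_LABELS
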