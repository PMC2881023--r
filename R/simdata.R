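#' @importFrom stats rchisq rnorm runif var sd
NULL

# Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Default configuration of the synthetic dioxin experiment
#'
#' Builds a [SimConfig-class] describing the study design the simulator
#' emulates: four rat strains (two dioxin-resistant, two dioxin-sensitive),
#' control vs TCDD-exposed treatment, four animals per condition, and a
#' gene universe with planted response classes. The default class counts
#' mirror the cross-classification reported for the original four-strain
#' hepatic study: 25 Type-I genes (20 induced, 5 repressed), 46 Type-II
#' genes (43 sensitive-only split 17 up / 26 down; 3 resistant-only split
#' 2 up / 1 down), 308 single-strain responders, remainder unresponsive.
#'
#' Gene-wise true variances are drawn from a scaled inverse-chi-square
#' prior `s0_sq * d0 / chisq(d0)`, the hierarchical model the moderated
#' t-statistic assumes, so that moderation parameters are recoverable.
#'
#' @param n_genes gene universe size (default 8605).
#' @param n_replicates animals per condition (default 4).
#' @param strains four strain labels; defaults `c("HW","LnA","LE","LnC")`.
#' @param collectives named map strain -> `"resistant"`/`"sensitive"`.
#' @param class_counts named integer vector over [geneClassLabels()];
#'   unlisted classes are 0, genes not planted are `NULL` class. When left
#'   at its default with a non-default `n_genes`, the published counts are
#'   rescaled proportionally (rounded) to the requested universe size.
#' @param effect_size named numeric |log2FC| magnitudes for `TYPE_I`,
#'   `TYPE_II` and `SINGLE_STRAIN` genes (defaults 3.0, 1.4, 1.5).
#' @param d0,s0_sq variance-prior degrees of freedom and scale
#'   (defaults 4 and 0.05).
#' @param baseline_mean_range uniform range of gene baseline means on the
#'   log2 scale (default `c(6, 12)`).
#' @param strain_shift_sd SD of gene-by-strain baseline offsets
#'   (default 0.25), kept well below the planted treatment effects.
#' @param seed RNG seed stored with the configuration.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(n_genes = 500, seed = 7)
#' cfg
#' @export
simConfig <- function(n_genes = 8605L,
                      n_replicates = 4L,
                      strains = c("HW", "LnA", "LE", "LnC"),
                      collectives = c(HW = "resistant", LnA = "resistant",
                                      LE = "sensitive", LnC = "sensitive"),
                      class_counts = c(TYPE_I_UP = 20L, TYPE_I_DOWN = 5L,
                                       TYPE_II_SENS_UP = 17L,
                                       TYPE_II_SENS_DOWN = 26L,
                                       TYPE_II_RES_UP = 2L,
                                       TYPE_II_RES_DOWN = 1L,
                                       SINGLE_STRAIN = 308L),
                      effect_size = c(TYPE_I = 3.0, TYPE_II = 1.4,
                                      SINGLE_STRAIN = 1.5),
                      d0 = 4, s0_sq = 0.05,
                      baseline_mean_range = c(6, 12),
                      strain_shift_sd = 0.25,
                      seed = 1L) {
  if (missing(class_counts) && n_genes != 8605L) {
    # keep the published class proportions for other universe sizes
    class_counts <- vapply(class_counts,
                           function(k) as.integer(round(k * n_genes / 8605)),
                           integer(1))
  }
  cc <- structure(rep(0L, length(GENE_CLASSES)), names = GENE_CLASSES)
  if (length(class_counts)) {
    unknown <- setdiff(names(class_counts), GENE_CLASSES)
    if (length(unknown))
      stop("configuration error in 'class_counts': unknown class label(s): ",
           paste(unknown, collapse = ", "))
    cc[names(class_counts)] <- as.integer(class_counts)
  }
  planted <- sum(cc[setdiff(GENE_CLASSES, "NULL")])
  if (planted <= n_genes) cc["NULL"] <- as.integer(n_genes) - planted
  new("SimConfig",
      n_genes = as.integer(n_genes), n_replicates = as.integer(n_replicates),
      strains = strains, collectives = collectives[strains],
      class_counts = cc, effect_size = effect_size,
      d0 = as.numeric(d0), s0_sq = as.numeric(s0_sq),
      baseline_mean_range = as.numeric(baseline_mean_range),
      strain_shift_sd = as.numeric(strain_shift_sd), seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@n_genes, "genes,",
      paste(object@strains, collapse = "/"), "x control/exposed x",
      object@n_replicates, "replicates\n")
  cc <- object@class_counts[object@class_counts > 0]
  cat("classes:", paste(names(cc), cc, sep = "=", collapse = ", "), "\n")
  cat(sprintf("variance prior: d0 = %g, s0_sq = %g; seed = %d\n",
              object@d0, object@s0_sq, object@seed))
  invisible(NULL)
})

# Deterministic truth layout: per-strain true log2 effects for each gene,
# in config order (Type-I first, then Type-II, single-strain round-robin
# with alternating direction, then NULL filler).
plant_effects <- function(config) {
  cc <- config@class_counts
  strains <- config@strains
  res <- strains[config@collectives == "resistant"]
  sen <- strains[config@collectives == "sensitive"]
  es <- config@effect_size
  eff <- matrix(0, config@n_genes, 4L, dimnames = list(NULL, strains))
  cls <- character(config@n_genes)
  i <- 0L
  take <- function(n) { out <- seq_len(n) + i; i <<- i + n; out }
  block <- function(label, n, cols, sign, size) {
    idx <- take(n)
    if (n > 0) eff[idx, cols] <<- sign * size
    cls[idx] <<- label
  }
  block("TYPE_I_UP", cc[["TYPE_I_UP"]], strains, +1, es[["TYPE_I"]])
  block("TYPE_I_DOWN", cc[["TYPE_I_DOWN"]], strains, -1, es[["TYPE_I"]])
  block("TYPE_II_SENS_UP", cc[["TYPE_II_SENS_UP"]], sen, +1, es[["TYPE_II"]])
  block("TYPE_II_SENS_DOWN", cc[["TYPE_II_SENS_DOWN"]], sen, -1, es[["TYPE_II"]])
  block("TYPE_II_RES_UP", cc[["TYPE_II_RES_UP"]], res, +1, es[["TYPE_II"]])
  block("TYPE_II_RES_DOWN", cc[["TYPE_II_RES_DOWN"]], res, -1, es[["TYPE_II"]])
  nss <- cc[["SINGLE_STRAIN"]]
  if (nss > 0) {
    idx <- take(nss)
    for (k in seq_len(nss)) {
      strain_k <- strains[((k - 1L) %% 4L) + 1L]
      dir_k <- if (((k - 1L) %/% 4L) %% 2L == 0L) +1 else -1
      eff[idx[k], strain_k] <- dir_k * es[["SINGLE_STRAIN"]]
    }
    cls[idx] <- "SINGLE_STRAIN"
  }
  cls[cls == ""] <- "NULL"
  list(effects = eff, class = cls)
}

#' Generate a synthetic four-strain dioxin expression dataset
#'
#' Simulates a log2 expression matrix under the additive model
#' `baseline + strain offset + treatment effect + noise`, where the noise
#' of gene g is Gaussian with variance `sigma_g^2` drawn once per gene
#' from the scaled inverse-chi-square prior `s0_sq * d0 / chisq(d0)`.
#' Planted Type-I genes carry the same signed effect in all four strains,
#' Type-II genes only in the two strains of one collective, single-strain
#' genes in exactly one strain (round-robin over strains, alternating
#' sign), and NULL genes in none. The layout of classes over genes is
#' deterministic, so truth tallies equal the configured counts exactly.
#'
#' @param config a [SimConfig-class]; `config@seed` drives all randomness
#'   unless overridden.
#' @param seed optional seed overriding `config@seed`.
#' @return A [ResponseExperiment-class] whose `rowData` holds the
#'   simulation truth: `class`, `effect_<strain>`, `direction_<strain>`
#'   and `sigma_sq`; the configuration is kept in `metadata(x)$config`.
#' @examples
#' re <- generateDataset(simConfig(n_genes = 200, seed = 3))
#' re
#' @export
generateDataset <- function(config, seed = NULL) {
  validObject(config)
  truth <- plant_effects(config)
  strains <- config@strains
  nrep <- config@n_replicates
  ng <- config@n_genes
  cd <- expand.grid(replicate = seq_len(nrep),
                    treatment = c("control", "exposed"),
                    strain = strains, stringsAsFactors = FALSE)
  cd <- cd[, c("strain", "treatment", "replicate")]
  sample_id <- sprintf("%s_%s_%d", cd$strain, cd$treatment, cd$replicate)
  gene_id <- sprintf("gene%05d", seq_len(ng))

  mat <- with_seed(if (is.null(seed)) config@seed else seed, {
    sigma_sq <- config@s0_sq * config@d0 / rchisq(ng, df = config@d0)
    baseline <- runif(ng, config@baseline_mean_range[1],
                      config@baseline_mean_range[2])
    shift <- matrix(rnorm(ng * 4L, sd = config@strain_shift_sd), ng, 4L,
                    dimnames = list(NULL, strains))
    mu <- baseline +
      shift[, cd$strain, drop = FALSE] +
      truth$effects[, cd$strain, drop = FALSE] *
        rep(as.numeric(cd$treatment == "exposed"), each = ng)
    mu + matrix(rnorm(ng * nrow(cd), sd = sqrt(sigma_sq)), ng, nrow(cd))
  })
  # recover sigma_sq deterministically for rowData (first draw of the stream)
  sigma_sq <- with_seed(if (is.null(seed)) config@seed else seed,
                        config@s0_sq * config@d0 / rchisq(ng, df = config@d0))
  dimnames(mat) <- list(gene_id, sample_id)

  rd <- DataFrame(class = truth$class, sigma_sq = sigma_sq)
  for (s in strains) {
    rd[[paste0("effect_", s)]] <- truth$effects[, s]
    rd[[paste0("direction_", s)]] <- as.integer(sign(truth$effects[, s]))
  }
  re <- ResponseExperiment(mat, strain = cd$strain, treatment = cd$treatment,
                           collectives = config@collectives,
                           replicate = cd$replicate, rowData = rd)
  metadata(re)$config <- config
  re
}

#' Moments of the simulated gene-wise variances
#'
#' Summarises the sampled true variances of a simulated experiment for
#' comparison with the generating prior: under
#' `sigma^2 ~ s0_sq * d0 / chisq(d0)` the mean is `s0_sq * d0 / (d0 - 2)`
#' (for `d0 > 2`) and the variance of `log(sigma^2)` is `trigamma(d0/2)`.
#'
#' @param x a [ResponseExperiment-class] with simulation truth, or a
#'   numeric vector of variances.
#' @return list with `mean_sigma_sq`, `var_log_sigma_sq` and `n_genes`.
#' @examples
#' re <- generateDataset(simConfig(n_genes = 2000, seed = 1))
#' empiricalVarianceSummary(re)
#' @export
empiricalVarianceSummary <- function(x) {
  s2 <- if (is(x, "ResponseExperiment")) simTruth(x)$sigma_sq else as.numeric(x)
  if (length(s2) < 100L)
    stop("insufficient data: need >= 100 genes, got ", length(s2))
  list(mean_sigma_sq = mean(s2), var_log_sigma_sq = var(log(s2)),
       n_genes = length(s2))
}

#' Export a simulated dataset as plain-text files
#'
#' Writes the expression matrix (`matrix.tsv`, first column `gene`), the
#' sample sheet (`samples.tsv`: sample, strain, treatment, replicate), the
#' simulation truth (`truth.tsv`) when present, and the configuration as
#' `config.json`.
#'
#' @param x a [ResponseExperiment-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeDataset <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "matrix.tsv"),
             samples = file.path(dir, "samples.tsv"))
  m <- data.frame(gene = rownames(x), assay(x, "log2"), check.names = FALSE)
  utils::write.table(m, paths["matrix"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(colData(x)), paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rd <- as.data.frame(rowData(x))
  if ("class" %in% colnames(rd)) {
    paths["truth"] <- file.path(dir, "truth.tsv")
    utils::write.table(cbind(gene = rownames(x), rd), paths["truth"],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg <- metadata(x)$config
  if (!is.null(cfg)) {
    paths["config"] <- file.path(dir, "config.json")
    jsonlite::write_json(configAsList(cfg), paths["config"],
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}

configAsList <- function(config) {
  list(n_genes = config@n_genes, n_replicates = config@n_replicates,
       strains = config@strains, collectives = as.list(config@collectives),
       class_counts = as.list(config@class_counts),
       effect_size = as.list(config@effect_size),
       d0 = config@d0, s0_sq = config@s0_sq,
       baseline_mean_range = config@baseline_mean_range,
       strain_shift_sd = config@strain_shift_sd, seed = config@seed)
}

#' Read an exported dataset back into a ResponseExperiment
#'
#' Counterpart of [writeDataset()]: reads `matrix.tsv` and `samples.tsv`
#' (and `truth.tsv` if present) from a directory.
#'
#' @param dir directory written by [writeDataset()].
#' @param collectives strain -> collective map; defaults to the standard
#'   four-strain layout when all four default strains are present.
#' @return A [ResponseExperiment-class].
#' @export
readDataset <- function(dir, collectives = c(HW = "resistant",
                                             LnA = "resistant",
                                             LE = "sensitive",
                                             LnC = "sensitive")) {
  m <- utils::read.delim(file.path(dir, "matrix.tsv"), check.names = FALSE)
  ss <- utils::read.delim(file.path(dir, "samples.tsv"))
  mat <- as.matrix(m[, -1, drop = FALSE])
  rownames(mat) <- m[[1]]
  rd <- NULL
  tp <- file.path(dir, "truth.tsv")
  if (file.exists(tp)) {
    tr <- utils::read.delim(tp)
    rd <- DataFrame(tr[, setdiff(colnames(tr), "gene"), drop = FALSE])
  }
  ResponseExperiment(mat, strain = ss$strain, treatment = ss$treatment,
                     collectives = collectives, replicate = ss$replicate,
                     rowData = rd)
}
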