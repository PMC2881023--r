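#' Run the full cross-strain analysis pipeline
#'
#' Orchestrates simulate -> fit -> score/classify -> cluster -> enrich on
#' one run directory, writing every intermediate as TSV/JSON plus a
#' `manifest.json` recording the seed, the configuration, package and R
#' versions and per-stage row counts. All randomness flows from `seed`:
#' the simulator uses `seed` itself and the enrichment permutations use
#' `seed + 1000`. Deterministic stages are byte-identical across reruns
#' with the same configuration and seed (the manifest carries no
#' timestamps).
#'
#' @param out_dir run directory (created; partial outputs are retained on
#'   stage failure).
#' @param config a [SimConfig-class] for the simulation stage; ignored
#'   when `experiment` is supplied.
#' @param experiment optional pre-built [ResponseExperiment-class] to
#'   analyse instead of simulating.
#' @param seed master seed of the run (overrides `config@seed`).
#' @param alpha adjusted-p threshold for scoring (default 0.01).
#' @param var_threshold variance filter for clustering (default 0.1).
#' @param annotation optional [AnnotationMap-class]; enables the
#'   enrichment stage on the responsive gene list of each strain.
#' @param n_perm permutations for the enrichment stage.
#' @param per_strain_fit passed to [runStrainContrasts()].
#' @param modules character subset of
#'   `c("simulate", "fit", "score", "cluster", "enrich")`; disabled
#'   stages are skipped and noted in the manifest.
#' @return Invisibly, a list with the in-memory stage objects and the
#'   manifest.
#' @examples
#' dir <- file.path(tempdir(), "run1")
#' res <- runPipeline(dir, simConfig(n_genes = 120, seed = 5), seed = 5)
#' names(res)
#' @export
runPipeline <- function(out_dir,
                        config = simConfig(),
                        experiment = NULL,
                        seed = config@seed,
                        alpha = 0.01,
                        var_threshold = 0.1,
                        annotation = NULL,
                        n_perm = 1000L,
                        per_strain_fit = FALSE,
                        modules = c("simulate", "fit", "score", "cluster",
                                    "enrich")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    seed = seed, alpha = alpha, var_threshold = var_threshold,
    n_perm = n_perm, per_strain_fit = per_strain_fit,
    modules = modules,
    package_version = as.character(utils::packageVersion("DioxinScore")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = configAsList(config),
    stages = list())
  out <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (!is.null(experiment)) {
    re <- experiment
    manifest$stages$simulate <- list(skipped = TRUE,
                                     reason = "experiment supplied")
  } else if ("simulate" %in% modules) {
    re <- stage("simulate", generateDataset(config, seed = seed))
    writeDataset(re, file.path(out_dir, "data"))
    manifest$stages$simulate <- list(n_genes = nrow(re),
                                     n_samples = ncol(re))
  } else stop("nothing to analyse: enable 'simulate' or pass 'experiment'")
  out$experiment <- re

  if ("fit" %in% modules) {
    sc <- stage("fit", runStrainContrasts(re, alpha = alpha,
                                          per_strain_fit = per_strain_fit))
    writeContrasts(sc, file.path(out_dir, "contrasts"))
    manifest$stages$fit <- list(
      d0 = unname(priorDf(sc)), s0_sq = unname(priorVar(sc)),
      df_residual = unname(sc@df_residual),
      n_genes = nrow(contrastResults(sc)[[1]]))
    out$contrasts <- sc

    if ("score" %in% modules) {
      gs <- stage("score", scoreGenes(sc, alpha = alpha))
      writeScores(gs, out_dir)
      sweep <- thresholdSweep(sc)
      utils::write.table(sweep, file.path(out_dir, "threshold_sweep.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      ov <- summarizeOverlap(gs)
      manifest$stages$score <- list(n_genes = nrow(as.data.frame(gs)),
                                    responsive_any = ov$responsive_any)
      out$scores <- gs

      if ("enrich" %in% modules && !is.null(annotation)) {
        enr <- stage("enrich", {
          lapply(names(contrastResults(sc)), function(s) {
            df <- contrastResults(sc, s)
            lst <- df$gene[df$p_adj < alpha]
            if (length(lst) == 0) return(NULL)
            permutationFdr(lst, annotation, n_perm = n_perm,
                           seed = seed + 1000L)
          })
        })
        names(enr) <- names(contrastResults(sc))
        for (s in names(enr)) if (!is.null(enr[[s]]))
          utils::write.table(enr[[s]],
                             file.path(out_dir, paste0("enrichment_", s, ".tsv")),
                             sep = "\t", quote = FALSE, row.names = FALSE)
        manifest$stages$enrich <- list(
          n_categories = length(annotation@sets),
          strains_tested = sum(!vapply(enr, is.null, logical(1))))
        out$enrichment <- enr
      } else if ("enrich" %in% modules) {
        manifest$stages$enrich <- list(skipped = TRUE,
                                       reason = "no annotation supplied")
      } else {
        manifest$stages$enrich <- list(skipped = TRUE, reason = "disabled")
      }
    } else {
      manifest$stages$score <- list(skipped = TRUE, reason = "disabled")
    }
  } else {
    manifest$stages$fit <- list(skipped = TRUE, reason = "disabled")
  }

  if ("cluster" %in% modules) {
    cl <- stage("cluster", {
      sm <- filterAndScale(re, var_threshold = var_threshold)
      hierarchicalCluster(sm)
    })
    writeClustering(cl, out_dir)
    manifest$stages$cluster <- list(
      n_samples = nrow(cl@dist),
      treatment_separation =
        treatmentSeparationScore(cl, colData(re)$treatment))
    out$clustering <- cl
  } else {
    manifest$stages$cluster <- list(skipped = TRUE, reason = "disabled")
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out$manifest <- manifest
  invisible(out)
}

#' Summarise a completed pipeline run
#'
#' Recomputes (never caches) the headline numbers from the files a run
#' directory contains: the two-way score grid, responsive / Type-I /
#' Type-II counts, overlap fractions, the collective proportion test and
#' the threshold-sweep curve. Missing stage outputs are reported as
#' absent rather than failing.
#'
#' @param out_dir a directory written by [runPipeline()].
#' @param quiet suppress printing.
#' @return Invisibly, a list with `twoway` (matrix or NULL), `overlap`,
#'   `proportion_test`, `sweep` and `absent` (character vector of
#'   missing pieces).
#' @export
pipelineReport <- function(out_dir, quiet = FALSE) {
  absent <- character()
  say <- function(...) if (!quiet) cat(...)
  res <- list()

  tw_path <- file.path(out_dir, "twoway_table.tsv")
  if (file.exists(tw_path)) {
    tw <- utils::read.delim(tw_path, check.names = FALSE)
    m <- as.matrix(tw[, -1, drop = FALSE])
    rownames(m) <- tw[[1]]
    ct <- crossTable(m)
    res$twoway <- as.matrix(ct)
    res$overlap <- summarizeOverlap(ct)
    ov <- res$overlap
    res$proportion_test <- proportionTest(
      ov$overlap_within_resistant, ov$responsive_resistant,
      ov$overlap_within_sensitive, ov$responsive_sensitive)
    say("Two-way collective score table (rows resistant, cols sensitive):\n")
    if (!quiet) print(res$twoway)
    say(sprintf("responsive in >= 1 strain: %d of %d (%.1f%%)\n",
                ov$responsive_any, ov$total,
                100 * ov$responsive_any / ov$total))
    say(sprintf("Type-I: %d (%d up, %d down); Type-II: %d (%d sensitive-only, %d resistant-only)\n",
                ov$type_I, ov$type_I_up, ov$type_I_down,
                ov$type_II, ov$type_II_sensitive_only,
                ov$type_II_resistant_only))
    say(sprintf("within-collective overlap: resistant %d/%d (%.1f%%), sensitive %d/%d (%.1f%%); proportion test p = %.2f\n",
                ov$overlap_within_resistant, ov$responsive_resistant,
                100 * ov$overlap_resistant_frac,
                ov$overlap_within_sensitive, ov$responsive_sensitive,
                100 * ov$overlap_sensitive_frac,
                res$proportion_test$p_value))
  } else absent <- c(absent, "twoway_table.tsv")

  sweep_path <- file.path(out_dir, "threshold_sweep.tsv")
  if (file.exists(sweep_path)) {
    res$sweep <- utils::read.delim(sweep_path, check.names = FALSE)
  } else absent <- c(absent, "threshold_sweep.tsv")

  if (length(absent) == length(c("twoway_table.tsv", "threshold_sweep.tsv")) &&
      !file.exists(file.path(out_dir, "manifest.json"))) {
    say("no stages completed\n")
  } else if (length(absent)) {
    say("absent outputs:", paste(absent, collapse = ", "), "\n")
  }
  res$absent <- absent
  invisible(res)
}
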