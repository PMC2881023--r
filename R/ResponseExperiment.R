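#' Expression experiment with strain and treatment annotations
#'
#' `ResponseExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment] for the four-strain,
#' two-treatment dioxin design: a `log2` assay of normalised intensities,
#' per-sample `strain` and `treatment` (control/exposed) columns, and a
#' strain-to-collective map in the metadata. Ground-truth gene classes
#' from the simulator, when present, live in `rowData`.
#'
#' @exportClass ResponseExperiment
setClass("ResponseExperiment", contains = "SummarizedExperiment")

setValidity("ResponseExperiment", function(object) {
  msg <- NULL
  cd <- colData(object)
  if (!all(c("strain", "treatment") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'strain' and 'treatment'")
  else {
    if (!all(cd$treatment %in% c("control", "exposed")))
      msg <- c(msg, "treatment must be 'control' or 'exposed'")
    cm <- metadata(object)$collectives
    if (is.null(cm) || !all(unique(cd$strain) %in% names(cm)))
      msg <- c(msg, "metadata$collectives must map every strain")
  }
  if (!"log2" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'log2' is required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated gene IDs")
  if (is.null(msg)) TRUE else msg
})

#' Construct a ResponseExperiment
#'
#' @param log2 numeric matrix of log2 intensities, genes x samples, with
#'   unique rownames (gene IDs) and colnames (sample IDs).
#' @param strain character vector, one strain label per sample.
#' @param treatment character vector of `"control"`/`"exposed"` per sample.
#' @param collectives named character mapping each strain label to
#'   `"resistant"` or `"sensitive"`.
#' @param replicate optional integer replicate index per sample.
#' @param rowData optional per-gene annotation (e.g. simulation truth).
#' @return A [ResponseExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(40), 5, 8,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
#' re <- ResponseExperiment(m,
#'   strain = rep(c("HW", "LE"), each = 4),
#'   treatment = rep(c("control", "exposed"), 4),
#'   collectives = c(HW = "resistant", LE = "sensitive"))
#' strains(re)
#' @export
ResponseExperiment <- function(log2, strain, treatment, collectives,
                               replicate = NULL, rowData = NULL) {
  stopifnot(is.matrix(log2), length(strain) == ncol(log2),
            length(treatment) == ncol(log2))
  cd <- DataFrame(sample = colnames(log2), strain = as.character(strain),
                  treatment = as.character(treatment))
  if (!is.null(replicate)) cd$replicate <- as.integer(replicate)
  se <- SummarizedExperiment(
    assays = list(log2 = log2), colData = cd,
    rowData = if (is.null(rowData)) NULL else rowData,
    metadata = list(collectives = collectives))
  new("ResponseExperiment", se)
}

#' Strain and collective annotations of an experiment
#'
#' @param x a [ResponseExperiment-class].
#' @return `strains()` returns the ordered unique strain labels;
#'   `collectiveMap()` the named strain -> collective character vector.
#' @name strainInfo
#' @aliases strains strains,ResponseExperiment-method
#'   collectiveMap collectiveMap,ResponseExperiment-method
NULL

#' @rdname strainInfo
#' @export
setMethod("strains", "ResponseExperiment", function(x)
  unique(colData(x)$strain))

#' @rdname strainInfo
#' @export
setMethod("collectiveMap", "ResponseExperiment", function(x)
  metadata(x)$collectives)

#' Ground-truth gene classes of a simulated experiment
#'
#' @param x a [ResponseExperiment-class] produced by [generateDataset()].
#' @return data.frame with the planted class label, per-strain true
#'   effects and directions, and the true gene variance.
#' @name simTruth
#' @aliases simTruth,ResponseExperiment-method
#' @export
setMethod("simTruth", "ResponseExperiment", function(x) {
  rd <- as.data.frame(rowData(x))
  if (!"class" %in% colnames(rd))
    stop("no simulation truth attached to this experiment")
  rd
})

setMethod("show", "ResponseExperiment", function(object) {
  cd <- colData(object)
  cat("ResponseExperiment:", nrow(object), "genes x", ncol(object), "samples\n")
  print(table(strain = cd$strain, treatment = cd$treatment))
  if ("class" %in% colnames(rowData(object))) {
    cat("planted classes:\n")
    print(table(rowData(object)$class))
  }
  invisible(NULL)
})
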