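#' Read gene categories from a GMT file
#'
#' Standard GMT layout: one tab-separated line per category, fields
#' `category`, `description`, then member gene IDs.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors of gene IDs; the descriptions
#'   are kept in the `"description"` attribute.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3L
  if (any(bad))
    stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  attr(sets, "description") <- vapply(parts, `[`, character(1), 2L)
  sets
}

#' Build an annotation map over a gene universe
#'
#' Restricts each category to the universe and drops categories left with
#' fewer than `min_size` genes.
#'
#' @param sets named list of character vectors (e.g. from [readGmt()]).
#' @param universe character vector of eligible gene IDs.
#' @param min_size minimum post-restriction category size (default 5).
#' @return An [AnnotationMap-class].
#' @examples
#' am <- annotationMap(list(catA = letters[1:6], catB = letters[4:10]),
#'                     universe = letters[1:10], min_size = 2)
#' am
#' @export
annotationMap <- function(sets, universe, min_size = 5L) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  universe <- unique(as.character(universe))
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  sets <- sets[vapply(sets, length, integer(1)) >= min_size]
  new("AnnotationMap", sets = sets, universe = universe,
      min_size = as.integer(min_size))
}

setMethod("show", "AnnotationMap", function(object) {
  cat("AnnotationMap:", length(object@sets), "categories over",
      length(object@universe), "genes (min_size =", object@min_size, ")\n")
  invisible(NULL)
})

#' Enrichment ratio of a category in a gene list
#'
#' `E = (k/n) / (K/N)`: the fraction of the list falling in the category
#' relative to the fraction of the universe in the category. `K = 0`
#' (category absent from the universe) yields `NA`.
#'
#' @param k list genes in the category.
#' @param n list size.
#' @param K universe genes in the category.
#' @param N universe size.
#' @return the enrichment ratio (vectorised), `NA` where `K = 0`.
#' @examples
#' enrichmentRatio(5, 46, 25, 8605)  # 37.41...
#' @export
enrichmentRatio <- function(k, n, K, N) {
  if (any(n <= 0) || any(n > N) || any(K < 0) || any(K > N) ||
      any(k < 0) || any(k > pmin(n, K)))
    stop("contract violation: need 0 < n <= N, 0 <= K <= N, 0 <= k <= min(n, K)")
  out <- (k / n) / (K / N)
  out[K == 0] <- NA_real_
  out
}

#' Permutation-based category enrichment with empirical FDR
#'
#' For every category the observed enrichment ratio is compared with the
#' ratios obtained on `n_perm` random gene lists of the same size drawn
#' without replacement from the universe. In the default `"family"` mode
#' the false-discovery rate of a category with observed ratio E is the
#' family-wise empirical FDR of the reference permutation methodology:
#' the mean number of permuted categories (across the whole family, per
#' permutation) reaching E, divided by the number of real categories
#' reaching E, clipped to `[0, 1]` and made monotone non-decreasing with
#' decreasing E. The `"per-category"` mode instead reports each
#' category's own empirical exceedance p-value
#' `(1 + #perm >= obs) / (n_perm + 1)` in the `fdr` column.
#'
#' @param genes character vector, the gene list (subset of the universe).
#' @param annotation an [AnnotationMap-class].
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed; results are reproducible given the seed.
#' @param mode `"family"` (default) or `"per-category"`, see above.
#' @return data.frame with one row per category: `category`, `n`, `k`,
#'   `N`, `K`, `E`, `fdr`, ordered by decreasing `E`.
#' @examples
#' am <- annotationMap(list(A = letters[1:3], B = letters[3:6]),
#'                     universe = letters[1:6], min_size = 2)
#' permutationFdr(c("a", "b"), am, n_perm = 200, seed = 1)
#' @export
permutationFdr <- function(genes, annotation, n_perm = 1000L, seed = 1L,
                           mode = c("family", "per-category")) {
  mode <- match.arg(mode)
  stopifnot(is(annotation, "AnnotationMap"), n_perm >= 1L)
  genes <- unique(as.character(genes))
  outside <- setdiff(genes, annotation@universe)
  if (length(outside))
    stop("gene list not contained in the universe: ",
         paste(utils::head(outside, 10), collapse = ", "))
  universe <- annotation@universe
  N <- length(universe)
  n <- length(genes)
  if (n == 0L) stop("empty gene list")
  sets <- annotation@sets
  if (!length(sets)) stop("annotation has no usable categories")

  # category x universe incidence for fast permutation counting
  M <- matrix(FALSE, length(sets), N,
              dimnames = list(names(sets), universe))
  for (i in seq_along(sets)) M[i, sets[[i]]] <- TRUE
  K <- rowSums(M)
  k_obs <- rowSums(M[, genes, drop = FALSE])
  E_obs <- (k_obs / n) / (K / N)

  perm_E <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(N, n)
      (rowSums(M[, idx, drop = FALSE]) / n) / (K / N)
    }, numeric(length(sets)))
  })
  perm_E <- matrix(perm_E, nrow = length(sets))

  ord <- order(E_obs, decreasing = TRUE)
  if (mode == "family") {
    fdr <- vapply(E_obs, function(e) {
      num <- mean(colSums(perm_E >= e))
      den <- sum(E_obs >= e)
      min(1, num / den)
    }, numeric(1))
    # monotone: a larger observed E never gets a larger FDR
    fdr[ord] <- cummax(fdr[ord])
  } else {
    fdr <- vapply(seq_along(E_obs), function(i)
      (1 + sum(perm_E[i, ] >= E_obs[i])) / (n_perm + 1), numeric(1))
  }

  out <- data.frame(category = names(sets), n = n, k = as.integer(k_obs),
                    N = N, K = as.integer(K), E = E_obs, fdr = fdr,
                    row.names = NULL)
  out[ord, , drop = FALSE]
}

#' Overlap of significant categories between gene lists
#'
#' Given the per-list sets of significant category IDs (e.g. at 5%
#' permutation FDR), tallies the all-way intersection, the union, per-list
#' sizes and the pairwise intersection matrix.
#'
#' @param sig_sets named list (>= 2) of character vectors of category IDs.
#' @return list with `n_all` (categories significant in every list),
#'   `n_union`, `sizes`, and `pairwise` intersection count matrix.
#' @examples
#' compareTermOverlap(list(a = c("x", "y"), b = c("y", "z")))
#' @export
compareTermOverlap <- function(sig_sets) {
  if (!is.list(sig_sets) || length(sig_sets) < 2L)
    stop("need at least 2 significant-category sets")
  if (is.null(names(sig_sets)))
    names(sig_sets) <- paste0("list", seq_along(sig_sets))
  sig_sets <- lapply(sig_sets, unique)
  nl <- length(sig_sets)
  pw <- matrix(0L, nl, nl, dimnames = list(names(sig_sets), names(sig_sets)))
  for (i in seq_len(nl)) for (j in seq_len(nl))
    pw[i, j] <- length(intersect(sig_sets[[i]], sig_sets[[j]]))
  list(n_all = length(Reduce(intersect, sig_sets)),
       n_union = length(Reduce(union, sig_sets)),
       sizes = vapply(sig_sets, length, integer(1)),
       pairwise = pw)
}
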