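# Per-BTU sample x sample dissimilarities on proportion-transformed
# abundances.

#' Transform counts to proportions of the whole library
#'
#' Each sample's counts are divided by its total library size (all ASVs,
#' before any BTU subsetting), so a BTU-subset of the rows sums to the
#' BTU's share of the library rather than to 1.
#'
#' @param x an [AsvExperiment-class] or an ASVs x samples count matrix.
#' @return Samples x ASVs matrix of proportions; full rows sum to 1.
#' @export
toProportions <- function(x) {
  cts <- if (methods::is(x, "AsvExperiment")) asvCounts(x) else as.matrix(x)
  lib <- colSums(cts)
  if (any(lib == 0))
    stop("samples with zero library size: ",
         paste(colnames(cts)[lib == 0], collapse = ", "))
  t(cts) / lib
}

#' Samples hosting a BTU
#'
#' @param x an [AsvExperiment-class] or ASVs x samples count matrix.
#' @param asvIds the BTU's member ASVs.
#' @return Character vector of sample ids with >= 1 read summed over the
#'   BTU's ASVs.
#' @export
btuSampleSubset <- function(x, asvIds) {
  cts <- if (methods::is(x, "AsvExperiment")) asvCounts(x) else as.matrix(x)
  if (!length(asvIds)) stop("asvIds must be nonempty")
  sub <- cts[intersect(asvIds, rownames(cts)), , drop = FALSE]
  colnames(cts)[colSums(sub) > 0]
}

.subsetProps <- function(props, sampleSubset, asvSubset, renormalize) {
  if (!is.null(sampleSubset)) props <- props[sampleSubset, , drop = FALSE]
  if (!is.null(asvSubset)) props <- props[, asvSubset, drop = FALSE]
  if (nrow(props) < 2) stop("need >= 2 samples")
  rs <- rowSums(props)
  if (any(rs == 0))
    stop("all-zero rows in the subset: ",
         paste(rownames(props)[rs == 0], collapse = ", "),
         " (exclude non-hosting samples first)")
  if (renormalize) props <- props / rs
  props
}

#' Bray-Curtis dissimilarity between samples
#'
#' BC(x, y) = 1 - 2 sum(min(x_i, y_i)) / sum(x_i + y_i) over the chosen
#' ASVs, computed on whole-library proportions (not renormalized within
#' the subset unless requested).
#'
#' @param props samples x ASVs proportion matrix (see [toProportions()]).
#' @param sampleSubset,asvSubset optional row/column selections.
#' @param renormalize renormalize subset rows to sum 1 first
#'   (sensitivity analysis; default `FALSE`).
#' @return Symmetric dissimilarity matrix in `[0, 1]`.
#' @export
brayCurtis <- function(props, sampleSubset = NULL, asvSubset = NULL,
                       renormalize = FALSE) {
  p <- .subsetProps(props, sampleSubset, asvSubset, renormalize)
  as.matrix(vegan::vegdist(p, method = "bray"))
}

#' Binary Jaccard dissimilarity between samples
#'
#' The classic set form on presence/absence: J(x, y) = 1 - |A and B| /
#' |A or B| over the supports of the two samples' subset rows.
#'
#' @inheritParams brayCurtis
#' @return Symmetric dissimilarity matrix in `[0, 1]`.
#' @export
jaccardBinary <- function(props, sampleSubset = NULL, asvSubset = NULL,
                          renormalize = FALSE) {
  p <- .subsetProps(props, sampleSubset, asvSubset, renormalize)
  as.matrix(vegan::vegdist(p, method = "jaccard", binary = TRUE))
}
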