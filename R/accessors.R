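# Accessor generics and methods for the S4 containers.

#' @name accessors
#' @title Accessors for AsvExperiment and BtuPartition
#' @param x an [AsvExperiment-class] or [BtuPartition-class] object.
#' @param btu a BTU label.
#' @description Slot access for the package's containers. `asvCounts`
#'   returns the integer count matrix (ASVs x samples); `librarySizes`
#'   the per-sample read totals; `hostSpecies` the named sample->species
#'   map; `taxonomyTable` the rank table as a plain data.frame;
#'   `btuAsvs`/`btuNames`/`binningMethod`/`excludedAsvs` inspect a
#'   partition.
NULL

#' @rdname accessors
#' @export
setGeneric("asvCounts", function(x) standardGeneric("asvCounts"))
#' @rdname accessors
#' @export
setMethod("asvCounts", "AsvExperiment", function(x)
  SummarizedExperiment::assay(x, "counts"))

#' @rdname accessors
#' @export
setGeneric("asvSequences", function(x) standardGeneric("asvSequences"))
#' @rdname accessors
#' @export
setMethod("asvSequences", "AsvExperiment", function(x) x@sequences)

#' @rdname accessors
#' @export
setGeneric("taxonomyTable", function(x) standardGeneric("taxonomyTable"))
#' @rdname accessors
#' @export
setMethod("taxonomyTable", "AsvExperiment", function(x)
  as.data.frame(SummarizedExperiment::rowData(x)[, .RANKS, drop = FALSE]))

#' @rdname accessors
#' @export
setGeneric("hostSpecies", function(x) standardGeneric("hostSpecies"))
#' @rdname accessors
#' @export
setMethod("hostSpecies", "AsvExperiment", function(x) {
  sp <- as.character(SummarizedExperiment::colData(x)$species)
  names(sp) <- colnames(x)
  sp
})

#' @rdname accessors
#' @export
setGeneric("hostTree", function(x) standardGeneric("hostTree"))
#' @rdname accessors
#' @export
setMethod("hostTree", "AsvExperiment", function(x) x@hostTree)

#' @rdname accessors
#' @export
setGeneric("librarySizes", function(x) standardGeneric("librarySizes"))
#' @rdname accessors
#' @export
setMethod("librarySizes", "AsvExperiment", function(x)
  colSums(asvCounts(x)))

#' @rdname accessors
#' @export
setGeneric("btuNames", function(x) standardGeneric("btuNames"))
#' @rdname accessors
#' @export
setMethod("btuNames", "BtuPartition", function(x) names(x@membership))

#' @rdname accessors
#' @export
setGeneric("btuAsvs", function(x, btu) standardGeneric("btuAsvs"))
#' @rdname accessors
#' @export
setMethod("btuAsvs", "BtuPartition", function(x, btu) {
  if (missing(btu)) return(x@membership)
  x@membership[[btu]]
})

#' @rdname accessors
#' @export
setGeneric("binningMethod", function(x) standardGeneric("binningMethod"))
#' @rdname accessors
#' @export
setMethod("binningMethod", "BtuPartition", function(x) x@method)

#' @rdname accessors
#' @export
setGeneric("excludedAsvs", function(x) standardGeneric("excludedAsvs"))
#' @rdname accessors
#' @export
setMethod("excludedAsvs", "BtuPartition", function(x) x@excluded)

#' Per-BTU read and richness tallies
#'
#' @param partition a [BtuPartition-class].
#' @param x the [AsvExperiment-class] whose counts supply the read totals.
#' @return data.frame with one row per BTU: label, ASV count, total reads.
#' @export
btuSummary <- function(partition, x) {
  cts <- asvCounts(x)
  labs <- btuNames(partition)
  data.frame(
    btu = labs,
    nAsvs = lengths(partition@membership),
    reads = vapply(partition@membership, function(a)
      sum(as.numeric(cts[intersect(a, rownames(cts)), , drop = FALSE])),
      numeric(1)),
    row.names = NULL)
}
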