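#' @importFrom methods setClass setValidity setMethod setGeneric new validObject is callNextMethod slot
#' @import SummarizedExperiment
#' @importClassesFrom Biostrings DNAStringSet
NULL

#' AsvExperiment: ASV counts, sequences, taxonomy and host phylogeny
#'
#' An S4 container extending [SummarizedExperiment::SummarizedExperiment]
#' that keeps the four cross-referenced inputs of a BTU-level analysis in
#' one object: an integer ASV count matrix (rows = ASVs, columns =
#' samples), the ASV 16S rRNA marker sequences, their taxonomy (ranks
#' phylum to genus in `rowData`), the host-species label of every sample
#' (`colData$species`) and the host phylogeny.
#'
#' @slot sequences a [Biostrings::DNAStringSet] named by ASV id, parallel
#'   to the rows.
#' @slot hostTree an [ape::phylo] whose tip labels cover all host species
#'   occurring in `colData$species`.
#'
#' @details Rows and `sequences` stay in sync under `[` subsetting. The
#'   `counts` assay must be non-negative integers; sample library sizes
#'   are the column sums ([librarySizes()]).
#' @aliases AsvExperiment-class
#' @exportClass AsvExperiment
setClass("AsvExperiment",
         contains = "SummarizedExperiment",
         slots = c(sequences = "DNAStringSet", hostTree = "ANY"))

.RANKS <- c("phylum", "class", "order", "family", "genus")

setValidity("AsvExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(cts != round(cts))) msg <- c(msg, "counts must be integers")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated ASV ids")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicated sample ids")
  if (length(object@sequences) != nrow(object) ||
      !identical(names(object@sequences), rownames(object)))
    msg <- c(msg, "sequences must be named by, and parallel to, the ASV ids")
  if (!"species" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'species' column")
  if (!all(.RANKS %in% colnames(SummarizedExperiment::rowData(object))))
    msg <- c(msg, paste("rowData must contain taxonomy ranks:",
                        paste(.RANKS, collapse = ", ")))
  if (!is.null(object@hostTree)) {
    if (!inherits(object@hostTree, "phylo"))
      msg <- c(msg, "hostTree must be an ape 'phylo' object")
    else {
      sp <- unique(as.character(SummarizedExperiment::colData(object)$species))
      missing <- setdiff(sp, object@hostTree$tip.label)
      if (length(missing))
        msg <- c(msg, paste("species missing from host tree:",
                            paste(missing, collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AsvExperiment
#'
#' @param counts integer matrix of read counts, ASVs x samples (rownames =
#'   ASV ids, colnames = sample ids).
#' @param sequences [Biostrings::DNAStringSet] named by ASV id.
#' @param taxonomy data.frame with columns `phylum`, `class`, `order`,
#'   `family`, `genus`, one row per ASV (rownames = ASV ids). `NA` or `""`
#'   marks an unassigned rank.
#' @param species character vector of host-species labels, one per sample
#'   (named by sample id, or in column order).
#' @param hostTree [ape::phylo] host phylogeny, or `NULL`.
#' @return An [AsvExperiment-class] object.
#' @export
AsvExperiment <- function(counts, sequences, taxonomy, species,
                          hostTree = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  asv <- rownames(counts)
  if (is.null(asv)) stop("counts must have ASV rownames")
  if (is.null(colnames(counts))) stop("counts must have sample colnames")
  sequences <- Biostrings::DNAStringSet(sequences)
  miss <- setdiff(asv, names(sequences))
  if (length(miss))
    stop("ASVs missing from sequences: ", paste(miss, collapse = ", "))
  sequences <- sequences[asv]
  taxonomy <- as.data.frame(taxonomy)
  miss <- setdiff(asv, rownames(taxonomy))
  if (length(miss))
    stop("ASVs missing from taxonomy: ", paste(miss, collapse = ", "))
  taxonomy <- taxonomy[asv, .RANKS, drop = FALSE]
  if (!is.null(names(species))) {
    miss <- setdiff(colnames(counts), names(species))
    if (length(miss))
      stop("samples missing from metadata: ", paste(miss, collapse = ", "))
    species <- species[colnames(counts)]
  } else if (length(species) != ncol(counts)) {
    stop("species must have one entry per sample")
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(taxonomy),
    colData = S4Vectors::DataFrame(species = as.character(species),
                                   row.names = colnames(counts)))
  new("AsvExperiment", se, sequences = sequences, hostTree = hostTree)
}

#' @describeIn AsvExperiment subsetting keeps sequences in sync with rows.
#' @param x,i,j,...,drop see [SummarizedExperiment::SummarizedExperiment].
#' @export
setMethod("[", c("AsvExperiment", "ANY", "ANY"), function(x, i, j, ..., drop = TRUE) {
  seqs <- x@sequences
  if (!missing(i)) seqs <- seqs[i]
  out <- callNextMethod()
  out@sequences <- seqs
  out
})

setMethod("show", "AsvExperiment", function(object) {
  cts <- SummarizedExperiment::assay(object, "counts")
  sp <- SummarizedExperiment::colData(object)$species
  cat("AsvExperiment:", ncol(object), "samples from",
      length(unique(sp)), "host species,", nrow(object), "ASVs,",
      format(sum(as.numeric(cts)), big.mark = ","), "reads\n")
  cat("  host tree:",
      if (is.null(object@hostTree)) "absent"
      else paste0(length(object@hostTree$tip.label), " tips"), "\n")
})

#' BtuPartition: a disjoint grouping of ASVs into Binned Taxonomic Units
#'
#' @slot membership named list, BTU label -> character vector of ASV ids.
#' @slot method one of `"genus"`, `"sim95"`, `"sim97"` (or another
#'   `"simXX"` tag for a custom similarity threshold).
#' @slot excluded ASV ids considered but left unbinned (e.g. ASVs with no
#'   genus assignment under reference-based binning).
#' @aliases BtuPartition-class
#' @exportClass BtuPartition
setClass("BtuPartition",
         slots = c(membership = "list", method = "character",
                   excluded = "character"))

setValidity("BtuPartition", function(object) {
  msg <- character()
  asvs <- unlist(object@membership, use.names = FALSE)
  if (anyDuplicated(asvs))
    msg <- c(msg, "BTU member sets must be disjoint")
  if (is.null(names(object@membership)) ||
      anyDuplicated(names(object@membership)))
    msg <- c(msg, "BTU labels must be unique and named")
  if (length(intersect(asvs, object@excluded)))
    msg <- c(msg, "excluded ASVs cannot also be members")
  if (length(object@method) != 1L)
    msg <- c(msg, "method must be a single tag")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BtuPartition", function(object) {
  n <- lengths(object@membership)
  cat("BtuPartition (", object@method, "): ", length(n), " BTUs covering ",
      sum(n), " ASVs (", length(object@excluded), " excluded)\n", sep = "")
})

#' SimulationConfig: study conditions for the synthetic community generator
#'
#' Defaults are the desk-scale conditions used throughout the package's
#' validation: 20 host species x 5 samples, 12 BTUs (4 per regime) of 25
#' ASVs each, 250 nt markers, mean library 6000 reads.
#'
#' @slot nSpecies number of host species (>= 3).
#' @slot samplesPerSpecies samples per species; scalar or length-nSpecies.
#' @slot nNullBtus,nSpecificBtus,nCodivergingBtus planted BTUs per regime.
#' @slot asvsPerBtu ASVs per planted BTU.
#' @slot seqLength marker length in nt (>= 50).
#' @slot substitutionRate expected substitutions/site from root to tip of
#'   each (unit-height) bacterial guide tree.
#' @slot specificityConcentration Dirichlet concentration alpha > 0 of the
#'   per-ASV species-affinity vectors in specific BTUs; small alpha means
#'   strong specificity.
#' @slot codivergenceScale decay scale lambda (in tree-height units) of the
#'   phylogenetic-proximity affinity of co-diverging BTUs; 0 gives strictly
#'   diagonal (one species per ASV) affinity.
#' @slot meanLibrarySize negative-binomial mean reads per sample.
#' @slot libraryDispersion negative-binomial size (dispersion) parameter.
#' @slot seed integer seed; the same seed gives bit-identical output.
#' @aliases SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig",
         slots = c(nSpecies = "integer", samplesPerSpecies = "integer",
                   nNullBtus = "integer", nSpecificBtus = "integer",
                   nCodivergingBtus = "integer", asvsPerBtu = "integer",
                   seqLength = "integer", substitutionRate = "numeric",
                   specificityConcentration = "numeric",
                   codivergenceScale = "numeric",
                   meanLibrarySize = "numeric",
                   libraryDispersion = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nSpecies < 3L) msg <- c(msg, "nSpecies must be >= 3")
  if (any(object@samplesPerSpecies < 1L))
    msg <- c(msg, "samplesPerSpecies must be >= 1")
  if (!length(object@samplesPerSpecies) %in% c(1L, object@nSpecies))
    msg <- c(msg, "samplesPerSpecies must be scalar or one per species")
  if (object@nNullBtus < 0L || object@nSpecificBtus < 0L ||
      object@nCodivergingBtus < 0L)
    msg <- c(msg, "BTU counts must be >= 0")
  if (object@nNullBtus + object@nSpecificBtus + object@nCodivergingBtus < 1L)
    msg <- c(msg, "at least one BTU must be planted")
  if (object@asvsPerBtu < 1L) msg <- c(msg, "asvsPerBtu must be >= 1")
  if (object@seqLength < 50L) msg <- c(msg, "seqLength must be >= 50")
  if (object@substitutionRate < 0) msg <- c(msg, "substitutionRate must be >= 0")
  if (object@specificityConcentration <= 0)
    msg <- c(msg, "specificityConcentration must be > 0")
  if (object@codivergenceScale < 0)
    msg <- c(msg, "codivergenceScale must be >= 0")
  if (object@meanLibrarySize < 1) msg <- c(msg, "meanLibrarySize must be >= 1")
  if (object@libraryDispersion <= 0)
    msg <- c(msg, "libraryDispersion must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname SimulationConfig-class
#' @param nSpecies,samplesPerSpecies,nNullBtus,nSpecificBtus,nCodivergingBtus
#'   see slots.
#' @param asvsPerBtu,seqLength,substitutionRate,specificityConcentration
#'   see slots.
#' @param codivergenceScale,meanLibrarySize,libraryDispersion,seed see slots.
#' @return A validated `SimulationConfig`.
#' @export
simulationConfig <- function(nSpecies = 20, samplesPerSpecies = 5,
                             nNullBtus = 4, nSpecificBtus = 4,
                             nCodivergingBtus = 4, asvsPerBtu = 25,
                             seqLength = 250, substitutionRate = 0.02,
                             specificityConcentration = 0.1,
                             codivergenceScale = 0.5,
                             meanLibrarySize = 6000,
                             libraryDispersion = 1.5, seed = 1L) {
  new("SimulationConfig",
      nSpecies = as.integer(nSpecies),
      samplesPerSpecies = as.integer(samplesPerSpecies),
      nNullBtus = as.integer(nNullBtus),
      nSpecificBtus = as.integer(nSpecificBtus),
      nCodivergingBtus = as.integer(nCodivergingBtus),
      asvsPerBtu = as.integer(asvsPerBtu),
      seqLength = as.integer(seqLength),
      substitutionRate = as.numeric(substitutionRate),
      specificityConcentration = as.numeric(specificityConcentration),
      codivergenceScale = as.numeric(codivergenceScale),
      meanLibrarySize = as.numeric(meanLibrarySize),
      libraryDispersion = as.numeric(libraryDispersion),
      seed = as.integer(seed))
}

#' AnalysisConfig: settings of the full per-BTU analysis pipeline
#'
#' Defaults mirror the analysis conditions of the study design this
#' package implements: 10,000 permutations for PERMANOVA and PACo, 9999
#' for the high-specificity subset test, sample read minimum 1000, BTU
#' inclusion thresholds 5000 reads / 10 ASVs, FDR alpha 0.05 and a
#' high-specificity cutoff of adjusted R-squared >= 0.2.
#'
#' @slot binning subset of `c("genus", "sim95", "sim97")`.
#' @slot distances subset of `c("bray", "jaccard")`.
#' @slot nPermPermanova,nPermPaco,nPermSubset permutation counts (>= 99).
#' @slot minSampleReads sample library-size minimum (strict `<` removal).
#' @slot minBtuReads,minBtuAsvs BTU inclusion minima (inclusive `>=`).
#' @slot fdrAlpha FDR significance level.
#' @slot highSpecificityCutoff adjusted R-squared cutoff for the
#'   high-specificity category and subset test.
#' @slot rawDistance cluster on uncorrected p-distances instead of
#'   Jukes-Cantor-corrected ones.
#' @slot renormalizeWithinBtu renormalize proportions within each BTU
#'   before dissimilarity computation (sensitivity analysis; default off,
#'   proportions are of the whole library).
#' @slot fdrPooling `"by-family"` (one Benjamini-Hochberg family per
#'   binning method x distance x statistic) or `"pooled"` (all p-values of
#'   a binning method together).
#' @slot seed integer seed driving every permutation stream.
#' @aliases AnalysisConfig-class
#' @exportClass AnalysisConfig
setClass("AnalysisConfig",
         slots = c(binning = "character", distances = "character",
                   nPermPermanova = "integer", nPermPaco = "integer",
                   nPermSubset = "integer", minSampleReads = "numeric",
                   minBtuReads = "numeric", minBtuAsvs = "numeric",
                   fdrAlpha = "numeric", highSpecificityCutoff = "numeric",
                   rawDistance = "logical",
                   renormalizeWithinBtu = "logical",
                   fdrPooling = "character", seed = "integer"))

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  if (!length(object@binning) ||
      !all(object@binning %in% c("genus", "sim95", "sim97")))
    msg <- c(msg, "binning must be a subset of genus/sim95/sim97")
  if (!length(object@distances) ||
      !all(object@distances %in% c("bray", "jaccard")))
    msg <- c(msg, "distances must be a subset of bray/jaccard")
  if (object@nPermPermanova < 99L || object@nPermPaco < 99L ||
      object@nPermSubset < 99L)
    msg <- c(msg, "all permutation counts must be >= 99")
  if (object@fdrAlpha <= 0 || object@fdrAlpha >= 1)
    msg <- c(msg, "fdrAlpha must be in (0,1)")
  if (!object@fdrPooling %in% c("by-family", "pooled"))
    msg <- c(msg, "fdrPooling must be 'by-family' or 'pooled'")
  if (length(msg)) msg else TRUE
})

#' @rdname AnalysisConfig-class
#' @param binning,distances,nPermPermanova,nPermPaco,nPermSubset see slots.
#' @param minSampleReads,minBtuReads,minBtuAsvs,fdrAlpha see slots.
#' @param highSpecificityCutoff,rawDistance,renormalizeWithinBtu see slots.
#' @param fdrPooling,seed see slots.
#' @return A validated `AnalysisConfig`.
#' @export
analysisConfig <- function(binning = c("genus", "sim95", "sim97"),
                           distances = c("bray", "jaccard"),
                           nPermPermanova = 10000, nPermPaco = 10000,
                           nPermSubset = 9999, minSampleReads = 1000,
                           minBtuReads = 5000, minBtuAsvs = 10,
                           fdrAlpha = 0.05, highSpecificityCutoff = 0.2,
                           rawDistance = FALSE,
                           renormalizeWithinBtu = FALSE,
                           fdrPooling = "by-family", seed = 1L) {
  new("AnalysisConfig",
      binning = binning, distances = distances,
      nPermPermanova = as.integer(nPermPermanova),
      nPermPaco = as.integer(nPermPaco),
      nPermSubset = as.integer(nPermSubset),
      minSampleReads = as.numeric(minSampleReads),
      minBtuReads = as.numeric(minBtuReads),
      minBtuAsvs = as.numeric(minBtuAsvs),
      fdrAlpha = as.numeric(fdrAlpha),
      highSpecificityCutoff = as.numeric(highSpecificityCutoff),
      rawDistance = isTRUE(rawDistance),
      renormalizeWithinBtu = isTRUE(renormalizeWithinBtu),
      fdrPooling = fdrPooling, seed = as.integer(seed))
}
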