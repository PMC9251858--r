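# Loading, validation and filtering of the input artifacts: counts TSV,
# FASTA, taxonomy TSV, sample metadata TSV and Newick host tree.

#' Write a dataset to plain-text files
#'
#' Emits the five artifacts read back by [loadDataset()]: `counts.tsv`
#' (rows = samples, header = ASV ids, first column `sample`),
#' `sequences.fasta`, `taxonomy.tsv`, `metadata.tsv` (columns `sample`,
#' `species`), `host_tree.nwk`; plus `truth.json` when a simulation
#' truth is supplied.
#'
#' @param x an [AsvExperiment-class], or the list returned by
#'   [simulateDataset()] (in which case the truth is written as well).
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(x, dir) {
  truth <- NULL
  if (is.list(x) && !methods::is(x, "AsvExperiment")) {
    truth <- x$truth
    x <- x$experiment
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cts <- t(asvCounts(x))
  df <- data.frame(sample = rownames(cts), cts, check.names = FALSE)
  utils::write.table(df, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(asvSequences(x),
                              file.path(dir, "sequences.fasta"))
  tax <- data.frame(asv = rownames(x), taxonomyTable(x),
                    check.names = FALSE)
  utils::write.table(tax, file.path(dir, "taxonomy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample = colnames(x), species = hostSpecies(x))
  utils::write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(hostTree(x)))
    ape::write.tree(hostTree(x), file.path(dir, "host_tree.nwk"))
  if (!is.null(truth))
    jsonlite::write_json(
      list(regime = as.list(truth$regime),
           strength = as.list(truth$strength),
           btuOf = as.list(truth$btuOf)),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

.readTsv <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse ", what, " (", path, "): ",
                             conditionMessage(e), call. = FALSE))
  if (!nrow(df) || !ncol(df)) stop(what, " file is empty: ", path)
  df
}

#' Load and cross-validate a dataset from its five input files
#'
#' The ASV sets of the count table, FASTA and taxonomy must be identical,
#' every sample must carry a species label, and every species must
#' resolve to a host-tree tip; violations raise an error naming the
#' offending ids. Ids are preserved verbatim (no case folding).
#'
#' @param countsPath TSV, rows = samples, first column `sample`, remaining
#'   columns = ASV read counts.
#' @param fastaPath FASTA of ASV marker sequences.
#' @param taxonomyPath TSV with columns `asv`, `phylum` ... `genus`.
#' @param metadataPath TSV with columns `sample`, `species`.
#' @param treePath Newick host phylogeny (or `NULL` to omit).
#' @param dir alternatively, a directory holding the standard file names
#'   produced by [writeDataset()]; individual paths override it.
#' @return An [AsvExperiment-class].
#' @export
loadDataset <- function(countsPath = NULL, fastaPath = NULL,
                        taxonomyPath = NULL, metadataPath = NULL,
                        treePath = NULL, dir = NULL) {
  if (!is.null(dir)) {
    if (is.null(countsPath)) countsPath <- file.path(dir, "counts.tsv")
    if (is.null(fastaPath)) fastaPath <- file.path(dir, "sequences.fasta")
    if (is.null(taxonomyPath)) taxonomyPath <- file.path(dir, "taxonomy.tsv")
    if (is.null(metadataPath)) metadataPath <- file.path(dir, "metadata.tsv")
    if (is.null(treePath) && file.exists(file.path(dir, "host_tree.nwk")))
      treePath <- file.path(dir, "host_tree.nwk")
  }
  cdf <- .readTsv(countsPath, "counts")
  if (colnames(cdf)[1] != "sample")
    stop("counts file must have 'sample' as its first column")
  counts <- as.matrix(cdf[, -1, drop = FALSE])
  rownames(counts) <- as.character(cdf$sample)
  if (anyDuplicated(rownames(counts)))
    stop("duplicated sample ids in counts")
  if (anyDuplicated(colnames(counts)))
    stop("duplicated ASV ids in counts")
  counts <- t(counts)                    # ASVs x samples

  seqs <- tryCatch(Biostrings::readDNAStringSet(fastaPath),
                   error = function(e) stop("failed to parse FASTA (",
                     fastaPath, "): ", conditionMessage(e), call. = FALSE))
  names(seqs) <- sub("\\s.*$", "", names(seqs))

  tax <- .readTsv(taxonomyPath, "taxonomy")
  if (!"asv" %in% colnames(tax))
    stop("taxonomy file must have an 'asv' column")
  rownames(tax) <- as.character(tax$asv)

  meta <- .readTsv(metadataPath, "metadata")
  if (!all(c("sample", "species") %in% colnames(meta)))
    stop("metadata file must have 'sample' and 'species' columns")
  species <- setNames(as.character(meta$species), as.character(meta$sample))

  tree <- NULL
  if (!is.null(treePath)) {
    tree <- tryCatch(suppressWarnings(ape::read.tree(treePath)),
                     error = function(e) NULL)
    if (is.null(tree))
      stop("failed to parse Newick tree: ", treePath)
  }

  asv <- rownames(counts)
  miss <- setdiff(asv, names(seqs))
  if (length(miss))
    stop("ASVs in counts but missing from FASTA: ",
         paste(miss, collapse = ", "))
  miss <- setdiff(asv, rownames(tax))
  if (length(miss))
    stop("ASVs in counts but missing from taxonomy: ",
         paste(miss, collapse = ", "))
  extra <- setdiff(names(seqs), asv)
  if (length(extra))
    stop("ASVs in FASTA but missing from counts: ",
         paste(extra, collapse = ", "))
  miss <- setdiff(colnames(counts), names(species))
  if (length(miss))
    stop("samples missing from metadata: ", paste(miss, collapse = ", "))

  x <- AsvExperiment(counts, seqs, tax, species, hostTree = tree)
  message("loaded ", ncol(x), " samples (",
          length(unique(hostSpecies(x))), " species), ", nrow(x),
          " ASVs, ", sum(as.numeric(asvCounts(x))), " reads")
  x
}

#' Remove non-target and unassignable ASVs
#'
#' Discards ASVs with no phylum-level assignment and ASVs whose rank
#' labels identify chloroplast, mitochondrial or archaeal sequences
#' (case-insensitive prefix match at any rank), the standard cleanup of a
#' 16S amplicon table before community analysis.
#'
#' @param x an [AsvExperiment-class].
#' @return The filtered [AsvExperiment-class].
#' @export
filterTaxa <- function(x) {
  tax <- taxonomyTable(x)
  unassigned <- function(v) is.na(v) | trimws(v) == ""
  bad <- unassigned(tax$phylum)
  for (r in .RANKS) {
    v <- tolower(trimws(as.character(tax[[r]])))
    bad <- bad | (!is.na(v) & grepl("^(chloroplast|mitochondri|archaea)", v))
  }
  x[!bad, ]
}

#' Remove samples with too few reads
#'
#' Samples whose library size (after any ASV filtering) is strictly below
#' `minReads` are dropped; apply [filterTaxa()] first so that library
#' sizes reflect retained ASVs only.
#'
#' @param x an [AsvExperiment-class].
#' @param minReads minimum library size; a sample with exactly `minReads`
#'   reads is kept.
#' @return The filtered [AsvExperiment-class].
#' @export
filterSamples <- function(x, minReads = 1000) {
  if (minReads < 0) stop("minReads must be >= 0")
  keep <- librarySizes(x) >= minReads
  if (!any(keep)) stop("no samples left after the library-size filter")
  x[, keep]
}

#' Cophenetic (tip-to-tip path) distances of a phylogeny
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @return A symmetric matrix over tip labels; entry (i, j) is the sum of
#'   branch lengths on the path between tips i and j.
#' @export
copheneticDistances <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo'")
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}
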