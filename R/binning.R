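# BTU definition: reference-based (genus) binning, center-star multiple
# alignment, Jukes-Cantor distances and complete-linkage clustering.

#' Reference-based binning: one BTU per assigned genus
#'
#' ASVs sharing a genus-level assignment form one BTU; ASVs with no genus
#' assignment are excluded (and reported via [excludedAsvs()]).
#'
#' @param x an [AsvExperiment-class].
#' @return A [BtuPartition-class] with method `"genus"`.
#' @export
binByGenus <- function(x) {
  g <- as.character(taxonomyTable(x)$genus)
  asv <- rownames(x)
  unassigned <- is.na(g) | trimws(g) == ""
  if (all(unassigned)) {
    warning("no ASV has a genus-level assignment; empty partition")
    return(new("BtuPartition", membership = setNames(list(), character(0)),
               method = "genus", excluded = asv))
  }
  membership <- split(asv[!unassigned], g[!unassigned])
  membership <- membership[order(names(membership))]
  message(sum(!unassigned), "/", length(asv), " ASVs assigned to ",
          length(membership), " genera (", sum(unassigned), " excluded)")
  new("BtuPartition", membership = membership, method = "genus",
      excluded = asv[unassigned])
}

# gaps inserted into the center before each center position (slots 0..Lc)
.insProfile <- function(cenChars, Lc) {
  ins <- integer(Lc + 1L)
  pos <- 0L
  for (ch in cenChars) {
    if (ch == "-") ins[pos + 1L] <- ins[pos + 1L] + 1L else pos <- pos + 1L
  }
  ins
}

.expandToMaster <- function(cenChars, othChars, Lc, master) {
  out <- character(0)
  buf <- character(0)
  pos <- 0L
  for (idx in seq_along(cenChars)) {
    if (cenChars[idx] == "-") {
      buf <- c(buf, othChars[idx])
    } else {
      out <- c(out, buf, rep("-", master[pos + 1L] - length(buf)),
               othChars[idx])
      buf <- character(0)
      pos <- pos + 1L
    }
  }
  c(out, buf, rep("-", master[Lc + 1L] - length(buf)))
}

#' Center-star multiple alignment of marker sequences
#'
#' Picks the sequence with the smallest summed k-mer distance to all
#' others as the center, aligns every other sequence to it by global
#' (Needleman-Wunsch) alignment with match +1, mismatch -1, gap -2, and
#' merges the pairwise alignments by pooling the gaps inserted into the
#' center. Same-locus amplicons of near-equal length (the intended input)
#' give alignments essentially identical to profile-based aligners.
#' Inputs whose sequences all share one length are treated as already
#' position-homologous and returned unchanged: denoised same-primer
#' amplicons of equal length need no gaps, whereas forcing pairwise
#' alignment between unrelated sequences would inject spurious ones.
#'
#' @param seqs a [Biostrings::DNAStringSet] (>= 1 sequence).
#' @return A gapped [Biostrings::DNAStringSet], all of equal width;
#'   removing gaps recovers the input exactly.
#' @export
alignSequences <- function(seqs) {
  seqs <- Biostrings::DNAStringSet(seqs)
  if (!length(seqs)) stop("alignSequences: empty input")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (length(seqs) == 1L) return(seqs)
  # same-locus amplicons of one length are already position-homologous;
  # pairwise alignment between unrelated (saturated) sequences would only
  # inject spurious gaps into the merged columns
  if (length(unique(Biostrings::width(seqs))) == 1L) return(seqs)

  kk <- max(1L, min(5L, min(Biostrings::width(seqs))))
  fr <- Biostrings::oligonucleotideFrequency(seqs, width = kk)
  D <- as.matrix(stats::dist(fr, method = "manhattan"))
  center <- which.min(rowSums(D))
  others <- setdiff(seq_along(seqs), center)

  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  pa <- Biostrings::pairwiseAlignment(
    seqs[others], seqs[[center]], type = "global",
    substitutionMatrix = sm, gapOpening = 0, gapExtension = 2)
  Lc <- Biostrings::width(seqs)[center]
  # pattern()/subject() clip terminal-gap columns, so restore them from
  # the aligned-region coordinates (much cheaper than alignedPattern())
  patA <- as.character(Biostrings::pattern(pa))
  subA <- as.character(Biostrings::subject(pa))
  ps <- Biostrings::start(Biostrings::pattern(pa))
  pe <- Biostrings::end(Biostrings::pattern(pa))
  ss <- Biostrings::start(Biostrings::subject(pa))
  se <- Biostrings::end(Biostrings::subject(pa))
  pstr <- as.character(seqs[others])
  cstr <- as.character(seqs[[center]])
  patPre <- substr(pstr, 1, ps - 1)
  patSuf <- substr(pstr, pe + 1, nchar(pstr))
  subPre <- substr(rep(cstr, length(ss)), 1, ss - 1)
  subSuf <- substr(rep(cstr, length(se)), se + 1, Lc)
  gaps <- function(n) strrep("-", n)
  othStr <- paste0(patPre, gaps(nchar(subPre)), patA,
                   patSuf, gaps(nchar(subSuf)))
  cenStr <- paste0(gaps(nchar(patPre)), subPre, subA,
                   gaps(nchar(patSuf)), subSuf)
  if (!any(grepl("-", othStr, fixed = TRUE)) &&
      !any(grepl("-", cenStr, fixed = TRUE))) {
    return(seqs)                       # indel-free: alignment is identity
  }
  cenAln <- strsplit(cenStr, "")
  othAln <- strsplit(othStr, "")

  cenChars <- strsplit(as.character(seqs[[center]]), "")[[1]]
  master <- Reduce(pmax, lapply(cenAln, .insProfile, Lc = Lc),
                   integer(Lc + 1L))

  out <- vector("list", length(seqs))
  cenOut <- character(0)
  for (i in seq_len(Lc))
    cenOut <- c(cenOut, rep("-", master[i]), cenChars[i])
  out[[center]] <- c(cenOut, rep("-", master[Lc + 1L]))
  for (j in seq_along(others))
    out[[others[j]]] <- .expandToMaster(cenAln[[j]], othAln[[j]], Lc, master)

  res <- Biostrings::DNAStringSet(vapply(out, paste0, "", collapse = ""))
  names(res) <- names(seqs)
  res
}

# pairwise site tallies over an aligned character matrix:
# comparable sites (both non-gap), matches, transitions
.pairTallies <- function(m) {
  ind <- lapply(c("A", "C", "G", "T"), function(b) (m == b) * 1)
  ng <- ind[[1]] + ind[[2]] + ind[[3]] + ind[[4]]
  comp <- tcrossprod(ng)
  matches <- Reduce("+", lapply(ind, tcrossprod))
  transitions <- tcrossprod(ind[[1]], ind[[3]]) +
    tcrossprod(ind[[3]], ind[[1]]) +
    tcrossprod(ind[[2]], ind[[4]]) + tcrossprod(ind[[4]], ind[[2]])
  list(comp = comp, matches = matches, transitions = transitions)
}

.jcTransform <- function(p) {
  d <- ifelse(p >= 0.75, Inf, -0.75 * log(pmax(1 - 4 * p / 3, 0)))
  d[p == 0] <- 0
  d
}

#' Pairwise distance matrix from aligned sequences
#'
#' Proportions of mismatching sites are computed over sites where both
#' sequences are ungapped, then corrected under the chosen model:
#' `"JC69"` applies d = -(3/4) log(1 - 4p/3), with an infinite sentinel
#' at saturation (p >= 0.75); `"raw"` returns p itself.
#'
#' @param aligned gapped [Biostrings::DNAStringSet] of equal widths (see
#'   [alignSequences()]).
#' @param correction `"JC69"` (default) or `"raw"`.
#' @return Symmetric distance matrix over the sequence names.
#' @export
jcDistanceMatrix <- function(aligned, correction = c("JC69", "raw")) {
  correction <- match.arg(correction)
  aligned <- Biostrings::DNAStringSet(aligned)
  if (length(unique(Biostrings::width(aligned))) != 1L)
    stop("aligned sequences must share one gapped length")
  m <- as.matrix(aligned)
  tl <- .pairTallies(m)
  off <- upper.tri(tl$comp)
  if (any(tl$comp[off] == 0))
    stop("undefined distance: some sequence pairs share no comparable sites")
  p <- (tl$comp - tl$matches) / tl$comp
  d <- if (correction == "raw") p else .jcTransform(p)
  diag(d) <- 0
  dimnames(d) <- list(names(aligned), names(aligned))
  d
}

#' Jukes-Cantor distance between two aligned sequences
#'
#' @param a,b aligned (gapped) sequences of equal length, as character
#'   strings or [Biostrings::DNAString]s.
#' @param correction `"JC69"` or `"raw"`.
#' @return The corrected distance; `Inf` at saturation (p >= 3/4).
#' @examples
#' jcDistance(strrep("A", 9), paste0(strrep("A", 8), "C"))  # p = 1/9
#' @export
jcDistance <- function(a, b, correction = c("JC69", "raw")) {
  correction <- match.arg(correction)
  s <- Biostrings::DNAStringSet(c(as.character(a), as.character(b)))
  if (length(unique(Biostrings::width(s))) != 1L)
    stop("sequences must share one gapped length")
  jcDistanceMatrix(s, correction)[1, 2]
}

#' Reference-free binning by complete-linkage clustering
#'
#' Agglomerative complete-linkage clustering of the distance matrix, cut
#' at height h = 1 - `similarityThreshold`. Complete linkage guarantees
#' that the maximum pairwise distance within every BTU is at most h;
#' this is asserted on the produced partition. Infinite (saturated)
#' distances act as "never merge".
#'
#' @param d symmetric distance matrix over ASV ids (may contain `Inf`).
#' @param similarityThreshold in (0, 1); e.g. 0.97 cuts at distance 0.03.
#' @param method tag stored in the partition (default `"simXX"` from the
#'   threshold).
#' @return A [BtuPartition-class]; labels `BTU_0001`, ... in dendrogram
#'   order of first appearance.
#' @export
completeLinkageBins <- function(d, similarityThreshold,
                                method = sprintf("sim%d",
                                  round(similarityThreshold * 100))) {
  if (similarityThreshold <= 0 || similarityThreshold >= 1)
    stop("similarityThreshold must be in (0, 1)")
  d <- as.matrix(d)
  if (is.null(rownames(d)))
    stop("distance matrix must carry ASV ids as dimnames")
  h <- 1 - similarityThreshold
  if (nrow(d) == 1L) {
    cl <- setNames(1L, rownames(d))
  } else {
    dd <- d
    finiteMax <- suppressWarnings(max(dd[is.finite(dd)], 0))
    dd[!is.finite(dd)] <- max(finiteMax, 1) * 2 + 1
    hc <- stats::hclust(stats::as.dist(dd), method = "complete")
    cl <- stats::cutree(hc, h = h)
  }
  membership <- split(names(cl), cl)
  names(membership) <- sprintf("BTU_%04d", seq_along(membership))
  # complete-linkage guarantee, asserted post hoc on every partition
  for (mem in membership) {
    if (length(mem) > 1L && max(d[mem, mem]) > h + 1e-12)
      stop("internal error: complete-linkage guarantee violated")
  }
  new("BtuPartition", membership = membership, method = method,
      excluded = character(0))
}

#' Align, compute distances and cluster in one call
#'
#' @param x an [AsvExperiment-class].
#' @param similarityThreshold e.g. 0.95 or 0.97.
#' @param rawDistance cluster on uncorrected p-distances instead of the
#'   Jukes-Cantor-corrected scale (the default matches the corrected
#'   scale of the distance matrix the clustering criterion is defined
#'   on; corrected distance exceeds 1 - identity, so the two cuts can
#'   differ for borderline pairs).
#' @param aligned optionally, a precomputed alignment (to share across
#'   thresholds).
#' @param distances optionally, a precomputed distance matrix.
#' @return A [BtuPartition-class].
#' @export
binBySimilarity <- function(x, similarityThreshold, rawDistance = FALSE,
                            aligned = NULL, distances = NULL) {
  if (is.null(distances)) {
    if (is.null(aligned)) aligned <- alignSequences(asvSequences(x))
    distances <- jcDistanceMatrix(aligned,
                                  if (rawDistance) "raw" else "JC69")
  }
  completeLinkageBins(distances, similarityThreshold)
}

#' Apply the BTU inclusion filters
#'
#' Keeps BTUs represented by at least `minReads` reads and `minAsvs`
#' ASVs (both thresholds inclusive).
#'
#' @param partition a [BtuPartition-class].
#' @param x the [AsvExperiment-class] providing read counts.
#' @param minReads,minAsvs inclusion minima.
#' @return The filtered [BtuPartition-class]; the retained-read fraction
#'   (of all reads in `x`) is reported via `message()` and attached as
#'   attribute `retainedReadFraction`.
#' @export
filterBtus <- function(partition, x, minReads = 5000, minAsvs = 10) {
  s <- btuSummary(partition, x)
  keep <- s$reads >= minReads & s$nAsvs >= minAsvs
  out <- new("BtuPartition",
             membership = partition@membership[s$btu[keep]],
             method = partition@method, excluded = partition@excluded)
  total <- sum(as.numeric(asvCounts(x)))
  frac <- if (total > 0) sum(s$reads[keep]) / total else 0
  message(sum(keep), "/", nrow(s), " BTUs retained (",
          round(100 * frac), "% of reads)")
  attr(out, "retainedReadFraction") <- frac
  out
}
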