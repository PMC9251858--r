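# Shared fixtures, built in code.

# tiny configurable simulation for fast tests
tinyConfig <- function(seed = 1, ...) {
  args <- list(nSpecies = 6, samplesPerSpecies = 3, nNullBtus = 1,
               nSpecificBtus = 1, nCodivergingBtus = 1, asvsPerBtu = 8,
               seqLength = 80, meanLibrarySize = 800,
               libraryDispersion = 5, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(simulationConfig, args)
}

# hand-built 4-sample symmetric toy: within-pair d = 1, between d = 2
toyDistance <- function() {
  d <- matrix(2, 4, 4) - diag(2, 4)
  d[1, 2] <- d[2, 1] <- 1
  d[3, 4] <- d[4, 3] <- 1
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  d
}

# an AsvExperiment assembled by hand with known counts/taxonomy
handExperiment <- function() {
  counts <- matrix(
    c(10, 30, 60,
      5,  0, 95,
      0, 50, 50,
      20, 20, 60),
    nrow = 4, byrow = TRUE,
    dimnames = list(paste0("asv", 1:4), paste0("smp", 1:3)))
  seqs <- Biostrings::DNAStringSet(setNames(
    c("ACGTACGTAC", "ACGTACGTAA", "TTGTACGTAC", "ACGAACGTAC"),
    paste0("asv", 1:4)))
  tax <- data.frame(
    phylum = c("Firmicutes", "Firmicutes", NA, "Proteobacteria"),
    class = c("Bacilli", "Bacilli", "X", "Gamma"),
    order = c("Lactobacillales", "Chloroplast", "Y", "Enterobacterales"),
    family = c("F1", "F2", "F3", "F4"),
    genus = c("Lactococcus", "Lactococcus", "G3", NA),
    row.names = paste0("asv", 1:4))
  tree <- ape::read.tree(text = "((spA:1,spB:1):1,spC:2);")
  AsvExperiment(counts, seqs, tax,
                species = setNames(c("spA", "spB", "spC"),
                                   paste0("smp", 1:3)),
                hostTree = tree)
}

# Euclidean distance matrix from random planar/3D points, with labels
randomEuclideanDist <- function(n, k = 2, seed = 1) {
  set.seed(seed)
  pts <- matrix(rnorm(n * k), n, k)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
  list(d = d, pts = pts)
}

# classical one-way MANOVA trace pseudo-F from coordinates (oracle for
# PERMANOVA on Euclidean distances)
manovaTraceF <- function(pts, labels) {
  f <- factor(labels)
  n <- nrow(pts)
  k <- nlevels(f)
  ctr <- scale(pts, scale = FALSE)
  sst <- sum(ctr^2)
  ssw <- 0
  for (g in split(seq_len(n), f)) {
    cg <- scale(pts[g, , drop = FALSE], scale = FALSE)
    ssw <- ssw + sum(cg^2)
  }
  ((sst - ssw) / (k - 1)) / (ssw / (n - k))
}
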