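test_that("genus binning groups assigned ASVs and excludes the rest", {
  counts <- matrix(1L, 6, 2,
                   dimnames = list(paste0("a", 1:6), c("s1", "s2")))
  seqs <- Biostrings::DNAStringSet(setNames(rep("ACGTAC", 6),
                                            paste0("a", 1:6)))
  tax <- data.frame(phylum = "P", class = "C", order = "O", family = "F",
                    genus = c("G1", "G1", "G1", "G2", "G2", NA),
                    row.names = paste0("a", 1:6))
  x <- AsvExperiment(counts, seqs, tax,
                     species = setNames(c("spA", "spB"), c("s1", "s2")))
  part <- suppressMessages(binByGenus(x))
  expect_setequal(btuNames(part), c("G1", "G2"))
  expect_length(btuAsvs(part, "G1"), 3)
  expect_length(btuAsvs(part, "G2"), 2)
  expect_identical(excludedAsvs(part), "a6")

  tax$genus <- NA
  x2 <- AsvExperiment(counts, seqs, tax,
                      species = setNames(c("spA", "spB"), c("s1", "s2")))
  expect_warning(p2 <- binByGenus(x2), "genus")
  expect_length(btuNames(p2), 0)
})

test_that("center-star alignment handles indels and round-trips", {
  # indel-free input: alignment is the identity
  sim <- simulateDataset(tinyConfig(seed = 5))
  seqs <- asvSequences(sim$experiment)[1:8]
  al <- alignSequences(seqs)
  expect_identical(as.character(al), as.character(seqs))

  # hand case at the stated scores: one terminal gap in the shorter
  al2 <- alignSequences(Biostrings::DNAStringSet(c(x = "ACGT", y = "ACG")))
  expect_equal(unique(Biostrings::width(al2)), 4L)
  expect_equal(sum(strsplit(as.character(al2[["y"]]), "")[[1]] == "-"), 1L)
  expect_equal(as.character(al2[["x"]]), "ACGT")

  # internal indel + round trip
  s3 <- Biostrings::DNAStringSet(c(a = "AACCGGTTAACC", b = "AACCGTTAACC",
                                   c = "AACCGGTTAACG"))
  al3 <- alignSequences(s3)
  expect_length(unique(Biostrings::width(al3)), 1L)
  expect_identical(gsub("-", "", as.character(al3)), as.character(s3))

  expect_error(alignSequences(Biostrings::DNAStringSet()), "empty")
})

test_that("Jukes-Cantor distances follow the closed form with saturation", {
  expect_equal(jcDistance("ACGTACGTAC", "ACGTACGTAC"), 0)
  # p = 0.1 over 10 comparable sites
  d <- jcDistance("ACGTACGTAC", "ACGTACGTAA")
  expect_equal(d, -0.75 * log(1 - 4 * 0.1 / 3))
  expect_lt(abs(d - 0.10732), 1e-5)
  # p = 0.75 hits the saturation sentinel
  expect_identical(jcDistance("AAAA", "ACGT"), Inf)
  # monotone in p on [0, 0.75)
  ds <- vapply(1:7, function(k)
    jcDistance(strrep("A", 10),
               paste0(strrep("C", k), strrep("A", 10 - k))), numeric(1))
  expect_true(all(diff(ds) > 0))
  # zero comparable sites is undefined
  expect_error(jcDistance("AA--", "--AA"), "comparable")
})

test_that("distance matrices agree with ape::dist.dna", {
  sim <- simulateDataset(tinyConfig(seed = 6, substitutionRate = 0.1))
  seqs <- asvSequences(sim$experiment)[1:10]
  al <- alignSequences(seqs)
  mine <- jcDistanceMatrix(al)
  bin <- ape::as.DNAbin(strsplit(tolower(as.character(al)), ""))
  ref <- suppressWarnings(as.matrix(ape::dist.dna(bin, model = "JC69",
                                                  pairwise.deletion = TRUE)))
  ref <- ref[rownames(mine), colnames(mine)]
  # saturated pairs: our Inf sentinel corresponds to ape's NaN
  expect_identical(unname(!is.finite(mine)), unname(!is.finite(ref)))
  fin <- is.finite(mine)
  expect_equal(unname(mine[fin]), unname(ref[fin]), tolerance = 1e-10)
})

test_that("complete linkage honours the cut height and its guarantee", {
  d <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  d["a", "b"] <- d["b", "a"] <- 0.01
  d["b", "c"] <- d["c", "b"] <- 0.01
  d["a", "c"] <- d["c", "a"] <- 0.04
  part <- completeLinkageBins(d, 0.97)
  sizes <- sort(lengths(btuAsvs(part)))
  expect_equal(unname(sizes), c(1L, 2L))
  # the produced 2-cluster must satisfy the guarantee (a and c cannot
  # co-occur); enumerate the valid partitions of 3 items at h = 0.03
  pair <- btuAsvs(part)[[which(lengths(btuAsvs(part)) == 2)]]
  expect_lte(max(d[pair, pair]), 0.03)

  dz <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_length(btuNames(completeLinkageBins(dz, 0.97)), 1L)
})

test_that("a looser threshold coarsens the stricter partition", {
  for (i in 1:10) {
    set.seed(i)
    n <- 15
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0, 0.12)
    d <- d + t(d)
    dimnames(d) <- list(paste0("a", 1:n), paste0("a", 1:n))
    p97 <- completeLinkageBins(d, 0.97)
    p95 <- completeLinkageBins(d, 0.95)
    of95 <- setNames(rep(btuNames(p95), lengths(btuAsvs(p95))),
                     unlist(btuAsvs(p95)))
    for (b in btuNames(p97))
      expect_length(unique(of95[btuAsvs(p97, b)]), 1L)
  }
})

test_that("saturated distances never merge", {
  d <- matrix(Inf, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  diag(d) <- 0
  d["a", "b"] <- d["b", "a"] <- 0.001
  part <- completeLinkageBins(d, 0.97)
  expect_length(btuNames(part), 2L)
})

test_that("BTU filters are inclusive at both thresholds", {
  nine <- matrix(667L, 9, 1, dimnames = list(paste0("x", 1:9), "s1"))
  ten <- matrix(500L, 10, 1, dimnames = list(paste0("y", 1:10), "s1"))
  counts <- rbind(nine, ten)
  counts <- cbind(counts, counts)  # two samples to satisfy the class
  colnames(counts) <- c("s1", "s2")
  seqs <- Biostrings::DNAStringSet(setNames(rep("ACGTAC", 19),
                                            rownames(counts)))
  tax <- data.frame(phylum = "P", class = "C", order = "O", family = "F",
                    genus = c(rep("Gnine", 9), rep("Gten", 10)),
                    row.names = rownames(counts))
  x <- AsvExperiment(counts, seqs, tax,
                     species = setNames(c("spA", "spB"), c("s1", "s2")))
  part <- suppressMessages(binByGenus(x))
  # Gnine: 9 ASVs, 12006 reads -> dropped on richness;
  # Gten: 10 ASVs, 10000 reads -> kept (inclusive)
  f <- suppressMessages(filterBtus(part, x, minReads = 5000, minAsvs = 10))
  expect_identical(btuNames(f), "Gten")
  f0 <- suppressMessages(filterBtus(part, x, minReads = 0, minAsvs = 0))
  expect_setequal(btuNames(f0), btuNames(part))
})

test_that("well-separated planted BTUs are recovered at both thresholds", {
  cfg <- simulationConfig(nSpecies = 5, samplesPerSpecies = 2,
                          nNullBtus = 3, nSpecificBtus = 0,
                          nCodivergingBtus = 0, asvsPerBtu = 6,
                          seqLength = 400, substitutionRate = 0.004,
                          meanLibrarySize = 500, seed = 8)
  sim <- simulateDataset(cfg)
  planted <- split(names(sim$truth$btuOf), sim$truth$btuOf)
  al <- alignSequences(asvSequences(sim$experiment))
  dm <- jcDistanceMatrix(al)
  for (thr in c(0.95, 0.97)) {
    part <- completeLinkageBins(dm, thr)
    got <- unname(lapply(btuAsvs(part), sort))
    want <- unname(lapply(planted, sort))
    expect_setequal(got, want)
  }
})
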