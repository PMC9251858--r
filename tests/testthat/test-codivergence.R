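test_that("PCoA reconstructs distances and flags non-Euclidean input", {
  # 3 collinear points: a-b = 1, b-c = 1, a-c = 2
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  pc <- pcoaScores(d)
  expect_equal(ncol(pc$points), 1L)
  expect_equal(as.matrix(dist(pc$points)), unname(d), tolerance = 1e-9,
               ignore_attr = TRUE)

  inst <- randomEuclideanDist(15, k = 3, seed = 7)
  pc2 <- pcoaScores(inst$d)
  expect_equal(unname(as.matrix(dist(pc2$points))), unname(inst$d),
               tolerance = 1e-8)
  expect_equal(pc2$negative, 0)

  bad <- matrix(c(0, 1, 3, 1, 0, 1, 3, 1, 0), 3, 3,
                dimnames = list(letters[1:3], letters[1:3]))
  expect_gt(pcoaScores(bad)$negative, 0)
})

test_that("Procrustes is invariant to similarity transforms and padding", {
  set.seed(3)
  X <- matrix(rnorm(40), 20, 2)
  th <- 37 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Y <- 5 * (X %*% R) + 2
  fit <- procrustesFit(X, Y)
  expect_equal(fit$m2, 0, tolerance = 1e-12)
  expect_equal(fit$r, 1, tolerance = 1e-8)

  # independent configurations: r falls inside its own permutation band
  set.seed(4)
  Y2 <- matrix(rnorm(200), 100, 2)
  X2 <- matrix(rnorm(200), 100, 2)
  robs <- procrustesFit(X2, Y2)$r
  rnull <- vapply(1:200, function(i)
    procrustesFit(X2[sample(100), ], Y2)$r, numeric(1))
  expect_gt(robs, quantile(rnull, 0.025) - 1e-9)
  expect_lt(robs, quantile(rnull, 0.975) + 1e-9)

  # differing axis counts match the explicit zero-padding oracle
  X3 <- matrix(rnorm(30), 15, 2)
  Y3 <- matrix(rnorm(75), 15, 5)
  direct <- procrustesFit(X3, Y3)$m2
  padded <- procrustesFit(cbind(X3, matrix(0, 15, 3)), Y3)$m2
  expect_equal(direct, padded, tolerance = 1e-12)

  expect_error(procrustesFit(X3[1:2, ], Y3[1:2, ]),
               class = "btudiv_untestable")
})

test_that("block permutation reassigns intact blocks", {
  species <- setNames(c("A", "A", "B", "C", "C", "C"), paste0("s", 1:6))
  for (i in 1:20) {
    set.seed(i)
    perm <- blockPermute(species)
    expect_setequal(unique(perm), c("A", "B", "C"))
    # block sizes preserved and blocks intact
    expect_length(unique(perm[c("s1", "s2")]), 1L)
    expect_length(unique(perm[c("s4", "s5", "s6")]), 1L)
    expect_equal(sort(as.vector(table(perm))), c(1, 2, 3))
  }
  # two-block worked case: any non-identity draw is the swap
  sp2 <- setNames(c("A", "A", "B"), c("s1", "s2", "s3"))
  found <- FALSE
  for (i in 1:50) {
    set.seed(i)
    perm <- blockPermute(sp2)
    if (perm[["s1"]] == "B") {
      expect_identical(unname(perm), c("B", "B", "A"))
      found <- TRUE
      break
    }
  }
  expect_true(found)
  expect_error(blockPermute(rep("A", 3)), class = "btudiv_untestable")

  # singleton blocks reduce to an ordinary label permutation
  sp3 <- setNames(letters[1:5], paste0("s", 1:5))
  set.seed(9)
  perm3 <- blockPermute(sp3)
  expect_setequal(unname(perm3), letters[1:5])
})

test_that("perfect congruence gives m2 = 0 and the floor p", {
  tr <- simulateHostTree(8, seed = 5)
  coph <- copheneticDistances(tr)
  sp <- setNames(rownames(coph), rownames(coph))  # one sample per species
  gm <- coph
  res <- pacoCompositional(gm, coph, sp, nPerm = 199, seed = 1)
  expect_lt(res$m2, 1e-10)
  expect_equal(res$r, 1, tolerance = 1e-5)
  expect_equal(res$p, 1 / 200)
})

test_that("the lifted species eigensolver equals the direct computation", {
  sim <- simulateDataset(tinyConfig(seed = 41))
  x <- sim$experiment[, librarySizes(sim$experiment) > 0]
  species <- hostSpecies(x)
  coph <- copheneticDistances(hostTree(x))
  props <- toProportions(x)
  asvs <- names(sim$truth$btuOf)[sim$truth$btuOf == "btu03"]
  hosting <- btuSampleSubset(x, asvs)
  d <- brayCurtis(props, hosting, asvs)
  res <- pacoCompositional(d, coph, species, nPerm = 0)
  sp <- species[hosting]
  dh <- coph[sp, sp]
  dimnames(dh) <- list(hosting, hosting)
  direct <- procrustesFit(pcoaScores(dh), pcoaScores(d))
  expect_equal(res$m2, direct$m2, tolerance = 1e-10)

  # P_PHYLO against an explicit stacked-occurrence oracle
  cts <- asvCounts(x)
  al <- alignSequences(asvSequences(x)[asvs])
  gd <- geneticDistances(al, model = "JC69")
  occ <- which(cts[asvs, hosting, drop = FALSE] >= 1, arr.ind = TRUE)
  inc <- data.frame(asv = asvs[occ[, 1]], sample = hosting[occ[, 2]])
  res2 <- pacoPhylogenetic(gd, coph, inc, species, nPerm = 0)
  Xs <- pcoaScores(dh)$points[inc$sample, , drop = FALSE]
  Ys <- pcoaScores(gd)$points[inc$asv, , drop = FALSE]
  direct2 <- procrustesFit(Xs, Ys)
  expect_equal(res2$m2, direct2$m2, tolerance = 1e-10)
})

test_that("species-level occurrence granularity collapses repeated sampling", {
  sim <- simulateDataset(tinyConfig(seed = 43))
  x <- sim$experiment[, librarySizes(sim$experiment) > 0]
  species <- hostSpecies(x)
  coph <- copheneticDistances(hostTree(x))
  cts <- asvCounts(x)
  asvs <- names(sim$truth$btuOf)[sim$truth$btuOf == "btu03"]
  hosting <- btuSampleSubset(x, asvs)
  gd <- geneticDistances(alignSequences(asvSequences(x)[asvs]), "JC69")
  occ <- which(cts[asvs, hosting, drop = FALSE] >= 1, arr.ind = TRUE)
  inc <- data.frame(asv = asvs[occ[, 1]], sample = hosting[occ[, 2]])
  bySpecies <- pacoPhylogenetic(gd, coph, inc, species, nPerm = 99,
                                seed = 4, granularity = "species")
  expect_true(bySpecies$r >= 0 && bySpecies$r <= 1)
  expect_lte(bySpecies$nSamples, length(unique(species[hosting])))

  # one sample per species: both granularities give the same statistic
  one <- !duplicated(species[hosting])
  keep <- inc$sample %in% hosting[one]
  inc1 <- inc[keep, ]
  a <- pacoPhylogenetic(gd, coph, inc1, species, nPerm = 0)
  b <- pacoPhylogenetic(gd, coph, inc1, species, nPerm = 0,
                        granularity = "species")
  expect_equal(a$m2, b$m2, tolerance = 1e-10)
})

test_that("with singleton blocks the block null equals the unrestricted null", {
  tr <- simulateHostTree(8, seed = 6)
  coph <- copheneticDistances(tr)
  sp <- setNames(rownames(coph), paste0("s", 1:8))
  set.seed(10)
  gm <- as.matrix(dist(matrix(rnorm(16), 8, 2)))
  dimnames(gm) <- list(names(sp), names(sp))
  # both nulls draw m2 after relabelling species; with one sample per
  # species these are the same procedure, so their samples must come
  # from one distribution
  draw <- function(perm) {
    spp <- setNames(perm, names(sp))
    pacoCompositional(gm[names(sp), names(sp)], coph, spp, nPerm = 0)$m2
  }
  set.seed(11)
  block <- vapply(1:400, function(i) draw(blockPermute(sp)), numeric(1))
  unrestricted <- vapply(1:400, function(i) draw(sample(sp)), numeric(1))
  qs <- quantile(c(block, unrestricted), seq(0.2, 0.8, 0.2))
  binify <- function(v) table(cut(v, c(-Inf, qs, Inf)))
  expect_gt(suppressWarnings(
    chisq.test(rbind(binify(block), binify(unrestricted)))$p.value), 0.01)
})

test_that("genetic distance models behave and are selected sensibly", {
  s <- Biostrings::DNAStringSet(c(a = "ACGTACGTAC", b = "ACGTACGTAC"))
  for (m in c("raw", "JC69", "K80"))
    expect_equal(max(geneticDistances(s, m)), 0)

  # transitions only at p = 0.1: K80 corrects more than JC69
  a <- strrep("A", 20)
  b <- paste0(strrep("G", 2), strrep("A", 18))
  dJ <- geneticDistances(Biostrings::DNAStringSet(c(a = a, b = b)), "JC69")
  dK <- geneticDistances(Biostrings::DNAStringSet(c(a = a, b = b)), "K80")
  expect_gt(dK["a", "b"], dJ["a", "b"])

  # JC-generated BTUs: auto-selection picks JC69 nearly always
  picks <- vapply(1:60, function(i) {
    tr <- ape::stree(6, "star"); tr$edge.length <- rep(1, 6)
    s <- simulateBtuSequences(tr, 300, rate = 0.05, seed = 500 + i)
    attr(geneticDistances(s, "auto"), "model")
  }, character(1))
  expect_gte(mean(picks == "JC69"), 0.95)

  # strongly transition-biased evolution: K80 wins
  tr <- ape::stree(6, "star"); tr$edge.length <- rep(1, 6)
  picksK <- vapply(1:20, function(i) {
    set.seed(600 + i)
    x <- phangorn::simSeq(tr, l = 300, type = "DNA", rate = 0.08,
                          Q = c(1, 20, 1, 1, 20, 1))
    s <- Biostrings::DNAStringSet(apply(toupper(as.character(x)), 1,
                                        paste0, collapse = ""))
    attr(geneticDistances(s, "auto"), "model")
  }, character(1))
  expect_gte(mean(picksK == "K80"), 0.9)

  # saturation: sentinel under an explicit model, raw fallback on auto
  sat <- Biostrings::DNAStringSet(c(a = "ACGTACGTACGT",
                                    b = "CAGTCATCAGCA",
                                    c = "GTCAGTAGTCGA"))
  dj <- geneticDistances(sat, "JC69")
  expect_true(any(!is.finite(dj[upper.tri(dj)])))
  da <- geneticDistances(sat, "auto")
  expect_identical(attr(da, "model"), "raw")
  expect_true(attr(da, "saturated"))
  expect_true(all(is.finite(da)))
})

test_that("Mantel test recovers linear relations and stays calibrated", {
  inst <- randomEuclideanDist(10, seed = 21)
  res <- mantelTest(inst$d, 2 * inst$d, nPerm = 99, seed = 1)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$p, 1 / 100)

  # statistic agrees with vegan::mantel
  set.seed(22)
  d2 <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
  dimnames(d2) <- dimnames(inst$d)
  expect_equal(mantelTest(inst$d, d2, nPerm = 99, seed = 2)$r,
               unname(vegan::mantel(as.dist(inst$d), as.dist(d2),
                                    permutations = 2)$statistic),
               tolerance = 1e-12)

  # null calibration
  ps <- vapply(1:100, function(i) {
    set.seed(2000 + i)
    dd <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
    dimnames(dd) <- dimnames(inst$d)
    mantelTest(inst$d, dd, nPerm = 99, seed = 3000 + i)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)

  expect_error(mantelTest(inst$d[1:3, 1:3], inst$d[1:3, 1:3]),
               class = "btudiv_untestable")
})

test_that("Mantel and PACo effect sizes agree in rank across BTUs", {
  rsM <- rsP <- c()
  for (s in 1:3) {
    sim <- simulateDataset(simulationConfig(
      nSpecies = 10, samplesPerSpecies = 3, nNullBtus = 4,
      nSpecificBtus = 3, nCodivergingBtus = 5, asvsPerBtu = 10,
      seqLength = 60, meanLibrarySize = 2000, seed = 800 + s))
    x <- sim$experiment[, librarySizes(sim$experiment) > 0]
    species <- hostSpecies(x)
    coph <- copheneticDistances(hostTree(x))
    props <- toProportions(x)
    for (b in unique(sim$truth$btuOf)) {
      asvs <- names(sim$truth$btuOf)[sim$truth$btuOf == b]
      hosting <- btuSampleSubset(x, asvs)
      if (length(hosting) < 4 ||
          length(unique(species[hosting])) < 4) next
      d <- brayCurtis(props, hosting, asvs)
      rsP <- c(rsP, pacoCompositional(d, coph, species, nPerm = 0)$r)
      mp <- speciesMeanProfiles(props[hosting, asvs, drop = FALSE],
                                species)
      dd <- brayCurtis(mp)
      rsM <- c(rsM, mantelTest(dd, coph[rownames(dd), rownames(dd)],
                               nPerm = 99, seed = 5)$r)
    }
  }
  expect_gte(length(rsM), 30)
  kt <- kendallTau(rsM, rsP)
  expect_gt(kt$tau, 0)
  expect_lt(kt$p, 0.05)
})
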