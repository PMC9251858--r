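# Synthetic community generator: host trees, BTU marker sequences and
# Dirichlet-multinomial count tables with planted null / host-specific /
# co-diverging BTUs.

.scaleTreeHeight <- function(tree, height = 1) {
  h <- max(ape::node.depth.edgelength(tree))
  if (h > 0) tree$edge.length <- tree$edge.length * (height / h)
  tree
}

.zeroPad <- function(prefix, i, n) {
  sprintf("%s%0*d", prefix, max(2L, nchar(as.character(n))), i)
}

#' Simulate an ultrametric pure-birth host phylogeny
#'
#' Tips are labelled `sp01`, `sp02`, ... and the tree is rescaled to unit
#' root-to-tip height so that cophenetic distances live on a fixed scale.
#'
#' @param nSpecies number of tips (>= 3).
#' @param seed integer seed, or `NULL` to draw from the current stream.
#' @return An ultrametric [ape::phylo] with `nSpecies` tips.
#' @examples
#' tr <- simulateHostTree(5, seed = 1)
#' max(ape::node.depth.edgelength(tr))  # unit height
#' @export
simulateHostTree <- function(nSpecies, seed = NULL) {
  if (nSpecies < 3) stop("nSpecies must be >= 3")
  tr <- .withSeed(seed, ape::rphylo(nSpecies, birth = 1, death = 0))
  tr$tip.label <- .zeroPad("sp", seq_len(nSpecies), nSpecies)
  .scaleTreeHeight(tr, 1)
}

#' Evolve indel-free marker sequences along a guide tree under JC69
#'
#' One sequence per tip, evolved site-independently under the
#' Jukes-Cantor model from a uniform-random root; branch lengths of the
#' guide tree are multiplied by `rate` (expected substitutions/site per
#' unit branch length). No indels, so all sequences share the root
#' length and a gap-free alignment of the output is the identity.
#'
#' @param guideTree [ape::phylo] with branch lengths.
#' @param seqLength marker length in nt.
#' @param rate expected substitutions/site per unit branch length (>= 0;
#'   0 returns the root sequence at every tip).
#' @param seed integer seed, or `NULL`.
#' @return A [Biostrings::DNAStringSet] named by tip label.
#' @export
simulateBtuSequences <- function(guideTree, seqLength, rate, seed = NULL) {
  if (rate < 0) stop("rate must be >= 0")
  m <- .withSeed(seed, {
    x <- phangorn::simSeq(guideTree, l = seqLength, type = "DNA", rate = rate)
    toupper(as.character(x))
  })
  out <- Biostrings::DNAStringSet(apply(m, 1L, paste0, collapse = ""))
  names(out) <- rownames(m)
  out
}

# Graft ASV tips onto the host tree so that the bacterial guide tree
# mirrors the host topology: each species tip becomes a shallow clade of
# its assigned ASVs (branch length eps).
.expandHostTree <- function(host, homeOf, eps = 1e-3) {
  k <- length(host$tip.label)
  tr <- host
  tr$tip.label <- paste0("qq", seq_len(k), "qq")
  nwk <- ape::write.tree(tr, digits = 12)
  for (i in seq_len(k)) {
    asvs <- names(homeOf)[homeOf == host$tip.label[i]]
    pat <- paste0(tr$tip.label[i], ":([0-9.eE+-]+)")
    m <- regmatches(nwk, regexpr(pat, nwk))[1]
    len <- as.numeric(sub(pat, "\\1", m))
    e <- min(eps, len / 2)
    rep_str <- if (length(asvs) == 1L) {
      paste0(asvs, ":", format(len, digits = 12))
    } else {
      paste0("(", paste0(asvs, ":", format(e, digits = 12), collapse = ","),
             "):", format(len - e, digits = 12))
    }
    nwk <- sub(pat, rep_str, nwk, fixed = FALSE)
  }
  ape::read.tree(text = nwk)
}

# Affinity of a co-diverging BTU: ASV homed at species h has affinity
# proportional to exp(-coph(h, s) / lambda) (lambda in units of tree
# height); lambda = 0 degenerates to the indicator of the home species.
.codivAffinity <- function(coph, home, lambda) {
  k <- ncol(coph)
  t(vapply(home, function(h) {
    d <- coph[h, ]
    a <- if (lambda <= 0) as.numeric(d == 0) else exp(-d / lambda)
    a / sum(a)
  }, numeric(k)))
}

#' Simulate a full synthetic ASV dataset with planted BTU regimes
#'
#' Generates a host tree, per-BTU bacterial guide trees and marker
#' sequences, per-ASV species-affinity vectors, and a sample x ASV count
#' table drawn multinomially per sample with negative-binomial library
#' sizes. Three regimes are planted: `null` BTUs whose expected
#' composition is identical across species, `specific` BTUs whose ASV
#' affinities are Dirichlet draws over randomly ordered species (species
#' signal without phylogenetic signal), and `codiverging` BTUs whose
#' guide tree mirrors the host tree and whose affinities decay with host
#' phylogenetic distance (both compositional and phylogenetic signal).
#' Every BTU receives the same expected share of each library, so the
#' regimes stay statistically independent across BTUs. Each planted BTU
#' gets a unique synthetic genus so reference-based binning recovers the
#' planted partition exactly.
#'
#' @param config a [SimulationConfig-class]; the seed it carries makes the
#'   output bit-identical across calls.
#' @return A list: `experiment` ([AsvExperiment-class]) and `truth`
#'   (list with `regime`, `strength`, `btuOf`, `affinity`).
#' @examples
#' sim <- simulateDataset(simulationConfig(nSpecies = 5, samplesPerSpecies = 2,
#'   nNullBtus = 1, nSpecificBtus = 1, nCodivergingBtus = 1, asvsPerBtu = 6,
#'   seqLength = 60, seed = 7))
#' sim$experiment
#' @export
simulateDataset <- function(config = simulationConfig()) {
  methods::validObject(config)
  .withSeed(config@seed, {
    k <- config@nSpecies
    host <- simulateHostTree(k, seed = NULL)
    speciesIds <- host$tip.label
    coph <- ape::cophenetic.phylo(host)[speciesIds, speciesIds]

    nPer <- rep(config@samplesPerSpecies, length.out = k)
    sampleSpecies <- rep(speciesIds, nPer)
    nSamples <- length(sampleSpecies)
    sampleIds <- .zeroPad("s", seq_len(nSamples), nSamples)
    names(sampleSpecies) <- sampleIds

    regimes <- rep(c("null", "specific", "codiverging"),
                   c(config@nNullBtus, config@nSpecificBtus,
                     config@nCodivergingBtus))
    nBtus <- length(regimes)
    btuIds <- .zeroPad("btu", seq_len(nBtus), nBtus)
    names(regimes) <- btuIds
    nAsv <- config@asvsPerBtu
    totalAsv <- nBtus * nAsv
    asvIds <- .zeroPad("asv", seq_len(totalAsv), totalAsv)

    seqs <- vector("list", nBtus)
    affinity <- vector("list", nBtus)
    names(affinity) <- btuIds
    strength <- setNames(rep(NA_real_, nBtus), btuIds)
    btuOf <- character(0)
    # expected relative-abundance profile of each species (rows) --
    # every BTU contributes exactly 1/nBtus to every species' profile
    E <- matrix(0, nrow = k, ncol = totalAsv,
                dimnames = list(speciesIds, asvIds))
    w <- 1 / nBtus

    for (b in seq_len(nBtus)) {
      members <- asvIds[((b - 1) * nAsv + 1):(b * nAsv)]
      btuOf[members] <- btuIds[b]
      if (regimes[b] == "codiverging") {
        home <- setNames(speciesIds[rep(seq_len(k), length.out = nAsv)],
                         members)
        guide <- .expandHostTree(host, home)
        A <- .codivAffinity(coph, home, config@codivergenceScale)
        strength[b] <- config@codivergenceScale
      } else {
        guide <- .scaleTreeHeight(ape::rphylo(nAsv, birth = 1, death = 0), 1)
        guide$tip.label <- members
        if (regimes[b] == "null") {
          A <- matrix(1 / k, nrow = nAsv, ncol = k)
        } else {
          A <- .rdirichlet(nAsv, rep(config@specificityConcentration, k))
          strength[b] <- config@specificityConcentration
        }
      }
      dimnames(A) <- list(members, speciesIds)
      affinity[[b]] <- A
      seqs[[b]] <- simulateBtuSequences(guide, config@seqLength,
                                        config@substitutionRate, seed = NULL)
      base <- as.numeric(.rdirichlet(1, rep(1, nAsv)))
      # within-BTU composition per species; the BTU's total share of each
      # species' profile is held at w so BTUs remain independent
      cmp <- t(A) * rep(base, each = k)          # k x nAsv
      den <- rowSums(cmp)
      cmp[den > 1e-12, ] <- cmp[den > 1e-12, , drop = FALSE] /
        den[den > 1e-12]
      cmp[den <= 1e-12, ] <- 0
      E[, members] <- w * cmp
    }

    sequences <- do.call(c, seqs)
    stopifnot(identical(length(sequences), totalAsv))
    sequences <- sequences[asvIds]

    libs <- stats::rnbinom(nSamples, mu = config@meanLibrarySize,
                           size = config@libraryDispersion)
    counts <- matrix(0L, nrow = totalAsv, ncol = nSamples,
                     dimnames = list(asvIds, sampleIds))
    for (j in seq_len(nSamples)) {
      p <- E[sampleSpecies[j], ]
      if (libs[j] > 0 && sum(p) > 0)
        counts[, j] <- as.integer(stats::rmultinom(1L, libs[j], p))
    }

    taxonomy <- data.frame(
      phylum = "SimPhylum", class = "SimClass", order = "SimOrder",
      family = paste0("Fam_", btuOf[asvIds]),
      genus = paste0("Genus_", btuOf[asvIds]),
      row.names = asvIds)

    exp <- AsvExperiment(counts, sequences, taxonomy,
                         species = sampleSpecies, hostTree = host)
    list(experiment = exp,
         truth = list(regime = regimes, strength = strength,
                      btuOf = btuOf[asvIds], affinity = affinity))
  })
}
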