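# Pipeline orchestration: per-BTU specificity and co-divergence tests,
# FDR, effect-size concordance, the high-specificity subset test, read
# and ASV accounting, and the report writer.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (clipped at 1, monotone in the sorted order).
#'
#' @param p vector of p-values in `(0, 1]`.
#' @return q-values of the same length.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhFdr <- function(p) {
  if (!length(p)) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' Kendall rank correlation (tau-b) between paired effect sizes
#'
#' @param x,y paired finite vectors, n >= 3.
#' @return List: `tau`, `p`, `n`.
#' @export
kendallTau <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("tau undefined for a constant vector")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
  list(tau = unname(ct$estimate), p = ct$p.value, n = length(x))
}

.majorityGenus <- function(asvs, tax) {
  g <- tax[asvs, "genus"]
  g <- g[!is.na(g) & trimws(g) != ""]
  if (!length(g)) return("unassigned")
  u <- unique(g)
  if (length(u) == 1L) u else "ambiguous"
}

.configAsList <- function(config) {
  sn <- methods::slotNames(config)
  out <- lapply(sn, function(s) methods::slot(config, s))
  names(out) <- sn
  out
}

.logRow <- function(method, btu, event, detail = "")
  data.frame(method = method, btu = btu, event = event, detail = detail,
             stringsAsFactors = FALSE)

#' Run the full BTU-level specificity and co-divergence analysis
#'
#' Filters taxa then samples, bins ASVs into BTUs with each configured
#' method, applies the BTU inclusion filters, and for every retained and
#' testable BTU computes: PERMANOVA of host-species specificity with
#' adjusted R-squared (per community distance), compositional
#' co-divergence P_COMP (per distance) and phylogenetic co-divergence
#' P_PHYLO (once per BTU; it does not depend on the community distance).
#' Benjamini-Hochberg FDR is applied per binning method x distance x
#' statistic family (or pooled per method, see
#' [analysisConfig()]). A whole-community analysis (all ASVs
#' unpartitioned) is run alongside, effect sizes are compared across
#' statistics and distances by Kendall's tau, the union of ASVs in
#' high-specificity BTUs is tested against random ASV subsets, and all
#' reads/ASVs are accounted into untested / non-significant /
#' significant / high-effect categories.
#'
#' BTUs hosted by fewer than 3 samples, fewer than 2 species, or no more
#' samples than species are untestable: they are skipped with a log
#' entry and counted as untested in the accounting.
#'
#' @param x an [AsvExperiment-class] with a host tree.
#' @param config an [AnalysisConfig-class].
#' @return A list of class `"btuReport"`: `btuResults`,
#'   `wholeCommunity`, `effectSizeCorrelations`, `subsetTests`,
#'   `accounting`, `log`, `partitions`, `config`.
#' @export
runPipeline <- function(x, config = analysisConfig()) {
  methods::validObject(config)
  if (is.null(hostTree(x))) stop("a host tree is required")
  x <- filterTaxa(x)
  x <- filterSamples(x, config@minSampleReads)
  species <- hostSpecies(x)
  coph <- copheneticDistances(hostTree(x))
  props <- toProportions(x)
  cts <- asvCounts(x)
  tax <- taxonomyTable(x)
  seqs <- asvSequences(x)
  logs <- list()

  partitions <- list()
  distmat <- NULL
  if (any(config@binning %in% c("sim95", "sim97"))) {
    aligned <- alignSequences(seqs)
    distmat <- jcDistanceMatrix(aligned,
                                if (config@rawDistance) "raw" else "JC69")
  }
  for (m in config@binning) {
    partitions[[m]] <- switch(m,
      genus = suppressMessages(binByGenus(x)),
      sim95 = completeLinkageBins(distmat, 0.95),
      sim97 = completeLinkageBins(distmat, 0.97))
  }
  retained <- lapply(partitions, function(p)
    suppressMessages(filterBtus(p, x, config@minBtuReads,
                                config@minBtuAsvs)))

  rows <- list()
  for (m in config@binning) {
    part <- retained[[m]]
    for (btu in btuNames(part)) {
      asvs <- btuAsvs(part, btu)
      hosting <- btuSampleSubset(x, asvs)
      spSub <- species[hosting]
      nsp <- length(unique(spSub))
      if (length(hosting) < 3 || nsp < 2 || length(hosting) <= nsp) {
        logs[[length(logs) + 1L]] <- .logRow(m, btu, "untestable",
          sprintf("%d hosting samples, %d species", length(hosting), nsp))
        next
      }
      seedB <- .seedFrom(config@seed, paste(m, btu))
      alnB <- alignSequences(seqs[asvs])
      gdist <- geneticDistances(alnB, model = "auto")
      if (attr(gdist, "saturated"))
        logs[[length(logs) + 1L]] <- .logRow(m, btu, "saturated-distances",
          paste("genetic model:", attr(gdist, "model")))
      occ <- which(cts[asvs, hosting, drop = FALSE] >= 1, arr.ind = TRUE)
      incidence <- data.frame(asv = asvs[occ[, 1]],
                              sample = hosting[occ[, 2]])
      pphylo <- tryCatch(
        pacoPhylogenetic(gdist, coph, incidence, species,
                         nPerm = config@nPermPaco,
                         seed = .seedFrom(seedB, "PHYLO")),
        btudiv_untestable = function(e) {
          logs[[length(logs) + 1L]] <<- .logRow(m, btu, "pphylo-skipped",
                                                conditionMessage(e))
          NULL
        })
      for (dm in config@distances) {
        distFun <- if (dm == "bray") brayCurtis else jaccardBinary
        d <- distFun(props, hosting, asvs,
                     renormalize = config@renormalizeWithinBtu)
        perm <- tryCatch(
          permanovaDist(d, spSub, nPerm = config@nPermPermanova,
                        seed = .seedFrom(seedB, "PERM")),
          btudiv_untestable = function(e) NULL)
        pcomp <- tryCatch(
          pacoCompositional(d, coph, species, nPerm = config@nPermPaco,
                            seed = .seedFrom(seedB, "COMP")),
          btudiv_untestable = function(e) NULL)
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, distance = dm,
          genusAssignment = .majorityGenus(asvs, tax), btu = btu,
          hostingIndividuals = length(hosting), hostingSpecies = nsp,
          nAsvs = length(asvs),
          reads = sum(as.numeric(cts[asvs, , drop = FALSE])),
          R2 = if (is.null(perm)) NA_real_ else perm$R2,
          R2adj = if (is.null(perm)) NA_real_ else perm$R2adj,
          pSpecificity = if (is.null(perm)) NA_real_ else perm$p,
          pcomp = if (is.null(pcomp)) NA_real_ else pcomp$r,
          pPcomp = if (is.null(pcomp)) NA_real_ else pcomp$p,
          pphylo = if (is.null(pphylo)) NA_real_ else pphylo$r,
          pPphylo = if (is.null(pphylo)) NA_real_ else pphylo$p,
          geneticModel = attr(gdist, "model"),
          nPermPermanova = config@nPermPermanova,
          nPermPaco = config@nPermPaco,
          stringsAsFactors = FALSE)
      }
    }
  }
  btuResults <- if (length(rows)) do.call(rbind, rows) else
    data.frame()

  # FDR families
  if (nrow(btuResults)) {
    btuResults$qSpecificity <- NA_real_
    btuResults$qPcomp <- NA_real_
    btuResults$qPphylo <- NA_real_
    if (config@fdrPooling == "by-family") {
      for (m in unique(btuResults$method)) {
        for (dm in unique(btuResults$distance)) {
          i <- btuResults$method == m & btuResults$distance == dm
          btuResults$qSpecificity[i] <- bhFdr(btuResults$pSpecificity[i])
          btuResults$qPcomp[i] <- bhFdr(btuResults$pPcomp[i])
        }
        # P_PHYLO is distance-independent: one family per method
        i <- btuResults$method == m
        first <- !duplicated(btuResults$btu[i])
        qv <- bhFdr(btuResults$pPphylo[i][first])
        names(qv) <- btuResults$btu[i][first]
        btuResults$qPphylo[i] <- qv[btuResults$btu[i]]
      }
    } else {
      for (m in unique(btuResults$method)) {
        i <- btuResults$method == m
        first <- !duplicated(btuResults$btu[i])
        pool <- c(btuResults$pSpecificity[i], btuResults$pPcomp[i],
                  btuResults$pPphylo[i][first])
        qs <- bhFdr(pool)
        n1 <- sum(i)
        btuResults$qSpecificity[i] <- qs[seq_len(n1)]
        btuResults$qPcomp[i] <- qs[n1 + seq_len(n1)]
        qv <- qs[2 * n1 + seq_len(sum(first))]
        names(qv) <- btuResults$btu[i][first]
        btuResults$qPphylo[i] <- qv[btuResults$btu[i]]
      }
    }
    a <- config@fdrAlpha
    btuResults$sigSpecificity <- !is.na(btuResults$qSpecificity) &
      btuResults$qSpecificity < a
    btuResults$sigPcomp <- !is.na(btuResults$qPcomp) &
      btuResults$qPcomp < a
    btuResults$sigPphylo <- !is.na(btuResults$qPphylo) &
      btuResults$qPphylo < a
  }

  # whole-community analysis (all ASVs unpartitioned)
  wc <- list()
  for (dm in config@distances) {
    distFun <- if (dm == "bray") brayCurtis else jaccardBinary
    d <- distFun(props)
    sw <- .seedFrom(config@seed, paste("whole", "community"))
    perm <- permanovaDist(d, species, nPerm = config@nPermPermanova,
                          seed = .seedFrom(sw, "PERM"))
    pcomp <- pacoCompositional(d, coph, species,
                               nPerm = config@nPermPaco,
                               seed = .seedFrom(sw, "COMP"))
    wc[[dm]] <- data.frame(distance = dm, R2 = perm$R2,
                           R2adj = perm$R2adj, pSpecificity = perm$p,
                           pcomp = pcomp$r, pPcomp = pcomp$p)
  }
  wholeCommunity <- do.call(rbind, wc)
  rownames(wholeCommunity) <- NULL

  # effect-size concordance across statistics and distances
  corRows <- list()
  addCor <- function(method, distance, comparison, a, b) {
    kt <- tryCatch(kendallTau(a, b), error = function(e) NULL)
    if (!is.null(kt))
      corRows[[length(corRows) + 1L]] <<- data.frame(
        method = method, distance = distance, comparison = comparison,
        tau = kt$tau, p = kt$p, n = kt$n, stringsAsFactors = FALSE)
  }
  if (nrow(btuResults)) {
    for (m in unique(btuResults$method)) {
      for (dm in unique(btuResults$distance)) {
        s <- btuResults[btuResults$method == m &
                          btuResults$distance == dm, ]
        addCor(m, dm, "R2adj~PCOMP", s$R2adj, s$pcomp)
        addCor(m, dm, "R2adj~PPHYLO", s$R2adj, s$pphylo)
        addCor(m, dm, "PCOMP~PPHYLO", s$pcomp, s$pphylo)
      }
      dms <- unique(btuResults$distance)
      if (length(dms) == 2) {
        s1 <- btuResults[btuResults$method == m &
                           btuResults$distance == dms[1], ]
        s2 <- btuResults[btuResults$method == m &
                           btuResults$distance == dms[2], ]
        s2 <- s2[match(s1$btu, s2$btu), ]
        addCor(m, paste(dms, collapse = "~"), "R2adj", s1$R2adj, s2$R2adj)
        addCor(m, paste(dms, collapse = "~"), "PCOMP", s1$pcomp, s2$pcomp)
      }
    }
  }
  effectSizeCorrelations <-
    if (length(corRows)) do.call(rbind, corRows) else data.frame()

  # high-specificity subset test per binning method
  dm0 <-
    if ("jaccard" %in% config@distances) "jaccard" else config@distances[1]
  subsetTests <- list()
  if (nrow(btuResults)) {
    for (m in unique(btuResults$method)) {
      s <- btuResults[btuResults$method == m &
                        btuResults$distance == dm0, ]
      hi <- s$btu[!is.na(s$R2adj) &
                    s$R2adj >= config@highSpecificityCutoff &
                    s$sigSpecificity]
      target <- unique(unlist(btuAsvs(retained[[m]])[hi]))
      if (length(target) >= 2 && length(target) < nrow(x)) {
        st <- tryCatch(
          subsetSpecificityTest(props, species, rownames(x), target,
                                distance = dm0,
                                nPerm = config@nPermSubset,
                                seed = .seedFrom(config@seed,
                                                 paste("subset", m))),
          btudiv_untestable = function(e) NULL)
        if (!is.null(st))
          subsetTests[[m]] <- list(method = m, distance = dm0,
                                   nHighBtus = length(hi),
                                   nTarget = st$nTarget,
                                   R2adjTarget = st$R2adjTarget,
                                   p = st$p, nPerm = st$nPerm)
      }
    }
  }

  # read/ASV accounting per method (categories use the dm0 results)
  accRows <- list()
  asvReads <- rowSums(cts)
  for (m in config@binning) {
    s <- if (nrow(btuResults)) {
      btuResults[btuResults$method == m & btuResults$distance == dm0, ]
    } else {
      data.frame()
    }
    cat_of <- setNames(rep("untested", nrow(x)), rownames(x))
    if (nrow(s)) {
      for (i in seq_len(nrow(s))) {
        sig <- isTRUE(s$sigSpecificity[i]) || isTRUE(s$sigPcomp[i]) ||
          isTRUE(s$sigPphylo[i])
        high <- (isTRUE(s$sigSpecificity[i]) &&
                   !is.na(s$R2adj[i]) &&
                   s$R2adj[i] > config@highSpecificityCutoff) ||
          (isTRUE(s$sigPcomp[i]) && !is.na(s$pcomp[i]) &&
             s$pcomp[i] > config@highSpecificityCutoff) ||
          (isTRUE(s$sigPphylo[i]) && !is.na(s$pphylo[i]) &&
             s$pphylo[i] > config@highSpecificityCutoff)
        lab <- if (high) {
          "high-effect"
        } else if (sig) {
          "significant"
        } else {
          "nonsignificant"
        }
        cat_of[btuAsvs(retained[[m]], s$btu[i])] <- lab
      }
    }
    for (lab in c("untested", "nonsignificant", "significant",
                  "high-effect")) {
      sel <- names(cat_of)[cat_of == lab]
      accRows[[length(accRows) + 1L]] <- data.frame(
        method = m, category = lab, nAsvs = length(sel),
        reads = sum(asvReads[sel]), stringsAsFactors = FALSE)
    }
  }
  accounting <- do.call(rbind, accRows)

  structure(list(
    btuResults = btuResults, wholeCommunity = wholeCommunity,
    effectSizeCorrelations = effectSizeCorrelations,
    subsetTests = subsetTests, accounting = accounting,
    log = if (length(logs)) do.call(rbind, logs) else
      .logRow(character(0), character(0), character(0), character(0)),
    partitions = retained,
    nSamples = ncol(x), nSpecies = length(unique(species)),
    nAsvs = nrow(x), totalReads = sum(asvReads),
    config = config), class = "btuReport")
}

#' @export
print.btuReport <- function(x, ...) {
  cat("BTU-level analysis report:", x$nSamples, "samples,", x$nSpecies,
      "species,", x$nAsvs, "ASVs,", format(x$totalReads, big.mark = ","),
      "reads\n")
  if (nrow(x$btuResults)) {
    for (m in unique(x$btuResults$method)) {
      s <- x$btuResults[x$btuResults$method == m, ]
      cat(sprintf("  %s: %d tested BTUs; specificity FDR<%.2g in %d/%d (first distance)\n",
                  m, length(unique(s$btu)), x$config@fdrAlpha,
                  sum(s$sigSpecificity[s$distance == s$distance[1]]),
                  sum(s$distance == s$distance[1])))
    }
  }
  invisible(x)
}

#' Write a report bundle to TSV/JSON files
#'
#' Emits `btu_results_<method>_<distance>.tsv` (Table-1-style columns),
#' `whole_community.tsv`, `effect_size_correlations.tsv`,
#' `subset_test.json`, `accounting.tsv`, `pipeline_log.tsv` and
#' `run_metadata.json`. Output is deterministic: the same dataset and
#' seed give byte-identical files.
#'
#' @param report a `"btuReport"` from [runPipeline()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, file)
    utils::write.table(df, file.path(dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  br <- report$btuResults
  if (nrow(br)) {
    for (m in unique(br$method)) {
      for (dm in unique(br$distance)) {
        s <- br[br$method == m & br$distance == dm, ]
        wt(s, sprintf("btu_results_%s_%s.tsv", m, dm))
      }
    }
  }
  wt(report$wholeCommunity, "whole_community.tsv")
  wt(report$effectSizeCorrelations, "effect_size_correlations.tsv")
  wt(report$accounting, "accounting.tsv")
  wt(report$log, "pipeline_log.tsv")
  jsonlite::write_json(report$subsetTests,
                       file.path(dir, "subset_test.json"),
                       auto_unbox = TRUE, digits = NA)
  meta <- list(seed = report$config@seed,
               config = .configAsList(report$config),
               nSamples = report$nSamples, nSpecies = report$nSpecies,
               nAsvs = report$nAsvs, totalReads = report$totalReads,
               packageVersion =
                 as.character(utils::packageVersion("btudiv")),
               rVersion = paste(R.version$major, R.version$minor,
                                sep = "."))
  jsonlite::write_json(meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
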