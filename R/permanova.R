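# PERMANOVA on a distance matrix with host species as the single factor,
# adjusted R-squared, and the high-specificity ASV-subset permutation
# test.

# within-group sum of squares of a squared-distance matrix: the trace
# identity tr(G) - tr(HGH) = sum_g sum_{i<j in g} d2_ij / n_g, valid for
# non-Euclidean matrices too
.ssWithin <- function(D2, groups) {
  s <- 0
  for (g in groups) s <- s + sum(D2[g, g]) / (2 * length(g))
  s
}

#' PERMANOVA of a sample dissimilarity matrix against species identity
#'
#' One-factor permutational MANOVA in the Gower-centered trace form: with
#' G = -1/2 C D^2 C and H the projection of the k-level species factor,
#' SS_total = tr(G), SS_model = tr(HGH),
#' F = (SS_model / (k-1)) / ((SS_total - SS_model) / (n-k)),
#' R^2 = SS_model / SS_total. Significance by unrestricted random
#' relabelling of samples: p = (1 + #\{F_perm >= F_obs\}) / (1 + nPerm).
#' Traces are computed directly on G, so non-Euclidean (negative
#' eigenvalue) matrices are handled without correction.
#'
#' @param d symmetric dissimilarity matrix over samples.
#' @param labels species label per sample (in `d`'s row order, or named).
#' @param nPerm number of permutations (0 skips the test, p = NA).
#' @param seed integer seed for the permutation stream, or `NULL`.
#' @return List of class `"btudivPermanova"`: `F`, `R2`, `R2adj`, `p`,
#'   `nSamples`, `nSpecies`, `nPerm`, `ssTotal`, `ssModel`.
#' @examples
#' d <- matrix(2, 4, 4) - diag(2, 4); d[1, 2] <- d[2, 1] <- 1
#' d[3, 4] <- d[4, 3] <- 1
#' dimnames(d) <- list(letters[1:4], letters[1:4])
#' permanovaDist(d, c("A", "A", "B", "B"), nPerm = 99, seed = 1)$F  # 7
#' @export
permanovaDist <- function(d, labels, nPerm = 10000, seed = NULL) {
  d <- .checkDistanceMatrix(d, "dissimilarity matrix")
  n <- nrow(d)
  if (!is.null(names(labels))) labels <- labels[rownames(d)]
  if (length(labels) != n) stop("one label per sample is required")
  f <- factor(labels)
  k <- nlevels(f)
  if (k < 2) .untestable("only one species present")
  if (n < 3) .untestable("fewer than 3 samples")
  if (n <= k) .untestable("no residual degrees of freedom (n <= k)")
  D2 <- d^2
  ssTotal <- sum(D2[upper.tri(D2)]) / n
  if (ssTotal <= 0) .untestable("all dissimilarities are zero")
  idx <- seq_len(n)
  stat <- function(ff) {
    ssw <- .ssWithin(D2, split(idx, ff))
    ssm <- ssTotal - ssw
    (ssm / (k - 1)) / (ssw / (n - k))
  }
  Fobs <- stat(f)
  ssWithinObs <- .ssWithin(D2, split(idx, f))
  ssModel <- ssTotal - ssWithinObs
  R2 <- ssModel / ssTotal
  p <- NA_real_
  if (nPerm > 0) {
    p <- .withSeed(seed, {
      hits <- 0L
      for (i in seq_len(nPerm))
        if (stat(sample(f)) >= Fobs) hits <- hits + 1L
      (1 + hits) / (1 + nPerm)
    })
  }
  structure(list(F = Fobs, R2 = R2, R2adj = adjustedR2(R2, n, k), p = p,
                 nSamples = n, nSpecies = k, nPerm = nPerm,
                 ssTotal = ssTotal, ssModel = ssModel),
            class = "btudivPermanova")
}

#' @export
print.btudivPermanova <- function(x, ...) {
  cat("PERMANOVA:", x$nSamples, "samples,", x$nSpecies, "species\n")
  cat(sprintf("  F = %.4g, R2 = %.4g, R2adj = %.4g, p = %s (%d perms)\n",
              x$F, x$R2, x$R2adj, format(x$p), x$nPerm))
  invisible(x)
}

#' Adjusted R-squared for a one-factor PERMANOVA
#'
#' R2adj = 1 - (1 - R2) (n - 1) / (n - k): the proportion of variance
#' explained by species identity corrected for the numbers of
#' observations and factor levels, making effect sizes comparable across
#' BTUs hosted by different numbers of samples and species. Can be
#' negative.
#'
#' @param R2 unadjusted R-squared in `[0, 1]`.
#' @param n number of samples.
#' @param k number of factor levels (n > k >= 2).
#' @return The adjusted R-squared.
#' @examples
#' adjustedR2(0.5, 10, 2)  # 0.4375
#' @export
adjustedR2 <- function(R2, n, k) {
  if (k < 2) stop("k must be >= 2")
  if (n <= k) stop("adjusted R2 undefined for n <= k")
  1 - (1 - R2) * (n - 1) / (n - k)
}

#' Permutation test: is a target ASV subset more host-specific than
#' random subsets of the same size?
#'
#' The observed statistic is the PERMANOVA adjusted R-squared of the
#' dissimilarity built from the target ASVs only (hosting samples only);
#' the null distribution re-runs the identical pipeline on `nPerm`
#' uniform draws of `length(targetAsvs)` ASVs from `fullAsvs` without
#' replacement. p = (1 + #\{stat_perm >= stat_obs\}) / (1 + nPerm).
#'
#' @param props samples x ASVs proportion matrix ([toProportions()]).
#' @param species species label per sample (named by sample id).
#' @param fullAsvs the ASV pool to draw from.
#' @param targetAsvs the subset of interest (within `fullAsvs`).
#' @param distance `"bray"` or `"jaccard"`.
#' @param nPerm number of random draws.
#' @param seed integer seed, or `NULL`.
#' @return List: `R2adjTarget`, `p`, `nPerm`, `nTarget`, `nullStats`.
#' @export
subsetSpecificityTest <- function(props, species, fullAsvs, targetAsvs,
                                  distance = c("jaccard", "bray"),
                                  nPerm = 9999, seed = NULL) {
  distance <- match.arg(distance)
  if (!all(targetAsvs %in% fullAsvs))
    stop("targetAsvs must be a subset of fullAsvs")
  if (length(targetAsvs) < 2) stop("need >= 2 target ASVs")
  distFun <- if (distance == "bray") brayCurtis else jaccardBinary
  stat <- function(asvs) {
    hosting <- rownames(props)[rowSums(props[, asvs, drop = FALSE]) > 0]
    sp <- species[hosting]
    if (length(hosting) < 3 || length(unique(sp)) < 2 ||
        length(hosting) <= length(unique(sp)))
      return(NA_real_)
    d <- distFun(props, hosting, asvs)
    tryCatch(permanovaDist(d, sp, nPerm = 0)$R2adj,
             btudiv_untestable = function(e) NA_real_)
  }
  obs <- stat(targetAsvs)
  if (is.na(obs)) .untestable("target subset is untestable")
  nullStats <- .withSeed(seed, vapply(seq_len(nPerm), function(i)
    stat(sample(fullAsvs, length(targetAsvs))), numeric(1)))
  p <- (1 + sum(nullStats >= obs, na.rm = TRUE)) / (1 + nPerm)
  list(R2adjTarget = obs, p = p, nPerm = nPerm,
       nTarget = length(targetAsvs), nullStats = nullStats)
}
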