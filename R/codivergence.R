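# Procrustean co-divergence: compositional (P_COMP) and phylogenetic
# (P_PHYLO) congruence between gut-microbiota divergence and host
# phylogeny, tested against a species-block permutation null.

#' Principal Coordinates Analysis of a distance matrix
#'
#' Eigendecomposition of the Gower-centered matrix G = -1/2 C D^2 C.
#' Axes are ordered by decreasing eigenvalue; only axes with an
#' eigenvalue above `tol` times the largest are kept (negative-eigenvalue
#' axes of non-Euclidean matrices are dropped and counted).
#'
#' @param d symmetric distance matrix.
#' @param tol relative eigenvalue tolerance.
#' @return List: `points` (items x axes, coordinates = eigenvector x
#'   sqrt(eigenvalue)), `eig` (all eigenvalues), `negative` (number of
#'   negative eigenvalues).
#' @export
pcoaScores <- function(d, tol = 1e-8) {
  d <- .checkDistanceMatrix(d, "distance matrix")
  n <- nrow(d)
  A <- -0.5 * d^2
  rm_ <- rowMeans(A)
  G <- A - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(A)
  e <- eigen(G, symmetric = TRUE)
  mx <- max(e$values, 0)
  keep <- if (mx > 0) e$values > tol * mx else rep(FALSE, n)
  negative <- sum(e$values < -tol * max(mx, .Machine$double.eps))
  if (!any(keep)) {
    pts <- matrix(0, n, 1, dimnames = list(rownames(d), NULL))
  } else {
    pts <- sweep(e$vectors[, keep, drop = FALSE], 2,
                 sqrt(e$values[keep]), "*")
    rownames(pts) <- rownames(d)
  }
  list(points = pts, eig = e$values, negative = negative)
}

#' Symmetric Procrustes superimposition of two configurations
#'
#' Both configurations are column-centered and scaled to unit total sum
#' of squares; the optimal rotation comes from the singular value
#' decomposition of X'Y (zero-padding the narrower configuration does
#' not change the nonzero singular values, so column counts may differ).
#' m2 = 1 - (sum of singular values)^2 is the residual sum of squares,
#' r = sqrt(1 - m2) the Procrustes correlation.
#'
#' @param X,Y configurations: matrices or [pcoaScores()] results.
#' @param xRows,yRows optional row indices (repeats allowed) selecting
#'   and duplicating rows before fitting, e.g. one row per
#'   host-microbe occurrence.
#' @return List: `m2` in `[0, 1]` and `r` in `[0, 1]`.
#' @export
procrustesFit <- function(X, Y, xRows = NULL, yRows = NULL) {
  getm <- function(z)
    if (is.list(z) && !is.null(z$points)) z$points else as.matrix(z)
  X <- getm(X); Y <- getm(Y)
  if (!is.null(xRows)) X <- X[xRows, , drop = FALSE]
  if (!is.null(yRows)) Y <- Y[yRows, , drop = FALSE]
  if (nrow(X) != nrow(Y))
    stop("configurations must have the same number of rows")
  if (nrow(X) < 3) .untestable("fewer than 3 stacked rows")
  X <- sweep(X, 2, colMeans(X)); Y <- sweep(Y, 2, colMeans(Y))
  tx <- sum(X^2); ty <- sum(Y^2)
  if (tx <= 0 || ty <= 0) .untestable("degenerate (coincident) configuration")
  sv <- svd(crossprod(X / sqrt(tx), Y / sqrt(ty)), nu = 0, nv = 0)$d
  m2 <- max(0, min(1, 1 - sum(sv)^2))
  list(m2 = m2, r = sqrt(1 - m2))
}

#' Species-block permutation of sample species identities
#'
#' Reassigns species identities to intact blocks of same-species samples
#' by a uniform random permutation of the species present; within-block
#' structure is untouched, so block sizes are preserved. With one sample
#' per species this reduces to an ordinary label permutation. Uses the
#' current RNG stream.
#'
#' @param species species label per item (names preserved).
#' @return The permuted label vector.
#' @export
blockPermute <- function(species) {
  u <- unique(species)
  if (length(u) < 2) .untestable("fewer than 2 species")
  s <- sample(u)
  out <- s[match(species, u)]
  names(out) <- names(species)
  out
}

# --- lifted species-level PCoA -------------------------------------------
# The host-side sample-level matrix d(si, sj) = coph(species(si),
# species(sj)) is block-constant, so G = M (-1/2 W) M' with M = C Z (Z
# the sample x species indicator) and W the squared cophenetic matrix of
# the assigned species. The nonzero eigenpairs of G are those of the
# k x k matrix S = -1/2 B' W B with B = U D^(1/2) from the fixed
# eigendecomposition of M'M = U D U'; coordinates are Mt V sqrt(lam)
# with Mt = M U D^(-1/2) orthonormal. Since only W changes when species
# identities are permuted across blocks, each permutation costs one
# k x k eigendecomposition instead of an n x n one. Exactness versus
# the direct PCoA is asserted in the test suite.

.speciesPcoaLift <- function(species) {
  u <- sort(unique(species))
  k <- length(u)
  n <- length(species)
  Z <- outer(as.character(species), u, "==") * 1
  s <- colSums(Z)
  As <- diag(s, k) - tcrossprod(s) / n
  es <- eigen(As, symmetric = TRUE)
  keep <- es$values > 1e-10 * max(es$values)
  U <- es$vectors[, keep, drop = FALSE]
  dh <- sqrt(es$values[keep])
  list(u = u,
       B = sweep(U, 2, dh, "*"),
       Mt = (Z - matrix(s, n, k, byrow = TRUE) / n) %*%
         sweep(U, 2, dh, "/"))
}

.liftedEigen <- function(lift, coph, assign) {
  W <- coph[assign, assign, drop = FALSE]^2
  S <- -0.5 * crossprod(lift$B, W %*% lift$B)
  S <- (S + t(S)) / 2
  ee <- eigen(S, symmetric = TRUE)
  mx <- max(ee$values, 0)
  keep <- ee$values > 1e-8 * mx
  if (!any(keep)) keep <- 1L
  list(V = ee$vectors[, keep, drop = FALSE], lam = pmax(ee$values[keep], 0))
}

#' Compositional co-divergence (P_COMP) by PACo with species-block nulls
#'
#' The explanatory configuration is the PCoA of the sample-level host
#' distance matrix (cophenetic distance between the samples' species;
#' zero within species), the response the PCoA of the community
#' dissimilarity matrix, paired by sample identity. The observed
#' symmetric Procrustes residual m2 is compared with its distribution
#' under [blockPermute()] of the species identities, rebuilding the
#' host-side configuration each round;
#' p = (1 + #\{m2_perm <= m2_obs\}) / (1 + nPerm).
#'
#' @param gmDist sample x sample community dissimilarity matrix.
#' @param hostCoph cophenetic distance matrix over species
#'   ([copheneticDistances()]).
#' @param speciesOfSample species label per sample, named by sample id.
#' @param nPerm number of block permutations.
#' @param seed integer seed, or `NULL`.
#' @return List of class `"btudivPaco"`: `m2`, `r` (= sqrt(1 - m2)),
#'   `p`, `mode = "COMP"`, `nPerm`, `nSamples`, `nSpecies`, `negEig`.
#' @export
pacoCompositional <- function(gmDist, hostCoph, speciesOfSample,
                              nPerm = 10000, seed = NULL) {
  gmDist <- .checkDistanceMatrix(gmDist, "GM dissimilarity matrix")
  samples <- rownames(gmDist)
  sp <- speciesOfSample[samples]
  if (any(is.na(sp))) stop("speciesOfSample must cover all samples")
  if (length(samples) < 3) .untestable("fewer than 3 samples")
  if (length(unique(sp)) < 2) .untestable("fewer than 2 species")
  bad <- setdiff(unique(sp), rownames(hostCoph))
  if (length(bad))
    stop("species missing from hostCoph: ", paste(bad, collapse = ", "))
  pc <- pcoaScores(gmDist)
  ty <- sum(pc$points^2)
  if (ty <= 0) .untestable("degenerate response configuration")
  Ys <- pc$points / sqrt(ty)
  lift <- .speciesPcoaLift(sp)
  MtY <- crossprod(lift$Mt, Ys)
  m2fun <- function(assign) {
    le <- .liftedEigen(lift, hostCoph, assign)
    cp <- sweep(crossprod(le$V, MtY), 1, sqrt(le$lam), "*") /
      sqrt(sum(le$lam))
    sv <- svd(cp, nu = 0, nv = 0)$d
    max(0, min(1, 1 - sum(sv)^2))
  }
  m2obs <- m2fun(lift$u)
  p <- NA_real_
  if (nPerm > 0) {
    p <- .withSeed(seed, {
      hits <- 0L
      for (i in seq_len(nPerm))
        if (m2fun(sample(lift$u)) <= m2obs) hits <- hits + 1L
      (1 + hits) / (1 + nPerm)
    })
  }
  structure(list(m2 = m2obs, r = sqrt(1 - m2obs), p = p, mode = "COMP",
                 nPerm = nPerm, nSamples = length(samples),
                 nSpecies = length(lift$u), negEig = pc$negative),
            class = "btudivPaco")
}

#' @export
print.btudivPaco <- function(x, ...) {
  cat(sprintf("PACo (%s): r = %.4g, m2 = %.4g, p = %s (%d perms, %d samples, %d species)\n",
              x$mode, x$r, x$m2, format(x$p), x$nPerm, x$nSamples,
              x$nSpecies))
  invisible(x)
}

#' Phylogenetic co-divergence (P_PHYLO) by PACo with species-block nulls
#'
#' The response configuration is the PCoA of the genetic distances among
#' the BTU's ASVs, one row per (ASV, sample) occurrence; the explanatory
#' configuration stacks the host-side sample-level PCoA coordinates (as
#' in [pacoCompositional()]) for the same occurrences. The null
#' redistributes species identities across sample blocks each round.
#'
#' @param asvDist ASV x ASV genetic distance matrix
#'   ([geneticDistances()]).
#' @param hostCoph cophenetic distance matrix over species.
#' @param incidence data.frame with columns `asv`, `sample`: one row per
#'   occurrence (count >= 1) of an ASV in a sample.
#' @param speciesOfSample species label per sample, named by sample id.
#' @param nPerm number of block permutations.
#' @param seed integer seed, or `NULL`.
#' @param granularity `"sample"` (default) keeps one association row per
#'   (ASV, sample) occurrence; `"species"` collapses the occurrences to
#'   unique (ASV, species) pairs, so repeated sampling of a species
#'   carries no extra weight. With one sample per species the two
#'   coincide.
#' @return List of class `"btudivPaco"` with `mode = "PHYLO"`.
#' @export
pacoPhylogenetic <- function(asvDist, hostCoph, incidence, speciesOfSample,
                             nPerm = 10000, seed = NULL,
                             granularity = c("sample", "species")) {
  granularity <- match.arg(granularity)
  asvDist <- .checkDistanceMatrix(asvDist, "ASV genetic distance matrix")
  if (!all(c("asv", "sample") %in% colnames(incidence)))
    stop("incidence needs 'asv' and 'sample' columns")
  if (granularity == "species") {
    sp <- speciesOfSample[as.character(incidence$sample)]
    incidence <- unique(data.frame(asv = as.character(incidence$asv),
                                   sample = unname(sp)))
    u <- unique(incidence$sample)
    speciesOfSample <- setNames(u, u)   # singleton species blocks
  }
  N <- nrow(incidence)
  if (N < 3) .untestable("fewer than 3 occurrence pairs")
  samples <- unique(as.character(incidence$sample))
  sp <- speciesOfSample[samples]
  if (any(is.na(sp))) stop("speciesOfSample must cover all samples")
  if (length(unique(sp)) < 2) .untestable("fewer than 2 species")
  pc <- pcoaScores(asvDist)
  Yocc <- pc$points[as.character(incidence$asv), , drop = FALSE]
  Yocc <- sweep(Yocc, 2, colMeans(Yocc))
  ty <- sum(Yocc^2)
  if (ty <= 0) .untestable("degenerate response configuration")
  Ys <- Yocc / sqrt(ty)
  lift <- .speciesPcoaLift(sp)
  K <- lift$Mt[match(as.character(incidence$sample), samples), ,
               drop = FALSE]
  K <- sweep(K, 2, colMeans(K))
  KtK <- crossprod(K)
  KtY <- crossprod(K, Ys)
  m2fun <- function(assign) {
    le <- .liftedEigen(lift, hostCoph, assign)
    trX <- sum(colSums(le$V * (KtK %*% le$V)) * le$lam)
    if (trX <= 0) return(1)
    cp <- sweep(crossprod(le$V, KtY), 1, sqrt(le$lam), "*") / sqrt(trX)
    sv <- svd(cp, nu = 0, nv = 0)$d
    max(0, min(1, 1 - sum(sv)^2))
  }
  m2obs <- m2fun(lift$u)
  p <- NA_real_
  if (nPerm > 0) {
    p <- .withSeed(seed, {
      hits <- 0L
      for (i in seq_len(nPerm))
        if (m2fun(sample(lift$u)) <= m2obs) hits <- hits + 1L
      (1 + hits) / (1 + nPerm)
    })
  }
  structure(list(m2 = m2obs, r = sqrt(1 - m2obs), p = p, mode = "PHYLO",
                 nPerm = nPerm, nSamples = length(samples),
                 nSpecies = length(lift$u), negEig = pc$negative),
            class = "btudivPaco")
}

#' Pairwise genetic distances with closed-form model choice
#'
#' Distances between aligned ASV marker sequences under `"raw"`
#' (p-distance), `"JC69"` or `"K80"` (Kimura two-parameter, separating
#' transitions P and transversions Q:
#' d = 1/2 log(1 / (1 - 2P - Q)) + 1/4 log(1 / (1 - 2Q))). With
#' `model = "auto"` the better of JC69 and K80 is chosen by AICc of a
#' pairwise multinomial likelihood over the site categories
#' match/transition/transversion (one free parameter per pair for JC69,
#' two for K80). Saturated pairs get an infinite sentinel; if the chosen
#' correction produces any sentinel the matrix falls back to raw
#' p-distances and is flagged (attribute `saturated`).
#'
#' @param aligned gapped [Biostrings::DNAStringSet] of equal widths.
#' @param model `"auto"`, `"raw"`, `"JC69"` or `"K80"`.
#' @return Distance matrix with attributes `model` (the model actually
#'   used) and `saturated` (logical).
#' @export
geneticDistances <- function(aligned, model = c("auto", "raw", "JC69",
                                                "K80")) {
  model <- match.arg(model)
  aligned <- Biostrings::DNAStringSet(aligned)
  if (length(aligned) < 2) stop("need >= 2 sequences")
  if (length(unique(Biostrings::width(aligned))) != 1L)
    stop("aligned sequences must share one gapped length")
  m <- as.matrix(aligned)
  tl <- .pairTallies(m)
  off <- upper.tri(tl$comp)
  if (any(tl$comp[off] == 0))
    stop("undefined distance: some sequence pairs share no comparable sites")
  comp <- tl$comp
  diag(comp) <- 1                       # avoid 0/0 on the diagonal
  P <- tl$transitions / comp
  Q <- (comp - tl$matches - tl$transitions) / comp
  p <- P + Q

  dRaw <- p
  dJC <- .jcTransform(p)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  dK80 <- ifelse(w1 > 0 & w2 > 0,
                 0.5 * log(1 / pmax(w1, .Machine$double.xmin)) +
                   0.25 * log(1 / pmax(w2, .Machine$double.xmin)), Inf)
  dK80[p == 0] <- 0

  used <- model
  if (model == "auto") {
    xlogy <- function(x, y) ifelse(x > 0, x * log(y), 0)
    nC <- comp[off]
    m0 <- (tl$matches)[off]
    ts <- (tl$transitions)[off]
    tv <- nC - m0 - ts
    pp <- p[off]; PP <- P[off]; QQ <- Q[off]
    llJC <- sum(xlogy(m0, 1 - pp) + xlogy(ts, pp / 3) +
                  xlogy(tv, 2 * pp / 3))
    llK80 <- sum(xlogy(m0, 1 - PP - QQ) + xlogy(ts, PP) + xlogy(tv, QQ))
    aicc <- function(ll, q, nTot) {
      pen <- if (nTot - q - 1 > 0) 2 * q * (q + 1) / (nTot - q - 1) else 0
      -2 * ll + 2 * q + pen
    }
    nTot <- sum(nC)
    npairs <- length(nC)
    used <- if (aicc(llJC, npairs, nTot) <= aicc(llK80, 2 * npairs, nTot))
      "JC69" else "K80"
  }
  d <- switch(used, raw = dRaw, JC69 = dJC, K80 = dK80)
  saturated <- any(!is.finite(d[off]))
  if (saturated && model == "auto") {
    d <- dRaw
    used <- "raw"
  }
  diag(d) <- 0
  dimnames(d) <- list(names(aligned), names(aligned))
  attr(d, "model") <- used
  attr(d, "saturated") <- saturated
  d
}

#' Mantel test between two distance matrices
#'
#' r is the Pearson correlation of the off-diagonal upper triangles;
#' significance by jointly permuting rows and columns of `d2`;
#' p = (1 + #\{r_perm >= r_obs\}) / (1 + nPerm).
#'
#' @param d1,d2 symmetric distance matrices over the same items (matched
#'   by name when dimnames are present).
#' @param nPerm number of permutations.
#' @param seed integer seed, or `NULL`.
#' @return List: `r`, `p`, `nPerm`.
#' @export
mantelTest <- function(d1, d2, nPerm = 9999, seed = NULL) {
  d1 <- .checkDistanceMatrix(d1, "d1")
  d2 <- .checkDistanceMatrix(d2, "d2")
  if (!is.null(rownames(d1)) && all(rownames(d1) %in% rownames(d2)))
    d2 <- d2[rownames(d1), rownames(d1)]
  n <- nrow(d1)
  if (n < 4) .untestable("fewer than 4 items")
  ut <- upper.tri(d1)
  robs <- stats::cor(d1[ut], d2[ut])
  p <- .withSeed(seed, {
    hits <- 0L
    for (i in seq_len(nPerm)) {
      idx <- sample(n)
      if (stats::cor(d1[ut], d2[idx, idx][ut]) >= robs) hits <- hits + 1L
    }
    (1 + hits) / (1 + nPerm)
  })
  list(r = robs, p = p, nPerm = nPerm)
}

#' Per-species mean ASV proportion profiles
#'
#' Averages the proportion rows of all samples of each species — the
#' species-level community profile used by the Mantel comparison against
#' host cophenetic distances.
#'
#' @param props samples x ASVs proportion matrix.
#' @param species species label per sample (named by sample id).
#' @return Species x ASVs matrix.
#' @export
speciesMeanProfiles <- function(props, species) {
  sp <- as.character(species[rownames(props)])
  agg <- rowsum(props, sp)
  sweep(agg, 1, as.vector(table(sp)[rownames(agg)]), "/")
}
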