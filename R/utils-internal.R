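# Internal helpers shared across modules. None exported.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards. seed = NULL uses the current stream.
.withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = genv)
      } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Stable derived seed (< 2^31) so that sub-analyses get reproducible but
# distinct streams; tag is a short label such as a BTU id.
.seedFrom <- function(seed, tag) {
  if (is.null(seed)) return(NULL)
  v <- utf8ToInt(as.character(tag))
  h <- sum(v * seq_along(v)) %% 104729
  as.integer((as.numeric(seed) %% 2147483629 * 7919 + h) %% 2147483629)
}

.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha, rate = 1),
              nrow = n, ncol = k, byrow = TRUE)
  sweep(x, 1L, rowSums(x), "/")
}

.checkDistanceMatrix <- function(d, what = "distance matrix", tol = 1e-12) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d))
    stop(what, " must be square", call. = FALSE)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("item", seq_len(nrow(d)))
  }
  fin <- is.finite(d)
  if (any(d[fin] < -tol))
    stop(what, " has negative entries", call. = FALSE)
  if (max(abs(d[fin] - t(d)[fin])) > 1e-8)
    stop(what, " is not symmetric", call. = FALSE)
  if (any(abs(diag(d)) > tol))
    stop(what, " has a nonzero diagonal", call. = FALSE)
  d
}

.upperTri <- function(m) m[upper.tri(m)]

# error with a dedicated class so that callers (the pipeline) can catch
# untestable-BTU conditions and log them rather than abort
.untestable <- function(msg) {
  stop(structure(class = c("btudiv_untestable", "error", "condition"),
                 list(message = msg, call = NULL)))
}

.isUntestable <- function(e) inherits(e, "btudiv_untestable")
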