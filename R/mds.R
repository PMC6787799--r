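#' Metric multidimensional scaling by stress majorization
#'
#' Embeds a distance matrix in K-dimensional Euclidean space by minimizing
#' the raw stress `sum_{i<j} (||x_i - x_j|| - D_ij)^2` with the SMACOF
#' (Guttman-transform) majorization iteration, initialized from classical
#' Torgerson scaling.  Majorization never increases stress, so the returned
#' configuration is at least as good as the classical start.  The result is
#' centered at the origin.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param K embedding dimension (default 3).
#' @param seed integer seed, used only to jitter a degenerate (coincident)
#'   initialization.
#' @param maxit,tol iteration cap and relative stress-change tolerance.
#' @return list: `coords` (n x K), `stress`, `stress_init`, `converged`,
#'   `n_iter`.
#' @export
metric_mds <- function(D, K = 3L, seed = 1L, maxit = 500L, tol = 1e-12) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (K < 1L) stop("K must be >= 1")
  stress_of <- function(X) {
    d <- as.matrix(dist(X))
    sum(((d - D)[upper.tri(D)])^2)
  }
  k_eff <- min(K, n - 1L)
  X <- suppressWarnings(cmdscale(D, k = k_eff))
  if (is.null(dim(X)) || ncol(X) < K) {
    pad <- matrix(0, n, K - ncol(as.matrix(X)))
    X <- cbind(as.matrix(X), pad)
  }
  # coincident-point degenerate start: jitter so majorization can move
  if (all(X == 0) && any(D[upper.tri(D)] > 0)) {
    set.seed(seed)
    X <- matrix(rnorm(n * K, sd = mean(D[upper.tri(D)]) / 10), n, K)
  }
  s0 <- stress_of(X)
  s_prev <- s0
  converged <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    d <- as.matrix(dist(X))
    B <- matrix(0, n, n)
    pos <- d > 0
    B[pos] <- -D[pos] / d[pos]
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X_new <- B %*% X / n
    s_new <- stress_of(X_new)
    if (s_new > s_prev + 1e-12) break  # safeguard; should not happen
    X <- X_new
    if (s_prev - s_new < tol * max(s_prev, .Machine$double.eps)) {
      s_prev <- s_new
      converged <- TRUE
      break
    }
    s_prev <- s_new
  }
  X <- sweep(X, 2, colMeans(X))
  list(coords = unname(X), stress = s_prev, stress_init = s0,
       converged = converged, n_iter = it)
}
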