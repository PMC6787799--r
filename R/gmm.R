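#' Build an isotropic Gaussian mixture from embedded clusters
#'
#' The mixture `G(x) = sum_i f_i N(x | x_i, sigma_i^2 I)` represents a
#' population's diversity structure: one isotropic component per haplotype
#' cluster, weighted by cluster frequency, with the cluster's normalized mean
#' difference as the component standard deviation.
#'
#' @param coords m x K matrix of cluster coordinates.
#' @param f component weights, positive and summing to 1 (tolerance 1e-6).
#' @param sigma component standard deviations, strictly positive (run
#'   [normalize_clusters()] first).
#' @return class `embedded_mixture`: `coords`, `f`, `sigma`, `K`, `m`.
#' @export
build_gmm <- function(coords, f, sigma) {
  coords <- as.matrix(coords)
  m <- nrow(coords)
  if (length(f) != m || length(sigma) != m) {
    stop("f and sigma must have one entry per coordinate row")
  }
  if (any(sigma <= 0)) stop("all sigmas must be > 0; run normalize_clusters")
  if (any(f <= 0)) stop("all component weights must be > 0")
  if (abs(sum(f) - 1) > 1e-6) stop("component weights must sum to 1")
  structure(list(coords = unname(coords), f = as.numeric(f / sum(f)),
                 sigma = as.numeric(sigma), K = ncol(coords), m = m),
            class = "embedded_mixture")
}

#' @export
print.embedded_mixture <- function(x, ...) {
  cat(sprintf("<embedded_mixture> %d components in %dD\n", x$m, x$K))
  invisible(x)
}

#' Evaluate a mixture density at points
#'
#' @param g an `embedded_mixture`.
#' @param x matrix of points (rows) in the mixture's K-dim space.
#' @return numeric vector of densities.
#' @export
gmm_density <- function(g, x) {
  x <- matrix(x, ncol = g$K)
  dens <- numeric(nrow(x))
  for (i in seq_len(g$m)) {
    d2 <- rowSums(sweep(x, 2, g$coords[i, ])^2)
    s2 <- g$sigma[i]^2
    dens <- dens + g$f[i] * (2 * pi * s2)^(-g$K / 2) * exp(-d2 / (2 * s2))
  }
  dens
}

# integral of the product of two isotropic mixtures, in closed form:
# int N(x|a, s1^2 I) N(x|b, s2^2 I) dx = N(a - b | 0, (s1^2 + s2^2) I)
gmm_cross <- function(g1, g2) {
  A <- g1$coords; B <- g2$coords; K <- g1$K
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  svar <- outer(g1$sigma^2, g2$sigma^2, "+")
  dens <- (2 * pi * svar)^(-K / 2) * exp(-d2 / (2 * svar))
  as.numeric(crossprod(g1$f, dens %*% g2$f))
}

#' Normalized L2 distance between two Gaussian mixtures (Delta-G)
#'
#' The L2 distance between the unit-L2-normalized mixtures: with
#' `E_ij = int G_i G_j dx` (computed exactly via Gaussian product
#' integrals), `DeltaG = int (G1/sqrt(E11) - G2/sqrt(E22))^2 dx =
#' 2 (1 - E12 / sqrt(E11 E22))`.  It is symmetric, lies in `[0, 2]`, is zero
#' iff the mixtures are identical, and tends to 2 as the mixtures separate.
#' Normalizing each mixture to unit L2 norm keeps the statistic a comparison
#' of shape (cluster geometry and weight profile) rather than of overall
#' peak sharpness, whose energy ratio would otherwise dominate whenever the
#' two pools' sigma profiles differ.  This is the dissimilarity minimized by
#' the Procrustes superimposition.
#'
#' @param g1,g2 `embedded_mixture` objects of the same dimension K.
#' @return scalar in `[0, 2]`.
#' @export
delta_g <- function(g1, g2) {
  stopifnot(inherits(g1, "embedded_mixture"),
            inherits(g2, "embedded_mixture"))
  if (g1$K != g2$K) stop("mixtures live in different dimensions")
  c11 <- gmm_cross(g1, g1)
  c22 <- gmm_cross(g2, g2)
  c12 <- gmm_cross(g1, g2)
  val <- 2 * (1 - c12 / sqrt(c11 * c22))
  min(max(val, 0), 2)
}
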