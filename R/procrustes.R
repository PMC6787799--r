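# --- rigid-transform utilities ---------------------------------------------

# skew-symmetric matrix from K(K-1)/2 parameters (upper triangle, row-major)
skew_from_params <- function(theta, K) {
  S <- matrix(0, K, K)
  idx <- 1L
  if (K >= 2L) for (i in 1:(K - 1)) for (j in (i + 1):K) {
    S[i, j] <- theta[idx]
    S[j, i] <- -theta[idx]
    idx <- idx + 1L
  }
  S
}

# matrix exponential by scaling-and-squaring Taylor series (small K only)
expm_small <- function(A) {
  nrm <- max(abs(A))
  s <- max(0L, ceiling(log2(max(nrm, .Machine$double.eps))) + 1L)
  A <- A / 2^s
  E <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in 1:14) {
    term <- term %*% A / k
    E <- E + term
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

rotation_from_params <- function(theta, K, R0 = diag(K)) {
  expm_small(skew_from_params(theta, K)) %*% R0
}

random_orthogonal <- function(K) {
  qr_d <- qr(matrix(rnorm(K * K), K, K))
  Q <- qr.Q(qr_d)
  Q %*% diag(sign(diag(qr.R(qr_d))), K)
}

# apply x' = x R^T + t to a mixture's coordinates (row-vector convention)
transform_mixture <- function(g, R, t) {
  g$coords <- sweep(g$coords %*% t(R), 2, t, "+")
  g
}

mixture_centroid <- function(g) as.numeric(crossprod(g$f, g$coords))

mixture_cov <- function(g) {
  c0 <- mixture_centroid(g)
  Xc <- sweep(g$coords, 2, c0)
  crossprod(Xc * g$f, Xc)
}

# --- Procrustes minimization of Delta-G ------------------------------------

#' Procrustes superimposition minimizing Delta-G
#'
#' Finds the rigid transform (rotation, translation, optional mirror
#' reflection) of the moving mixture that minimizes [delta_g()] against the
#' reference mixture.  Components are unlabeled, so the search is over
#' transforms, not correspondences: candidate rotations come from aligning
#' the frequency-weighted component covariances' principal axes under all
#' 2^K axis-sign combinations (which covers reflections), plus `n_starts`
#' random orthogonal matrices and an optional warm start; the best few
#' candidates are refined by derivative-free local optimization over rotation
#' parameters and translation.
#'
#' @param g_ref,g_mov `embedded_mixture` objects of equal dimension.
#' @param seed integer seed for the random starts.
#' @param n_starts number of random-rotation starts (default 20) in addition
#'   to the principal-axes candidates.
#' @param n_refine how many top candidates get local refinement.
#' @param maxit Nelder-Mead iteration cap per refinement.
#' @param init_transform optional warm start, a list with `rotation` and
#'   `translation` (e.g. a previous result's transform).
#' @param reltol Nelder-Mead relative tolerance.
#' @param polish if TRUE (default) the winner gets one extra restarted
#'   refinement; turn off in hot loops.
#' @return class `delta_g_result`: `delta_g`, `rotation` (K x K, det may be
#'   -1), `translation`, `reflection` (logical), `converged`.
#' @export
procrustes_min_delta_g <- function(g_ref, g_mov, seed = 1L, n_starts = 20L,
                                   n_refine = 10L, maxit = 400L,
                                   init_transform = NULL, reltol = 1e-14,
                                   polish = TRUE) {
  stopifnot(inherits(g_ref, "embedded_mixture"),
            inherits(g_mov, "embedded_mixture"))
  K <- g_ref$K
  if (g_mov$K != K) stop("mixtures live in different dimensions")
  set.seed(seed)
  c_ref <- mixture_centroid(g_ref)
  c_mov <- mixture_centroid(g_mov)
  E_ref <- eigen(mixture_cov(g_ref), symmetric = TRUE)$vectors
  E_mov <- eigen(mixture_cov(g_mov), symmetric = TRUE)$vectors
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), K)))
  cands <- lapply(seq_len(nrow(signs)), function(i) {
    E_ref %*% diag(signs[i, ], K) %*% t(E_mov)
  })
  for (i in seq_len(n_starts)) cands[[length(cands) + 1L]] <-
    random_orthogonal(K)
  inits <- list()
  if (!is.null(init_transform)) {
    inits <- if (!is.null(init_transform$rotation)) list(init_transform)
    else init_transform  # a list of warm-start transforms
    for (it in inits) cands[[length(cands) + 1L]] <- it$rotation
  }
  # Delta-G under a rigid transform of g_mov: the self terms c11, c22 and the
  # cross-pair variances are invariant, so only the squared cross distances
  # need recomputation per candidate
  c11 <- gmm_cross(g_ref, g_ref)
  c22 <- gmm_cross(g_mov, g_mov)
  norm_c <- sqrt(c11 * c22)
  A <- g_ref$coords
  B0 <- g_mov$coords
  a2 <- rowSums(A^2)
  svar <- outer(g_ref$sigma^2, g_mov$sigma^2, "+")
  pref <- tcrossprod(g_ref$f, g_mov$f) * (2 * pi * svar)^(-K / 2)
  inv2s <- 1 / (2 * svar)
  eval_at <- function(R, t) {
    Bt <- B0 %*% t(R)
    Bt <- sweep(Bt, 2, t, "+")
    d2 <- outer(a2, rowSums(Bt^2), "+") - 2 * tcrossprod(A, Bt)
    c12 <- sum(pref * exp(-d2 * inv2s))
    min(max(2 * (1 - c12 / norm_c), 0), 2)
  }
  t_for <- function(R) c_ref - as.numeric(R %*% c_mov)
  trans <- lapply(cands, t_for)
  if (length(inits)) {
    for (k in seq_along(inits)) {
      trans[[length(cands) - length(inits) + k]] <- inits[[k]]$translation
    }
  }
  scores <- vapply(seq_along(cands), function(i)
    eval_at(cands[[i]], trans[[i]]), numeric(1))
  ord <- order(scores)
  n_par_rot <- K * (K - 1) / 2
  refine <- function(R0, t0, maxit_loc) {
    obj <- function(p) {
      R <- rotation_from_params(p[seq_len(n_par_rot)], K, R0)
      eval_at(R, t0 + p[n_par_rot + seq_len(K)])
    }
    res <- optim(rep(0, n_par_rot + K), obj, method = "Nelder-Mead",
                 control = list(maxit = maxit_loc, reltol = reltol))
    list(R = rotation_from_params(res$par[seq_len(n_par_rot)], K, R0),
         t = t0 + res$par[n_par_rot + seq_len(K)],
         value = res$value, conv = res$convergence == 0L)
  }
  best <- list(value = Inf, R = cands[[ord[1]]], t = t_for(cands[[ord[1]]]),
               conv = FALSE)
  for (i in head(ord, n_refine)) {
    r <- refine(cands[[i]], trans[[i]], maxit)
    if (r$value < best$value) best <- r
  }
  # a second refinement pass from the winner, restarted, escapes shallow
  # Nelder-Mead stalls cheaply
  if (n_refine > 1L) {
    r <- refine(best$R, best$t, maxit)
    if (r$value < best$value) best <- r
  }
  # polish: restart Nelder-Mead at the winner (helps it reach tight optima)
  if (polish) {
    r <- refine(best$R, best$t, maxit)
    if (r$value < best$value) best <- r
  }
  structure(list(delta_g = best$value, rotation = best$R,
                 translation = best$t,
                 reflection = det(best$R) < 0,
                 converged = isTRUE(best$conv)),
            class = "delta_g_result")
}

#' @export
print.delta_g_result <- function(x, ...) {
  cat(sprintf("<delta_g_result> DeltaG = %.6g (%s%s)\n", x$delta_g,
              if (x$reflection) "with reflection" else "rotation only",
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' Apply a Procrustes result to a mixture
#'
#' @param g an `embedded_mixture`.
#' @param res a `delta_g_result` (or list with `rotation`, `translation`).
#' @return the transformed mixture.
#' @export
align_mixture <- function(g, res) {
  transform_mixture(g, res$rotation, res$translation)
}
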