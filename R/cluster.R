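#' Frequency-weighted agglomerative clustering of haplotypes
#'
#' Starts from singleton clusters (sigma = 0) and repeatedly merges the pair
#' of clusters at the smallest distance until `m` clusters remain.  On a
#' merge of clusters i' and j' the distance of the new cluster to any other
#' cluster k is the frequency-weighted average
#' `(D[i',k] f[i'] + D[j',k] f[j']) / (f[i'] + f[j'])`, the new frequency is
#' `f[i'] + f[j']`, and the new cluster's mean difference (sigma) is the
#' merge distance `D[i',j']`.  Distance ties are broken by the smallest
#' (i, j) index pair in the current cluster ordering; the merged cluster
#' takes position i'.
#'
#' @param D symmetric haplotype distance matrix (zero diagonal).
#' @param f haplotype frequencies (positive, summing to 1).
#' @param m target number of clusters, `1 <= m <= nrow(D)`.
#' @return class `cluster_set`: `m`, `frequencies`, `sigmas`, `reduced_D`,
#'   `member_map` (haplotype index -> cluster index), `n_haplotypes`.
#' @export
frequency_weighted_clustering <- function(D, f, m) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (length(f) != n) stop("length(f) must match nrow(D)")
  if (m < 1L) stop("m must be >= 1")
  if (m > n) stop("m (", m, ") exceeds the number of haplotypes (", n, ")")
  if (abs(sum(f) - 1) > 1e-9) stop("frequencies must sum to 1")
  if (any(f <= 0)) stop("frequencies must be positive")
  cur_D <- D
  cur_f <- as.numeric(f)
  cur_s <- rep(0, n)
  members <- as.list(seq_len(n))
  while (length(cur_f) > m) {
    nd <- length(cur_f)
    # minimum over the upper triangle; ties broken by smallest (i, j) pair
    M <- cur_D
    M[lower.tri(M, diag = TRUE)] <- Inf
    bestv <- min(M)
    hits <- which(M == bestv, arr.ind = TRUE)
    pick <- order(hits[, 1], hits[, 2])[1]
    i <- hits[pick, 1]; j <- hits[pick, 2]
    fi <- cur_f[i]; fj <- cur_f[j]
    newrow <- (cur_D[i, ] * fi + cur_D[j, ] * fj) / (fi + fj)
    cur_D[i, ] <- newrow
    cur_D[, i] <- newrow
    cur_D[i, i] <- 0
    cur_s[i] <- bestv
    cur_f[i] <- fi + fj
    members[[i]] <- c(members[[i]], members[[j]])
    keep <- setdiff(seq_len(nd), j)
    cur_D <- cur_D[keep, keep, drop = FALSE]
    cur_f <- cur_f[keep]
    cur_s <- cur_s[keep]
    members <- members[keep]
  }
  member_map <- integer(n)
  for (ci in seq_along(members)) member_map[members[[ci]]] <- ci
  dimnames(cur_D) <- list(seq_len(m), seq_len(m))
  structure(list(m = as.integer(m), frequencies = cur_f, sigmas = cur_s,
                 reduced_D = cur_D, member_map = member_map,
                 n_haplotypes = n),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d clusters over %d haplotypes\n",
              x$m, x$n_haplotypes))
  invisible(x)
}

#' Normalize a cluster set's distances and sigmas
#'
#' Divides the reduced distance matrix and the sigmas by the median of the
#' off-diagonal upper-triangle distances, making cluster sets from pools of
#' different absolute divergence comparable.  Singleton clusters (sigma = 0)
#' then receive a positive sigma by the zero-sigma rule:
#' `"min_product"` (default) sets them to `min over clusters with sigma != 0
#' of sigma_i * f_i`; `"min_sigma_times_own_f"` sets cluster i to
#' `min(sigma[sigma != 0]) * f_i`.  If every sigma is zero they are all set
#' to `zero_sigma_fraction` of the (normalized) median and the result is
#' flagged degenerate.
#'
#' @param cs a `cluster_set`.
#' @param zero_sigma_rule which reading of the substitution rule to use.
#' @param zero_sigma_fraction fallback sigma, as a fraction of the median,
#'   when no cluster has positive sigma.
#' @return a `cluster_set` with normalized `reduced_D` and strictly positive
#'   `sigmas`, plus fields `median_D` (the divisor) and `degenerate`.
#' @export
normalize_clusters <- function(cs,
                               zero_sigma_rule = c("min_product",
                                                   "min_sigma_times_own_f"),
                               zero_sigma_fraction = 0.1) {
  stopifnot(inherits(cs, "cluster_set"))
  zero_sigma_rule <- match.arg(zero_sigma_rule)
  D <- cs$reduced_D
  s <- cs$sigmas
  f <- cs$frequencies
  degenerate <- FALSE
  off <- D[upper.tri(D)]
  if (length(off) == 0L || all(off == 0)) {
    med <- 1  # unit fallback: nothing to scale by
    degenerate <- TRUE
  } else {
    med <- median(off)
    if (med <= 0) { med <- median(off[off > 0]); degenerate <- TRUE }
  }
  D <- D / med
  s <- s / med
  if (any(s == 0)) {
    nz <- s != 0
    if (any(nz)) {
      repl <- switch(zero_sigma_rule,
                     min_product = min(s[nz] * f[nz]),
                     min_sigma_times_own_f = min(s[nz]) * f)
      if (zero_sigma_rule == "min_product") s[!nz] <- repl
      else s[!nz] <- repl[!nz]
    } else {
      s[] <- zero_sigma_fraction
      degenerate <- TRUE
    }
  }
  out <- cs
  out$reduced_D <- D
  out$sigmas <- s
  out$median_D <- med
  out$degenerate <- degenerate
  out
}
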