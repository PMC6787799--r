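# pi from haplotype counts and a haplotype hamming matrix:
# mean pairwise difference per site across all n(n-1)/2 sequence pairs
pi_from_counts <- function(counts, dmat, L) {
  n <- sum(counts)
  if (n < 2L) stop("pi needs at least 2 sequences")
  num <- as.numeric(crossprod(counts, dmat %*% counts))  # sums i != j twice
  num / (n * (n - 1)) / L
}

#' Nucleotide diversity pi of a pool
#'
#' Nei-Li nucleotide diversity: the mean proportion of mismatching sites over
#' all unordered sequence pairs (raw p-distance; no multiple-hit correction).
#'
#' @param pool an [aligned_pool()].
#' @return a list of class `diversity_estimate` with `pi`, `sample_size`,
#'   `pool_id`.
#' @export
pi_diversity <- function(pool) {
  stopifnot(inherits(pool, "aligned_pool"))
  hs <- collapse_haplotypes(pool)
  d <- hamming_matrix(hs)
  structure(list(pi = pi_from_counts(hs$counts, d, hs$length),
                 sample_size = pool$n, pool_id = pool$pool_id),
            class = "diversity_estimate")
}

#' @export
print.diversity_estimate <- function(x, ...) {
  cat(sprintf("<diversity_estimate> %s: pi = %.5f (n = %d)\n",
              x$pool_id, x$pi, x$sample_size))
  invisible(x)
}

#' Bootstrap distribution of pi
#'
#' Each trial draws `subsample_size` sequences with replacement from the pool
#' and computes pi.  The defaults (70 sequences, 2000 trials) are the
#' conventional settings for ~100-clone receptor pools; they are reused for
#' rhizobial pools unless overridden.
#'
#' @param pool an [aligned_pool()].
#' @param subsample_size sequences per trial (>= 2).
#' @param trials number of bootstrap trials.
#' @param seed integer seed; identical seeds give identical distributions.
#' @return class `bootstrap_distribution`: `values`, `subsample_size`,
#'   `trials`, `seed`, `pool_id`.
#' @export
bootstrap_pi <- function(pool, subsample_size = 70L, trials = 2000L,
                         seed = 1L) {
  stopifnot(inherits(pool, "aligned_pool"))
  if (subsample_size < 2L) stop("subsample_size must be >= 2")
  hs <- collapse_haplotypes(pool)
  d <- hamming_matrix(hs)
  probs <- hs$frequencies
  set.seed(seed)
  vals <- vapply(seq_len(trials), function(b) {
    cnt <- as.vector(rmultinom(1L, subsample_size, probs))
    pi_from_counts(cnt, d, hs$length)
  }, numeric(1))
  structure(list(values = vals, subsample_size = as.integer(subsample_size),
                 trials = as.integer(trials), seed = as.integer(seed),
                 pool_id = pool$pool_id),
            class = "bootstrap_distribution")
}

#' Rarefaction of pi over sampling depths
#'
#' Subsamples the pool with replacement at each depth and reports the mean and
#' standard deviation of pi, to check whether sequencing depth saturates the
#' diversity estimate.
#'
#' @param pool an [aligned_pool()].
#' @param depths integer vector of subsample sizes (each >= 2).
#' @param trials_per_depth trials at each depth.
#' @param seed integer seed.
#' @return data.frame with columns `depth`, `mean_pi`, `sd_pi`.
#' @export
rarefaction_pi <- function(pool, depths, trials_per_depth = 100L, seed = 1L) {
  stopifnot(inherits(pool, "aligned_pool"), all(depths >= 2))
  hs <- collapse_haplotypes(pool)
  d <- hamming_matrix(hs)
  set.seed(seed)
  rows <- lapply(sort(as.integer(depths)), function(dep) {
    v <- vapply(seq_len(trials_per_depth), function(b) {
      cnt <- as.vector(rmultinom(1L, dep, hs$frequencies))
      pi_from_counts(cnt, d, hs$length)
    }, numeric(1))
    data.frame(depth = dep, mean_pi = mean(v), sd_pi = sd(v))
  })
  do.call(rbind, rows)
}

#' Spearman concordance between paired plant and nodule pi distributions
#'
#' For each host species the plant-pool and nodule-pool bootstrap values are
#' randomly paired one-to-one (a uniform permutation of one side); pairs from
#' all species are concatenated and Spearman's rank correlation is computed on
#' the combined paired sample.  With the default three species x 2000 trials
#' this is the 6000-pair design; rho above the threshold (0.8 by convention)
#' is read as a monotonic diversity relationship.
#'
#' @param plant_dists,nodule_dists named lists (same species names) of
#'   `bootstrap_distribution` objects or plain numeric vectors, equal lengths
#'   per species.
#' @param threshold monotonicity threshold on rho.
#' @param seed integer seed for the random pairing.
#' @return class `concordance_result`: `spearman_rho`, `n_pairs`, `threshold`,
#'   `is_monotonic`, `degenerate` (TRUE when all ranks tie and rho is set 0).
#' @export
paired_spearman_concordance <- function(plant_dists, nodule_dists,
                                        threshold = 0.8, seed = 1L) {
  sp <- names(plant_dists)
  if (is.null(sp) || !setequal(sp, names(nodule_dists))) {
    stop("plant and nodule distributions must share species names")
  }
  vals <- function(x) if (inherits(x, "bootstrap_distribution")) x$values
  else as.numeric(x)
  set.seed(seed)
  xs <- ys <- numeric(0)
  for (s in sp) {
    a <- vals(plant_dists[[s]]); b <- vals(nodule_dists[[s]])
    if (length(a) != length(b)) stop("unequal trial counts for species ", s)
    xs <- c(xs, a)
    ys <- c(ys, b[sample.int(length(b))])
  }
  degenerate <- (length(unique(xs)) == 1L || length(unique(ys)) == 1L)
  rho <- if (degenerate) 0 else
    suppressWarnings(cor(xs, ys, method = "spearman"))
  if (is.na(rho)) { rho <- 0; degenerate <- TRUE }
  structure(list(spearman_rho = rho, n_pairs = length(xs),
                 threshold = threshold, is_monotonic = rho > threshold,
                 degenerate = degenerate),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "<concordance_result> rho = %.3f over %d pairs (threshold %.2f): %s%s\n",
    x$spearman_rho, x$n_pairs, x$threshold,
    if (x$is_monotonic) "monotonic" else "not monotonic",
    if (x$degenerate) " [degenerate ties]" else ""))
  invisible(x)
}
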