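#' Joint embedding of rhizobial pools and separate mixture construction
#'
#' The plant pool is clustered, normalized and embedded on its own.  The
#' nodule and soil pools are pooled first, so that shared haplotypes are
#' clustered and embedded identically in both comparisons; per-origin
#' mixtures are then built on the same coordinates and sigmas, with component
#' weights equal to each origin's share of sequences in each cluster
#' (clusters an origin never touches are omitted from its mixture).
#'
#' @param plant_pool,nodule_pool,soil_pool [aligned_pool()]s.
#' @param m target cluster count (capped, with a warning, at the number of
#'   unique haplotypes on each side).
#' @param K embedding dimension.
#' @param seed integer seed (MDS degenerate-start jitter only; the procedure
#'   is otherwise deterministic).
#' @param zero_sigma_rule passed to [normalize_clusters()].
#' @return class `joint_embedding`: `g_plant`, `g_nodule`, `g_soil`
#'   (`embedded_mixture`s), plus the machinery needed for bootstrap:
#'   `rhizobia_cluster_of_nodule`, `rhizobia_cluster_of_soil` (cluster index
#'   per sequence), `rhizobia_coords`, `rhizobia_sigmas`, `plant_clusters`,
#'   `rhizobia_clusters` (normalized `cluster_set`s), `m_plant`,
#'   `m_rhizobia`.
#' @export
joint_embed_split <- function(plant_pool, nodule_pool, soil_pool, m = 10L,
                              K = 3L, seed = 1L,
                              zero_sigma_rule = "min_product") {
  stopifnot(inherits(plant_pool, "aligned_pool"),
            inherits(nodule_pool, "aligned_pool"),
            inherits(soil_pool, "aligned_pool"))
  embed_one <- function(hs, m_eff) {
    d <- hamming_matrix(hs)
    cs <- frequency_weighted_clustering(d, hs$frequencies, m_eff)
    ns <- normalize_clusters(cs, zero_sigma_rule = zero_sigma_rule)
    emb <- metric_mds(ns$reduced_D, K = K, seed = seed)
    list(cs = ns, coords = emb$coords)
  }
  # plant side
  hs_p <- collapse_haplotypes(plant_pool)
  m_p <- min(m, hs_p$n_unique)
  if (m_p < m) warning("plant pool has only ", hs_p$n_unique,
                       " haplotypes; m capped at ", m_p)
  ep <- embed_one(hs_p, m_p)
  g_plant <- build_gmm(ep$coords, ep$cs$frequencies, ep$cs$sigmas)
  # joint rhizobial side
  joint_seqs <- c(nodule_pool$sequences, soil_pool$sequences)
  if (nodule_pool$length != soil_pool$length) {
    stop("nodule and soil pools must share alignment length")
  }
  joint_pool <- aligned_pool(joint_seqs, pool_id = "rhizobia_joint",
                             species = nodule_pool$species,
                             origin = "nodule")
  hs_j <- collapse_haplotypes(joint_pool)
  m_j <- min(m, hs_j$n_unique)
  if (m_j < m) warning("joint rhizobial pool has only ", hs_j$n_unique,
                       " haplotypes; m capped at ", m_j)
  ej <- embed_one(hs_j, m_j)
  cluster_of_seq <- ej$cs$member_map[hs_j$membership]
  idx_nod <- seq_len(nodule_pool$n)
  idx_soil <- nodule_pool$n + seq_len(soil_pool$n)
  origin_mixture <- function(cl_of) {
    cnt <- tabulate(cl_of, nbins = m_j)
    if (sum(cnt) == 0L) stop("an origin has no sequences in any cluster")
    fo <- cnt / sum(cnt)
    keep <- fo > 0
    build_gmm(ej$coords[keep, , drop = FALSE], fo[keep],
              ej$cs$sigmas[keep])
  }
  g_nodule <- origin_mixture(cluster_of_seq[idx_nod])
  g_soil <- origin_mixture(cluster_of_seq[idx_soil])
  structure(list(g_plant = g_plant, g_nodule = g_nodule, g_soil = g_soil,
                 rhizobia_cluster_of_nodule = cluster_of_seq[idx_nod],
                 rhizobia_cluster_of_soil = cluster_of_seq[idx_soil],
                 rhizobia_coords = ej$coords,
                 rhizobia_sigmas = ej$cs$sigmas,
                 plant_clusters = ep$cs, rhizobia_clusters = ej$cs,
                 plant_coords = ep$coords,
                 m_plant = m_p, m_rhizobia = m_j, K = K),
            class = "joint_embedding")
}

# per-origin mixture from a cluster-count vector on the fixed joint embedding
mixture_from_counts <- function(cnt, coords, sigmas) {
  fo <- cnt / sum(cnt)
  keep <- fo > 0
  build_gmm(coords[keep, , drop = FALSE], fo[keep], sigmas[keep])
}

#' Bootstrap Delta-G for the nodule and soil comparisons
#'
#' The joint clustering and MDS are computed once on the full data and held
#' fixed.  Each bootstrap replicate resamples sequences with replacement
#' within each rhizobial origin, recomputes that origin's cluster
#' frequencies through the fixed haplotype-to-cluster map, rebuilds the two
#' mixtures and re-runs the Procrustes minimization against the fixed plant
#' mixture (warm-started from the full-data alignment).  The two Delta-G sets
#' are compared by a one-sided Mann-Whitney test of H1:
#' `DeltaG(nodule) < DeltaG(soil)`, i.e. the nodule pool's topology is closer
#' to the plant's.
#'
#' @param plant_pool,nodule_pool,soil_pool [aligned_pool()]s.
#' @param m,K,zero_sigma_rule passed to [joint_embed_split()].
#' @param n_boot bootstrap replicates per comparison.
#' @param seed integer seed.
#' @param n_starts random starts for the two full-data alignments.
#' @param boot_n_starts random starts per bootstrap alignment (the full-data
#'   transform is always included as a warm start).
#' @param alpha significance level.
#' @return class `topology_test_result`: `delta_g_nodule`, `delta_g_soil`
#'   (bootstrap vectors), `full_delta_g_nodule`, `full_delta_g_soil`,
#'   `U_statistic`, `p_value`, `alpha`, `significant`, `embedding`,
#'   `transform_nodule`, `transform_soil`.
#' @export
bootstrap_delta_g <- function(plant_pool, nodule_pool, soil_pool, m = 10L,
                              K = 3L, n_boot = 100L, seed = 1L,
                              n_starts = 20L, boot_n_starts = 1L,
                              alpha = 0.01, zero_sigma_rule = "min_product") {
  if (n_boot < 1L) stop("n_boot must be >= 1")
  emb <- joint_embed_split(plant_pool, nodule_pool, soil_pool, m = m, K = K,
                           seed = seed, zero_sigma_rule = zero_sigma_rule)
  res_nod <- procrustes_min_delta_g(emb$g_plant, emb$g_nodule, seed = seed,
                                    n_starts = n_starts)
  res_soil <- procrustes_min_delta_g(emb$g_plant, emb$g_soil,
                                     seed = seed + 1L, n_starts = n_starts)
  mj <- emb$m_rhizobia
  # both full-data transforms serve as warm starts for every replicate, so
  # the two arms see symmetric candidate sets (otherwise an arm could
  # inherit a systematically better alignment basin)
  warm_starts <- list(res_nod, res_soil)
  # all resampled count vectors are drawn from one continuous RNG stream
  # before any alignment runs: the alignment internally reseeds for its
  # random starts, and interleaving those reseeds with the resampling draws
  # would turn the two arms into slices of an integer-indexed sequence
  # instead of clean iid draws (observed as a lumpy Mann-Whitney null)
  set.seed(seed)
  draw_counts <- function(cl_of) {
    nseq <- length(cl_of)
    for (attempt in 1:100) {
      cnt <- tabulate(sample(cl_of, nseq, replace = TRUE), nbins = mj)
      if (sum(cnt) > 0L) return(cnt)
    }
    stop("bootstrap emptied an origin repeatedly")
  }
  cnt_nod <- cnt_soil <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    cnt_nod[[b]] <- draw_counts(emb$rhizobia_cluster_of_nodule)
    cnt_soil[[b]] <- draw_counts(emb$rhizobia_cluster_of_soil)
  }
  boot_one <- function(cnt, bseed) {
    g <- mixture_from_counts(cnt, emb$rhizobia_coords, emb$rhizobia_sigmas)
    procrustes_min_delta_g(emb$g_plant, g, seed = bseed,
                           n_starts = boot_n_starts, n_refine = 1L,
                           maxit = 120L, init_transform = warm_starts,
                           reltol = 1e-9, polish = FALSE)$delta_g
  }
  dg_nod <- dg_soil <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    dg_nod[b] <- boot_one(cnt_nod[[b]], bseed = seed + 2L * b)
    dg_soil[b] <- boot_one(cnt_soil[[b]], bseed = seed + 2L * b + 1L)
  }
  mw <- mann_whitney_one_sided(dg_nod, dg_soil, alternative = "a_less",
                               alpha = alpha)
  structure(list(delta_g_nodule = dg_nod, delta_g_soil = dg_soil,
                 full_delta_g_nodule = res_nod$delta_g,
                 full_delta_g_soil = res_soil$delta_g,
                 U_statistic = mw$statistic, p_value = mw$p_value,
                 alpha = alpha, significant = mw$p_value < alpha,
                 embedding = emb, transform_nodule = res_nod,
                 transform_soil = res_soil),
            class = "topology_test_result")
}

#' @export
print.topology_test_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<topology_test_result> DeltaG nodule=%.4f soil=%.4f ",
    "(medians %.4f / %.4f); U=%g p=%.4g alpha=%.3g\n"),
    x$full_delta_g_nodule, x$full_delta_g_soil,
    median(x$delta_g_nodule), median(x$delta_g_soil),
    x$U_statistic, x$p_value, x$alpha))
  invisible(x)
}

#' One-sided Mann-Whitney U test
#'
#' U counts the pairs where an `a` value exceeds a `b` value (ties count
#' one half).  With no ties and `min(n_a, n_b) <= 8` the p-value is exact
#' (Wilcoxon distribution); otherwise a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param a,b numeric vectors.
#' @param alternative `"a_less"` (H1: a stochastically smaller) or
#'   `"a_greater"`.
#' @param alpha significance level recorded in the result.
#' @return class `contrast_result` with `statistic` (U), `p_value`,
#'   `alternative`, `alpha`, `significant`, `method`.
#' @export
mann_whitney_one_sided <- function(a, b,
                                   alternative = c("a_less", "a_greater"),
                                   alpha = 0.01) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  na <- length(a); nb <- length(b)
  gt <- outer(a, b, ">")
  eq <- outer(a, b, "==")
  U <- sum(gt) + 0.5 * sum(eq)
  ties <- any(eq) || anyDuplicated(a) > 0L || anyDuplicated(b) > 0L
  if (!ties && min(na, nb) <= 8L) {
    p <- if (alternative == "a_less") pwilcox(U, na, nb) else
      pwilcox(U - 1, na, nb, lower.tail = FALSE)
    method <- "exact"
  } else {
    N <- na + nb
    tie_tab <- table(c(a, b))
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- na * nb / 12 * ((N + 1) - tie_term)
    mu <- na * nb / 2
    if (sigma2 <= 0) {
      p <- 0.5
    } else if (alternative == "a_less") {
      p <- pnorm((U + 0.5 - mu) / sqrt(sigma2))
    } else {
      p <- pnorm((U - 0.5 - mu) / sqrt(sigma2), lower.tail = FALSE)
    }
    method <- "normal_approx"
  }
  structure(list(statistic = U, p_value = p, alternative = alternative,
                 alpha = alpha, significant = p < alpha, method = method,
                 degenerate = FALSE),
            class = "contrast_result")
}
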