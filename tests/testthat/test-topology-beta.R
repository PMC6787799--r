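test_that("frequency-weighted clustering reproduces the worked example", {
  D <- matrix(c(0, 1, 4,
                1, 0, 4,
                4, 4, 0), 3, byrow = TRUE)
  cs <- frequency_weighted_clustering(D, c(0.25, 0.25, 0.5), m = 2)
  expect_equal(cs$frequencies, c(0.5, 0.5))
  expect_equal(cs$sigmas, c(1, 0))
  expect_equal(unname(cs$reduced_D[1, 2]), 4)
  expect_equal(cs$member_map, c(1L, 1L, 2L))
})

test_that("clustering boundary cases and conservation", {
  D <- hamming_matrix(c("AAAA", "AATT", "TTTT", "TTAA"))
  f <- c(0.4, 0.3, 0.2, 0.1)
  id <- frequency_weighted_clustering(D, f, m = 4)
  expect_equal(id$frequencies, f)
  expect_equal(id$sigmas, rep(0, 4))
  expect_equal(unname(id$reduced_D), unname(D))

  one <- frequency_weighted_clustering(D, f, m = 1)
  expect_equal(one$frequencies, 1)
  expect_equal(one$m, 1L)

  for (m in 1:4) {
    cs <- frequency_weighted_clustering(D, f, m)
    expect_equal(sum(cs$frequencies), 1, tolerance = 1e-12)
    expect_true(all(cs$sigmas >= 0))
    expect_true(all(cs$member_map %in% seq_len(m)))
  }
  expect_error(frequency_weighted_clustering(D, f, 5), "exceeds")
  expect_error(frequency_weighted_clustering(D, f, 0), ">= 1")
})

test_that("normalize_clusters applies the median and zero-sigma rules", {
  cs <- structure(list(m = 2L, frequencies = c(0.5, 0.5), sigmas = c(1, 0),
                       reduced_D = matrix(c(0, 2, 2, 0), 2),
                       member_map = c(1L, 2L), n_haplotypes = 2L),
                  class = "cluster_set")
  ns <- normalize_clusters(cs)
  expect_equal(unname(ns$reduced_D), matrix(c(0, 1, 1, 0), 2))
  expect_equal(ns$sigmas, c(0.5, 0.25))  # min over nonzero of sigma*f

  ns2 <- normalize_clusters(cs, zero_sigma_rule = "min_sigma_times_own_f")
  expect_equal(ns2$sigmas, c(0.5, 0.5 * 0.5))

  # scaling invariance: c * D leaves the normalized result unchanged
  cs_scaled <- cs
  cs_scaled$reduced_D <- cs$reduced_D * 7
  cs_scaled$sigmas <- cs$sigmas * 7
  ns_s <- normalize_clusters(cs_scaled)
  expect_equal(ns_s$reduced_D, ns$reduced_D)
  expect_equal(ns_s$sigmas, ns$sigmas)

  # all sigmas positive -> only scaling
  cs3 <- cs; cs3$sigmas <- c(1, 3)
  ns3 <- normalize_clusters(cs3)
  expect_equal(ns3$sigmas, c(0.5, 1.5))

  # all-zero distances -> degenerate flag, unit fallback
  cs4 <- cs; cs4$reduced_D <- matrix(0, 2, 2); cs4$sigmas <- c(0, 0)
  ns4 <- normalize_clusters(cs4)
  expect_true(ns4$degenerate)
  expect_true(all(ns4$sigmas > 0))
})

test_that("metric MDS reproduces embeddable distances and honors the
           majorization contract", {
  set.seed(4)
  X <- matrix(rnorm(12), 4, 3)
  D <- as.matrix(dist(X))
  emb <- metric_mds(D, K = 3, seed = 1)
  expect_equal(as.matrix(dist(emb$coords)), D, ignore_attr = TRUE,
               tolerance = 1e-6)
  expect_lte(emb$stress, emb$stress_init + 1e-12)
  expect_equal(colMeans(emb$coords), rep(0, 3), tolerance = 1e-9)

  D2 <- matrix(c(0, 5, 5, 0), 2)
  e2 <- metric_mds(D2, K = 3, seed = 1)
  expect_equal(as.matrix(dist(e2$coords))[1, 2], 5, tolerance = 1e-9)

  # non-embeddable distances still improve on the classical start
  D3 <- matrix(1, 5, 5); diag(D3) <- 0
  e3 <- metric_mds(D3, K = 1, seed = 1)
  expect_lte(e3$stress, e3$stress_init + 1e-12)
})

test_that("build_gmm closed forms and normalization", {
  g <- build_gmm(matrix(0, 1, 3), 1, 0.7)
  expect_equal(gmm_density(g, matrix(0, 1, 3)),
               (2 * pi * 0.49)^(-3 / 2))

  # two equal components at the same center equal a single Gaussian
  g2 <- build_gmm(matrix(0, 2, 2), c(0.5, 0.5), c(0.7, 0.7))
  g1 <- build_gmm(matrix(0, 1, 2), 1, 0.7)
  pts <- matrix(rnorm(20), 10, 2)
  expect_equal(gmm_density(g2, pts), gmm_density(g1, pts))

  # Monte-Carlo integral ~ 1 (2D, importance-free box)
  set.seed(8)
  gg <- build_gmm(matrix(rnorm(6), 3, 2), c(0.2, 0.3, 0.5),
                  c(0.4, 0.6, 0.5))
  box <- 12
  pts <- matrix(runif(2e6, -box / 2, box / 2), ncol = 2)
  integral <- mean(gmm_density(gg, pts)) * box^2
  expect_equal(integral, 1, tolerance = 0.01)

  expect_error(build_gmm(matrix(0, 1, 2), 1, 0), "> 0")
  expect_error(build_gmm(matrix(0, 2, 2), c(0.7, 0.7), c(1, 1)), "sum to 1")
})

test_that("delta_g closed form, symmetry, limits and quadrature", {
  set.seed(12)
  mk2d <- function() build_gmm(matrix(rnorm(6), 3, 2),
                               {f <- runif(3); f / sum(f)},
                               runif(3, 0.3, 0.8))
  for (i in 1:5) {
    g1 <- mk2d(); g2 <- mk2d()
    expect_equal(delta_g(g1, g1), 0, tolerance = 1e-12)
    expect_equal(delta_g(g1, g2), delta_g(g2, g1), tolerance = 1e-12)
    expect_equal(delta_g(g1, g2), grid_delta_g(g1, g2),
                 tolerance = 1e-4)
  }
  # far-apart equal-energy Gaussians -> 2
  ga <- build_gmm(matrix(0, 1, 3), 1, 1)
  gb <- build_gmm(matrix(c(100, 0, 0), 1, 3), 1, 1)
  expect_equal(delta_g(ga, gb), 2, tolerance = 1e-9)
  expect_error(delta_g(ga, mk2d()), "dimension")
})

test_that("Procrustes alignment recovers rigid transforms and never hurts", {
  set.seed(21)
  for (trial in 1:5) {
    X <- matrix(rnorm(15), 5, 3)
    f <- {w <- runif(5); w / sum(w)}
    s <- runif(5, 0.3, 0.9)
    g1 <- build_gmm(X, f, s)
    R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (trial %% 2 == 0) R[, 1] <- -R[, 1]  # include reflections
    tv <- rnorm(3, sd = 2)
    g2 <- build_gmm(sweep(X %*% t(R), 2, tv, "+"), f, s)
    raw <- delta_g(g1, g2)
    res <- procrustes_min_delta_g(g1, g2, seed = trial, n_starts = 20)
    expect_lte(res$delta_g, 1e-6)
    expect_lte(res$delta_g, raw + 1e-12)
    # aligned mixture attains the reported value
    expect_equal(delta_g(g1, align_mixture(g2, res)), res$delta_g,
                 tolerance = 1e-9)
  }
  g <- build_gmm(matrix(rnorm(9), 3, 3), rep(1 / 3, 3), rep(0.5, 3))
  res_id <- procrustes_min_delta_g(g, g, seed = 1, n_starts = 5)
  expect_lte(res_id$delta_g, 1e-10)
})

test_that("joint embedding splits origins coherently", {
  sys <- simulate_system(small_cfg(3))
  # identical nodule and soil pools give identical mixtures
  emb <- joint_embed_split(sys$plant_pool, sys$nodule_pool, sys$nodule_pool,
                           m = 6, K = 3, seed = 1)
  expect_equal(emb$g_nodule$coords, emb$g_soil$coords)
  expect_equal(emb$g_nodule$f, emb$g_soil$f)
  expect_equal(sum(emb$g_nodule$f), 1, tolerance = 1e-12)
  expect_equal(sum(emb$g_plant$f), 1, tolerance = 1e-12)

  # private clade: soil lacks a clade the nodule pool has, so the nodule
  # mixture spans clusters the soil mixture misses
  cfgp <- small_cfg(17, n_clades = 3, nodule_private_clade = TRUE,
                    clade_frequencies = c(0.5, 0.35, 0.15))
  sysp <- simulate_system(cfgp)
  drop_clade <- sysp$truth$private_clade
  expect_false(is.na(drop_clade))
  private_haps <- sysp$truth$rhiz_clade_haps[[drop_clade]]
  expect_true(any(sysp$nodule_pool$sequences %in% private_haps))
  expect_false(any(sysp$soil_pool$sequences %in% private_haps))
  embp <- joint_embed_split(sysp$plant_pool, sysp$nodule_pool,
                            sysp$soil_pool, m = 8, K = 3, seed = 1)
  expect_gt(embp$g_nodule$m, embp$g_soil$m - 1)  # soil omits empty clusters
})

test_that("bootstrap_delta_g is deterministic and separates matched from
           null", {
  sys <- simulate_system(topo_cfg(29))
  t1 <- bootstrap_delta_g(sys$plant_pool, sys$nodule_pool, sys$soil_pool,
                          m = 4, K = 3, n_boot = 5, seed = 7, n_starts = 8)
  t2 <- bootstrap_delta_g(sys$plant_pool, sys$nodule_pool, sys$soil_pool,
                          m = 4, K = 3, n_boot = 5, seed = 7, n_starts = 8)
  expect_identical(t1$delta_g_nodule, t2$delta_g_nodule)
  expect_identical(t1$delta_g_soil, t2$delta_g_soil)
  expect_length(t1$delta_g_nodule, 5L)
  # matched system: nodule topologically closer than soil
  t3 <- bootstrap_delta_g(sys$plant_pool, sys$nodule_pool, sys$soil_pool,
                          m = 4, K = 3, n_boot = 30, seed = 8, n_starts = 12)
  expect_lt(median(t3$delta_g_nodule), median(t3$delta_g_soil))
})

test_that("Mann-Whitney exact and approximate branches", {
  r <- mann_whitney_one_sided(c(1, 2), c(3, 4), alternative = "a_less")
  expect_equal(r$p_value, 1 / 6, tolerance = 1e-12)
  expect_equal(r$method, "exact")
  expect_equal(r$statistic, 0)

  set.seed(14)
  x <- rnorm(100)
  ri <- mann_whitney_one_sided(x, x, "a_less")
  expect_equal(ri$p_value, 0.5, tolerance = 0.05)

  # exact enumeration oracle on small samples
  for (seed in 1:6) {
    set.seed(seed)
    a <- rnorm(5); b <- rnorm(6)
    for (alt in c("a_less", "a_greater")) {
      expect_equal(mann_whitney_one_sided(a, b, alt)$p_value,
                   brute_mw_p(a, b, alt), tolerance = 1e-12)
    }
  }

  # exact vs normal approximation within 0.02 at n = 8 vs 8
  set.seed(15)
  a <- rnorm(8); b <- rnorm(8, 0.3)
  ex <- mann_whitney_one_sided(a, b, "a_less")
  expect_equal(ex$method, "exact")
  U <- ex$statistic
  mu <- 8 * 8 / 2; sig <- sqrt(8 * 8 * (8 + 8 + 1) / 12)
  approx_p <- pnorm((U + 0.5 - mu) / sig)
  expect_lt(abs(ex$p_value - approx_p), 0.02)

  # ties route to the corrected normal approximation
  rt <- mann_whitney_one_sided(c(1, 1, 2), c(1, 2, 2), "a_less")
  expect_equal(rt$method, "normal_approx")
  expect_true(rt$p_value > 0 && rt$p_value < 1)
})
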