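test_that("Nei-Gojobori site counts match enumeration and conserve 3 per
           codon", {
  expect_equal(ng_site_counts("TTT"), c(syn_sites = 1 / 3,
                                        nonsyn_sites = 8 / 3))
  expect_equal(ng_site_counts("ATG"), c(syn_sites = 0, nonsyn_sites = 3))
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  for (cod in sense) {
    got <- ng_site_counts(cod)
    expect_equal(sum(got), 3, tolerance = 1e-12)
    expect_equal(unname(got["syn_sites"]), brute_codon_syn_sites(cod))
  }
  expect_error(ng_site_counts("ATGTAA"), "stop")
  # frame trim: offset 1 with trailing remainder dropped
  expect_equal(sum(ng_site_counts("AATGGGC", frame_offset = 1)), 6)
})

test_that("pn_ps matches the exhaustive pathway oracle", {
  mono <- aligned_pool(rep("ATGTTTAAA", 4), origin = "nodule")
  st <- pn_ps(mono)
  expect_equal(st$pN, 0)
  expect_equal(st$pS, 0)
  expect_true(is.na(st$pN_over_pS))

  # TTT (Phe) -> TTA (Leu): a single nonsynonymous change
  p2 <- aligned_pool(c("ATGTTT", "ATGTTA"), origin = "nodule")
  st2 <- pn_ps(p2)
  expect_gt(st2$pN, 0)
  expect_equal(st2$pS, 0)

  for (seed in 1:4) {
    p <- rand_coding_pool(10, n_codons = 8, seed = seed)
    got <- pn_ps(p)
    oracle <- brute_pn_ps(p)
    expect_equal(got$pN, oracle$pN, tolerance = 1e-10)
    expect_equal(got$pS, oracle$pS, tolerance = 1e-10)
  }
})

test_that("Tajima's D follows the 1989 formula and sign logic", {
  mono <- aligned_pool(rep("ACGTACGTAC", 5), origin = "soil")
  expect_warning(d0 <- tajimas_d(mono), "undefined")
  expect_true(is.na(d0))

  # four sequences, three singleton variants -> negative D; compare with a
  # direct evaluation of the formula
  p <- aligned_pool(c("AAA", "AAT", "ATA", "TAA"), origin = "soil")
  d <- tajimas_d(p)
  expect_lt(d, 0)
  n <- 4; S <- 3
  pi_total <- mean(c(1, 1, 1, 2, 2, 2))  # hand-counted pairwise differences
  a1 <- sum(1 / 1:3); a2 <- sum(1 / (1:3)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  expect_equal(d, (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1)),
               tolerance = 1e-12)

  expect_error(tajimas_d(aligned_pool(c("AA", "AT"), origin = "soil")),
               "n >= 4")

  # balanced two-haplotype pool -> positive D
  bal <- aligned_pool(c(rep("AAAAAAAAAA", 10), rep("TTTTTTTTTT", 10)),
                      origin = "soil")
  expect_gt(tajimas_d(bal), 0)
})

test_that("welch_contrast matches t.test and handles degenerate input", {
  set.seed(31)
  a <- rnorm(40); b <- rnorm(40, 1)
  got <- welch_contrast(a, b, alternative = "a_less")
  ref <- t.test(a, b, alternative = "less", var.equal = FALSE)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  expect_true(got$significant)

  got_g <- welch_contrast(a, b, alternative = "a_greater")
  ref_g <- t.test(a, b, alternative = "greater", var.equal = FALSE)
  expect_equal(got_g$p_value, ref_g$p.value, tolerance = 1e-12)

  same <- rnorm(100)
  expect_equal(welch_contrast(same, same, "a_less")$p_value, 0.5)

  # large-effect power
  set.seed(32)
  expect_lt(welch_contrast(rnorm(200), rnorm(200, 1), "a_less")$p_value,
            0.01)

  deg <- welch_contrast(rep(1, 10), rep(1, 10), "a_less")
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 0.5)
  deg2 <- welch_contrast(rep(0, 10), rep(1, 10), "a_less")
  expect_true(deg2$degenerate)
  expect_equal(deg2$p_value, 0)
})

test_that("bootstrap_selection replicates center on the pool statistics", {
  p <- rand_coding_pool(150, n_codons = 20, seed = 5, n_haps = 8,
                        mut_per_hap = 4)
  bs <- bootstrap_selection(p, subsample_size = 70, trials = 150, seed = 2)
  st <- pn_ps(p)
  expect_lt(abs(mean(bs$pN$values) - st$pN), 4 * sd(bs$pN$values) + 1e-9)
  expect_lt(abs(mean(bs$pS$values) - st$pS), 4 * sd(bs$pS$values) + 1e-9)
  bs2 <- bootstrap_selection(p, subsample_size = 70, trials = 150, seed = 2)
  expect_identical(bs$D$values, bs2$D$values)
})

test_that("site linkage check flags complete linkage and degenerate pools", {
  # two equifrequent haplotypes differing at one syn and one nonsyn site:
  # GGA->GGG is synonymous (Gly), TTA->TCA is nonsynonymous (Leu->Ser);
  # add two monomorphic codons for background
  h1 <- paste0("GGA", "TTA", "AAA", "CCC", "GGT", "TTG")
  h2 <- paste0("GGG", "TCA", "AAA", "CCC", "GGT", "TTG")
  # need >= 2 sites per class: duplicate the variable codons
  h1 <- paste0(h1, "GGA", "TTA")
  h2 <- paste0(h2, "GGG", "TCA")
  pool <- aligned_pool(c(rep(h1, 10), rep(h2, 10)), origin = "nodule")
  res <- site_linkage_check(pool, permutations = 100, seed = 1)
  expect_equal(res$n_syn_sites, 2L)
  expect_equal(res$n_nonsyn_sites, 2L)
  expect_equal(res$observed_mean_r2, 1, tolerance = 1e-12)
  expect_lte(res$p_value, 0.05)

  mono <- aligned_pool(rep("ATGAAA", 5), origin = "nodule")
  expect_warning(r0 <- site_linkage_check(mono, permutations = 10),
                 "insufficient")
  expect_true(is.na(r0$p_value))
})
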