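# Independent brute-force oracles.  These deliberately avoid the package's
# internal code paths: plain double loops, enumeration, or quadrature.

rand_pool <- function(n, L, seed, n_haps = NULL, origin = "plant") {
  set.seed(seed)
  if (is.null(n_haps)) {
    seqs <- replicate(n, paste(sample(c("A", "C", "G", "T"), L,
                                      replace = TRUE), collapse = ""))
  } else {
    haps <- replicate(n_haps, paste(sample(c("A", "C", "G", "T"), L,
                                           replace = TRUE), collapse = ""))
    seqs <- sample(haps, n, replace = TRUE)
  }
  aligned_pool(seqs, pool_id = paste0("rand", seed), origin = origin)
}

# random stop-free coding pool (codon-sampled), for selection-module tests
rand_coding_pool <- function(n, n_codons, seed, n_haps = 5L,
                             mut_per_hap = 3L) {
  set.seed(seed)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  base <- sample(sense, n_codons, replace = TRUE)
  haps <- replicate(n_haps, {
    h <- base
    for (k in seq_len(mut_per_hap)) {
      i <- sample.int(n_codons, 1)
      h[i] <- sample(sense, 1)
    }
    paste(h, collapse = "")
  })
  aligned_pool(sample(haps, n, replace = TRUE), pool_id = "coding",
               origin = "nodule")
}

brute_hamming <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  sum(a != b)
}

brute_pi <- function(pool) {
  n <- pool$n; tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + brute_hamming(pool$sequences[i], pool$sequences[j])
  }
  tot / (n * (n - 1) / 2) / pool$length
}

# Nei-Gojobori synonymous site count of one codon by explicit enumeration
brute_codon_syn_sites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  sp <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) for (b in setdiff(c("A", "C", "G", "T"), sp[pos])) {
    alt <- sp; alt[pos] <- b
    if (gc[paste(alt, collapse = "")] == gc[codon]) s <- s + 1
  }
  s / 3
}

# pathway-averaged syn/nonsyn differences between two codons (stop-passing
# pathways excluded unless all are blocked)
brute_codon_pair <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  s1 <- strsplit(c1, "")[[1]]; s2 <- strsplit(c2, "")[[1]]
  dp <- which(s1 != s2)
  if (length(dp) == 0) return(c(0, 0))
  perms <- if (length(dp) == 1) list(dp) else {
    pp <- combinat_perms(dp)
    pp
  }
  walk <- function(ord, allow_stop) {
    cur <- s1; syn <- 0; non <- 0
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- s2[pos]
      aa_a <- gc[paste(cur, collapse = "")]
      aa_b <- gc[paste(nxt, collapse = "")]
      if (!allow_stop && (aa_a == "*" || aa_b == "*")) return(NULL)
      if (aa_a == aa_b && aa_a != "*") syn <- syn + 1 else non <- non + 1
      cur <- nxt
    }
    c(syn, non)
  }
  res <- Filter(Negate(is.null), lapply(perms, walk, allow_stop = FALSE))
  if (length(res) == 0) res <- lapply(perms, walk, allow_stop = TRUE)
  colMeans(do.call(rbind, res))
}

combinat_perms <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) for (r in combinat_perms(x[-i])) {
    out[[length(out) + 1]] <- c(x[i], r)
  }
  out
}

# pN/pS of a pool by exhaustive double loops over sequences and codons
brute_pn_ps <- function(pool, frame_offset = 0) {
  seqs <- pool$sequences
  n <- length(seqs)
  L <- pool$length
  ncod <- (L - frame_offset) %/% 3
  codons_of <- function(s) substring(s, frame_offset + 1 + 3 * (0:(ncod - 1)),
                                     frame_offset + 3 * (1:ncod))
  sites <- sapply(seqs, function(s) {
    syn <- sum(sapply(codons_of(s), brute_codon_syn_sites))
    c(syn, 3 * ncod - syn)
  })
  nd <- sd <- 0; np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ci <- codons_of(seqs[i]); cj <- codons_of(seqs[j])
    for (k in which(ci != cj)) {
      d <- brute_codon_pair(ci[k], cj[k])
      sd <- sd + d[1]; nd <- nd + d[2]
    }
    np <- np + 1
  }
  list(pN = (nd / np) / mean(sites[2, ]), pS = (sd / np) / mean(sites[1, ]))
}

# grid quadrature of the normalized L2 distance between two 2D mixtures
grid_delta_g <- function(g1, g2, half_width = 8, step = 0.05) {
  gr <- seq(-half_width, half_width, by = step)
  pts <- as.matrix(expand.grid(gr, gr))
  d1 <- gmm_density(g1, pts); d2 <- gmm_density(g2, pts)
  cell <- step^2
  i11 <- sum(d1 * d1) * cell
  i22 <- sum(d2 * d2) * cell
  i12 <- sum(d1 * d2) * cell
  2 * (1 - i12 / sqrt(i11 * i22))
}

# exact one-sided Mann-Whitney p by enumerating all rank assignments
brute_mw_p <- function(a, b, alternative) {
  na <- length(a); nb <- length(b)
  obs_u <- sum(outer(a, b, ">"))
  pool_v <- c(a, b)
  idx <- combn(na + nb, na)
  us <- apply(idx, 2, function(ii) {
    sum(outer(pool_v[ii], pool_v[-ii], ">"))
  })
  if (alternative == "a_less") mean(us <= obs_u) else mean(us >= obs_u)
}

# brute-force mutual k-nearest-neighbour edges
brute_mutual_knn <- function(A, B, k) {
  nl <- nrow(A); nr <- nrow(B)
  d <- as.matrix(dist(rbind(A, B)))[1:nl, nl + (1:nr), drop = FALSE]
  edges <- NULL
  for (i in 1:nl) for (j in 1:nr) {
    nn_i <- order(d[i, ], seq_len(nr))[seq_len(min(k, nr))]
    nn_j <- order(d[, j], seq_len(nl))[seq_len(min(k, nl))]
    if (j %in% nn_i && i %in% nn_j) edges <- rbind(edges, c(i, j))
  }
  edges
}

# random additive distance matrix from a random tree with positive lengths
random_additive <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, br = function(n) runif(n, 0.2, 2))
  tr <- ape::unroot(tr)
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# small synthetic config scaled down for test runtime
small_cfg <- function(seed, ...) {
  simulation_config(plant_pool_size = 80, rhizobial_pool_size = 400,
                    n_haps_per_clade = 8, seed = seed, ...)
}

# the topology-test world: biovar-filtered pools with clade-resolved
# clusters (m = n_clades), moderate divergence so cluster blobs overlap
topo_cfg <- function(seed, ...) {
  simulation_config(plant_pool_size = 100, rhizobial_pool_size = 400,
                    n_clades = 4, n_haps_per_clade = 6,
                    between_clade_divergence = 10,
                    within_clade_divergence = 2,
                    clade_frequencies = c(0.4, 0.3, 0.2, 0.1),
                    sfs_skew = 0.5, seed = seed, ...)
}
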