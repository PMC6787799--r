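test_that("FASTA reading enforces pool invariants", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGTACGTACGT", ">b", "ACGTACGTACGT",
               ">c", "ACGTACGTACGT"), tmp)
  p <- read_aligned_fasta(tmp, origin = "plant")
  expect_equal(p$n, 3L)
  expect_equal(p$length, 12L)

  writeLines(c(">a", "ACGTACGTACGT", ">b", "ACGTACGTACG"), tmp)
  expect_error(read_aligned_fasta(tmp), "length mismatch")

  writeLines(character(0), tmp)
  expect_error(read_aligned_fasta(tmp))
  expect_error(read_aligned_fasta("/nonexistent/nope.fa"), "not found")
})

test_that("write/read round trip preserves a 100-record pool", {
  pool <- rand_pool(100, 210, seed = 11)
  tmp <- withr::local_tempfile(fileext = ".fasta")
  write_pool_fasta(pool, tmp)
  back <- read_aligned_fasta(tmp, origin = "plant")
  expect_equal(back$n, 100L)
  expect_identical(back$sequences, pool$sequences)
})

test_that("filter_pool removes gaps and internal stops, conserving counts", {
  seqs <- c("ATGAAACCCGGG", "ATGAA-CCCGGG",  # gap
            "ATGTAACCCGGG",                  # TAA in frame at codon 2
            "ATGAAACCCGGG")
  pool <- aligned_pool(seqs, origin = "nodule")
  res <- filter_pool(pool, frame_offset = 0L)
  expect_equal(res$pool$n, 2L)
  expect_equal(sort(res$report$index), c(2L, 3L))
  expect_setequal(res$report$reason,
                  c("non-ACGT or gap character", "internal stop"))
  expect_equal(res$pool$n + nrow(res$report), pool$n)
  expect_false(any(grepl("[^ACGT]", res$pool$sequences)))

  clean <- aligned_pool(c("ATGAAA", "ATGAAC"), origin = "soil")
  res2 <- filter_pool(clean, 0L)
  expect_identical(res2$pool$sequences, clean$sequences)
  expect_equal(nrow(res2$report), 0L)

  # frame offset moves the codon grid: TAA at positions 4-6 is in frame 0
  # but not in frame 1
  shifty <- aligned_pool(c("ATGTAACCC", "ATGTAACCC", "CTGTAACCA"),
                         origin = "soil")
  expect_error(filter_pool(shifty, 0L), "every sequence")
  expect_equal(filter_pool(shifty, 1L)$pool$n, 3L)

  allbad <- aligned_pool(c("AT-AAA", "A-GAAA"), origin = "soil")
  expect_error(filter_pool(allbad, 0L), "every sequence")
})

test_that("collapse_haplotypes matches a dictionary count and orders by
           frequency then sequence", {
  pool <- aligned_pool(c(rep("AAAA", 4), "TTTT"), origin = "plant")
  hs <- collapse_haplotypes(pool)
  expect_equal(hs$frequencies, c(0.8, 0.2))
  expect_equal(hs$haplotypes, c("AAAA", "TTTT"))

  uniq <- rand_pool(20, 30, seed = 3)
  hsu <- collapse_haplotypes(uniq)
  expect_equal(hsu$n_unique, length(unique(uniq$sequences)))

  for (seed in 1:5) {
    p <- rand_pool(50, 12, seed = seed, n_haps = 6)
    hs <- collapse_haplotypes(p)
    oracle <- table(p$sequences)
    expect_equal(sum(hs$frequencies), 1, tolerance = 1e-12)
    expect_equal(sort(hs$counts), sort(as.integer(oracle)))
    expect_equal(hs$counts,
                 as.integer(oracle[hs$haplotypes]))
    # descending frequency, ties lexicographic
    expect_true(all(diff(hs$counts) <= 0))
    # membership reconstructs the pool
    expect_identical(hs$haplotypes[hs$membership], p$sequences)
  }
})

test_that("hamming_matrix equals the per-position loop oracle", {
  expect_equal(hamming_matrix(c("AAAA", "AAAT"))[1, 2], 1)
  expect_equal(hamming_matrix(c("ACGT", "ACGT"))[1, 2], 0)
  for (seed in 1:5) {
    set.seed(seed)
    haps <- replicate(10, paste(sample(c("A", "C", "G", "T"), 30,
                                       replace = TRUE), collapse = ""))
    d <- hamming_matrix(haps)
    expect_equal(diag(d), rep(0, 10), ignore_attr = TRUE)
    expect_true(isSymmetric(unname(d)))
    for (i in 1:9) for (j in (i + 1):10) {
      expect_equal(unname(d[i, j]), brute_hamming(haps[i], haps[j]))
    }
  }
})

test_that("greedy OTU picking honors the identity threshold", {
  pool <- aligned_pool(c("AAAAAAAAAA", "AAAAAAAAAA"), origin = "nodule")
  expect_equal(greedy_identity_otus(pool)$n_otus, 1L)

  # 90% identity pair at a 95% threshold -> 2 OTUs
  p2 <- aligned_pool(c("AAAAAAAAAA", "TAAAAAAAAT"), origin = "nodule")
  expect_equal(greedy_identity_otus(p2, 0.95)$n_otus, 2L)
  expect_equal(greedy_identity_otus(p2, 0.80)$n_otus, 1L)

  # threshold -> 0 collapses everything; -> 1 separates every haplotype
  p3 <- rand_pool(30, 40, seed = 7, n_haps = 8)
  expect_equal(greedy_identity_otus(p3, 1e-9)$n_otus, 1L)
  hs <- collapse_haplotypes(p3)
  expect_equal(greedy_identity_otus(p3, 0.999)$n_otus, hs$n_unique)

  # every sequence in exactly one OTU
  ot <- greedy_identity_otus(p3, 0.9)
  expect_length(ot$otu_membership, p3$n)
  expect_true(all(ot$otu_membership %in% seq_len(ot$n_otus)))
})

test_that("two-clade pools yield two OTU clades at 95%", {
  sys <- simulate_system(small_cfg(21, between_clade_divergence = 30,
                                   within_clade_divergence = 2))
  ot <- greedy_identity_otus(sys$nodule_pool, 0.95)
  # between-clade identity < 90%, within > 97% at 210 bp
  expect_equal(ot$n_otus, 2L)
})

test_that("neighbor joining recovers additive trees exactly", {
  # two taxa: single split edge
  D2 <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- neighbor_joining(D2)
  expect_equal(sort(t2$edge.length), c(2, 2))

  # hand-computed additive 4-taxon matrix from ((A:1,B:2):1,(C:3,D:1))
  D4 <- matrix(c(0, 3, 5, 3,
                 3, 0, 6, 4,
                 5, 6, 0, 4,
                 3, 4, 4, 0), 4, byrow = TRUE,
               dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  t4 <- neighbor_joining(D4)
  expect_equal(ape::cophenetic.phylo(t4)[rownames(D4), colnames(D4)], D4,
               tolerance = 1e-12)
  # topology: AB|CD split present
  expect_true(ape::is.monophyletic(ape::root(t4, "C"), c("A", "B")))

  # 3 equidistant taxa resolve with pendant edges d/2
  D3 <- matrix(2, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  diag(D3) <- 0
  t3 <- neighbor_joining(D3)
  expect_equal(unname(t3$edge.length), rep(1, 3))

  expect_error(neighbor_joining(matrix(0, 1, 1)), "at least 2")
})

test_that("NJ property: random additive matrices recovered within 1e-9", {
  for (seed in 1:10) {
    ad <- random_additive(sample(4:9, 1), seed = seed)
    tr <- neighbor_joining(ad$D)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(ad$D), colnames(ad$D)],
                 ad$D, tolerance = 1e-9)
  }
})

test_that("outgroup rooting splits the pendant edge at its midpoint", {
  ad <- random_additive(6, seed = 42)
  og <- rownames(ad$D)[1]
  tr <- neighbor_joining(ad$D, outgroup_label = og)
  expect_true(ape::is.rooted(tr))
  root_node <- ape::Ntip(tr) + 1L
  kid_edges <- which(tr$edge[, 1] == root_node)
  expect_length(kid_edges, 2L)
  expect_equal(tr$edge.length[kid_edges[1]], tr$edge.length[kid_edges[2]])
  # path lengths between leaves unchanged by rooting
  expect_equal(ape::cophenetic.phylo(tr)[rownames(ad$D), colnames(ad$D)],
               ad$D, tolerance = 1e-9)
})

test_that("biovar filter keeps majority clades and reports admixture", {
  # build two well-separated clades and pools with known admixture
  set.seed(5)
  a <- paste(rep("A", 40), collapse = "")
  b <- paste(rep("T", 40), collapse = "")
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(40, k)
    ch[pos] <- sapply(ch[pos], function(x) setdiff(c("A", "C", "G", "T"),
                                                   x)[1])
    paste(ch, collapse = "")
  }
  cladeA <- c(a, mut(a, 1), mut(a, 1))
  cladeB <- c(b, mut(b, 1), mut(b, 1))
  pool97 <- aligned_pool(c(sample(cladeA, 97, TRUE), sample(cladeB, 3, TRUE)),
                         pool_id = "p97", origin = "nodule")
  pool_pure <- aligned_pool(sample(cladeB, 50, TRUE), pool_id = "pure",
                            origin = "soil")
  joint <- aligned_pool(c(pool97$sequences, pool_pure$sequences),
                        pool_id = "joint", origin = "nodule")
  otus <- greedy_identity_otus(joint, 0.95)
  expect_equal(otus$n_otus, 2L)
  out_seq <- paste(rep(c("G", "C"), 20), collapse = "")
  labs <- c(paste0("otu_", seq_len(otus$n_otus)), "outgroup")
  D <- hamming_matrix(c(otus$otu_centroids, out_seq))
  dimnames(D) <- list(labs, labs)
  tree <- neighbor_joining(D, outgroup_label = "outgroup")
  res <- biovar_partition_filter(list(pool97, pool_pure), otus, tree)
  expect_equal(res$report$improper_fraction, c(0.03, 0))
  expect_equal(res$pools[[1]]$n, 97L)
  expect_equal(res$pools[[2]]$n, 50L)
  expect_false(res$report$clade[1] == res$report$clade[2])

  pool_tie <- aligned_pool(c(sample(cladeA, 25, TRUE),
                             sample(cladeB, 25, TRUE)),
                           pool_id = "tie", origin = "nodule")
  joint2 <- aligned_pool(c(pool_tie$sequences), pool_id = "j2",
                         origin = "nodule")
  otus2 <- greedy_identity_otus(joint2, 0.95)
  D2 <- hamming_matrix(c(otus2$otu_centroids, out_seq))
  labs2 <- c(paste0("otu_", seq_len(otus2$n_otus)), "outgroup")
  dimnames(D2) <- list(labs2, labs2)
  tree2 <- neighbor_joining(D2, outgroup_label = "outgroup")
  expect_error(biovar_partition_filter(list(pool_tie), otus2, tree2),
               "tie")
})
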