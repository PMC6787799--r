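# --- codon machinery (standard genetic code, from Biostrings) ---------------

codon_env <- new.env(parent = emptyenv())

genetic_code <- function() {
  if (is.null(codon_env$gc)) codon_env$gc <- Biostrings::GENETIC_CODE
  codon_env$gc
}

is_stop <- function(codon) unname(genetic_code()[codon]) == "*"

translate_codon <- function(codon) unname(genetic_code()[codon])

# fractional synonymous sites of one codon (Nei-Gojobori 1986): each position
# contributes (# synonymous single-base changes)/3; changes to stop codons
# count as nonsynonymous
codon_syn_sites <- function(codon) {
  if (is.null(codon_env$syn_sites)) {
    gc <- genetic_code()
    bases <- c("A", "C", "G", "T")
    tab <- setNames(numeric(length(gc)), names(gc))
    for (cod in names(gc)) {
      if (gc[cod] == "*") { tab[cod] <- NA_real_; next }
      s <- 0
      sp <- strsplit(cod, "")[[1]]
      for (pos in 1:3) for (b in setdiff(bases, sp[pos])) {
        alt <- sp; alt[pos] <- b
        altc <- paste(alt, collapse = "")
        if (gc[altc] == gc[cod]) s <- s + 1
      }
      tab[cod] <- s / 3
    }
    codon_env$syn_sites <- tab
  }
  unname(codon_env$syn_sites[codon])
}

# split a sequence into codons in the declared frame; trailing partial codon
# dropped
codon_split <- function(seq, frame_offset = 0L) {
  L <- nchar(seq)
  n_codons <- (L - frame_offset) %/% 3L
  if (n_codons < 1L) stop("no complete codon in frame ", frame_offset)
  substring(seq, frame_offset + 1L + 3L * (seq_len(n_codons) - 1L),
            frame_offset + 3L * seq_len(n_codons))
}

#' Nei-Gojobori synonymous/nonsynonymous site counts of one sequence
#'
#' Every codon position contributes a fractional synonymous weight equal to
#' the number of its three possible single-nucleotide changes that preserve
#' the amino acid, divided by 3; the remainder is nonsynonymous, so the two
#' counts always sum to 3 per codon.  Changes to stop codons count as
#' nonsynonymous.
#'
#' @param sequence a single ACGT string.
#' @param frame_offset 0, 1 or 2 leading bases before the first codon; a
#'   trailing partial codon is dropped.
#' @return named numeric vector `c(syn_sites, nonsyn_sites)`.
#' @export
ng_site_counts <- function(sequence, frame_offset = 0L) {
  cods <- codon_split(sequence, frame_offset)
  if (any(is_stop(cods))) stop("stop codon present; run filter_pool first")
  syn <- sum(codon_syn_sites(cods))
  c(syn_sites = syn, nonsyn_sites = 3 * length(cods) - syn)
}

# average syn/nonsyn differences between two codons over all mutational
# pathways (Nei-Gojobori equal-pathway weighting); pathways passing through a
# stop codon are excluded unless all do
codon_pair_diffs <- function(c1, c2) {
  key <- paste0(c1, c2)
  if (is.null(codon_env$pair_cache)) codon_env$pair_cache <-
      new.env(parent = emptyenv())
  hit <- codon_env$pair_cache[[key]]
  if (!is.null(hit)) return(hit)
  s1 <- strsplit(c1, "")[[1]]; s2 <- strsplit(c2, "")[[1]]
  diffpos <- which(s1 != s2)
  nd <- length(diffpos)
  if (nd == 0L) {
    res <- c(syn = 0, nonsyn = 0)
  } else {
    paths <- if (nd == 1L) list(diffpos) else
      lapply(seq_len(factorial(nd)), function(i) diffpos)
    if (nd > 1L) {
      perm <- permutations_of(diffpos)
      paths <- perm
    }
    acc <- list()
    for (p in paths) {
      cur <- s1; syn <- 0; nonsyn <- 0; blocked <- FALSE
      for (pos in p) {
        nxt <- cur; nxt[pos] <- s2[pos]
        cod_a <- paste(cur, collapse = ""); cod_b <- paste(nxt, collapse = "")
        if (is_stop(cod_b) || is_stop(cod_a)) { blocked <- TRUE }
        if (!blocked) {
          if (translate_codon(cod_a) == translate_codon(cod_b)) {
            syn <- syn + 1
          } else nonsyn <- nonsyn + 1
        }
        cur <- nxt
      }
      acc[[length(acc) + 1L]] <- list(ok = !blocked, syn = syn,
                                      nonsyn = nonsyn)
    }
    ok <- vapply(acc, `[[`, logical(1), "ok")
    use <- if (any(ok)) acc[ok] else {
      # all pathways blocked by stops: fall back to counting along all paths
      lapply(paths, function(p) {
        cur <- s1; syn <- 0; nonsyn <- 0
        for (pos in p) {
          nxt <- cur; nxt[pos] <- s2[pos]
          a <- translate_codon(paste(cur, collapse = ""))
          b <- translate_codon(paste(nxt, collapse = ""))
          if (!is.na(a) && !is.na(b) && a == b && a != "*") syn <- syn + 1
          else nonsyn <- nonsyn + 1
          cur <- nxt
        }
        list(ok = TRUE, syn = syn, nonsyn = nonsyn)
      })
    }
    res <- c(syn = mean(vapply(use, `[[`, numeric(1), "syn")),
             nonsyn = mean(vapply(use, `[[`, numeric(1), "nonsyn")))
  }
  codon_env$pair_cache[[key]] <- res
  res
}

permutations_of <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1L]] <-
        c(x[i], rest)
  }
  out
}

# per-haplotype-pair syn/nonsyn difference matrices (upper structure reused
# by pn_ps and the selection bootstrap)
ng_pair_matrices <- function(haps, frame_offset) {
  h <- length(haps)
  cods <- lapply(haps, codon_split, frame_offset = frame_offset)
  SD <- ND <- matrix(0, h, h)
  if (h > 1L) for (i in 1:(h - 1)) for (j in (i + 1):h) {
    diffc <- which(cods[[i]] != cods[[j]])
    sdiff <- ndiff <- 0
    for (ci in diffc) {
      d <- codon_pair_diffs(cods[[i]][ci], cods[[j]][ci])
      sdiff <- sdiff + d["syn"]; ndiff <- ndiff + d["nonsyn"]
    }
    SD[i, j] <- SD[j, i] <- sdiff
    ND[i, j] <- ND[j, i] <- ndiff
  }
  sites <- t(vapply(haps, ng_site_counts, numeric(2),
                    frame_offset = frame_offset))
  list(SD = SD, ND = ND, syn_sites = sites[, 1], nonsyn_sites = sites[, 2])
}

#' Within-pool pN, pS and pN/pS (Nei-Gojobori counting)
#'
#' Polymorphism-level analogs of dN/dS: for every unordered sequence pair,
#' each mismatching codon's differences are classified synonymous or
#' nonsynonymous (multi-difference codons averaged over all mutational
#' pathways); pN is the mean pairwise nonsynonymous difference count divided
#' by the mean nonsynonymous site count over sequences, pS analogously.  Raw
#' proportions, no multiple-hit correction.
#'
#' @param pool an [aligned_pool()] (gap-free, stop-free in frame).
#' @param frame_offset reading-frame offset, 0/1/2.
#' @return class `selection_stats`: `pN`, `pS`, `pN_over_pS` (`NA` when
#'   `pS == 0`), `syn_sites`, `nonsyn_sites` (pool means), `n`.
#' @export
pn_ps <- function(pool, frame_offset = 0L) {
  stopifnot(inherits(pool, "aligned_pool"))
  hs <- collapse_haplotypes(pool)
  m <- ng_pair_matrices(hs$haplotypes, frame_offset)
  cnt <- hs$counts; n <- hs$sample_size
  npairs2 <- n * (n - 1)  # ordered pairs; quadratic form counts both orders
  mean_nd <- as.numeric(crossprod(cnt, m$ND %*% cnt)) / npairs2
  mean_sd <- as.numeric(crossprod(cnt, m$SD %*% cnt)) / npairs2
  syn_sites <- sum(m$syn_sites * cnt) / n
  nonsyn_sites <- sum(m$nonsyn_sites * cnt) / n
  pN <- mean_nd / nonsyn_sites
  pS <- mean_sd / syn_sites
  structure(list(pN = pN, pS = pS,
                 pN_over_pS = if (pS > 0) pN / pS else NA_real_,
                 syn_sites = syn_sites, nonsyn_sites = nonsyn_sites, n = n),
            class = "selection_stats")
}

#' @export
print.selection_stats <- function(x, ...) {
  cat(sprintf("<selection_stats> pN=%.4f pS=%.4f pN/pS=%s (n=%d)\n",
              x$pN, x$pS,
              if (is.na(x$pN_over_pS)) "NA" else sprintf("%.4f",
                                                         x$pN_over_pS),
              x$n))
  invisible(x)
}

#' Tajima's D of a pool
#'
#' Standard 1989 normalization: `D = (pi_total - S/a1) / sqrt(e1 S + e2 S
#' (S-1))` where `pi_total` is the mean pairwise difference count (summed over
#' sites, not per site) and S the number of segregating sites.  Negative D
#' indicates an excess of rare alleles; positive D a deficit.
#'
#' @param pool an [aligned_pool()] with n >= 4.
#' @return the D statistic, or `NA` (with a warning) when S = 0.
#' @export
tajimas_d <- function(pool) {
  stopifnot(inherits(pool, "aligned_pool"))
  n <- pool$n
  if (n < 4L) stop("Tajima's D needs n >= 4")
  hs <- collapse_haplotypes(pool)
  mat <- seq_matrix(hs$haplotypes)
  S <- sum(apply(mat, 2, function(col) length(unique(col)) > 1L))
  if (S == 0L) {
    warning("no segregating sites; Tajima's D undefined")
    return(NA_real_)
  }
  d <- hamming_matrix(hs)
  pi_total <- pi_from_counts(hs$counts, d, hs$length) * hs$length
  tajima_d_from(pi_total, S, n)
}

# the 1989 constants, exposed for reuse by the selection bootstrap
tajima_d_from <- function(pi_total, S, n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Bootstrap distributions of selection statistics
#'
#' Resamples sequences with replacement (as [bootstrap_pi()] does) and
#' recomputes pN, pS and Tajima's D per replicate; these replicate sets are
#' the samples fed to [welch_contrast()].
#'
#' @param pool an [aligned_pool()].
#' @param frame_offset reading-frame offset.
#' @param subsample_size,trials,seed as in [bootstrap_pi()].
#' @return list of `bootstrap_distribution` objects: `pN`, `pS`, `D`.
#' @export
bootstrap_selection <- function(pool, frame_offset = 0L, subsample_size = 70L,
                                trials = 2000L, seed = 1L) {
  stopifnot(inherits(pool, "aligned_pool"))
  hs <- collapse_haplotypes(pool)
  m <- ng_pair_matrices(hs$haplotypes, frame_offset)
  hmat <- seq_matrix(hs$haplotypes)
  dmat <- hamming_matrix(hs)
  set.seed(seed)
  nsub <- as.integer(subsample_size)
  pN <- pS <- D <- numeric(trials)
  for (b in seq_len(trials)) {
    cnt <- as.vector(rmultinom(1L, nsub, hs$frequencies))
    denom <- nsub * (nsub - 1)
    mean_nd <- as.numeric(crossprod(cnt, m$ND %*% cnt)) / denom
    mean_sd <- as.numeric(crossprod(cnt, m$SD %*% cnt)) / denom
    pN[b] <- mean_nd / (sum(m$nonsyn_sites * cnt) / nsub)
    pS[b] <- mean_sd / (sum(m$syn_sites * cnt) / nsub)
    present <- cnt > 0L
    S <- if (sum(present) > 1L) {
      sub <- hmat[present, , drop = FALSE]
      sum(apply(sub, 2, function(col) length(unique(col)) > 1L))
    } else 0L
    D[b] <- if (S > 0L && nsub >= 4L) {
      pt <- pi_from_counts(cnt, dmat, hs$length) * hs$length
      tajima_d_from(pt, S, nsub)
    } else NA_real_
  }
  wrap <- function(v) structure(
    list(values = v, subsample_size = nsub, trials = as.integer(trials),
         seed = as.integer(seed), pool_id = pool$pool_id),
    class = "bootstrap_distribution")
  list(pN = wrap(pN), pS = wrap(pS), D = wrap(D))
}

#' One-sided Welch t contrast between two replicate sets
#'
#' Welch's unequal-variance t statistic with Satterthwaite degrees of
#' freedom, applied to bootstrap replicate values of a statistic in two pools.
#'
#' @param dist_a,dist_b `bootstrap_distribution` objects or numeric vectors.
#' @param alternative `"a_less"` (H1: mean a < mean b) or `"a_greater"`.
#' @param alpha significance level recorded in the result.
#' @return class `contrast_result`: `statistic`, `df`, `p_value`,
#'   `alternative`, `alpha`, `significant`, `degenerate` (both samples with
#'   zero variance).
#' @export
welch_contrast <- function(dist_a, dist_b,
                           alternative = c("a_less", "a_greater"),
                           alpha = 0.01) {
  alternative <- match.arg(alternative)
  a <- if (inherits(dist_a, "bootstrap_distribution")) dist_a$values else
    as.numeric(dist_a)
  b <- if (inherits(dist_b, "bootstrap_distribution")) dist_b$values else
    as.numeric(dist_b)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) stop("need >= 2 values per sample")
  va <- var(a); vb <- var(b); na <- length(a); nb <- length(b)
  degenerate <- (va == 0 && vb == 0)
  if (degenerate) {
    tstat <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
    df <- NA_real_
    p <- if (mean(a) == mean(b)) 0.5 else if (alternative == "a_less") {
      if (mean(a) < mean(b)) 0 else 1
    } else {
      if (mean(a) > mean(b)) 0 else 1
    }
  } else {
    se2 <- va / na + vb / nb
    tstat <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- if (alternative == "a_less") pt(tstat, df) else
      pt(tstat, df, lower.tail = FALSE)
  }
  structure(list(statistic = tstat, df = df, p_value = p,
                 alternative = alternative, alpha = alpha,
                 significant = is.finite(p) && p < alpha,
                 degenerate = degenerate),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("<contrast_result> %s: stat=%.4g p=%.4g (alpha=%.3g)%s\n",
              x$alternative, x$statistic, x$p_value, x$alpha,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Linkage between synonymous and nonsynonymous polymorphic sites
#'
#' Classifies biallelic polymorphic sites as synonymous or nonsynonymous
#' (by substituting the minor allele into the consensus codon), computes the
#' mean r-squared over all cross-class site pairs, and compares it with a
#' permutation null built by jointly permuting sequence labels at the
#' synonymous sites (within-class linkage preserved, cross-class broken).
#' A small cross-class p-value means pN and pS are not independent.
#'
#' @param pool an [aligned_pool()].
#' @param frame_offset reading-frame offset.
#' @param permutations number of label permutations.
#' @param seed integer seed.
#' @return list: `r2_matrix` (syn x nonsyn), `observed_mean_r2`, `p_value`
#'   (fraction of permuted means >= observed), `n_syn_sites`,
#'   `n_nonsyn_sites`; all-`NA` with a warning when either class has < 2
#'   usable sites.
#' @export
site_linkage_check <- function(pool, frame_offset = 0L, permutations = 200L,
                               seed = 1L) {
  stopifnot(inherits(pool, "aligned_pool"))
  mat <- seq_matrix(pool$sequences)
  n <- nrow(mat); L <- ncol(mat)
  n_codons <- (L - frame_offset) %/% 3L
  usable <- seq_len(3L * n_codons) + frame_offset
  site_class <- rep(NA_character_, L)
  biallelic <- logical(L)
  for (s in usable) {
    alleles <- sort(unique(mat[, s]))
    if (length(alleles) != 2L) next
    biallelic[s] <- TRUE
    codon_idx <- (s - frame_offset - 1L) %/% 3L
    pos_in_codon <- (s - frame_offset - 1L) %% 3L + 1L
    cod_cols <- frame_offset + 3L * codon_idx + 1:3
    consensus <- apply(mat[, cod_cols, drop = FALSE], 2, function(col)
      names(sort(table(col), decreasing = TRUE))[1])
    c1 <- consensus; c1[pos_in_codon] <- alleles[1]
    c2 <- consensus; c2[pos_in_codon] <- alleles[2]
    aa1 <- translate_codon(paste(c1, collapse = ""))
    aa2 <- translate_codon(paste(c2, collapse = ""))
    site_class[s] <- if (identical(aa1, aa2)) "syn" else "nonsyn"
  }
  syn_sites <- which(biallelic & site_class == "syn")
  non_sites <- which(biallelic & site_class == "nonsyn")
  if (length(syn_sites) < 2L || length(non_sites) < 2L) {
    warning("insufficient polymorphic sites of each class")
    return(list(r2_matrix = NULL, observed_mean_r2 = NA_real_,
                p_value = NA_real_, n_syn_sites = length(syn_sites),
                n_nonsyn_sites = length(non_sites)))
  }
  bin <- function(s) as.integer(mat[, s] == sort(unique(mat[, s]))[1])
  syn_m <- vapply(syn_sites, bin, integer(n))
  non_m <- vapply(non_sites, bin, integer(n))
  r2 <- function(x, y) {
    if (var(x) == 0 || var(y) == 0) return(NA_real_)
    cor(x, y)^2
  }
  cross_mean <- function(A, B) {
    vals <- outer(seq_len(ncol(A)), seq_len(ncol(B)),
                  Vectorize(function(i, j) r2(A[, i], B[, j])))
    mean(vals, na.rm = TRUE)
  }
  r2_mat <- outer(seq_along(syn_sites), seq_along(non_sites),
                  Vectorize(function(i, j) r2(syn_m[, i], non_m[, j])))
  dimnames(r2_mat) <- list(paste0("syn_", syn_sites),
                           paste0("nonsyn_", non_sites))
  obs <- mean(r2_mat, na.rm = TRUE)
  set.seed(seed)
  perm_means <- vapply(seq_len(permutations), function(p) {
    cross_mean(syn_m[sample.int(n), , drop = FALSE], non_m)
  }, numeric(1))
  list(r2_matrix = r2_mat, observed_mean_r2 = obs,
       p_value = mean(perm_means >= obs),
       n_syn_sites = length(syn_sites), n_nonsyn_sites = length(non_sites))
}
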