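# --- low-level sequence machinery ------------------------------------------

BASES <- c("A", "C", "G", "T")

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[sample.int(length(g), 1L)] <- 1
  g / sum(g)
}

# random stop-free coding sequence of n_codons codons
random_coding_seq <- function(length_bp) {
  stopifnot(length_bp %% 3 == 0)
  gc <- genetic_code()
  sense <- names(gc)[gc != "*"]
  paste(sample(sense, length_bp / 3, replace = TRUE), collapse = "")
}

# apply n_mut single-base substitutions; each is nonsynonymous with
# probability nonsyn_fraction (falling back to the other class when the
# desired class is unavailable at the sampled position); stop codons are
# never created
mutate_coding_seq <- function(seq, n_mut, nonsyn_fraction) {
  if (n_mut == 0L) return(seq)
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  gc <- genetic_code()
  for (mu in seq_len(n_mut)) {
    want_nonsyn <- runif(1) < nonsyn_fraction
    placed <- FALSE
    for (try in 1:300) {
      pos <- sample.int(L, 1L)
      ci <- (pos - 1L) %/% 3L
      cod_idx <- 3L * ci + 1:3
      cod <- chars[cod_idx]
      aa0 <- gc[paste(cod, collapse = "")]
      alts <- setdiff(BASES, chars[pos])
      cand_syn <- character(0); cand_non <- character(0)
      for (b in alts) {
        nc <- cod; nc[(pos - 1L) %% 3L + 1L] <- b
        aa1 <- gc[paste(nc, collapse = "")]
        if (aa1 == "*") next
        if (aa1 == aa0) cand_syn <- c(cand_syn, b) else
          cand_non <- c(cand_non, b)
      }
      pickfrom <- if (want_nonsyn) {
        if (length(cand_non)) cand_non else cand_syn
      } else {
        if (length(cand_syn)) cand_syn else character(0)
      }
      # for a desired synonymous change, retry elsewhere rather than forcing
      # a nonsynonymous one; most positions offer no synonymous option
      if (length(pickfrom)) {
        chars[pos] <- sample(pickfrom, 1L)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place a mutation of the requested class; ",
                      "infeasible nonsyn_fraction for this sequence")
  }
  paste(chars, collapse = "")
}

# --- configuration ----------------------------------------------------------

#' Build a validated simulation configuration
#'
#' Defaults emulate the sampled world these analyses target: per-species
#' pools of ~100 plant receptor clones and ~3500 rhizobial amplicon reads of
#' 210 bp that collapse to a few dozen haplotypes in two deep clades
#' (biovar analog), with rare-allele excess (negative Tajima's D).
#'
#' @param n_species number of host species this config stands for (used by
#'   ladder constructions; one call to [simulate_system()] emits one
#'   plant/nodule/soil triplet).
#' @param seq_length_bp alignment width, a codon multiple.
#' @param plant_pool_size,rhizobial_pool_size sequences per pool.
#' @param n_clades deep clades per side.
#' @param clade_frequencies plant-side clade frequencies (recycled to
#'   `n_clades`, normalized); default proportional `n_clades:1`.
#' @param n_haps_per_clade haplotypes generated within each clade.
#' @param within_clade_divergence expected substitutions separating a
#'   haplotype from its clade founder.
#' @param between_clade_divergence expected substitutions separating a clade
#'   founder from the ancestor.
#' @param nonsyn_fraction probability that a placed mutation is
#'   nonsynonymous.
#' @param sfs_skew >= 0; within-clade haplotype weights are flat Dirichlet
#'   plus `sfs_skew` extra mass on the clade founder.  Under the star
#'   genealogy every segregating variant is carried by one derived
#'   haplotype, so tilting mass onto the founder skews the site-frequency
#'   spectrum toward rare alleles (lower Tajima's D).  0 is the
#'   neutral-like setting.
#' @param topology_match `"matched"`: the nodule pool's clade and haplotype
#'   frequency profile mirrors the plant pool's; `"mismatched"`: it is
#'   permuted and redrawn.
#' @param nodule_private_clade if TRUE the soil pool excludes the rarest
#'   plant-side clade, which stays present in the nodule pool.
#' @param soil_mode `"perturbed"` (default): soil clade frequencies are a
#'   Dirichlet perturbation of the plant's and its within-clade weights are
#'   redrawn; `"mirror_nodule"`: the soil pool is drawn from exactly the
#'   nodule pool's distribution (null setting).
#' @param soil_concentration Dirichlet concentration multiplier for the soil
#'   perturbation (smaller = stronger perturbation).
#' @param seed integer seed; generation is fully deterministic per seed.
#' @return class `simulation_config`.
#' @export
simulation_config <- function(n_species = 1L, seq_length_bp = 210L,
                              plant_pool_size = 100L,
                              rhizobial_pool_size = 3500L,
                              n_clades = 2L, clade_frequencies = NULL,
                              n_haps_per_clade = 12L,
                              within_clade_divergence = 3,
                              between_clade_divergence = 25,
                              nonsyn_fraction = 0.3, sfs_skew = 1,
                              topology_match = c("matched", "mismatched"),
                              nodule_private_clade = TRUE,
                              soil_mode = c("perturbed", "mirror_nodule"),
                              soil_concentration = 1, seed = 1L) {
  topology_match <- match.arg(topology_match)
  soil_mode <- match.arg(soil_mode)
  if (seq_length_bp %% 3 != 0) stop("seq_length_bp must be a codon multiple")
  if (within_clade_divergence < 0 || between_clade_divergence < 0) {
    stop("divergences must be >= 0")
  }
  if (sfs_skew < 0) stop("sfs_skew must be >= 0")
  if (nonsyn_fraction < 0 || nonsyn_fraction > 1) {
    stop("nonsyn_fraction must be in [0,1]")
  }
  if (is.null(clade_frequencies)) {
    clade_frequencies <- rev(seq_len(n_clades))
  }
  clade_frequencies <- rep_len(clade_frequencies, n_clades)
  clade_frequencies <- clade_frequencies / sum(clade_frequencies)
  if (any(clade_frequencies <= 0)) stop("clade frequencies must be positive")
  structure(list(
    n_species = as.integer(n_species),
    seq_length_bp = as.integer(seq_length_bp),
    plant_pool_size = as.integer(plant_pool_size),
    rhizobial_pool_size = as.integer(rhizobial_pool_size),
    n_clades = as.integer(n_clades),
    clade_frequencies = clade_frequencies,
    n_haps_per_clade = as.integer(n_haps_per_clade),
    within_clade_divergence = within_clade_divergence,
    between_clade_divergence = between_clade_divergence,
    nonsyn_fraction = nonsyn_fraction, sfs_skew = sfs_skew,
    topology_match = topology_match,
    nodule_private_clade = isTRUE(nodule_private_clade),
    soil_mode = soil_mode, soil_concentration = soil_concentration,
    seed = as.integer(seed)), class = "simulation_config")
}

# --- system generation ------------------------------------------------------

#' Simulate a plant/nodule/soil pool triplet
#'
#' Generation: (1) draw stop-free ancestral coding sequences for the plant
#' and rhizobial genes; (2) derive clade founders at the between-clade
#' divergence; (3) within each clade, generate haplotypes by a
#' star-with-jitter genealogy, with frequencies from a Dirichlet whose
#' concentration decreases with `sfs_skew`; (4) sample the plant pool over
#' plant clades, the nodule pool over rhizobial clades (mirroring the plant's
#' frequency profile when `topology_match = "matched"`), and the soil pool
#' from perturbed frequencies, optionally excluding one nodule-present clade;
#' (5) mutations respect the codon table with the configured nonsynonymous
#' fraction; (6) an outgroup sequence at twice the between-clade divergence
#' is emitted.
#'
#' @param cfg a [simulation_config()].
#' @return class `synthetic_system`: `plant_pool`, `nodule_pool`,
#'   `soil_pool`, `outgroup` (named character), `truth` (clade haplotypes,
#'   per-origin clade/haplotype distributions, matched flag).
#' @export
simulate_system <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  L <- cfg$seq_length_bp
  nc <- cfg$n_clades
  nh <- cfg$n_haps_per_clade
  anc_plant <- random_coding_seq(L)
  anc_rhiz <- random_coding_seq(L)
  draw_clade <- function(anc, n_founder_mut, n_hap_mut) {
    founder <- mutate_coding_seq(anc, n_founder_mut, cfg$nonsyn_fraction)
    # star genealogy: haplotype 1 is the founder itself, the rest are
    # derived by private mutations
    haps <- c(founder, vapply(seq_len(nh - 1L), function(i) {
      mutate_coding_seq(founder, n_hap_mut[i + 1L], cfg$nonsyn_fraction)
    }, character(1)))
    list(founder = founder, haps = haps)
  }
  # under a star genealogy the haplotype distance matrix is governed by the
  # per-haplotype mutation counts, so "matched" topology shares one set of
  # counts between the plant and rhizobial sides (mutation positions stay
  # independent), making the two cluster geometries congruent
  founder_mut <- rpois(nc, cfg$between_clade_divergence)
  hap_mut <- lapply(seq_len(nc), function(c)
    rpois(nh, cfg$within_clade_divergence))
  plant_clades <- lapply(seq_len(nc), function(c)
    draw_clade(anc_plant, founder_mut[c], hap_mut[[c]]))
  if (cfg$topology_match == "matched") {
    rhiz_founder_mut <- founder_mut
    rhiz_hap_mut <- hap_mut
  } else {
    rhiz_founder_mut <- rpois(nc, cfg$between_clade_divergence)
    rhiz_hap_mut <- lapply(seq_len(nc), function(c)
      rpois(nh, cfg$within_clade_divergence))
  }
  rhiz_clades <- lapply(seq_len(nc), function(c)
    draw_clade(anc_rhiz, rhiz_founder_mut[c], rhiz_hap_mut[[c]]))
  # within-clade weights: flat Dirichlet, then extra mass sfs_skew on the
  # founder haplotype; under the star genealogy the site-frequency spectrum
  # equals the weights of the derived carriers, so tilting mass onto the
  # founder makes every segregating variant rarer (lower Tajima's D)
  draw_weights <- function() {
    w <- rdirichlet1(rep(1, nh))
    w[1] <- w[1] + cfg$sfs_skew
    w / sum(w)
  }
  w_template <- lapply(seq_len(nc), function(i) draw_weights())
  # plant distribution
  f_clade_plant <- cfg$clade_frequencies
  # nodule distribution
  if (cfg$topology_match == "matched") {
    f_clade_nod <- f_clade_plant
    w_nod <- w_template
  } else {
    f_clade_nod <- rdirichlet1(rev(f_clade_plant) * nc *
                                 cfg$soil_concentration)
    w_nod <- lapply(seq_len(nc), function(i) draw_weights())
  }
  # soil distribution
  if (cfg$soil_mode == "mirror_nodule") {
    f_clade_soil <- f_clade_nod
    w_soil <- w_nod
  } else {
    # soil does not mirror the plant: its clade-level profile is permuted
    # before the Dirichlet perturbation; within-clade rank-abundance stays
    # shared with the nodule pool (one common haplotype reservoir)
    f_clade_soil <- rdirichlet1(rev(f_clade_plant) * nc *
                                  cfg$soil_concentration)
    w_soil <- w_nod
    if (cfg$nodule_private_clade && nc > 1L) {
      # the host-amplified clade missing from soil: prominent on the
      # plant/nodule side (second-most-frequent), undetected in soil
      drop <- order(-f_clade_plant)[2L]
      f_clade_soil[drop] <- 0
      f_clade_soil <- f_clade_soil / sum(f_clade_soil)
    }
  }
  sample_pool <- function(clades, f_clade, w_within, size, pool_id, species,
                          origin) {
    probs <- unlist(lapply(seq_len(nc), function(c)
      f_clade[c] * w_within[[c]]))
    haps <- unlist(lapply(clades, `[[`, "haps"))
    cnt <- as.vector(rmultinom(1L, size, probs))
    aligned_pool(rep(haps, cnt), pool_id = pool_id, species = species,
                 origin = origin)
  }
  plant_pool <- sample_pool(plant_clades, f_clade_plant, w_template,
                            cfg$plant_pool_size, "plant", "synth_sp",
                            "plant")
  nodule_pool <- sample_pool(rhiz_clades, f_clade_nod, w_nod,
                             cfg$rhizobial_pool_size, "nodule", "synth_sp",
                             "nodule")
  soil_pool <- sample_pool(rhiz_clades, f_clade_soil, w_soil,
                           cfg$rhizobial_pool_size, "soil", "synth_sp",
                           "soil")
  outgroup <- mutate_coding_seq(anc_rhiz,
                                max(1L, rpois(1L,
                                              2 * cfg$between_clade_divergence)),
                                cfg$nonsyn_fraction)
  truth <- list(
    plant_clade_haps = lapply(plant_clades, `[[`, "haps"),
    rhiz_clade_haps = lapply(rhiz_clades, `[[`, "haps"),
    f_clade_plant = f_clade_plant, f_clade_nodule = f_clade_nod,
    f_clade_soil = f_clade_soil,
    w_plant = w_template, w_nodule = w_nod, w_soil = w_soil,
    matched = cfg$topology_match == "matched",
    private_clade = if (cfg$nodule_private_clade && nc > 1L &&
                        cfg$soil_mode == "perturbed")
      order(-f_clade_plant)[2L] else NA_integer_,
    outgroup = outgroup)
  structure(list(plant_pool = plant_pool, nodule_pool = nodule_pool,
                 soil_pool = soil_pool,
                 outgroup = c(outgroup_1 = outgroup),
                 truth = truth, config = cfg),
            class = "synthetic_system")
}

#' @export
print.synthetic_system <- function(x, ...) {
  cat(sprintf(
    "<synthetic_system> plant n=%d, nodule n=%d, soil n=%d (%d bp, %s)\n",
    x$plant_pool$n, x$nodule_pool$n, x$soil_pool$n,
    x$plant_pool$length, x$config$topology_match))
  invisible(x)
}

#' Write a synthetic system as FASTA fixtures plus manifest and truth
#'
#' @param sys a `synthetic_system`.
#' @param dir output directory (created if needed).
#' @return invisibly, a list with `manifest` (data.frame) and `paths`.
#' @export
write_fixture_set <- function(sys, dir) {
  stopifnot(inherits(sys, "synthetic_system"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pools <- list(plant = sys$plant_pool, nodule = sys$nodule_pool,
                soil = sys$soil_pool)
  rows <- lapply(names(pools), function(nm) {
    p <- file.path(dir, paste0(nm, ".fasta"))
    write_pool_fasta(pools[[nm]], p)
    data.frame(pool_id = pools[[nm]]$pool_id,
               species = pools[[nm]]$species, origin = pools[[nm]]$origin,
               path = p, frame_offset = 0L, stringsAsFactors = FALSE)
  })
  out_path <- file.path(dir, "outgroup.fasta")
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(sys$outgroup), filepath = out_path)
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.tsv")
  write.table(manifest, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sys$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest,
                 paths = c(vapply(rows, function(r) r$path, character(1)),
                           out_path, mpath)))
}

#' Generate a ladder of systems with increasing diversity
#'
#' Takes configs ordered by increasing `within_clade_divergence` (one per
#' host species) and simulates each; plant and nodule pools inside one
#' system share their generating divergence, so realized pi rankings agree
#' between the two sides.
#'
#' @param cfgs list of at least two [simulation_config()]s.
#' @return list of `synthetic_system`s.
#' @export
diversity_ladder <- function(cfgs) {
  if (length(cfgs) < 2L) stop("need at least 2 configs")
  lapply(cfgs, simulate_system)
}

#' Neutral coalescent pool (calibration mode)
#'
#' Standard Kingman coalescent with infinite-sites mutation at rate theta/2
#' per lineage per unit coalescent time, emitted as an ACGT alignment
#' (ancestral base A, derived base C at each segregating site).  Used to
#' calibrate Tajima's D; it is not a substitute for the codon-structured
#' generator.
#'
#' @param n sample size.
#' @param theta population mutation rate (per locus).
#' @param length_bp alignment width; must exceed the realized number of
#'   segregating sites (enlarged automatically if not).
#' @param seed integer seed.
#' @return an [aligned_pool()].
#' @export
simulate_coalescent_pool <- function(n, theta, length_bp = 999L, seed = 1L) {
  set.seed(seed)
  active <- lapply(seq_len(n), identity)  # tip sets of active lineages
  muts <- list()                          # each: vector of carrying tips
  k <- n
  while (k > 1L) {
    t <- rexp(1L, rate = k * (k - 1) / 2)
    for (li in seq_len(k)) {
      nm <- rpois(1L, theta / 2 * t)
      if (nm > 0L) for (z in seq_len(nm)) muts[[length(muts) + 1L]] <-
          active[[li]]
    }
    pair <- sample.int(k, 2L)
    active[[pair[1]]] <- c(active[[pair[1]]], active[[pair[2]]])
    active[[pair[2]]] <- NULL
    k <- k - 1L
  }
  S <- length(muts)
  L <- max(length_bp, 2L * S + 3L)
  mat <- matrix("A", n, L)
  if (S > 0L) {
    sites <- sample.int(L, S)
    for (s in seq_len(S)) mat[muts[[s]], sites[s]] <- "C"
  }
  aligned_pool(apply(mat, 1, paste, collapse = ""),
               pool_id = "coalescent", species = "sim", origin = "soil")
}
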