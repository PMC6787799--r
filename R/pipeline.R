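# stage seed fan-out: a documented deterministic hash of the stage name mixed
# with the global seed, kept below 2^31
stage_seed <- function(global_seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  s <- ((global_seed %% 2147483647) * 48271) %% 2147483647
  as.integer((s + h) %% 2147483647)
}

#' Validate a pool manifest
#'
#' The manifest is a TSV with columns `pool_id`, `species`, `origin`
#' (plant/nodule/soil), `path` (FASTA, relative paths resolved against the
#' manifest's directory) and optional `frame_offset` (default 0).
#'
#' @param path manifest file path.
#' @return the validated manifest data.frame (with absolute paths); errors
#'   list every offending row and field.
#' @export
validate_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("pool_id", "species", "origin", "path")
  missing_cols <- setdiff(need, names(man))
  if (length(missing_cols)) stop("manifest lacks columns: ",
                                 paste(missing_cols, collapse = ", "))
  if (!"frame_offset" %in% names(man)) man$frame_offset <- 0L
  errs <- character(0)
  for (i in seq_len(nrow(man))) {
    if (!man$origin[i] %in% c("plant", "nodule", "soil")) {
      errs <- c(errs, sprintf(
        "row %d (%s): origin '%s' not one of plant, nodule, soil",
        i, man$pool_id[i], man$origin[i]))
    }
    p <- man$path[i]
    if (!file.exists(p)) {
      p2 <- file.path(dirname(path), p)
      if (file.exists(p2)) man$path[i] <- p2
      else errs <- c(errs, sprintf("row %d (%s): FASTA path not found: %s",
                                   i, man$pool_id[i], p))
    }
    if (!man$frame_offset[i] %in% 0:2) {
      errs <- c(errs, sprintf("row %d (%s): frame_offset must be 0, 1 or 2",
                              i, man$pool_id[i]))
    }
  }
  if (length(errs)) stop("invalid manifest:\n", paste(errs, collapse = "\n"))
  man
}

#' Run the full analysis pipeline
#'
#' Stages, in order: ingest and filter the pools; OTU-partition the combined
#' rhizobial sequences, build the outgroup-rooted NJ tree over OTU
#' representatives and drop improper-biovar-clade sequences (skipped when no
#' outgroup is supplied); per-pool pi with bootstrap and the cross-species
#' plant-nodule Spearman concordance; per-rhizobial-pool selection table
#' (pN, pS, pN/pS, Tajima's D) with one-sided Welch contrasts of nodule over
#' soil; per-species bootstrap Delta-G with one-sided Mann-Whitney; mutual
#' k-NN tanglegrams.  Every stage's seed derives deterministically from the
#' global seed, so reruns with one seed are identical.
#'
#' @param manifest validated manifest data.frame (or a path, which is run
#'   through [validate_manifest()]).
#' @param out_dir output directory for the JSON report and sidecar files.
#' @param seed global integer seed.
#' @param outgroup_path optional FASTA with one outgroup sequence for
#'   rooting/biovar filtering.
#' @param params list of stage parameters; defaults:
#'   `subsample_size = 70`, `trials = 2000`, `otu_threshold = 0.95`,
#'   `m = 10`, `K = 3`, `n_boot = 100`, `n_starts = 20`, `k_tangle = 5`,
#'   `alpha = 0.01`, `rho_threshold = 0.8`.
#' @return the report list (also written to `<out_dir>/report.json`).
#' @export
run_full <- function(manifest, out_dir, seed = 1L, outgroup_path = NULL,
                     params = list()) {
  if (is.character(manifest)) manifest <- validate_manifest(manifest)
  defaults <- list(subsample_size = 70L, trials = 2000L,
                   otu_threshold = 0.95, m = 10L, K = 3L, n_boot = 100L,
                   n_starts = 20L, k_tangle = 5L, alpha = 0.01,
                   rho_threshold = 0.8)
  params <- modifyList(defaults, params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  # --- ingest + filter ---
  pools <- list()
  for (i in seq_len(nrow(manifest))) {
    p <- read_aligned_fasta(manifest$path[i], species = manifest$species[i],
                            origin = manifest$origin[i],
                            pool_id = manifest$pool_id[i])
    pools[[manifest$pool_id[i]]] <-
      filter_pool(p, manifest$frame_offset[i])$pool
  }
  species <- unique(manifest$species)
  rhiz_idx <- which(manifest$origin %in% c("nodule", "soil"))
  # --- biovar filter (needs an outgroup and >= 2 OTU clades) ---
  biovar_report <- NULL
  if (!is.null(outgroup_path) && length(rhiz_idx) > 0L) {
    rhiz_ids <- manifest$pool_id[rhiz_idx]
    joint <- aligned_pool(
      unlist(lapply(pools[rhiz_ids], `[[`, "sequences")),
      pool_id = "rhizobia_all", species = "all", origin = "nodule")
    otus <- greedy_identity_otus(joint, threshold = params$otu_threshold)
    og <- Biostrings::readBStringSet(outgroup_path)
    og_seq <- toupper(as.character(og[[1]]))
    cents <- otus$otu_centroids
    labels <- c(paste0("otu_", seq_along(cents)), "outgroup")
    D <- hamming_from_matrix(seq_matrix(c(cents, og_seq)))
    dimnames(D) <- list(labels, labels)
    tree <- neighbor_joining(D, outgroup_label = "outgroup")
    if (otus$n_otus >= 2L) {
      bf <- biovar_partition_filter(pools[rhiz_ids], otus, tree)
      pools[rhiz_ids] <- bf$pools
      biovar_report <- bf$report
      ape::write.tree(tree, file.path(out_dir, "otu_tree.nwk"))
    }
  }
  # --- diversity ---
  sd1 <- stage_seed(seed, "diversity")
  pi_tab <- do.call(rbind, lapply(pools, function(p)
    data.frame(pool_id = p$pool_id, species = p$species, origin = p$origin,
               n = p$n, pi = pi_diversity(p)$pi)))
  plant_boot <- nodule_boot <- soil_boot <- list()
  for (s in species) {
    pick <- function(orig) {
      id <- manifest$pool_id[manifest$species == s &
                               manifest$origin == orig]
      if (length(id) == 1L) pools[[id]] else NULL
    }
    for (orig in c("plant", "nodule", "soil")) {
      p <- pick(orig)
      if (is.null(p)) next
      bd <- bootstrap_pi(p, subsample_size = params$subsample_size,
                         trials = params$trials,
                         seed = stage_seed(sd1, paste0(orig, "_", s)))
      if (orig == "plant") plant_boot[[s]] <- bd
      if (orig == "nodule") nodule_boot[[s]] <- bd
      if (orig == "soil") soil_boot[[s]] <- bd
    }
  }
  concordance <- NULL
  if (length(plant_boot) >= 2L &&
      setequal(names(plant_boot), names(nodule_boot))) {
    concordance <- paired_spearman_concordance(
      plant_boot, nodule_boot, threshold = params$rho_threshold,
      seed = stage_seed(sd1, "pairing"))
  }
  # --- selection ---
  sd2 <- stage_seed(seed, "selection")
  sel_rows <- list()
  sel_contrasts <- list()
  for (s in species) {
    for (orig in c("nodule", "soil")) {
      id <- manifest$pool_id[manifest$species == s & manifest$origin == orig]
      if (length(id) != 1L) next
      p <- pools[[id]]
      fo <- manifest$frame_offset[manifest$pool_id == id]
      st <- pn_ps(p, frame_offset = fo)
      sel_rows[[id]] <- data.frame(
        pool_id = id, species = s, origin = orig, pN = st$pN, pS = st$pS,
        pN_over_pS = st$pN_over_pS, tajimas_D = tajimas_d(p))
    }
    id_n <- manifest$pool_id[manifest$species == s &
                               manifest$origin == "nodule"]
    id_s <- manifest$pool_id[manifest$species == s &
                               manifest$origin == "soil"]
    if (length(id_n) == 1L && length(id_s) == 1L) {
      fo <- manifest$frame_offset[manifest$pool_id == id_n]
      bs_n <- bootstrap_selection(pools[[id_n]], frame_offset = fo,
                                  subsample_size = params$subsample_size,
                                  trials = params$trials,
                                  seed = stage_seed(sd2, paste0("n_", s)))
      bs_s <- bootstrap_selection(pools[[id_s]], frame_offset = fo,
                                  subsample_size = params$subsample_size,
                                  trials = params$trials,
                                  seed = stage_seed(sd2, paste0("s_", s)))
      sel_contrasts[[s]] <- list(
        pN = welch_contrast(bs_n$pN, bs_s$pN, alternative = "a_greater",
                            alpha = params$alpha),
        D = welch_contrast(bs_n$D, bs_s$D, alternative = "a_greater",
                           alpha = params$alpha))
    }
  }
  # --- topology + tanglegram ---
  sd3 <- stage_seed(seed, "topology")
  topo <- list(); tangle_files <- list()
  for (s in species) {
    ids <- vapply(c("plant", "nodule", "soil"), function(orig) {
      id <- manifest$pool_id[manifest$species == s & manifest$origin == orig]
      if (length(id) == 1L) id else NA_character_
    }, character(1))
    if (anyNA(ids)) next
    tr <- bootstrap_delta_g(pools[[ids[1]]], pools[[ids[2]]],
                            pools[[ids[3]]], m = params$m, K = params$K,
                            n_boot = params$n_boot,
                            seed = stage_seed(sd3, s),
                            n_starts = params$n_starts,
                            alpha = params$alpha)
    topo[[s]] <- tr
    emb <- tr$embedding
    if (emb$m_plant >= 2L && emb$m_rhizobia >= 2L) {
      g_nod_aligned <- align_mixture(emb$g_nodule, tr$transform_nodule)
      edges <- mutual_knn_edges(emb$g_plant, g_nod_aligned,
                                k = params$k_tangle)
      tg <- tanglegram(cluster_nj_tree(emb$plant_clusters),
                       cluster_nj_tree(emb$rhizobia_clusters), edges,
                       k = params$k_tangle)
      tangle_files[[s]] <- as.character(
        export_tanglegram(tg, file.path(out_dir, paste0("tangle_", s))))
    }
  }
  report <- list(
    parameters = params, seed = seed,
    pools = lapply(pools, function(p) list(pool_id = p$pool_id,
                                           species = p$species,
                                           origin = p$origin, n = p$n,
                                           length = p$length)),
    biovar = if (!is.null(biovar_report)) biovar_report else NULL,
    pi = pi_tab,
    concordance = if (!is.null(concordance)) list(
      spearman_rho = concordance$spearman_rho,
      n_pairs = concordance$n_pairs,
      is_monotonic = concordance$is_monotonic,
      threshold = concordance$threshold) else NULL,
    selection = if (length(sel_rows)) do.call(rbind, sel_rows) else NULL,
    selection_contrasts = lapply(sel_contrasts, function(ct) list(
      pN_p = ct$pN$p_value, pN_significant = ct$pN$significant,
      D_p = ct$D$p_value, D_significant = ct$D$significant)),
    topology = lapply(topo, function(tr) list(
      full_delta_g_nodule = tr$full_delta_g_nodule,
      full_delta_g_soil = tr$full_delta_g_soil,
      median_delta_g_nodule = median(tr$delta_g_nodule),
      median_delta_g_soil = median(tr$delta_g_soil),
      U = tr$U_statistic, p_value = tr$p_value,
      significant = tr$significant)),
    tanglegrams = tangle_files)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
  invisible(report)
}
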