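#' Greedy identity-threshold OTU picking
#'
#' Deterministic abundance-ordered greedy centroid clustering (the core
#' heuristic of UCLUST-style OTU pickers): haplotypes are processed in
#' descending abundance (ties by lexicographic order), each is assigned to
#' the existing centroid of highest identity if that identity reaches the
#' threshold, otherwise it opens a new OTU.  Identity between two aligned
#' sequences is `1 - hamming/length`.
#'
#' @param pool an [aligned_pool()].
#' @param threshold identity threshold in (0, 1); default 0.95, the
#'   conventional cutoff for these amplicons.
#' @return an object of class `otu_partition`: `otu_centroids` (sequences),
#'   `otu_membership` (per input sequence), `hap_membership` (per haplotype),
#'   `identity_threshold`, `haplotypes` (the underlying `haplotype_set`),
#'   and `clade_assignment` (filled by [biovar_partition_filter()], `NA`
#'   until then).
#' @export
greedy_identity_otus <- function(pool, threshold = 0.95) {
  stopifnot(inherits(pool, "aligned_pool"))
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0,1)")
  hs <- collapse_haplotypes(pool)
  L <- hs$length
  hmat <- seq_matrix(hs$haplotypes)
  centroids <- integer(0)       # haplotype indices serving as centroids
  hap_member <- integer(hs$n_unique)
  for (i in seq_len(hs$n_unique)) {
    if (length(centroids) == 0L) {
      centroids <- i
      hap_member[i] <- 1L
      next
    }
    cm <- hmat[centroids, , drop = FALSE]
    ham <- rowSums(cm != matrix(hmat[i, ], nrow(cm), L, byrow = TRUE))
    ident <- 1 - ham / L
    best <- which.max(ident)     # ties: earliest centroid
    if (ident[best] >= threshold) {
      hap_member[i] <- best
    } else {
      centroids <- c(centroids, i)
      hap_member[i] <- length(centroids)
    }
  }
  structure(
    list(otu_centroids = hs$haplotypes[centroids],
         otu_membership = hap_member[hs$membership],
         hap_membership = hap_member,
         identity_threshold = threshold,
         haplotypes = hs,
         n_otus = length(centroids),
         clade_assignment = rep(NA_character_, length(centroids))),
    class = "otu_partition"
  )
}

#' @export
print.otu_partition <- function(x, ...) {
  cat(sprintf("<otu_partition> %d OTUs at %.0f%% identity (%d haplotypes)\n",
              x$n_otus, 100 * x$identity_threshold, x$haplotypes$n_unique))
  invisible(x)
}

#' Neighbor-joining tree, optionally rooted on an outgroup
#'
#' Standard Saitou-Nei NJ (via [ape::nj()]); negative branch lengths are
#' clamped to zero (the common MEGA convention; the number of clamped edges is
#' recorded in `attr(tree, "n_clamped")`).  If an outgroup label is given the
#' root is placed at the midpoint of the outgroup's pendant edge.
#'
#' @param D square symmetric distance matrix with row/column names, >= 2 taxa.
#' @param outgroup_label leaf label to root on, or `NULL` for an unrooted
#'   tree.
#' @return an [ape::phylo] tree.
#' @export
neighbor_joining <- function(D, outgroup_label = NULL) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2L) stop("neighbor joining needs at least 2 taxa")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("t", 1:n)
  labs <- rownames(D)
  if (!is.null(outgroup_label) && !outgroup_label %in% labs) {
    stop("outgroup '", outgroup_label, "' not among taxon labels")
  }
  if (n == 2L) {
    tr <- ape::read.tree(
      text = sprintf("(%s:%g,%s:%g);", labs[1], D[1, 2] / 2,
                     labs[2], D[1, 2] / 2))
    attr(tr, "n_clamped") <- 0L
    return(tr)
  }
  tr <- ape::nj(as.dist(D))
  ncl <- sum(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  if (!is.null(outgroup_label)) {
    tr <- ape::root(tr, outgroup = outgroup_label, resolve.root = TRUE)
    # split the outgroup's pendant edge evenly across the new root
    tip <- which(tr$tip.label == outgroup_label)
    root_node <- ape::Ntip(tr) + 1L
    e_tip <- which(tr$edge[, 1] == root_node & tr$edge[, 2] == tip)
    e_sis <- which(tr$edge[, 1] == root_node & tr$edge[, 2] != tip)
    if (length(e_tip) == 1L && length(e_sis) == 1L) {
      d <- tr$edge.length[e_tip] + tr$edge.length[e_sis]
      tr$edge.length[e_tip] <- d / 2
      tr$edge.length[e_sis] <- d / 2
    }
  }
  attr(tr, "n_clamped") <- ncl
  tr
}

#' Partition pools into two biovar clades and drop improper-clade sequences
#'
#' The rooted OTU-representative tree is split into the two clades defined by
#' the root's children (the outgroup, if present as a leaf, is ignored).  Each
#' pool is assigned the clade holding the majority of its sequences; its
#' minority ("improper") sequences are removed, mirroring the admixture of
#' foreign-biovar rhizobia adhering to nodule surfaces.
#'
#' @param pools list of [aligned_pool()]s whose sequences are all present in
#'   `otus` (they must have been clustered together).
#' @param otus an `otu_partition` built on the combined sequences.
#' @param tree a rooted [ape::phylo] over OTU centroid labels `otu_<i>`
#'   (plus optionally an outgroup leaf).
#' @return a list with `pools` (filtered pools, same order), `report`
#'   (data.frame: pool_id, clade, improper_fraction, n_before, n_after) and
#'   `clade_assignment` (per-OTU clade, `"clade_A"`/`"clade_B"`).
#' @export
biovar_partition_filter <- function(pools, otus, tree) {
  stopifnot(inherits(otus, "otu_partition"), inherits(tree, "phylo"))
  otu_labels <- paste0("otu_", seq_len(otus$n_otus))
  tips_under <- function(node) {
    if (node <= ape::Ntip(tree)) return(tree$tip.label[node])
    ape::extract.clade(tree, node)$tip.label
  }
  # descend from the root past the outgroup (and any OTU-free branches) to
  # the first node whose children both hold OTU leaves: its two sides are
  # the biovar clades
  node <- ape::Ntip(tree) + 1L
  repeat {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    if (length(kids) < 2L) stop("tree root must have two children")
    has_otu <- vapply(kids, function(k)
      length(intersect(tips_under(k), otu_labels)) > 0L, logical(1))
    if (sum(has_otu) >= 2L) break
    if (sum(has_otu) == 0L) stop("tree holds no OTU-labeled leaves")
    node <- kids[which(has_otu)]
    if (node <= ape::Ntip(tree)) stop("only one OTU-labeled leaf in tree")
  }
  kids <- kids[has_otu]
  if (length(kids) > 2L) stop("root bipartition is not binary over OTUs")
  clade_of <- setNames(rep(NA_character_, otus$n_otus), otu_labels)
  side <- c("clade_A", "clade_B")
  for (s in 1:2) {
    clade_of[intersect(tips_under(kids[s]), otu_labels)] <- side[s]
  }
  if (any(is.na(clade_of))) {
    stop("OTUs not covered by the root bipartition: ",
         paste(names(clade_of)[is.na(clade_of)], collapse = ", "))
  }
  # map each pool's sequences -> haplotype -> otu -> clade
  out_pools <- vector("list", length(pools))
  rep_rows <- vector("list", length(pools))
  for (pi in seq_along(pools)) {
    p <- pools[[pi]]
    hap_idx <- match(p$sequences, otus$haplotypes$haplotypes)
    if (anyNA(hap_idx)) stop("pool ", p$pool_id,
                             " has sequences absent from the OTU partition")
    clades <- clade_of[otus$hap_membership[hap_idx]]
    tab <- table(factor(clades, levels = side))
    if (tab[1] == tab[2]) stop("majority tie in pool ", p$pool_id)
    major <- side[which.max(tab)]
    keep <- clades == major
    improper <- 1 - mean(keep)
    out_pools[[pi]] <- aligned_pool(p$sequences[keep], pool_id = p$pool_id,
                                    species = p$species, origin = p$origin)
    rep_rows[[pi]] <- data.frame(pool_id = p$pool_id, clade = major,
                                 improper_fraction = improper,
                                 n_before = p$n, n_after = sum(keep),
                                 stringsAsFactors = FALSE)
  }
  list(pools = out_pools, report = do.call(rbind, rep_rows),
       clade_assignment = clade_of)
}
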