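#' Neighbor-joining tree over a cluster set
#'
#' NJ on the (possibly normalized) between-cluster distance matrix; leaves
#' are labeled `c<i>` by cluster index.  The tree is unrooted; layout code
#' may draw it from an arbitrary deterministic root.
#'
#' @param cs a `cluster_set` with `m >= 2`.
#' @return an [ape::phylo] tree.
#' @export
cluster_nj_tree <- function(cs) {
  stopifnot(inherits(cs, "cluster_set"))
  if (cs$m < 2L) stop("need at least 2 clusters for a tree")
  D <- cs$reduced_D
  rownames(D) <- colnames(D) <- paste0("c", seq_len(cs$m))
  neighbor_joining(D)
}

#' Mutual k-nearest-neighbor edges between two aligned embeddings
#'
#' Connects left component i to right component j iff j is among the k
#' right-side points nearest to i AND i is among the k left-side points
#' nearest to j (Euclidean distance in the shared frame; apply
#' [align_mixture()] first).  Neighborhoods are taken within the opposite
#' set only.  Distance ties are broken by index order.
#'
#' @param g_left,g_right `embedded_mixture`s in the same K-dim frame.
#' @param k neighborhood size (default 5); capped with a warning when either
#'   side has k or fewer points.
#' @return data.frame with columns `left`, `right`, `distance`.
#' @export
mutual_knn_edges <- function(g_left, g_right, k = 5L) {
  stopifnot(inherits(g_left, "embedded_mixture"),
            inherits(g_right, "embedded_mixture"))
  if (g_left$K != g_right$K) stop("mixtures live in different dimensions")
  if (k < 1L) stop("k must be >= 1")
  nl <- g_left$m; nr <- g_right$m
  if (k >= min(nl, nr) && min(nl, nr) > 0L && k > min(nl, nr)) {
    warning("k capped at the smaller side's size")
  }
  kl <- min(k, nr)  # neighbors of a left point live on the right side
  kr <- min(k, nl)
  A <- g_left$coords; B <- g_right$coords
  d2 <- outer(rowSums(A^2), rep(1, nr)) + outer(rep(1, nl), rowSums(B^2)) -
    2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  # rank with index tie-break: order() is stable on the index argument
  nn_right_of_left <- lapply(seq_len(nl), function(i)
    order(d2[i, ], seq_len(nr))[seq_len(kl)])
  nn_left_of_right <- lapply(seq_len(nr), function(j)
    order(d2[, j], seq_len(nl))[seq_len(kr)])
  rows <- list()
  for (i in seq_len(nl)) for (j in nn_right_of_left[[i]]) {
    if (i %in% nn_left_of_right[[j]]) {
      rows[[length(rows) + 1L]] <- data.frame(left = i, right = j,
                                              distance = sqrt(d2[i, j]))
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(left = integer(0), right = integer(0),
                      distance = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Assemble a tanglegram
#'
#' @param tree_left,tree_right [ape::phylo] trees (plant and rhizobial
#'   cluster trees).
#' @param edges edge data.frame from [mutual_knn_edges()].
#' @param k the neighborhood size used.
#' @return class `tanglegram`.
#' @export
tanglegram <- function(tree_left, tree_right, edges, k = 5L) {
  stopifnot(inherits(tree_left, "phylo"), inherits(tree_right, "phylo"))
  lab_l <- if (nrow(edges)) paste0("c", edges$left) else character(0)
  lab_r <- if (nrow(edges)) paste0("c", edges$right) else character(0)
  if (!all(lab_l %in% tree_left$tip.label) ||
      !all(lab_r %in% tree_right$tip.label)) {
    stop("edge endpoints must exist as tree leaves")
  }
  structure(list(tree_left = tree_left, tree_right = tree_right,
                 edges = edges, k = as.integer(k)),
            class = "tanglegram")
}

#' @export
print.tanglegram <- function(x, ...) {
  cat(sprintf("<tanglegram> %d vs %d leaves, %d mutual-%dNN edges\n",
              ape::Ntip(x$tree_left), ape::Ntip(x$tree_right),
              nrow(x$edges), x$k))
  invisible(x)
}

#' Export a tanglegram to files
#'
#' Writes `<prefix>_left.nwk`, `<prefix>_right.nwk` and `<prefix>_edges.tsv`
#' (columns left_cluster, right_cluster, distance).
#'
#' @param t a `tanglegram`.
#' @param prefix output path prefix.
#' @return invisibly, the three file paths.
#' @export
export_tanglegram <- function(t, prefix) {
  stopifnot(inherits(t, "tanglegram"))
  p_left <- paste0(prefix, "_left.nwk")
  p_right <- paste0(prefix, "_right.nwk")
  p_edges <- paste0(prefix, "_edges.tsv")
  ape::write.tree(t$tree_left, file = p_left)
  ape::write.tree(t$tree_right, file = p_right)
  ed <- t$edges
  names(ed) <- c("left_cluster", "right_cluster", "distance")
  write.table(ed, p_edges, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p_left, p_right, p_edges))
}

#' Plot a tanglegram (two facing dendrograms with connecting lines)
#'
#' Cosmetic helper; the tested surface is the exported Newick + TSV data.
#'
#' @param x a `tanglegram`.
#' @param ... ignored.
#' @export
plot.tanglegram <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(par(op))
  ape::plot.phylo(x$tree_left, main = "left", direction = "rightwards")
  ape::plot.phylo(x$tree_right, main = "right", direction = "leftwards")
  invisible(x)
}
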