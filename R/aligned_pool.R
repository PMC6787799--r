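#' Construct an aligned sequence pool
#'
#' A pool is a set of aligned, equal-length nucleotide sequences aggregated
#' from many individuals of one origin (plant clones, nodule reads, or soil
#' reads) for one host species.  It is the unit of every downstream analysis.
#'
#' @param sequences character vector of uppercase nucleotide strings, all of
#'   the same length.  Gap (`-`) or ambiguity characters are tolerated here so
#'   that raw input can be routed through [filter_pool()]; analyses require a
#'   clean ACGT alignment.
#' @param pool_id identifier for the pool.
#' @param species host species label.
#' @param origin one of `"plant"`, `"nodule"`, `"soil"`.
#' @return an object of class `aligned_pool` with fields `sequences`,
#'   `pool_id`, `species`, `origin`, `length` (alignment width) and `n`.
#' @export
aligned_pool <- function(sequences, pool_id = "pool", species = "sp",
                         origin = c("plant", "nodule", "soil")) {
  origin <- match.arg(origin)
  sequences <- toupper(as.character(sequences))
  if (length(sequences) < 2L) {
    stop("a pool needs at least 2 sequences, got ", length(sequences))
  }
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1L])
    stop("length mismatch: sequences ", paste(head(bad, 10L), collapse = ", "),
         " differ from the first record's length (", lens[1L], " bp)")
  }
  structure(
    list(sequences = sequences, pool_id = pool_id, species = species,
         origin = origin, length = lens[1L], n = length(sequences)),
    class = "aligned_pool"
  )
}

#' @export
print.aligned_pool <- function(x, ...) {
  cat(sprintf("<aligned_pool> %s  species=%s origin=%s  n=%d  length=%d bp\n",
              x$pool_id, x$species, x$origin, x$n, x$length))
  invisible(x)
}

#' Read an aligned multi-FASTA into a pool
#'
#' @param path path to a FASTA file (plain or gzip).
#' @param species,origin labels attached to the pool.
#' @param pool_id pool identifier; defaults to the file name.
#' @return an [aligned_pool()].  Records of unequal length are a hard error
#'   (the offending IDs are listed); non-ACGT characters are kept and left to
#'   [filter_pool()].
#' @export
read_aligned_fasta <- function(path, species = "sp",
                               origin = c("plant", "nodule", "soil"),
                               pool_id = NULL) {
  origin <- match.arg(origin)
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path)
  lens <- Biostrings::width(ss)
  if (length(unique(lens)) != 1L) {
    bad <- names(ss)[lens != lens[1L]]
    stop("length mismatch in ", path, ": ",
         paste(head(bad, 10L), collapse = ", "))
  }
  if (is.null(pool_id)) pool_id <- sub("\\.(fa|fasta)(\\.gz)?$", "",
                                       basename(path))
  aligned_pool(as.character(ss), pool_id = pool_id, species = species,
               origin = origin)
}

#' Write a pool to FASTA
#'
#' @param pool an [aligned_pool()].
#' @param path output file path.
#' @param ids optional record names; default `<pool_id>_<i>`.
#' @export
write_pool_fasta <- function(pool, path, ids = NULL) {
  stopifnot(inherits(pool, "aligned_pool"))
  if (is.null(ids)) ids <- sprintf("%s_%d", pool$pool_id, seq_len(pool$n))
  ss <- Biostrings::BStringSet(setNames(pool$sequences, ids))
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

# pool -> n x L character matrix (rows = sequences)
seq_matrix <- function(sequences) {
  do.call(rbind, strsplit(sequences, "", fixed = TRUE))
}

#' Remove gapped and frameshifted sequences from a pool
#'
#' Sequences containing gap or non-ACGT characters, or an internal stop codon
#' in the declared reading frame, are removed; the survivors form a clean
#' gap-free pool.  A trailing partial codon (alignment width not a multiple of
#' 3 after the frame offset) is ignored in the stop-codon scan.
#'
#' @param pool an [aligned_pool()].
#' @param frame_offset 0, 1 or 2: number of leading bases before the first
#'   complete codon.
#' @return a list with `pool` (the filtered pool) and `report`, a data.frame
#'   of removed record indices and reasons.  Removing everything is an error.
#' @export
filter_pool <- function(pool, frame_offset = 0L) {
  stopifnot(inherits(pool, "aligned_pool"))
  if (!frame_offset %in% 0:2) stop("frame_offset must be 0, 1 or 2")
  seqs <- pool$sequences
  reason <- character(length(seqs))
  bad_char <- grepl("[^ACGT]", seqs)
  reason[bad_char] <- "non-ACGT or gap character"
  n_codons <- (pool$length - frame_offset) %/% 3L
  if (n_codons > 0L) {
    stops <- c("TAA", "TAG", "TGA")
    for (i in which(!bad_char)) {
      cods <- substring(seqs[i],
                        frame_offset + 1L + 3L * (seq_len(n_codons) - 1L),
                        frame_offset + 3L * seq_len(n_codons))
      if (any(cods %in% stops)) reason[i] <- "internal stop"
    }
  }
  keep <- reason == ""
  report <- data.frame(index = which(!keep), reason = reason[!keep],
                       stringsAsFactors = FALSE)
  if (sum(keep) == 0L) stop("filter_pool removed every sequence in ",
                            pool$pool_id)
  if (sum(keep) < 2L) stop("filter_pool left fewer than 2 sequences in ",
                           pool$pool_id)
  out <- aligned_pool(seqs[keep], pool_id = pool$pool_id,
                      species = pool$species, origin = pool$origin)
  list(pool = out, report = report)
}

#' Collapse a pool to its unique haplotypes
#'
#' @param pool an [aligned_pool()].
#' @return an object of class `haplotype_set`: `haplotypes` (unique sequence
#'   strings, ordered by descending frequency, ties by lexicographic order),
#'   `counts`, `frequencies`, `n_unique`, `sample_size`, and `membership`
#'   (haplotype index of each input sequence).
#' @export
collapse_haplotypes <- function(pool) {
  stopifnot(inherits(pool, "aligned_pool"))
  tab <- table(pool$sequences)
  ord <- order(-as.integer(tab), names(tab), method = "radix")
  haps <- names(tab)[ord]
  cnt <- as.integer(tab)[ord]
  structure(
    list(haplotypes = haps, counts = cnt, frequencies = cnt / pool$n,
         n_unique = length(haps), sample_size = pool$n,
         membership = match(pool$sequences, haps), length = pool$length),
    class = "haplotype_set"
  )
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("<haplotype_set> %d haplotypes from %d sequences (%d bp)\n",
              x$n_unique, x$sample_size, x$length))
  invisible(x)
}

# pairwise hamming distances between rows of a character matrix, via
# per-letter indicator cross-products (fast for the ACGT alphabet)
hamming_from_matrix <- function(mat) {
  n <- nrow(mat); L <- ncol(mat)
  letters_seen <- unique(as.vector(mat))
  matches <- matrix(0, n, n)
  for (a in letters_seen) {
    ind <- (mat == a) * 1
    matches <- matches + tcrossprod(ind)
  }
  d <- L - matches
  diag(d) <- 0
  d
}

#' Pairwise hamming distance matrix of a haplotype set
#'
#' Entry (i, j) is the raw count of mismatching alignment positions between
#' haplotypes i and j ("numbers of differences"; no substitution model).
#'
#' @param hs a `haplotype_set` (or a character vector of equal-length
#'   sequences).
#' @return a symmetric matrix with zero diagonal, labelled by haplotype index.
#' @export
hamming_matrix <- function(hs) {
  seqs <- if (inherits(hs, "haplotype_set")) hs$haplotypes else
    as.character(hs)
  stopifnot(length(unique(nchar(seqs))) == 1L)
  d <- hamming_from_matrix(seq_matrix(seqs))
  dimnames(d) <- list(seq_along(seqs), seq_along(seqs))
  d
}
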