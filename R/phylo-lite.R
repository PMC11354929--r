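# Light phylogenetic summaries: concatenated shared-gene supermatrix,
# p-distance, neighbor-joining (via ape), and average-linkage clustering
# of RSCU vectors. These are sanity-check tools, not substitutes for a
# full Bayesian analysis.

#' Concatenate shared genes into a per-taxon supermatrix
#'
#' Keeps only genes present in every taxon, concatenated in alphabetical
#' gene order; a partition map records where each gene starts and ends.
#'
#' @param panel Named list gene -> named character vector of aligned
#'   sequences per taxon (equal length within a gene).
#' @return A \code{supermatrix}: list with \code{seqs} (named character
#'   vector, one row per taxon), \code{partitions} (data.frame gene /
#'   start / end), \code{taxa}.
#' @export
concat_shared_pcgs <- function(panel) {
  stopifnot(length(panel) >= 1L)
  taxa_sets <- lapply(panel, names)
  taxa <- sort(Reduce(union, taxa_sets))
  shared <- sort(names(panel)[vapply(panel, function(g)
    all(taxa %in% names(g)), TRUE)])
  shared <- shared[vapply(shared, function(g)
    length(unique(nchar(panel[[g]][taxa]))) == 1L, TRUE)]
  if (!length(shared) || length(taxa) < 2L)
    stop("no genes shared by all taxa")
  pos <- 0L
  partitions <- data.frame(gene = shared, start = NA_integer_,
                           end = NA_integer_)
  rows <- setNames(rep("", length(taxa)), taxa)
  for (i in seq_along(shared)) {
    g <- panel[[shared[i]]][taxa]
    partitions$start[i] <- pos + 1L
    partitions$end[i] <- pos + nchar(g[[1]])
    pos <- partitions$end[i]
    rows <- paste0(rows, toupper(g))
  }
  names(rows) <- taxa
  structure(list(seqs = rows, partitions = partitions, taxa = taxa),
            class = "supermatrix")
}

#' Pairwise p-distance matrix
#'
#' Mismatch fraction over columns where both rows are ungapped.
#'
#' @param sm A \code{supermatrix} or named character vector of
#'   equal-length sequences.
#' @return A \code{dist_matrix}: list with \code{taxa} and \code{d}
#'   (symmetric matrix, zero diagonal).
#' @export
p_distance <- function(sm) {
  seqs <- if (inherits(sm, "supermatrix")) sm$seqs else sm
  stopifnot(length(unique(nchar(seqs))) == 1L, length(seqs) >= 2L)
  taxa <- names(seqs)
  mat <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  n <- length(taxa)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- mat[i, ] != "-" & mat[j, ] != "-"
    if (!any(ok)) stop("no comparable columns between ", taxa[i], " and ",
                       taxa[j])
    d[i, j] <- d[j, i] <- mean(mat[i, ok] != mat[j, ok])
  }
  structure(list(taxa = taxa, d = d), class = "dist_matrix")
}

#' Neighbor-joining summary tree
#'
#' Saitou-Nei neighbor joining on a distance matrix (via \pkg{ape});
#' fewer than 4 taxa yield the degenerate star/cherry topology with a
#' warning. Branch lengths below zero are clamped to zero for the
#' summary use-case.
#'
#' @param dm A \code{dist_matrix} (or a symmetric matrix with dimnames).
#' @return An \pkg{ape} \code{phylo} tree.
#' @export
nj_tree <- function(dm) {
  d <- if (inherits(dm, "dist_matrix")) dm$d else as.matrix(dm)
  if (nrow(d) < 4L)
    warning("fewer than 4 taxa: neighbor joining is degenerate")
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Hierarchical clustering of RSCU vectors
#'
#' Average-linkage clustering on Euclidean distance over codons with a
#' defined RSCU in both taxa of each pair (missing families are skipped
#' pairwise).
#'
#' @param rscu_vectors Named list taxon -> named RSCU vector
#'   (\code{NA} for unobserved families).
#' @return An \pkg{ape} \code{phylo} dendrogram (from \code{hclust}).
#' @export
rscu_cluster <- function(rscu_vectors) {
  stopifnot(length(rscu_vectors) >= 3L)
  taxa <- sort(names(rscu_vectors))
  codons <- Reduce(intersect, lapply(rscu_vectors, names))
  if (!length(codons)) stop("no shared codons across taxa")
  n <- length(taxa)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- rscu_vectors[[taxa[i]]][codons]
    b <- rscu_vectors[[taxa[j]]][codons]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) stop("no shared non-missing codons between ", taxa[i],
                       " and ", taxa[j])
    d[i, j] <- d[j, i] <- sqrt(sum((a[ok] - b[ok])^2))
  }
  ape::as.phylo(stats::hclust(stats::as.dist(d), method = "average"))
}

#' Write a tree to Newick
#'
#' @param tree An \pkg{ape} \code{phylo}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
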