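# Genome-architecture statistics: gene inventories, coding fraction,
# pairwise gene overlaps and intergenic-spacer totals, plus circular gene
# order and cross-genome gene-content comparison.

#' Architecture summary of an annotated genome
#'
#' Computes the per-genome statistics of a comparative table: length, GC,
#' gene counts per class, the fraction of the genome covered by
#' protein-coding genes, every pairwise overlap between distinct named
#' genes, and the total intergenic-spacer length. Overlap is counted once
#' per unordered gene pair; spacers are the bases covered by no feature,
#' so \code{covered + spacer_total == length} always tiles the genome.
#' Intron features count toward gene span (hence reduce spacers) but are
#' excluded from coding coverage.
#'
#' @param genome An \code{\link{annotated_genome}}.
#' @return A \code{genome_summary}: list with \code{genome_id},
#'   \code{length}, \code{gc}, \code{counts}, \code{pcg_fraction},
#'   \code{overlap_pairs} (data.frame geneA/geneB/bp),
#'   \code{overlap_total}, \code{spacer_total}, \code{covered}.
#' @export
summarize_genome <- function(genome) {
  stopifnot(inherits(genome, "annotated_genome"))
  L <- genome$length
  counts <- table(factor(vapply(genome$features, `[[`, "", "gene_class"),
                         levels = GENE_CLASSES))
  occupied <- logical(L)
  pcg_cov <- logical(L)
  pos_by_feature <- lapply(genome$features, feature_positions)
  for (i in seq_along(genome$features)) {
    occupied[pos_by_feature[[i]]] <- TRUE
    if (genome$features[[i]]$gene_class %in% c("PCG", "ORF"))
      pcg_cov[pos_by_feature[[i]]] <- TRUE
  }
  # overlaps between distinct named genes, each unordered pair once
  names_ <- vapply(genome$features, `[[`, "", "name")
  pairs <- list()
  n <- length(genome$features)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (names_[i] == names_[j]) next
      ov <- length(intersect(pos_by_feature[[i]], pos_by_feature[[j]]))
      if (ov > 0L)
        pairs[[length(pairs) + 1L]] <-
          data.frame(geneA = names_[i], geneB = names_[j], bp = ov)
    }
  }
  overlap_pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(geneA = character(), geneB = character(), bp = integer())
  structure(list(genome_id = genome$id, length = L,
                 gc = gc_content(genome$sequence),
                 counts = c(counts),
                 pcg_fraction = sum(pcg_cov) / L,
                 overlap_pairs = overlap_pairs,
                 overlap_total = sum(overlap_pairs$bp),
                 spacer_total = L - sum(occupied),
                 covered = sum(occupied)),
            class = "genome_summary")
}

#' @export
print.genome_summary <- function(x, ...) {
  cat(sprintf("<genome_summary> %s: %d bp, GC %.2f%%\n",
              x$genome_id, x$length, 100 * x$gc))
  cat(sprintf("  coding (PCG+ORF) %.2f%% | overlap %d bp in %d pairs | spacer %d bp\n",
              100 * x$pcg_fraction, x$overlap_total, nrow(x$overlap_pairs),
              x$spacer_total))
  cat("  ", paste(sprintf("%s: %d", names(x$counts), x$counts),
                  collapse = "  "), "\n")
  invisible(x)
}

#' Circular gene order anchored at a gene
#'
#' Deterministic rotation of the genomic gene order so that \code{anchor}
#' comes first; the cyclic order itself is invariant to where the genome's
#' origin sits. Genes are ordered by the start of their first normalized
#' interval (ties broken by name).
#'
#' @param genome An \code{\link{annotated_genome}}.
#' @param anchor Gene name to rotate to the front.
#' @return A \code{gene_order}: data.frame with columns \code{gene},
#'   \code{strand}, attribute \code{genome_id}.
#' @export
gene_order <- function(genome, anchor) {
  stopifnot(inherits(genome, "annotated_genome"))
  if (!length(genome$features)) stop("genome has no features")
  starts <- vapply(genome$features, function(f) f$intervals[1L, 1L], 0L)
  nm <- vapply(genome$features, `[[`, "", "name")
  st <- vapply(genome$features, `[[`, "", "strand")
  o <- order(starts, nm)
  nm <- nm[o]; st <- st[o]
  k <- match(anchor, nm)
  if (is.na(k))
    stop("anchor gene '", anchor, "' not found; available: ",
         paste(nm, collapse = ", "))
  idx <- c(seq.int(k, length(nm)), if (k > 1L) seq_len(k - 1L))
  structure(data.frame(gene = nm[idx], strand = st[idx]),
            genome_id = genome$id, class = c("gene_order", "data.frame"))
}

#' Compare gene content across genomes
#'
#' Set operations over gene names, grouped by the \code{order} rank of each
#' genome's taxon label (a Venn-style report): the core shared by all
#' groups, per-group private genes, per-group missing genes (present in
#' every other group, absent here), and pairwise differences.
#'
#' @param genomes List of \code{\link{annotated_genome}} objects (>= 2),
#'   each carrying a taxon label.
#' @param gene_class Feature class compared (default \code{"PCG"}).
#' @return A \code{gene_content_report}: list with \code{core},
#'   \code{groups} (gene-name sets), \code{private}, \code{missing},
#'   \code{pairwise} (named list \code{"A-B"} of genes in A not in B).
#' @export
compare_gene_content <- function(genomes, gene_class = "PCG") {
  stopifnot(length(genomes) >= 2L)
  grp <- vapply(genomes, function(g) {
    if (is.null(g$taxon) || !nzchar(g$taxon$order))
      stop("genome ", g$id, " has no taxon order for grouping")
    g$taxon$order
  }, "")
  sets <- lapply(genomes, function(g)
    unique(vapply(Filter(function(f) f$gene_class == gene_class, g$features),
                  `[[`, "", "name")))
  if (any(!lengths(sets))) stop("a genome has an empty gene set")
  groups <- lapply(split(sets, grp), function(s) sort(unique(unlist(s))))
  core <- Reduce(intersect, groups)
  private <- lapply(seq_along(groups), function(i)
    setdiff(groups[[i]], unlist(groups[-i])))
  missing <- lapply(seq_along(groups), function(i) {
    others <- groups[-i]
    if (!length(others)) return(character())
    setdiff(Reduce(intersect, others), groups[[i]])
  })
  names(private) <- names(missing) <- names(groups)
  pairwise <- list()
  gn <- names(groups)
  for (a in gn) for (b in gn) if (a != b)
    pairwise[[paste(a, b, sep = "-")]] <- setdiff(groups[[a]], groups[[b]])
  structure(list(core = core, groups = groups, private = private,
                 missing = missing, pairwise = pairwise),
            class = "gene_content_report")
}

#' @export
print.gene_content_report <- function(x, ...) {
  cat(sprintf("<gene_content_report> %d groups, core of %d genes\n",
              length(x$groups), length(x$core)))
  for (g in names(x$groups))
    cat(sprintf("  %s: %d genes, %d private, %d missing\n", g,
                length(x$groups[[g]]), length(x$private[[g]]),
                length(x$missing[[g]])))
  invisible(x)
}
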