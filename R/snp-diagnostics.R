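# Per-gene ortholog alignment, SNP calling with synonymous/non-synonymous
# classification, and identification of sites diagnostic for taxonomic
# groups (subgenus / section / species level).

#' Codon-aware ortholog alignment
#'
#' Aligns the CDS of one gene across taxa. Taxa are sorted by name so no
#' output depends on input order. Equal-length inputs are used as given
#' (positional identity); otherwise translations are globally aligned to
#' the reference taxon (first after sorting) and gaps are back-threaded
#' onto the nucleotides in whole codons, so alignment length stays
#' divisible by 3. Terminal stop codons are stripped before aligning.
#' A translated identity below \code{min_identity} against the reference
#' aborts (mis-orthology guard).
#'
#' @param cds_per_taxon Named list taxon -> \code{coding_sequence} or
#'   in-frame DNA string (>= 2 taxa, one gene).
#' @param gene Gene name (taken from the first CDS when available).
#' @param min_identity Translated-identity floor (default 0.5).
#' @return An \code{ortholog_alignment}: list with \code{gene},
#'   \code{taxa}, \code{seqs} (named, equal-length aligned nt with
#'   \code{-} gaps).
#' @export
align_orthologs <- function(cds_per_taxon, gene = NULL, min_identity = 0.5) {
  stopifnot(length(cds_per_taxon) >= 2L, !is.null(names(cds_per_taxon)))
  nt <- vapply(cds_per_taxon, function(x)
    if (inherits(x, "coding_sequence")) x$nt else toupper(x), "")
  if (is.null(gene))
    gene <- if (inherits(cds_per_taxon[[1]], "coding_sequence"))
      cds_per_taxon[[1]]$gene else "gene"
  nt <- nt[order(names(nt))]
  stopifnot(all(nchar(nt) %% 3L == 0L))
  code <- genetic_code_table(1L)
  strip_stop <- function(s) {
    cods <- split_codons(s)
    if (length(cods) && !is.na(code[cods[length(cods)]]) &&
        code[cods[length(cods)]] == "*")
      cods <- cods[-length(cods)]
    paste(cods, collapse = "")
  }
  nt <- vapply(nt, strip_stop, "")
  aa <- vapply(nt, translate_dna, "")
  ident_to <- function(a, b) {
    if (nchar(a) == nchar(b)) {
      v1 <- strsplit(a, "")[[1]]; v2 <- strsplit(b, "")[[1]]
      return(mean(v1 == v2))
    }
    # unequal lengths (indels): identity from a global alignment
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
    Biostrings::pid(aln, type = "PID3") / 100
  }
  for (i in seq_along(aa)[-1]) {
    if (ident_to(aa[[1]], aa[[i]]) < min_identity)
      stop("translated identity of ", names(aa)[i], " to ", names(aa)[1],
           " below ", min_identity, " for gene ", gene,
           "; suspected mis-orthology")
  }
  if (length(unique(nchar(nt))) == 1L) {
    seqs <- nt
  } else {
    # reference-anchored merge: align each translation to the reference,
    # collect insertion lengths after each reference position, then emit
    # whole-codon columns
    ref_aa <- aa[[1]]
    nref <- nchar(ref_aa)
    percds <- lapply(seq_along(nt), function(i) {
      if (i == 1L)
        return(list(at = as.list(split_codons(nt[[i]])),
                    ins = vector("list", nref + 1L)))
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(aa[[i]]), Biostrings::AAString(ref_aa),
        type = "global", substitutionMatrix = "BLOSUM62",
        gapOpening = 10, gapExtension = 0.5)
      p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
      s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
      cods <- split_codons(nt[[i]])
      at <- as.list(rep("---", nref))
      ins <- vector("list", nref + 1L)
      ip <- 0L; ir <- 0L
      for (k in seq_along(p)) {
        if (p[k] != "-") ip <- ip + 1L
        if (s[k] != "-") {
          ir <- ir + 1L
          if (p[k] != "-") at[[ir]] <- cods[ip]
        } else if (p[k] != "-") {
          ins[[ir + 1L]] <- c(ins[[ir + 1L]], cods[ip])
        }
      }
      list(at = at, ins = ins)
    })
    ins_len <- vapply(seq_len(nref + 1L), function(r)
      max(c(0L, vapply(percds, function(x) length(x$ins[[r]]), 0L))), 0L)
    seqs <- vapply(percds, function(x) {
      parts <- character()
      for (r in seq_len(nref + 1L)) {
        insc <- x$ins[[r]]
        pad <- ins_len[r] - length(insc)
        parts <- c(parts, insc, rep("---", pad))
        if (r <= nref) parts <- c(parts, x$at[[r]])
      }
      paste(parts, collapse = "")
    }, "")
    names(seqs) <- names(nt)
  }
  structure(list(gene = gene, taxa = names(seqs), seqs = seqs),
            class = "ortholog_alignment")
}

#' @export
print.ortholog_alignment <- function(x, ...) {
  cat(sprintf("<ortholog_alignment> %s: %d taxa, %d columns\n",
              x$gene, length(x$taxa), nchar(x$seqs[[1]])))
  invisible(x)
}

#' Call SNP sites from an ortholog alignment
#'
#' Every gap-free column with at least two distinct alleles becomes one
#' SNP site (multi-allelic columns are still one site; columns
#' containing gaps are excluded, indels are not SNPs). Effect is
#' computed by substituting each allele into its codon position within
#' the panel-majority codon (ties toward the alphabetically first
#' codon): any amino-acid-changing allele makes the site nonsynonymous.
#'
#' @param aln An \code{ortholog_alignment}.
#' @param transl_table Genetic-code number.
#' @return A \code{snp_table}: list with \code{gene}, \code{taxa},
#'   \code{column} (alignment positions), \code{effect}
#'   (\code{"synonymous"}/\code{"nonsynonymous"}), \code{alleles}
#'   (sites x taxa character matrix), \code{aln_length}.
#' @export
call_snps <- function(aln, transl_table = 1L) {
  stopifnot(inherits(aln, "ortholog_alignment"))
  mat <- do.call(rbind, strsplit(unname(aln$seqs), "", fixed = TRUE))
  rownames(mat) <- aln$taxa
  ncol_ <- ncol(mat)
  code <- genetic_code_table(transl_table)
  gapfree <- colSums(mat == "-") == 0L
  variable <- gapfree & apply(mat, 2L, function(col) length(unique(col)) >= 2L)
  cols <- which(variable)
  effect <- character(length(cols))
  for (k in seq_along(cols)) {
    col <- cols[k]
    ci <- (col - 1L) %/% 3L
    cstart <- 3L * ci + 1L
    pos_in_codon <- col - cstart + 1L
    codons <- apply(mat[, cstart:(cstart + 2L), drop = FALSE], 1L, paste,
                    collapse = "")
    codons <- codons[!grepl("-", codons, fixed = TRUE)]
    tab <- table(codons)
    maj <- sort(names(tab)[tab == max(tab)])[1]
    alleles <- unique(mat[, col])
    nonsyn <- FALSE
    for (a in alleles) {
      v <- maj
      substring(v, pos_in_codon, pos_in_codon) <- a
      aa_m <- code[maj]; aa_v <- code[v]
      if (is.na(aa_v) || !identical(unname(aa_v), unname(aa_m))) {
        nonsyn <- TRUE; break
      }
    }
    effect[k] <- if (nonsyn) "nonsynonymous" else "synonymous"
  }
  structure(list(gene = aln$gene, taxa = aln$taxa, column = cols,
                 effect = effect,
                 alleles = t(mat[, cols, drop = FALSE]),
                 aln_length = ncol_),
            class = "snp_table")
}

#' @export
print.snp_table <- function(x, ...) {
  lab <- if (length(unique(x$gene)) > 1L)
    sprintf("%d genes", length(unique(x$gene))) else x$gene[1L]
  cat(sprintf("<snp_table> %s: %d SNP sites (%d nonsynonymous, %d synonymous) over %d taxa\n",
              lab, length(x$column), sum(x$effect == "nonsynonymous"),
              sum(x$effect == "synonymous"), length(x$taxa)))
  invisible(x)
}

#' Combine per-gene SNP tables
#'
#' @param snp_list List of \code{snp_table} objects over the same taxa.
#' @return A \code{snp_table} with a \code{gene} vector per site.
#' @export
combine_snps <- function(snp_list) {
  stopifnot(length(snp_list) >= 1L)
  taxa <- snp_list[[1]]$taxa
  for (s in snp_list) stopifnot(identical(s$taxa, taxa))
  structure(list(
    gene = unlist(lapply(snp_list, function(s)
      rep(s$gene, length(s$column)))),
    taxa = taxa,
    column = unlist(lapply(snp_list, `[[`, "column")),
    effect = unlist(lapply(snp_list, `[[`, "effect")),
    alleles = do.call(rbind, lapply(snp_list, `[[`, "alleles")),
    aln_length = sum(vapply(snp_list, `[[`, 0L, "aln_length"))),
    class = "snp_table")
}

#' Sites diagnostic for a taxonomic group
#'
#' A site is diagnostic for group G when all members of G carry one and
#' the same allele (monomorphic within G) and no non-member carries that
#' allele. Under this predicate a single sequence suffices to identify
#' the group. Singleton groups are allowed (species-level
#' identification).
#'
#' @param snps A \code{snp_table}.
#' @param grouping Named character vector taxon -> group label at the
#'   desired level (subgenus, section, species, ...).
#' @param group Target group label.
#' @return List with \code{index} (site indices into \code{snps}),
#'   \code{allele} (the diagnostic allele per site), \code{effect},
#'   \code{n_synonymous}, \code{n_nonsynonymous}.
#' @export
diagnostic_sites <- function(snps, grouping, group) {
  stopifnot(inherits(snps, "snp_table"))
  if (!all(snps$taxa %in% names(grouping)))
    stop("grouping must assign every taxon: missing ",
         paste(setdiff(snps$taxa, names(grouping)), collapse = ", "))
  members <- snps$taxa[grouping[snps$taxa] == group]
  if (!length(members)) stop("empty group '", group, "'")
  others <- setdiff(snps$taxa, members)
  idx <- integer(); dall <- character()
  for (k in seq_len(length(snps$column))) {
    a_in <- unique(snps$alleles[k, members])
    if (length(a_in) != 1L) next
    if (length(others) && any(snps$alleles[k, others] == a_in)) next
    idx <- c(idx, k); dall <- c(dall, a_in)
  }
  eff <- snps$effect[idx]
  list(index = idx, allele = dall, effect = eff,
       n_synonymous = sum(eff == "synonymous"),
       n_nonsynonymous = sum(eff == "nonsynonymous"))
}

#' Rank genes by SNP load
#'
#' @param snps A combined \code{snp_table} (multi-gene).
#' @param gene_lengths Optional named vector of gene lengths in bp for
#'   the per-kb ranking.
#' @return data.frame with \code{gene}, \code{n_snps}, \code{share} and,
#'   when lengths are given, \code{per_kb}; sorted by count.
#' @export
per_gene_snp_density <- function(snps, gene_lengths = NULL) {
  stopifnot(inherits(snps, "snp_table"))
  if (!length(snps$column))
    return(data.frame(gene = character(), n_snps = integer(),
                      share = numeric()))
  tab <- sort(table(snps$gene), decreasing = TRUE)
  out <- data.frame(gene = names(tab), n_snps = as.integer(tab),
                    share = as.numeric(tab) / sum(tab))
  if (!is.null(gene_lengths)) {
    out$per_kb <- out$n_snps / (gene_lengths[out$gene] / 1000)
    out <- out[order(-out$n_snps, out$gene), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
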