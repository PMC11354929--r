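# Homology-guided C-to-U RNA-editing prediction (PREP-style) and the
# hydropathy-based classification/summary of predicted edits.

# Pinned (ref_aa -> edited_aa) category lookup reproducing the published
# block assignments for brown-algal organellar edits. Note two deliberate
# quirks kept for reproducibility: R->C is filed as unchanged-hydrophilic
# and R->W as unchanged-hydrophobic although Arg is conventionally
# hydrophilic; P counts as hydrophobic (P->L unchanged, P->S
# became-hydrophilic).
EDIT_CATEGORIES <- c("unchanged-hydrophilic", "unchanged-hydrophobic",
                     "became-hydrophobic", "became-hydrophilic")
EDIT_CATEGORY_LOOKUP <- c(
  "H>Y" = "unchanged-hydrophilic",
  "R>C" = "unchanged-hydrophilic",
  "L>F" = "unchanged-hydrophobic",
  "R>W" = "unchanged-hydrophobic",
  "P>L" = "unchanged-hydrophobic",
  "A>V" = "unchanged-hydrophobic",
  "T>M" = "became-hydrophobic",
  "S>L" = "became-hydrophobic",
  "S>F" = "became-hydrophobic",
  "T>I" = "became-hydrophobic",
  "P>S" = "became-hydrophilic")

# Kyte-Doolittle hydropathy, used only for pairs absent from the pinned
# lookup (flagged "extrapolated"): hydrophobic iff KD > 0.
KYTE_DOOLITTLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' One predicted C-to-U editing site
#'
#' Validates the invariants: the edited codon differs from the reference
#' codon at exactly one position, by C to T on the coding strand, and the
#' amino acid changes (synonymous edits are undetectable by homology and
#' excluded by design).
#'
#' @param gene Gene name.
#' @param codon_index 1-based codon index within the CDS.
#' @param codon_pos Edited position within the codon (1, 2 or 3).
#' @param ref_codon,edited_codon Reference and edited codons.
#' @param support Fraction of homologs carrying the edited amino acid.
#' @param transl_table Genetic-code number.
#' @return An \code{edit_site} with derived \code{ref_aa},
#'   \code{edited_aa}, \code{category}, \code{extrapolated}.
#' @export
edit_site <- function(gene, codon_index, codon_pos, ref_codon, edited_codon,
                      support = NA_real_, transl_table = 1L) {
  ref_codon <- toupper(ref_codon); edited_codon <- toupper(edited_codon)
  d <- which(strsplit(ref_codon, "")[[1]] != strsplit(edited_codon, "")[[1]])
  if (length(d) != 1L || substring(ref_codon, d, d) != "C" ||
      substring(edited_codon, d, d) != "T")
    stop("edit must be a single C->T change: ", ref_codon, " -> ", edited_codon)
  if (d != codon_pos) stop("codon_pos does not match the changed position")
  code <- genetic_code_table(transl_table)
  ref_aa <- unname(code[ref_codon]); edited_aa <- unname(code[edited_codon])
  if (identical(ref_aa, edited_aa))
    stop("synonymous edit ", ref_codon, " -> ", edited_codon,
         " violates the edit_site invariant")
  cls <- classify_aa_change(ref_aa, edited_aa)
  structure(list(gene = gene, codon_index = as.integer(codon_index),
                 codon_pos = as.integer(codon_pos), ref_codon = ref_codon,
                 edited_codon = edited_codon, ref_aa = ref_aa,
                 edited_aa = edited_aa, support = support,
                 category = cls$category, extrapolated = cls$extrapolated),
            class = "edit_site")
}

classify_aa_change <- function(ref_aa, edited_aa) {
  key <- paste0(ref_aa, ">", edited_aa)
  if (key %in% names(EDIT_CATEGORY_LOOKUP))
    return(list(category = unname(EDIT_CATEGORY_LOOKUP[key]),
                extrapolated = FALSE))
  phob <- function(a) !is.na(KYTE_DOOLITTLE[a]) && KYTE_DOOLITTLE[a] > 0
  cat <- if (phob(ref_aa) && phob(edited_aa)) "unchanged-hydrophobic"
    else if (!phob(ref_aa) && !phob(edited_aa)) "unchanged-hydrophilic"
    else if (!phob(ref_aa) && phob(edited_aa)) "became-hydrophobic"
    else "became-hydrophilic"
  list(category = cat, extrapolated = TRUE)
}

#' Classify an editing site by hydropathy effect
#'
#' Category comes from a fixed lookup of (reference aa, edited aa) pairs
#' pinned to the published block assignments; pairs outside the lookup
#' fall back to the Kyte-Doolittle sign and are flagged
#' \code{extrapolated}.
#'
#' @param site An \code{edit_site}.
#' @return One of \code{"unchanged-hydrophilic"},
#'   \code{"unchanged-hydrophobic"}, \code{"became-hydrophobic"},
#'   \code{"became-hydrophilic"}.
#' @export
classify_edit <- function(site) {
  stopifnot(inherits(site, "edit_site"))
  site$category
}

#' @export
print.edit_site <- function(x, ...) {
  cat(sprintf("<edit_site> %s codon %d pos %d: %s(%s)->%s(%s) [%s]%s\n",
              x$gene, x$codon_index, x$codon_pos, x$ref_codon, x$ref_aa,
              x$edited_codon, x$edited_aa, x$category,
              if (x$extrapolated) " (extrapolated)" else ""))
  invisible(x)
}

# Map CDS amino-acid positions to panel columns. Columns gapped in >= 50%
# of panel members are skipped; remaining mapping is positional when
# lengths agree, otherwise via global alignment to the panel consensus.
map_cds_to_panel <- function(aa, panel) {
  mat <- do.call(rbind, strsplit(panel, "", fixed = TRUE))
  gapfrac <- colMeans(mat == "-")
  use <- which(gapfrac < 0.5)
  cons <- apply(mat[, use, drop = FALSE], 2L, function(col) {
    col <- col[col != "-"]
    names(sort(table(col), decreasing = TRUE))[1]
  })
  aav <- strsplit(aa, "", fixed = TRUE)[[1]]
  if (length(aav) == length(use)) {
    map <- use
  } else {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(aa),
      Biostrings::AAString(paste(cons, collapse = "")),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
    p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    map <- rep(NA_integer_, length(aav))
    ip <- 0L; is <- 0L
    for (k in seq_along(p)) {
      if (p[k] != "-") ip <- ip + 1L
      if (s[k] != "-") is <- is + 1L
      if (p[k] != "-" && s[k] != "-") map[ip] <- use[is]
    }
  }
  list(map = map, matrix = mat, consensus_cols = use)
}

#' Predict C-to-U RNA-editing sites from a homolog protein panel
#'
#' For every cytidine in the CDS whose C-to-T substitution changes the
#' encoded amino acid (stop-creating changes excluded), an edit is
#' predicted when the edited amino acid matches at least
#' \code{threshold} of the homologs at the aligned column while the
#' unedited amino acid matches fewer than \code{threshold}. Sites are
#' returned 5' to 3'.
#'
#' @param cds A \code{coding_sequence}.
#' @param homologs Aligned protein panel: named character vector,
#'   \code{AAStringSet}, or path to an aligned protein FASTA
#'   (>= 2 sequences, equal length, \code{-} gaps allowed).
#' @param threshold Homolog-support cutoff, in (0.5, 1] (default 0.8).
#' @param min_identity Mis-orthology guard: minimum identity of the CDS
#'   translation to the panel consensus (default 0.5).
#' @return List of \code{edit_site} objects.
#' @export
predict_edits <- function(cds, homologs, threshold = 0.8,
                          min_identity = 0.5) {
  stopifnot(inherits(cds, "coding_sequence"))
  if (!(threshold > 0.5 && threshold <= 1))
    stop("threshold must lie in (0.5, 1]")
  if (is.character(homologs) && length(homologs) == 1L &&
      file.exists(homologs))
    homologs <- Biostrings::readAAStringSet(homologs)
  if (inherits(homologs, "AAStringSet"))
    homologs <- setNames(as.character(homologs), names(homologs))
  if (length(homologs) < 2L) stop("homolog panel needs >= 2 sequences")
  if (length(unique(nchar(homologs))) != 1L)
    stop("homolog panel sequences must be aligned (equal length)")
  aa <- sub("\\*$", "", cds$aa)
  pm <- map_cds_to_panel(aa, homologs)
  aav <- strsplit(aa, "", fixed = TRUE)[[1]]
  mapped <- which(!is.na(pm$map))
  if (!length(mapped)) stop("CDS could not be mapped to the panel")
  colmatch <- function(col, a) {
    obs <- pm$matrix[, col]; obs <- obs[obs != "-"]
    if (!length(obs)) return(0)
    mean(obs == a)
  }
  ident <- mean(vapply(mapped, function(i)
    colmatch(pm$map[i], aav[i]) > 0.5, TRUE))
  if (ident < min_identity)
    stop("CDS-panel identity ", round(ident, 3), " below floor ",
         min_identity, "; suspected mis-orthology")
  code <- genetic_code_table(cds$transl_table)
  cods <- split_codons(cds$nt)
  sites <- list()
  for (i in mapped) {
    cod <- cods[i]
    for (p in 1:3) {
      if (substring(cod, p, p) != "C") next
      ed <- cod
      substring(ed, p, p) <- "T"
      ref_aa <- unname(code[cod]); ed_aa <- unname(code[ed])
      if (is.na(ed_aa) || ed_aa == "*" || identical(ed_aa, ref_aa)) next
      sup_ed <- colmatch(pm$map[i], ed_aa)
      sup_ref <- colmatch(pm$map[i], ref_aa)
      if (sup_ed >= threshold && sup_ref < threshold)
        sites[[length(sites) + 1L]] <-
          edit_site(cds$gene, i, p, cod, ed, support = sup_ed,
                    transl_table = cds$transl_table)
    }
  }
  sites
}

#' Summarize editing sites
#'
#' Accepts either a list of \code{edit_site} objects or a printed-table
#' style data frame with columns \code{ref_codon}, \code{edited_codon}
#' and \code{count}. Tallies edits by codon-to-codon transition type,
#' hydropathy category, edited codon position and (when sites are given)
#' gene, and reports editing density as a percentage of genome length.
#'
#' @param sites List of \code{edit_site} or a transition-count data frame.
#' @param genome_length Genome length in bp (> 0).
#' @return An \code{edit_summary}: list with \code{n}, \code{transitions}
#'   (data.frame), \code{category_counts}, \code{category_pct},
#'   \code{position_counts}, \code{position_pct}, \code{gene_counts},
#'   \code{density_pct}.
#' @export
summarize_edits <- function(sites, genome_length) {
  if (!is.numeric(genome_length) || genome_length <= 0)
    stop("genome_length must be positive")
  if (is.data.frame(sites)) {
    stopifnot(all(c("ref_codon", "edited_codon", "count") %in% names(sites)))
    expanded <- sites[rep(seq_len(nrow(sites)), sites$count), , drop = FALSE]
    sl <- lapply(seq_len(nrow(expanded)), function(i) {
      rc <- expanded$ref_codon[i]; ec <- expanded$edited_codon[i]
      d <- which(strsplit(rc, "")[[1]] != strsplit(ec, "")[[1]])
      edit_site(gene = if ("gene" %in% names(expanded))
        expanded$gene[i] else "NA", codon_index = 1L, codon_pos = d,
        ref_codon = rc, edited_codon = ec)
    })
  } else {
    sl <- sites
  }
  if (!length(sl)) stop("no editing sites to summarize")
  stopifnot(all(vapply(sl, inherits, TRUE, "edit_site")))
  n <- length(sl)
  tr <- vapply(sl, function(s)
    sprintf("%s(%s)>%s(%s)", s$ref_codon, s$ref_aa, s$edited_codon,
            s$edited_aa), "")
  trans <- as.data.frame(table(transition = tr), stringsAsFactors = FALSE)
  names(trans)[2] <- "count"
  catc <- table(factor(vapply(sl, `[[`, "", "category"),
                       levels = EDIT_CATEGORIES))
  posc <- table(factor(vapply(sl, `[[`, 0L, "codon_pos"), levels = 1:3))
  genec <- sort(table(vapply(sl, `[[`, "", "gene")), decreasing = TRUE)
  structure(list(n = n, transitions = trans,
                 category_counts = c(catc),
                 category_pct = 100 * c(catc) / n,
                 position_counts = c(posc),
                 position_pct = 100 * c(posc) / n,
                 gene_counts = c(genec),
                 density_pct = 100 * n / genome_length),
            class = "edit_summary")
}

#' @export
print.edit_summary <- function(x, ...) {
  cat(sprintf("<edit_summary> %d C-to-U sites (%.2f%% of genome)\n",
              x$n, x$density_pct))
  for (k in names(x$category_counts))
    cat(sprintf("  %-22s %3d (%.2f%%)\n", k, x$category_counts[k],
                x$category_pct[k]))
  cat(sprintf("  codon positions 1/2/3: %d/%d/%d\n",
              x$position_counts[1], x$position_counts[2],
              x$position_counts[3]))
  invisible(x)
}

#' Write per-site and summary editing TSVs
#'
#' @param sites List of \code{edit_site}.
#' @param summary An \code{edit_summary}.
#' @param site_path,summary_path Output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_edit_reports <- function(sites, summary, site_path, summary_path) {
  df <- do.call(rbind, lapply(sites, function(s)
    data.frame(gene = s$gene, codon_index = s$codon_index,
               codon_pos = s$codon_pos,
               transition = sprintf("%s(%s)>%s(%s)", s$ref_codon, s$ref_aa,
                                    s$edited_codon, s$edited_aa),
               support = s$support, category = s$category)))
  utils::write.table(df, site_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(summary$transitions, summary_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(site_path, summary_path))
}
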