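# Domain types for annotated organellar genomes: circular/linear DNA plus
# typed gene features, with circular-coordinate arithmetic and CDS extraction.

IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")
GENE_CLASSES <- c("PCG", "tRNA", "rRNA", "ORF", "tmRNA", "intron")

#' Taxonomic label for a genome
#'
#' Hierarchical taxon assignment used by the grouping-aware stages
#' (gene-content comparison, diagnostic SNPs). Only \code{species} is
#' mandatory; intrageneric ranks (subgenus, section) may be empty.
#'
#' @param species Species name (non-empty).
#' @param genus,family,order,subgenus,section Higher/intrageneric ranks,
#'   empty string when unassigned.
#' @return An object of class \code{taxon_label}.
#' @export
taxon_label <- function(species, genus = "", family = "", order = "",
                        subgenus = "", section = "") {
  stopifnot(is.character(species), length(species) == 1L, nzchar(species))
  structure(list(order = order, family = family, genus = genus,
                 subgenus = subgenus, section = section, species = species),
            class = "taxon_label")
}

#' Gene feature on an organellar genome
#'
#' @param name Gene name (e.g. \code{"cox1"}, \code{"trnA"}).
#' @param gene_class One of \code{"PCG"}, \code{"tRNA"}, \code{"rRNA"},
#'   \code{"ORF"}, \code{"tmRNA"}, \code{"intron"}.
#' @param strand \code{"+"} or \code{"-"}; \code{"-"} means the coding
#'   sequence is the reverse complement of the spliced interval (the
#'   "light chain").
#' @param intervals Two-column matrix (start, end), 1-based inclusive, in
#'   transcription splice order. On circular genomes an interval with
#'   start > end wraps the origin and is normalized into two intervals.
#' @param codon_start Reading-frame offset (1, 2 or 3), GenBank convention.
#' @param transl_table NCBI genetic-code table number (default 1, standard).
#' @return An object of class \code{gene_feature}.
#' @export
gene_feature <- function(name, gene_class, strand, intervals,
                         codon_start = 1L, transl_table = 1L) {
  gene_class <- match.arg(gene_class, GENE_CLASSES)
  strand <- match.arg(strand, c("+", "-"))
  intervals <- matrix(as.integer(intervals), ncol = 2L,
                      dimnames = list(NULL, c("start", "end")))
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            all(intervals >= 1L), codon_start %in% 1:3)
  structure(list(name = name, gene_class = gene_class, strand = strand,
                 intervals = intervals, codon_start = as.integer(codon_start),
                 transl_table = as.integer(transl_table)),
            class = "gene_feature")
}

#' Annotated organellar genome
#'
#' The container every pipeline stage consumes: a DNA sequence (IUPAC
#' symbols), its topology, and typed gene features. Origin-wrapping
#' feature intervals are normalized at construction.
#'
#' @param id Genome identifier (accession-like).
#' @param sequence DNA string (IUPAC symbols; case-insensitive input).
#' @param features List of \code{\link{gene_feature}} objects.
#' @param topology \code{"circular"} or \code{"linear"}.
#' @param organelle \code{"mt"} (mitochondrion) or \code{"cp"} (plastid).
#' @param taxon A \code{\link{taxon_label}}, or \code{NULL}.
#' @return An object of class \code{annotated_genome} with elements
#'   \code{id}, \code{organelle}, \code{topology}, \code{sequence},
#'   \code{length}, \code{features}, \code{taxon}.
#' @export
annotated_genome <- function(id, sequence, features = list(),
                             topology = c("circular", "linear"),
                             organelle = c("mt", "cp"), taxon = NULL) {
  topology <- match.arg(topology)
  organelle <- match.arg(organelle)
  sequence <- toupper(sequence)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(sequence), length(sequence) == 1L)
  bad <- setdiff(unique(strsplit(sequence, "", fixed = TRUE)[[1]]), IUPAC_DNA)
  if (length(bad))
    stop("sequence contains non-IUPAC symbols: ", paste(bad, collapse = ", "))
  len <- nchar(sequence)
  features <- lapply(features, normalize_feature, genome_length = len,
                     topology = topology)
  g <- structure(list(id = id, organelle = organelle, topology = topology,
                      sequence = sequence, length = len,
                      features = features, taxon = taxon),
                 class = "annotated_genome")
  g
}

# Split origin-wrapping intervals (start > end on a circular molecule) into
# [start, L] + [1, end]; verify everything lies within [1, L] afterwards.
normalize_feature <- function(f, genome_length, topology) {
  stopifnot(inherits(f, "gene_feature"))
  out <- NULL
  for (i in seq_len(nrow(f$intervals))) {
    s <- f$intervals[i, 1L]; e <- f$intervals[i, 2L]
    if (s <= e) {
      out <- rbind(out, c(s, e))
    } else {
      if (topology != "circular")
        stop("feature '", f$name, "': start > end on a linear genome")
      out <- rbind(out, c(s, genome_length), c(1L, e))
    }
  }
  if (any(out > genome_length))
    stop("feature '", f$name, "' extends beyond genome length ", genome_length)
  f$intervals <- matrix(as.integer(out), ncol = 2L,
                        dimnames = list(NULL, c("start", "end")))
  f
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s (%s, %s): %d bp, %d features\n",
              x$id, x$organelle, x$topology, x$length, length(x$features)))
  tab <- table(factor(vapply(x$features, `[[`, "", "gene_class"),
                      levels = GENE_CLASSES))
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = "  "), "\n")
  if (!is.null(x$taxon))
    cat("  taxon:", x$taxon$species, "\n")
  invisible(x)
}

#' @export
print.gene_feature <- function(x, ...) {
  loc <- paste(sprintf("%d..%d", x$intervals[, 1], x$intervals[, 2]),
               collapse = ",")
  cat(sprintf("<gene_feature> %s [%s] strand %s  %s\n",
              x$name, x$gene_class, x$strand, loc))
  invisible(x)
}

# ---- sequence utilities -----------------------------------------------------

#' Reverse complement of a DNA string
#'
#' @param seq DNA string (IUPAC symbols handled).
#' @return Reverse-complemented string.
#' @export
revcomp <- function(seq) {
  chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
         "TGCAYRSWMKVHDBNtgcayrswmkvhdbn",
         vapply(seq, function(s)
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""), "",
           USE.NAMES = FALSE))
}

complement_dna <- function(seq) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", seq)
}

#' GC content of a DNA sequence
#'
#' Fraction (#G + #C) / (#A + #C + #G + #T). IUPAC ambiguity symbols are
#' excluded from both numerator and denominator.
#'
#' @param seq DNA string, non-empty.
#' @return Fraction in [0, 1].
#' @export
gc_content <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("empty sequence")
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  unamb <- ch %in% c("A", "C", "G", "T")
  if (!any(unamb)) stop("sequence contains no unambiguous bases")
  sum(ch %in% c("G", "C")) / sum(unamb)
}

# Genomic positions covered by a feature, in splice order (ascending within
# each normalized interval).
feature_positions <- function(f) {
  unlist(lapply(seq_len(nrow(f$intervals)), function(i)
    seq.int(f$intervals[i, 1L], f$intervals[i, 2L])), use.names = FALSE)
}

feature_span_length <- function(f) {
  sum(f$intervals[, 2L] - f$intervals[, 1L] + 1L)
}

# Spliced genomic sequence of a feature (strand applied).
feature_sequence <- function(genome, f) {
  chs <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  s <- paste(chs[feature_positions(f)], collapse = "")
  if (f$strand == "-") s <- revcomp(s)
  s
}

# ---- translation ------------------------------------------------------------

genetic_code_table <- function(transl_table = 1L) {
  gc <- Biostrings::getGeneticCode(as.character(transl_table))
  names(gc) <- chartr("U", "T", names(gc))
  gc
}

#' Translate an in-frame DNA string
#'
#' Codons containing ambiguity symbols translate to \code{"X"}; a trailing
#' incomplete codon is dropped.
#'
#' @param nt In-frame DNA string.
#' @param transl_table NCBI genetic-code number.
#' @return Amino-acid string (stop = \code{"*"}).
#' @export
translate_dna <- function(nt, transl_table = 1L) {
  code <- genetic_code_table(transl_table)
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  cods <- substring(toupper(nt), 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- code[cods]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

split_codons <- function(nt) {
  n <- nchar(nt) %/% 3L
  substring(toupper(nt), 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# ---- CDS extraction ---------------------------------------------------------

#' Extract coding sequences from an annotated genome
#'
#' Splices each feature of the requested class, reverse-complements
#' light-chain (strand \code{-}) genes, applies the \code{codon_start}
#' frame offset and translates. The terminal stop codon is retained in
#' \code{nt} and as \code{"*"} in \code{aa}. Genes whose corrected length
#' is not a multiple of 3 are flagged \code{incomplete} and should be
#' excluded from codon statistics.
#'
#' @param genome An \code{\link{annotated_genome}}.
#' @param gene_class Feature class to extract (default \code{"PCG"}).
#' @return List of \code{coding_sequence} objects, each with elements
#'   \code{gene}, \code{genome_id}, \code{nt}, \code{aa},
#'   \code{transl_table}, and logical flags \code{non_atg_start},
#'   \code{internal_stop}, \code{incomplete}.
#' @export
extract_cds <- function(genome, gene_class = "PCG") {
  stopifnot(inherits(genome, "annotated_genome"))
  feats <- Filter(function(f) f$gene_class == gene_class, genome$features)
  lapply(feats, function(f) {
    nt <- feature_sequence(genome, f)
    if (f$codon_start > 1L) nt <- substring(nt, f$codon_start)
    incomplete <- (nchar(nt) %% 3L) != 0L
    if (incomplete) {
      warning("gene '", f$name, "': length ", nchar(nt),
              " not a multiple of 3; flagged incomplete", call. = FALSE)
      nt <- substring(nt, 1L, nchar(nt) - nchar(nt) %% 3L)
    }
    aa <- translate_dna(nt, f$transl_table)
    naa <- nchar(aa)
    internal_stop <- naa > 1L &&
      grepl("*", substring(aa, 1L, naa - 1L), fixed = TRUE)
    structure(list(gene = f$name, genome_id = genome$id, nt = nt, aa = aa,
                   transl_table = f$transl_table,
                   non_atg_start = substring(nt, 1L, 3L) != "ATG",
                   internal_stop = internal_stop, incomplete = incomplete),
              class = "coding_sequence")
  })
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("<coding_sequence> %s (%s): %d nt, %d aa%s%s%s\n",
              x$gene, x$genome_id, nchar(x$nt), nchar(x$aa),
              if (x$non_atg_start) " [non-ATG start]" else "",
              if (x$internal_stop) " [internal stop]" else "",
              if (x$incomplete) " [incomplete]" else ""))
  invisible(x)
}

#' Build a coding_sequence directly from an in-frame DNA string
#'
#' @param nt In-frame DNA string.
#' @param gene Gene name.
#' @param genome_id Genome identifier.
#' @param transl_table Genetic-code number.
#' @return A \code{coding_sequence}.
#' @export
coding_sequence <- function(nt, gene = "gene", genome_id = "genome",
                            transl_table = 1L) {
  nt <- toupper(nt)
  stopifnot(nchar(nt) %% 3L == 0L, nchar(nt) >= 3L)
  aa <- translate_dna(nt, transl_table)
  naa <- nchar(aa)
  structure(list(gene = gene, genome_id = genome_id, nt = nt, aa = aa,
                 transl_table = as.integer(transl_table),
                 non_atg_start = substring(nt, 1L, 3L) != "ATG",
                 internal_stop = naa > 1L &&
                   grepl("*", substring(aa, 1L, naa - 1L), fixed = TRUE),
                 incomplete = FALSE),
            class = "coding_sequence")
}

#' Write coding or protein sequences to FASTA
#'
#' @param cds_set List of \code{coding_sequence} objects.
#' @param path Output file.
#' @param what \code{"nt"} or \code{"aa"}.
#' @return \code{path}, invisibly.
#' @export
write_cds_fasta <- function(cds_set, path, what = c("nt", "aa")) {
  what <- match.arg(what)
  seqs <- vapply(cds_set, `[[`, "", what)
  names(seqs) <- vapply(cds_set, function(x)
    paste(x$genome_id, x$gene, sep = "|"), "")
  if (what == "nt") {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  } else {
    Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  }
  invisible(path)
}

#' Rotate the origin of a circular genome
#'
#' Moves the origin so that old position \code{offset + 1} becomes
#' position 1; features are shifted modulo the length and re-normalized
#' (wrapping features are split). All genome statistics are invariant
#' under rotation.
#'
#' @param genome A circular \code{\link{annotated_genome}}.
#' @param offset Number of bases to rotate by (0 <= offset < length).
#' @return The rotated \code{annotated_genome}.
#' @export
rotate_genome <- function(genome, offset) {
  stopifnot(inherits(genome, "annotated_genome"),
            genome$topology == "circular")
  L <- genome$length
  offset <- as.integer(offset) %% L
  if (offset == 0L) return(genome)
  seq2 <- paste0(substring(genome$sequence, offset + 1L, L),
                 substring(genome$sequence, 1L, offset))
  feats <- lapply(genome$features, function(f) {
    iv <- f$intervals
    # shift, re-join contiguous pieces, and let the constructor re-split
    pos <- ((feature_positions(f) - 1L - offset) %% L) + 1L
    # rebuild runs of consecutive positions
    br <- c(0L, which(diff(pos) != 1L), length(pos))
    iv2 <- cbind(pos[br[-length(br)] + 1L], pos[br[-1L]])
    gene_feature(f$name, f$gene_class, f$strand, iv2,
                 codon_start = f$codon_start, transl_table = f$transl_table)
  })
  annotated_genome(genome$id, seq2, feats, topology = "circular",
                   organelle = genome$organelle, taxon = genome$taxon)
}
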