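# Truth-known generator of annotated circular organellar genomes and
# clade-structured genome panels. The defaults emulate a compact
# brown-algal mitogenome: 65 genes (35 PCG / 25 tRNA / 3 rRNA / 2 ORF),
# 34,686 bp, 188 bp of gene overlap in 12 pairs, 1,597 bp of intergenic
# spacers, 8,780 encoded amino acids, AT-biased third codon positions.
# Every planted structure (repeats, edits, substitutions) is recorded in
# a truth object re-derivable from the emitted files.

MT_PCG_NAMES <- c("atp6", "atp8", "atp9", "cob", "cox1", "cox2", "cox3",
                  "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6",
                  "nad7", "nad9", "nad11", "rpl2", "rpl5", "rpl6", "rpl14",
                  "rpl16", "rpl31", "rps2", "rps3", "rps4", "rps7", "rps8",
                  "rps10", "rps11", "rps12", "rps13", "rps14", "rps19",
                  "tatC")
MT_TRNA_NAMES <- c("trnA", "trnC", "trnD", "trnE", "trnF", "trnG", "trnH",
                   "trnI", "trnK", "trnL1", "trnL2", "trnM1", "trnM2",
                   "trnN", "trnP", "trnQ", "trnR1", "trnR2", "trnS",
                   "trnS2", "trnT", "trnV", "trnW", "trnY", "trnX")
MT_RRNA_NAMES <- c("rns", "rnl", "rrn5")
MT_ORF_NAMES <- c("orf129", "orf377")
LIGHT_CHAIN_PCGS <- c("rpl2", "rpl16", "rps3", "rps19", "tatC")

#' Configuration for the synthetic-genome generator
#'
#' Defaults describe the stated world the generator emulates: a
#' 65-gene circular mitogenome with 188 bp of overlap in 12 pairs,
#' 1,597 bp of spacers, 8,780 encoded amino acids over 35 PCGs, and
#' AT-biased codon usage. All sizes are configurable down to toy scales.
#'
#' @param seed Integer seed; fully determines the output.
#' @param counts Named integer vector of gene counts per class
#'   (\code{PCG}, \code{tRNA}, \code{rRNA}, \code{ORF}).
#' @param pcg_aa_total Total amino acids encoded by all PCGs
#'   (excluding stops).
#' @param trna_len tRNA gene length (bp).
#' @param rrna_lens rRNA gene lengths, recycled over rRNA genes.
#' @param orf_aa Amino-acid lengths of ORFs, recycled.
#' @param overlap_total Total gene-overlap length (bp) to plant.
#' @param n_overlaps Number of overlapping gene pairs.
#' @param spacer_total Total intergenic-spacer length (bp) to plant.
#' @param gc_bg Background (spacer / RNA-gene) GC fraction.
#' @param at3_bias Odds multiplier favouring A/T-ending codons within
#'   each synonymous family (> 1 biases third positions toward A/U).
#' @param boost_codons Codons given extra weight (the classic
#'   high-RSCU leucine/valine codons by default).
#' @param n_edits Number of C-to-U editing sites to plant in PCGs.
#' @param gtg_start_gene Optional PCG name forced to a GTG start codon.
#' @param ssrs,tandems,dispersed Lists of repeats to plant; entries are
#'   lists: \code{list(motif=, copies=)} for SSRs,
#'   \code{list(unit=, copies=)} for tandems,
#'   \code{list(kind=, length=)} for dispersed pairs.
#' @param organelle,id,taxon Genome metadata.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(seed = 1L,
                       counts = c(PCG = 35L, tRNA = 25L, rRNA = 3L,
                                  ORF = 2L),
                       pcg_aa_total = 8780L,
                       trna_len = 72L,
                       rrna_lens = c(1189L, 2200L, 119L),
                       orf_aa = c(129L, 377L),
                       overlap_total = 188L,
                       n_overlaps = 12L,
                       spacer_total = 1597L,
                       gc_bg = 0.35,
                       at3_bias = 3,
                       boost_codons = c("TTA", "GTT"),
                       n_edits = 0L,
                       gtg_start_gene = NULL,
                       ssrs = list(), tandems = list(), dispersed = list(),
                       organelle = "mt", id = "SYN000001",
                       taxon = taxon_label("Synthetica exemplaris",
                                           genus = "Synthetica",
                                           family = "Sargassaceae",
                                           order = "Fucales")) {
  structure(list(seed = as.integer(seed), counts = counts,
                 pcg_aa_total = as.integer(pcg_aa_total),
                 trna_len = as.integer(trna_len), rrna_lens = rrna_lens,
                 orf_aa = orf_aa, overlap_total = as.integer(overlap_total),
                 n_overlaps = as.integer(n_overlaps),
                 spacer_total = as.integer(spacer_total), gc_bg = gc_bg,
                 at3_bias = at3_bias, boost_codons = boost_codons,
                 n_edits = as.integer(n_edits),
                 gtg_start_gene = gtg_start_gene, ssrs = ssrs,
                 tandems = tandems, dispersed = dispersed,
                 organelle = organelle, id = id, taxon = taxon),
            class = "sim_config")
}

# Codon sampling weights per synonymous family: A/T-ending codons get
# odds `at3_bias`, boosted codons an extra factor 3.
codon_weights <- function(cfg, transl_table = 1L) {
  code <- genetic_code_table(transl_table)
  sense <- names(code)[code != "*"]
  w <- setNames(rep(1, length(sense)), sense)
  third <- substring(sense, 3L, 3L)
  w[third %in% c("A", "T")] <- cfg$at3_bias
  w[cfg$boost_codons[cfg$boost_codons %in% sense]] <-
    w[cfg$boost_codons[cfg$boost_codons %in% sense]] * 3
  w
}

random_dna <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# In-frame CDS: ATG start, weighted sense codons, TAA stop.
random_cds <- function(n_aa, w, start_codon = "ATG") {
  body <- sample(names(w), n_aa - 1L, replace = TRUE, prob = w)
  paste(c(start_codon, body, "TAA"), collapse = "")
}

# Deterministic gene order: tRNAs interleaved among PCGs, with the
# trnS-trnD-trnA-rps10 block kept contiguous (Fucales-style signature),
# rRNAs and ORFs spread through the second half.
layout_gene_order <- function(counts) {
  pcg <- rep_len(MT_PCG_NAMES, counts[["PCG"]])
  if (counts[["PCG"]] > length(MT_PCG_NAMES))
    pcg <- c(MT_PCG_NAMES, sprintf("pcg%02d",
                                   seq_len(counts[["PCG"]] -
                                             length(MT_PCG_NAMES))))
  trna <- rep_len(MT_TRNA_NAMES, max(counts[["tRNA"]], 0L))
  rrna <- rep_len(MT_RRNA_NAMES, max(counts[["rRNA"]], 0L))
  orf <- rep_len(MT_ORF_NAMES, max(counts[["ORF"]], 0L))
  block <- intersect(c("trnS", "trnD", "trnA"), trna)
  if (length(block) != 3L || !"rps10" %in% pcg) block <- character()
  trna_rest <- setdiff(trna, block)
  pcg_rest <- setdiff(pcg, "rps10")
  out <- list()
  push <- function(nm, cl) out[[length(out) + 1L]] <<- c(nm, cl)
  others <- c(trna_rest, rrna, orf)
  other_cls <- c(rep("tRNA", length(trna_rest)), rep("rRNA", length(rrna)),
                 rep("ORF", length(orf)))
  oi <- 0L
  for (i in seq_along(pcg_rest)) {
    push(pcg_rest[i], "PCG")
    # two interleaved non-PCG features per PCG keeps junction classes mixed
    for (k in 1:2) {
      if (oi < length(others)) {
        oi <- oi + 1L
        push(others[oi], other_cls[oi])
      }
    }
  }
  if (length(block) == 3L && "rps10" %in% pcg) {
    for (b in block) push(b, "tRNA")
    push("rps10", "PCG")
  } else if ("rps10" %in% pcg) {
    push("rps10", "PCG")
  }
  while (oi < length(others)) {
    oi <- oi + 1L
    push(others[oi], other_cls[oi])
  }
  data.frame(name = vapply(out, `[`, "", 1L),
             gene_class = vapply(out, `[`, "", 2L))
}

split_total <- function(total, n) {
  if (n == 0L) return(integer())
  base <- total %/% n
  sizes <- rep(base, n)
  extra <- total - base * n
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

#' Generate a truth-known annotated circular genome
#'
#' Builds a circular genome with the configured gene layout: genes are
#' placed sequentially around the circle, with \code{n_overlaps}
#' junctions overlapping (always involving at least one RNA/ORF feature
#' so PCG reading frames stay intact) for exactly
#' \code{overlap_total} bp, and the remaining junction gaps tiling
#' exactly \code{spacer_total} bp. PCGs are in-frame with ATG starts
#' (unless \code{gtg_start_gene} is set), weighted codon usage, and TAA
#' stops; light-chain PCGs go on strand \code{-}. Requested repeats are
#' planted into spacers or RNA-gene interiors, and editing sites into
#' PCG codons, all at recorded coordinates.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return List with \code{genome} (an
#'   \code{\link{annotated_genome}}) and \code{truth} (layout table,
#'   planted repeat/edit records, overlap and spacer bookkeeping).
#' @export
generate_genome <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ord <- layout_gene_order(cfg$counts)
  n_genes <- nrow(ord)
  if (cfg$n_overlaps >= n_genes)
    stop("infeasible packing: more overlaps than gene junctions")

  # gene lengths
  len <- integer(n_genes)
  pcg_idx <- which(ord$gene_class == "PCG")
  aa <- split_total(cfg$pcg_aa_total, length(pcg_idx))
  len[pcg_idx] <- 3L * aa + 3L    # aa includes the ATG Met, plus one stop
  len[ord$gene_class == "tRNA"] <- cfg$trna_len
  len[ord$gene_class == "rRNA"] <-
    rep_len(cfg$rrna_lens, sum(ord$gene_class == "rRNA"))
  orf_idx <- which(ord$gene_class == "ORF")
  len[orf_idx] <- 3L * rep_len(cfg$orf_aa, length(orf_idx)) + 3L

  # junction plan: junction i sits after gene i (junction n closes the
  # circle). Overlap junctions need a non-PCG participant.
  cls <- ord$gene_class
  nxt <- c(seq_len(n_genes)[-1L], 1L)
  eligible <- which(!(cls %in% c("PCG", "ORF") &
                        cls[nxt] %in% c("PCG", "ORF")))
  if (length(eligible) < cfg$n_overlaps)
    stop("infeasible packing: not enough RNA-adjacent junctions for overlaps")
  ov_j <- eligible[seq_len(cfg$n_overlaps)]
  ov_sizes <- split_total(cfg$overlap_total, cfg$n_overlaps)
  max_ov <- pmin(len[ov_j], len[nxt[ov_j]]) - 2L
  if (any(ov_sizes > max_ov))
    stop("infeasible packing: overlap larger than participating gene")
  gap_j <- setdiff(seq_len(n_genes), ov_j)

  # reserve room in gaps for planted repeats (span + 2 clearance)
  plant_spans <- c(
    vapply(cfg$ssrs, function(p) nchar(p$motif) * p$copies, 0),
    vapply(cfg$tandems, function(p) nchar(p$unit) * p$copies, 0),
    unlist(lapply(cfg$dispersed, function(p) rep(p$length, 2L))))
  reserve <- as.integer(plant_spans + 4L)
  if (sum(reserve) > cfg$spacer_total)
    stop("infeasible packing: planted repeats exceed the spacer budget")
  if (length(reserve) > length(gap_j))
    stop("infeasible packing: more planted repeats than spacer gaps")
  gap_sizes <- integer(length(gap_j))
  gap_sizes[seq_along(reserve)] <- reserve
  rest <- split_total(cfg$spacer_total - sum(reserve),
                      length(gap_j) - length(reserve))
  if (length(rest)) gap_sizes[(length(reserve) + 1L):length(gap_j)] <- rest

  # coordinates
  starts <- integer(n_genes)
  starts[1L] <- 1L
  after <- integer(n_genes)   # shift applied after gene i
  after[ov_j] <- -ov_sizes
  after[gap_j] <- gap_sizes
  for (i in seq_len(n_genes - 1L))
    starts[i + 1L] <- starts[i] + len[i] + after[i]
  L <- starts[n_genes] + len[n_genes] + after[n_genes] - 1L

  # sequence assembly: background, then RNA/ORF-by-RNA order so that
  # PCGs written last keep their frames intact at overlap junctions
  chs <- strsplit(random_dna(L, cfg$gc_bg), "", fixed = TRUE)[[1]]
  w <- codon_weights(cfg)
  strand <- ifelse(ord$name %in% LIGHT_CHAIN_PCGS, "-", "+")
  cds_store <- list()
  write_gene <- function(i) {
    span <- seq.int(starts[i], starts[i] + len[i] - 1L)
    if (cls[i] %in% c("PCG", "ORF")) {
      start_codon <- if (!is.null(cfg$gtg_start_gene) &&
                         ord$name[i] == cfg$gtg_start_gene) "GTG" else "ATG"
      s <- random_cds(len[i] %/% 3L - 1L, w, start_codon)  # aa = len/3 - 1
      cds_store[[ord$name[i]]] <<- s
      chs[span] <<- strsplit(if (strand[i] == "-") revcomp(s) else s,
                             "", fixed = TRUE)[[1]]
    } else {
      chs[span] <<- strsplit(random_dna(len[i], cfg$gc_bg), "",
                             fixed = TRUE)[[1]]
    }
  }
  for (i in order(cls %in% c("PCG", "ORF")))
    write_gene(i)

  # plant repeats into the reserved gaps
  gap_starts <- starts[gap_j] + len[gap_j]
  truth_ssr <- truth_tan <- truth_disp <- NULL
  slot <- 0L
  next_slot <- function(need) {
    slot <<- slot + 1L
    if (slot > length(gap_j) || gap_sizes[slot] < need + 4L)
      stop("infeasible packing: repeat does not fit its spacer slot")
    gap_starts[slot] + 2L
  }
  mismatch_base <- function(b) setdiff(c("A", "C", "G", "T"), b)[1L]
  plant_run <- function(unit, copies) {
    span <- nchar(unit) * copies
    at <- next_slot(span)
    run <- strsplit(paste(rep(unit, copies), collapse = ""), "",
                    fixed = TRUE)[[1]]
    chs[at:(at + span - 1L)] <<- run
    # block extension on both sides so the planted span is maximal:
    # leftward continuation would need the unit's last base, rightward
    # continuation its first
    chs[at - 1L] <<- mismatch_base(run[span])
    chs[at + span] <<- mismatch_base(run[1L])
    c(start = at, end = at + span - 1L)
  }
  for (p in cfg$ssrs) {
    pos <- plant_run(p$motif, p$copies)
    truth_ssr <- rbind(truth_ssr,
                       data.frame(motif = p$motif,
                                  unit_length = nchar(p$motif),
                                  copies = p$copies, start = pos[["start"]],
                                  end = pos[["end"]]))
  }
  for (p in cfg$tandems) {
    pos <- plant_run(p$unit, p$copies)
    truth_tan <- rbind(truth_tan,
                       data.frame(unit = p$unit, period = nchar(p$unit),
                                  copies = p$copies, start = pos[["start"]],
                                  end = pos[["end"]]))
  }
  for (p in cfg$dispersed) {
    seg <- random_dna(p$length, 0.5)
    second <- switch(p$kind, forward = seg, palindromic = revcomp(seg),
                     reverse = reverse_dna(seg),
                     complement = complement_dna(seg),
                     stop("unknown dispersed kind: ", p$kind))
    a1 <- next_slot(p$length); a2 <- next_slot(p$length)
    chs[a1:(a1 + p$length - 1L)] <- strsplit(seg, "", fixed = TRUE)[[1]]
    chs[a2:(a2 + p$length - 1L)] <- strsplit(second, "", fixed = TRUE)[[1]]
    # flank blockers: A vs G mismatch under every orientation transform,
    # so the planted pair is maximal at exactly the recorded span
    chs[c(a1 - 1L, a1 + p$length)] <- "A"
    chs[c(a2 - 1L, a2 + p$length)] <- "G"
    truth_disp <- rbind(truth_disp,
                        data.frame(kind = p$kind, length = p$length,
                                   pos1 = a1, pos2 = a2))
  }

  # plant C-to-U editing sites: overwrite interior PCG codons with a
  # reference codon whose C->T change is nonsynonymous
  EDITABLE <- c("CCT", "CCA", "CCG", "CCC", "GCT", "GCA", "ACA", "ACT",
                "TCA", "CAT", "CTT", "CGG")
  truth_edits <- NULL
  if (cfg$n_edits > 0L) {
    hosts <- which(cls == "PCG" & strand == "+")
    capacity <- sum(len[hosts] %/% 3L - 2L)
    if (capacity < cfg$n_edits)
      stop("infeasible packing: not enough PCG codons for planted edits")
    slots <- do.call(rbind, lapply(hosts, function(i)
      data.frame(gi = i, codon = 2:(len[i] %/% 3L - 1L))))
    pick <- slots[sample.int(nrow(slots), cfg$n_edits), , drop = FALSE]
    code <- genetic_code_table(1L)
    for (r in seq_len(nrow(pick))) {
      i <- pick$gi[r]; ci <- pick$codon[r]
      ref <- sample(EDITABLE, 1L)
      cpos_opts <- which(strsplit(ref, "")[[1]] == "C")
      # keep only C positions whose C->T change is nonsynonymous, non-stop
      ok <- vapply(cpos_opts, function(p) {
        ed <- ref
        substring(ed, p, p) <- "T"
        code[ed] != "*" && code[ed] != code[ref]
      }, TRUE)
      cpos <- cpos_opts[ok][1L]
      ed <- ref
      substring(ed, cpos, cpos) <- "T"
      at <- starts[i] + 3L * (ci - 1L)
      chs[at:(at + 2L)] <- strsplit(ref, "", fixed = TRUE)[[1]]
      truth_edits <- rbind(truth_edits,
                           data.frame(gene = ord$name[i], codon_index = ci,
                                      codon_pos = cpos, ref_codon = ref,
                                      edited_codon = ed,
                                      ref_aa = unname(code[ref]),
                                      edited_aa = unname(code[ed])))
    }
  }

  feats <- lapply(seq_len(n_genes), function(i)
    gene_feature(ord$name[i], cls[i], strand[i],
                 matrix(c(starts[i], starts[i] + len[i] - 1L), ncol = 2L)))
  genome <- annotated_genome(cfg$id, paste(chs, collapse = ""), feats,
                             topology = "circular",
                             organelle = cfg$organelle, taxon = cfg$taxon)
  layout <- data.frame(name = ord$name, gene_class = cls, strand = strand,
                       start = starts, end = starts + len - 1L, length = len)
  truth <- list(layout = layout,
                overlaps = data.frame(geneA = ord$name[ov_j],
                                      geneB = ord$name[nxt[ov_j]],
                                      bp = ov_sizes),
                overlap_total = cfg$overlap_total,
                spacer_total = cfg$spacer_total,
                ssrs = truth_ssr, tandems = truth_tan,
                dispersed = truth_disp, edits = truth_edits)
  list(genome = genome, truth = truth)
}

#' Build a homolog protein panel encoding planted edits
#'
#' For each gene the panel members equal the genomic translation except
#' at planted editing sites, where each member independently carries
#' the edited amino acid with probability \code{agreement} (1 = a
#' noise-free panel). The panel consensus therefore encodes the edited
#' state at planted sites and the genomic state elsewhere, which is
#' exactly the signal the homology-guided predictor looks for.
#'
#' @param cds_set List of \code{coding_sequence} objects (one per gene).
#' @param edits Planted-edit table (the \code{truth$edits} of
#'   \code{\link{generate_genome}}).
#' @param n_homologs Panel size per gene (default 6).
#' @param agreement Probability a member carries the edited state
#'   (default 1.0).
#' @param seed Integer seed.
#' @return Named list gene -> character vector of aligned proteins.
#' @export
plant_edit_panel <- function(cds_set, edits, n_homologs = 6L,
                             agreement = 1.0, seed = 1L) {
  set.seed(seed)
  panels <- list()
  for (cds in cds_set) {
    aa <- sub("\\*$", "", cds$aa)
    aav <- strsplit(aa, "", fixed = TRUE)[[1]]
    ed <- if (is.null(edits)) NULL else edits[edits$gene == cds$gene, ,
                                              drop = FALSE]
    members <- vapply(seq_len(n_homologs), function(m) {
      v <- aav
      if (!is.null(ed) && nrow(ed)) {
        for (r in seq_len(nrow(ed))) {
          if (stats::runif(1) <= agreement)
            v[ed$codon_index[r]] <- ed$edited_aa[r]
        }
      }
      paste(v, collapse = "")
    }, "")
    names(members) <- sprintf("%s_hom%02d", cds$gene, seq_len(n_homologs))
    panels[[cds$gene]] <- members
  }
  panels
}

#' Generate a clade-structured genome panel with planted substitutions
#'
#' Descends every taxon from one ancestor genome (built by
#' \code{\link{generate_genome}}) and plants single-base substitutions
#' in plus-strand PCG codons with exact control of effect and
#' diagnostic scope: synonymous sites are changed at 4-fold third
#' positions, nonsynonymous sites at 0-fold positions (checked against
#' \code{\link{classify_degeneracy}}), each in its own codon. A
#' substitution is applied to every member of its target group, so the
#' site is monomorphic inside the group and the derived allele is
#' absent outside it (diagnostic by construction).
#'
#' @param groups Named list group -> character vector of species names.
#' @param n_sites Named list group -> c(syn =, nonsyn =) site counts;
#'   names may also be single species for species-level private sites.
#' @param genome_cfg A \code{\link{sim_config}} for the ancestor.
#' @param subgenus_of Optional named vector species -> subgenus label
#'   used in each genome's taxon label.
#' @param section_of Optional named vector species -> section label.
#' @param seed Integer seed.
#' @return List with \code{genomes} (named list of
#'   \code{annotated_genome}), \code{ancestor}, \code{truth}
#'   (per-site table with gene, codon, position, genomic position,
#'   group, effect, ancestral and derived alleles).
#' @export
generate_clade_panel <- function(groups, n_sites,
                                 genome_cfg = sim_config(),
                                 subgenus_of = NULL, section_of = NULL,
                                 seed = 1L) {
  stopifnot(length(groups) >= 1L, all(names(n_sites) != ""))
  anc <- generate_genome(genome_cfg)
  set.seed(seed + 1L)
  species <- unique(unlist(groups))
  membership <- function(key) {
    if (key %in% names(groups)) groups[[key]]
    else if (key %in% species) key
    else stop("unknown group or species: ", key)
  }
  layout <- anc$truth$layout
  hosts <- layout[layout$gene_class == "PCG" & layout$strand == "+", ,
                  drop = FALSE]
  code <- genetic_code_table(1L)
  # pool of unused (gene, codon) slots, interior codons only
  pool <- do.call(rbind, lapply(seq_len(nrow(hosts)), function(i)
    data.frame(gene = hosts$name[i], start = hosts$start[i],
               codon = 2:((hosts$length[i] %/% 3L) - 1L))))
  pool <- pool[sample.int(nrow(pool)), , drop = FALSE]
  used <- 0L
  anc_ch <- strsplit(anc$genome$sequence, "", fixed = TRUE)[[1]]
  seqs <- stats::setNames(lapply(species, function(s) anc_ch), species)
  truth <- NULL
  plant_one <- function(target, effect) {
    repeat {
      used <<- used + 1L
      if (used > nrow(pool))
        stop("substitution budget exceeds panel capacity")
      gene <- pool$gene[used]; ci <- pool$codon[used]
      at <- pool$start[used] + 3L * (ci - 1L)
      cod <- paste(anc_ch[at:(at + 2L)], collapse = "")
      if (effect == "synonymous") {
        if (classify_degeneracy(cod, 3L) != 4L) next
        p <- 3L
        alt <- setdiff(c("A", "C", "G", "T"), substring(cod, p, p))[1L]
      } else {
        p <- which(vapply(1:3, function(q)
          classify_degeneracy(cod, q) == 0L, TRUE))[1L]
        if (is.na(p)) next
        alts <- setdiff(c("A", "C", "G", "T"), substring(cod, p, p))
        ok <- vapply(alts, function(b) {
          v <- cod
          substring(v, p, p) <- b
          code[v] != "*" && code[v] != code[cod]
        }, TRUE)
        if (!any(ok)) next
        alt <- alts[ok][1L]
      }
      pos <- at + p - 1L
      for (s in membership(target)) seqs[[s]][pos] <<- alt
      truth <<- rbind(truth,
                      data.frame(gene = gene, codon_index = ci,
                                 codon_pos = p, position = pos,
                                 group = target, effect = effect,
                                 ancestral = substring(cod, p, p),
                                 derived = alt))
      return(invisible(NULL))
    }
  }
  for (key in names(n_sites)) {
    ns <- n_sites[[key]]
    for (k in seq_len(ns[["syn"]])) plant_one(key, "synonymous")
    for (k in seq_len(ns[["nonsyn"]])) plant_one(key, "nonsynonymous")
  }
  grp_of <- stats::setNames(rep(names(groups), lengths(groups)),
                            unlist(groups))
  genomes <- lapply(species, function(s) {
    tx <- taxon_label(s, genus = "Synthetica", family = "Sargassaceae",
                      order = "Fucales",
                      subgenus = if (!is.null(subgenus_of))
                        subgenus_of[[s]] else unname(grp_of[s]),
                      section = if (!is.null(section_of))
                        section_of[[s]] else "")
    annotated_genome(gsub("[^A-Za-z0-9]", "_", s),
                     paste(seqs[[s]], collapse = ""),
                     anc$genome$features, topology = "circular",
                     organelle = anc$genome$organelle, taxon = tx)
  })
  names(genomes) <- species
  list(genomes = genomes, ancestor = anc, truth = truth)
}

#' Extract a per-gene CDS panel from a list of genomes
#'
#' Convenience bridge from a genome panel to the ortholog-alignment and
#' Ka/Ks interfaces.
#'
#' @param genomes Named list of \code{annotated_genome} (names = taxa).
#' @param gene_class Feature class (default \code{"PCG"}).
#' @return Named list gene -> named character vector of CDS per taxon.
#' @export
cds_panel <- function(genomes, gene_class = "PCG") {
  per_tax <- lapply(genomes, extract_cds, gene_class = gene_class)
  genes <- sort(unique(unlist(lapply(per_tax, function(x)
    vapply(x, `[[`, "", "gene")))))
  out <- list()
  for (g in genes) {
    v <- character()
    for (tx in names(per_tax)) {
      hit <- Filter(function(c) c$gene == g, per_tax[[tx]])
      if (length(hit)) v[tx] <- hit[[1]]$nt
    }
    out[[g]] <- v
  }
  out
}

#' Simulate a diverged coding-sequence pair with controlled dN/dS
#'
#' Plants substitutions on a random ancestral CDS in the site units of
#' the counting estimators: synonymous changes at 4-fold third
#' positions, nonsynonymous changes at 0-fold positions (each validated
#' against \code{\link{classify_degeneracy}}, at most one substitution
#' per codon), with counts \code{round(ks * S)} and
#' \code{round(omega * ks * N)} over the LWL-style site totals
#' S = L4 + L2/3 and N = L0 + 2 L2/3 of the ancestor. The planted
#' dN/dS is therefore \code{omega} by construction in exactly the units
#' the estimator reports. The default divergence (\code{ks} = 0.04) is
#' in the congeneric organellar range, where multiple-hit corrections
#' perturb the ratio by under ~3 percent.
#'
#' @param n_codons Number of codons.
#' @param omega Target dN/dS.
#' @param ks Target synonymous divergence (substitutions per
#'   synonymous site).
#' @param seed Integer seed.
#' @return List with \code{a}, \code{b} (in-frame DNA strings),
#'   \code{n_syn}, \code{n_nonsyn}, \code{S}, \code{N} (planted counts
#'   and site totals).
#' @export
simulate_kaks_pair <- function(n_codons = 500L, omega = 1, ks = 0.04,
                               seed = 1L) {
  set.seed(seed)
  code <- genetic_code_table(1L)
  sense <- names(code)[code != "*"]
  cods <- sample(sense, n_codons, replace = TRUE)
  cls <- vapply(cods, function(cd)
    vapply(1:3, function(p) classify_degeneracy(cd, p), 0L),
    integer(3))
  S <- sum(cls == 4L) + sum(cls == 2L) / 3
  N <- sum(cls == 0L) + 2 * sum(cls == 2L) / 3
  n_syn <- round(ks * S)
  n_nonsyn <- round(omega * ks * N)
  if (n_syn + n_nonsyn > n_codons)
    stop("requested divergence exceeds one substitution per codon")
  slots <- sample.int(n_codons)
  b <- cods
  take <- 0L
  plant <- function(effect) {
    repeat {
      take <<- take + 1L
      if (take > n_codons) stop("ran out of codons while planting")
      i <- slots[take]
      cd <- cods[i]
      if (effect == "syn") {
        p <- which(cls[, i] == 4L)
        if (!length(p)) next
        p <- p[1L]
        alt <- sample(setdiff(c("A", "C", "G", "T"),
                              substring(cd, p, p)), 1L)
      } else {
        p <- which(cls[, i] == 0L)
        if (!length(p)) next
        p <- p[1L]
        alts <- setdiff(c("A", "C", "G", "T"), substring(cd, p, p))
        ok <- vapply(alts, function(bb) {
          v <- cd
          substring(v, p, p) <- bb
          code[v] != "*" && code[v] != code[cd]
        }, TRUE)
        if (!any(ok)) next
        alt <- sample(rep(alts[ok], 2L), 1L)
      }
      v <- cd
      substring(v, p, p) <- alt
      b[i] <<- v
      return(invisible(NULL))
    }
  }
  for (k in seq_len(n_syn)) plant("syn")
  for (k in seq_len(n_nonsyn)) plant("nonsyn")
  list(a = paste(cods, collapse = ""), b = paste(b, collapse = ""),
       n_syn = n_syn, n_nonsyn = n_nonsyn, S = S, N = N)
}
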