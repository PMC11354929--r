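# Pipeline orchestration: runs the requested stages in dependency order
# over one genome (plus an optional genome panel), writes per-stage TSV
# reports, a JSON manifest with the parameters used, and a log.

#' Run the comparative-analysis pipeline
#'
#' Executes the requested stages over one annotated genome and,
#' when a panel is supplied, the panel-level stages:
#' \code{summary} (architecture), \code{codon} (usage suite),
#' \code{repeats} (SSR / tandem / dispersed census), \code{editing}
#' (needs a homolog panel), \code{snps} and \code{kaks} (need a genome
#' panel), \code{tree} (neighbor joining over the panel supermatrix).
#' Every stage writes a TSV under \code{out_dir}; a \code{manifest.json}
#' records parameters and package version. Outputs are deterministic
#' for fixed inputs.
#'
#' @param genome An \code{\link{annotated_genome}} (or a GenBank path).
#' @param out_dir Output directory (created if absent).
#' @param stages Character vector of stage names (default: all runnable
#'   with the supplied inputs).
#' @param panel Optional named list of \code{annotated_genome} objects
#'   (a taxon panel including the focal genome) for SNP/Ka-Ks/tree
#'   stages.
#' @param homologs Optional named list gene -> aligned protein panel
#'   for the editing stage.
#' @param reference_taxon Reference taxon for the Ka/Ks matrix
#'   (defaults to the focal genome's taxon species).
#' @param params List of stage parameters: \code{edit_threshold},
#'   \code{ssr_thresholds}, \code{tandem_match_prob},
#'   \code{dispersed_min_len}, \code{kaks_method}.
#' @return Invisibly, a named list of per-stage result objects.
#' @export
run_pipeline <- function(genome, out_dir, stages = NULL, panel = NULL,
                         homologs = NULL, reference_taxon = NULL,
                         params = list()) {
  if (is.character(genome)) genome <- read_genbank(genome)
  stopifnot(inherits(genome, "annotated_genome"))
  p <- utils::modifyList(list(edit_threshold = 0.8,
                              ssr_thresholds = ssr_default_thresholds(),
                              tandem_match_prob = 0.80,
                              dispersed_min_len = 30L,
                              kaks_method = "MLWL"), params)
  if (is.null(stages)) {
    stages <- c("summary", "codon", "repeats")
    if (!is.null(homologs)) stages <- c(stages, "editing")
    if (!is.null(panel)) stages <- c(stages, "snps", "kaks", "tree")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "pipeline.log")
  logline <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", file = logfile, append = TRUE, sep = "")
    message(msg)
  }
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  results <- list()

  if ("summary" %in% stages) {
    logline("stage summary: genome ", genome$id)
    sm <- summarize_genome(genome)
    results$summary <- sm
    tsv(data.frame(genome_id = sm$genome_id, length = sm$length,
                   gc = sm$gc, pcg_fraction = sm$pcg_fraction,
                   overlap_total = sm$overlap_total,
                   spacer_total = sm$spacer_total,
                   t(as.matrix(sm$counts))), "genome_summary.tsv")
    tsv(sm$overlap_pairs, "gene_overlaps.tsv")
  }

  cds <- extract_cds(genome, "PCG")
  cds_ok <- Filter(function(x) !x$incomplete && !x$internal_stop, cds)

  if ("codon" %in% stages) {
    logline("stage codon: ", length(cds_ok), " PCGs")
    pooled <- count_codons(cds_ok)
    r <- rscu(pooled)
    encs <- lapply(cds_ok, function(x) suppressMessages(enc(x)))
    enc_df <- data.frame(
      gene = vapply(encs, `[[`, "", "gene"),
      enc = vapply(encs, `[[`, 0, "enc"),
      gc3 = vapply(encs, `[[`, 0, "gc3"),
      n_codons = vapply(encs, `[[`, 0L, "n_codons"))
    pgs <- lapply(cds_ok, positional_gc)
    nf <- neutrality_fit(list(
      gc3 = vapply(pgs, `[[`, 0, "gc3"),
      gc12 = vapply(pgs, `[[`, 0, "gc12")))
    results$codon <- list(usage = pooled, rscu = r, enc = enc_df,
                          neutrality = nf)
    tsv(data.frame(codon = names(pooled$counts),
                   count = as.integer(pooled$counts), rscu = unname(r)),
        "codon_usage.tsv")
    tsv(enc_df, "enc.tsv")
    tsv(data.frame(slope = nf$slope, intercept = nf$intercept, r = nf$r,
                   n = nf$n), "neutrality.tsv")
    if (length(cds_ok) >= 10L) {
      oc <- optimal_codons(cds_ok)
      results$codon$optimal <- oc
      tsv(data.frame(codon = names(oc$delta_rscu),
                     rscu_high = unname(oc$rscu_high),
                     rscu_low = unname(oc$rscu_low),
                     delta_rscu = unname(oc$delta_rscu),
                     optimal = names(oc$delta_rscu) %in% oc$optimal),
          "optimal_codons.tsv")
    }
  }

  if ("repeats" %in% stages) {
    logline("stage repeats")
    circ <- genome$topology == "circular"
    ssrs <- find_ssrs(genome$sequence, thresholds = p$ssr_thresholds,
                      circular = circ)
    tans <- find_tandem(genome$sequence, match_prob = p$tandem_match_prob)
    disp <- find_dispersed(genome$sequence, min_len = p$dispersed_min_len)
    results$repeats <- list(ssrs = ssrs, tandems = tans, dispersed = disp)
    tsv(ssrs, "ssrs.tsv"); tsv(tans, "tandem_repeats.tsv")
    tsv(disp, "dispersed_repeats.tsv")
  }

  if ("editing" %in% stages) {
    if (is.null(homologs)) stop("editing stage needs a homolog panel")
    logline("stage editing: threshold ", p$edit_threshold)
    sites <- list()
    for (x in cds_ok) {
      if (!x$gene %in% names(homologs)) next
      sites <- c(sites, predict_edits(x, homologs[[x$gene]],
                                      threshold = p$edit_threshold))
    }
    results$editing <- sites
    if (length(sites)) {
      es <- summarize_edits(sites, genome$length)
      results$edit_summary <- es
      write_edit_reports(sites, es, file.path(out_dir, "edit_sites.tsv"),
                         file.path(out_dir, "edit_summary.tsv"))
    } else {
      logline("stage editing: no sites predicted")
    }
  }

  if (any(c("snps", "kaks", "tree") %in% stages)) {
    if (is.null(panel)) stop("snps/kaks/tree stages need a genome panel")
    pan <- cds_panel(panel)
    alns <- lapply(names(pan), function(g) {
      if (length(pan[[g]]) < 2L) return(NULL)
      align_orthologs(pan[[g]], gene = g)
    })
    alns <- Filter(Negate(is.null), alns)
    if ("snps" %in% stages) {
      logline("stage snps: ", length(alns), " genes")
      snps <- combine_snps(lapply(alns, call_snps))
      results$snps <- snps
      tsv(data.frame(gene = snps$gene, column = snps$column,
                     effect = snps$effect), "snp_sites.tsv")
      tsv(per_gene_snp_density(snps), "snp_density.tsv")
    }
    if ("kaks" %in% stages) {
      ref <- reference_taxon
      if (is.null(ref))
        ref <- if (!is.null(genome$taxon)) genome$taxon$species
          else names(panel)[1L]
      logline("stage kaks: reference ", ref, " [", p$kaks_method, "]")
      km <- kaks_matrix(lapply(alns, function(a) a$seqs) |>
                          stats::setNames(vapply(alns, `[[`, "", "gene")),
                        reference_taxon = ref, method = p$kaks_method)
      results$kaks <- km
      out <- as.data.frame(km$ratio)
      out <- cbind(gene = rownames(out), out)
      tsv(out, "kaks_ratio.tsv")
    }
    if ("tree" %in% stages) {
      logline("stage tree: neighbor joining")
      sm <- concat_shared_pcgs(lapply(alns, function(a) a$seqs) |>
                                 stats::setNames(vapply(alns, `[[`, "",
                                                        "gene")))
      tr <- nj_tree(p_distance(sm))
      results$tree <- tr
      write_newick(tr, file.path(out_dir, "nj_tree.nwk"))
    }
  }

  manifest <- list(
    package = "organellr",
    version = as.character(utils::packageVersion("organellr")),
    genome_id = genome$id, genome_length = genome$length,
    stages = stages,
    parameters = p[vapply(p, function(x)
      is.numeric(x) || is.character(x), TRUE)])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logline("pipeline complete: ", length(stages), " stages -> ", out_dir)
  invisible(results)
}
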