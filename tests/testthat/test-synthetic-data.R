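test_that("the generator is fully deterministic under the seed", {
  cfg <- sim_config(seed = 61, counts = c(PCG = 4L, tRNA = 3L, rRNA = 1L,
                                          ORF = 1L),
                    pcg_aa_total = 400L, rrna_lens = 150L, orf_aa = 40L,
                    overlap_total = 12L, n_overlaps = 2L,
                    spacer_total = 250L, n_edits = 4L)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$genome$sequence, g2$genome$sequence)
  expect_identical(g1$truth, g2$truth)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_genbank(g1$genome, f1)
  write_genbank(g2$genome, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical output
  # a different seed changes the sequence
  g3 <- generate_genome(sim_config(seed = 62, counts = cfg$counts,
                                   pcg_aa_total = 400L, rrna_lens = 150L,
                                   orf_aa = 40L, overlap_total = 12L,
                                   n_overlaps = 2L, spacer_total = 250L))
  expect_false(identical(g1$genome$sequence, g3$genome$sequence))
})

test_that("the default world mirrors the compact-mitogenome layout", {
  g <- generate_genome(sim_config(seed = 9))
  sm <- summarize_genome(g$genome)
  expect_equal(g$genome$length, 34686L)
  expect_equal(unname(sm$counts[c("PCG", "tRNA", "rRNA", "ORF")]),
               c(35L, 25L, 3L, 2L))
  expect_equal(sm$overlap_total, 188L)
  expect_equal(nrow(sm$overlap_pairs), 12L)
  expect_equal(sm$spacer_total, 1597L)
  cds <- extract_cds(g$genome)
  expect_equal(sum(vapply(cds, function(x) nchar(x$aa) - 1L, 0L)), 8780L)
  expect_equal(count_codons(cds)$n_codons, 8780L)
  # every CDS is clean: ATG start, single terminal stop
  expect_false(any(vapply(cds, `[[`, TRUE, "non_atg_start")))
  expect_false(any(vapply(cds, `[[`, TRUE, "internal_stop")))
  # light-chain genes really are on the minus strand
  strands <- setNames(vapply(g$genome$features, `[[`, "", "strand"),
                      vapply(g$genome$features, `[[`, "", "name"))
  expect_true(all(strands[c("rpl2", "rpl16", "rps3", "rps19", "tatC")] == "-"))
})

test_that("zero planted repeats means no dispersed hits in small genomes", {
  cfg <- sim_config(seed = 71, counts = c(PCG = 2L, tRNA = 1L, rRNA = 1L,
                                          ORF = 0L),
                    pcg_aa_total = 350L, rrna_lens = 200L,
                    overlap_total = 0L, n_overlaps = 0L,
                    spacer_total = 400L)
  g <- generate_genome(cfg)
  expect_lte(g$genome$length, 2500L)
  expect_equal(nrow(find_dispersed(g$genome$sequence)), 0L)
  ss <- find_ssrs(g$genome$sequence)
  # chance SSRs are possible but must not sit at unplanted "truth" spots
  expect_null(g$truth$ssrs)
})

test_that("infeasible packings fail before emission", {
  base <- function(...) sim_config(
    seed = 1, counts = c(PCG = 2L, tRNA = 1L, rRNA = 1L, ORF = 0L),
    pcg_aa_total = 100L, rrna_lens = 80L, overlap_total = 0L,
    n_overlaps = 0L, spacer_total = 50L, ...)
  expect_error(generate_genome(base(
    dispersed = list(list(kind = "forward", length = 400L)))),
    "infeasible")
  expect_error(generate_genome(sim_config(
    seed = 1, counts = c(PCG = 2L, tRNA = 1L, rRNA = 1L, ORF = 0L),
    pcg_aa_total = 100L, rrna_lens = 80L, overlap_total = 100L,
    n_overlaps = 20L, spacer_total = 50L)), "infeasible")
  expect_error(generate_clade_panel(
    list(G = c("s1", "s2")), n_sites = list(G = c(syn = 5000, nonsyn = 0)),
    genome_cfg = base(), seed = 1), "capacity|codons")
})

test_that("edit-panel agreement is monotone in recovered fraction", {
  g <- generate_genome(sim_config(
    seed = 83, counts = c(PCG = 4L, tRNA = 2L, rRNA = 1L, ORF = 0L),
    pcg_aa_total = 900L, rrna_lens = 150L, overlap_total = 0L,
    n_overlaps = 0L, spacer_total = 200L, n_edits = 30L))
  cds <- extract_cds(g$genome)
  recov <- vapply(c(0.5, 0.85, 1.0), function(agree) {
    n <- 0L
    panel <- plant_edit_panel(cds, g$truth$edits, n_homologs = 20L,
                              agreement = agree, seed = 13)
    for (x in cds)
      n <- n + length(predict_edits(x, panel[[x$gene]], threshold = 0.8))
    n
  }, 0L)
  expect_true(all(diff(recov) >= 0L))
  expect_equal(recov[3], 30L)
  expect_lt(recov[1], 30L)
  # zero planted edits -> zero predictions
  panel0 <- plant_edit_panel(cds, NULL, seed = 13)
  expect_length(predict_edits(cds[[1]], panel0[[cds[[1]]$gene]]), 0L)
})
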