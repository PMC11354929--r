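test_that("edit sites validate the single-position C-to-T invariant", {
  s <- edit_site("g", 5, 1, "CCT", "TCT")
  expect_identical(s$ref_aa, "P")
  expect_identical(s$edited_aa, "S")
  expect_error(edit_site("g", 5, 1, "CCT", "GCT"), "C->T")
  expect_error(edit_site("g", 5, 1, "CCT", "TTT"), "single")
  expect_error(edit_site("g", 5, 3, "CTC", "CTT"), "synonymous")
})

test_that("classification reproduces the pinned category table", {
  expect_identical(classify_edit(edit_site("g", 1, 2, "ACA", "ATA")),
                   "became-hydrophobic")
  expect_identical(classify_edit(edit_site("g", 1, 1, "CCT", "TCT")),
                   "became-hydrophilic")
  expect_identical(classify_edit(edit_site("g", 1, 1, "CTT", "TTT")),
                   "unchanged-hydrophobic")
  expect_identical(classify_edit(edit_site("g", 1, 1, "CAT", "TAT")),
                   "unchanged-hydrophilic")
  # the two deliberately pinned arginine quirks
  expect_identical(classify_edit(edit_site("g", 1, 1, "CGG", "TGG")),
                   "unchanged-hydrophobic")
  expect_identical(classify_edit(edit_site("g", 1, 1, "CGC", "TGC")),
                   "unchanged-hydrophilic")
  # pairs outside the table fall back to Kyte-Doolittle and are flagged.
  # Under the standard code every nonsynonymous C->T pair is pinned, so
  # the fallback is exercised through the internal classifier directly.
  expect_false(edit_site("g", 1, 2, "GCG", "GTG")$extrapolated)  # A->V pinned
  fb <- organellr:::classify_aa_change("Q", "L")
  expect_true(fb$extrapolated)
  expect_identical(fb$category, "became-hydrophobic")
  fb2 <- organellr:::classify_aa_change("I", "V")
  expect_identical(fb2$category, "unchanged-hydrophobic")
})

test_that("prediction recovers planted edits and nothing else", {
  g <- generate_genome(sim_config(
    seed = 17, counts = c(PCG = 6L, tRNA = 3L, rRNA = 1L, ORF = 0L),
    pcg_aa_total = 1200L, rrna_lens = 200L, overlap_total = 0L,
    n_overlaps = 0L, spacer_total = 300L, n_edits = 25L))
  cds <- extract_cds(g$genome)
  panel <- plant_edit_panel(cds, g$truth$edits, agreement = 1, seed = 3)
  found <- list()
  for (x in cds)
    found <- c(found, predict_edits(x, panel[[x$gene]], threshold = 0.8))
  key <- function(df) paste(df$gene, df$codon_index, df$codon_pos)
  found_df <- data.frame(gene = vapply(found, `[[`, "", "gene"),
                         codon_index = vapply(found, `[[`, 0L, "codon_index"),
                         codon_pos = vapply(found, `[[`, 0L, "codon_pos"))
  expect_setequal(key(found_df), key(g$truth$edits))   # sens = prec = 1
  expect_true(all(vapply(found, `[[`, 0, "support") == 1))
  # every prediction is a single-position C->T (asserted by construction)
  for (s in found) {
    d <- which(strsplit(s$ref_codon, "")[[1]] != strsplit(s$edited_codon, "")[[1]])
    expect_length(d, 1L)
    expect_identical(substring(s$ref_codon, d, d), "C")
  }
  # identical panel -> zero predictions
  clean <- plant_edit_panel(cds, NULL, seed = 3)
  expect_length(predict_edits(cds[[1]], clean[[cds[[1]]$gene]]), 0L)
})

test_that("raising the threshold never increases predictions; noise keeps sensitivity", {
  g <- generate_genome(sim_config(
    seed = 23, counts = c(PCG = 4L, tRNA = 2L, rRNA = 1L, ORF = 0L),
    pcg_aa_total = 800L, rrna_lens = 150L, overlap_total = 0L,
    n_overlaps = 0L, spacer_total = 200L, n_edits = 15L))
  cds <- extract_cds(g$genome)
  count_at <- function(panel, thr) {
    n <- 0L
    for (x in cds)
      n <- n + length(predict_edits(x, panel[[x$gene]], threshold = thr))
    n
  }
  for (agree in c(1, 0.9)) {
    panel <- plant_edit_panel(cds, g$truth$edits, n_homologs = 10L,
                              agreement = agree, seed = 9)
    counts <- vapply(c(0.6, 0.7, 0.8, 0.9, 1.0), function(t)
      count_at(panel, t), 0L)
    expect_true(all(diff(counts) <= 0L))
  }
  # panel disagreement below 1 - threshold keeps sensitivity at 1
  panel2 <- plant_edit_panel(cds, g$truth$edits, n_homologs = 40L,
                             agreement = 0.95, seed = 11)
  expect_equal(count_at(panel2, 0.8), nrow(g$truth$edits))
})

test_that("summaries reproduce printed-table arithmetic and densities", {
  sites <- list(edit_site("a", 2, 1, "CAT", "TAT"),
                edit_site("a", 9, 2, "GCT", "GTT"),
                edit_site("b", 4, 2, "ACA", "ATA"),
                edit_site("b", 7, 1, "CCT", "TCT"))
  es <- summarize_edits(sites, genome_length = 10000)
  expect_equal(es$n, 4L)
  expect_equal(sum(es$category_pct), 100, tolerance = 0.01)
  expect_equal(unname(es$position_counts), c(2L, 2L, 0L))
  expect_equal(es$density_pct, 0.04)
  expect_equal(unname(es$gene_counts[c("a", "b")]), c(2L, 2L))
  expect_error(summarize_edits(sites, 0), "positive")
  # the data.frame (printed-table) interface agrees with the site list
  df <- data.frame(ref_codon = c("CAT", "GCT", "ACA", "CCT"),
                   edited_codon = c("TAT", "GTT", "ATA", "TCT"),
                   count = c(1L, 1L, 1L, 1L))
  es2 <- summarize_edits(df, genome_length = 10000)
  expect_equal(es2$category_counts, es$category_counts)
  expect_equal(es2$position_counts, es$position_counts)
})
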