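test_that("ortholog alignment handles identity, SNPs and in-frame indels", {
  a <- random_cds_fixture(60, seed = 1)$nt
  expect_equal(nchar(align_orthologs(list(t1 = a, t2 = a))$seqs[["t1"]]),
               nchar(a) - 3L)   # terminal stop stripped
  # equal-length pair with 3 substitutions: 3 variable columns
  b <- a
  for (p in c(10L, 25L, 40L)) {
    alt <- setdiff(c("A", "C", "G", "T"), substring(b, p, p))[1]
    substring(b, p, p) <- alt
  }
  aln <- align_orthologs(list(t1 = a, t2 = b))
  snps <- call_snps(aln)
  expect_lte(length(snps$column), 3L)
  expect_gte(length(snps$column), 1L)
  # planted codon insertion: gap placed in-frame
  ins <- paste0(substring(a, 1, 30), "GGA", substring(a, 31))
  aln2 <- align_orthologs(list(t1 = a, t2 = ins))
  expect_equal(nchar(aln2$seqs[["t1"]]) %% 3L, 0L)
  expect_true(grepl("---", aln2$seqs[["t1"]], fixed = TRUE))
  expect_equal(nchar(aln2$seqs[["t1"]]), nchar(aln2$seqs[["t2"]]))
  # mis-orthology guard
  c2 <- random_cds_fixture(60, seed = 99)$nt
  expect_error(align_orthologs(list(t1 = a, t2 = c2)), "identity")
})

test_that("SNP effects follow the majority-codon substitution rule", {
  # GGA vs GGC at a 4-fold third position: synonymous
  aln <- structure(list(gene = "toy", taxa = c("t1", "t2"),
                        seqs = c(t1 = "ATGGGA", t2 = "ATGGGC")),
                   class = "ortholog_alignment")
  s <- call_snps(aln)
  expect_equal(length(s$column), 1L)
  expect_identical(s$effect, "synonymous")
  # AAA vs GAA at codon position 1: K -> E nonsynonymous
  aln2 <- structure(list(gene = "toy", taxa = c("t1", "t2"),
                         seqs = c(t1 = "ATGAAA", t2 = "ATGGAA")),
                    class = "ortholog_alignment")
  expect_identical(call_snps(aln2)$effect, "nonsynonymous")
  # gapped columns are excluded from SNP calling
  aln3 <- structure(list(gene = "toy", taxa = c("t1", "t2"),
                         seqs = c(t1 = "ATG---GAA", t2 = "ATGCCTTAA")),
                    class = "ortholog_alignment")
  expect_false(any(call_snps(aln3)$column %in% 4:6))
  # syn + nonsyn partition every site
  for (s in 1:5) {
    al <- random_alignment(6, 40, seed = 500 + s)
    sn <- call_snps(al)
    expect_true(all(sn$effect %in% c("synonymous", "nonsynonymous")))
  }
})

test_that("diagnostic sites equal the exhaustive oracle and respect groups", {
  # hand cases from the worked examples
  mk_snps <- function(rows, taxa) {
    alleles <- do.call(rbind, rows)
    colnames(alleles) <- taxa
    structure(list(gene = rep("g", nrow(alleles)), taxa = taxa,
                   column = seq_len(nrow(alleles)),
                   effect = rep("synonymous", nrow(alleles)),
                   alleles = alleles, aln_length = 100L),
              class = "snp_table")
  }
  taxa <- c("A", "B", "C", "D")
  snps <- mk_snps(list(c("T", "T", "C", "C"), c("T", "C", "C", "C")), taxa)
  grouping <- c(A = "G1", B = "G1", C = "G2", D = "G2")
  expect_equal(diagnostic_sites(snps, grouping, "G1")$index, 1L)
  expect_equal(diagnostic_sites(snps, grouping, "G2")$index, 1L)
  # singleton species-level identification: site 1 is shared with B, so
  # only site 2 (private T) identifies A from a single sequence
  gsp <- c(A = "A", B = "rest", C = "rest", D = "rest")
  expect_equal(diagnostic_sites(snps, gsp, "A")$index, 2L)
  expect_error(diagnostic_sites(snps, grouping, "G9"), "empty")
  # oracle equivalence on random panels
  for (s in 1:20) {
    al <- random_alignment(6, 17, seed = 700 + s, p_var = 0.3)
    sn <- call_snps(al)
    if (!length(sn$column)) next
    grp <- setNames(sample(c("X", "Y", "Z"), 6, replace = TRUE), al$taxa)
    for (g in unique(grp))
      expect_equal(diagnostic_sites(sn, grp, g)$index,
                   oracle_diagnostic(sn, grp, g),
                   label = paste("seed", s, "group", g))
  }
})

test_that("taxon input order never changes any result", {
  pan <- lapply(1:6, function(i) {
    x <- random_cds_fixture(50, seed = 42)$nt
    if (i > 1) {
      p <- 6L + 3L * i
      alt <- setdiff(c("A", "C", "G", "T"), substring(x, p, p))[1]
      substring(x, p, p) <- alt
    }
    x
  })
  names(pan) <- sprintf("t%d", 1:6)
  s1 <- call_snps(align_orthologs(pan))
  s2 <- call_snps(align_orthologs(rev(pan)))
  expect_identical(s1$column, s2$column)
  expect_identical(s1$effect, s2$effect)
  expect_identical(s1$alleles, s2$alleles)
})

test_that("clade panels recover the planted site structure exactly", {
  groups <- list(G1 = sprintf("a%02d", 1:4), G2 = sprintf("b%02d", 1:4))
  pan <- generate_clade_panel(groups,
    n_sites = list(G1 = c(syn = 12, nonsyn = 9),
                   G2 = c(syn = 11, nonsyn = 8),
                   a01 = c(syn = 5, nonsyn = 2)),
    genome_cfg = sim_config(seed = 19,
                            counts = c(PCG = 6L, tRNA = 3L, rRNA = 1L,
                                       ORF = 0L),
                            pcg_aa_total = 1500L, rrna_lens = 200L,
                            overlap_total = 0L, n_overlaps = 0L,
                            spacer_total = 300L),
    seed = 19)
  cp <- cds_panel(pan$genomes)
  snps <- combine_snps(lapply(names(cp), function(g)
    call_snps(align_orthologs(cp[[g]], gene = g))))
  expect_equal(length(snps$column), nrow(pan$truth))
  expect_equal(sum(snps$effect == "nonsynonymous"),
               sum(pan$truth$effect == "nonsynonymous"))
  grouping <- setNames(rep(names(groups), lengths(groups)), unlist(groups))
  # species-private sites diagnose only their species
  gsp <- setNames(unlist(groups), unlist(groups))
  # exactly the 7 private sites: clade-wide sites are shared with a02-a04
  da <- diagnostic_sites(snps, gsp, "a01")
  expect_equal(length(da$index), 7L)
  expect_equal(da$n_synonymous, 5L)
  expect_equal(da$n_nonsynonymous, 2L)
  # density ranking: gene with most planted sites ranks first
  dens <- per_gene_snp_density(snps)
  top_truth <- names(sort(table(pan$truth$gene), decreasing = TRUE))[1]
  expect_identical(dens$gene[1], top_truth)
  expect_equal(sum(dens$share), 1)
})
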