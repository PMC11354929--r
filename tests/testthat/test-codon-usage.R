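test_that("codon counting is additive and separates stops", {
  cs <- coding_sequence("ATGTGGTAA")
  tab <- count_codons(cs)
  expect_equal(unname(tab$counts["ATG"]), 1L)
  expect_equal(unname(tab$counts["TGG"]), 1L)
  expect_equal(tab$n_codons, 2L)
  expect_equal(unname(tab$stop_counts["TAA"]), 1L)
  # concatenation invariance
  a <- random_cds_fixture(40, seed = 1, gene = "a")
  b <- random_cds_fixture(60, seed = 2, gene = "b")
  both <- count_codons(list(a, b))
  expect_equal(both$counts, count_codons(a)$counts + count_codons(b)$counts)
  # ambiguous codons dropped with a message
  expect_message(tabn <- count_codons("ATGNNNGGG"), "dropped")
  expect_equal(tabn$n_codons, 2L)
})

test_that("RSCU obeys the family normalization and the direct formula", {
  # Leu counts {TTA: 3, TTG: 1} -> RSCU(TTA) = 3/(4/6) = 4.5
  cs <- coding_sequence(paste(c("ATG", rep("TTA", 3), "TTG", "TAA"),
                              collapse = ""))
  r <- rscu(count_codons(cs))
  expect_equal(unname(r["TTA"]), 4.5)
  expect_equal(unname(r["TTG"]), 1.5)
  expect_equal(unname(r["ATG"]), 1)          # single-codon family
  expect_true(is.na(r["GGA"]))               # unobserved family is missing
  # uniform 4-fold usage -> all RSCU 1
  cs2 <- coding_sequence(paste(c("ATG", "GGA", "GGC", "GGG", "GGT", "TAA"),
                               collapse = ""))
  expect_equal(unname(rscu(count_codons(cs2))[c("GGA", "GGC", "GGG", "GGT")]),
               rep(1, 4))
  # sum over each observed family equals family size, across random inputs
  fams <- split(names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"],
                Biostrings::GENETIC_CODE[Biostrings::GENETIC_CODE != "*"])
  names(fams) <- NULL
  for (s in 1:10) {
    r2 <- rscu(count_codons(random_cds_fixture(300, seed = 100 + s)))
    for (f in fams) {
      f <- chartr("U", "T", f)
      if (all(!is.na(r2[f])))
        expect_equal(sum(r2[f]), length(f), tolerance = 1e-9)
    }
  }
})

test_that("positional GC and PR2 coordinates are hand-checkable", {
  pg <- positional_gc("ATGGCC")
  expect_equal(pg$gc1, 0.5)
  expect_equal(pg$gc2, 0.5)
  expect_equal(pg$gc3, 1.0)
  expect_equal(pg$gc12, 0.5)
  expect_equal(positional_gc("ATTATTAAA")$gc_all, 0)
  # gc12 is definitionally the mean of gc1 and gc2
  for (s in 1:5) {
    p <- positional_gc(random_cds_fixture(80, seed = 200 + s))
    expect_equal(p$gc12, (p$gc1 + p$gc2) / 2)
  }
  expect_equal(unname(pr2_point(list(g3 = 3, c3 = 1, a3 = 1, t3 = 3))),
               c(0.75, 0.25))
  expect_equal(unname(pr2_point(list(g3 = 2, c3 = 2, a3 = 5, t3 = 5))),
               c(0.5, 0.5))
  expect_equal(unname(pr2_point(list(g3 = 1, c3 = 1, a3 = 0, t3 = 4))[2]), 0)
  expect_true(is.na(pr2_point(list(g3 = 0, c3 = 0, a3 = 1, t3 = 1))[1]))
})

test_that("ENC matches the independent Wright-formula oracle", {
  # extreme bias: one codon per family -> 20
  one_per_fam <- c("TTT", "TTA", "ATT", "GTT", "TCT", "CCT", "ACT", "GCT",
                   "TAT", "CAT", "CAA", "AAT", "AAA", "GAT", "GAA", "TGT",
                   "CGT", "GGT", "ATG", "TGG")
  cs <- coding_sequence(paste(c("ATG", rep(one_per_fam, 15), "TAA"),
                              collapse = ""))
  expect_equal(suppressMessages(enc(cs))$enc, 20)
  # perfectly uniform synonymous usage -> 61
  code <- Biostrings::GENETIC_CODE
  names(code) <- chartr("U", "T", names(code))
  sense <- names(code)[code != "*"]
  cs2 <- coding_sequence(paste(c("ATG", rep(sense, 10), "TAA"),
                               collapse = ""))
  expect_equal(suppressMessages(enc(cs2))$enc, 61)
  # seeded genes vs oracle to 1e-9
  for (s in 1:12) {
    g <- random_cds_fixture(200, seed = 300 + s)
    counts <- count_codons(g)$counts
    expect_equal(suppressMessages(enc(g))$enc, oracle_enc(counts),
                 tolerance = 1e-9)
  }
  # monotonicity: skewing one family never increases ENC
  shared <- c(rep(c("TTT", "TTC"), 20), rep("GAA", 10), rep("ATT", 6),
              rep(c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"), 5))
  base <- paste(c("ATG", rep(c("GGA", "GGC", "GGG", "GGT"), 25),
                  shared, "TAA"), collapse = "")
  skew <- paste(c("ATG", rep("GGA", 100), shared, "TAA"), collapse = "")
  expect_lt(suppressMessages(enc(skew))$enc,
            suppressMessages(enc(base))$enc)
})

test_that("the expected-ENC curve and the neutrality regression behave", {
  expect_equal(enc_expected(0), 31)
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(1), 32)
  expect_error(enc_expected(1.2), "0, 1")
  # symmetric about 0.5 once the linear +GC3 term is removed
  for (g in c(0.1, 0.25, 0.4))
    expect_equal(enc_expected(g) - g, enc_expected(1 - g) - (1 - g))
  expect_equal(neutrality_fit(list(gc3 = c(.1, .2, .3, .4),
                                   gc12 = rep(.35, 4)))$slope, 0)
  nf <- neutrality_fit(list(gc3 = c(.1, .2, .3, .4),
                            gc12 = c(.1, .2, .3, .4)))
  expect_equal(nf$slope, 1)
  expect_equal(nf$r, 1)
  expect_error(neutrality_fit(list(gc3 = rep(.3, 5), gc12 = 1:5 / 10)),
               "variance")
})

test_that("optimal codons follow the delta-RSCU rule and ignore gene order", {
  cds <- lapply(1:14, function(i)
    random_cds_fixture(120, seed = 400 + i, gene = sprintf("g%02d", i)))
  rep1 <- optimal_codons(cds)
  rep2 <- optimal_codons(rev(cds))
  expect_identical(rep1$optimal, rep2$optimal)
  expect_identical(sort(rep1$high_pool), sort(rep2$high_pool))
  expect_true(all(rep1$rscu_high[rep1$optimal] > 1))
  expect_true(all(rep1$delta_rscu[rep1$optimal] >= 0.08))
  expect_error(optimal_codons(cds[1:5]), "at least 10")
  # identical usage in both pools -> empty optimal set
  same <- lapply(1:12, function(i) {
    cs <- random_cds_fixture(100, seed = 77, gene = sprintf("s%02d", i))
    cs$gene <- sprintf("s%02d", i)
    cs
  })
  expect_length(optimal_codons(same)$optimal, 0L)
  # biased world calls the planted TTA / GTT codons optimal
  g <- generate_genome(sim_config(seed = 6))
  cds_g <- extract_cds(g$genome)
  oc <- optimal_codons(cds_g)
  expect_true(all(c("TTA", "GTT") %in% names(which(rscu(count_codons(cds_g)) > 1))))
})

test_that("high-frequency codons reflect the planted A/U third-position bias", {
  g <- generate_genome(sim_config(seed = 8))
  tab <- count_codons(extract_cds(g$genome))
  hf <- high_frequency_codons(tab)
  expect_gt(length(hf$codons), 10L)
  at_ending <- mean(substring(hf$codons, 3, 3) %in% c("A", "T"))
  expect_gte(at_ending, 0.95)
  expect_gt(hf$fraction, 0.5)   # biased codons dominate occurrences
  # uniform usage has no strictly high-frequency codon
  code <- Biostrings::GENETIC_CODE
  names(code) <- chartr("U", "T", names(code))
  sense <- names(code)[code != "*"]
  uni <- count_codons(coding_sequence(
    paste(c("ATG", rep(sense, 5), "TAA"), collapse = "")))
  expect_length(high_frequency_codons(uni)$codons, 0L)
})
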