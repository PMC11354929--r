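test_that("SSR thresholds, primitivity and phase behave as specified", {
  expect_equal(nrow(find_ssrs(strrep("A", 9))), 0L)      # below threshold
  s10 <- find_ssrs(strrep("A", 10))
  expect_equal(s10$motif, "A")
  expect_equal(s10$copies, 10L)
  # primitivity: (AT)x6 is never additionally (ATAT)x3
  s <- find_ssrs("ATATATATATAT", thresholds = c(`1` = 10L, `2` = 6L,
                                                `4` = 2L))
  expect_equal(nrow(s), 1L)
  expect_equal(s$motif, "AT")
  expect_equal(s$copies, 6L)
})

test_that("SSR calls equal the brute-force scan on seeded sequences", {
  for (s in 1:30) {
    sq <- random_seq(400, seed = 1000 + s, gc = 0.4)
    if (s %% 2 == 0) {   # plant a run in half the cases
      motif <- sample(c("A", "AT", "AAG", "ACGT"), 1)
      cp <- max(ssr_default_thresholds()[[as.character(nchar(motif))]], 5L)
      at <- sample(50:300, 1)
      substring(sq, at, at + nchar(motif) * cp - 1L) <-
        strrep(motif, cp)
    }
    expect_identical(find_ssrs(sq), oracle_ssrs(sq), label = paste("seed", s))
  }
})

test_that("circular scanning finds origin-spanning SSRs exactly once", {
  # A-run split across the origin: 6 at the end + 5 at the start
  mid <- random_seq(200, seed = 9, gc = 0.6)
  substring(mid, 1, 1) <- "C"; substring(mid, 200, 200) <- "C"
  sq <- paste0(strrep("A", 5), mid, strrep("A", 6))
  hits <- find_ssrs(sq, circular = TRUE)
  arun <- hits[hits$motif == "A", , drop = FALSE]
  expect_equal(nrow(arun), 1L)
  expect_equal(arun$copies, 11L)
  expect_equal(arun$start, nchar(sq) - 5L)
  expect_gt(arun$end, nchar(sq))   # wraps
})

test_that("tandem detection matches the spec worked examples", {
  tn <- find_tandem(strrep("ACGTT", 5))
  expect_equal(nrow(tn), 1L)
  expect_equal(tn$period, 5L)
  expect_equal(tn$copies, 5)
  expect_equal(tn$matches, 1)
  x <- strrep("ACGTT", 5)
  substring(x, 12, 12) <- "A"      # one substitution
  tn2 <- find_tandem(x)
  expect_equal(nrow(tn2), 1L)
  expect_equal(tn2$start, 1L)
  expect_equal(tn2$end, 25L)
  expect_equal(tn2$matches, 24 / 25)
})

test_that("tandem calls equal the independent transliteration oracle", {
  for (s in 1:25) {
    sq <- random_seq(160, seed = 2000 + s, gc = 0.45)
    if (s %% 2 == 0) {
      unit <- random_seq(sample(3:7, 1), seed = 3000 + s)
      cp <- sample(3:5, 1)
      at <- sample(30:80, 1)
      substring(sq, at, at + nchar(unit) * cp - 1L) <- strrep(unit, cp)
    }
    expect_equal(find_tandem(sq, max_period = 10L),
                 oracle_tandem(sq, max_period = 10L),
                 label = paste("seed", s))
  }
})

test_that("dispersed repeats cover the four orientations with exact spans", {
  seg <- random_seq(30, seed = 77)
  pad <- function(n, s) random_seq(n, seed = s, gc = 0.5)
  # forward pair; A/G flank blockers pin the maximal span exactly
  sq <- paste0(pad(40, 1), "A", seg, "A", pad(48, 2), "G", seg, "G",
               pad(40, 3))
  d <- find_dispersed(sq)
  expect_true(any(d$kind == "forward" & d$length == 30 &
                    d$pos1 == 42 & d$pos2 == 122))
  # palindromic pair
  sq2 <- paste0(pad(40, 4), "A", seg, "A", pad(48, 5), "G", revcomp(seg),
                "G", pad(40, 6))
  d2 <- find_dispersed(sq2)
  expect_true(any(d2$kind == "palindromic" & d2$length == 30 &
                    d2$pos1 == 42 & d2$pos2 == 122))
  # zero-gap forward copies belong to the tandem detector, not here;
  # pin the segment ends so chance flank matches cannot blur adjacency
  seg2 <- seg
  substring(seg2, 1, 1) <- "C"; substring(seg2, 30, 30) <- "T"
  sq3 <- paste0(pad(40, 7), "A", seg2, seg2, "G", pad(40, 8))
  d3 <- find_dispersed(sq3)
  expect_false(any(d3$kind == "forward" & d3$pos1 == 42 & d3$pos2 == 72))
})

test_that("dispersed calls equal the diagonal-runs oracle", {
  for (s in 1:20) {
    sq <- random_seq(300, seed = 4000 + s)
    if (s %% 2 == 0) {
      seg <- random_seq(sample(30:36, 1), seed = 5000 + s)
      kind <- sample(c("forward", "palindromic", "reverse", "complement"), 1)
      second <- switch(kind, forward = seg, palindromic = revcomp(seg),
                       reverse = paste(rev(strsplit(seg, "")[[1]]),
                                       collapse = ""),
                       complement = chartr("ACGT", "TGCA", seg))
      substring(sq, 40, 39 + nchar(seg)) <- seg
      substring(sq, 200, 199 + nchar(second)) <- second
    }
    expect_equal(find_dispersed(sq), oracle_dispersed(sq),
                 label = paste("seed", s))
  }
  # seeded random 2-kb sequence: no repeats >= 30 bp at all
  sq <- random_seq(2000, seed = 6000)
  expect_equal(nrow(find_dispersed(sq)), 0L)
  expect_equal(nrow(oracle_dispersed(sq)), 0L)
})

test_that("reverse-complementing the input reflects forward and palindromic calls", {
  seg <- random_seq(31, seed = 88)
  sq <- paste0(random_seq(60, 10), seg, random_seq(70, 11), seg,
               random_seq(60, 12))
  d_fwd <- find_dispersed(sq)
  d_rc <- find_dispersed(revcomp(sq))
  n <- nchar(sq)
  f1 <- d_fwd[d_fwd$kind == "forward", ]
  f2 <- d_rc[d_rc$kind == "forward", ]
  expect_equal(nrow(f1), nrow(f2))
  # reflected coordinates: start' = n - end + 1
  refl <- sort(n - (f1$pos2 + f1$length - 1) + 1)
  expect_equal(sort(f2$pos1), refl)
})

test_that("planted repeats in generated genomes are recovered at exact spans", {
  cfg <- sim_config(
    seed = 41, counts = c(PCG = 3L, tRNA = 2L, rRNA = 1L, ORF = 0L),
    pcg_aa_total = 300L, rrna_lens = 200L, overlap_total = 0L,
    n_overlaps = 0L, spacer_total = 700L,
    ssrs = list(list(motif = "AG", copies = 8L),
                list(motif = "T", copies = 12L)),
    tandems = list(list(unit = "GATTACA", copies = 4L)),
    dispersed = list(list(kind = "forward", length = 33L)))
  g <- generate_genome(cfg)
  sq <- g$genome$sequence
  ss <- find_ssrs(sq)
  for (r in seq_len(nrow(g$truth$ssrs)))
    expect_true(any(ss$motif == g$truth$ssrs$motif[r] &
                      ss$start == g$truth$ssrs$start[r] &
                      ss$end == g$truth$ssrs$end[r]))
  tn <- find_tandem(sq)
  expect_true(any(tn$start == g$truth$tandems$start &
                    tn$end == g$truth$tandems$end & tn$matches == 1))
  dp <- find_dispersed(sq)
  expect_true(any(dp$kind == "forward" &
                    dp$pos1 == g$truth$dispersed$pos1 &
                    dp$pos2 == g$truth$dispersed$pos2 &
                    dp$length == g$truth$dispersed$length))
})
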