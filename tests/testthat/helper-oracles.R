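# Independent brute-force oracles and small fixture builders shared by
# the unit and acceptance suites. Each oracle re-derives the result by a
# different algorithm than the implementation it checks.

random_seq <- function(n, seed, gc = 0.5) {
  set.seed(seed)
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# SSR oracle: positionwise scan. For unit length k, run lengths from
# direct s[j] == s[j-k] comparisons; a maximal run of r k-spaced matches
# covers r + k bases = floor((r + k) / k) full copies starting at the
# run head.
oracle_ssrs <- function(seq, thresholds = ssr_default_thresholds()) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(ch)
  out <- NULL
  primitive <- function(motif) {
    k <- nchar(motif)
    for (d in seq_len(k - 1L)) {
      if (k %% d) next
      if (paste(rep(substring(motif, 1, d), k / d), collapse = "") == motif)
        return(FALSE)
    }
    TRUE
  }
  for (k in as.integer(names(thresholds))) {
    if (2L * k > n) next
    eq <- ch[(k + 1L):n] == ch[1L:(n - k)]
    r <- rle(eq)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (h in which(r$values)) {
      a <- starts[h]              # first matching pair: positions a, a+k
      run <- r$lengths[h]
      copies <- (run + k) %/% k
      if (copies < thresholds[[as.character(k)]]) next
      motif <- paste(ch[a:(a + k - 1L)], collapse = "")
      if (!primitive(motif)) next
      out <- rbind(out, data.frame(motif = motif, unit_length = k,
                                   copies = copies, start = a,
                                   end = a + k * copies - 1L))
    }
  }
  if (is.null(out))
    return(data.frame(motif = character(), unit_length = integer(),
                      copies = integer(), start = integer(),
                      end = integer()))
  out[order(out$start, out$unit_length), , drop = FALSE]
}

# Tandem oracle: independent transliteration of the published rule
# (seed = run of >= k k-spaced matches; stepwise consensus extension
# with isolated-mismatch rescue), written without rle/vectorization.
oracle_tandem <- function(seq, match_prob = 0.80, min_span = 14L,
                          max_period = 200L) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(ch)
  cons_of <- function(a, b, k) {
    cons <- character(k)
    for (ph in 0:(k - 1L)) {
      idx <- seq.int(a + ph, b, by = k)
      tb <- table(ch[idx])
      cons[ph + 1L] <- names(sort(tb, decreasing = TRUE))[1]
    }
    cons
  }
  frac_of <- function(a, b, k, cons)
    mean(ch[a:b] == cons[((a:b - a) %% k) + 1L])
  cand <- NULL
  for (k in seq_len(min(max_period, n %/% 2L))) {
    i <- 1L
    while (i <= n - k) {
      if (ch[i] != ch[i + k]) { i <- i + 1L; next }
      j <- i
      while (j + 1L <= n - k && ch[j + 1L] == ch[j + 1L + k]) j <- j + 1L
      if (j - i + 1L >= k) {
        a <- i; b <- j + k
        for (dir in c(-1L, 1L, -1L)) {
          repeat {
            cons <- cons_of(a, b, k)
            phase <- function(x) ((x - a) %% k) + 1L
            nxt <- if (dir > 0L) b + 1L else a - 1L
            if (nxt < 1L || nxt > n) break
            if (ch[nxt] == cons[phase(nxt)]) {
              if (dir > 0L) b <- nxt else a <- nxt
              next
            }
            beyond <- if (dir > 0L) (b + 2L):(b + 1L + k)
              else (a - 2L):(a - 1L - k)
            if (any(beyond < 1L | beyond > n)) break
            if (!all(ch[beyond] == cons[phase(beyond)])) break
            a2 <- if (dir > 0L) a else a - 1L - k
            b2 <- if (dir > 0L) b + 1L + k else b
            if (frac_of(a2, b2, k, cons_of(a2, b2, k)) < match_prob) break
            a <- a2; b <- b2
          }
        }
        span <- b - a + 1L
        if (span >= max(min_span, 2L * k)) {
          cons <- cons_of(a, b, k)
          cand <- rbind(cand,
                        data.frame(unit = paste(cons, collapse = ""),
                                   period = k, copies = span / k,
                                   start = a, end = b,
                                   matches = frac_of(a, b, k, cons)))
        }
        i <- j + 1L
      } else {
        i <- j + 1L
      }
    }
  }
  if (is.null(cand))
    return(data.frame(unit = character(), period = integer(),
                      copies = numeric(), start = integer(),
                      end = integer(), matches = numeric()))
  cand <- unique(cand)
  o <- order(-(cand$end - cand$start), -cand$matches, cand$period,
             cand$start)
  cand <- cand[o, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ov <- FALSE
    for (j in which(keep)) {
      lo <- max(cand$start[i], cand$start[j])
      hi <- min(cand$end[i], cand$end[j])
      if (hi - lo + 1L > 0.5 * (cand$end[i] - cand$start[i] + 1L)) {
        ov <- TRUE; break
      }
    }
    keep[i] <- !ov
  }
  res <- cand[keep, , drop = FALSE]
  rownames(res) <- NULL
  res[order(res$start, res$period), , drop = FALSE]
}

# Dispersed-repeat oracle: diagonal run-length formulation. For each
# orientation compare s against the transformed sequence along every
# diagonal offset; maximal equal runs >= min_len are the repeat pairs.
oracle_dispersed <- function(seq, min_len = 30L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  sch <- strsplit(seq, "", fixed = TRUE)[[1]]
  rev_str <- function(x) paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                               collapse = "")
  comp <- function(x) chartr("ACGT", "TGCA", x)
  transforms <- list(
    forward = list(t = seq, map = function(j, len) j),
    palindromic = list(t = revcomp(seq),
                       map = function(j, len) n - (j + len - 1L) + 1L),
    reverse = list(t = rev_str(seq),
                   map = function(j, len) n - (j + len - 1L) + 1L),
    complement = list(t = comp(seq), map = function(j, len) j))
  out <- NULL
  for (kind in names(transforms)) {
    tch <- strsplit(transforms[[kind]]$t, "", fixed = TRUE)[[1]]
    map <- transforms[[kind]]$map
    for (d in (-(n - 1L)):(n - 1L)) {
      i0 <- max(1L, 1L - d); i1 <- min(n, n - d)
      if (i1 - i0 + 1L < min_len) next
      idx <- i0:i1
      eq <- sch[idx] == tch[idx + d]
      r <- rle(eq)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (h in which(r$values & r$lengths >= min_len)) {
        i <- idx[starts[h]]; len <- r$lengths[h]
        j <- i + d
        p1 <- i; p2 <- map(j, len)
        if (p1 == p2) next
        lo <- min(p1, p2); hi <- max(p1, p2)
        if (kind == "forward" && hi == lo + len) next
        out <- rbind(out, data.frame(kind = kind, length = len,
                                     pos1 = lo, pos2 = hi))
      }
    }
  }
  out <- if (is.null(out))
    data.frame(kind = character(), length = integer(), pos1 = integer(),
               pos2 = integer()) else unique(out)
  rownames(out) <- NULL
  out[order(out$kind, out$pos1, out$pos2), , drop = FALSE]
}

# Diagnostic-SNP oracle: direct enumeration over all (site, group).
oracle_diagnostic <- function(snps, grouping, group) {
  members <- snps$taxa[grouping[snps$taxa] == group]
  others <- setdiff(snps$taxa, members)
  idx <- integer()
  for (k in seq_along(snps$column)) {
    al <- snps$alleles[k, ]
    a_in <- unique(al[members])
    if (length(a_in) != 1L) next
    if (length(others) && a_in %in% al[others]) next
    idx <- c(idx, k)
  }
  idx
}

# Wright ENC oracle: direct evaluation from a codon-count vector.
oracle_enc <- function(counts, transl_table = 1L) {
  code <- Biostrings::getGeneticCode(as.character(transl_table))
  names(code) <- chartr("U", "T", names(code))
  fams <- split(names(code)[code != "*"], code[code != "*"])
  fbar <- sapply(c(2, 3, 4, 6), function(k) {
    vals <- c()
    for (f in fams[lengths(fams) == k]) {
      nn <- sum(counts[f])
      if (nn < 2) next
      pp <- counts[f] / nn
      fv <- (nn * sum(pp^2) - 1) / (nn - 1)
      if (fv > 0) vals <- c(vals, fv)
    }
    if (length(vals)) mean(vals) else NA_real_
  })
  names(fbar) <- c("2", "3", "4", "6")
  if (is.na(fbar["3"])) fbar["3"] <- (fbar["2"] + fbar["4"]) / 2
  if (anyNA(fbar)) return(NA_real_)
  unname(min(61, max(20, 2 + 9 / fbar["2"] + 1 / fbar["3"] +
                       5 / fbar["4"] + 3 / fbar["6"])))
}

# Per-base occupancy oracle for architecture statistics.
oracle_occupancy <- function(genome) {
  L <- genome$length
  cover <- integer(L)
  for (f in genome$features)
    cover[organellr:::feature_positions(f)] <-
      cover[organellr:::feature_positions(f)] + 1L
  list(covered = sum(cover > 0L), spacer = sum(cover == 0L))
}

# Small in-frame CDS fixture with no internal stops.
random_cds_fixture <- function(n_aa, seed, gene = "g1") {
  set.seed(seed)
  code <- Biostrings::getGeneticCode("1")
  names(code) <- chartr("U", "T", names(code))
  sense <- names(code)[code != "*"]
  coding_sequence(paste(c("ATG", sample(sense, n_aa - 1L, replace = TRUE),
                          "TAA"), collapse = ""), gene = gene)
}

# Toy two-clade alignment fixture for SNP tests: random codon alignment
# over taxa with per-column variability.
random_alignment <- function(n_taxa, n_codons, seed, p_var = 0.15) {
  set.seed(seed)
  code <- Biostrings::getGeneticCode("1")
  names(code) <- chartr("U", "T", names(code))
  sense <- names(code)[code != "*"]
  base <- sample(sense, n_codons, replace = TRUE)
  taxa <- sprintf("t%02d", seq_len(n_taxa))
  seqs <- sapply(taxa, function(tx) {
    cods <- base
    for (i in seq_len(n_codons)) {
      if (runif(1) < p_var) {
        p <- sample.int(3L, 1L)
        b <- sample(c("A", "C", "G", "T"), 1L)
        v <- cods[i]
        substring(v, p, p) <- b
        if (code[v] != "*") cods[i] <- v
      }
    }
    paste(cods, collapse = "")
  })
  structure(list(gene = "toy", taxa = taxa, seqs = seqs),
            class = "ortholog_alignment")
}
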