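# Repeat census: perfect microsatellites (MISA-style thresholds), a
# deterministic simplified tandem-repeat finder, and exact dispersed
# repeats >= 30 bp in four orientations.

#' Default SSR copy-number thresholds
#'
#' MISA-style minimum copy numbers per unit length:
#' mono 10, di 6, tri/tetra/penta/hexa 5.
#' @export
ssr_default_thresholds <- function() {
  c(`1` = 10L, `2` = 6L, `3` = 5L, `4` = 5L, `5` = 5L, `6` = 5L)
}

# A motif is primitive when it is not itself a repetition of a shorter
# motif (e.g. ATAT is not; AT is).
is_primitive_motif <- function(motif) {
  k <- nchar(motif)
  for (d in seq_len(k - 1L)) {
    if (k %% d != 0L) next
    unit <- substring(motif, 1L, d)
    if (paste(rep(unit, k %/% d), collapse = "") == motif) return(FALSE)
  }
  TRUE
}

#' Find perfect simple sequence repeats (microsatellites)
#'
#' Maximal non-extendable perfect runs of a primitive 1-6 bp motif with
#' at least the per-unit-length copy threshold. The motif is reported in
#' its first-occurrence phase. Runs of different unit lengths may
#' overlap; only non-primitive motifs are suppressed (an (AT)x6 run is
#' never additionally reported as (ATAT)x3). On circular sequences the
#' doubled sequence is scanned so origin-spanning runs are found once
#' (reported \code{end} may exceed the sequence length).
#'
#' @param seq DNA string.
#' @param thresholds Named vector unit_length -> minimum copies
#'   (default \code{\link{ssr_default_thresholds}}).
#' @param circular Scan as a circular molecule.
#' @return data.frame with \code{motif}, \code{unit_length},
#'   \code{copies}, \code{start}, \code{end}.
#' @export
find_ssrs <- function(seq, thresholds = ssr_default_thresholds(),
                      circular = FALSE) {
  seq <- toupper(seq)
  L <- nchar(seq)
  scan <- if (circular) paste0(seq, seq) else seq
  out <- list()
  for (k in as.integer(names(thresholds))) {
    if (2L * k > nchar(scan)) next
    pat <- sprintf("([ACGT]{%d})\\1+", k)
    m <- gregexpr(pat, scan, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    for (h in seq_along(m)) {
      s <- m[h]
      len <- attr(m, "match.length")[h]
      copies <- len %/% k
      motif <- substring(scan, s, s + k - 1L)
      if (!is_primitive_motif(motif)) next
      if (copies < thresholds[[as.character(k)]]) next
      if (circular && s > L) next
      out[[length(out) + 1L]] <-
        data.frame(motif = motif, unit_length = k, copies = copies,
                   start = s, end = s + k * copies - 1L)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(motif = character(), unit_length = integer(),
               copies = integer(), start = integer(), end = integer())
  if (circular && nrow(res) > 1L) {
    # drop calls whose covered positions (mod L) lie inside another call
    cover <- lapply(seq_len(nrow(res)), function(i)
      sort(unique((seq.int(res$start[i], res$end[i]) - 1L) %% L)))
    keep <- rep(TRUE, nrow(res))
    for (i in seq_len(nrow(res))) for (j in seq_len(nrow(res))) {
      if (i == j || !keep[i]) next
      if (length(cover[[i]]) < length(cover[[j]]) &&
          all(cover[[i]] %in% cover[[j]])) keep[i] <- FALSE
    }
    res <- res[keep, , drop = FALSE]
  }
  rownames(res) <- NULL
  res[order(res$start, res$unit_length), , drop = FALSE]
}

period_consensus <- function(ch, a, b, k) {
  idx <- seq.int(a, b)
  phase <- (idx - a) %% k
  cons <- vapply(split(ch[idx], phase), function(col)
    names(sort(table(col), decreasing = TRUE))[1], "")
  list(consensus = cons, frac = mean(ch[idx] == cons[as.character(phase)]))
}

#' Find tandem repeats (deterministic, simplified)
#'
#' A deterministic stand-in for probabilistic tandem-repeat finders:
#' for each period k, runs of k-spaced exact matches at least one full
#' unit long seed a candidate array. The array is extended base by base
#' while the next position matches the per-phase majority consensus; an
#' isolated mismatch is crossed only when the k positions beyond it all
#' match the consensus and the overall match fraction stays at or above
#' \code{match_prob} (mismatch rescue). A perfect array is therefore
#' reported with its exact span and \code{matches = 1}; one internal
#' substitution costs exactly one mismatch. Indels are not modeled
#' (ungapped extension only), so arrays containing insertions or
#' deletions may be split or missed. Contained or heavily overlapping
#' calls are resolved toward the longer span and the shorter period.
#'
#' @param seq DNA string.
#' @param match_prob Minimum consensus-match fraction (default 0.80).
#' @param min_span Minimum reported span in bp (default 14); a span must
#'   also cover at least two periods.
#' @param max_period Largest period considered (default 200).
#' @return data.frame with \code{unit} (consensus), \code{period},
#'   \code{copies}, \code{start}, \code{end}, \code{matches}.
#' @export
find_tandem <- function(seq, match_prob = 0.80, min_span = 14L,
                        max_period = 200L) {
  seq <- toupper(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  cand <- list()
  for (k in seq_len(min(max_period, n %/% 2L))) {
    eq <- ch[seq_len(n - k)] == ch[seq_len(n - k) + k]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (h in which(r$values & r$lengths >= k)) {
      a <- starts[h]; b <- ends[h] + k
      a <- extend_tandem(ch, a, b, k, match_prob, dir = -1L)
      b <- extend_tandem(ch, a, b, k, match_prob, dir = +1L)
      a <- extend_tandem(ch, a, b, k, match_prob, dir = -1L)
      span <- b - a + 1L
      if (span < max(min_span, 2L * k)) next
      pc <- period_consensus(ch, a, b, k)
      cand[[length(cand) + 1L]] <-
        data.frame(unit = paste(pc$consensus, collapse = ""), period = k,
                   copies = span / k, start = a, end = b,
                   matches = pc$frac)
    }
  }
  if (!length(cand))
    return(data.frame(unit = character(), period = integer(),
                      copies = numeric(), start = integer(),
                      end = integer(), matches = numeric()))
  cand <- unique(do.call(rbind, cand))
  # non-redundancy: prefer longer spans, then higher identity, then the
  # smallest period; drop calls overlapping a kept call by > 50%
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

# One-sided tandem extension: step while the next base matches the
# current consensus at its phase; cross an isolated mismatch only when
# the k bases beyond it all match the consensus and the match fraction
# of the extended interval stays >= match_prob. Returns the new boundary
# (a for dir = -1, b for dir = +1).
extend_tandem <- function(ch, a, b, k, match_prob, dir) {
  n <- length(ch)
  repeat {
    cons <- period_consensus(ch, a, b, k)$consensus
    phase_of <- function(i) as.character((i - a) %% k)
    nxt <- if (dir > 0L) b + 1L else a - 1L
    if (nxt < 1L || nxt > n) return(if (dir > 0L) b else a)
    if (ch[nxt] == cons[[phase_of(nxt)]]) {
      if (dir > 0L) b <- nxt else a <- nxt
      next
    }
    beyond <- if (dir > 0L) (b + 2L):(b + 1L + k) else (a - 2L):(a - 1L - k)
    if (any(beyond < 1L | beyond > n)) return(if (dir > 0L) b else a)
    if (!all(ch[beyond] == vapply(beyond, function(i)
      cons[[phase_of(i)]], ""))) return(if (dir > 0L) b else a)
    a2 <- if (dir > 0L) a else a - 1L - k
    b2 <- if (dir > 0L) b + 1L + k else b
    if (period_consensus(ch, a2, b2, k)$frac < match_prob)
      return(if (dir > 0L) b else a)
    a <- a2; b <- b2
  }
}

reverse_dna <- function(seq) {
  vapply(seq, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""), "",
    USE.NAMES = FALSE)
}

# Maximal exact matches >= w between s and t via left-maximal seed pairs.
maximal_pairs <- function(s, t, w, max_kmer_hits = 200L) {
  n <- nchar(s); m <- nchar(t)
  if (n < w || m < w) return(NULL)
  ks <- substring(s, 1:(n - w + 1L), w:n)
  kt <- substring(t, 1:(m - w + 1L), w:m)
  byk <- split(seq_along(kt), kt)
  sch <- strsplit(s, "", fixed = TRUE)[[1]]
  tch <- strsplit(t, "", fixed = TRUE)[[1]]
  hits <- list()
  for (i in seq_along(ks)) {
    js <- byk[[ks[i]]]
    if (is.null(js) || length(js) > max_kmer_hits) next
    for (j in js) {
      # left-maximal only: the extension loop then yields each maximal
      # match exactly once
      if (i > 1L && j > 1L && sch[i - 1L] == tch[j - 1L]) next
      len <- w
      while (i + len <= n && j + len <= m &&
             sch[i + len] == tch[j + len]) len <- len + 1L
      hits[[length(hits) + 1L]] <- c(i = i, j = j, len = len)
    }
  }
  if (!length(hits)) return(NULL)
  unique(do.call(rbind, hits))
}

#' Find dispersed (interspersed) repeats
#'
#' All maximal exact repeat pairs of at least \code{min_len} bp in four
#' orientations: \code{forward} (both copies on the same strand),
#' \code{palindromic} (one copy matches the reverse complement of the
#' other), \code{reverse} (matches the reversed sequence) and
#' \code{complement} (matches the base-complemented, unreversed
#' sequence). A segment paired with itself is excluded, as are
#' zero-gap adjacent forward copies (those belong to the tandem
#' detector); each unordered pair is reported once with
#' \code{pos1 <= pos2}.
#'
#' @param seq DNA string.
#' @param min_len Minimum repeat length in bp (default 30).
#' @return data.frame with \code{kind}, \code{length}, \code{pos1},
#'   \code{pos2} (start coordinates of the two occurrences on the input
#'   strand).
#' @export
find_dispersed <- function(seq, min_len = 30L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  res <- list()
  add <- function(kind, p1, p2, len) {
    if (p1 == p2) return()                          # self-trivial
    if (p1 > p2) { tmp <- p1; p1 <- p2; p2 <- tmp }
    if (kind == "forward" && p2 == p1 + len) return()  # tandem-adjacent
    res[[length(res) + 1L]] <<-
      data.frame(kind = kind, length = len, pos1 = p1, pos2 = p2)
  }
  transforms <- list(
    forward = list(t = seq, map = function(j, len) j),
    palindromic = list(t = revcomp(seq),
                       map = function(j, len) n - (j + len - 1L) + 1L),
    reverse = list(t = reverse_dna(seq),
                   map = function(j, len) n - (j + len - 1L) + 1L),
    complement = list(t = complement_dna(seq), map = function(j, len) j))
  for (kind in names(transforms)) {
    tr <- transforms[[kind]]
    mp <- maximal_pairs(seq, tr$t, min_len)
    if (is.null(mp)) next
    for (r in seq_len(nrow(mp)))
      add(kind, mp[r, "i"], tr$map(mp[r, "j"], mp[r, "len"]), mp[r, "len"])
  }
  out <- if (length(res)) unique(do.call(rbind, res)) else
    data.frame(kind = character(), length = integer(), pos1 = integer(),
               pos2 = integer())
  rownames(out) <- NULL
  out[order(out$kind, out$pos1, out$pos2), , drop = FALSE]
}
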