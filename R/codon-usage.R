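# Codon-usage-bias suite: codon counts, RSCU, positional GC, Wright's
# effective number of codons (ENC), the ENC-GC3 expected curve, neutrality
# regression (GC12 on GC3), PR2 coordinates, and delta-RSCU optimal codons.

# Synonymous families (aa -> codons) for a genetic code, stops excluded.
synonymous_families <- function(transl_table = 1L) {
  code <- genetic_code_table(transl_table)
  code <- code[code != "*"]
  split(names(code), code)
}

stop_codons <- function(transl_table = 1L) {
  code <- genetic_code_table(transl_table)
  names(code)[code == "*"]
}

#' Count codons over a set of coding sequences
#'
#' Tallies all complete codons of in-frame CDS. Stop codons are tracked
#' separately and excluded from RSCU and amino-acid frequencies when
#' \code{drop_stops} (the default); codons containing ambiguity symbols
#' are dropped with a message. Counts are additive over CDS by
#' construction.
#'
#' @param cds_set List of \code{coding_sequence} objects (or a single one).
#' @param drop_stops Exclude stop codons from the usage table
#'   (default \code{TRUE}).
#' @param transl_table Genetic-code number (taken from the first CDS when
#'   available).
#' @return A \code{codon_usage_table}: list with \code{counts} (named
#'   integer vector over sense codons), \code{stop_counts},
#'   \code{aa_freq}, \code{n_codons}, \code{transl_table}.
#' @export
count_codons <- function(cds_set, drop_stops = TRUE, transl_table = NULL) {
  if (inherits(cds_set, "coding_sequence")) cds_set <- list(cds_set)
  stopifnot(length(cds_set) >= 1L)
  if (is.null(transl_table))
    transl_table <- if (inherits(cds_set[[1]], "coding_sequence"))
      cds_set[[1]]$transl_table else 1L
  code <- genetic_code_table(transl_table)
  cods <- unlist(lapply(cds_set, function(x)
    split_codons(if (inherits(x, "coding_sequence")) x$nt else x)),
    use.names = FALSE)
  if (!length(cods)) stop("no complete codons in input")
  amb <- !cods %in% names(code)
  if (any(amb)) {
    message(sum(amb), " codon(s) with ambiguity symbols dropped")
    cods <- cods[!amb]
  }
  if (!length(cods)) stop("no unambiguous complete codons in input")
  stops <- stop_codons(transl_table)
  stop_counts <- table(factor(cods[cods %in% stops], levels = stops))
  sense <- cods[!cods %in% stops]
  if (!drop_stops) sense <- cods
  counts <- table(factor(sense, levels = names(code)[code != "*"]))
  aa <- code[sense]
  aa_freq <- table(factor(aa[aa != "*"], levels = sort(unique(code[code != "*"]))))
  aa_freq <- aa_freq / sum(aa_freq)
  structure(list(counts = c(counts), stop_counts = c(stop_counts),
                 aa_freq = c(aa_freq), n_codons = sum(counts),
                 transl_table = transl_table),
            class = "codon_usage_table")
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat(sprintf("<codon_usage_table> %d sense codons (+%d stops), code %d\n",
              x$n_codons, sum(x$stop_counts), x$transl_table))
  invisible(x)
}

#' Relative synonymous codon usage
#'
#' RSCU(c) = observed(c) / (family_total / family_size): the observed
#' count relative to uniform use within the codon's synonymous family.
#' Single-codon families (Met AUG, Trp UGG in the standard code) have
#' RSCU exactly 1 whenever observed. Families with zero observations get
#' \code{NA} ("missing"), never 0.
#'
#' @param table A \code{codon_usage_table}.
#' @return Named numeric vector over sense codons.
#' @export
rscu <- function(table) {
  stopifnot(inherits(table, "codon_usage_table"))
  fams <- synonymous_families(table$transl_table)
  out <- setNames(rep(NA_real_, length(table$counts)), names(table$counts))
  for (f in fams) {
    tot <- sum(table$counts[f])
    if (tot > 0L) out[f] <- table$counts[f] / (tot / length(f))
  }
  out
}

#' Positional GC content of a CDS set
#'
#' GC fraction at codon positions 1, 2, 3 (stop codons excluded, as in
#' \code{\link{count_codons}}; ambiguous bases excluded positionwise),
#' the GC12 mean, and third-position base counts retained for PR2
#' analysis.
#'
#' @param cds_set List of \code{coding_sequence} objects or in-frame
#'   DNA strings.
#' @param transl_table Genetic-code number.
#' @return A \code{positional_gc}: list with \code{gc_all}, \code{gc1},
#'   \code{gc2}, \code{gc3}, \code{gc12}, \code{a3}, \code{t3}, \code{g3},
#'   \code{c3}.
#' @export
positional_gc <- function(cds_set, transl_table = NULL) {
  if (inherits(cds_set, "coding_sequence")) cds_set <- list(cds_set)
  if (is.null(transl_table))
    transl_table <- if (inherits(cds_set[[1]], "coding_sequence"))
      cds_set[[1]]$transl_table else 1L
  cods <- unlist(lapply(cds_set, function(x)
    split_codons(if (inherits(x, "coding_sequence")) x$nt else x)),
    use.names = FALSE)
  cods <- cods[!cods %in% stop_codons(transl_table)]
  if (!length(cods)) stop("no sense codons in input")
  pos <- lapply(1:3, function(p) substring(cods, p, p))
  gc_at <- function(b) {
    ok <- b %in% c("A", "C", "G", "T")
    sum(b %in% c("G", "C")) / sum(ok)
  }
  b3 <- pos[[3]]
  structure(list(
    gc_all = gc_at(unlist(pos)),
    gc1 = gc_at(pos[[1]]), gc2 = gc_at(pos[[2]]), gc3 = gc_at(pos[[3]]),
    gc12 = (gc_at(pos[[1]]) + gc_at(pos[[2]])) / 2,
    a3 = sum(b3 == "A"), t3 = sum(b3 == "T"),
    g3 = sum(b3 == "G"), c3 = sum(b3 == "C")),
    class = "positional_gc")
}

#' Wright's effective number of codons (ENC)
#'
#' For each synonymous family with n >= 2 observed codons, the family
#' homozygosity is F = (n * sum(p^2) - 1) / (n - 1); families with
#' F <= 0 are uninformative and skipped. Class means over degeneracy
#' classes k in {2, 3, 4, 6} give
#' Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, clamped to [20, 61]. A missing
#' 3-fold class (Ile unobserved) is imputed as (F2 + F4)/2 per Wright;
#' any other missing class leaves ENC undefined (NA).
#'
#' @param cds An in-frame \code{coding_sequence} or DNA string.
#' @param min_codons Genes shorter than this many codons are flagged with
#'   a message but still computed (default 30).
#' @param transl_table Genetic-code number.
#' @return An \code{enc_result}: list with \code{gene}, \code{enc},
#'   \code{gc3}, \code{n_codons}, \code{fbar} (per-class means).
#' @export
enc <- function(cds, min_codons = 30L, transl_table = NULL) {
  gene <- if (inherits(cds, "coding_sequence")) cds$gene else "gene"
  if (is.null(transl_table))
    transl_table <- if (inherits(cds, "coding_sequence"))
      cds$transl_table else 1L
  nt <- if (inherits(cds, "coding_sequence")) cds$nt else cds
  cods <- split_codons(nt)
  cods <- cods[cods %in% names(genetic_code_table(transl_table))]
  cods <- cods[!cods %in% stop_codons(transl_table)]
  if (length(cods) < min_codons)
    message("gene '", gene, "': only ", length(cods), " codons (< ",
            min_codons, ")")
  fams <- synonymous_families(transl_table)
  sizes <- lengths(fams)
  fvals <- lapply(c(`2` = 2L, `3` = 3L, `4` = 4L, `6` = 6L), function(k) {
    vals <- c()
    for (f in fams[sizes == k]) {
      n <- sum(cods %in% f)
      if (n < 2L) next
      p <- as.numeric(table(factor(cods[cods %in% f], levels = f))) / n
      fv <- (n * sum(p^2) - 1) / (n - 1)
      if (fv > 0) vals <- c(vals, fv)
    }
    vals
  })
  fbar <- vapply(fvals, function(v) if (length(v)) mean(v) else NA_real_, 0)
  if (is.na(fbar["3"]) && !is.na(fbar["2"]) && !is.na(fbar["4"]))
    fbar["3"] <- (fbar["2"] + fbar["4"]) / 2
  nc <- if (anyNA(fbar)) NA_real_ else
    min(61, max(20, 2 + 9 / fbar["2"] + 1 / fbar["3"] +
                      5 / fbar["4"] + 3 / fbar["6"]))
  pg <- positional_gc(list(nt), transl_table = transl_table)
  structure(list(gene = gene, enc = unname(nc), gc3 = pg$gc3,
                 n_codons = length(cods), fbar = fbar),
            class = "enc_result")
}

#' @export
print.enc_result <- function(x, ...) {
  cat(sprintf("<enc_result> %s: ENC %.2f, GC3 %.3f, %d codons\n",
              x$gene, x$enc, x$gc3, x$n_codons))
  invisible(x)
}

#' Expected ENC under mutation pressure alone
#'
#' The null curve ENC = 2 + GC3 + 29 / (GC3^2 + (1 - GC3)^2): the ENC a
#' gene would have if codon usage were shaped only by third-position
#' composition. Genes below the curve are candidates for
#' selection-driven bias.
#'
#' @param gc3 Third-position GC fraction, in [0, 1] (vectorized).
#' @return Expected ENC value(s).
#' @export
enc_expected <- function(gc3) {
  if (any(gc3 < 0 | gc3 > 1)) stop("gc3 must lie in [0, 1]")
  2 + gc3 + 29 / (gc3^2 + (1 - gc3)^2)
}

#' Neutrality regression of GC12 on GC3
#'
#' Ordinary least squares of per-gene GC12 against GC3. The slope is read
#' as the share of codon-usage bias attributable to mutation pressure
#' (slope 1 = pure mutation, slope 0 = pure selection).
#'
#' @param points Data frame or list with numeric \code{gc3} and
#'   \code{gc12} (>= 3 genes, non-degenerate GC3).
#' @return List with \code{slope}, \code{intercept}, \code{r}
#'   (Pearson correlation), \code{n}.
#' @export
neutrality_fit <- function(points) {
  gc3 <- points$gc3; gc12 <- points$gc12
  stopifnot(length(gc3) == length(gc12))
  if (length(gc3) < 3L) stop("need at least 3 (gc3, gc12) points")
  if (stats::var(gc3) == 0) stop("zero variance in gc3; slope undefined")
  fit <- stats::lm(gc12 ~ gc3)
  r <- if (stats::var(gc12) == 0) NA_real_ else stats::cor(gc3, gc12)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r = r, n = length(gc3))
}

#' PR2 (parity rule 2) coordinates
#'
#' x = G3/(G3 + C3), y = A3/(A3 + T3) over third codon positions;
#' (0.5, 0.5) is the no-strand-bias center where A = T and G = C.
#'
#' @param pg A \code{positional_gc} (or list with a3/t3/g3/c3 counts).
#' @return Named numeric \code{c(x =, y =)}; a coordinate with zero
#'   denominator is \code{NA}.
#' @export
pr2_point <- function(pg) {
  x <- if ((pg$g3 + pg$c3) > 0) pg$g3 / (pg$g3 + pg$c3) else NA_real_
  y <- if ((pg$a3 + pg$t3) > 0) pg$a3 / (pg$a3 + pg$t3) else NA_real_
  c(x = x, y = y)
}

#' Optimal codons from ENC-defined expression pools
#'
#' Ranks genes by ENC, takes the ceiling(10%) extremes as expression
#' pools (high expression = lowest ENC, i.e. strongest bias; invert with
#' \code{invert_pools}), computes pooled RSCU per pool, and calls a codon
#' optimal when its RSCU in the high-expression pool exceeds 1 and
#' delta-RSCU = RSCU(high) - RSCU(low) is at least \code{delta_min}.
#' ENC ties are broken by gene name so the pools are deterministic.
#'
#' @param cds_set List of \code{coding_sequence} objects (>= 10 genes
#'   with defined ENC).
#' @param pool_fraction Fraction of genes per pool (default 0.10).
#' @param delta_min Delta-RSCU threshold (default 0.08).
#' @param invert_pools Treat the high-ENC decile as high-expression.
#' @return An \code{optimal_codon_report}: list with \code{high_pool},
#'   \code{low_pool} (gene names), \code{rscu_high}, \code{rscu_low},
#'   \code{delta_rscu}, \code{optimal} (codon names).
#' @export
optimal_codons <- function(cds_set, pool_fraction = 0.10, delta_min = 0.08,
                           invert_pools = FALSE) {
  encs <- lapply(cds_set, function(x) suppressMessages(enc(x)))
  ok <- !vapply(encs, function(e) is.na(e$enc), TRUE)
  if (sum(ok) < 10L)
    stop("need at least 10 genes with defined ENC (have ", sum(ok), ")")
  cds_set <- cds_set[ok]; encs <- encs[ok]
  vals <- vapply(encs, `[[`, 0, "enc")
  nms <- vapply(encs, `[[`, "", "gene")
  o <- order(vals, nms)
  k <- ceiling(pool_fraction * length(vals))
  low_enc <- o[seq_len(k)]                         # strongest bias
  high_enc <- rev(o)[seq_len(k)]
  hi <- if (invert_pools) high_enc else low_enc    # high-expression pool
  lo <- if (invert_pools) low_enc else high_enc
  rscu_high <- rscu(count_codons(cds_set[hi]))
  rscu_low <- rscu(count_codons(cds_set[lo]))
  delta <- rscu_high - rscu_low
  optimal <- names(delta)[!is.na(rscu_high) & !is.na(delta) &
                            rscu_high > 1 & delta >= delta_min]
  structure(list(high_pool = sort(nms[hi]), low_pool = sort(nms[lo]),
                 rscu_high = rscu_high, rscu_low = rscu_low,
                 delta_rscu = delta, optimal = sort(optimal)),
            class = "optimal_codon_report")
}

#' @export
print.optimal_codon_report <- function(x, ...) {
  cat(sprintf("<optimal_codon_report> pools of %d genes; %d optimal codons\n",
              length(x$high_pool), length(x$optimal)))
  if (length(x$optimal)) cat("  ", paste(x$optimal, collapse = " "), "\n")
  invisible(x)
}

#' High-frequency codons (RSCU > 1)
#'
#' @param table A \code{codon_usage_table}.
#' @return List with \code{codons} (RSCU strictly above 1) and
#'   \code{fraction}: the share of codon occurrences falling in that set.
#' @export
high_frequency_codons <- function(table) {
  r <- rscu(table)
  hf <- names(r)[!is.na(r) & r > 1]
  list(codons = hf,
       fraction = if (table$n_codons)
         sum(table$counts[hf]) / table$n_codons else NA_real_)
}
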