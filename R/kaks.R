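# Pairwise Ka/Ks by the Li-Wu-Luo (LWL, 1985) counting method and its
# modified form (MLWL, Tzeng et al. 2004).
#
# LWL85, as pinned here:
#   - every codon position is 0-, 2- or 4-fold degenerate (3-fold Ile
#     third positions are assigned to the 2-fold class);
#   - L0, L2, L4 are per-class site counts averaged over the two
#     sequences; a changed position whose class differs between the two
#     codons contributes 1/2 to each class;
#   - multi-difference codons are averaged over all substitution
#     pathways (orderings), pathways through stop codons excluded;
#   - P_i, Q_i are transition/transversion proportions per class,
#     A_i = 1/2 ln(1/(1-2P_i-Q_i)) - 1/4 ln(1/(1-2Q_i)),
#     B_i = 1/2 ln(1/(1-2Q_i)), K_i = A_i + B_i (Kimura 2-parameter);
#   - Ks = (L2 A2 + L4 K4) / (L2/3 + L4),
#     Ka = (L0 K0 + L2 B2) / (L0 + 2 L2/3):
#     transitions at 2-fold sites are taken as synonymous, transversions
#     as nonsynonymous, and one third of each 2-fold site is synonymous.
#
# MLWL amendments, as pinned here:
#   - the fixed 1/3 synonymous share of 2-fold sites is replaced by
#     rho = kappa/(kappa+2), the transitional share of the substitution
#     rate, with kappa estimated by K2P over all compared sites
#     (rho = A/(A+B) on the pooled distances); at kappa = 1 this reduces
#     to LWL85 exactly:
#     Ks = (L2 A2 + L4 K4)/(L2 rho + L4),
#     Ka = (L0 K0 + L2 B2)/(L0 + L2 (1-rho));
#   - arginine-family first positions (AGA/AGG/CGA/CGG), where the
#     synonymous single-base change is a transversion, have their
#     transition/transversion roles swapped when accumulating the
#     2-fold-class proportions, so their synonymous transversions are
#     not booked as nonsynonymous. LWL mode keeps the classical
#     (uncorrected) assignment.

TRANSITIONS <- c(A = "G", G = "A", C = "T", T = "C")

is_transition <- function(b1, b2) TRANSITIONS[[b1]] == b2

# First positions whose synonymous alternative is a transversion
# (standard code): the CGN/AGR arginine overlap.
ARG_2V_FIRST <- c("AGA", "AGG", "CGA", "CGG")

#' Degeneracy class of a codon position
#'
#' How many of the three alternative bases preserve the encoded amino
#' acid: none = 0-fold, all three = 4-fold, otherwise 2-fold (this
#' assigns the 3-fold Ile third position to the 2-fold class, the LWL
#' convention).
#'
#' @param codon Sense codon.
#' @param position 1, 2 or 3.
#' @param transl_table Genetic-code number.
#' @return 0, 2 or 4.
#' @export
classify_degeneracy <- function(codon, position, transl_table = 1L) {
  codon <- toupper(codon)
  code <- genetic_code_table(transl_table)
  aa <- code[codon]
  if (is.na(aa) || aa == "*")
    stop("not a sense codon: ", codon)
  stopifnot(position %in% 1:3)
  alt <- setdiff(c("A", "C", "G", "T"), substring(codon, position, position))
  nsyn <- sum(vapply(alt, function(b) {
    v <- codon
    substring(v, position, position) <- b
    identical(unname(code[v]), unname(aa))
  }, TRUE))
  if (nsyn == 0L) 0L else if (nsyn == 3L) 4L else 2L
}

# Class label used in accumulation: "0", "2", "4", or "2V" for the
# transversion-degenerate arginine first positions in MLWL mode.
site_class <- function(codon, position, method, code) {
  aa <- code[codon]
  alt <- setdiff(c("A", "C", "G", "T"), substring(codon, position, position))
  nsyn <- sum(vapply(alt, function(b) {
    v <- codon
    substring(v, position, position) <- b
    identical(unname(code[v]), unname(aa))
  }, TRUE))
  cls <- if (nsyn == 0L) "0" else if (nsyn == 3L) "4" else "2"
  if (method == "MLWL" && cls == "2" && position == 1L &&
      codon %in% ARG_2V_FIRST) cls <- "2V"
  cls
}

k2p_components <- function(P, Q) {
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) return(list(A = NA_real_, B = NA_real_,
                                      saturated = TRUE))
  list(A = 0.5 * log(1 / a1) - 0.25 * log(1 / a2),
       B = 0.5 * log(1 / a2), saturated = FALSE)
}

#' Pairwise Ka and Ks for one aligned gene pair
#'
#' Codon-aligned, equal-length CDS pair; codon pairs containing a gap,
#' an ambiguity symbol or a stop codon are dropped pairwise. See the
#' header of this file for the pinned equations.
#'
#' @param cdsA,cdsB \code{coding_sequence} objects or aligned in-frame
#'   DNA strings of equal length.
#' @param method \code{"MLWL"} (default) or \code{"LWL"}.
#' @param transl_table Genetic-code number.
#' @return A \code{kaks_result}: list with \code{gene}, \code{taxonA},
#'   \code{taxonB}, \code{L} (site counts by class), \code{P}, \code{Q},
#'   \code{A}, \code{B}, \code{Ka}, \code{Ks}, \code{ratio},
#'   \code{kappa}, \code{method}, \code{saturated}, \code{n_codons}.
#' @export
kaks_pair <- function(cdsA, cdsB, method = c("MLWL", "LWL"),
                      transl_table = 1L) {
  method <- match.arg(method)
  gene <- "gene"; ta <- "A"; tb <- "B"
  if (inherits(cdsA, "coding_sequence")) {
    gene <- cdsA$gene; ta <- cdsA$genome_id
    transl_table <- cdsA$transl_table
    cdsA <- cdsA$nt
  }
  if (inherits(cdsB, "coding_sequence")) {
    tb <- cdsB$genome_id
    cdsB <- cdsB$nt
  }
  cdsA <- toupper(cdsA); cdsB <- toupper(cdsB)
  if (nchar(cdsA) != nchar(cdsB))
    stop("sequences must be codon-aligned to equal length")
  code <- genetic_code_table(transl_table)
  stops <- names(code)[code == "*"]
  ca <- split_codons(cdsA); cb <- split_codons(cdsB)
  ok <- ca %in% names(code) & cb %in% names(code) &
    !ca %in% stops & !cb %in% stops
  ca <- ca[ok]; cb <- cb[ok]
  if (!length(ca)) stop("no comparable codon pairs")

  classes <- c("0", "2", "2V", "4")
  # site-class lookup over all sense codons, once per call
  sense <- names(code)[code != "*"]
  cls_tab <- matrix("", length(sense), 3L, dimnames = list(sense, NULL))
  for (cd in sense) for (p in 1:3)
    cls_tab[cd, p] <- site_class(cd, p, method, code)
  L_a <- L_b <- setNames(numeric(4), classes)
  Pn <- Qn <- setNames(numeric(4), classes)   # transition/transversion counts
  for (i in seq_along(ca)) {
    for (p in 1:3) {
      L_a[cls_tab[ca[i], p]] <- L_a[cls_tab[ca[i], p]] + 1
      L_b[cls_tab[cb[i], p]] <- L_b[cls_tab[cb[i], p]] + 1
    }
    if (ca[i] == cb[i]) next
    diffs <- which(strsplit(ca[i], "")[[1]] != strsplit(cb[i], "")[[1]])
    paths <- all_pathways(ca[i], cb[i], diffs, stops)
    wt <- 1 / length(paths)
    for (path in paths) {
      for (step in path) {
        # stop intermediates can only occur in the all-stop fallback
        if (step$from %in% stops || step$to %in% stops) next
        cls_from <- cls_tab[step$from, step$pos]
        cls_to <- cls_tab[step$to, step$pos]
        ts <- is_transition(substring(step$from, step$pos, step$pos),
                            substring(step$to, step$pos, step$pos))
        for (cl in c(cls_from, cls_to)) {
          # role swap at transversion-degenerate sites (MLWL only)
          eff_ts <- if (cl == "2V") !ts else ts
          if (eff_ts) Pn[cl] <- Pn[cl] + 0.5 * wt
          else Qn[cl] <- Qn[cl] + 0.5 * wt
        }
      }
    }
  }
  L <- (L_a + L_b) / 2
  # fold the (role-swapped) 2V accumulators into the 2-fold class
  L2 <- L[["2"]] + L[["2V"]]
  P2n <- Pn[["2"]] + Pn[["2V"]]; Q2n <- Qn[["2"]] + Qn[["2V"]]
  Lc <- c(`0` = L[["0"]], `2` = L2, `4` = L[["4"]])
  Pc <- c(`0` = Pn[["0"]], `2` = P2n, `4` = Pn[["4"]])
  Qc <- c(`0` = Qn[["0"]], `2` = Q2n, `4` = Qn[["4"]])
  P <- ifelse(Lc > 0, Pc / Lc, 0)
  Q <- ifelse(Lc > 0, Qc / Lc, 0)
  comp <- lapply(seq_along(Lc), function(i) k2p_components(P[i], Q[i]))
  names(comp) <- names(Lc)
  saturated <- any(vapply(comp, `[[`, TRUE, "saturated"))
  A <- vapply(comp, `[[`, 0, "A"); B <- vapply(comp, `[[`, 0, "B")
  K <- A + B
  if (!saturated) {
    if (method == "LWL") {
      Ks <- (Lc[["2"]] * A[["2"]] + Lc[["4"]] * K[["4"]]) /
        (Lc[["2"]] / 3 + Lc[["4"]])
      Ka <- (Lc[["0"]] * K[["0"]] + Lc[["2"]] * B[["2"]]) /
        (Lc[["0"]] + 2 * Lc[["2"]] / 3)
    } else {
      tot <- sum(Lc)
      pk <- k2p_components(sum(Pc) / tot, sum(Qc) / tot)
      rho <- if (!pk$saturated && (pk$A + pk$B) > 0)
        pk$A / (pk$A + pk$B) else 1 / 3
      Ks <- (Lc[["2"]] * A[["2"]] + Lc[["4"]] * K[["4"]]) /
        (Lc[["2"]] * rho + Lc[["4"]])
      Ka <- (Lc[["0"]] * K[["0"]] + Lc[["2"]] * B[["2"]]) /
        (Lc[["0"]] + Lc[["2"]] * (1 - rho))
    }
    kappa <- {
      tot <- sum(Lc)
      pk <- k2p_components(sum(Pc) / tot, sum(Qc) / tot)
      if (!pk$saturated && pk$B > 0) 2 * pk$A / pk$B else NA_real_
    }
  } else {
    Ks <- Ka <- kappa <- NA_real_
  }
  ratio <- if (!saturated && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  structure(list(gene = gene, taxonA = ta, taxonB = tb,
                 L = Lc, P = P, Q = Q, A = A, B = B,
                 Ka = unname(Ka), Ks = unname(Ks), ratio = unname(ratio),
                 kappa = kappa, method = method, saturated = saturated,
                 n_codons = length(ca)),
            class = "kaks_result")
}

# All substitution orderings between two codons; each path is a list of
# steps (from-codon, to-codon, changed position). Paths passing through
# stop codons are dropped unless all do.
all_pathways <- function(c1, c2, diffs, stops) {
  perms <- if (length(diffs) == 1L) list(diffs) else {
    if (length(diffs) == 2L) list(diffs, rev(diffs)) else {
      idx <- list()
      for (a in 1:3) for (b in 1:3) for (d in 1:3)
        if (length(unique(c(a, b, d))) == 3L)
          idx[[length(idx) + 1L]] <- diffs[c(a, b, d)]
      idx
    }
  }
  b2 <- strsplit(c2, "")[[1]]
  paths <- list(); clean <- logical()
  for (ord in perms) {
    cur <- c1
    steps <- list(); ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substring(nxt, p, p) <- b2[p]
      steps[[length(steps) + 1L]] <- list(from = cur, to = nxt, pos = p)
      if (nxt %in% stops) ok <- FALSE
      cur <- nxt
    }
    paths[[length(paths) + 1L]] <- steps
    clean[length(clean) + 1L] <- ok
  }
  if (any(clean)) paths[clean] else paths
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("<kaks_result> %s %s vs %s [%s]: Ka %.4f, Ks %.4f, Ka/Ks %s%s\n",
              x$gene, x$taxonA, x$taxonB, x$method,
              x$Ka, x$Ks,
              if (is.na(x$ratio)) "NA" else sprintf("%.3f", x$ratio),
              if (x$saturated) " (saturated)" else ""))
  invisible(x)
}

#' Per-gene Ka/Ks of a genome panel against a reference taxon
#'
#' @param panel Named list: gene -> named character vector of aligned
#'   in-frame CDS per taxon (as produced by \code{\link{align_orthologs}}
#'   via its \code{seqs} element, or the synthetic panel generator).
#' @param reference_taxon Taxon used as the comparison reference.
#' @param method \code{"MLWL"} or \code{"LWL"}.
#' @param transl_table Genetic-code number.
#' @return A \code{kaks_matrix}: list with \code{ratio} (genes x taxa
#'   matrix), \code{ka}, \code{ks}, \code{positive} (logical matrix,
#'   ratio > 1), \code{reference}, \code{method}.
#' @export
kaks_matrix <- function(panel, reference_taxon, method = c("MLWL", "LWL"),
                        transl_table = 1L) {
  method <- match.arg(method)
  genes <- sort(names(panel))
  taxa <- sort(unique(unlist(lapply(panel, names))))
  taxa <- setdiff(taxa, reference_taxon)
  if (!length(taxa)) stop("panel has no non-reference taxa")
  mk <- function() matrix(NA_real_, length(genes), length(taxa),
                          dimnames = list(genes, taxa))
  ka <- ks <- ratio <- mk()
  for (g in genes) {
    seqs <- panel[[g]]
    if (!reference_taxon %in% names(seqs)) next
    for (tx in intersect(taxa, names(seqs))) {
      r <- kaks_pair(coding_sequence(seqs[[reference_taxon]], gene = g,
                                     genome_id = reference_taxon,
                                     transl_table = transl_table),
                     coding_sequence(seqs[[tx]], gene = g, genome_id = tx,
                                     transl_table = transl_table),
                     method = method)
      ka[g, tx] <- r$Ka; ks[g, tx] <- r$Ks; ratio[g, tx] <- r$ratio
    }
  }
  structure(list(ratio = ratio, ka = ka, ks = ks,
                 positive = !is.na(ratio) & ratio > 1,
                 reference = reference_taxon, method = method),
            class = "kaks_matrix")
}

#' @export
print.kaks_matrix <- function(x, ...) {
  cat(sprintf("<kaks_matrix> %d genes x %d taxa vs %s [%s]; %d cells with Ka/Ks > 1\n",
              nrow(x$ratio), ncol(x$ratio), x$reference, x$method,
              sum(x$positive)))
  invisible(x)
}
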