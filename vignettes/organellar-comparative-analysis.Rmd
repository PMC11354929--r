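---
title: "Methods: comparative organellar-genome analysis with organellr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative organellar-genome analysis with organellr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organellr)
```

This vignette is the package's own account of the models and
procedures it implements, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## The setting

Organellar genomes of brown algae are small, gene-dense and highly
conserved: mitogenomes of roughly 35 kb carrying ~65 genes and
plastomes of roughly 125 kb carrying ~173 genes, with intergenic
spacers of only a few percent of the molecule and short overlaps
between neighbouring genes. Comparative studies of such genomes lean
on a standard battery — architecture statistics, codon-usage bias,
C-to-U RNA-editing prediction, repeat censuses, diagnostic SNPs, and
pairwise Ka/Ks — which this package implements as composable, tested R
functions over a single container, the `annotated_genome`.

## Genome model and architecture statistics

Coordinates are 1-based inclusive (the GenBank convention). A feature
interval with start > end on a circular molecule wraps the origin and
is normalized at construction into an ordered pair of intervals; all
downstream statistics are rotation invariant, which the test suite
asserts by rotating genomes and comparing results.

"Overlap" is counted once per unordered pair of *distinct named*
genes, as the size of their positional intersection; gene/CDS
duplicates of one locus therefore never inflate the total. Spacers are
the bases covered by no feature at all, so coverage + spacers always
tile the genome exactly — an invariant checked against a brute-force
per-base occupancy array. Coding fraction uses the union of PCG and
ORF spans (overlaps not double-counted); intron features count toward
gene span (they are not spacer) but not toward coding coverage.

## Codon-usage suite

All codon statistics exclude stop codons and any codon containing an
ambiguity symbol (dropped with a message). RSCU is observed count over
the uniform-use expectation within the synonymous family; families
with zero observations are reported as missing (`NA`), never as zero,
so downstream distances can skip them pairwise. Single-codon families
(AUG, UGG under the standard code) have RSCU exactly 1 whenever
observed — a definitional identity the acceptance suite pins.

The effective number of codons follows Wright: per-family
homozygosity F̂ = (n·Σp̂² − 1)/(n − 1) for families with n ≥ 2,
class means over degeneracy classes {2, 3, 4, 6}, and
Nc = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆, clamped to [20, 61].
Numerical choices: families with F̂ ≤ 0 (possible at small n) are
uninformative and skipped; a missing 3-fold class (Ile unobserved) is
imputed as (F̄₂ + F̄₄)/2 per Wright; any other missing class leaves
ENC undefined rather than guessed. Genes shorter than 30 codons are
flagged but not excluded. An independently written evaluation of the
same formulas serves as the test oracle (agreement to 1e-9).

The mutation-only expectation ENC = 2 + GC3 + 29/[GC3² + (1 − GC3)²]
and the neutrality regression (OLS of GC12 on GC3; slope read as the
mutation-pressure share) are exact transcriptions. PR2 coordinates are
x = G3/(G3 + C3), y = A3/(A3 + T3) over third positions of sense
codons.

Optimal codons: genes are ranked by ENC; the lowest-ENC
ceiling(10%) are the *high-expression* pool and the highest-ENC decile
the low pool. This orientation is a design choice — the ΔRSCU
methodology presumes strongly biased genes are highly expressed — and
can be inverted with a flag. Ties on ENC break by gene name so pools
are deterministic. A codon is optimal when its RSCU in the
high-expression pool exceeds 1 and ΔRSCU ≥ 0.08; the RSCU > 1
condition is applied to the high pool (the convention is ambiguous in
parts of the literature).

## C-to-U editing prediction

The predictor is homology-guided, in the tradition of organellar
editing-site tools: for each cytidine whose C→T substitution changes
the encoded amino acid (stop-creating changes excluded), an edit is
predicted when the *edited* amino acid matches at least a threshold
fraction of an aligned homolog panel at that column while the
*unedited* amino acid matches less than the threshold. Only
non-synonymous candidates are scored — synonymous edits are invisible
to homology by construction. The default threshold is 0.8 (the
upstream tools do not publish their cutoff); panel columns gapped in
half or more of the members are skipped, and a translated-identity
floor of 0.5 against the panel consensus guards against mis-orthology.
Raising the threshold can only remove predictions (monotonicity is a
tested property).

Classification by hydropathy effect uses a pinned lookup of
(reference aa → edited aa) pairs reproducing the published block
assignments for brown-algal organellar edits, including two quirks
kept deliberately for reproducibility: R→C files under
unchanged-hydrophilic and R→W under unchanged-hydrophobic although
arginine is conventionally hydrophilic, and proline counts as
hydrophobic (P→L unchanged, P→S became-hydrophilic). Pairs outside
the table fall back to the Kyte–Doolittle sign (hydrophobic if
KD > 0) and are flagged `extrapolated`. Under the standard code every
non-synonymous C→T amino-acid pair happens to be in the table, so the
fallback only matters for non-standard codes. Summary percentages are
always reported over the actual site count; editing density is
100 × sites / genome length.

## Repeat detection

Microsatellites are maximal perfect runs of a primitive 1–6 bp motif
at MISA-style copy thresholds (mono 10, di 6, tri–hexa 5; the source
literature does not state thresholds, so the MISA defaults are adopted
and exposed). Motif primitivity suppresses (ATAT)×3 in favour of
(AT)×6. Circular molecules are scanned on the doubled sequence with
calls deduplicated, so origin-spanning runs are found exactly once.

The tandem finder is a *deterministic simplification* of the
probabilistic tools in common use: a period-k array is seeded by a run
of at least k exact k-spaced matches and extended base by base while
the next base matches the per-phase majority consensus; an isolated
mismatch is crossed only when the k bases beyond it all match the
consensus and the overall match fraction stays at or above 0.80. A
perfect array is therefore reported at its exact span with
matches = 1, and a single internal substitution costs exactly one
mismatch (e.g. 24/25 for a 25-bp array). Indels are not modelled:
the published parameter set includes an indel probability, but this
implementation performs ungapped extension only, so arrays containing
insertions or deletions may be split or missed — tandem counts from
gappy arrays are reproduction attempts, not guarantees. Minimum
reported span is 14 bp (the smallest tandem reported in the motivating
data) and never less than two periods.

Dispersed repeats are *exact* maximal pairs of at least 30 bp in four
orientations (forward, reverse, complement, palindromic =
reverse-complement), found by seed-and-extend on left-maximal k-mer
matches; a segment paired with itself and zero-gap adjacent forward
copies (which belong to the tandem detector) are excluded. All three
detectors are validated against independently written brute-force
enumerations over hundreds of seeded cases.

## Diagnostic SNPs

Ortholog panels are aligned codon-aware: equal-length inputs are taken
positionally; otherwise translations are globally aligned to a
reference taxon and gaps back-threaded in whole codons. Columns
containing gaps are excluded from SNP calling (indels are not SNPs);
any gap-free column with two or more alleles is one SNP site
(multi-allelic columns are still one site). Effect is classified by
substituting each allele into the panel-majority codon context, ties
broken toward the alphabetically first codon; any amino-acid-changing
allele makes the site non-synonymous. Taxa are sorted internally so no
output depends on input order.

A site is *diagnostic* for a group when the group is monomorphic for
one allele and no outsider carries it — the only predicate under which
a single sequence identifies the group. The predicate is symmetric for
a two-group world: a site separating two clades diagnoses both. The
asymmetric per-group counts seen in real section-level analyses arise
only with three or more groups. Singleton groups are allowed
(species-level identification).

## Ka/Ks by counting methods

The package implements the Li–Wu–Luo 1985 method and its modified
form, with the equations pinned in the source: per-position degeneracy
classes (0-, 2-, 4-fold; 3-fold Ile third positions assigned to
2-fold), site counts averaged over the two sequences with 1/2-splits
when the two codons disagree, pathway averaging for multi-difference
codons (stop-crossing pathways excluded), Kimura two-parameter A/B
corrections per class, and

Ks = (L₂A₂ + L₄K₄)/(L₂/3 + L₄), Ka = (L₀K₀ + L₂B₂)/(L₀ + 2L₂/3).

The modified method replaces the fixed 1/3 synonymous share of
two-fold sites with ρ = κ/(κ + 2) — the transitional share of the
substitution rate — using the K2P κ estimated from the full pairwise
comparison; at κ = 1 it reduces exactly to the classical formulas.
Arginine-family first positions (AGA/AGG/CGA/CGG), where the
synonymous single-base change is a *transversion*, have their
transition/transversion roles swapped in the modified method's
two-fold accumulation so their synonymous transversions are not booked
as non-synonymous; classical mode keeps the uncorrected assignment.
Ks = 0 yields a missing ratio (never infinity); saturated pairs
(K2P log argument ≤ 0) are flagged, not silently dropped.

**Recovery harness.** `simulate_kaks_pair()` plants substitution
counts *in the estimator's own site units* (synonymous changes at
4-fold third positions, non-synonymous at 0-fold positions, one per
codon, counts = round(ks·S) and round(ω·ks·N) with S = L₄ + L₂/3,
N = L₀ + 2L₂/3), so the planted dN/dS is ω by construction in exactly
the units the estimator reports. The default synonymous divergence is
ks = 0.04, the congeneric organellar range. Two properties of counting
methods surfaced while designing this harness and are worth knowing:
(1) at higher divergence, count-planting without multiple hits makes
the multiple-hit corrections overshoot (≈ +6% on ω = 3 at ks = 0.08);
(2) the mutation–selection ω of a substitution *process* differs from
the counting-method estimand by code-structure factors (stop-codon
rejection depresses the non-synonymous rate; Ile 3-fold sites,
classified 2-fold, inflate the synonymous rate) — a process simulated
at ω = 3 has a realized count-ratio near 2.7. Recovery is therefore
checked in estimand-consistent units at low divergence, where the mean
estimate over 20 replicates of 500 codons lands within 0.05 of ω for
ω ∈ {0.2, 1, 3}.

## Phylogenetic summaries

These are sanity-check tools, not replacements for model-based
inference (Bayesian tree building is explicitly out of scope):
p-distance over gap-free shared columns of an alphabetically
concatenated shared-gene supermatrix, Saitou–Nei neighbor joining (via
ape, negative branch lengths clamped to zero), and average-linkage
clustering of RSCU vectors on Euclidean distance over shared
non-missing codons. NJ on additive matrices recovers the generating
topology, which the tests assert with the classic 4-taxon additive
matrix.

## The synthetic world

The generator's defaults *are* the stated world the package is tested
in: a circular 34,686-bp mitogenome with 65 genes (35 PCG, 25 tRNA,
3 rRNA, 2 ORF), 188 bp of overlap in 12 pairs, 1,597 bp of intergenic
spacers, 8,780 encoded amino acids, a Fucales-style contiguous
trnS–trnD–trnA–rps10 block, five light-chain PCGs, AT-biased third
codon positions (odds 3 for A/U-ending codons, extra weight on TTA
and GTT), and background GC of 0.35. Where sizes had to be invented
(tRNA 72 bp; rRNAs 1189/2200/119 bp; ORFs of 129 and 377 aa), they
were chosen once to make the architecture totals close exactly at the
stated genome length and are not revisited.

Construction choices worth knowing:

* Overlapping junctions always involve at least one RNA/ORF feature,
  never two PCGs, so overlapping genes cannot violate each other's
  reading frames; real genomes do overlap PCG pairs, but for every
  statistic in this package only the totals and pair counts matter.
* Planted repeats are written into reserved spacer slots with
  mismatching flank bases on both sides (chosen to mismatch under all
  four orientation transforms), so planted spans are maximal and
  recovery can be asserted exactly.
* Planted editing sites overwrite interior codons of plus-strand PCGs
  with codons whose C→T change is non-synonymous; the homolog panel
  then carries the edited amino acid at those positions with a
  configurable agreement rate.
* Clade panels descend all taxa from one ancestor and plant
  substitutions with exact effect control: synonymous at 4-fold third
  positions, non-synonymous at 0-fold positions (validated against the
  degeneracy classifier), one per codon, applied to every member of
  the target group — diagnostic by construction.

What a green test does *not* establish: the generator's background is
i.i.d. and its genes are random-codon sequences, so it has none of the
compositional heterogeneity, strand asymmetry, or repeat-mediated
rearrangement structure of real organellar genomes; detector
equivalence and parameter recovery on this world say the algorithms
implement their stated rules, not that the rules capture every
property of real data.

## Known limitations

* The tandem finder's ungapped extension misses indel-containing
  arrays (see above).
* The GenBank parser covers the subset needed here (LOCUS topology,
  join/complement locations, the qualifiers the package writes);
  exotic location operators and rich qualifier sets of arbitrary
  records are out of scope.
* Counting-method Ka/Ks is known to be biased at high divergence and
  under strong transition bias relative to ML estimators; the modified
  method mitigates, not removes, this.
* The reference-anchored protein alignment is adequate for congeneric
  panels (the intended use); deeply diverged orthologs should be
  aligned externally and supplied pre-aligned.
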