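---
title: "Methods: duplication, molecular evolution, and expression profiling in famevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: duplication, molecular evolution, and expression profiling in famevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famevol)
```

`famevol` characterizes a plant gene family from three kinds of input: a
gene-coordinate table (id, chromosome, start, end, strand; 1-based
inclusive), CDS and protein FASTA files, and a qPCR Cq table. This vignette
explains the models and procedures behind each stage, the parameters that
matter, and the choices made where conventions genuinely diverge.

## Duplicate calling and classification

Duplicate pairs are called from all-against-all pairwise protein alignment:
Smith–Waterman with affine gaps (open 11, extend 1) and BLOSUM62. This is a
deterministic, exhaustive stand-in for the reciprocal BLASTP searches
normally used at this step — the duplicate rule consumes only identity and
coverage, not E-values, so search heuristics and their statistics add
nothing here. Identity is counted over all aligned columns of the local
region (gap columns count as mismatches); coverage of each sequence is its
locally aligned span over its length. A pair is a duplicate when identity
and **both** coverages are strictly greater than the threshold (default
80%): duplicate pairing is reciprocal, so the coverage requirement is
applied symmetrically. Whether identity should be computed on protein or
CDS is not settled usage; protein is used here, matching how family
surveys BLAST protein queries.

Classification uses only the coordinate table. The distance between two
genes is the **nearest-edge** gap between their spans (0 if they overlap);
a pair on one chromosome with distance ≤ 100 kb (inclusive boundary —
"within 100 kb" is read inclusively) is tandem, anything else segmental.
Cross-chromosome pairs are segmental by construction, and scaffold labels
such as `Chr00` are ordinary chromosome values for the same/different
test. Nearest-edge rather than start-to-start is the stricter reading of
"distance between genes"; on the bundled pumpkin GST table both conventions
agree on every published pair.

Clusters are found by a greedy left-to-right sweep per chromosome: a run is
anchored at the leftmost unassigned gene and collects all genes whose start
lies within 200 kb of the anchor's start; runs of ≥ 3 members ("more than
two genes") are reported, and no gene joins two clusters. The greedy
anchored sweep is deterministic and reproduces the single published cluster
on chromosome 4; a maximal-window formulation could in principle merge
chains of genes pairwise within 200 kb but spanning more, which is not what
"genes within 200 kb" describes.

## Nei–Gojobori Ka/Ks

The codon-level machinery implements the unweighted Nei–Gojobori (1986)
method. For each sense codon, each of its nine single-nucleotide neighbors
is classified as synonymous or not; the synonymous fraction per position
accumulates into the synonymous site count S, with N = 3 − S. Changes that
would create a stop codon are excluded and the position's fraction is
renormalized over the remaining alternatives, so S + N = 3 holds exactly
for every codon. (Implementations differ here; renormalization keeps the
site identity exact and is the common choice.)

Differences between two codons mismatching at k positions are averaged
over all k! single-step pathways; pathways through stop codons are
excluded. If *every* pathway is blocked — possible for a handful of the
61 × 61 sense-codon pairs — all k steps are counted as nonsynonymous and a
warning is raised, since calling any step synonymous would require an
inviable intermediate.

Codon alignments are built by back-translating a protein alignment
(`back_translate()`), so alignment happens in amino-acid space and frame is
preserved by construction; columns gapped in either sequence are dropped
(complete deletion at codon level, consistent with the tree module).
Sites are averaged between the two sequences (S = (S₁+S₂)/2), proportions
pS = Sd/S and pN = Nd/N are corrected with the Jukes–Cantor formula
d = −(3/4)·ln(1 − (4/3)p), and the ratio ω = Ka/Ks is classified as
purifying (< 1), neutral (= 1 within 1e-9), or positive (> 1). The
correction saturates at p ≥ 3/4 (flagged `NA`), and ω is undefined when
Ks = 0 — identical sequences carry no selection signal. No
transition/transversion or codon-frequency weighting is applied: this is
the plain NG86 estimator, which is what distance-based family surveys
report.

Divergence times use the fixed dicot synonymous clock,
T = Ks/(2r) with r = 1.5 × 10⁻⁸ substitutions/site/year, reported in Mya.
Both the rate and the bootstrap/threshold defaults in `pipeline_config()`
are the standard values used in such surveys.

## Phylogeny

Trees are built from protein p-distances under **complete deletion**: every
column containing a gap in any sequence is removed globally before
distances are computed. Neighbor-joining uses the standard Saitou–Nei
agglomeration (`ape::nj`). Negative branch lengths, which NJ can produce on
non-additive matrices, are clamped to zero with the deficit transferred to
a sibling branch at the same node, preserving adjacent path lengths — a
standard practical repair; on additive inputs NJ reproduces the generating
tree exactly and the clamp never fires.

Bootstrap supports resample the retained (gap-free) columns with
replacement, rebuild the tree per replicate, and report for each internal
edge of the full-data tree the percentage of replicates containing that
bipartition. The resampling is seeded and reproducible. An alignment whose
retained columns are all identical yields a degenerate distance matrix; the
arbitrary resolution is returned flagged `unresolved` rather than dressed
up with supports.

Class assignment mirrors how family surveys read class membership off a
reference tree: each unlabeled leaf takes the class of the smallest side of
any bipartition that contains it together with at least one labeled
reference, provided the references in that side are unanimous; conflicts or
absence of such a side leave the leaf `unclassified`. Note that a leaf
attached between two unanimous groups is assigned to the nearer (smaller)
one — the rule is about surrounding clades, not about distances.

## Protein properties

Molecular weight is the sum of average residue masses plus one water
(18.01524 Da), in kDa. The isoelectric point bisects the
Henderson–Hasselbalch net charge on pH ∈ [0, 14] to 10⁻³ pH units; charge
is monotone decreasing in pH and strictly positive/negative at the
bracket ends, so bisection always converges. The pKa table is the
Bjellqvist set as used by the ExPASy Compute pI/Mw tool, including its
residue-specific N-terminal (A, E, M, P, S, T, V) and C-terminal (D, E)
values. One consequence worth knowing: appending an acidic residue changes
the C-terminal pKa (3.55 → 4.55 for D), so it can *raise* the pI of a
short basic peptide slightly even though acidic side chains pull pI down;
the tests therefore probe side-chain monotonicity with internal
insertions. Published per-gene pI/MW tables for specific genomes cannot be
reproduced without the underlying sequences, so validation is
property-based plus a cross-check against an independent implementation.

## Expression profiling

Relative expression uses the Livak 2^-ΔΔCt method. Within each
(gene, line, temperature, time) cell, replicate Cq values are averaged
*before* ΔCt = Cq_target − Cq_reference is formed; ΔΔCt is taken against
the calibrator cell of the same (gene, line, temperature) stratum, by
convention the 0 h time point. Averaging Cq before differencing is the
Livak convention; replicate-level folds (replicate ΔCt against the
calibrator mean) are kept alongside for ANOVA, since letters need
within-group variance. The reference gene (e.g. *Actin*) is carried as a
paired `cq_reference` column rather than as rows of a long table — one
configurable reference, since combining multiple reference genes has no
single standard recipe.

Group comparisons use one-way ANOVA (`stats::aov`) with Tukey's HSD
summarized as a compact letter display (`multcomp::cld`) at α = 0.05.
Zero residual variance with equal means leaves F undefined and is flagged
rather than reported as a number. Heatmap matrices are log2 fold-changes
without row-centering ("transcript abundance" heatmaps in family surveys
are shown on the fold scale); missing cells are imputed as 0 (no change)
and flagged, and optional row ordering uses average-linkage clustering on
correlation distance, with zero-variance rows given correlation 0.

## Synthetic data: what it emulates, and what it does not

`simulate_family()` generates what the coordinate/sequence readers expect:
ancestral CDSs drawn uniformly over the 61 sense codons, duplicate pairs
diverged by point substitutions, and a genomic layout honoring the planted
tandem (same chromosome, configurable nearest-edge offset < 100 kb) or
segmental (different chromosomes) type, with all other spacings > 300 kb so
no unplanned tandem pairs or clusters arise. Substitution budgets invert
the Jukes–Cantor correction: n_syn = p(Ks)·S and n_nonsyn = p(Ka)·N with
p(d) = (3/4)(1 − e^(−4d/3)), placed at random eligible positions, rejecting
changes through stops, with at most one substitution per codon. That last
restriction keeps the planted counts identifiable at the divergences used
(Ks < 0.7 over ≥ 100 codons leaves ample room), which is why parameter
recovery is tight: at ω = 0.3, Ks = 0.2 over 300 codons the median
estimated ratio across 50 seeds sits within ±0.1 of target. Recovery
degrades as Ks grows toward saturation, which the tests check
qualitatively.

The generator does **not** emulate indels, intron structure, codon-usage
bias, rate heterogeneity, or multiple hits per codon. Passing recovery
tests therefore demonstrates correctness of the counting and inference
machinery under the model's own assumptions — not robustness to real
genomes' alignment errors or saturation, where NG86 is known to be
conservative.

`simulate_cq()` plants per-cell log2 fold-changes relative to the time-0
calibrator and adds Gaussian replicate noise (default sd 0.2 cycles, 3
replicates — typical qPCR triplicate behavior) to both target and
reference Cq. Noiseless runs recover planted folds exactly; with noise,
the ΔΔCt error is Gaussian with sd √(4σ²/n), and the tests assert the
observed recovery fraction against that closed form rather than a round
number.

## Problem sizes and determinism

Everything is deterministic given a seed: the simulators, the bootstrap,
and the NJ tie-break (lowest-index pair, inherited from `ape::nj`). The
shipped tests and the acceptance script use 50-seed recovery batches at
300 codons, 200 bootstrap replicates on 8-taxon alignments, and 100–200
simulated qPCR experiments — sizes at which every Monte-Carlo check is
stable across seeds while the whole suite runs in well under a minute for
any single module. The 61 × 61 codon-pair difference table is enumerated
once per session and memoized.

## Known limitations

* NG86 with equal substitution rates underestimates Ks when transitions
  dominate; no ML codon models are provided.
* The duplicate caller is exact pairwise alignment, quadratic in family
  size — fine for families of tens to hundreds, not for genome-scale
  all-vs-all searches.
* Class assignment requires reference leaves in the same tree; it does not
  place queries into an external reference phylogeny.
* The pI model ignores conformational effects and cysteine disulfides, as
  all composition-based calculators do.
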