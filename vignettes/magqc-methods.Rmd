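---
title: "Alignment-free quality prediction for metagenomic bins: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free quality prediction for metagenomic bins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Metagenome-assembled genomes (MAGs) are produced by assembling shotgun reads
and grouping contigs into bins, each hypothesized to represent one genome.
Two quantities summarise how well that worked: **completeness** (what
fraction of the underlying genome's base pairs made it into the bin) and
**purity** (what fraction of the bin's base pairs actually belong to that
genome; the complement of contamination). The dominant way to estimate them
counts single-copy marker genes, which covers only a tiny fraction of a
genome and inherits the biases of existing annotation databases.

`magqc` takes a different route: it estimates completeness and purity from
the *internal compositional consistency* of a bin, with no reference
database and no gene calling. A pure, complete bin consists of fragments
that all look alike compositionally; contamination mixes in fragments from
a genome with a different oligonucleotide signature, and low completeness
changes how much sequence is available and how variable the intra-bin
distances look. A regression model can learn to read those distributional
fingerprints.

## From sequence to predictors

1. **Fragmentation.** Every contig is cut into non-overlapping fixed-length
   fragments (trailing remainders discarded; fragments under 90%
   unambiguous A/C/G/T dropped). Coordinates are 0-based half-open;
   fragments never span contigs.
2. **Signatures.** Four compositional signatures are computed per fragment,
   all on strand-symmetrized k-mer window counts (windows containing N are
   skipped):
   * *Karlin tetranucleotide relative abundance* (the PaSiT4 basis):
     `rho(wxyz) = f(wxyz) f(xy) / (f(wxy) f(xyz))`, observed frequency over
     its second-order Markov expectation; zero denominators give the
     neutral value 1.
   * *Markov z-scores* for trinucleotides (MMZ3) and tetranucleotides
     (MMZ4), the TETRA construction: for k-mer `s` with prefix `p`, suffix
     `q`, overlap `m`, `N_exp = N(p) N(q) / N(m)`,
     `var = N_exp (N(m) - N(p)) (N(m) - N(q)) / N(m)^2`,
     `z = (N_obs - N_exp) / sqrt(var)`, with `z = 0` wherever the variance
     degenerates. For k = 3 the analogous first-order expectation
     (2-mer prefix/suffix, 1-mer overlap) is used — it is the only
     consistent reading of the construction at that word length.
   * *Tetranucleotide frequency profile* (Freq4), the normalized 256-vector.
   * *GC content* per 1 kb fragment (ambiguous bases excluded from both
     numerator and denominator), which stays available even for bins made
     of short contigs.
3. **Distances.** All unordered fragment pairs within a bin are compared:
   PaSiT distance (fraction of Karlin-signature positions differing by more
   than a tolerance, default 0.05) for the Karlin block; Pearson
   correlation mapped to `(1 - r) / 2` for MMZ3/MMZ4/Freq4. Pearson is used
   because that is the comparison TETRA-style z-score vectors were designed
   for. The `(1 - r) / 2` mapping puts all methods on `[0, 1]`; the
   distribution statistics are affine-equivariant, so the choice only
   rescales features consistently. Zero-variance vectors get `r = 0`
   (maximal ignorance) rather than NaN. Beyond 500,000 pairs a seeded
   uniform subsample is used and recorded.
4. **Distribution statistics.** Each distance set (and the set of
   per-fragment GC values) is summarised by 11 statistics: mean, sample SD,
   skewness `m3/m2^1.5`, excess kurtosis `m4/m2^2 - 3` (n-denominator
   moments; both defined as 0 for zero-variance input), median, and the
   2.5/5/10/90/95/97.5 percentiles under the `h = (n-1) q` interpolation —
   the defaults of the major statistical environments, recorded in the
   model schema so train and predict always agree.

Each of the five blocks contributes its 11 statistics plus the fraction of
the bin covered by its fragments and its number of comparisons; with the
bin size that totals **66 predictors** (5 × 13 + 1). The GC block uses the
raw per-fragment GC values, not pairwise differences: it describes a
distribution of a per-fragment property, and its bookkeeping columns are
counted like the distance methods' — the only decomposition consistent
with the 66-variable schema.

### Fragment lengths and tiers

Each method has a fragment length at which its signature is informative:
the production mapping is PaSiT4 at 50 kb, MMZ3 and MMZ4 at 10 kb, Freq4 at
5 kb, GC at 1 kb. Long fragments give more stable signatures but exclude
bins without long contigs, so the blocks degrade gracefully: a block is
*available* when the bin yields at least 3 fragments at its length (2 for
the GC block, whose statistics need no pairs), and the bin's **tier** is
the largest fragment length at which everything at or below it is
available. The per-tier predictor counts are fixed by the schema: 66, 53,
27 and 14 for the 50/10/5/1 kb tiers. A bin is *eligible* when it has one
contig longer than twice the GC fragment length or at least two contigs
longer than the GC length (with 1 kb GC fragments: one contig > 2 kb or
multiple > 1 kb). Taken literally, one contig just over 2 kb yields only
two non-overlapping 1 kb fragments — which is why the GC block's minimum
is 2; the distance blocks require 3.

## The model

Per tier, predictors are log10-transformed after a per-variable shift
(`1 - min` when the minimum is non-positive — skewness and kurtosis can be
negative), centred, unit-scaled and projected by PCA; the smallest number
of components explaining ≥ 95% of variance is kept. The random forest (500
trees, `mtry = floor(p/3)`, node size 5 — the long-standing defaults of the
reference implementation of random forests in R) sees the *original
untransformed predictors plus the PCA scores*. A linear calibration
(ordinary least squares of truth on 10-fold out-of-fold forest
predictions, refitting the preprocessor inside each fold) corrects the
forest's shrinkage towards the training mean; predictions are clipped to
`[0, 100]` and F1 is the harmonic mean of predicted completeness and
purity. At prediction time every eligible bin is served by the largest
bundle tier not exceeding its own, so bins lacking long contigs fall back
to models trained without the missing blocks — every eligible bin gets a
score.

Open choices resolved here (stored in the bundle so train/predict agree):
calibration is fitted per tier; PCA loadings are tier-specific (the only
option that avoids masked cells); test-time log arguments that fall at or
below zero are clamped to the smallest positive training argument.

The optional CheckM-augmented variant appends the numeric columns of a
CheckM `qa` table (completeness, contamination, strain heterogeneity) to
the predictor set of every tier before preprocessing; everything else is
unchanged. A bundle trained with covariates refuses to predict without
them.

## Ground truth and evaluation

With known contig origins (exact in synthetic data), a bin's best-matching
genome is the one with the most assigned base pairs (ties to the
lexicographically smallest id); completeness is `100 * matching_bp /
genome_size` (capped at 100 against pathological duplication), purity is
`100 * matching_bp / bin_size`, and `F1 = 2 RP / (R + P)` with completeness
as recall and purity as precision. CheckM's redundancy-based contamination
(which can exceed 100%) converts to a bounded purity via
`100 * 100 / (100 + contamination)`, a bijection whose inverse recovers
contamination exactly. Predictions are scored by
`R2_yx = 1 - sum((y - x)^2) / sum((x - xbar)^2)` — negative when worse than
predicting the observed mean — and RMSE.

## Fragment-length optimisation

`qda_fraglen_accuracy()` scores a (method, length) combination on a panel
of genomes: fragment every genome with 50% overlap, compute signatures,
reduce the pooled signatures to two principal components, find the genome
pair with the closest centroids ("most overlapping"), and report the
resubstitution accuracy of a quadratic discriminant between that pair's
fragments in 2-PC space. "Most overlapping" is operationalized as nearest
centroids because separability is what the downstream scan ranks;
resubstitution (not cross-validated) accuracy is used because the score is
a separability index, not a generalisation claim. Identical genomes sit at
chance (0.5); accuracy rises with fragment length as signatures stabilise.
`select_fragment_lengths()` returns the production mapping restricted to
the scanned grid (closest available length when the canonical one is
absent) together with the full grid for manual override.

## The synthetic data generator

Because the method is purely compositional, order-2 Markov chains generate
exactly the signal structure the signatures detect. Each genome draws
per-context transition probabilities from a Dirichlet distribution
(concentration 0.5 by default — smaller is more distinctive), with every
context's conditional G+C probability pinned to the genome's GC target so
realized GC concentrates tightly around it. Bins are cut from a randomly
placed contiguous region of the source genome totalling the target
completeness, with log-normal contig lengths (median 5 kb at desk scale);
contaminant contigs are appended from other genomes, spread so no
contaminant outweighs the source. Truth is recorded exactly from
provenance and always equals what `gold_standard()` recomputes.

What the generator does *not* emulate: real assembly artefacts (chimeric
contigs, coverage-dependent fragmentation, sequencing error), strain-level
mosaicism, repeats shared across genomes, and the phylogenetic structure
of real communities. Passing the recovery tests therefore shows the
pipeline is implemented coherently end to end and that compositional
signal of realistic strength is recovered — not that the trained desk-scale
bundle transfers to real assemblies; production use requires training on
bins from real or mock communities at the production fragment lengths.

## Problem sizes and numerical choices

The package's own validation runs at desk scale: genomes of 200–500 kb,
fragment lengths scaled by ten (5/2/2/1/0.5 kb, `desk_config()`), 20
genomes × 200 bins with completeness targets uniform on [0.2, 1] and
purity on [0.3, 1], and 5-fold cross-validation of the full pipeline —
held-out completeness `R2_yx` ≈ 0.57 and purity ≈ 0.99 with both targets
far below the mean-label baseline RMSE (the exact numbers are recomputed
by `scripts/acceptance.R` and by the test suite, never copied). Purity is
the easier target here because contamination mixes visibly distinct
compositions, while completeness must be inferred indirectly from bin size
and fragment-count bookkeeping against genomes of unknown size.

Determinism: every stochastic step (genome and bin simulation, pair
subsampling, fold assignment, forest fitting) flows from explicit integer
seeds, and repeated runs are byte-identical. Degenerate inputs are
defined, not special-cased away: constant distance sets give zero
skewness/kurtosis, constant labels give constant calibrated predictions,
zero-variance predictor columns are kept with scale 1 and flagged.

## Known limitations

* Numeric identity with the original GenDisCal/PaSiT implementation of the
  Karlin signature is not guaranteed (that tool's exact normalisation is
  not reproduced here, and whether its counts were symmetrized is
  unknown); the framework is self-consistent either way because the same
  signature code runs at train and predict time.
* Purity predictions on real data should be treated with caution — the
  compositional route and the marker-gene route both have high error on
  contaminated bins; on synthetic data purity looks far easier than it is
  in reality.
* The eligibility rule admits bins (one contig just over 2 kb) whose
  50/10/5 kb blocks are all unavailable; they are served by the GC-only
  tier, whose predictors are the weakest.
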