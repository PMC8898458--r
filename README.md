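# magqc — alignment-free quality prediction for metagenome-assembled genomes

Binning metagenomic assemblies produces bins of contigs, each hoped to be
one genome. `magqc` estimates the two standard quality metrics of such a
bin — **completeness** (fraction of the source genome's base pairs present,
%) and **purity** (fraction of the bin's base pairs belonging to that
genome, %) — *without* reference databases, marker genes or gene calling.
It is aimed at people assembling and binning metagenomes, in particular
from poorly characterised environments where single-copy-marker-gene tools
(CheckM and kin) lean on references that do not cover the community.

## How it works

Contigs are cut into fixed-length fragments and four compositional
signatures are computed per fragment on strand-symmetrized k-mer counts:

* **PaSiT4** — Karlin tetranucleotide relative abundances
  ρ(wxyz) = f(wxyz)·f(xy) / (f(wxy)·f(xyz)), compared between fragments by
  the fraction of positions differing by more than a tolerance (0.05);
* **MMZ3 / MMZ4** — TETRA-style Markov z-scores,
  z(s) = (N_obs − N_exp)/√var with N_exp = N(p)N(q)/N(m) from
  prefix/suffix/overlap counts, compared by Pearson correlation;
* **Freq4** — raw tetranucleotide frequency profiles, also compared by
  correlation;
* **GC** — per-fragment GC content.

Each method runs at its own fragment length (50/10/10/5 kb, GC at 1 kb).
The distribution of all-against-all intra-bin distances per method is
summarised by 11 statistics (mean, SD, skewness, kurtosis, median,
2.5/5/10/90/95/97.5 percentiles) plus the bin fraction used and the number
of comparisons; with the bin size this gives **66 predictors**. Tiered
random forests (with log/PCA-augmented inputs and cross-validated linear
calibration) map the predictors to completeness and purity; bins lacking
long contigs fall back to models trained without the missing blocks, so
every bin with one contig > 2 kb or two contigs > 1 kb gets a prediction.
An optional variant additionally consumes the numeric columns of a CheckM
`qa` table as covariates.

Because training needs bins of known quality, the package includes a
synthetic mock-community generator (seeded order-2 Markov-chain genomes,
bins cut with exact per-contig provenance) whose completeness/purity labels
are exact by construction, plus the gold-standard labeller, the evaluation
metrics (R²_{y∼x}, RMSE, F1, the CheckM contamination→purity conversion)
and a QDA-based fragment-length optimiser.

## Worked example

Simulate a small labelled community, extract features, train, predict and
score (desk-scale fragment lengths for the small genomes):

```r
library(magqc)
cfg <- desk_config()
sim <- simulate_dataset(n_genomes = 5, n_bins = 30,
                        genome_length_range = c(60000, 100000), seed = 42)
feats  <- magqc_features(sim$bins, cfg)
bundle <- train_quality_model(feats, sim$truth, cfg, seed = 42)
pred   <- predict_quality(bundle, feats)
head(pred, 4)
#>   bin_id tier completeness_pred purity_pred f1_pred
#> 1 bin001 5000             78.39       52.14   62.63
#> 2 bin002 2000             25.90       53.87   34.98
#> 3 bin003 5000             34.64       70.39   46.43
#> 4 bin004 5000             89.90       71.34   79.55
evaluate_predictions(pred, sim$truth)
#>         target r2_yx rmse  n
#> 1 completeness 0.964 4.23 30
#> 2       purity 0.971 3.32 30
#> 3           f1 0.958 3.35 30
```

`tier` is the fragment length (bp) of the model that served each bin —
bin002 lacks 5 kb-capable contigs and was scored by the 2 kb-tier model.
The predictions are percentages; `r2_yx = 1 − Σ(y−x)²/Σ(x−x̄)²` compares
them to the known truth (these are resubstitution numbers on the training
bins, hence optimistic; held-out performance is what the acceptance script
measures). A command-line front end with the same verbs is installed as
`exec/magqc` (`magqc simulate | features | train | predict | evaluate |
optimize-fraglen`).

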