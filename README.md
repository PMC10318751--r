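# microdiscrim

Compositional discrimination of two microbiome populations from metagenomic
feature-count tables.

## The problem

Shotgun metagenomics delivers a table of counts — samples × features, where a
feature is a taxon at some rank or a functional gene family (KEGG/COG ID) —
and a question: *which features separate two populations, and how large are
the shifts?* A motivating setting is livestock selection experiments, e.g.
two rabbit lines divergently selected for the environmental variance of
litter size (a resilience proxy), where the populations' cecal microbiomes
must be discriminated from a few dozen samples and up to ~10⁴ features.
Counts are compositional: only relative information is meaningful, so the
analysis must work in log-ratio coordinates.

`microdiscrim` implements that complete workflow as tested, reusable pieces:

1. **Compositional preparation.** PCA-based outlier sample removal; removal
   of features with ≥ 20% zeros (within either population or overall) unless
   the between-population difference in zero fraction exceeds 0.5 (such
   features are presence/absence-informative); a pseudocount of 1; the
   additive log-ratio (ALR) transform

   `ALR(j | ref) = log(X_j / X_ref) = log X_j − log X_ref`

   with the reference chosen by the Greenacre criteria — lowest coefficient
   of variation of log counts among high-abundance features, accepted only if
   the Procrustes correlation between the ALR geometry and the full (centered
   log-ratio) geometry exceeds 0.9 — followed by auto-scaling to mean 0,
   SD 1.
2. **PLS-DA feature selection.** A from-scratch NIPALS PLS-DA (≤ 10
   components) on the dummy-coded population vector; component count tuned by
   the balanced error rate (BER) of Mahalanobis-distance classification under
   stratified fourfold cross-validation repeated 100 times; iterative
   retention of features with VIP > 1 until BER < 0.02 or no further
   improvement; validation by a cross-validated confusion matrix (default
   10,000 repeats) and a label-permuted confusion matrix whose true-positive
   rate should sit at the 50% two-class chance level.
3. **Bayesian relevance screen.** Per selected feature, a flat-prior
   two-group normal model sampled by Gibbs (4 chains × 50,000 iterations,
   lag 10, burn-in 1,000), convergence checked by split R-hat < 1.05;
   reported as the posterior mean difference in SD units, P0 (posterior
   probability the difference is > 0 if positive, < 0 if negative) and the
   narrowest 95% HPD interval; features with |mean| > 0.5 SD and P0 > 0.9 are
   flagged relevant.
4. **Diversity.** Shannon H′ and inverse Simpson with Mann–Whitney U group
   tests; Bray–Curtis dissimilarity, nonmetric MDS (Kruskal stress-1,
   PAVA monotone regression), and PERMANOVA on the first two ordination
   dimensions.

A synthetic-data generator (`simulation_design()` / `generate_counts()`)
produces two-population count tables with planted differential features —
log-normal abundance spectrum, multinomial counting with overdispersed
library sizes, structural zero inflation, and a designated reference-like
feature — so every stage can be tested against known ground truth.

## Worked example

```r
library(microdiscrim)

cfg <- pipeline_config(
  design = simulation_design(n_pop1 = 34, n_pop2 = 28, n_features = 200,
                             n_differential = 30, effect_sizes = c(1, -1),
                             seed = 11),
  tuning_repeats = 20, confusion_repeats = 100, iterations = 5000,
  burn_in = 1000, thinning_lag = 10, seed = 202)
report <- run_pipeline(cfg)
print(report)
```

```
<run_report>
  input:     62 samples x 200 features (simulation)
  transform: 200 features kept, reference F173, 0 sample(s) removed
  plsda:     51 features, 1 components, CV-BER 0.0007, accuracy 0.999, precision 1.000
  permuted classification rate: 54.6% / 47.0%
  bayes:     51 screened, 51 converged, 38 relevant
  diversity: Shannon p 0.416, invSimpson p 0.882, NMDS stress 0.171, PERMANOVA p 0.272
```

Reading the report: the generator planted 30 differential features (half
up-shifted in population 1, half down) at one within-feature SD. The
iterative PLS-DA kept 51 features and classifies the two populations almost
perfectly (CV-BER 0.0007), while the label-permuted confusion matrix stays
near the 50% chance level — the separation is not spurious. The Bayesian
screen confirms 38 of the 51 as relevant (|posterior mean| > 0.5 SD,
P0 > 0.9, R-hat < 1.05). Alpha diversity and the PERMANOVA on the NMDS
ordination show no population difference — with balanced up/down shifts in a
handful of features the two communities remain globally similar, and the
discrimination rests on the specific features, not on overall diversity.

```r
head(report$relevant_features[, c("feature_id", "mean_diff_sd_units", "p0",
                                  "hpd95_lower", "hpd95_upper", "rhat")], 5)
```

```
  feature_id mean_diff_sd_units p0 hpd95_lower hpd95_upper      rhat
1       F017           1.177676  1   0.7549313   1.6150997 1.0017849
2       F170           1.149574  1   0.7019525   1.5385446 1.0009261
3       F072           1.147672  1   0.7085027   1.5763605 1.0000992
4       F126           1.119395  1   0.6660627   1.5346533 0.9996490
5       F080          -1.078185  1  -1.5268388  -0.6276148 0.9999783
```

Each row is one feature's posterior: the mean shift between populations in
units of the (auto-scaled) feature's SD, P0, the 95% highest-density
interval, and the convergence diagnostic.

## Command line

Every stage is also a subcommand of the installed `exec/microdiscrim`
script, reading/writing delimited text in an output directory so stages can
be run or resumed independently:

```sh
Rscript exec/microdiscrim run-all  --config config.json --out results/
Rscript exec/microdiscrim simulate --config config.json --out results/
Rscript exec/microdiscrim bayes    --config config.json --out results/
```

`config.json` is written/read by `write_pipeline_config()` /
`read_pipeline_config()`.

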