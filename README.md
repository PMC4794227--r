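# entvar

Entropy- and structure-based prediction of disease-associated missense
variants in human proteins.

Most amino-acid substitutions found in an exome are harmless; the few that
cause Mendelian disease tend to hit evolutionarily conserved positions and
structurally constrained neighbourhoods.  entvar scores a substitution by
combining, in a gradient-boosted regression-tree model:

* **relative sequence entropy** — the Shannon entropy
  `S = -Σ f_l ln f_l` of a homolog-alignment profile column, centred by
  the protein mean (`RS = S - <S>`), with homologs filtered to a 35–90%
  identity window to the query and to each other;
* **contact composition** — amino-acid-type fractions among residues whose
  Cα lies within 12 Å of the mutated Cα in a (predicted) 3D model;
* **domain composition** — type fractions over the domain/segment
  containing the position;
* **one-hot wild-type and mutant residue encodings**.

That is 81 features per substitution.  The score is the additive ensemble
`f(x) = Σ_m ε·T_m(x)` (ε = 0.005, 2000 trees, depth ≤ 8) trained by
least-squares boosting on 0/1 labels; scores above 0.45 (strict) are
called disease-associated, with 0.20/0.55 as recall/precision-leaning
alternatives.  The package is written for variant-effect-prediction
researchers: it contains the whole training protocol (balanced-protein 6×
over-sampling, variation-level and family-grouped splits, allele-frequency
pre-filter), the evaluation suite (MCC, accuracy, sensitivity,
specificity, PPV, NPV, tie-exact AUC, false-positive-rate
cross-regression), saturation-mutagenesis hot-spot analysis, and a seeded
synthetic-data generator with planted signal so every stage is testable
without external downloads.

The package is tidyverse-native: user-facing functions take data frames
first and return tibbles, fitted models have `tidy()`/`glance()` methods,
and result types have `autoplot()` methods.

## Worked example

```r
library(entvar)

# a fully seeded synthetic benchmark: 20 proteins x 100 residues,
# 40-homolog alignments, chain models, 2,000 labelled substitutions
ds <- make_dataset(synthetic_spec(seed = 11))
sp <- split_variants(ds$variants, 0.5, seed = 42)

train <- encode_variants(oversample_balanced(sp$train),
                         ds$alignments, ds$structures, ds$segments)
test  <- encode_variants(sp$test, ds$alignments, ds$structures, ds$segments)

model  <- gbrt_fit(train, n_trees = 200)
scores <- predict(model, test)
evaluation_report(scores, test$variants$label, cutoff = 0.45)
#> # A tibble: 1 × 12
#>   cutoff    tp    tn    fp    fn   MCC   ACC   Sen   Spe   PPV   NPV   AUC
#>    <dbl> <int> <int> <int> <int> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1   0.45   542   442     4    12 0.968 0.984 0.978 0.991 0.993 0.974 0.985
```

The report reads: at the 0.45 cutoff the model recovers 97.8% of the
held-out disease variations (sensitivity) while calling only 4 of 446
neutral ones disease-associated (specificity 0.991); the threshold-free
AUC of 0.985 confirms the planted conservation/contact signal is almost
fully recovered.  Scanning all 19 substitutions at every position of the
first protein and calling positions where *all* of them score > 0.45:

```r
scan <- saturation_scan(model, ds$alignments[[1]], ds$structures[[1]], ds$segments)
hot_positions(scan, cutoff = 0.45)
#> <hotspot_profile> 'SP001': 51/100 covered positions hot (fraction 0.510, cutoff 0.45)
```

A command-line front end over the same functions is in
`inst/cli/entvar.R` (subcommands `simulate`, `entropy`, `train`,
`predict`, `evaluate`).

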