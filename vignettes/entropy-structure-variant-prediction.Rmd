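---
title: "Predicting disease-associated missense variants from sequence entropy and predicted structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting disease-associated missense variants from sequence entropy and predicted structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entvar)
```

## The problem and the model

Exome sequencing yields thousands of missense variants per individual, very
few of which cause disease.  entvar scores a single amino-acid substitution
for disease association by combining three kinds of evidence in a boosted
regression-tree model:

1. **Evolutionary conservation.**  From a multiple alignment of homologs to
   the query protein, a per-position frequency profile over the 20 standard
   residues is built.  Before counting, homologs are filtered to a 35–90%
   identity window — to the query *and* to each other — so that
   near-duplicate database sequences cannot dominate the counts.  Each
   column's Shannon entropy $S = -\sum_{l=1}^{20} f_l \ln f_l$ (nats) runs
   from 0 at a fully conserved position to $\ln 20 = 2.996$ at a uniform
   one.  The feature actually used is the *relative* entropy
   $RS = S - \langle S \rangle$, the column entropy minus the protein-wide
   mean.  Centring removes protein-level effects: a protein with a shallow
   profile (in the limit, only the query itself) has $S = 0$ everywhere,
   which says nothing about any particular position; after centring it
   contributes $RS = 0$ everywhere.  $RS$ sums to zero over each protein by
   construction.

2. **Structural context.**  From a C$_\alpha$ trace of the (typically
   predicted) 3D structure, the *contact composition* is the fraction of
   each residue type among residues whose C$_\alpha$ lies within 12 Å of
   the mutated position's C$_\alpha$ (8 Å as an ablation variant).  The
   *domain composition* is the residue-type fraction over the
   domain/segment containing the position; segment boundaries are inputs
   (1-based inclusive spans), and positions not covered by any segment fall
   back to the whole sequence.  Composition vectors sum to 1, or are an
   all-zero sentinel when there is no neighbor or segment content.

3. **Substitution identity.**  The wild-type and mutant residues are
   one-hot encoded (20 + 20 values), reflecting that some substitution
   types (e.g. cysteine loss) are systematically more damaging.

The full feature vector has 81 values in a fixed block order —
$RS$ (1) | wild one-hot (20) | mutant one-hot (20) | domain (20) |
contact (20) — and the score is an additive tree ensemble

$$ f(x) = \sum_{m=1}^{N_{tree}} \varepsilon\, T_m(x), $$

trained by least-squares gradient boosting on labels 1
(disease-associated) and 0 (neutral), with $\varepsilon = 0.005$,
$N_{tree} = 2000$ and maximum tree depth 8 as the standard operating
point.  A variant is called disease-associated when its score exceeds a
cutoff, by default 0.45 (strictly greater); 0.55 trades recall for fewer
false positives and 0.20 does the reverse.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_id`, `max_id` | 0.35, 0.90 | homolog identity window (fractions) for profile counting |
| `contact_cutoff` | 12 Å | C$_\alpha$ distance defining the contact shell (8 Å in the `cut8` preset) |
| `n_trees` | 2000 | boosting iterations |
| `shrinkage` | 0.005 | learning rate $\varepsilon$ |
| `max_depth` | 8 | maximum tree depth |
| `min_leaf` | 5 | minimum samples per leaf |
| `cutoff` | 0.45 | disease call threshold (alternatives 0.20, 0.55) |
| `copies` | 6 | total copies of balanced-protein variations after over-sampling |
| balance bounds | [0.3, 3.0] | inclusive neutral/disease ratio window defining a balanced protein |
| allele-frequency filter | 0.17 | variants at or above this population frequency are assumed neutral |

The boosting hyperparameters are deliberately plain: no row or feature
subsampling, no early stopping, so a fit is a pure function of its inputs
and two fits on identical data are bit-identical.  `min_leaf = 5` is our
own regularisation choice — the depth-8 trees would otherwise carve
single-sample leaves on small data; it is configurable and the unit tests
exercise `min_leaf = 1` where exact interpolation is the point.

## Training protocol

Real variant collections are dominated by proteins that carry only neutral
(or only disease) variations, so a model can score well by classifying
*proteins* rather than *variations*.  The protocol counters this in two
places:

* **Balanced-protein over-sampling.**  A protein is *balanced* when it has
  at least one disease variation and its neutral/disease ratio lies in
  [0.3, 3.0] (bounds inclusive).  Before training, every variation on a
  balanced protein is replicated to 6 total copies
  (`oversample_balanced()`), so neutral variations on balanced and
  unbalanced proteins carry roughly equal weight.  Over-sampling is applied
  to the training side only, after splitting.
* **Splits.**  `split_variants()` partitions at the variation level with a
  required seed.  `grouped_kfold()` assigns whole protein families to
  folds (greedy largest-first packing into the smallest fold), so a test
  fold shares no family with its training fold — the hardest evaluation
  setting.

For exome screening, `allele_frequency_filter()` removes variants with
population allele frequency ≥ 0.17 up front: such common variants are
essentially never disease-associated, and the filter shrinks the
annotation workload to roughly a quarter.

## Evaluation

`classification_metrics()` implements MCC, accuracy, sensitivity,
specificity, PPV and NPV from the confusion counts (disease = positive);
`roc_auc()` uses the tie-aware rank (Mann–Whitney) formulation, which is
exact under ties.  Conventions for degenerate tables: a zero factor in the
MCC denominator gives MCC = 0; an undefined PPV/NPV (empty predicted
class) is reported as `NA`, never 0.  `false_positive_rate()` is the
disease-call fraction on an all-neutral set, and
`fpr_cross_regression()` fits one benchmark's per-method FPRs on
another's by OLS — the intercept at FPR $x = 0$ estimates the apparent
contamination of the $y$-axis benchmark.  OLS (not an errors-in-variables
fit) matches the one-directional form in which such extrapolations are
reported.

## Hot-spot analysis

`saturation_scan()` scores all 19 substitutions at every covered position
of a protein; a position is a *hot spot* when **all** 19 scores strictly
exceed the cutoff.  The hot-spot fraction divides by covered positions
only — positions without structural coverage enter neither numerator nor
denominator, a choice we record here because reported coverage in
practice is ~90% and the alternative (total residues) would
systematically deflate fractions.  Fractions of isoforms sharing a
protein id are averaged.  `threshold_curve()` relates the fractions to an
external per-protein attribute (e.g. protein–protein interaction counts,
or a 0/1 disease flag whose mean is a cumulative fraction) by averaging
the attribute over proteins with fraction ≥ t and reporting the Pearson
correlation along the curve.

## The synthetic generator

`make_dataset()` produces a complete, fully seeded benchmark: per protein
an alignment with a controllable fraction of conserved columns (variable
columns resample letters uniformly at a given rate, which places homolog
identities relative to the 35–90% window), a C$_\alpha$ chain model
(`extended`: collinear at 3.8 Å spacing, so interior residues have
exactly 6 neighbors at 12 Å and 4 at 8 Å; `helix`: 1.5 Å rise, 100°/turn,
2.3 Å radius), a two-segment domain table, and labelled substitutions.

The disease probability of a substitution at position $p$ is

$$ P(\text{disease}) = \mathrm{logis}\big(b + w_{ent}\,(-RS_p) +
   w_{cnt}\,(h_p - \bar h)\big), $$

where $h_p$ is the hydrophobic fraction of the contact shell and the
per-protein intercept $b$ is calibrated (by root finding) so the expected
disease fraction matches the target neutral/disease ratio.  Defaults:
$w_{ent} = 6$, $w_{cnt} = 2$, ratio 1, 20 proteins × 100 residues,
40 homologs, half the columns conserved, 2,000 variants.  The slopes are
chosen to plant a *strong, recoverable* signal — conserved (low-$RS$)
positions are disease-enriched, the premise the entropy feature encodes —
while keeping the signal exclusively in blocks we control: with
$w_{cnt} = 0$ the entropy feature is the only carrier, which gives
ablation experiments a known ground truth, and with both slopes 0 labels
are independent of every feature (the null).

What the generator does **not** emulate: phylogenetic correlation among
homologs (rows are i.i.d. given the query), realistic folds or contact
graphs, position-dependent substitution matrices, domain-level disease
propensity, and label noise from misannotated databases.  Passing the
recovery experiments therefore shows the pipeline is correct and the
learner can extract a conservation/structure signal at realistic sizes —
not that real-data benchmark numbers are reproduced here, which would
require the original profiles and predicted structures for tens of
thousands of proteins.

At these scales the full experiment (generate, encode, train 200 trees,
evaluate) runs in well under a minute; the package's standard 2,000-tree
operating point is exercised on a 500 × 5 training-dynamics check.  We use
200 trees for the recovery experiments because the ranking of feature
configurations is already stable there.

## Numerical choices

* **Split search.**  Candidate thresholds are midpoints between
  consecutive distinct sorted feature values; equal-gain ties resolve to
  the lowest feature index, then the lowest threshold; routing is
  left iff $x \le$ threshold.  Zero-variance nodes are leaves.  Residual
  sums are accumulated in extended precision so the C++ core and a plain-R
  reference implementation compute identical gains and grow identical
  trees.
* **Serialisation.**  Model files are JSON with floating-point fields
  written as C99 hexadecimal float literals, so a reloaded model predicts
  bit-identically — decimal text would lose an ulp.
* **Entropy conventions.**  $0 \ln 0 := 0$; an all-gap (zero-coverage)
  column gets $S = 0$, the same value as a fully conserved column, by the
  same logic that maps a query-only profile to zero entropy.  Natural
  logarithms throughout.
* **Profile counting.**  The query row is included in the counts (so a
  query-only input yields a one-hot profile); gaps and non-standard
  letters are excluded from numerator and denominator alike.  These are
  conventions, not forced choices, and are frozen here.
* **Identity filtering.**  "To the query and each other" is implemented
  greedily in input order: keep a homolog iff it is inside the window
  against the query and at most `max_id` identical to every previously
  kept homolog.  Greedy selection is deterministic and O(n²); it finds *a*
  maximal non-redundant subset, not a maximum one, which matches standard
  redundancy-reduction practice.  Pairwise identity is matches over
  mutually ungapped columns (0 if none exist).
* **Strictness.**  Disease calls and hot-spot calls use strict `>` at the
  cutoff.  Balance-ratio bounds are inclusive.  The wild-type letter of
  every variant is checked against the query sequence and a mismatch is an
  error — silently scoring the wrong residue is the worst failure mode of
  a variant annotator.
* **Missing structure.**  Variants on positions without structural
  coverage are dropped with a warning by default (`"zero"` keeps them with
  all-zero composition sentinels); saturation scans simply exclude such
  positions from the covered set.

## Known limitations

* The score is a least-squares regression output, not a calibrated
  probability; it is comparable against the fixed cutoffs but not across
  retrainings with different feature configurations.
* Upstream steps — homology search, structure prediction, domain boundary
  detection — are consumed as inputs, not performed.
* Contact features use wild-type coordinates for both wild and mutant
  (no mutant remodelling), and contacts are computed over whatever
  structure model is supplied; when segments are modelled independently,
  contacts do not cross model boundaries.
* The domain composition is computed on the query segment (not on an
  aligned template), one of two readings of how such a feature can be
  defined; the choice is recorded here and in the model file's feature
  tag.

## A worked example

```{r example, eval = FALSE}
library(entvar)

ds <- make_dataset(synthetic_spec(seed = 11))
sp <- split_variants(ds$variants, 0.5, seed = 42)

train <- encode_variants(oversample_balanced(sp$train),
                         ds$alignments, ds$structures, ds$segments)
test  <- encode_variants(sp$test, ds$alignments, ds$structures, ds$segments)

model  <- gbrt_fit(train, n_trees = 200)
scores <- predict(model, test)
evaluation_report(scores, test$variants$label, cutoff = 0.45)

scan <- saturation_scan(model, ds$alignments[[1]], ds$structures[[1]], ds$segments)
hot_positions(scan, cutoff = 0.45)
```
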