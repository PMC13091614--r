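---
title: "Post hoc genotype recalling for SNP microarrays: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post hoc genotype recalling for SNP microarrays: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snprecall)
```

## The problem

Illumina-style SNP arrays measure two fluorescence channels per biallelic
site — an A-allele intensity `X` and a B-allele intensity `Y` — and the
on-platform software clusters the polar summaries `R = X + Y` (total
signal) and theta (the angular position of the B signal relative to A)
into AA, AB and BB genotype clusters. That clustering is unsupervised and
tuned for high-quality, high-input DNA. When DNA input falls, total
signal drops, angular noise grows, and heterozygote signal collapses
(one allele's probe signal is lost, so a true AB site drifts toward a
homozygote cluster). The platform then either mis-calls confidently or
declines to call, and its per-call score (GenCall) is not a probability,
so there is no principled way to trade call rate against accuracy.

`snprecall` treats genotype assignment as a *supervised* problem on the
platform's own exported summary statistics. High-input runs of the same
individuals provide ground-truth labels; a classifier trained on degraded
runs learns where the platform's fixed cluster boundaries stop being
optimal, and returns a posterior probability over {AA, AB, BB} for every
record. The posterior yields a Phred-scaled genotype quality
`Q = -10 log10(1 - max p)`, which supports quality thresholds (hard-call
consumers) or direct likelihood use (PL fields in VCF).

## Data model

The central container is `IntensitySet`, a `SummarizedExperiment` with
SNPs as rows and sample runs (one individual at one DNA input) as
columns. Assays hold the per-record summaries (`X`, `Y`, `R`, `Theta` in
the normalized [0, 1] convention, `GenCall`, and the platform call as a
B-allele dosage code); per-SNP metadata (identifier, chromosome,
position, alleles, GenTrain score, cluster separation) live in `rowData`,
and the sample manifest (individual, DNA input in ng, ground-truth flag)
in `colData`. `recordTable()` flattens this into the long form consumed
by feature engineering and modeling.

Exported Theta is assumed normalized to [0, 1] and is converted to
radians (`theta = theta_norm * pi/2`) before any geometry. The expected
heterozygote angle is then pi/4, which is the convention under which the
angle-error features below are meaningful. The conversion is isolated in
`buildFeatures()`, so a radian-exporting dialect only needs a changed
column map and an identity conversion.

## Quality control

`qcFilter()` applies, in a fixed order: removal of non-autosomal and
indeterminate chromosomes (X, Y, MT, "0"); removal of SNPs with invalid
identifiers (empty, ".", or containing a dash); removal of *all* copies
of any duplicated SNP name (probe identity is ambiguous when two probes
share a name, so keeping "the first" would keep an arbitrary one); and
demotion of calls with GenCall below 0.15 (the platform's conventional
no-call threshold, boundary kept) to NC. Demotion rather than deletion is
the default because the recaller can still classify a record the platform
declined to call — those records carry intensities. A strict mode
(`drop_low_gencall = TRUE`) deletes the records instead, for pipelines
that want the conventional behavior. The filter is idempotent and reports
per-rule record counts.

## Feature engineering

Fifteen features per record, computed by `buildFeatures()`:

* the raw summaries `gencall`, `gentrain`, `cluster_sep`, `r`, `x`, `y`,
  `theta`;
* three signed *angle errors* — deviations of theta from the expected
  cluster angles 0, pi/4, pi/2 — `a_AA = theta`, `a_AB = pi/4 - theta`,
  `a_BB = pi/2 - theta`. No absolute value is taken: the sign says which
  side of the cluster a record sits on, and both the tree and network
  models exploit it;
* three *subtended arcs* `s_g = r * a_g`, the arc length associated with
  each angle error at the record's intensity — an interaction of radial
  and angular information;
* the record's sample-level intensity mean and unbiased variance
  (`sample_mean_r`, `sample_var_r`). Mean signal falls and signal
  variability rises as DNA input drops, so these act as proxies for
  sample quality/quantity and let one model adapt its decision boundaries
  across degradation levels.

All features are z-normalized. The normalizer is fit on the training
partition only and stored with the model; this is a deliberate guard
against train/test leakage, and the test suite asserts that held-out
individuals are not centered by the training normalizer. Constant
features are dropped with a warning rather than producing division by
zero.

## Labels, partitions, and the two-phase strategy

The highest-input run of each individual (50 ng in the emulated design)
is designated ground truth; its called genotypes label the corresponding
sites of the same individual's lower-input runs (`buildTruth()`,
`makeExamples()`). Truth-run no-calls yield no label. All partitioning is
*by individual* (`splitByIndividual()`, and group-wise folds inside
`gridSearch()`): records of one individual never appear on both sides of
a split, because records of the same genome are not independent.

Training runs in two phases, mirroring a selection-then-final-fit
strategy:

1. **Model selection.** The training set is down-sampled to equal counts
   of platform-correct and platform-incorrect records
   (`downsampleBalanced()`; platform NC counts as incorrect). This
   binary balancing is unusual for a 3-class problem but is kept
   deliberately: the quantity being balanced is the platform's error
   indicator, which concentrates the selection phase on the records
   where recalling can matter, and it cuts the cost of the grid search.
   A 3-class balancing mode exists for comparison. Hyperparameters are
   chosen by grid search under leave-one-individual-out cross-validation,
   scored by mean negative log loss; ties resolve to the first grid
   point.
2. **Final fit.** The winning configuration is retrained on the *full*
   training data with inverse-frequency class weights
   `w(c) = N / (3 N_c)` (`classWeights()`), which gives the three
   genotype classes equal total mass — a flat prior on genotypes, so the
   posterior behaves like a likelihood — without discarding data.

## Classifier families

* **rmlr** — elastic-net multinomial logistic regression via glmnet.
  The sklearn-style inverse regularization strength `C` maps to
  `lambda = 1/(C n)`, and `l1_ratio` is the elastic-net mixing
  parameter.
* **gbt** — gradient-boosted trees via xgboost with the multiclass
  softmax cross-entropy objective, emitting per-class probabilities.
  `tree_method = "hist"` is the default for speed; `"exact"` places
  split points mid-gap between observed values, which matters in the
  degenerate separated-clusters limit (the histogram sketch can place a
  bin edge on a cluster boundary, flipping held-out points that fall
  marginally outside the training hull).
* **nn** — a three-hidden-layer feed-forward network (default sizes
  50, 100, 50; the third layer size is a design choice — small and
  symmetric with the first — since only the first two are pinned by the
  reference architecture), Leaky ReLU activations, softmax output,
  trained by Adam on class-weighted categorical cross-entropy. It is
  implemented natively in the package in plain matrix R: it needs no
  external deep-learning backend, is fully seeded, and at the data
  scales this package targets the matrix operations are not the
  bottleneck. No early stopping; a fixed epoch budget (default 50) keeps
  runs reproducible.

Posteriors are renormalized to the simplex, the call is the argmax with
ties broken in fixed class order AA < AB < BB, and probabilities are
floored at 1e-99 before any log scaling. Raw probabilities are used as
quality thresholds by default; an optional one-vs-rest Platt scaling
(`calibrateModel()`, fit on a held-out calibration set) is available for
downstream consumers that need calibrated posteriors.

## Filtering and comparison with the platform

`phredQuality()` converts a posterior to `Q = -10 log10(P_err)` with
`P_err = 1 - max p`, capped at 99 (the VCF integer convention; tree
leaves can emit probability exactly 1). `phredFilter()` retains calls
with `Q >= threshold` — "minimum threshold" semantics, so the study grid
0/10/20/30 nests. Because GenCall is not a probability, classifier and
platform cannot be compared at a common threshold; instead comparisons
use *equal-cardinality rank-matched sets*: for a classifier set of size
k, the platform set is its k highest-GenCall calls
(`rankMatchGenCall()`, deterministic lexicographic tie-break), and
`runEval()` symmetrically takes the classifier's top k by Q when the
platform has fewer called sites than the classifier retained. A
concordance filter (`concordanceFilter()`) optionally retains only calls
agreeing with the platform; platform NC is never concordant, since NC is
not a genotype.

Evaluation metrics (`metricsReport()`, `runEval()`): absolute call rate
(denominator: autosomal sites on the chip — 4,198,873 for the
full-scale array this emulates, configurable), relative call rate
(denominator: sites assayed for that input), accuracy over called sites
only, one-vs-rest precision/recall/F1 per class (AB is the
failure-prone class: it mixes two probe signals, and heterozygote
dropout erodes it first), and an exact two-sided paired sign test for
method comparisons (zeros dropped — the standard exact convention; the
implementation is the closed-form binomial tail sum and is cross-checked
against `binom.test` in the suite).

## Kinship

`kingRobust()` implements the between-family KING-robust estimator from
shared-site counts:

phi = (N_both_het - 2 N_opp_hom) / (2 m) + 1/2 - (N_het_i + N_het_j) / (4 m),
with m = min(N_het_i, N_het_j).

Sites with a no-call in either individual are excluded pairwise (not
listwise) to maximize shared information. Expected values are 0.5
(duplicate), 0.25 (first degree), 0.125 (second degree), 0 (unrelated);
genotyping error biases estimates toward zero for related pairs, which
is exactly why recalled genotypes help downstream relatedness inference.
Numerical parity with any particular external implementation is not a
goal — recovery of pedigree expectations on simulated genotypes is the
validation, and the suite asserts it to ±0.02 at 50,000 SNPs.

## The simulator

`simulateArrayData()` generates the full study design: a pedigree of 8
individuals (two founder pairs; two full siblings and one other
offspring; one half-sibling — yielding duplicate, first-degree,
second-degree and unrelated pairs), genotyped at a titration series of
50, 1, 0.5, 0.1, 0.05 and 0.01 ng.

* **Genotypes**: founders in Hardy–Weinberg proportions at B-allele
  frequencies Uniform(0.05, 0.95); offspring by uniform Mendelian
  transmission; sites unlinked.
* **Intensities** live in (r, theta) space — the pipeline consumes only
  the polar summaries, so degradation is modeled there directly, keeping
  the generative model minimal and controllable. Cluster centers sit at
  0, pi/4, pi/2 plus a small per-SNP probe offset (SD 0.02 rad). Observed
  theta is truncated-normal on [0, pi/2]; `r` is LogNormal. The channel
  split `x = r cos(theta)/(cos(theta)+sin(theta))`, `y = r - x` is exact:
  `x + y = r` and `atan2(y, x) = theta` hold to machine precision, so
  fixtures round-trip.
* **Degradation laws** interpolate in log10(input) between the 50 ng and
  0.01 ng anchors. Mean log-intensity falls log-linearly (mean R about 2
  at 50 ng, about 1 at 0.01 ng); LogNormal spread rises 0.2 to 0.5;
  angular SD rises 0.03 to 0.35 rad with a quartic interpolant — the
  punctuated profile deliberately keeps mid-series inputs mild and
  collapses quality at the lowest input, the characteristic cliff of
  array genotyping under degradation. Values are the package's choices
  of a realistic regime; the anchors and shapes are `simConfig()`
  parameters.
* **Heterozygote dropout** is the sole genotype-dependent error mode: a
  true AB record collapses, with probability `0.25 * frac^2` (0 at 50 ng,
  0.25 at 0.01 ng), partway toward a fair-coin homozygote center
  (shrink factor Uniform(0.5, 1)) with total intensity attenuated by 0.5
  (losing one allele's signal roughly halves the total). Partial
  collapse plus intensity loss is what makes dropout *learnable*: the
  platform caller sees only theta and confidently mis-calls or NCs these
  records, while the supervised model recognizes the depressed `r` and
  the sample-quality features.
* **The surrogate platform caller** assigns the nearest cluster center in
  theta (centers include the probe offset) and scores
  `gencall = max(0, 1 - d/(pi/8))`, NC below 0.15. It is a deliberately
  simple stand-in for the proprietary on-platform clustering — not a
  reverse-engineering of it — and reproduces its qualitative failure
  profile: high accuracy and call rate at high input, declining call rate
  and a collapsing accuracy at the lowest inputs.

What passing tests on this simulator do and do not show: they validate
the pipeline's statistical machinery (geometry, leakage guards, filter
semantics, estimator recovery) and the *qualitative* claim that a
supervised recaller beats a fixed-cluster caller under degradation with
heterozygote dropout. They do not certify performance on real array
chemistry — batch effects, probe-specific artifacts, non-polar noise
structure and the real GenTrain algorithm are all outside the generative
model.

## Numerical and design choices

* Genotypes are coded as B-allele dosage 0/1/2 with NA for NC throughout
  the matrix layer; the long tables use the AA/AB/BB/NC labels.
* PL fields are `-10 log10 p` shifted to minimum 0, rounded, capped at
  990; GQ capped at 99; probabilities floored at 1e-99 first.
* Truncated normals are sampled by inverse-CDF, so the noiseless limit
  is exact and no rejection loop is needed.
* Fixture files are written with 17 significant digits so reading them
  back reproduces every double bit-exactly; a fixed seed yields
  byte-identical files.
* `gridSearch` fold assignment shuffles individuals under the run seed
  and chunks them round-robin; with folds = individuals this is
  leave-one-individual-out.
* The F1 of a class absent from both calls and truth is NA (undefined);
  a class present but never matched scores 0 via `2tp/(2tp+fp+fn)`.
* Problem sizes in the test suite are the package's choices for a
  desk-scale validation: 800-SNP grids for pipeline mechanics, 20,000
  SNPs and 8 individuals for the end-to-end recaller-vs-platform
  comparison, 50,000 SNPs for kinship recovery, 100,000 draws for
  distributional checks.

## Known limitations

* The surrogate caller's GenCall is a clean monotone function of
  distance-to-center; real GenCall is noisier and less well ordered, so
  rank-matched platform sets here are, if anything, flattered.
* Dropout is the only genotype-dependent degradation mode; allele-biased
  amplification, batch effects and probe cross-hybridization are not
  modeled.
* The NN family is a small dense network without early stopping or
  architecture search; it is included as a reference family, not tuned
  for peak performance.
* Kinship uses hard calls only; a posterior-weighted estimator is a
  natural extension but out of scope.
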