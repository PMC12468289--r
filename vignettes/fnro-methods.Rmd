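---
title: "Hybrid gene selection with statistical filters and Nuclear Reaction Optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid gene selection with statistical filters and Nuclear Reaction Optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Microarray (and pseudobulk single-cell) expression studies typically measure
thousands of genes on a few dozen samples. Classifiers trained on the full
matrix overfit, and the resulting signatures are uninterpretable. Gene
selection addresses both issues by finding a small subset of genes whose
expression discriminates the sample classes. `fnro` implements a two-stage
hybrid:

1. **Filter stage.** A fast univariate or multivariate statistic ranks all
   genes by class relevance and only a top-ranked candidate pool (hundreds of
   genes) is retained.
2. **Wrapper stage.** The Nuclear Reaction Optimization (NRO) metaheuristic
   searches the pool for a subset of exactly `k` genes maximizing the
   leave-one-out cross-validated (LOOCV) accuracy of a linear support-vector
   machine (SVM).

The package also ships a synthetic-data generator with planted informative
genes, so the whole pipeline can be validated end to end against a known
ground truth without any external downloads.

## Preprocessing

`read_expression()` accepts ARFF (via `foreign::read.arff()`) or delimited
text and produces a tibble of gene columns plus one factor `label` column.
Three transformations mirror the standard microarray workflow:

* **Mean imputation** (`impute_mean()`): each missing cell is replaced by the
  mean of the observed values of its gene. Observed values are never touched,
  so the operation is idempotent. A column with no observed values is an
  error.
* **Z-score normalization** (`zscore_normalize()`): each gene is centred and
  scaled to unit variance. We use the *population* standard deviation
  (divide by $n$); the choice is a convention — with $n$ in the tens the two
  denominators differ by under 1% and never change a ranking — but it is fixed
  and documented so results are bit-reproducible. Constant genes cannot be
  standardized; they are set to zero and flagged via the `constant_genes`
  attribute rather than dropped, keeping gene indices stable across stages.
* **Label encoding** (`encode_labels()`): classes are sorted
  lexicographically and coded `0..m-1`, a deterministic convention across
  platforms.

Normalization (and later, filtering) is computed on the **full** dataset
before any cross-validation. This mirrors the workflow this method family
uses in practice, and it matters for interpretation: information from the
held-out sample leaks into the preprocessing and the candidate pool, so
LOOCV accuracies estimated downstream are optimistic relative to a fully
nested protocol. We deliberately do not "fix" this — the point of the
package is to reproduce the protocol faithfully — but see *Known
limitations* for how the leak shows up even on synthetic data.

## Filter statistics

Four filters are available through `gene_scores()`; all tie-breaks are by
ascending gene index so every ranking is deterministic.

* **F-score** (`fscore_binary()`), for two classes:
  $$F_i = \frac{(\mu_i^+ - \mu_i)^2 + (\mu_i^- - \mu_i)^2}
               {s_+^2 + s_-^2},$$
  with within-class *sample* variances ($n_\pm - 1$ divisors). A gene with
  zero within-class variance and distinct means is a perfect separator: it
  scores `Inf`, which deliberately sorts first. With more than two classes
  `gene_scores(method = "fscore")` uses the one-way ANOVA F statistic
  (`anova_f()`), the natural multiclass generalization — both are monotone
  in the between/within variance ratio, and for balanced binary data they
  induce the same ranking (property-tested).
* **Information gain** (`information_gain()`):
  $\mathrm{Gain}(A) = \mathrm{Info}(D) - \sum_j \frac{|D_j|}{|D|}\,\mathrm{Info}(D_j)$,
  with continuous expression values discretized into equal-frequency bins
  (10 by default). The histogram estimator realizes the defining equations
  literally and is exactly testable against brute-force enumeration; the
  bin count is an estimator setting, not part of the statistic.
* **ReliefF** (`relieff_scores()`): the standard multiclass formulation —
  for each instance, subtract the mean range-scaled difference to the
  nearest same-class neighbours, add the class-prior-weighted mean
  difference to the nearest neighbours of each other class. Defaults:
  10 neighbours, Manhattan distance on range-scaled genes, and one
  deterministic pass over all samples rather than random sampling, so the
  default run needs no seed.
* **mRMR** (`mrmr_rank()`): greedy forward selection maximizing
  $MI(f, c) - \frac{1}{|S|}\sum_{s \in S} MI(f, s)$ (the difference form),
  with both relevance and redundancy estimated on the same equal-frequency
  discretization.

`top_k()` cuts the deterministic ranking to the candidate pool;
`evaluate_filters()` compares methods across pool sizes by the LOOCV
accuracy of each top-$s$ pool, breaking ties toward smaller pools and then a
fixed method order (fscore, infogain, relieff, mrmr).

## The NRO search

NRO is a physics-inspired population metaheuristic alternating a *fission*
phase (exploration) and a *fusion* phase (ionization + recombination,
exploitation), with Lévy-flight escapes when the population stagnates.

**Encoding.** Each candidate solution is a continuous position
$x \in [0,1]^d$ over the $d$ pooled genes, decoded to a subset by taking the
$k$ largest components (`decode_top_k()`, ties to the lower index). The
continuous encoding keeps every NRO operator applicable verbatim and
guarantees subsets of exactly $k$ genes, which the subset-size sweep
requires. A thresholding decoder (components $\ge 0.5$, variable subset
size) is available via `nro_config(decode = "threshold")` for users who
prefer a literal binary reading.

**Fission.** For solution $i$ at generation $g$, with probability
$P_\beta$ (default 0.5) the candidate is drawn around the global best
("subaltern products"), otherwise around itself ("essential products"):
$$x^{Fi} = \mathcal{N}(c,\ \sigma) + \mathrm{randn}\cdot
           (x_{best} - P_{ne}\cdot Nei),$$
where $c$ is $x_{best}$ or $x_i$, the per-dimension spread is
$\sigma = \frac{\log g}{g}\,|x - x_{best}|$ (shrinking over generations;
zero at $g = 1$, where the Gaussian degenerates to its centre and only the
recoil term perturbs), the mutation factor $P_{ne}$ is
$\mathrm{round}(\mathrm{rand})+1 \in \{1,2\}$ (subaltern) or
$\mathrm{round}(\mathrm{rand})+2 \in \{2,3\}$ (essential), and the heated
neutron $Nei$ is the elementwise **mean** of two distinct random peers.
(The original formulation's rendering of $Nei$ is ambiguous between a mean
and a product of two peers; the mean keeps the neutron inside the bounds,
and the product is available via `nro_config(neutron = "product")`.)

**Ionization.** Per solution, two distinct peers $r_1 \ne r_2 \ne i$ are
drawn; each dimension with $|x_{r_2} - x_i| \ge$ `similarity_tol` moves to
$x_{r_1} \pm \mathrm{rand}\cdot(x_{r_2} - x_i)$ (sign by
$\mathrm{rand} \le 0.5$; one `rand` per solution, since the update is
dimension-subscripted but `rand` is not), and too-similar dimensions take a
Lévy escape $x_i + \alpha\,\mathrm{Levy}(\beta)\,(x_i - x_{best})$.

**Fusion.** If the two peers differ in norm, the solution moves by
$\mathrm{rand}\cdot(x_{r_1} - x_{best}) + \mathrm{rand}\cdot(x_{r_2} - x_{best})$
with two independent uniform draws; a degenerate pair triggers the Lévy
escape again. The "best" in every escape is the global best: the phase-local
alternative is not distinguishable from the published description, and the
global best is the conservative reading.

**Lévy steps** use Mantegna's algorithm, $u/|v|^{1/\beta}$ with
$u \sim \mathcal{N}(0, \sigma_u^2)$, $v \sim \mathcal{N}(0,1)$ and
$$\sigma_u = \left\{\frac{\Gamma(1+\beta)\sin(\pi\beta/2)}
  {\Gamma\!\left(\frac{1+\beta}{2}\right)\beta\,2^{(\beta-1)/2}}\right\}^{1/\beta},$$
which is 0.696575 at the canonical $\beta = 1.5$ (`mantegna_sigma()`).
Defaults $\alpha = 0.01$, $\beta = 1.5$; the source method states these were
taken from the original NRO formulation without printing numbers, so the
canonical Mantegna choices are adopted and exposed in `nro_config()`.

**Replacement and stopping.** After each phase's candidates are evaluated, a
candidate replaces its parent only if *strictly* better (greedy elitist
replacement), and the global best is updated. The patience counter resets on
strict improvement of the global best and increments otherwise; the run
stops after `patience` stagnant generations (default 5) or at the
generation cap (default 30). Strictness matters: LOOCV accuracy takes a
discrete set of values, so with non-strict comparisons plateaus would reset
patience and early stopping would never fire. All positions are clipped to
$[0,1]$ after every operator; random peers are always drawn distinct from
each other and from the current solution so difference terms cannot
silently vanish. With a fixed `seed`, the run — trace, best subset and
evaluation count — is bit-identical across invocations.

## Fitness

`loocv_accuracy()` trains a linear SVM (`e1071::svm`, $C = 1$, no internal
rescaling — the data are already Z-scored) on all samples but one,
restricted to the candidate genes, and predicts the held-out sample; pooled
held-out predictions give accuracy, precision, recall and F1.
Class-support-**weighted** averaging is the default for the multiclass
metrics (macro averaging is a config switch): in published tables of this
protocol, precision and recall track accuracy almost exactly, which is the
weighted convention's signature. Stratified `kfold_accuracy()` is available
as the cheaper alternative; with `folds = n` it reproduces LOOCV exactly
(tested), which is also why `folds = n` is exempt from the
folds-at-most-smallest-class rule that stratification otherwise imposes.

One edge case is pinned down by a test because it depends on the
classifier's tie behaviour: on a dataset whose features are constant,
every LOOCV fold trains on a majority of the *opposite* class, and the
linear SVM follows that majority, so accuracy is exactly 0 for balanced
binary labels.

`cached_fitness()` memoizes evaluations on the sorted gene-index tuple.
The NRO population revisits subsets constantly — cache hit rates of 20-80%
are typical — and repeated runs on the same dataset (the 30-repeat
protocol) share one cache, which is what makes LOOCV-based fitness
affordable.

## Experiment protocol

`run_fnro_sweep()` reproduces the reporting protocol: for each subset size
`k` (default 2-25), `repeats` NRO runs (default 30) with seeds
`base_seed + 0..repeats-1` yield best/average/worst accuracy and a 95%
confidence interval of the mean, $\bar{a} \pm 1.96\,s/\sqrt{n}$ with the
sample standard deviation (a Student-t variant is available in
`aggregate_ci()`; at $n = 30$ the two differ by 2% of the half-width).
Precision/recall/F1 are recomputed on the best run's subset — the tables
this mirrors pair those metrics with the best run. With `stop_at_perfect`
(default), the sweep stops at the first `k` reaching accuracy 1, matching
the convention of not tabulating sizes past perfection. A fixed `base_seed`
reproduces every cell of the summary bit-identically.

## The synthetic generator

`simulate_expression()` emulates benchmark microarray structure: `n_samples`
(default 62) by `n_genes` (default 2000), 2-4 classes, `n_informative`
planted genes whose class means sit on a ladder $0, \Delta, 2\Delta, \dots$
with $\Delta = \texttt{effect\_size} \times \texttt{noise\_sd}$ (defaults
$2.0$ and $1.0$ — a strong but not trivial univariate signal, $d' = 2$
per gene for adjacent classes, the regime where filters succeed but single
genes do not classify perfectly), independent Gaussian noise elsewhere, and
optional uniformly planted missing values (a few percent, as real
lymphoma-class datasets show). The ladder guarantees pairwise separability
for any class count; `recovery_score()` measures the fraction of planted
genes a selection recovered.

What the generator does *not* emulate: heavy-tailed microarray noise,
gene-gene correlation blocks, and platform batch effects. Passing tests on
this generator therefore demonstrate the pipeline's mechanics — filters
detect mean shifts, the optimizer finds high-fitness subsets, the protocol
aggregates honestly — not robustness to real-data pathologies.

## A caution on perfect accuracies (observed on synthetic data)

Because the candidate pool is filtered on the same data that LOOCV
evaluates, pool genes that are pure noise still carry selection-bias
inflated class correlation. On a planted dataset (60 samples, 200 genes, 5
informative at effect 2.0, F-score top-20 pool, $k = 5$), LOOCV accuracy
reaches exactly 1.0 for many subsets containing only 2-3 of the 5 planted
genes. Once the search touches this plateau, strict-improvement replacement
freezes the global best, so *which* perfect subset is reported is path
luck: across repeated seeds the planted-gene recovery of the reported
subset is typically 0.4-0.8 even though accuracy is always 1.0. The same
mechanism operates on real benchmark data, which is worth remembering when
interpreting perfect accuracies from compact subsets under this protocol:
they certify separability under the in-sample filter, not that the specific
genes are the biological signal. The test suite asserts the filter-stage
recovery (all planted genes pooled) and documents the wrapper-stage
saturation; an externally validated protocol would nest filtering inside
the cross-validation, which is out of scope here by design.

## Numerical choices and problem sizes

* Equal-frequency bin edges come from `quantile(type = 7)`; duplicated
  edges collapse, and a feature with fewer than two distinct edges counts
  as a single partition (information gain 0).
* Zero-denominator F statistics map to an `Inf` sentinel that sorts first;
  zero numerators map to 0 regardless of the denominator.
* `similarity_tol` is $10^{-10}$, compared per dimension during ionization
  and by vector norm during fusion.
* The test suite and the bundled acceptance script run the full pipeline at
  reduced scale — populations of 6-30, 200-gene datasets, 10 repeats —
  chosen so the whole suite completes in minutes on one core while still
  exercising every operator; the scientific defaults in the config
  constructors (population 500, 30 generations, 30 repeats, pool 500)
  remain the published protocol.

## Known limitations

* LOOCV on filtered pools is optimistic (see the caution above); no nested
  cross-validation is provided.
* ReliefF cost is quadratic in samples (full distance matrix) — fine for
  microarray-scale $n$, not for thousands of cells.
* mRMR to depth $k$ costs $O(k \cdot d)$ mutual-information estimates;
  ranking all 2000 genes greedily is the slowest filter by far.
* No probe annotation, batch correction, or downloads of the classic
  benchmark compendia; bring your own matrix (ARFF or CSV/TSV).
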