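---
title: "Methylation biomarker discovery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation biomarker discovery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimarker)
```

## The problem

Genome-scale methylation arrays measure, for every CpG probe, two channel
intensities: a methylated signal $I_{Meth}$ and an unmethylated signal
$I_{UnMeth}$. In a matched case–control design the goal is to find a small
panel of CpG sites whose methylation separates healthy donors from (here,
two) cancer classes, and to quantify how well standard classifiers perform
on that panel when evaluated honestly — by resampling on a training set and
by a single blind pass over an independent test set.

`epimarker` implements that pipeline end to end, and ships a seeded
synthetic-cohort generator so every stage can be validated against planted
ground truth without any external download.

## Signal summaries and normalization

Three per-probe, per-sample summaries are used:

$$\beta = \frac{I_{Meth}}{I_{Meth}+I_{UnMeth}}, \qquad
  M = \log_2 \frac{I_{Meth}}{I_{UnMeth}}, \qquad
  I = \tfrac12 \log_2 \left( I_{Meth}\, I_{UnMeth} \right).$$

$\beta$ is the intuitive methylated fraction; $M$ is its logit and is
approximately homoscedastic, which makes it the right scale for t-statistics;
$I$ is the average log intensity, the axis along which array technical bias
varies. Base 2 is used for both logs (the convention of the M-value
statistic); intensities below 1 are floored to 1 before taking logs, which
keeps values finite without reordering informative intensities. On unfloored
input the identity $\beta = 2^M/(2^M+1)$ holds to machine precision and is
asserted in the tests.

Normalization leans entirely on the replicated technical QC sample — the
same control DNA hybridized on every chip, so that its replicate spread is a
pure measure of technical variation:

1. **Within-chip correction.** Per chip, QC residuals (QC replicate $M$
   minus the per-probe cross-chip QC consensus) are pooled and binned by
   their $I$ value into `n_bins` percentile bins (default 100; bins with
   fewer than 3 QC points merge into a neighbour so bin errors stay
   estimable). The bin mean is the chip's intensity-resolved error, and it
   is subtracted from every measurement on the chip according to the
   measurement's own $I$. A constant chip offset is absorbed exactly; a
   linear-in-$I$ bias is absorbed up to binning resolution.
2. **Across-probe correction.** The per-probe QC replicate standard
   deviation $\sigma_{QC}$ (sample sd, $n-1$ denominator; defined as 0 with
   a warning when only one QC replicate exists) is subtracted from every
   sample of that probe. This step is a constant per-probe shift: it cannot
   change any paired difference or between-sample contrast, and no
   downstream statistic depends on it. It is retained because
   $\sigma_{QC}$ is exactly the technical-noise denominator the scaled-CV
   statistic needs, and because the correction pipeline is defined as the
   two-step composition.

The QC consensus is the per-probe mean of $M$ over all QC replicates on all
chips — the QC is one physical sample, so its cross-chip mean is the best
available reference. Bin errors are estimated per chip from that chip's own
QC measurements, not pooled, since the bias being removed is chip-level.

## Statistical pre-selection

Per case–control experiment (each disease arm keeps its own matched
control arm), two statistics are combined:

- **Scaled CV**: $\mathrm{CV}_{pool}/\mathrm{CV}_{QC}$ with
  $\mathrm{CV}= \mathrm{sd}/|\mathrm{mean}|$ on $M$ over the pooled
  controls-plus-cases versus over the QC replicates. Values above 1 flag
  variability beyond technical noise. Because $M$ crosses zero, the raw CV
  is unstable near mean 0: probes whose pool or QC mean magnitude falls
  below $10^{-8}$ fall back to the plain sd ratio and are flagged;
  $\sigma_{QC}=0$ yields $+\infty$, which passes the criterion by
  construction.
- **Paired t with sign-flip bootstrap correction**: per probe,
  $t = \bar d / (s_d/\sqrt n)$ on case-minus-control differences over
  matched pairs, two-sided p on $n-1$ df. The correction forms null
  replicates by randomly flipping each pair's difference sign — exact under
  the symmetric null and faithful to the matched design, unlike resampling
  with replacement — and reports
  $p_{boot} = (1 + \#\{b: p^*_b \le p_{raw}\})/(B+1)$, bounded below by
  $1/(B+1)$. The replicate count is not fixed by the method; the package
  default is $B = 1000$, logged with every run.

Selection keeps the top $\lceil 0.01 P \rceil$ probes by $p_{boot}$ (ties
broken by smaller $p_{raw}$, then probe id, so the cut is deterministic and
input-order free) intersected with $\{\mathrm{ScaledCV} > 1\}$; the
per-experiment sets are unioned with provenance, because the semantic
selection later intersects its probe set with each experiment's
pre-selection.

## Evolutionary feature selection

A chromosome is a binary inclusion mask over the candidate probes with
popcount in $[1, D_{max}]$ (the lower bound 1 is the package's choice; the
upper bound — 150 or 400 in typical use — is the dimensionality threshold).
Fitness is the pooled accuracy of a distance-weighted 12-NN classifier on
the masked features under stratified 3-fold cross-validation; the fold
assignment is drawn once per run, independent of the mask, so every
chromosome is scored on identical folds and fitnesses are comparable.
Selection is roulette (probability proportional to fitness, uniform
fallback when all fitnesses are zero), crossover is uniform (per-pair
probability $P_c = 0.5$, each bit swapping with probability 0.5) applied to
consecutive pairs of the full-size parent pool, mutation flips each bit
with $P_m = 1/N$, and a repair step randomly clears surplus bits (or sets
one bit in an empty mask) after the operators. One elite chromosome is
copied unchanged per generation — the paper's "best chromosome of the last
generation" is then also the best ever seen, and best fitness is provably
non-decreasing. The budget is a fixed number of generations (default 50)
with no early stopping. Fitness ties are resolved toward smaller
cardinality, then lexicographically, for determinism and parsimony.

### The recovery experiment

The package validates the GA on a seeded recovery problem: 500 candidate
features of which 10 are informative with a standardized effect of 2.0,
population 100, 30 generations. The informative structure is a five-class
balanced design in which each class elevates its own pair of marker
features by 2.0 within-class standard deviations (classes of 60 samples
each; $D_{max}=30$); the 490 uninformative features are low-variability
probes (sd 0.2), as most array probes are. This layout was chosen over a
two-class shift because wrapper selection needs a fitness gradient across
the whole marker set: in a two-class design a handful of shifted features
already saturates the embedded classifier and the remaining markers become
selectively neutral, whereas with per-class marker pairs every marker
carries class-specific information and the cross-validated accuracy keeps
rewarding each additional recovered marker; low-variability uninformative
probes keep that gradient from being swamped by distance noise. The
expectation, asserted in the tests, is that the final mask contains at
least 8 of the 10 markers and that best fitness never decreases. Under
roulette selection with a population of 100 the recovery is stochastic:
across seeds the run typically recovers 8–9 markers, occasionally 7.

## Semantic (ontology-centrality) selection

Genes mapped from the pre-selected probes are re-ranked by how many
*distinct, mutually non-redundant* functional contexts they occupy:

- **Information content**: $IC(t) = -\ln(n_t/n_{root})$ over
  ancestor-propagated annotation counts.
- **Normalized Resnik distance**:
  $d(t_1,t_2) = 1 - IC(\mathrm{MICA})/IC_{max}$, where MICA is the common
  ancestor of maximal IC. Normalizing by the corpus maximum puts the
  relaxation threshold (default 0.15) on a fixed $[0,1]$ scale; a raw-IC
  threshold would be corpus-dependent.
- **Pruning**: among a gene's *direct* annotations, while any pair lies
  closer than the relaxation, the closest pair is found and its lower-IC
  (more generic) member dropped — retaining the most specific description
  of each functional context. IC uses propagated annotations (frequencies
  need the closure); pruning operates on the gene's own term list.
- **Centrality score**: the retained-term count. Genes are ranked by score
  with lexicographic tie-breaks; the output is restricted to the input
  list. A clique-expansion helper (`bubble_cliques()`) exposes the
  one-step functional neighbourhood (genes of a term, its parents and
  children, root excluded) for exploratory use.

The neighbour-expansion reading of the clique step and the
threshold-on-distance reading of the relaxation are interpretations of a
published web tool whose internals are not restated here; both are flagged
as such. No explicit score cutoff is canonical, so the number of
top-centrality genes carried forward is an exposed parameter.

## Classifiers and evaluation

- **Weighted k-NN** (k = 1, 6, 12): Euclidean distances, vote weight
  $1/(d+10^{-9})$ — stable at $d = 0$ — ties broken by the class of the
  single nearest neighbour.
- **Gini tree**: binary CART-style splits minimizing weighted Gini
  impurity over all feature/midpoint candidates; nodes split while
  impurity decreases and hold at least 2 samples; no pruning (only the
  split criterion is prescribed).
- **ANN**: one hidden layer of $\lfloor (F+C)/2 \rfloor + 1$ sigmoid units
  (the rule can be fractional, so it is floored), sigmoid outputs, one-hot
  targets, per-sample backpropagation with learning rate 0.3 and momentum
  0.2 for exactly 1000 epochs, uniform $[-0.5, 0.5]$ seeded weight
  initialization, argmax decision. Inputs to k-NN and the ANN are
  standardized with training-set statistics only (distance and
  sigmoid-gradient scales; training-only statistics prevent leakage);
  trees are scale-equivariant and skip it.

Evaluation is leave-one-out on the training set, or a single fit applied
to a disjoint held-out set (overlapping sample ids are an error; test
labels are consulted only after prediction). Reports carry the confusion
matrix, total accuracy $100\cdot\mathrm{trace}/\mathrm{sum}$ and per-class
sensitivities $100\cdot\mathrm{diag}/\mathrm{rowsum}$.

## Enrichment reporting

Selected gene lists are scored against term (or pathway) gene sets with
the hypergeometric upper tail $P(X \ge a)$; the background universe is the
chip's annotated gene universe, not the genome, because selection only
ever operated on chip probes. Raw p-values are reported by default —
Benjamini–Hochberg adjustment and an empirical same-size-resampling null
are available behind options. The genomic-region distribution uses the
seven-category array vocabulary (TSS200, TSS1500, 5'UTR, 1stExon — the
promoter subgroups — plus Body, 3'UTR and Intergenic).

## The synthetic cohort: what it emulates, and what it does not

`simulate_cohort()` generates: baseline per-probe methylation from an
equal-weight Beta(2,10)/Beta(10,2) mixture plus 10% Beta(2,2) (the bimodal
marginal of array methylation); matched pairs for two disease arms with
per-arm control cohorts; chips of configurable size carrying one QC
replicate each (QC placement per chip is not specified by the design being
emulated; one per chip is assumed); planted differentially-methylated
probe sets, disjoint between diseases, shifted by `effect_delta` exactly
on the M scale; log-normal total intensity with independent multiplicative
channel noise; and chip bias `slope * I + offset` injected exactly on the
M scale with channels rewritten so `I` is preserved — making normalization
recovery measurable without confounding. The configured `bias_slope` and
`bias_offset` are maximum magnitudes, spread across chips with
deterministic multipliers `seq(-1, 1)`: identical bias on every chip would
be absorbed into the cross-chip QC consensus and would be invisible to a
within-chip correction, so varying coefficients are what make the
normalization recoverable at all.

Deliberate simplifications: QC replicates share one fixed profile with no
biological variation (they model a single technical sample); study samples
share the probe's baseline β, so all within-class variation is technical —
adequate for testing calibration and recovery, but real cohorts add
inter-individual biological variance, cell-type composition effects,
non-CpG/SNP probes and realistic genome coordinates, none of which are
emulated. A single ontology aspect is generated (the selection algorithm
is aspect-agnostic). Passing tests therefore demonstrate correctness of
the machinery and calibration under the stated generative model, not
performance on real cohorts.

## Numerical choices and degeneracies

- Channel floor at 1 before logs; both-channels-zero is an error for β.
- Bins with fewer than 3 QC points merge rightward into a neighbour.
- $\sigma_{QC} = 0$ (single QC replicate) warns and degrades gracefully.
- Zero-variance nonzero paired differences get the smallest representable
  p with a warning; zero-variance zero differences get $t=0$, $p=1$.
- All ranking and pruning ties break lexicographically (p_raw then probe
  id; term id; gene id) so outputs are order-free and reproducible.
- Every stochastic step takes an explicit seed; identical configuration
  and seed give byte-identical serialized outputs.
- The k-NN distance/vote kernels (single prediction and pooled CV) are
  implemented in C++ for the GA's fitness loop, with long-double
  accumulation so results agree bit-for-bit with the vectorized R
  formulation; the test suite asserts exact agreement against a
  brute-force R oracle on random instances.

## Problem sizes used in the shipped experiments

The package's own simulation experiments run at desk scale, chosen to
exercise every code path with stable statistics: cohorts of a few hundred
to 10,000 probes, 30–40 pairs per disease arm, $B = 1000$ bootstrap
replicates for calibration runs, the GA recovery at 500 features /
population 100 / 30 generations, and end-to-end runs at 1,500 probes with
40 pairs per class. Larger cohorts change runtimes, not code paths.
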