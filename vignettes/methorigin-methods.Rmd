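---
title: "Methods: tissue-of-origin classification from methylation haplotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue-of-origin classification from methylation haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Metastatic tumors — and cancers of unknown primary (CUP) in particular —
retain the DNA-methylation architecture of the tissue they arose from.
Reduced-representation bisulfite sequencing (RRBS) of a biopsy therefore
carries a readable tissue-of-origin signal, even from fragmented
formalin-fixed (FFPE) material. `methorigin` implements a complete
classifier for this setting: it scores CpG-island (CGI) methylation from
read-level haplotypes, selects cancer-type-specific marker islands,
trains a calibrated multiclass model, and reports ranked top-k
predictions with confidence tiers.

## Read-level methylation statistics

The unit of observation is the *methylation haplotype*: the 0/1 pattern of
methylation carried by the consecutive CpGs of one sequenced molecule
(epiallele), with a multiplicity count. Four region-level statistics are
computed per CGI; a pattern with count $c$ behaves as $c$ identical reads.

* **Beta value** — methylated CpG calls over total CpG calls:
  $\beta = \sum_i c_i k_i \big/ \sum_i c_i L_i$ for patterns of length
  $L_i$ with $k_i$ methylated positions.
* **PDR** (proportion of discordant reads) — among reads with at least
  `min_cpgs` CpGs (default 4, the convention of read-discordance scoring),
  the weighted fraction containing both a 0 and a 1. Regions with no
  eligible read report missing rather than zero.
* **CHALM** (cell heterogeneity-adjusted clonal methylation) — the
  weighted fraction of reads with at least one methylated CpG.
* **MHL** (methylated haplotype load) — with $S_l$ the number of length-$l$
  CpG substrings and $F_l$ the number that are fully methylated,
  $\mathrm{MHL} = \sum_l w_l F_l / S_l$, $w_l \propto l$. The stretch
  length is capped at $L = \min(\text{longest pattern}, 10)$ to bound
  cost, and the weights are renormalized over the lengths actually
  realized ($S_l > 0$), which keeps MHL within $[0,1]$ when read lengths
  are ragged.

All four implementations are checked against brute-force enumeration
oracles (explicit expansion of every read and every substring) to
$10^{-12}$ on randomized inputs.

## Coverage filter and matrix assembly

Only well-covered islands are informative, so a feature-matrix cell is
observed only when the sample's region coverage strictly exceeds
`min_depth = 100`. Coverage is measured as the region's haplotype count.
A mean per-CpG depth measure is also available
(`depth_measure = "mean_depth"`), but it is not the default: per-CpG depth
scales with read *length*, so under the simulator's default depth
(Poisson mean 150 reads per region) the FFPE-typical short patterns would
push nearly every region below a 100x per-CpG threshold even though the
region is sequenced 150 times over. Read-count coverage reflects the
sampling depth of the epiallele population, which is what the read-level
statistics consume.

Regions missing in more than 20% of samples are dropped; the remaining
missing cells take the region's cross-sample median. The median is
label-agnostic (no leakage of class information), and the training-set
imputation values are stored on the matrix so that prediction-time
alignment fills absent markers from the *training* medians, never from
statistics of the new samples. Prediction aborts when fewer than half of
the marker regions are present (`min_marker_frac = 0.5`).

The coverage filter is a *marker-discovery* device. At prediction time
the default is to use every covered region (`min_depth = 0`): for a
shallow library, an observed low-coverage beta value is better evidence
about that sample than the training-cohort median that would replace it,
and this is what lets accuracy degrade gracefully (rather than collapse
to the imputation baseline) when libraries are downsampled.

## Marker selection

For each cancer type $t$ and region $r$, two two-sided Wilcoxon rank-sum
tests are run on the chosen metric: type $t$ against all other tumor
types, and type $t$ against the normal-tissue controls. Within each
comparison family (one type, one condition) p-values are converted to
Benjamini–Hochberg q-values across regions — the family is per-comparison
because each (type, condition) pair asks a separate scientific question —
and $r$ is selected for $t$ when both q-values are at most
$\alpha = 0.01$. Hypo- and hypermethylated markers are both admitted; the
direction is recorded but never used as a filter. The classifier's
feature list is the union of the per-type marker sets. Markers are
selected on the full training cohort before the 4:1 split; this mirrors
the published procedure but is a potential optimism source for the
validation estimate, which is why the synthetic evaluation always scores
a held-out test cohort generated independently of training.

The rank-sum p-value uses the exact null distribution of the
Mann–Whitney statistic when the smaller group has at most 8 observations
and no ties are present, and otherwise the normal approximation with tie
and continuity corrections. Eight is a cost/accuracy trade-off: beyond
it the approximation error is far below any decision threshold used
here, and the exact branch is verified against full permutation
enumeration for all splits with $n + m \le 10$.

## Classifier grid, oversampling, calibration

Four metrics crossed with seven learners give the 28-model grid:
AdaBoost (multiclass SAMME over depth-1 stumps), k-nearest neighbors
(uniform or distance weighting), multinomial logistic regression
(elastic-net regularized), a linear support vector classifier
(one-vs-rest), multinomial naive Bayes with additive smoothing, random
forest, and an RBF-kernel SVM (one-vs-rest). The default coordinate —
beta value with the linear SVC — is the configuration that performs best
for primary-site prediction.

Training proceeds per model as:

1. **Stratified 4:1 split.** Per class, $\lfloor n/5 \rfloor$ (at least
   one) samples are held out for validation.
2. **Oversampling** of the training portion only: every minority class is
   brought to the majority count with interpolation-based synthetic
   samples $x + u(x' - x)$, $u \sim U(0,1)$, between a minority sample
   and one of its 5 nearest same-class neighbors (duplication for
   singleton classes). Restricting this to the training portion keeps
   synthetic points out of the calibration set.
3. **Budgeted hyperparameter search**: 50 settings drawn at random from
   each learner's declared space, scored by stratified 5-fold
   cross-validation accuracy, best-first tie-break. A random search is
   used deliberately: with a declared space, a fixed budget and a seed it
   is reproducible and interface-equivalent to any sequential optimizer,
   and published search spaces/budgets for this problem do not exist, so
   the spaces here are declared defaults rather than inferred ones.
4. **Calibration** on the held-out validation stratum: one sigmoid
   (Platt) map per class on one-vs-rest scores, with smoothed targets
   $(n_+ + 1)/(n_+ + 2)$ and $1/(n_- + 2)$, renormalized to a probability
   vector. SVM decision values have no native probability scale, so
   calibration is the only score-to-probability route; for learners with
   native probabilities the sigmoid is fitted on those. Isotonic
   regression is available as an alternative
   (`calibration = "isotonic"`).

Predictions rank classes by calibrated probability with lexicographic
tie-breaks, and carry a confidence tier: *high* when the top probability
strictly exceeds 0.75, *medium* when it strictly exceeds 0.5, *low*
otherwise. The 0.75 boundary is the published high-confidence cut; the
0.5 medium cut is this package's choice of a natural majority threshold.

Every random draw derives deterministically from a single master seed,
so identical seeds give byte-identical serialized models.

## The synthetic cohort generator

No public data are required to exercise the pipeline: the generator
builds labelled cohorts with the features the method actually consumes.

* **Tissue architecture.** Each of 10 tissues gets 25 disjoint marker
  islands out of 300 regions (10 CpGs each, 20 bp apart). Every region
  has one shared baseline level — a Beta($\kappa m$, $\kappa(1-m)$) draw
  around $m_0 = 0.15$ — carried by all tissues and the normal profile;
  a tissue's own markers get tissue-specific draws around $m_1 = 0.85$
  (hypermethylated) or $1 - m_1$ (hypomethylated, against an $m_1$
  regional baseline so the direction is detectable). Sharing the
  baseline across tissues is deliberate: if every tissue drew its own
  background level, each of the 40-sample tissue groups would carry a
  real, detectable shift at *every* region and the notion of a "false"
  marker region would collapse.
* **Sample generation.** Per region the read count is Poisson(150); each
  read comes from the tumor profile with probability equal to the tumor
  purity $\pi$, else from the normal profile; the read's epiallele state
  is methylated with probability equal to a per-sample Beta($\kappa$)
  draw around the profile level; each CpG flips with discordance
  probability $\varepsilon = 0.05$. The two-state epiallele plus
  flip-noise is the simplest mechanism that makes PDR, CHALM and MHL
  genuinely different from the beta value.
* **FF vs FFPE.** Fresh-frozen reads span 4–10 CpGs; FFPE reads 2–6.
  FFPE mode shortens patterns without reducing read counts, matching the
  observation that FFPE libraries have shorter inserts yet no shallower
  CGI coverage.
* $\kappa = 50$ gives between-sample standard deviations of roughly 0.05
  at the background level — tight enough that markers dominate, loose
  enough that tests see biological spread.

What the generator does *not* emulate: genomic CGI density and probe
mapping, coverage non-uniformity across islands, bisulfite-conversion
failure, alignment artifacts, batch effects, or inter-patient copy-number
variation. Passing the recovery study therefore demonstrates the
correctness and internal consistency of the pipeline under its stated
noise model — not clinical-grade accuracy on real cohorts.

## The recovery study

`too_recovery_study()` re-runs the whole validation from one seed:
a fresh-frozen training cohort (10 tissues x 40 samples at purity 1,
plus 20 normals), marker selection, the beta + linear SVC fit, and an
FFPE-mode test cohort of 10 samples per tissue at purity 0.7. Expected
behavior under the default conditions: marker selection recovers
essentially all planted markers with no false regions, and test top-1 /
top-3 accuracies clear 0.90 / 0.97. The tumor-content trend uses 5
samples per tissue at purities 0.1/0.3/0.5/0.7/1.0 — small bins chosen to
keep the full study inside a few minutes on one CPU while still showing
the monotone accuracy trend — and the sequencing-depth trend thins the
test cohort's haplotype counts binomially to 10%, 50% and 100%. Thinning
acts on haplotype counts rather than raw reads (read processing is
upstream of this package); it is the record-level analogue of
downsampling a library.

## Degenerate inputs and tie handling

* Empty regions report missing metrics, zero depth and zero reads.
* Clipped patterns of length zero are discarded; a record overlapping
  several regions contributes its restriction to each.
* Ranked predictions break probability ties lexicographically by class
  name, making every report order deterministic.
* A class never predicted reports precision and F1 of 0 with an
  `undefined` flag instead of being dropped, keeping macro averages
  defined.
* QC thresholds are strict on the failing side (a conversion rate of
  exactly 0.99 passes), matching the published filter wording.

## Known limitations

* The linear SVC exposes cost and tolerance for search; penalty norm,
  loss and multiclass strategy are fixed by the underlying libsvm
  backend (L2/hinge/one-vs-rest) and recorded, not searched.
* The nearest-neighbor "search algorithm" hyperparameter is recorded but
  inert: with cohort-scale data an exact brute-force search is both
  deterministic and fast.
* Marker selection on the full cohort before splitting (see above)
  slightly optimistically biases validation-set estimates.
* Real-array ingestion expects region-level beta values; probe-to-island
  mapping is out of scope.
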