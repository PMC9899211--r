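---
title: "Mapping arterial territories from stroke lesion cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping arterial territories from stroke lesion cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vascter)
```

## The problem

An ischemic stroke destroys tissue inside the territory perfused by the
occluded artery. Given a cohort of patients whose strokes each affected
exactly one major arterial territory — anterior (ACA), middle (MCA), or
posterior (PCA) cerebral artery, or the vertebro-basilar system (VB) —
and whose binary lesion masks have been mapped to a common template grid,
the spatial distribution of the lesions carries information about where
each territory lies. `vascter` turns such a cohort into:

* per-territory **probabilistic maps** (how often each voxel is lesioned in
  strokes of that territory),
* **border-zone** ratio maps and voxelwise **certainty indices**,
* a sharp, hierarchical **label atlas** in which every brain voxel carries
  exactly one territory label, and
* **registration QC** metrics for the deformed volumes that produced the
  common-space masks.

Everything is testable end to end on a synthetic phantom cohort with
planted parameters, so no patient data are required to validate the
implementation.

## The two probabilistic models

### Average method

With $N_s$ subjects in territory group $s$ and binary masks $X_i$, the
lesion-frequency map is the voxelwise mean

$$p_s(j) = \frac{1}{N_s} \sum_{i:\, s_i = s} X_{i,j}.$$

Every value is an integer multiple of $1/N_s$; `average_prob_map()`
preserves this exactly. The method is unbiased but dilutes probability
wherever lesion size varies a lot within a group: a voxel only hit by
large strokes can never approach probability 1 even if it always belongs
to the territory.

### Bernoulli mixture model

`bmm()` instead models each group as a mixture of $K$ latent lesion
patterns. Cluster $k$ has prior $\pi_k$ and a rate map $\mu_k$; given its
cluster, a subject's voxels are independent Bernoulli draws:

$$P(X \mid \pi, \mu) = \sum_{k=1}^{K} \pi_k \prod_j
  \mu_{k,j}^{x_j} (1-\mu_{k,j})^{1-x_j}.$$

Although voxels are independent *within* a cluster, the latent cluster
induces correlation between voxels marginally (`model_moments()` exposes
the implied mean and covariance), which is how the model captures
joint volume-and-location structure of lesions. The fit is by
expectation-maximization:

* E-step: responsibilities
  $r_{ik} = \pi_k P(X_i \mid \mu_k) / \sum_l \pi_l P(X_i \mid \mu_l)$,
  computed in log space with a log-sum-exp so that long masks cannot
  underflow.
* M-step: soft counts $N_k = \sum_i r_{ik}$, priors $\pi_k = N_k / N$, and
  rates $\mu_k = \sum_i r_{ik} X_i / N_k$. Normalizing the rate update by
  the soft count $N_k$ (not by $N$) is the update consistent with the
  E-step and with the requirement that a single-cluster fit reproduce the
  average map; the $K=1$ equivalence is pinned by a test at $10^{-12}$.

The territory's model-based probability map is the voxelwise cluster
maximum $\mu_{\max}(j) = \max_k \mu_{k,j}$ (`mu_max_map()`), which always
dominates both the mixture mean and the average map.

### Choosing K

`select_k()` fits $K = 1 \dots k_{\max}$ and keeps the largest $K$ for
which every fitted cluster retains at least a minimum fraction
(default 10%) of the group. Two implementation decisions tie the rule
down at the edges:

* A fit whose clusters have *identical* rate maps (which is what EM
  provably converges to when all masks are identical — the weighted mean
  of identical rows is the same row for any weights) is treated as
  inadmissible: a duplicated cluster is not a distinct lesion pattern.
  Such fits carry a `duplicate_clusters` flag rather than erroring.
* On data that genuinely contain only one noisy pattern, a two-way split
  of the noise can keep both halves above 10% of the subjects; the bare
  minimum-fraction rule cannot exclude this, and we do not pretend
  otherwise. The rule is intended for cohorts with real multi-pattern
  structure, where superfluous clusters collapse onto one or two subjects
  (well below the threshold) — the behaviour we verify on planted
  mixtures.

## From probabilities to a sharp atlas

**Claiming.** A voxel is claimed by a territory when some cluster rate is
within $\alpha$ Bernoulli standard deviations of certainty:
$\mu + \alpha\sqrt{\mu(1-\mu)} \ge 1$. For rates in $[0,1]$ this is
algebraically equivalent to $\mu \ge 1/(1+\alpha^2)$, so at the default
$\alpha = 3$ claiming is exactly thresholding $\mu_{\max}$ at 0.1
(`claim_threshold()`); the claimed set grows with $\alpha$. Voxels claimed
by several territories are coded OVERLAP, brain voxels claimed by none
UNDEFINED.

**Overlap resolution.** Each OVERLAP voxel goes to the territory with the
largest $\mu_{\max}$ there.

**Water-spreading.** Each remaining unlabeled brain voxel receives the
label of its nearest labeled voxel by exact Euclidean distance (computed
with a separable lower-envelope distance transform in compiled code,
honouring anisotropic voxel sizes). After this step the labels partition
the brain mask.

**Ties.** Exact ties — equal probabilities at argmax, equal distances in
water-spreading, tied modal counts in smoothing — are broken by the fixed
priority MCA > PCA > VB > ACA (descending stroke frequency in typical
cohorts), then ascending label id. This makes every stage deterministic.

**Smoothing and hierarchy.** `sharp_atlas_from_prob()` assigns each voxel
to the territory with the highest average-method probability and fills
the rest by water-spreading; `smooth_labels()` then applies one pass of a
spherical modal filter (default radius 1 voxel) to regularize coarse,
discontinuous borders deterministically. Background never invades the
brain and no new label can appear. `subdivide_by_anatomy()` intersects
territory labels with any user-supplied anatomical parcellation to define
sub-territories (e.g. lobar subdivisions), and `merge_to_level2()`
collapses them back to the four major territories via the lookup scheme,
conserving voxel counts.

## Border zones and certainty

`border_ratio()` computes $p_a / p_b$ exactly on the voxels where both
probabilities are positive; off that support the ratio is undefined and
stored as missing with an explicit support mask, not as 0 or infinity.
`certainty_index()` normalizes the territory probabilities voxelwise,
$CI_s = P_s / \sum_t P_t$; the indices sum to 1 on the support by
construction and are reported in percent by `mean_ci_by_roi()` (fractions
internally).

## Registration QC

`make_strips()` builds three strips of configurable bandwidth (default 5
voxels) around the template brain surface (outside: OSBM, inside: ISBM)
and outside the lateral ventricles (OSLV). `qc_ratios()` scores a
deformed B0-like volume by

* $\gamma_{OSBM}$: fraction of OSBM voxels with positive intensity
  (tissue spilling out of the template brain),
* $\gamma_{ISBM}$: fraction of ISBM voxels with zero intensity
  (background intruding into the brain),
* $\gamma_{OSLV}$: fraction of OSLV voxels brighter than a CSF cutoff
  $\lambda$.

The cutoff is $\lambda = \bar{v} - 0.5\,\mathrm{sd}(v)$ over the deformed
intensities inside the template ventricle mask — a lower CSF-intensity
bound, so that bright CSF-like voxels outside the template ventricles are
counted as mis-deformed. Because reasonable alternatives exist, the rule
is an ordinary function argument (`lambda_rule`) and can be swapped
without touching the metric.

## The synthetic phantom

`make_phantom()` builds an ellipsoidal brain with an interior ventricle,
partitions it into contiguous angular sectors (one per territory), and
plants a Bernoulli mixture per territory: each cluster occupies a
distinct radial band of its sector (a compact deep band, a broad
peripheral band) with constant rates drawn in $[0.45, 0.9]$ and bounded
within $[0.05, 0.95]$. `sample_cohort()` draws subjects cluster-first,
then voxelwise Bernoulli; a configurable fraction (default 0.475, typical
of unselected stroke cohorts) is mirrored to the right hemisphere to
exercise the left-lateralization step. `make_phantom_b0()` produces
piecewise-intensity volumes with a known integer mis-alignment so QC
outcomes can be counted by hand.

What the phantom emulates: the generative mixture structure, group
imbalance, hemisphere mixing, countable misregistration. What it does
not: real lesion morphology (smooth rate gradients, spatially correlated
noise within a cluster), registration error fields, scanner effects, or
anatomy. Passing tests therefore demonstrate correctness of the
algorithms under the stated model, not clinical validity of any atlas
built from real data.

## Numerical choices

* Rates are clipped to $[\varepsilon, 1-\varepsilon]$ with
  $\varepsilon = 10^{-6}$ wherever a likelihood is evaluated, because the
  binary MLE sits on the boundary; `unclip_rates()` restores exact 0/1
  for map output.
* EM initialization draws per-subject responsibilities from a symmetric
  Dirichlet; 10 restarts by default, keeping the best final
  log-likelihood; convergence when the absolute improvement drops below
  $10^{-6}$ or after 500 iterations. The log-likelihood trace is
  non-decreasing within a run (tested with slack $10^{-8}$ across many
  seeds).
* All randomness flows from explicit integer seeds; identical inputs and
  seeds give bit-identical fits and atlases.
* Cluster matching in recovery tests uses the best permutation by total
  variation distance between rate maps; printed cluster sizes use
  round-half-away-from-zero.
* Degenerate inputs: empty territory groups error with the territory
  named; an M-step cluster collapse triggers a re-initialization and, if
  persistent, a flagged (not fatal) fit; claim maps refuse to spread
  while OVERLAP voxels remain.

## Scale of the validation suite

Tests and the acceptance script run the full machinery at desk scale:
phantoms of $16^3$–$32^3$ voxels, cohorts of 10–200 subjects per
territory, $k_{\max} \le 5$. These sizes were chosen so that planted
parameters are comfortably recoverable (binomial noise well below the
recovery tolerances) while a complete run stays in the seconds-to-minutes
range; the algorithms themselves are resolution-agnostic and accept
full-resolution template grids.

## Known limitations

* The claiming rule depends only on $\mu_{\max}$, so territories with
  very heterogeneous lesion sizes rely on the mixture having separated
  that heterogeneity into clusters first.
* The minimum-fraction K rule is a heuristic; see the discussion above
  for its behaviour on degenerate data.
* `mean_ci_by_roi()` inherits the sample-size sensitivity of the average
  method; with strongly imbalanced groups the certainty index is biased
  toward the larger group.
* No registration is performed here: masks are assumed co-registered, and
  the QC metrics only *score* deformations produced elsewhere.
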