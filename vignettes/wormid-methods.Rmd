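---
title: "Annotating every cell of an L1 larva: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating every cell of an L1 larva: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormid)
```

This vignette explains the statistical models behind `wormid`, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical and design decisions taken where the problem was
genuinely open.

## The position model

A straightened L1 larva is a rod roughly 250 µm long in which every one of
the 558 cells occupies a stereotyped position. The atlas (a `worm_template`)
models each cell identity $j$ as an independent anisotropic Gaussian with
mean $(\bar x_j, \bar y_j, \bar z_j)$ and per-axis standard deviations
$(\sigma_{x_j}, \sigma_{y_j}, \sigma_{z_j})$, estimated from labelled
training worms after registering each worm to a target animal with a
12-parameter affine transform. The affine fit is unweighted least squares;
nothing in the training data justifies down-weighting particular cells.

Two derived quantities use this model:

* the **atlas matching score** of a template is the mean of
  $f = \exp\{-\tfrac12 \sum_{\text{axis}} (\Delta/\sigma)^2\}$ over all
  worms × cells after global-plus-piecewise registration (amplitude 1, no
  smoothing constant) — for 100 worms this averages 55,800 per-cell values;
* the **CAC/WAC confidence scores** use the same Gaussian with the SDs
  inflated by the smoothness constant $\alpha = 20$, so that the score
  field stays informative over displacements tens of SDs wide. WAC is the
  plain mean of the 558 CACs.

**sd_floor.** Every score divides by $\sigma$; degenerate training (e.g.
identical worms) would produce zeros. SDs are floored at 0.1 µm, roughly
the centroid precision of a well-segmented nucleus at 0.116–0.122 µm
voxel pitch.

## Registration

1. **PCA rigid pre-alignment.** Principal axes leave a four-fold sign
   ambiguity among right-handed frames. The frame minimizing the symmetric
   mean nearest-neighbour distance is chosen; rotations always have
   determinant +1, so a mirrored worm is never silently reflected.
2. **Robust point matching.** Deterministic-annealing softassign: the
   soft correspondence $m_{ij} \propto \exp(-\|x_i - A \bar x_j\|^2 / 2T)$
   is normalized towards doubly stochastic (30 alternating row/column
   sweeps) with one slack row/column absorbing outliers, alternated with a
   weighted least-squares update of the affine map $A$, while
   $T$ cools geometrically (rate 0.93) from
   $T_\text{init} = \max_{ii'} \|x_i - x_{i'}\|^2 / k$ down to
   $T_\text{final} = (\overline{\sigma})^2$. These schedule constants are
   not dictated by the method's description, which defers to the generic
   annealing framework; the defaults are exposed in `rpm_config()` and the
   data-derived temperatures adapt them to any worm size. The final soft
   matrix is rounded to a hard bijection by maximum-score bipartite
   matching.
3. **Piecewise affine.** Windows 1/8 of the template's anteroposterior
   extent slide in steps of 1/8 window; membership is decided by the
   template-side X coordinate (stable under subject noise), intervals are
   half-open except the last, windows with fewer than 8 pairs fall back to
   the global affine, and a point mapped by several windows takes the
   unweighted average (window-overlap weighting is not specified anywhere;
   uniform averaging keeps the map continuous in practice).

The affine family is used inside the annealing loop, matching the global
transform model; spline-based deformations are deliberately out of scope.

## Assignment and refinement

Identity assignment maximizes the *sum of Gaussian scores* (not
log-scores) with the Hungarian algorithm — a compiled $O(n^3)$
shortest-augmenting-path solver in `src/`, as no installed R package
provides weighted linear-sum assignment. Far from the template every
$f_{ij}$ underflows towards zero and the assignment would become
arbitrary; a secondary key of $-10^{-12} \times$ squared Mahalanobis
distance keeps it geometrically sensible and deterministic without
affecting well-scored blocks. Extra nuclei are absorbed by zero-score
slack columns; missing identities are reported rather than force-assigned.

Refinement re-runs global affine → piecewise affine → scoring → bipartite
assignment three times (the tool's standard operating point). Only these
steps iterate; the annealing is not restarted, since the bipartite
correspondence strictly dominates the soft one by then. Per-iteration
affine refits use all current pairs unweighted.

The RPM-based and bipartite-improved annotations both carry CAC/WAC under
the same final mapping geometry. The output rule returns the
bipartite-improved result when its WAC passes 0.995 — the comparison is
inclusive (≥), a convention choice at an unstated boundary — and the
RPM-based result otherwise, because the bipartite step helps precisely
when the worm already fits the template well. With several templates, all
are tried and the highest-WAC output wins.

## Confidence calibration and EPC

Cell-specific CAC thresholds are calibrated on annotated validation worms:
the threshold of a cell is intended to separate a low-CAC region where its
assignment accuracy falls below 50%. The estimator is not fully
determined by that statement, and the obvious scan ("largest observed CAC
whose below-threshold accuracy is < 0.5") drifts above isolated correct
assignments whenever errors make up just under half of everything below
the top of the range. `wormid` therefore anchors candidate thresholds at
the CAC values of *incorrect* instances and picks the largest one whose
at-or-below accuracy is under 50%. Cells with fewer than 20 validation
instances get the default threshold 0 (never flagged) — conservative, to
avoid spurious flags from tiny samples.

EPC (error prediction and correction) flags assigned cells below their
threshold; user-curated fixes are pinned and the residual score submatrix
is re-solved, so one corrected member of a swapped pair typically repairs
the other as well. Accuracy is always reported against the template size
$k$ (558 for a full worm): a missing identity counts as an error.

## Expression quantification

Background is the mean reporter intensity of ten pseudonuclei. The
method's description divides background-subtracted reporter fluorescence
by DAPI fluorescence "to account for spherical aberration" and then adds a
500-unit offset inside a log: a bare ratio would be on the wrong scale for
that offset. `wormid` multiplies the ratio by the worm's median DAPI,
which preserves intensity units (the stated +500/level-1 anchor keeps its
meaning) while still cancelling per-nucleus attenuation. This algebra is a
documented interpretation, flagged as such. Negative background-subtracted
values clamp to level 0 ("undetectable"); detector thresholds of "$n$-fold
background" translate to levels above $\log_2(n+1)$, since 500 normalized
units is the stated background-equivalent scale.

Strain profiles are stack means; TF profiles average the strains of the
most faithful reporter class available (knock-in/fosmid, then
high-context promoter, then low-context promoter). Z2/Z3 are dropped for
transgene silencing, leaving 556 somatic cells.

## Profile analytics

Clustering uses average linkage on $1 - r$ (Pearson across TFs). Node
support is a multiscale bootstrap proportion: TFs are resampled at
relative sizes 0.5–1.4 (step 0.1), 1000 replicates each, and a node's
support is the share of replicate trees containing its exact leaf set.
These are plain BP values over the stated grid — the selective-inference
extrapolation of multiscale bootstrap theory is deliberately not
implemented, and outputs are labelled accordingly.

Subtyping labels internal dendrogram nodes by small parsimony over the
binary given-type/other state, minimizing bichromatic edges (verified
against exhaustive labelling for trees up to 12 leaves). Ambiguities
resolve top-down by inheriting the parent's state, with root ties going to
"other" — fewer, tighter subtypes. A subtype's *neighbor clade* is the
maximal clade containing no given-type cell that is reachable through the
fewest inter-type edges; because edges between other-type nodes are free
under that metric, ties break by tree distance (the nearest such clade),
then clade size, then traversal order. Group JSD normalizes each cell's
non-negative profile to a probability vector (all-zero cells become
uniform, preventing undefined Kullback–Leibler terms) and averages base-2
pairwise divergences; the normalized inter-subtype score divides by the
mean cross-neighbor-clade JSD and refuses denominators below $10^{-12}$.

The four spatial detectors follow fixed rules (10-cell window present in
all four bundles with silence elsewhere; per-bundle linear regression of
level on anteroposterior rank with an undetectable end cell and slope
$p < 10^{-3}$ in more than one bundle — the criterion's "lineage
regression" is read as linear regression; strict founder-group dominance
with the single AB-derived muscle excluded; per-worm fourfold asymmetry
with one silent mate, called at ≥ 75% directional consensus over at least
8 worms). Enrichment of asymmetric calls in lineage-convergent over
lineage-symmetric pairs uses an exact two-sided Fisher test implemented by
direct hypergeometric enumeration (two-sided by summing all tables no more
probable than the observed one), cross-checked in the tests against both
enumeration and `stats::fisher.test`.

## The synthetic-data generator

`make_synthetic_template()` places `n_cells` (default 558) along a 250 µm
rod with anterior crowding (positions $\propto u^{1.5}$, mimicking the
dense head), radial spread 5 µm, and per-cell per-axis SDs drawn uniformly
from 0.2–0.6 µm. `simulate_worm()` adds per-cell Gaussian jitter
(SD × `noise_multiplier`), an optional quadratic bend, a random affine
(rotation ±10°, anisotropic scale 0.9–1.1, shear ±0.05, translation
±10 µm), optional uniform outliers, and a random point permutation, all
recorded as ground truth.

**Calibration of the SD scale.** The positional-variability scale is the
one generator parameter with no printed value, and it controls task
difficulty through the ratio of variability to inter-nuclear spacing. It
was calibrated so that the synthetic task reproduces the tool's published
operating point on real animals (annotation accuracy in the mid-90s at
1.0× noise, WAC near 0.995): an earlier, larger guess (0.5–1.5 µm)
produced a regime in which even the Bayes-style oracle — bipartite
matching on perfectly registered true coordinates — topped out near 70%,
i.e. a task strictly harder than the real data, which would have said
nothing about the pipeline. At 0.2–0.6 µm the oracle sits at ~97% and the
full pipeline lands within a point or two of it.

What the generator does **not** emulate: segmentation errors beyond
uniform outlier points, the stereotyped left–right mirroring of real
anatomy, correlated (worm-wide) positional deviations beyond the global
affine and bend, and background variability in photometry (non-expressing
nuclei sit exactly at background so that "undetectable" is exact; signal
noise is lognormal, σ_log = 0.2). Passing tests therefore demonstrate
correct mechanics and calibrated behaviour under idealized conditions, not
performance on real image stacks.

## Problem sizes and determinism

The shipped test-suite and acceptance script run, per invocation: 20
full-scale (558-cell) worms at 1.0× noise and 20 at 0.3× for accuracy, 50
worms across 0.5–2.0× for the WAC–accuracy correlation, a 50-worm template
rebuild, 200 random assignment matrices against brute force, trees up to
12 leaves against exhaustive labelling, and a 54-TF planted-pattern screen
with 50 null TFs. These sizes keep a full run in the minutes range on one
CPU while leaving each statistic well-determined. All generators are pure
functions of their seed; annotation itself contains no randomness beyond
documented tie-breaks, so identical inputs give identical outputs.

## Known limitations

* The annealing schedule and window parameters are sensible defaults, not
  fitted values; unusually shaped animals may need `rpm_config()` tuning.
* Subtype support values are BP, not selective-inference corrected;
  clades with support near the conventional 95 threshold should not be
  over-interpreted.
* The DAPI-normalization algebra is an interpretation (scale-preserving
  ratio); absolute expression levels depend on it, though detector calls
  depend only on fold-thresholds and zeros.
* Accuracy claims are synthetic-regime results; real stacks add
  segmentation artefacts the generator does not model.
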