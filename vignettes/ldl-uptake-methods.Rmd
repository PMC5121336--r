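---
title: "Models and procedures behind the LDL-uptake screen analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and procedures behind the LDL-uptake screen analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldlscreen)
```

`ldlscreen` implements the quantitative procedures of a genome-wide RNAi
screen for LDL uptake in endothelial cells and of its follow-up assays: plate
normalization and hit calling, the siRNA deconvolution filter cascade,
TIRF-based detection of vesicle fusion (transcytosis) events, colocalization
statistics, and equilibrium/kinetic ligand-binding fits. Because the
underlying raw plates and image stacks are not publicly deposited, the
package ships synthetic-data generators that emulate the statistical
structure of every input, with planted ground truth; the drivers under
`analysis/` walk the full pipeline on such data.

## Plate statistics and hit calling

Each 384-well plate is normalized with the robust z-score over its *sample*
wells only:

$$z = \frac{x - \mathrm{median}(x)}{1.4826\,\mathrm{MAD}(x)},$$

with control wells excluded from the location/scale estimate — they are
reserved for the Z'-factor gate,

$$Z' = 1 - \frac{3(\sigma_{pos} + \sigma_{neg})}{|\mu_{pos} - \mu_{neg}|},$$

computed from the negative (control siRNA) and positive (DNM2 siRNA) control
wells; plates with $Z' \le 0.2$ are discarded (the inequality is strict).
Wells with fewer than 100 cells or more than 20% dead cells are removed
before scoring; both QC boundaries count as passing, reading the rules
literally ("at least 100 cells", death "over 20%" rejected). A plate whose
sample MAD is zero raises an error rather than falling back to a standard
deviation: a silent scale substitution would mask a failed plate.

Replicates (three per plate) are combined per gene by the median — the
aggregation is not dictated by the screen's description, and the median
matches its robust-statistics ethos; the mean and an any-replicate
exceedance mode are available (`aggregate_and_call(mode = "any")`) since it
is equally defensible to call a gene on any single replicate. Calling is
two-sided at $|z| \ge 2.5$ with direction labels (`decrease` for reduced
uptake, the tail all downstream analysis uses), boundary inclusive.

The synthetic screen (`gen_screen()`) draws null well intensities from a
log-normal (fluorescence is positive and right-skewed; defaults
$\mu_{\log} = \log 1000$, $\sigma_{\log} = 0.12$, chosen to put the plate
Z' comfortably above the gate at 8 + 8 control wells, as a well-behaved
production screen runs). Effects act multiplicatively; planted hit sizes are
specified in plate-MAD units so that a $-6$ effect lands at an expected
robust z of $-6$. The default test scale is 2,000 genes x 6 plates x 3
replicates — a desk-scale stand-in for the 18,119-gene library; the planted
hit fraction in the analysis drivers (89/2000) mirrors the primary screen's
hit rate. What the generator does *not* model: spatial plate effects (edge
rows, gradients), batch drift between replicates, and siRNA off-target
structure; a pass on synthetic screens therefore certifies the statistics,
not robustness to spatial artefacts (B-score-style polish is out of scope).

## The deconvolution filter cascade

Candidate genes are re-tested with four individual siRNAs, in duplicate
(sets 1 and 2), and filtered in four stages with the study thresholds:

1. **DiI-LDL confirmation** — an siRNA is active when it inhibits uptake by
   $\ge 50\%$ in *both* sets; a gene needs $\ge 2$ active siRNAs.
2. **Transferrin specificity** — $\ge 2$ siRNAs with $< 30\%$
   transferrin-FITC inhibition in both sets (strict inequality). By default
   at least one clean siRNA must also be DiI-active
   (`tf_overlap = "one"`): the legend's "at least 2 siRNAs" does not state
   whether they must coincide with the active ones, so the requirement is a
   package choice, configurable to `"none"` or `"all"`.
3. **LDLR independence** — per siRNA, the ratio of percent effect between
   LDLR-high and LDLR-low lines (sets averaged); $\ge 2$ siRNAs at a
   two-fold or larger difference — in either direction, since a "2-fold
   difference" is directionless — mark the gene LDLR-dependent and excluded.
   A zero or sign-flipped denominator counts as a 2-fold difference and is
   reported.
4. **HUVEC re-confirmation** — rule 1 on the HUVEC assay.

The stage order runs the LDLR filter before HUVEC re-confirmation, matching
the summary-figure ordering of the screen; because every stage is a pure
per-gene predicate the two orders can only differ in which stage is blamed
for a failure, and `huvec_last = FALSE` swaps them. Genes with negative
inhibition (enhanced uptake) pass through transferrin filtering but can
never count as active. The generator (`gen_followup()`) plants decoy classes
that each violate exactly one rule, so tests can verify that every decoy
dies at its intended stage and nowhere else.

## TIRF fusion-event detection

Movies are 150 frames at 6.67 frames/s of the basal ~110 nm of the cell.
The pipeline is detect → link → classify:

* **Detection** (`detect_spots()`): Gaussian smoothing, thresholding at
  `k_sigma` robust noise s.d. above the frame median, and watershed
  splitting of touching blobs on the smoothed intensity relief (plain
  connected components would merge near neighbours into one elongated blob
  and lose both). Blobs are filtered by area, circularity and peak height
  above background. Circularity $4\pi A / P^2$ is measured on the
  half-maximum sub-mask with the perimeter counted as exposed pixel edges:
  the smoothed detection mask fattens thin objects enough to disguise them,
  while the FWHM contour keeps discs at ~0.5-0.8 and a one-pixel line near
  0.3 (default cut 0.4). Background-relative thresholding makes detection
  invariant to constant offsets.
* **Linking** (`link_tracks()`): greedy nearest-neighbour frame-to-frame
  assignment, links accepted up to `max_displacement` px per elapsed frame,
  gap closing up to `max_gap = 2` missing frames. The original study's
  tracker is unpublished; greedy NN is the simplest standard choice and is
  exercised against planted straight-line and gap fixtures.
* **Classification** (`detect_fusion()`): over the track's intensity series
  $I_t$, the difference series $d_t = I_t - I_{t-1}$ is formed; a fusion is
  called at the earliest $t$ where $d_t$ and $d_{t+1}$ both fall below
  $\mathrm{mean}(d) - 2.5\,\mathrm{sd}(d)$ — a decrease exceeding 2.5 s.d.
  of the track's own intensity-change rate, sustained for two consecutive
  frames — provided the vesicle was stationary (net drift $\le 3$ px over
  the trailing 5 observations, i.e. docked) and the post-drop intensity
  stays below half the pre-drop level. The mean-centred reading of the
  criterion is used; a raw-difference reading differs only by the bleaching
  slope, which is negligible at realistic rates. The no-recovery condition
  operationalizes what a fusion *is* — the vesicle is gone afterwards — and
  rejects transient photometric dips that the two-frame rule alone would
  accept on long, quiet tracks.

The per-track intensity series is measured by PSF-weighted (matched-filter)
photometry at the tracked positions rather than by summing the detection
mask: the estimator is then consistent between bright and dim frames (so the
two collapse steps register as comparable differences) and light from
vesicles a few pixels away is suppressed by orders of magnitude. The series
is extended three frames past the last detection at the final position, so
the collapse to background is part of the data even though the spot itself
is no longer detectable. Eligibility requires 10 observations (a stable
`sd(d)`); when `sd(d)` degenerates, a floor of 3x the propagated
camera-noise s.d. of the readout applies and the event is flagged. An
affine (linear-in-time) decay has constant $d$ and can never trigger;
smooth exponential photobleaching at realistic rates is likewise below
threshold at every point.

The movie generator renders vesicles as Gaussian PSF spots (sigma 1.3 px)
with Brownian lateral motion, stochastic docking, global photobleaching and
Gaussian camera noise. Three modelling points deserve mention. Fusion is
rendered as a collapse to background in two comparable steps (full → 1/2 →
0), the natural rendering of a two-frame decay and the regime the two-frame
criterion is designed for. Non-fusing vesicles leave the evanescent field by
directed transport that starts a few frames before the intensity fades —
undocking precedes axial exit — because a vesicle that fades *while
stationary* is indistinguishable from a fusion by any detector implementing
the stated rule. And vesicle anchor positions keep a minimum spacing of 4.5
PSF sigma (distinct docking sites): two vesicles stacked within one PSF
width make the planted truth unresolvable in principle. Real movies contain
unresolvable coincidences, blinking dyes and uneven illumination; the
recovery rates measured here (recall and precision both above 0.9 across
seeds) certify the algorithm under resolvable conditions, not performance on
arbitrary raw data. Event counts are reported per movie, with optional
per-cell normalization when a cell count is supplied, since the study's
typical 20-40 events per 150 frames is most consistent with a per-field
reading.

Colocalization uses the standard Pearson correlation over masked pixels and
Manders split coefficients $M_1 = \sum_i a_i [b_i > T_b] / \sum_i a_i$ (and
symmetrically $M_2$), with errors raised on zero-variance or all-zero
channels rather than returning NaN.

## Binding models

**Saturation binding.** `fit_saturation()` fits
$B(L) = B_{max} L / (K_d + L)$, optionally plus a linear nonspecific term,
by Levenberg-Marquardt least squares with equal weights (a `1/B`
Poisson-style weighting is available for count-derived data). Rescaling the
concentration axis rescales $K_d$ exactly and leaves $B_{max}$ untouched,
so units follow the data (µg/ml for the cell-surface assay).

**SPR kinetics.** The 1:1 interaction model
$$\frac{dR}{dt} = k_a C(t) (R_{max} - R) - k_d R$$
with a piecewise-constant injection schedule $C(t)$ has an exact
piecewise-exponential solution (within a segment at constant $C$:
$R(t) = R_{eq} + (R_0 - R_{eq}) e^{-(k_a C + k_d)(t - t_0)}$ with
$R_{eq} = k_a C R_{max}/(k_a C + k_d)$, response carried over between
single-cycle injections). Both the simulator and the fitter use this closed
form rather than a numerical ODE integrator — it is exact at the
discontinuities that make generic integrators stumble, and fast enough for
global fitting. Fitting is over all phases jointly with $(k_a, k_d,
R_{max})$ on the log scale (positivity) and a small multi-start grid over
$k_a$; $K_d = k_d/k_a$ in the schedule's concentration units (molar for the
SPR assays; the cellular µg/ml scale is never converted to molar because
the LDL particle's molar mass is not defined). Mass-transport limitation is
deliberately not modelled — the analysis is a simple 1:1 fit, and the
affinities it returns are apparent ones. Double referencing subtracts the
reference-surface and buffer-blank traces point-for-point on a shared time
base. Competition is judged from the $K_d$ and amplitude ratios between a
naive and a pre-saturated surface (non-competitive within two-fold both
ways); the stability reference point is read 5 s into the final
dissociation — the description says only "initial phase", and 5 s clears
bulk refractive-index transients at the 1 Hz sampling used here.

## Numerical choices and degenerate inputs

* Plate MAD of zero, equal control means, fewer than 3 control values,
  zero-variance colocalization channels, saturated/flat frames, flat
  sensorgrams: all raise typed errors naming the degeneracy.
* Missing siRNA duplicates count as inactive and are reported via
  attributes, never silently imputed.
* The saturation fitter refuses $K_d$ estimates pinned at the parameter
  bounds (unconstrained isotherm).
* Problem sizes in the test-suite and drivers — 2,000-gene screens, 5-20
  movies of 150 frames at 180x180 px, 20 kinetic round trips — were chosen
  as the smallest scales at which every recovery statistic stabilizes.

## Known limitations

* The manual curation that reduced the primary hit list to the 140-gene
  follow-up panel was a human step in the study and is not modelled; the
  cascade starts from a candidate table.
* Cell segmentation is out of scope; TIRF event counts are per field unless
  a cell count is supplied.
* The tracker is greedy and can mis-assign crossing vesicles; the planted
  minimum docking-site spacing means tests do not exercise dense crossing
  regimes.
* Heterogeneous-ligand and two-state SPR models, and Biacore native file
  parsing, are not implemented.
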