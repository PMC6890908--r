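---
title: "Quantifying striatal DAT SPECT: indices, VOI schemes, and a combined SVM classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying striatal DAT SPECT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Dopamine-transporter (DAT) SPECT with ^123^I-Ioflupane images presynaptic
dopaminergic integrity of the striatum. A normal scan shows two symmetric,
comma-shaped regions of high uptake spanning caudate and putamen; in
parkinsonian syndromes (PS) uptake falls, recedes from the posterior
putamen toward the caudate ("dot" shape), and becomes asymmetric. Visual
reading therefore weighs three findings — intensity, shape, and lateral
asymmetry — and quantitative reading can mirror that with three families of
indices. `datspect` implements six such indices under the two
volume-of-interest (VOI) conventions in widespread clinical use, combines
each scheme's triplet with a linear support-vector machine, and evaluates
the single and combined indices with nonparametric group tests, ROC
analysis and paired AUC comparisons.

Because clinical scans cannot be redistributed, the package carries its own
synthetic data stage: a voxelized striatal phantom generator and a fast
tabular cohort simulator, both calibrated to published PS/NPS group
statistics, so that every stage of the analysis can be exercised and tested
end to end.

## The two VOI schemes

**Fitted scheme (`fitted_q`).** Six sub-VOIs coincide with the template's
anatomical compartments — caudate, anterior putamen, posterior putamen,
per hemisphere — plus a bilateral occipital reference. This mirrors
template-based software that registers scans to a normalized space and
measures mean counts in tight striatal VOIs.

**Pentagonal scheme (`pentagonal_v`).** One large pentagonal prism per
hemisphere encloses the striatum with a wide margin (the template striatum
dilated by 12 mm, apex anterior, mirrored across the midline, extruded
across slices), with a whole-brain reference that excludes a zone around
the basal ganglia (both prisms dilated by one voxel). Because the prism
captures essentially *all* striatal counts, total-count quantification in
this scheme is insensitive to resolution loss — the partial-volume
rationale for large-VOI methods.

Two geometry choices are ours. The pentagon has no published dimensions,
so its cross-section is derived from the template striatum (12 mm
dilation, apex extension 0.45 of the box width) and is config-driven. The
whole-brain reference is additionally restricted to the brain interior
(18 mm margin from the brain surface): voxels at the brain edge lose
counts to the surrounding air under finite resolution, and including them
would bias the reference concentration downward and make the prism SBR
resolution-dependent, defeating the scheme's purpose.

## The six indices

With `L`/`R` the per-hemisphere values and an index reported as the mean
of sides unless noted:

* **SBR-Q** — mean counts of the striatal VOI (union of the three
  sub-VOIs), background-subtracted, divided by the occipital mean:
  `SBR = (S - O) / O`.
* **SBR-V** — the Southampton total-count formulation. With `C_t` the
  total prism counts, `C_r` the reference count concentration (counts/mL)
  and `V_voi` the prism volume: `SBR = (C_t / C_r - V_voi) / V_str`, with
  `V_str = 11.2` mL per hemisphere (the method's canonical assumed
  striatal volume; configurable). A plain concentration-ratio variant is
  exposed via `sbr_v_formula = "concentration"` since the two readings of
  the method differ in the literature.
* **PCR-Q** — raw mean putamen counts (anterior ∪ posterior) over raw mean
  caudate counts, per side then averaged. Raw, not background-subtracted,
  read literally from the index's definition.
* **AI** — `|L - R| / ((L + R) / 2)`, computed from the per-side SBRs of
  each scheme. Published values make AI-Q a fraction (~0.03–0.09) and AI-V
  a percentage (~4–15), so the package scales AI-Q by 1 and AI-V by 100 by
  default.
* **FD-V** — the fractal-dimension shape index. Five threshold stages
  `t_i` (default 0.35–0.55 of the in-VOI maximum, configurable) delineate
  the striatum; `N_i` counts the in-prism voxels at or above `t_i × max`;
  FD is the negated least-squares slope of `ln N_i` on `ln t_i`, averaged
  over hemispheres. Compact comma-shaped uptake shrinks slowly with
  threshold (low FD); dot-like uptake shrinks fast (high FD). Voxels are
  counted in 3D throughout the prism by default; single-slice 2D counting
  is available (`counting = "2d"`).

Every index is a ratio or a threshold-relative count, so all six are
exactly invariant under positive rescaling of the volume; left/right
mirroring swaps the per-side values and leaves AI, mean SBR and FD
unchanged. Both properties are enforced by tests.

## The classifier stage

Each scheme's triplet (SBR-Q, PCR-Q, AI-Q; SBR-V, FD-V, AI-V) feeds a
linear soft-margin SVM on standardized features `x' = (x - mean) / sd`,
with the separating hyperplane `W·x' + b = 0`. The cohort is split
75/25 with stratification (largest-remainder seat allocation per class —
for 71 PS / 40 NPS the test split is 18 + 10 = 28 subjects; published
test denominators of 19 + 9 imply a different, unstated rounding rule,
which we do not chase). The cost parameter is selected from
{0.01, 0.1, 1, 10, 100} by stratified 10-fold cross-validated accuracy on
the training part (ties to the smallest cost — the paper reports neither a
cost nor a selection metric), then the model is refit on the full training
set. Standardization parameters are estimated on the training part only
and reused on the test part; a leaking variant exists behind a flag for
sensitivity checks. Fold assignment ranks subjects canonically within
class before the seeded shuffle, so permuting input rows changes nothing.
The decision orientation is normalized so PS scores positively.

## Evaluation

* **Mann-Whitney U** with midrank ties; the two-sided p is exact (dynamic
  programming over the rank multiset) when `n_a·n_b ≤ 400`, else a
  normal approximation with tie and continuity correction.
* **ROC/AUC** via ranks, ties counting one half; the AUC identically
  equals `U / (n_pos · n_neg)`.
* **DeLong comparisons** of paired AUCs from placement-value covariance;
  a curve compared with itself returns z = 0, p = 1 by convention.
* **Cutoffs** maximize Youden's J (ties toward higher sensitivity),
  reported as midpoints between adjacent observed scores. The criterion is
  configurable in principle; Youden is the default because the source
  analyses name none.
* **Confusion metrics** as percentages rounded half-up to one decimal
  (matching clinical table conventions); undefined ratios (zero
  denominators) are `NA`, never 0.
* The report evaluates single indices on the full cohort with
  resubstitution cutoffs and the SVMs on the held-out split — an
  asymmetry the report labels explicitly, mirroring how such analyses are
  commonly published. No multiple-testing correction is applied, and the
  report footer says so.

## The phantom generator

A subject is a uniform brain ellipsoid (background 1) carrying three
ellipsoidal striatal compartments per hemisphere at specified count
concentrations. Three degrees of freedom emulate disease:

* `shape_erosion` e ∈ [0, 1] attenuates putaminal contrast toward
  background with posterior priority: anterior weight `(1 - e)`, posterior
  weight `(1 - e)^2`, so e = 1 leaves a caudate-only dot.
* `asymmetry_factor` multiplies one hemisphere's intensities. Note it
  scales whole intensities, not contrasts, so the SBR asymmetry index
  slightly exceeds the factor's own asymmetry.
* Resolution and noise: isotropic Gaussian PSF (default FWHM 12 mm, a
  typical post-reconstruction resolution for ^123^I brain SPECT with
  fan-beam collimators; the source protocol states none) and Poisson
  sampling after scaling to `total_counts` (default 2×10⁶, typical for a
  30-min acquisition).

The default grid is 128×128×48 voxels at 4.4 mm isotropic, matching the
stated acquisition matrix. Geometry lives in a versioned JSON template in
template space; registration of real brains is out of scope, so phantoms
are generated directly in that space. Blurring is a separable 1D
convolution (kernel truncated at 3.5σ, unit-sum taps, zero boundary),
which conserves interior mass to well under 0.1%; compartment bases are
blurred once per template and cached, so cohort generation is a linear
combination plus Poisson noise per subject (~50 ms each after the first).

What the phantom does **not** emulate: anatomically realistic striata,
ventricles and sulci (whose dilatation is a known confounder of large-VOI
methods), attenuation, scatter, projection-domain physics and
reconstruction artifacts, and inter-subject anatomical variability.
Passing tests therefore demonstrate correctness of the measurement and
decision machinery under the stated generative model — not clinical
performance on real scans.

## Cohort calibration

Two generators produce labeled cohorts (default 71 PS / 40 NPS):

**Tabular** (`tabular_cohort`): six-index vectors drawn per class from
zero-truncated normal marginals whose *parent* parameters are
moment-matched so the truncated mean/SD equal the published group
means/SDs — this matters for strongly truncated margins such as AI-V in
PS (15.2 ± 13.3). A Gaussian copula applies an optional between-index
correlation; the default is independence because the source reports no
correlation structure. A consequence worth stating: with independent
calibrated marginals the cohort AUCs need not reproduce the published
AUCs exactly (the binormal AUC implied by the SBR-Q means/SDs alone is
≈0.96 against a published 0.978); the simulator is calibrated to
*marginal statistics* and recovers the published ranking of indices
directionally, which is what the acceptance checks assert.

**Image** (`sample_cohort` + `image_cohort_panels`): per-class phantom
parameters are drawn as a common uptake scale (CV 0.25 NPS / 0.33 PS)
times fixed base intensities, with small per-compartment jitter, plus
class-specific erosion and asymmetry distributions. The base intensities
were solved once, on the default template at 12 mm FWHM, so that the
NPS cohort means of SBR-Q, SBR-V and PCR-Q land on the published 2.32 /
5.61 / 0.86; the template compartment semi-axes were likewise fixed so
that the blur-induced SBR-Q/SBR-V ratio matches the published ratio of
means. For PS the solve anchors SBR-V (3.26) and PCR-Q (0.75) exactly,
with erosion centred at 0.5; the implied PS SBR-Q (~1.4) then sits
somewhat above the published 1.07 — a consequence of using one geometry
for both classes that we accept rather than distort the template per
class.

## Numerical notes and edge cases

* All randomness flows from explicit per-operation seeds through a
  save/restore of the RNG state; no global state leaks.
* FD stages with zero count are dropped with a warning (at least three
  stages must survive); in practice a positive in-VOI maximum guarantees
  every stage counts at least one voxel. FD of a flat (binary) profile is
  exactly 0.
* FD is not strictly monotone in erosion over the whole [0, 1] range:
  once the putamen has fully vanished the thresholds re-reference to the
  surviving caudate maximum and FD plateaus. It is monotone over the
  PS-typical range and the full dot always scores above the intact comma.
* Compartments clipped by the grid raise an error naming the compartment;
  empty masks, grid mismatches, constant features, single-class training
  sets and degenerate ROC inputs all fail fast with specific messages.
* Exact Mann-Whitney enumeration uses doubled midranks (integers) in a
  subset-sum dynamic program, so tied data are handled exactly.

## Problem sizes used by the test suite

Unit and property tests run on the default 128×128×48 template (one
cached blur basis per session). Cohort-level checks use one full-size
image cohort (71/40, ~10 s) and tabular cohorts of up to 10,000 per class
for convergence checks; the behaviour-recovery suite runs 20 tabular
cohort seeds at 71/40 with both SVM stages per seed. The full suite
completes in well under a minute on one CPU.
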