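---
title: "Methods and design choices in septaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in septaquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(septaquant)
```

# The scientific problem

During ventricular septation the interventricular septum (IVS) forms at the
interface of two cardiomyocyte lineages. A compartment boundary — an
interface that restricts intermingling of adjacent lineages — keeps the
boundary-marking lineage in a narrow, well-positioned, well-oriented band.
Genetic perturbations (reduced Tbx5 dosage, loss of the guidance genes Slit2
or Ntn1) disrupt this boundary and produce ventricular septal defects
(VSDs). septaquant implements the four quantitative analysis families used
to establish and measure such a boundary and its disruption, plus a
synthetic phantom generator that provides ground-truthed inputs for all of
them.

# Lineage linear profiles

A boundary's position and integrity are read out from fluorescence line
profiles drawn right-to-left across the ventricles on maximum slab
projections. The pipeline is: rolling-ball background subtraction
(`subtract_background()`, 50-pixel radius by default), slab maximum
projections (`slab_max_projection()`, 50 um slabs at E13.5–E14.0 and 100 um
at E14.5), bilinear profile sampling anchored at the septal midline
(`sample_profile()`; position 0 = midline, positive = anatomical left),
max-normalization (`normalize_profile()`), and aggregation onto a common
1-um grid over the overlap of all profiles (`aggregate_profiles()`).

Each profile is summarized by its intensity-weighted first moment
$m = \sum w_i x_i / \sum w_i$ (boundary position, um) and spread
$s = \sqrt{\sum w_i (x_i - m)^2 / \sum w_i}$ (boundary integrity). Group
comparisons (`compare_boundaries()`) use Welch's two-sided t-test on the
per-profile $m_i$ for position shift and a two-sided F-test on the variance
of $m_i$ for boundary broadening. The source experiments never state the
per-profile statistic behind their mean/variance tests; the first moment is
used because a single position per profile matches the reported
profiles-per-sample degrees of freedom. The alternative variance operand
(the mean per-profile spread $s_i$) is available via
`compare_boundaries(spread_operand = "profile_s")`.

Pointwise comparisons (`pointwise_welch()`) run Welch's t-test at every grid
position and report raw p-values — no multiplicity correction, matching the
source convention of flagging raw $P < 0.05$ runs; Benjamini–Hochberg is
available off-by-default (`adjust = "BH"`). Zero-variance conventions:
identical constant groups give $t = 0, p = 1$; differing constants give
$p = 0$; an F-test between two zero-variance groups is flagged undefined.

The rolling-ball background is implemented as grayscale opening with a
non-flat ball element (height $\sqrt{r^2 - d^2}$), the standard
morphological equivalent of the rolling-ball procedure.

# Orientation scoring

Cell arrangement in the IVS is scored with a structure tensor
(`structure_tensor_field()`): Gaussian-derivative gradients at scale
`gradient_sigma` (1 px), tensor components smoothed over a Gaussian window,
per-pixel orientation $\theta = \tfrac12\,\mathrm{atan2}(2J_{xy},\,
J_{xx} - J_{yy}) + 90^\circ$ mapped to the iso-intensity (structure)
direction, coherency $C = (\lambda_1 - \lambda_2)/(\lambda_1 + \lambda_2)$
and energy $E = \lambda_1 + \lambda_2$. Convention: 0 degrees = image
x-axis, counter-clockwise positive, axial period 180.

**Window size.** The tensor window defaults to `window_sigma = 4`, not the
smaller window sometimes used for fine textures, because per-pixel
eigen-anisotropy is positively biased when the window holds few independent
gradient samples: white noise scores apparent coherency near 0.28 at a
sigma-2 window (about 0.22 even with central-difference gradients) and only
drops below 0.2 — the level at which isotropic input is reliably
distinguished from oriented tissue — around sigma 4. Stripe coherency and
angle recovery are unaffected by the wider window.

`directionality_histogram()` bins per-pixel structure orientations weighted
by squared gradient magnitude into 2-degree axial bins whose centres are
multiples of the bin width (so 0 is always a centre), `align_to_dominant()`
rotates the dominant bin to 0 under the axial wrap, and
`pool_angle_scores()` sums weight within a centre +/- halfwidth under the
wrap, so pooling at 90 collects both the +90 and -90 neighbourhoods. The
"directionality score" is the histogram weight itself (the plugin-equivalent
amplitude definition is not used; which one the source used is unstated).

Distributions are compared with the two-sample Watson U² statistic
(`watson_u2_two_sample()`), computed from pooled cumulative-fraction
differences with midrank tie handling. The p-value defaults to label
permutation — exhaustive enumeration whenever the number of label
assignments does not exceed `n_perm`, otherwise random permutations with the
$(k+1)/(B+1)$ estimator — because panel-sized samples make the asymptotic
series an approximation; the series is available via
`method = "asymptotic"`. Pooled angle scores are compared with
`wilcoxon_rank_sum()`, the two-sided normal-approximation rank-sum test with
continuity correction and tie-corrected variance.

# Serial-section morphometry

Morphometry operates on serial-section class-label stacks (one class per
pixel; 5 um slice thickness by default, the standard histological slide
thickness). Lumen "empty space" is an explicit class: the module's contract
is label-based, and intensity thresholds (the dark-pixel rule, mean RGB
< 200) apply only to RGB section inputs.

* `ivs_fill()`: tissue pixels over all pixels of the IVS region including
  its internal empty space. For label input the region is a supplied mask
  or the morphological closing of the IVS class (which fills pores).
* `trabeculation_fraction()`: $V_\mathrm{att} / (V_\mathrm{att} +
  V_\mathrm{IVS})$, where attached trabeculae are 26-connected trabecular
  components that touch the IVS by face adjacency.
* `compact_thickness()`: per-slice local thickness (largest inscribed disk)
  of the compact myocardium restricted to the apical 20% of the base–apex
  extent, averaged per side. Centre-to-centre distances make a w-pixel slab
  read w (odd) or w-1 (even) pixels — nominal within one pixel. Image
  borders are treated as continuation, so walls must be surrounded by
  labelled background to be measurable.
* `detect_vsds()`: contact voxels are LV-lumen voxels face-adjacent
  (6-neighbourhood, avoiding diagonal leaks) to RV-lumen voxels and vice
  versa; 26-connected components of contact voxels become defect records.
* `vsd_area()`: per slice, the closing chord $c_k$ is the geodesic through
  non-tissue space between the two septal rim endpoints bounding the
  aperture (straight chord available; the source traced these paths by
  hand, so both readings are provided and the geodesic is the default),
  minus one pixel so the open gap between rim faces is measured; the defect
  area is $A = \sum_k c_k \cdot t$ with $t$ the slice thickness.
* `classify_vsd()`: membranous if the contact region lies within 50 um of
  atrioventricular-complex tissue, else muscular; subtype assignment was
  manual in the source, so a manual override is accepted and recorded with
  provenance.
* Cell morphometry: `cell_shape_from_axes()` treats cells as ellipses
  (area $\pi L W/4$, eccentricity $\sqrt{1-(W/L)^2}$, diameter of the
  equivalent-area circle $\sqrt{LW}$ — "diameter" is otherwise undefined
  for an ellipse); `detect_nuclei()` finds smoothed intensity peaks with
  non-maximum suppression; `nuclei_density()` divides detections by ROI
  area.

**Convergence of the defect area.** At fixed 5-um slices the chord-sum
estimator converges, as pixel size shrinks, to the analytic chord sum on
that slice grid (for a 50-um cylinder: 7881 um², +0.34% of $\pi r^2$), not
to $\pi r^2$ itself; and summed per-slice quantization errors can tie
exactly between pixel sizes. Refinement checks therefore track the mean
per-slice closing-chord error (which halves per 2x refinement), while the
area itself is asserted against $\pi r^2$ at the stated 5% band.

# Genetic interaction GLM

VSD incidence across genotypes is modelled as binomial counts with
$\mathrm{logit}\,p = \beta_0 + \beta_T\,d_T + \beta_G\,d_G +
\beta_{TG}\,d_T d_G$, where $d_T \in \{0,1\}$ counts Tbx5 mutant alleles and
$d_G \in \{0,1,2\}$ counts Slit2 or Ntn1 mutant alleles. Because control
groups can be all-unaffected (0 of 14), ordinary maximum likelihood
diverges; `fit_firth()` maximizes the Jeffreys-prior penalized likelihood
$\ell(\beta) + \tfrac12 \log\det I(\beta)$ by Newton iteration on the
Firth-modified score with step-halving, which keeps every estimate finite.
Convergence requires max |score| < 1e-6 and relative penalized-likelihood
change < 1e-8. Wald z and p-values come from $I(\hat\beta)^{-1}$; a
penalized-likelihood grid oracle (`brute_force_penalized_loglik()`)
cross-checks the optimum independently. `reported_effects()` returns the
per-allele (heterozygous) coefficient, its doubling for homozygotes
(hom = 2 x het exactly, by the linear dose coding), and the interaction
log(OR).

The wild-type control denominator and the inclusion of homozygous groups in
interaction fits are ambiguous in the source counts; the control row is an
explicit input in the shipped CSVs (never hard-coded), and
`firth_sensitivity()` tabulates the reported effects across the plausible
group sets (all groups vs heterozygote-only; control n = 14 vs 7). One
model is fitted per defect type per gene pair.

# The synthetic phantom generator

Every analysis family has a paired generator whose defaults are the stated
experimental world; each is a pure function of its spec and seed
(bit-identical reruns, no global RNG state).

* `make_boundary_volume()`: channel 1 follows a logistic step of the
  boundary centre and width along right–left; channel 2 a Gaussian band at
  the centre. Cells are Gaussian blobs of sigma 4 um on a Poisson point
  process (mean spacing 12 um), retained per-channel with labeling
  efficiency 0.8 — reporter recombination is mosaic but never quantified in
  the source, so 0.8 is a modelling choice, not a calibration. Background
  0.05 and noise sd 0.05 on the unit-plateau scale. With `cells = FALSE`
  the smooth expectation field itself is returned; noiseless analytic
  claims (the half-plateau midpoint, 1-um centre recovery) hold exactly for
  that field and only in slab-mean expectation for the blob texture.
* `make_oriented_texture()`: sinusoidal stripes mixed with unsmoothed white
  noise (isotropic at every scale); measured coherency increases
  monotonically with the mixing weight.
* `make_section_stack()`: a simplified four-chamber geometry (compact
  shell, septum, AV complex, atrial band, lumens, optional trabecular
  ridges) with optional cylindrical septal holes of known radius; ground
  truth stores both $\pi r^2$ and the slice-grid chord sum.
* `make_cell_mask_set()`: non-overlapping ellipses with a truth table.
* `sample_incidence()`: binomial draws from an `allele_dose_model()`.
* `make_profile_set()`: profile-level Gaussian-band ensembles with centre
  jitter, used where full volumes would be wasteful (repeated power
  simulations); the volume path is exercised by the noiseless
  centre-recovery checks.

**What a green test does not establish.** The phantoms have no optics (no
point-spread function, attenuation, or multi-view fusion artifacts), no
H&E colour variation beyond the dark-pixel rule, no real segmentation noise
in the label maps, and idealized hole geometry. Green tests establish that
the estimators recover known truth under the stated noise model — not that
segmentation or acquisition errors of real embryo data are absorbed.

# Numerical choices and degenerate inputs

* Profiles: all-zero profiles refuse to normalize; positions must strictly
  increase; aggregation requires a common overlap.
* The Watson U² of two all-identical samples is 0 with p = 1; all-tied
  rank-sum data give p = 1.
* Structure-tensor energies below 1e-18 x max(image)² are treated as exact
  zeros so constant images report zero energy and coherency.
* Label stacks must use legend codes only; readers reject unknown codes,
  shape mismatches and missing sidecars rather than defaulting.
* Seeds are explicit everywhere; derived streams stay below 2^31.

# Known limitations

* The anatomical midline anchor is an input (the source anchored manually
  at the interventricular groove); no automatic midline detection.
* The geodesic closing path is computed on the pixel 8-neighbour graph;
  strongly concave apertures may read up to ~8% long — the straight-chord
  option bounds this from below.
* The 95%-Wald coverage of the interaction coefficient in small-sample
  incidence designs is correct to within sampling noise (~0.95 measured at
  600 replicates) but not conservative.
* Pure-R morphology makes very large rolling-ball radii (hundreds of
  pixels) slow; the stated 50-pixel default is fast at panel-sized images.
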