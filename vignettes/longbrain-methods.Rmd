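---
title: "Consistent 4D analysis of longitudinal brain MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consistent 4D analysis of longitudinal brain MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Serial T1-weighted MRI of one subject is the standard instrument for
measuring slow structural brain change — cortical thinning of a few
hundredths of a millimetre per month, hippocampal volume loss of a percent
per year. Processing each timepoint independently wastes the strongest prior
available: it is the *same* brain. Independent runs of skull stripping,
tissue segmentation and atlas labeling each add their own noise-driven
jitter, which easily exceeds the biological signal over a two-year
follow-up. `longbrain` implements a jointly-processed ("4D") pipeline in
which every stage couples the timepoints:

1. **Preprocessing** — geometry canonicalization to RAS, N3-style bias-field
   correction per image, histogram matching of follow-ups to the baseline.
2. **4D brain extraction** — one deformable surface per timepoint, evolved
   simultaneously under a temporal-smoothness force, initialized from a
   common sphere after probability-map stripping.
3. **4D tissue segmentation** — three coupled level sets per timepoint with
   local Gaussian intensity models and spatial + temporal cortical-thickness
   constraints.
4. **4D ROI labeling** — groupwise registration of the series to an unbiased
   group mean, symmetric atlas-to-mean registration, deformation composition
   and label propagation.
5. **ROI analysis** — per-ROI volumes, tissue masking, baseline-normalized
   trends.

Every stage is testable without clinical data through a synthetic phantom
generator that emits complete ground truth.

## Preprocessing

Bias correction follows the classic histogram-deconvolution scheme: in the
log-intensity domain the observed distribution is modeled as the true
distribution blurred by a Gaussian gain spread. Each iteration Wiener-deconvolves
the masked histogram (200 bins; kernel FWHM 0.15 log units), forms the
conditional expectation of the true log-intensity given the observed one,
and fits a tensor-product cubic B-spline (knot spacing 40 mm, ridge-stabilized
least squares) to the residual; about fifty such iterations remove
20–30% smooth gain fields almost completely on the bundled phantoms
(recovered-field correlation > 0.999 on a two-class object with a 30% sine
gain). The gain constant is chosen so the masked mean intensity is
preserved; a zero-mean log-field would leave a Jensen gap of about half the
field variance, so the log-field mean is slightly negative instead.

Histogram matching maps 256 interior quantiles of each follow-up onto the
baseline's, with the range endpoints as additional anchors so the map is a
true monotone bijection of the observed range rather than a clamp.

## 4D brain extraction

Each timepoint's brain surface is a subdivided icosahedron (2562 vertices at
the default subdivision 4) sharing one triangulation across timepoints, so
vertex `i` corresponds across time. Initialization: groupwise affine
alignment (12-parameter, SSD, matrix-log recentring so the common space is
the unbiased Karcher-style mean of the poses), probability-map warping
(affine then demons refinement), stripping at P >= 0.5, per-timepoint
equivalent-sphere estimates, and their average as the common initial sphere.

Four forces act on every vertex: neighbourhood-centroid smoothing (tangential
part applied fully, normal part attenuated by a curvature sigmoid); a local
intensity force comparing the minimum intensity along the inward normal
(depth 7 mm) and the local maximum (depth 3 mm) against a fractional
threshold `bt` of the local maximum; a probability force along the normal
proportional to P − 0.5; and the temporal force pulling each vertex toward
the mean of its corresponding vertices at the neighbouring timepoints
(endpoints use their single neighbour). With the temporal weight at zero the
4D loop is arithmetically identical to independent 3D evolutions — this
reduction is asserted bit-for-bit in the test suite.

`bt = 0.3` is the package default. The classic default of 0.5 assumes dark
CSF; on T1-like contrast where CSF sits midway between background and GM
(the phantom uses 0/40/80/120 for background/CSF/GM/WM), a threshold at half
the local maximum lands exactly on the CSF intensity and the force loses its
sign there. 0.3 places the threshold between skull (20) and CSF (40), where
the decision is actually made. All force weights (1.0/0.3/0.3/0.5), the step
(0.1 mm) and the classic 1000-iteration convention are configuration, not
constants; phantom runs converge by ~300 iterations.

## 4D tissue segmentation

Three level sets per timepoint carry the WM/GM, GM/CSF and CSF/background
interfaces; the last is fixed by the extraction mask. Voxel intensities are
modeled as Gaussians with spatially-varying means and variances, estimated
as Gaussian-window-weighted statistics (default window FWHM 5 mm) over each
class region. Two estimation details matter in practice and are worth
stating:

* statistics are fitted on *interface-eroded* cores (0.9 voxel), because
  partial-volume voxels inflate class variances asymmetrically and would
  bias the decision boundary off the true interface;
* the data term uses a *pooled* local variance per interface pair, so the
  boundary condition is the midpoint of the local class means. With
  per-class variances, the variance asymmetry that survives erosion pushes
  the GM/CSF boundary outward into a self-consistent wrong equilibrium
  (about half a millimetre on the phantom).

The 5 mm window follows the intensity texture of parenchyma; wide windows
(15 mm) cannot track it and cost several points of overlap. A window this
small also absorbs smooth gain fields by itself, which is why the
segmentation experiments run on uncorrected images: the global bias stage's
small residual otherwise shifts sub-voxel boundary positions of thin shells.

The spatial thickness term penalizes cortical thickness outside the
biologically plausible 1–6.5 mm band; the temporal term clamps each
timepoint's thickness to the interval spanned by its immediate neighbours
("in-between" semantics: if the neighbours already bracket the current
value, the constraint is silent, so genuine monotone atrophy is untouched).
Both constraints read thickness from a dedicated field: the signed
difference of the two corrected signed distances, which equals the local
sheet thickness *everywhere* — inside WM, in GM, and in CSF — unlike the sum
of unsigned distances, which grows away from the sheet and would feed
spurious signals to the constraint inside the Dirac band. Two numerical
precautions: the constraint field is recomputed from freshly reinitialized
distances (the evolving level-set values saturate between
reinitializations under clipped updates and are not metric), and the clamp
compares 4 mm-smoothed fields (sheet thickness is a property of the sheet,
and voxel-level noise in the warped neighbour maps would otherwise act as a
stochastic forcing).

Distance quantization: a voxel-center distance transform overshoots the true
sub-voxel interface by half a voxel along the dominant axis of the interface
normal; every thickness readout subtracts `(h/2) * max|n_i|` per interface.
On the phantom this removes a +0.8 mm bias exactly. For longitudinal trend
fitting the per-timepoint summary is the *median* thickness over GM voxels
(the mean is compressed by partial-volume tails); a sub-voxel *global*
summary — GM volume over mid-surface area (`thickness_global`) — is also
provided.

Optimization alternates an independent 3D pass per timepoint (data + spatial
term), demons registration of consecutive tissue maps (affine-initialized,
so global modes are carried), and a 4D pass with the temporal term, until
fewer than 0.1% of voxels change label. The temporal term is applied at
interior timepoints; at the series ends the in-between interval degenerates
to an equality pull toward the single neighbour, which measurably flattens
genuine atrophy there, so endpoints keep the data and spatial terms only
(configurable via `temporal_endpoints`).

## 4D ROI labeling

The groupwise stage repeats: select key points on the current group mean,
match them to every timepoint by patch NCC, assemble per-key-point temporal
trajectories, kernel-smooth them along time (Nadaraya–Watson, bandwidth 1
timepoint), densify to per-timepoint fields by thin-plate splines, subtract
the mean field (unbiased common space), warp and update the mean. The atlas
is then registered to the group mean with the same machinery run
symmetrically in both directions, and labels ride the composed deformations
onto each timepoint by nearest-neighbour pullback.

Key-point saliency is the smallest eigenvalue of the local structure tensor
(the 3D analogue of "good features to track"). A gradient-based saliency
ranks smooth edges highest; on a head image those are the scalp and skull
shells, whose tangential position is not observable from a local patch —
selected points all land there and their matches corrupt the TPS globally.
The structure-tensor criterion scores only points localizable in all three
directions. Matching robustness stacks four filters: an NCC floor (0.6),
mutual-best consistency within one voxel, a distinctiveness margin over the
best competitor two or more voxels away (0.005), and a robust trim of
correspondences more than 3 MAD from a global affine fit. Trajectories use
key points matched in at least two timepoints; the kernel smoother fills the
gaps.

TPS uses the 3D kernel U(r) = r with an exact affine part; with zero
regularization it interpolates the control displacements exactly and
reproduces affine maps everywhere — both properties are asserted at 1e-6 in
the tests.

## ROI analysis

ROI volumes are voxel counts (unions of basic labels count shared voxels
once) times the voxel volume; tissue-masked variants intersect an ROI with a
segmentation class, e.g. hippocampal GM. Longitudinal series are normalized
by baseline and summarized by ordinary least squares; the canonical worked
example — normalized hippocampal volumes 1, 0.995, 0.99, 0.981 at months 0,
6, 12, 24 — gives a slope of −7.9048e-4 per month in closed form
(−0.249/315), which `normalize_and_trend()` reproduces to machine precision.
Results are tibbles; `tidy()`/`glance()` expose the fit, and
`plot_roi_trends()`/`autoplot()` draw trajectories.

## The phantom: what it emulates, and what it does not

The generator builds concentric spherical compartments (scalp 44, skull 40,
CSF 36, GM 33, WM 30 mm at the default 96^3 / 1 mm test profile; the classic
full-size profile is 256^3), with per-timepoint GM thinning (default 0.025
mm/month, i.e. 3.0 to 2.4 mm over the 0/6/12/24-month schedule), a smooth
multiplicative bias field (20%, product of sines), additive Gaussian noise
(sd 3), rigid jitter per follow-up (up to 2 mm / 2 degrees), a cerebellum
blob for removal tests, angular-sector ROI parcels (10 per hemisphere), and
a matched synthetic atlas (noise/bias/jitter-free baseline anatomy with
brain-probability map, tissue priors, labels and cerebellum mask).

Spheres rather than brain-shaped anatomy keep every ground-truth quantity
analytic — shell thickness is exactly the radius difference. Two kinds of
fixed anatomical texture are added: four deep-WM blobs (amplitude ~30) and a
smooth parenchymal texture field (correlation length 3 mm; amplitudes 12/8/4
for WM/GM/CSF, about 10% of tissue means, matching realistic T1 tissue
heterogeneity). Without texture the phantom is rotationally symmetric and
locally featureless — rigid pose would be unobservable and feature-based
registration would have literally nothing to match, so a texture-free
phantom cannot exercise the labeling machinery at all.

What passing phantom tests does *not* show: performance on real cortical
geometry (folded, variable thickness), real MR artifacts (ghosting, motion,
partial-volume beyond Gaussian smoothing), multi-subject anatomy differences,
or pathology. The phantom validates the machinery — consistency mechanics,
constraint behaviour, sub-voxel recovery — not clinical accuracy.

## Experiment design choices

* Consistency experiments compare paired arms (with/without the temporal
  coupling) on static phantoms with independent noise per timepoint, sharing
  everything else. Extraction consistency runs at the default noise; the
  segmentation consistency phantom uses noise sd 8 (SNR 5 at the GM/CSF
  contrast) because at sd 3 independent segmentation is already stable to
  ~0.01 mm and the comparison is vacuous — temporal regularization matters
  exactly in noise-limited regimes.
* Consistency phantoms are 64^3 (extraction) and 48^3 (segmentation), five
  seeds each; accuracy experiments run at the full 96^3 test profile.
* The labeling experiment warps the labeled template by known smooth random
  fields — a shared anatomical offset (mean 2 mm) plus a progressive drift
  (to 1.5 mm), temporally coherent like real longitudinal deformation —
  plus noise, and scores propagated labels against the warped truth.
* The segmentation experiments are motion-free so they measure segmentation,
  not registration, and feed truth-masked raw images (see above).

## Known limitations

* The demons and TPS registrations carry no diffeomorphic guarantee;
  composition inverse-consistency is verified numerically (~0.2–0.5 voxel)
  rather than by construction.
* The CSF/background interface is frozen at the extraction mask; errors in
  skull stripping propagate into CSF volume.
* Thickness readouts are reliable down to roughly 2–2.5 mm shells at 1 mm
  voxels; thinner sheets are increasingly quantization-limited.
* On single-timepoint input every stage runs its 3D reduction; the package
  then offers no advantage over conventional 3D tools, by design.
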