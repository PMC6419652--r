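---
title: "Respiratory gating, PET radiomics and survival: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiratory gating, PET radiomics and survival: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Respiratory motion during PET acquisition smears activity near the diaphragm
across the cranio-caudal axis. For lesions in the pancreas this blurring
inflates the apparent metabolic tumor volume, depresses single-voxel and mean
uptake values, and washes out intratumoral heterogeneity. Amplitude-based
optimal respiratory gating (ORG) counters this by keeping only list-mode data
acquired while the respiratory surrogate lies inside a narrow amplitude
window, at the price of using only a fraction (the *duty cycle*) of the
acquired counts.

`orgpet` implements this entire analysis chain on synthetic data with known
ground truth: a digital phantom with respiratory motion, the optimal-window
gating algorithm, isocontour tumor delineation, a 35-feature radiomic
panel (standard metabolic parameters, first-order histogram statistics, and
GLCM/GLRLM/GLSZM texture features), and the statistical layer that relates
features to overall survival (paired Wilcoxon signed-rank comparison,
standard-scaled univariate Cox models, and maximally selected log-rank
cutoffs on Kaplan–Meier curves).

# The phantom and motion model

`make_phantom()` renders a warm uniform background (default 1.0 SUV) with one
or more spherical lesions whose radial profile is a truncated Gaussian
(`sigma = radius / 2`, rescaled to reach exactly 0 at the boundary), an
optional necrotic core, and a Gaussian point-spread function. Defaults follow
typical whole-body PET reconstruction: isotropic 4.07 mm voxels and a 3.0 mm
FWHM post-filter. Because the PSF sigma (1.27 mm) is below the voxel size,
the blur kernel uses bin-integrated Gaussian weights
(`pnorm(k + 0.5, 0, sigma) - pnorm(k - 0.5, 0, sigma)`); a point-sampled
kernel at this sigma/spacing ratio underblurs by several percent, which a
high-resolution convolution oracle in the test suite would catch.

The respiratory surrogate is a Lujan-type waveform
\[ z(t) = A \cos^{2n}(\pi t / \tau), \]
which dwells near 0 mm (end-expiration) for most of each cycle — the
property that makes amplitude gating data-efficient. Defaults: period
\(\tau = 4\) s, amplitude \(A = 15\) mm (a typical pancreatic cranio-caudal
excursion), exponent \(n = 2\), 5% per-cycle amplitude jitter, no baseline
drift, sampled at 0.4 s (the sampling contract requires `dt < period / 8`).

`simulate_acquisition()` produces one frame per trace sample: the lesion
foreground is rigidly translated along the cranio-caudal axis by that
sample's amplitude (sub-voxel linear interpolation over the constant
background), then per-frame Poisson noise is applied on counts
`noise_scale * SUV`. The default `noise_scale = 10` counts/SUV gives roughly
10% per-frame coefficient of variation in lesion voxels around 10 SUV.
Frames stand in for list-mode events: with equal-duration frames, the time
fraction inside the window equals the data fraction, so the duty cycle is
measured over frames. Count-weighted and time-weighted selection coincide
under this proxy; for real list-mode data they can differ slightly.

Image formation averages frames rather than summing them, so gated and
ungated images share one SUV scale regardless of how many frames are kept.
The pipeline mirrors the clinical matched-statistics protocol: the
acquisition lasts `duration_s / duty` seconds (about 343 s at the defaults),
the ungated reference image averages the first 120 s of frames, and the
gated image averages the ~35% of all frames selected by the optimal window —
both therefore use the same amount of data. The frame mean is computed as a
base frame plus the mean of deviations from it, which makes the
zero-motion/zero-noise case give bit-identical gated and ungated images.

# The gating algorithm

`optimal_amplitude_window()` finds the narrowest amplitude window \([L, U]\)
containing at least `ceiling(duty * n)` of the `n` amplitude samples. Because
an optimal window for at-least-`k` coverage can always be shrunk until both
limits are attained sample values, scanning a sorted sliding window of size
`k` is exact; the package also ships `brute_force_window()`, an exhaustive
quadratic search used as the independent oracle in tests. Design choices the
vendor description leaves open, fixed here: the interval is closed on both
ends; coverage is at-least (`ceiling`); ties in the minimal width go to the
smallest \(L\), preferring the physiologically stable end-expiration phase;
candidate limits are the observed sample values (provably sufficient).

# Segmentation and features

`isocontour_voi()` delineates the metabolic tumor volume as the 26-connected
component, containing the maximum voxel, of voxels at or above 40% of the
regional SUVmax. The reference maximum is taken after subtracting manual
exclusions, so adjacent bright structures (duodenal uptake, biliary stents)
cannot set the threshold. The 26-connectivity of the retained component
mirrors the texture-matrix neighborhood; the VOI connectivity rule is
otherwise unspecified in clinical software. In synthetic runs the "manual"
seed region is the ground-truth lesion bounding box dilated by 2 voxels and
extended along the motion axis by the maximal displacement, which emulates
an annotator enclosing the blurred lesion.

Feature extraction discretizes in-VOI intensities into a fixed number of
bins (default 255) spanning the in-VOI min–max range. Fixed bin *count* (as
opposed to fixed bin width) makes all discretized features invariant to
adding a constant to the image, an invariance asserted in the tests. Texture
matrices use the 13 unique directions of the 26-neighborhood at distance 1
voxel. Conventions, chosen to match the common radiomics-toolbox
definitions behind each feature name:

* GLCM matrices are symmetrized per direction; the eight features are
  computed per direction on the normalized matrix and averaged (unweighted)
  over non-empty directions — not the merged-matrix variant.
  `Homogeneity.1` is Inverse Difference, `Homogeneity.2` is Inverse
  Difference Moment. Sum and difference entropies come from the
  \(p_{x+y}\) and \(p_{|x-y|}\) marginals.
* GLRLM runs are maximal straight same-level segments per direction;
  features use the standard emphases/non-uniformities, averaged over
  directions; Run Percentage divides by the VOI voxel count.
* The GLSZM is direction-free: zones are 26-connected components of
  equal-level voxels.
* Kurtosis is non-excess (a normal sample gives 3). `Energy` is the
  histogram uniformity \(\sum p^2\) over the 255-bin histogram.
* `SUVdiff` is SUVmax − SUVmin inside the VOI.
* The numeric suffixes in `Difference Entropy.1`, `Joint Entropy.2`,
  `Sum Entropy.3` are toolbox column artifacts preserved verbatim in output
  headers.

Degenerate (constant) VOIs return flagged limit values (entropies 0, Energy
1, Skewness/Kurtosis 0, Correlation 1) rather than erroring, so tiny
synthetic lesions cannot abort a cohort run. Every feature is checked
against an independently coded literal-definition oracle (plain loops over
voxels) to 1e-9 relative tolerance on randomized VOIs.

# The statistical layer

The paired comparison between reconstructions uses the Wilcoxon signed-rank
test (two-sided). Zero differences are dropped; for up to 25 informative
pairs the exact null distribution is computed by dynamic programming over
the sign assignments (doubling the average ranks makes them integers, so
ties are handled exactly); beyond that the normal approximation with
continuity correction is used.

Univariate Cox models are fitted per feature after standard scaling
(population SD, mean 0 / SD 1) so hazard ratios are per 1 SD; tie handling
is Efron's. Perfect separation (monotone likelihood) is flagged. The
log-rank statistic and Kaplan–Meier product-limit curves are computed from
first principles (hypergeometric 2×2 tables at each event time); tests
verify the hand-coded statistic against an independent reference
implementation and against the Cox score test, which it must equal for a
binary covariate.

`optimal_cutoff()` implements maximally selected log-rank dichotomization:
candidate cutoffs are the unique feature values between the 10th and 90th
percentiles, both groups must contain at least `max(5, 10% of n)` subjects,
and ties go to the smaller cutoff. The reported p value is the naive
log-rank p at the selected cutoff; it is anti-conservative because the
maximum of many correlated statistics is selected, and no multiple-testing
correction is applied across the 70 feature-by-reconstruction tests. Both
caveats are deliberate — they mirror common practice in exploratory
imaging-biomarker studies — and are surfaced in the documentation rather
than corrected silently.

Synthetic survival uses an exponential baseline hazard (default
\(\lambda_0 = 0.015\)/week, median ~46 weeks at HR 1, matching the scale of
advanced pancreatic-cancer cohorts) with proportional hazards on chosen
standardized features, and independent uniform censoring whose upper bound
is calibrated by root finding so the expected censoring fraction hits the
target (default 20%).

# Cohort defaults and what the simulation does (not) show

A default cohort subject has one lesion of radius 12–18 mm (uniform across
subjects; tumor diameters of 2.4–3.6 cm are typical for pancreatic ductal
adenocarcinoma at diagnosis), peak uptake lognormal around 8 SUV, two hot
foci (25–60% of the main peak excess, radius 0.45 r) at random positions
inside the lesion, and an off-center necrotic core at background uptake —
a deliberately heterogeneous lesion, since intratumoral heterogeneity is
what the texture panel quantifies. Problem sizes used throughout the tests
and the acceptance script — 50-subject cohorts on 28×28×36 grids, 857-frame
acquisitions, 200-replicate Cox recovery — were chosen as the smallest
sizes at which the directional effects and calibration statements are
stable across seeds.

Under these conditions the simulation reproduces the expected directional
effects robustly: gating raises SUVmax and SUVmean, shrinks MTV40%, and
increases the in-VOI standard deviation, each in essentially all subjects,
with paired Wilcoxon p values far below 0.05 at n = 50.

Two honest divergences from what is reported on patients. First, histogram
entropy *decreases* under gating here: with 255 bins and VOIs of only
50–300 voxels, the entropy is dominated by the voxel count, and gating
shrinks the VOI. In patients with larger tumors relative to the bin count,
or heterogeneity effects strong enough to dominate, entropy can rise.
Second, skewness and kurtosis increase under gating in only ~70–80% of
synthetic subjects, not near-universally. The phantom's heterogeneity
(smooth foci + core + Poisson noise) is evidently a weaker driver of
third/fourth moments than real tracer-uptake heterogeneity. Passing tests
therefore demonstrate the machinery (gating optimality, feature
definitions, statistical calibration) and the volume/uptake directions, not
every reported heterogeneity direction.

Other features of real data the generator does not emulate: deformable
(non-rigid) motion, attenuation/scatter effects, reconstruction artifacts
of iterative algorithms, inter-lesion anatomical variation, and correlated
(non-Poisson) noise. The survival generator plants effects on chosen
features; it cannot tell which features *should* predict survival.

# Numerical and degenerate-input choices

* Gating: exact sliding-window optimum; ties by smallest lower limit;
  `duty = 1` reduces to the full amplitude range.
* Blur: bin-integrated Gaussian weights, kernel truncated at 4 sigma (at
  least radius 1), edge replication so constants are preserved.
* Frame averaging: base-plus-deviations mean (exact for identical frames).
* Discretization: the maximum intensity maps to the top bin; constant VOIs
  map to level 1.
* Cox: `survival::coxph` with Efron ties; estimates with |beta| > 15 or
  SE > 50 are flagged as separation.
* Cutoff search: errors when no candidate satisfies the group-size
  constraint (e.g. constant features).
* Reproducibility: one global seed fans out to per-subject substreams via a
  counter-based map, so subject k's data do not depend on cohort size or
  order; CSV output is serialized at 9 significant digits and identical
  across reruns.

# Known limitations

The phantom is a single-lesion, rigid-motion, isotropic-voxel idealization;
gating efficacy depends on the waveform's end-expiration dwell (exponent
`n`), and amplitude-based windows are less effective for irregular
breathing than this jittered-but-periodic surrogate suggests. The naive
cutoff p values must not be read as confirmatory. Hazard-ratio magnitudes
from the synthetic survival layer reflect the planted effects, not
clinical effect sizes.
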