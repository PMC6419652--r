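# orgpet

Synthetic-phantom simulation and analysis of **amplitude-based optimal
respiratory gating (ORG)** in FDG-PET of pancreatic tumors: how correcting
for respiratory motion changes quantitative image features — single-voxel
uptake, metabolic volume, and intratumoral-heterogeneity (radiomic) measures
— and how that, in turn, changes their apparent association with overall
survival.

The package is aimed at imaging scientists who want a controlled, fully
reproducible test bed for gating and radiomics methodology where patient
list-mode data cannot be shared: every stage of the clinical analysis chain
is implemented on a digital phantom with known ground truth.

## What it implements

**Gating.** For a respiratory surrogate with amplitudes $z_1,\dots,z_n$ and
duty cycle $d$ (default 35%), the optimal amplitude window is the narrowest
interval $[L, U]$ containing at least $\lceil d\,n \rceil$ samples:

$$ W = \min_{L \le U}\; (U - L) \quad \text{s.t.}\quad
   \#\{i : L \le z_i \le U\} \ge \lceil d\,n\rceil , $$

found exactly by a sliding window over the sorted amplitudes (an exhaustive
quadratic search ships as the test oracle). Frames inside the window form
the gated image; frame averaging keeps gated and ungated images on one SUV
scale.

**Phantom.** `make_phantom()` renders heterogeneous hot lesions
(Gaussian-profile spheres, optional uptake foci and necrotic core) on a warm
background at 4.07 mm voxels with a 3.0 mm FWHM PSF; `lujan_waveform()`
generates the $A\cos^{2n}(\pi t/\tau)$ breathing surrogate;
`simulate_acquisition()` translates the lesion cranio-caudally per frame and
applies Poisson count noise.

**Segmentation and features.** `isocontour_voi()` delineates the metabolic
tumor volume at 40% of regional SUVmax (26-connected component of the
maximum, manual exclusions supported). `extract_all()` computes 35 features:
MTV, SUVmin/max/mean/diff, six first-order histogram statistics, and
GLCM/GLRLM/GLSZM texture features over a 255-bin discretized VOI
(13 directions, distance 1, 26-connectivity).

**Survival layer.** Paired Wilcoxon signed-rank comparison of reconstructions
(exact null distribution up to n = 25, ties handled), standard-scaled
univariate Cox models (hazard ratio per 1 SD, Efron ties), hand-coded
log-rank / Kaplan–Meier, maximally selected log-rank cutoffs, and a
proportional-hazards survival generator with planted feature effects.

## Worked example

Simulate a small cohort through the full chain — phantom, motion, gating,
isocontour VOI, features, paired statistics:

```r
library(orgpet)
cfg <- default_config()
cfg$cohort$n_subjects <- 8L
cfg$seed <- 11L
res <- run_pipeline(cfg)

res$windows[1:3, ]
#>   subject_id lower_L_mm upper_U_mm width_W_mm achieved_duty
#> 1          1   2.15e-72       1.72       1.72          0.35
#> 2          2   1.26e-01       1.84       1.71          0.35
#> 3          3   2.24e-72       1.74       1.74          0.35
```

Each subject's optimal window hugs end-expiration (lower limit at or near
0 mm) and is under 2 mm wide despite 15 mm of peak motion — the
end-expiration dwell of the breathing waveform is what makes a 35% duty
cycle this selective.

```r
data.frame(
  feature       = c("SUVmax", "SUVmean", "MTV"),
  median_nonORG = sapply(c("SUVmax", "SUVmean", "MTV"),
                         function(f) median(res$features[[f]][res$features$reconstruction == "nonORG"])),
  median_ORG    = sapply(c("SUVmax", "SUVmean", "MTV"),
                         function(f) median(res$features[[f]][res$features$reconstruction == "ORG"])),
  wilcoxon_p    = sapply(c("SUVmax", "SUVmean", "MTV"),
                         function(f) res$wilcoxon$p[res$wilcoxon$feature == f]))
#>  feature median_nonORG median_ORG wilcoxon_p
#>   SUVmax          5.57       8.12    0.00781
#>  SUVmean          3.26       4.70    0.00781
#>      MTV          4.75       2.39    0.00781
```

Motion correction raises the median SUVmax from 5.6 to 8.1 and SUVmean from
3.3 to 4.7, and halves the 40%-isocontour metabolic volume (4.8 → 2.4 ml):
ungated imaging smears lesion activity over a larger volume and dilutes it.
With all 8 subjects moving in the same direction, the paired Wilcoxon p is
the exact two-sided minimum for n = 8, $2/2^8 = 0.0078$.

`res$table2` additionally holds per-feature univariate Cox results (HR per
1 SD, 95% CI, Wald p) and maximally selected log-rank cutoffs for both
reconstructions, written as `table2.csv`/`cutoffs.csv` when an output
directory is given.

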