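---
title: "Measuring perforating-artery pulsatility from 2D phase-contrast MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring perforating-artery pulsatility from 2D phase-contrast MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfopulse)
```

## The measurement problem

Cerebral small vessel disease affects the sub-millimetre perforating
arteries (lenticulostriate and thalamic perforators) that supply the basal
ganglia. Velocity-encoded 2D cine phase-contrast (2D-PC) MRI can measure
blood velocity in these vessels: a slice through the basal ganglia is
acquired repeatedly over the cardiac cycle, and the image phase at each
pixel is proportional to the through-plane velocity,

$$ v = \mathrm{venc} \cdot \frac{\varphi}{\pi}, $$

where venc (20 cm/s here) is the velocity mapped to a phase of $\pi$.
Because the vessels are smaller than the in-plane voxel (0.3 mm acquired,
zero-filled to 0.2 mm on a 250 mm field of view), they appear as isolated
bright, high-velocity specks rather than resolved lumens. Three scan-level
outcomes summarize a scan:

* $N_\mathrm{detected}$ — the number of perforators surviving all detection
  filters;
* $V_\mathrm{mean}$ — the temporal mean of the velocity waveform averaged
  over all detected vessels (cm/s);
* the velocity pulsatility index of the mean normalized waveform,
  $\mathrm{vPI} = (V_\max - V_\min) / V_\mathrm{mean}$, where each vessel's
  curve is first divided by its own temporal mean so that the mean of the
  averaged normalized curve is exactly 1.

The package implements the full detection and quantification chain, the
agreement statistics used to judge its test–retest and inter-rater
reliability (Bland–Altman limits of agreement, coefficient of
repeatability, intraclass correlation, Dice overlap, paired t-tests, power
calculations), and a synthetic cine generator with known ground truth so
that every stage is testable without scanner data.

## The detection algorithm

Within a basal-ganglia ROI, `detect_perforators()` runs six stages, each
exposed as its own function:

1. **Noise estimation** (`estimate_noise_map()`): per pixel, the SD of the
   complex signal over the cardiac cycle,
   $\sigma_c = \sqrt{\mathrm{var(Re)} + \mathrm{var(Im)}}$, with per-channel
   SD $\sigma = \sigma_c/\sqrt2$. Static tissue varies little over the
   cycle, so this isolates thermal noise.
2. **Magnitude SNR mask** (`magnitude_snr_mask()`): pixels whose
   cycle-averaged magnitude is 2 per-channel SDs or less are removed (strict
   `> 2` keep).
3. **Velocity significance** (`significant_velocity_mask()`): the
   single-phase velocity noise is propagated as
   $\sigma_v = (\mathrm{venc}/\pi)\,\sigma/\bar M$. By default a pixel is
   significant when its temporal-mean velocity exceeds the two-sided
   $\alpha$ quantile of that noise level,
   $|\bar v| > z_{1-\alpha/2}\,\sigma_v$ (see *Numerical choices*).
4. **Clustering** (`cluster_and_select()`): significant pixels are grouped
   into 8-connected components; because the vessels are sub-voxel, the
   pixel with the highest $|\bar v|$ represents the vessel (raster-order
   tie-break).
5. **Circularity filter** (`circularity_filter()`): clusters whose
   principal-axis length ratio exceeds 2 are vessels crossing the slice
   obliquely and are removed.
6. **Proximity rule** (`proximity_dedup()`): among candidates within
   1.2 mm of each other — usually ghosting replicas of one vessel — only the
   fastest is kept, resolved greedily in descending $|\bar v|$.

Every removed candidate is retained with the filter that removed it
(`detection_provenance()`).

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `venc_cm_s` | 20 | cm/s | velocity-encoding limit (phase $\pi$) |
| `magnitude_snr_min` | 2 | – | magnitude SNR cutoff (exclusive keep) |
| `alpha` | 0.05 | – | level of the velocity-significance test |
| `velocity_test` | `"noise_level"` | – | noise-level vs SEM z criterion |
| `multiple_testing` | `"fdr"` | – | BH correction for the `"sem_z"` test |
| `connectivity` | 8 | – | pixel adjacency for clustering |
| `axis_ratio_max` | 2 | – | circularity cutoff |
| `min_separation_mm` | 1.2 | mm | proximity-rule distance |

The agreement statistics use the conventional 1.96 multiplier throughout:
limits of agreement are $\bar d \pm 1.96\,\mathrm{SD}(d)$, the coefficient
of repeatability is $\mathrm{CoR} = 1.96\,\mathrm{SD}(d)$ (reported also as
a percentage of the mean measured value), and the coefficient of variation
is $\mathrm{CV} = \mathrm{CoR}/1.96$.

## Numerical choices

**Velocity significance.** Two criteria are implemented. The default,
`"noise_level"`, declares a pixel significant when its mean velocity
exceeds the propagated *single-phase* noise level
($|\bar v| > z_{1-\alpha/2}\sigma_v$). The alternative, `"sem_z"`, tests
the mean against its standard error
($z = |\bar v|/(\sigma_v/\sqrt{n_\mathrm{phases}})$, BH-corrected across
tested pixels). The SEM test is exact in level, but that is precisely its
weakness as a detector: under FDR control the number of falsely significant
*pixels* grows proportionally with the number of truly significant ones, so
scenes with ~50 vessels acquire tens of single-pixel false vessels; and
with 12 cardiac phases the noise SD estimate has only 22 degrees of
freedom, so the nominal normal statistic is really Student-t and its far
tail is substantially heavier (measured null level 0.063 at
$\alpha = 0.05$; the unit tests assert the exact $t_{22}$ level). The
noise-level criterion is scale-matched to the noise itself, has an
effective $z^* = z_{1-\alpha/2}\sqrt{n}$ against the SEM, and yields
essentially no chance detections at any ROI size, which matches both the
intent of "velocity significantly above the noise level" and the observed
behaviour of scans with ~8 detected vessels in ~10⁴ ROI pixels.

**Cluster shape.** Axis lengths are $2\sqrt{\lambda_i}$ from the
population covariance of the cluster's pixel coordinates, floored at half a
pixel, so single-pixel clusters are exactly isotropic (ratio 1) and a 1×5
line has ratio $5.7 > 2$.

**Zero-filling.** Reconstruction to a finer grid pads the 2D DFT
symmetrically, keeping the DC bin in place; the spatial mean of each frame
is preserved to numerical precision and values at original sample positions
are reproduced exactly. When the target spacing does not divide the FOV
into an integer matrix, the matrix size rounds up and the achieved spacing
is recorded in the metadata.

**Degenerate inputs.** Zero estimated noise means infinite SNR (pixel
kept, significant iff its mean velocity is nonzero); identical paired
vectors give $t = 0, p = 1$ by convention, and a nonzero mean difference
with zero SD gives $p \to 0$ with a degeneracy flag; vessels with
nonpositive temporal-mean velocity are excluded from the vPI (with a
warning) rather than failing the scan.

**Sample size.** `sample_size_two_group()` defaults to the normal
approximation
$n = \lceil 2 (z_{1-\alpha/2}+z_{\mathrm{power}})^2 (\sigma/\delta)^2 \rceil$
per group — the convention used for the published feasibility number this
package reproduces (18 subjects for a 50% vPI increase at baseline
0.43 ± 0.16). The exact noncentral-t variant (`method = "t"`, via
`power.t.test()`) returns 10 per group; its achieved power (0.807) is what
the simulation-based validation test checks, since the normal
approximation's n = 9 has exact power 0.763.

**ICC.** Test–retest reliability uses the absolute-agreement
single-measurement ICC(A,1) from two-way ANOVA mean squares (the
consistency variant is available); the model label is carried in every
report.

## What the synthetic generator emulates — and what it does not

`render_cine()` simulates the acquisition at the acquired resolution and
reconstructs through the same `zero_fill_reconstruct()` the pipeline uses:
each perforator is an anisotropic Gaussian blob of complex signal whose
phase encodes a raised-cosine velocity waveform constructed to have
*exactly* the requested temporal mean and vPI (`cardiac_waveform()`; the
waveform family itself is a modelling choice — only the mean and vPI are
constrained by the measurement model). Static tissue is a flat background
at phase zero, complex Gaussian noise is i.i.d. per channel at the acquired
grid, and optional half-FOV ghost replicas can be added. Partial-volume
attenuation emerges naturally from the complex sum of tissue and blood
signal: measured vessel velocities are attenuated by
$\arg(T + B e^{i\varphi})/\varphi$, and because the vPI is computed from
mean-normalized curves it is far less affected than $V_\mathrm{mean}$
(the simulations show a small vPI *over*estimation, consistent with how
partial voluming is known to act on pulsatility).

The standard validation scene (`standard_scene()`) uses 50 circular
vessels (velocities ~6.5 ± 1.0 cm/s, vPI ~0.45 ± 0.14 — healthy-control
values), 10 oblique decoys (axis ratio 3) for the circularity filter, and
10 ghost decoys (half-amplitude same-waveform replicas 1.0 mm from their
host) for the proximity rule, at a vessel peak SNR of 10 with a tissue
floor of twice the noise SD. Two scene choices deserve comment. First, the
tissue floor: a signal-free background would populate the ROI with pixels
whose phase is uniformly random, a pathology real basal-ganglia tissue
does not exhibit and which no noise-propagation-based test can survive at
scale. Second, ghost amplitude: replicas at half amplitude keep the ghost
detectable yet separate its measured (tissue-attenuated) velocity from the
host's by several noise SDs, so the proximity rule deterministically keeps
the host — at amplitudes approaching the host's, which replica "wins" is a
coin flip in any algorithm that keeps the fastest candidate.

The generator does **not** model: relaxation or flip-angle effects, inflow
enhancement, SENSE reconstruction, background-phase offsets or eddy
currents, velocity aliasing, motion beyond rigid repositioning, or
through-plane partial voluming along the 2 mm slice. Passing the recovery
tests therefore demonstrates that the algorithm correctly implements its
filters and statistics under realistic geometry, noise, and partial-volume
mixing — not that detection performance on scanner data will match the
simulated sensitivity and precision.

## The simulated test–retest study

`run_retest_experiment()` mirrors the three-scan design used to
characterize reliability: per subject, scan 1 at the initial position;
scan 2 after a random rigid repositioning (uniform sub-voxel translation,
±2° rotation) with an independently re-drawn ROI (symmetric ±0.5 mm edge
jitter — a redrawn ROI is as likely larger as smaller); scan 3 repeating
scan 2's geometry with fresh noise only. Per-subject ground truth is drawn
from population distributions (mean velocity ~N(6.5, 1.0) cm/s, vPI
~N(0.45, 0.14) truncated positive, vessel count ~round N(8, 3) truncated to
[1, 12], heart rate ~N(68, 10) bpm mapped to 8–15 reconstructed phases).
Each scan runs the full detection and hemodynamics chain; Bland–Altman
reports compare scan 1 vs 2 (*with* repositioning) and scan 2 vs 3
(*without*).

Problem sizes were chosen so the whole study is quick to simulate while
preserving the physics that matters, all of which is local to each vessel:
subjects are rendered on a 22 mm sub-field at the true resolutions, venc,
and filter thresholds (a 35-subject × 3-scan experiment takes ~10 s; the
50-vessel validation scene uses a 50 mm patch). The scanner-noise
magnitude is a free parameter of the simulation (the protocol's actual
noise level is not published); the default vessel SNR of 10 is the
condition the recovery properties are stated at.

With only noise between repeats, the with-repositioning CoR can only gain
variance in expectation, but at 35 subjects the CoR-ratio estimator is
noisy (empirically ±~35% even with repositioning disabled, because
per-subject differences are a heavy-tailed mixture of waveform noise and
occasional vessel-inclusion flips). The end-to-end test therefore allows a
25% sampling tolerance on the comparison, and the zero-noise,
no-repositioning control is required to give exactly zero between-scan
differences.

## Known limitations

* The phase-to-velocity scaling assumes an ideal scanner: no
  background-phase correction is modelled or needed for synthetic data.
* Analyses are single-slice, single-venc; multi-slice series and DICOM
  ingestion are out of scope (NIfTI + YAML sidecar only).
* Reported velocities are magnitudes; retrograde flow is not distinguished
  in the hemodynamic summaries.
* The published per-subject outcome values depend on the original scanner
  data and are not reproduction targets; what the package reproduces
  arithmetically are the agreement statistics derivable from the published
  summary table and the power calculation.
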