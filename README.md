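# perfopulse

Detection and hemodynamic quantification of cerebral **perforating
arteries** in velocity-encoded 2D cine phase-contrast (2D-PC) MRI of the
basal ganglia, together with the test–retest and inter-rater reliability
statistics used to validate such measurements. The package targets
researchers studying cerebral small vessel disease who want the
perforator-detection chain, its agreement statistics, and a fully synthetic
validation bench in one place — no scanner data is required to exercise any
part of it.

## What it computes

In a 2D-PC acquisition the image phase encodes through-plane blood
velocity, `v = venc · φ / π` (venc = 20 cm/s). Perforators are smaller than
the in-plane voxel, so they appear as isolated high-velocity pixels. Inside
a basal-ganglia ROI the detection pipeline:

1. estimates per-pixel noise from the SD of the complex signal over the
   cardiac cycle,
2. removes pixels with mean-magnitude SNR ≤ 2,
3. keeps pixels whose temporal-mean velocity is significantly above the
   propagated velocity noise level,
4. clusters them (8-connected) and takes the fastest voxel per cluster as
   the vessel representative,
5. removes elongated clusters (major/minor axis ratio > 2, i.e. vessels
   crossing the slice obliquely), and
6. keeps only the fastest of any candidates within 1.2 mm of each other
   (ghosting replicas).

Per scan it reports **N_detected**, the mean velocity of the vessel-average
waveform **V_mean**, and the velocity pulsatility index of the
mean-normalized waveform,

```
vPI = (V_max − V_min) / V_mean ,   V_mean ≡ 1 after per-vessel normalization.
```

Reliability statistics: Bland–Altman mean difference, SD, limits of
agreement (`mean ± 1.96·SD`), coefficient of repeatability
(`CoR = 1.96·SD`, also as % of the mean), `CV = CoR/1.96`, ICC(A,1), Dice
overlap for ROI pairs, paired t-tests, and two-sample sample-size
calculations.

## Worked example

Simulate a scene with known ground truth (8 perforators at physiologic
velocities, 2 oblique decoys, 2 ghost replicas), detect, and summarize:

```r
library(perfopulse)

scene   <- standard_scene(n_vessels = 8, n_oblique = 2, n_ghost = 2,
                          fov_mm = 30, seed = 5)
r       <- render_cine(scene$perforators, scene$acq, scene$roi_spec)
vessels <- detect_perforators(r$series, r$roi)
vessels
#> <vessel_set> N_detected = 8
#> # A tibble: 8 × 10
#>   vessel_id   row   col  y_mm  x_mm mean_velocity_cm_s n_pixels major_axis …
#> 1         1    32   125   6.3  24.9               5.11       12       1.91
#> 2         2    43    49   8.5   9.7               6.51       12       2.24
#> 3         3    52   121  10.3  24.1               3.80       10       2.05
#> # …

glance(waveform_stats(r$series, vessels))
#> # A tibble: 1 × 6
#>   n_detected v_mean_cm_s   vpi v_max v_min heart_rate_bpm
#> 1          8        5.64 0.640  1.30 0.659             68

table(detection_provenance(vessels)$removed_by)
#> circularity        none   proximity
#>           2           8           2
```

All 8 planted vessels are recovered; both oblique decoys were removed by
the circularity filter and both ghost replicas by the 1.2 mm proximity
rule. `V_mean` (5.64 cm/s) sits below the planted ~6.5 cm/s because the
vessel signal mixes with tissue in the voxel (partial-volume attenuation);
the vPI, computed from normalized curves, is much less affected.

Agreement between paired scans:

```r
ba <- bland_altman(c(8, 6, 9, 7, 11, 8, 5, 9, 10, 7),
                   c(7, 6, 10, 8, 10, 9, 5, 8, 11, 8), outcome = "n_detected")
ba
#> <agreement_report> n_detected (n = 10)
#>   mean diff -0.2, SD 0.9189, LoA [-2.001, 1.601]
#>   CoR 1.801 (22% of mean 8.1), CV 11.34%
#>   ICC 0.882, paired t = -0.688 (p = 0.509)
autoplot(ba)   # Bland–Altman plot
```

A full three-scan test–retest study (repositioning between scans 1 and 2,
none between 2 and 3) runs end-to-end with
`run_retest_experiment(retest_config(n_subjects = 35, seed = 1))` and
returns per-subject outcomes plus per-outcome agreement reports.

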