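test_that("noise map recovers a planted channel SD and ignores offsets", {
  # temporally constant signal -> zero noise
  s0 <- make_series(array(2, c(5, 5, 6)), array(0.3, c(5, 5, 6)))
  nm0 <- estimate_noise_map(s0, full_roi(s0))
  expect_equal(max(nm0), 0)
  # pure complex Gaussian noise, channel SD 5, > 1e4 pixels: mean within 3%
  set.seed(2)
  n <- 12
  cplx <- array(complex(real = rnorm(110 * 110 * n, 40, 5),
                        imaginary = rnorm(110 * 110 * n, 0, 5)),
                c(110, 110, n))
  s <- make_series(Mod(cplx), Arg(cplx))
  nm <- estimate_noise_map(s, full_roi(s))
  expect_equal(mean(nm), 5, tolerance = 0.03)
  # SD is invariant to a constant complex offset
  cplx2 <- cplx + (17 + 9i)
  s2 <- make_series(Mod(cplx2), Arg(cplx2))
  nm2 <- estimate_noise_map(s2, full_roi(s2))
  expect_equal(nm2, nm, tolerance = 1e-8)
})

test_that("SNR mask keeps strictly above the cutoff, inside the ROI only", {
  # hand-made noise map of ones so the SNR values are exact by construction
  mag <- array(0, c(1, 4, 6))
  mag[1, 1, ] <- 2                        # SNR exactly 2 -> removed
  mag[1, 2, ] <- 10                       # SNR 10 -> kept
  mag[1, 3, ] <- 2 + 1e-9                 # strictly above -> kept
  mag[1, 4, ] <- 50                       # high SNR but outside ROI
  s <- make_series(mag, array(0, dim(mag)))
  nm <- matrix(1, 1, 4)
  roi <- roi_mask(matrix(c(TRUE, TRUE, TRUE, FALSE), 1, 4))
  msk <- magnitude_snr_mask(s, roi, nm)
  expect_equal(as.vector(msk), c(FALSE, TRUE, TRUE, FALSE))
  # zero estimated noise counts as infinite SNR and is kept
  nm0 <- matrix(c(0, 1, 1, 1), 1, 4)
  expect_true(magnitude_snr_mask(s, roi, nm0)[1, 1])
})

test_that("SEM z-test keeps its nominal level under the null", {
  s <- noise_only_series(nr = 128, nc = 128, n_phases = 12, tissue = 60,
                         sigma = 2, seed = 4)
  roi <- full_roi(s)
  nm <- estimate_noise_map(s, roi)
  snr <- magnitude_snr_mask(s, roi, nm)
  expect_gt(mean(snr), 0.999)                       # tissue well above cutoff
  cfg_none <- detection_config(velocity_test = "sem_z",
                               multiple_testing = "none")
  sig <- significant_velocity_mask(s, roi, nm, snr, cfg_none)
  # with the noise SD estimated from 12 phases the z statistic is Student-t
  # with 2*(n-1) df, so the exact level is P(|t_22| > z_{0.975}) = 0.063
  level <- 2 * stats::pt(-stats::qnorm(0.975), df = 22)
  expect_equal(mean(sig), level, tolerance = 0.012)
  expect_lt(abs(mean(sig) - 0.05), 0.02)            # ~alpha, small-sample slack
  cfg_fdr <- detection_config(velocity_test = "sem_z",
                              multiple_testing = "fdr")
  sig_fdr <- significant_velocity_mask(s, roi, nm, snr, cfg_fdr)
  expect_lte(sum(sig_fdr), 10)                      # ~0 of 16k under BH null
  # noise-level criterion: no chance detections at all
  sig_lvl <- significant_velocity_mask(s, roi, nm, snr, detection_config())
  expect_equal(sum(sig_lvl), 0)
})

test_that("a strong planted velocity is significant under either criterion", {
  s <- noise_only_series(nr = 32, nc = 32, n_phases = 12, tissue = 60,
                         sigma = 2, seed = 6)
  sigma_v <- (20 / pi) * 2 / 60
  s$phase[16, 16, ] <- pi * (10 * sigma_v) / 20     # velocity = 10 sigma_v
  roi <- full_roi(s)
  nm <- estimate_noise_map(s, roi)
  snr <- magnitude_snr_mask(s, roi, nm)
  for (cfg in list(detection_config(),
                   detection_config(velocity_test = "sem_z"))) {
    sig <- significant_velocity_mask(s, roi, nm, snr, cfg)
    expect_true(sig[16, 16])
  }
})

test_that("clustering respects connectivity and picks the fastest voxel", {
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE                  # diagonal touch
  vmap <- matrix(0, 5, 5); vmap[2, 2] <- 4; vmap[3, 3] <- 9
  cl8 <- cluster_and_select(m, vmap, c(0.2, 0.2),
                            detection_config(connectivity = 8))
  expect_equal(nrow(cl8), 1)
  expect_equal(cl8$mean_velocity_cm_s, 9)
  cl4 <- cluster_and_select(m, vmap, c(0.2, 0.2),
                            detection_config(connectivity = 4))
  expect_equal(nrow(cl4), 2)
  # representative = max |mean velocity| (here {4, 9, 7} -> 9)
  m2 <- matrix(FALSE, 3, 5); m2[2, 2:4] <- TRUE
  v2 <- matrix(0, 3, 5); v2[2, 2:4] <- c(4, 9, 7)
  cl <- cluster_and_select(m2, v2, c(0.2, 0.2))
  expect_equal(cl$row, 2); expect_equal(cl$col, 3)
  # equal-velocity tie -> raster-order winner (smallest row, then col)
  v3 <- matrix(0, 3, 5); v3[2, 2:4] <- c(9, 9, 9)
  cl3 <- cluster_and_select(m2, v3, c(0.2, 0.2))
  expect_equal(unname(c(cl3$row, cl3$col)), c(2, 2))
  # empty mask -> empty result, not an error
  expect_equal(nrow(cluster_and_select(matrix(FALSE, 3, 3),
                                       matrix(0, 3, 3), c(0.2, 0.2))), 0)
})

test_that("circularity filter uses principal-axis lengths with a floor", {
  cfg <- detection_config()
  mk <- function(rows, cols) {
    m <- matrix(FALSE, 9, 9); m[cbind(rows, cols)] <- TRUE
    v <- matrix(1, 9, 9)
    circularity_filter(cluster_and_select(m, v, c(0.2, 0.2), cfg), cfg)
  }
  single <- mk(5, 5)                       # isotropy floor
  expect_equal(single$axis_ratio, 1)
  expect_true(single$circular)
  line <- mk(rep(5, 5), 2:6)               # 1x5 straight line
  # population covariance of 0..4 is 2 -> major 2*sqrt(2), minor floored 0.5
  expect_equal(line$major_axis, 2 * sqrt(2))
  expect_equal(line$minor_axis, 0.5)
  expect_false(line$circular)
  square <- mk(rep(4:6, each = 3), rep(4:6, 3))   # 3x3 square
  expect_equal(square$axis_ratio, 1)
  expect_true(square$circular)
})

test_that("proximity rule keeps the fastest vessel within 1.2 mm", {
  cand <- function(x, v) tibble::tibble(
    cluster_id = seq_along(x), row = 1L, col = seq_along(x),
    y_mm = 0, x_mm = x, mean_velocity_cm_s = v, n_pixels = 1L,
    major_axis = 0.5, minor_axis = 0.5, axis_ratio = 1
  )
  d1 <- proximity_dedup(cand(c(0, 1.0), c(8, 6)))
  expect_equal(d1$accepted, c(TRUE, FALSE))        # 1.0 mm apart: keep faster
  d2 <- proximity_dedup(cand(c(0, 1.3), c(8, 6)))
  expect_equal(d2$accepted, c(TRUE, TRUE))         # above threshold: keep both
  # chain A-B-C at 1.0 mm steps, velocities 9, 8, 7 -> greedy keeps A and C
  d3 <- proximity_dedup(cand(c(0, 1.0, 2.0), c(9, 8, 7)))
  expect_equal(d3$accepted, c(TRUE, FALSE, TRUE))
})

test_that("full pipeline rejects oblique and ghost decoys", {
  sc <- standard_scene(n_vessels = 10, n_oblique = 3, n_ghost = 0,
                       fov_mm = 25, seed = 8)
  r <- render_cine(sc$perforators, sc$acq, sc$roi_spec)
  v <- detect_perforators(r$series, r$roi)
  obl <- r$truth[r$truth$role == "oblique", ]
  for (i in seq_len(nrow(obl))) {                 # no detection near an oblique
    d <- sqrt((v$x_mm - obl$x_mm[i])^2 + (v$y_mm - obl$y_mm[i])^2)
    expect_gt(min(d), 0.7)
  }
  prov <- detection_provenance(v)
  expect_gte(sum(prov$removed_by == "circularity"), 3)
  s <- score_detection(v, r$truth)
  expect_gte(s$sensitivity, 0.9)
  expect_gte(s$precision, 0.9)
})

test_that("a ghost replica 0.8 mm from a vessel is removed, the vessel kept", {
  host <- perforator_table(10.0, 10.0, 6.5, 0.45, diameter_mm = 0.3)
  decoy <- perforator_table(10.8, 10.0, 6.5, 0.45, diameter_mm = 0.3,
                            signal_gain = 0.7 * 25, role = "ghost")
  perf <- dplyr::bind_rows(host, decoy)
  acq <- acquisition_spec(fov_mm = 20, noise_sigma = 1, tissue_magnitude = 5,
                          n_cardiac_phases = 12, seed = 3)
  r <- render_cine(perf, acq)
  v <- detect_perforators(r$series, r$roi)
  expect_equal(n_detected(v), 1)
  expect_lt(sqrt((v$x_mm - 10)^2 + (v$y_mm - 10)^2), 0.5)   # the host
  expect_true("proximity" %in% detection_provenance(v)$removed_by)
})

test_that("empty noise scene detects nothing and pipeline is deterministic", {
  perf <- perforator_table(numeric(0), numeric(0), numeric(0), numeric(0))
  acq <- acquisition_spec(fov_mm = 15, noise_sigma = 2.5, tissue_magnitude = 15,
                          n_cardiac_phases = 12, seed = 21)
  r <- render_cine(perf, acq)
  v <- detect_perforators(r$series, r$roi)
  expect_equal(n_detected(v), 0)
  # under the SEM z-test the 12-phase noise estimate gives the statistic
  # Student-t tails, so BH leaves a vanishing (not exactly zero) rate:
  # a few detections per ~1e4 ROI pixels at most
  vfdr <- detect_perforators(r$series, r$roi,
                             detection_config(velocity_test = "sem_z"))
  expect_lte(n_detected(vfdr), 5)
  # determinism: same input, same output
  sc <- small_scene(seed = 13)
  rr <- render_cine(sc$perforators, sc$acq, sc$roi_spec)
  v1 <- detect_perforators(rr$series, rr$roi)
  v2 <- detect_perforators(rr$series, rr$roi)
  expect_identical(as.data.frame(v1), as.data.frame(v2))
})

test_that("every stage is monotone in its own threshold", {
  sc <- standard_scene(n_vessels = 8, n_oblique = 2, n_ghost = 2,
                       fov_mm = 25, seed = 17)
  r <- render_cine(sc$perforators, sc$acq, sc$roi_spec)
  base <- detection_config()
  n0 <- n_detected(detect_perforators(r$series, r$roi, base))
  stricter <- list(
    detection_config(magnitude_snr_min = 4),
    detection_config(alpha = 0.001),
    detection_config(axis_ratio_max = 1.3),
    detection_config(min_separation_mm = 3)
  )
  for (cfg in stricter) {
    expect_lte(n_detected(detect_perforators(r$series, r$roi, cfg)), n0)
  }
})
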