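test_that("phase maps to velocity by v = venc * phi / pi", {
  phi <- array(c(0, pi / 2, -pi, 0.3, -0.3, 1), c(1, 2, 3))
  s <- make_series(array(1, dim(phi)), phi, venc = 20)
  v <- phase_to_velocity(s)
  expect_equal(v[1, 1, 1], 0)
  expect_equal(v[1, 2, 1], 10)       # pi/2 at venc 20
  expect_equal(v[1, 1, 2], -20)      # encoding-range boundary
  expect_equal(dim(v), dim(phi))
  expect_true(all(abs(v) <= 20))
  # linear and odd-symmetric in phase (away from the -pi boundary, whose
  # negation is not representable in [-pi, pi))
  phi2 <- array(c(0.3, -0.3, 1, -1, 2.5, 0), c(1, 2, 3))
  v2 <- phase_to_velocity(make_series(array(1, dim(phi2)), phi2, venc = 20))
  s_neg <- make_series(array(1, dim(phi2)), -phi2, venc = 20)
  expect_equal(phase_to_velocity(s_neg), -v2)
  s_half <- make_series(array(1, dim(phi2)), phi2 / 2, venc = 20)
  expect_equal(phase_to_velocity(s_half), v2 / 2)
})

test_that("series constructor enforces its invariants", {
  mag <- array(1, c(4, 4, 3))
  expect_error(cine_pc_series(mag, array(0, c(4, 4, 2)), 0.3, 20),
               "identical shapes")
  expect_error(cine_pc_series(mag - 2, array(0, dim(mag)), 0.3, 20),
               "non-negative")
  expect_error(cine_pc_series(mag, array(0, dim(mag)), -0.3, 20), "positive")
  expect_error(cine_pc_series(mag, array(0, dim(mag)), 0.3, NA),
               "configuration error")
  expect_error(cine_pc_series(array(1, c(4, 4, 65)), array(0, c(4, 4, 65)),
                              0.3, 20), "\\[2, 64\\]")
  expect_warning(s <- cine_pc_series(mag, array(3 * pi / 2, dim(mag)), 0.3, 20),
                 "wrapped")
  expect_equal(s$phase[1, 1, 1], -pi / 2)
})

test_that("zero-filling preserves constants and the frame mean", {
  mag <- array(3.7, c(10, 10, 2))
  s <- make_series(mag, array(0.4, dim(mag)), spacing = 0.4,
                   grid_kind = "acquired")
  z <- zero_fill_reconstruct(s, 0.2)
  expect_equal(dim(z$magnitude), c(20, 20, 2))
  expect_equal(z$grid_kind, "reconstructed")
  # spatially constant frame stays constant at the same value
  expect_equal(max(abs(z$magnitude - 3.7)), 0, tolerance = 1e-9)
  expect_equal(max(abs(z$phase - 0.4)), 0, tolerance = 1e-9)
  # frame means preserved for a random frame too
  set.seed(1)
  mag2 <- array(runif(10 * 10 * 2, 1, 2), c(10, 10, 2))
  phi2 <- array(runif(10 * 10 * 2, -1, 1), c(10, 10, 2))
  s2 <- make_series(mag2, phi2, spacing = 0.4, grid_kind = "acquired")
  z2 <- zero_fill_reconstruct(s2, 0.2)
  for (k in 1:2) {
    c1 <- mean(mag2[, , k] * exp(1i * phi2[, , k]))
    c2 <- mean(z2$magnitude[, , k] * exp(1i * z2$phase[, , k]))
    expect_equal(c2, c1, tolerance = 1e-9)
  }
})

test_that("zero-filling agrees with a brute-force DFT oracle on a point source", {
  n1 <- 16; n2 <- 32
  fr <- matrix(0 + 0i, n1, n1)
  fr[6, 11] <- 1 + 0.5i                       # off-center point source
  # oracle: explicit DFT -> symmetric pad -> explicit inverse DFT
  kf <- dft_matrix(n1) %*% fr %*% t(dft_matrix(n1))
  pad <- matrix(0 + 0i, n2, n2)
  id <- c(1:8, n2 - 8 + 1:8)                  # first 8 bins front, last 8 back
  pad[id, id] <- kf
  oracle <- (dft_matrix(n2, inverse = TRUE) %*% pad %*%
               t(dft_matrix(n2, inverse = TRUE))) / (n1 * n1)
  got <- perfopulse:::zero_fill_frame(fr, n2, n2)
  expect_equal(got, oracle, tolerance = 1e-9)
  # peak lands within one fine pixel of the coarse location
  peak <- which(Mod(got) == max(Mod(got)), arr.ind = TRUE)[1, ]
  expect_lte(abs(peak[1] - (2 * 6 - 1)), 1)
  expect_lte(abs(peak[2] - (2 * 11 - 1)), 1)
})

test_that("Fourier interpolation is exact at original sample points", {
  set.seed(7)
  mag <- array(runif(12 * 12 * 2, 1, 3), c(12, 12, 2))
  phi <- array(runif(12 * 12 * 2, -0.5, 0.5), c(12, 12, 2))
  s <- make_series(mag, phi, spacing = 0.4, grid_kind = "acquired")
  z <- zero_fill_reconstruct(s, 0.2)          # exact factor 2
  orig <- mag * exp(1i * phi)
  fine <- z$magnitude * exp(1i * z$phase)
  sub <- fine[seq(1, 23, by = 2), seq(1, 23, by = 2), ]
  expect_equal(sub, orig, tolerance = 1e-6)
})

test_that("non-integer padding rounds the matrix up and records the spacing", {
  mag <- array(1, c(10, 10, 2))
  s <- make_series(mag, array(0, dim(mag)), spacing = 0.3,
                   grid_kind = "acquired")
  z <- zero_fill_reconstruct(s, 0.2)          # 3 mm / 0.2 = 15 exactly
  expect_equal(dim(z$magnitude)[1:2], c(15L, 15L))
  z2 <- zero_fill_reconstruct(s, 0.22)        # 3 / 0.22 = 13.6 -> 14
  expect_equal(dim(z2$magnitude)[1:2], c(14L, 14L))
  expect_equal(z2$pixel_spacing_mm, rep(3 / 14, 2))
  expect_equal(attr(z2, "requested_spacing_mm"), c(0.22, 0.22))
  expect_error(zero_fill_reconstruct(s, 0.4), "<= the acquired")
  expect_error(zero_fill_reconstruct(z, 0.1), "acquired grid")
})

test_that("series round-trips through NIfTI + YAML bit-exactly", {
  set.seed(42)
  mag <- array(runif(8 * 8 * 4, 0, 100), c(8, 8, 4))
  phi <- array(runif(8 * 8 * 4, -pi, pi * 0.999), c(8, 8, 4))
  s <- cine_pc_series(mag, phi, c(0.2, 0.2), 20, heart_rate_bpm = 66,
                      grid_kind = "reconstructed")
  prefix <- file.path(withr::local_tempdir(), "scan")
  write_cine_series(s, prefix)
  s2 <- read_cine_series(prefix)
  expect_identical(s2$magnitude, s$magnitude)
  expect_identical(s2$phase, s$phase)
  expect_equal(s2$pixel_spacing_mm, s$pixel_spacing_mm)
  expect_equal(s2$venc_cm_s, 20)
  expect_equal(s2$heart_rate_bpm, 66)
  expect_equal(s2$grid_kind, "reconstructed")
})

test_that("reader flags missing metadata and wraps out-of-range phase", {
  dir <- withr::local_tempdir()
  expect_error(read_cine_series(file.path(dir, "nope")), "missing sidecar")
  # sidecar with a missing required field
  mag <- array(1, c(4, 4, 3))
  s <- make_series(mag, array(0, dim(mag)))
  prefix <- file.path(dir, "scan")
  write_cine_series(s, prefix)
  meta <- yaml::read_yaml(paste0(prefix, ".yaml"))
  meta$venc_cm_s <- NULL
  yaml::write_yaml(meta, paste0(prefix, ".yaml"))
  expect_error(read_cine_series(prefix), "venc_cm_s")
  # phase stored outside [-pi, pi) wraps with a warning
  s3 <- make_series(mag, array(0, dim(mag)))
  write_cine_series(s3, prefix)
  RNifti::writeNifti(RNifti::asNifti(array(3 * pi / 2, dim(mag)),
                                     datatype = "double"),
                     paste0(prefix, "_phase.nii.gz"))
  expect_warning(s4 <- read_cine_series(prefix), "wrapped")
  expect_equal(s4$phase[1, 1, 1], -pi / 2)
})

test_that("ROI masks round-trip and are validated against the series", {
  m <- matrix(FALSE, 6, 6); m[2:4, 3:5] <- TRUE
  roi <- roi_mask(m, label = "bg")
  path <- file.path(withr::local_tempdir(), "roi.nii.gz")
  write_roi_mask(roi, path)
  roi2 <- read_roi_mask(path)
  expect_equal(unclass(roi2)[, ], unclass(roi)[, ], ignore_attr = TRUE)
  s <- make_series(array(1, c(6, 6, 3)), array(0, c(6, 6, 3)))
  expect_error(estimate_noise_map(s, roi_mask(matrix(TRUE, 3, 3))),
               "does not match")
  expect_error(estimate_noise_map(s, roi_mask(matrix(FALSE, 6, 6))), "empty")
})
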