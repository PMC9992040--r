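#' Synthetic cardiac velocity waveform with exact mean and pulsatility
#'
#' Builds a raised-cosine velocity pulse sampled at uniform fractions of the
#' cardiac cycle, rescaled so that its temporal mean is exactly `v_mean` and
#' its velocity pulsatility index `(max - min) / mean` is exactly `vpi_true`.
#' The waveform family is a modelling choice: smooth, unimodal, periodic and
#' exactly parameterizable by the two quantities the analysis measures.
#'
#' @param n_phases Number of cardiac phases (>= 2).
#' @param v_mean Temporal mean velocity, cm/s (> 0).
#' @param vpi_true Target pulsatility index (>= 0).
#' @param peak_time_frac Cycle fraction in `[0, 1)` at which the pulse peaks.
#' @param allow_reversal If `FALSE` (default) a waveform that would dip below
#'   zero is a parameter error.
#' @return Numeric vector of length `n_phases`, cm/s.
#' @export
cardiac_waveform <- function(n_phases, v_mean, vpi_true, peak_time_frac = 0.25,
                             allow_reversal = FALSE) {
  stopifnot(n_phases >= 2, v_mean > 0, vpi_true >= 0,
            peak_time_frac >= 0, peak_time_frac < 1)
  if (vpi_true == 0) return(rep(v_mean, n_phases))
  t <- (seq_len(n_phases) - 1) / n_phases
  p <- 0.5 * (1 + cos(2 * pi * (t - peak_time_frac)))
  rng <- max(p) - min(p)
  if (rng < .Machine$double.eps^0.5) {
    stop("parameter error: pulse is not resolved at this phase sampling; ",
         "cannot impose vpi_true > 0", call. = FALSE)
  }
  curve <- v_mean * (1 + vpi_true * (p - mean(p)) / rng)
  if (!allow_reversal && min(curve) < 0) {
    stop("parameter error: vpi_true = ", vpi_true,
         " drives the waveform below zero (min = ", signif(min(curve), 4),
         " cm/s); set allow_reversal = TRUE to permit flow reversal",
         call. = FALSE)
  }
  curve
}

#' Velocity pulsatility index of a velocity curve
#'
#' `vPI = (V_max - V_min) / V_mean` evaluated on the curve as given.
#'
#' @param curve Numeric velocity curve (one value per cardiac phase).
#' @return The pulsatility index (scalar).
#' @export
vpi_index <- function(curve) {
  stopifnot(length(curve) >= 2, all(is.finite(curve)))
  m <- mean(curve)
  if (m == 0) stop("vPI undefined: curve has zero mean", call. = FALSE)
  (max(curve) - min(curve)) / m
}

#' Acquisition parameters for the synthetic generator
#'
#' Defaults mirror the basal-ganglia 2D-PC protocol the package targets:
#' 250 mm field of view, 0.3 mm acquired in-plane resolution zero-filled to
#' 0.2 mm, venc 20 cm/s, and a cardiac cycle reconstructed into 8-15 phases
#' (12 by default).
#'
#' @param fov_mm Field of view (square), mm.
#' @param acquired_spacing_mm Acquired in-plane pixel spacing, mm.
#' @param recon_spacing_mm Reconstructed spacing after k-space zero-filling.
#' @param venc_cm_s Velocity-encoding limit, cm/s.
#' @param n_cardiac_phases Number of reconstructed cardiac phases.
#' @param tissue_magnitude Magnitude of the static-tissue background
#'   (arbitrary signal units; tissue phase is zero).
#' @param noise_sigma Per-channel (real/imaginary) SD of the additive complex
#'   Gaussian noise, same units as `tissue_magnitude`.
#' @param ghost_fraction Amplitude fraction of half-FOV ghost copies of each
#'   vessel; 0 disables ghosting.
#' @param heart_rate_bpm Simulated heart rate recorded in the series metadata.
#' @param seed Integer seed controlling all randomness of a render.
#' @return A list of class `acquisition_spec`.
#' @export
acquisition_spec <- function(fov_mm = 250, acquired_spacing_mm = 0.3,
                             recon_spacing_mm = 0.2, venc_cm_s = 20,
                             n_cardiac_phases = 12, tissue_magnitude = 1,
                             noise_sigma = 0, ghost_fraction = 0,
                             heart_rate_bpm = 68, seed = 1L) {
  spec <- list(fov_mm = fov_mm, acquired_spacing_mm = acquired_spacing_mm,
               recon_spacing_mm = recon_spacing_mm, venc_cm_s = venc_cm_s,
               n_cardiac_phases = as.integer(n_cardiac_phases),
               tissue_magnitude = tissue_magnitude, noise_sigma = noise_sigma,
               ghost_fraction = ghost_fraction, heart_rate_bpm = heart_rate_bpm,
               seed = as.integer(seed))
  with(spec, stopifnot(
    fov_mm > 0, acquired_spacing_mm > 0, recon_spacing_mm > 0,
    recon_spacing_mm <= acquired_spacing_mm, venc_cm_s > 0,
    n_cardiac_phases >= 2, tissue_magnitude >= 0, noise_sigma >= 0,
    ghost_fraction >= 0, ghost_fraction < 1
  ))
  structure(spec, class = "acquisition_spec")
}

#' Build a table of planted perforators
#'
#' One row per simulated vessel (or decoy). Positions are physical mm in the
#' field of view; `axis_ratio` > 1 elongates the blob footprint (emulating a
#' vessel crossing the slice obliquely), `role` records what the object is
#' meant to exercise.
#'
#' @param x_mm,y_mm Blob center coordinates, mm.
#' @param v_mean_cm_s Temporal-mean velocity of the planted waveform.
#' @param vpi_true Planted pulsatility index.
#' @param peak_time_frac Cycle fraction of the systolic peak.
#' @param diameter_mm Blob diameter (Gaussian footprint radius is half this).
#' @param axis_ratio Major/minor footprint ratio; 1 = perpendicular vessel.
#' @param orientation_deg In-plane orientation of the major axis.
#' @param signal_gain Peak complex-signal magnitude of the blob.
#' @param role One of `"vessel"`, `"oblique"`, `"ghost"` (free text allowed).
#' @return A tibble with one row per perforator and an `id` column.
#' @export
perforator_table <- function(x_mm, y_mm, v_mean_cm_s, vpi_true,
                             peak_time_frac = 0.25, diameter_mm = 0.45,
                             axis_ratio = 1, orientation_deg = 0,
                             signal_gain = 25, role = "vessel") {
  tb <- tibble::tibble(
    x_mm = x_mm, y_mm = y_mm, v_mean_cm_s = v_mean_cm_s, vpi_true = vpi_true,
    peak_time_frac = peak_time_frac, diameter_mm = diameter_mm,
    axis_ratio = axis_ratio, orientation_deg = orientation_deg,
    signal_gain = signal_gain, role = role
  )
  stopifnot(all(tb$v_mean_cm_s > 0), all(tb$vpi_true >= 0),
            all(tb$diameter_mm > 0), all(tb$axis_ratio >= 1),
            all(tb$signal_gain > 0))
  dplyr::mutate(tb, id = dplyr::row_number(), .before = 1)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Rigid in-plane transform of perforator centers about the FOV center.
apply_rigid <- function(perforators, transform, fov_mm) {
  if (is.null(transform)) return(perforators)
  th <- transform$rot_deg * pi / 180
  cx <- fov_mm / 2
  x0 <- perforators$x_mm - cx; y0 <- perforators$y_mm - cx
  dplyr::mutate(perforators,
    x_mm = cx + cos(th) * x0 - sin(th) * y0 + transform$dx_mm,
    y_mm = cx + sin(th) * x0 + cos(th) * y0 + transform$dy_mm
  )
}

#' Render a synthetic cine phase-contrast series
#'
#' Simulates the complex image at the acquired resolution and passes it
#' through [zero_fill_reconstruct()], mirroring how the scanner reconstructs
#' a finer grid by k-space zero-filling. Per cardiac phase the complex image
#' is a flat static-tissue background (phase 0) plus one anisotropic Gaussian
#' blob per perforator whose phase encodes its waveform velocity
#' (`phi = pi * v / venc`), optional half-FOV ghost copies, and i.i.d.
#' complex Gaussian noise. Partial-volume attenuation arises naturally from
#' the complex sum of tissue and blood signal.
#'
#' @param perforators A [perforator_table()].
#' @param acq An [acquisition_spec()].
#' @param roi_spec `NULL` for a default rectangular ROI inset by
#'   `margin_mm = 2.5` from the FOV edge, a list with `margin_mm` (optionally
#'   `jitter_mm` and `jitter_seed` to perturb the rectangle edges, emulating
#'   independent manual redrawing), or an explicit [roi_mask()] on the
#'   reconstructed grid.
#' @param transform Optional rigid repositioning applied to the object before
#'   rendering: list with `dx_mm`, `dy_mm`, `rot_deg` (about the FOV center).
#' @param seed Overrides `acq$seed` for the noise realization.
#' @return List with elements `series` (reconstructed [cine_pc_series()]),
#'   `roi` ([roi_mask()]), and `truth` (tibble: planted perforators with their
#'   per-phase waveform in list-column `waveform`, plus `detectable` — circular,
#'   inside the ROI, above the noise floor, and not shadowed by a stronger
#'   vessel within the proximity-rule distance).
#' @export
render_cine <- function(perforators, acq, roi_spec = NULL, transform = NULL,
                        seed = NULL) {
  stopifnot(inherits(acq, "acquisition_spec"))
  perf <- apply_rigid(perforators, transform, acq$fov_mm)
  if (any(perf$x_mm < 0 | perf$x_mm > acq$fov_mm |
          perf$y_mm < 0 | perf$y_mm > acq$fov_mm)) {
    stop("parameter error: perforator center outside the field of view",
         call. = FALSE)
  }
  n1 <- as.integer(round(acq$fov_mm / acq$acquired_spacing_mm))
  dx <- acq$fov_mm / n1                       # achieved acquired spacing
  waveforms <- purrr::pmap(
    list(perf$v_mean_cm_s, perf$vpi_true, perf$peak_time_frac),
    function(v, p, pk) cardiac_waveform(acq$n_cardiac_phases, v, p, pk)
  )

  # static blob footprints (amplitude maps), computed once per perforator
  xc <- (seq_len(n1) - 0.5) * dx
  footprints <- purrr::pmap(
    list(perf$x_mm, perf$y_mm, perf$diameter_mm, perf$axis_ratio,
         perf$orientation_deg, perf$signal_gain),
    function(x0, y0, d, ar, th_deg, gain) {
      s_min <- d / 2; s_maj <- s_min * ar
      half <- 4 * s_maj
      rows <- which(abs(xc - y0) <= half)
      cols <- which(abs(xc - x0) <= half)
      if (!length(rows) || !length(cols)) return(NULL)
      th <- th_deg * pi / 180
      dyv <- xc[rows] - y0; dxv <- xc[cols] - x0
      # rotate into the blob frame: u along major axis, w along minor
      u <- outer(dyv, dxv, function(a, b) sin(th) * a + cos(th) * b)
      w <- outer(dyv, dxv, function(a, b) cos(th) * a - sin(th) * b)
      list(rows = rows, cols = cols,
           amp = gain * exp(-0.5 * ((u / s_maj)^2 + (w / s_min)^2)))
    }
  )

  seed <- seed %||% acq$seed
  ghost_shift <- as.integer(round(n1 / 2))
  stacks <- with_seed(seed, {
    mag <- array(0, c(n1, n1, acq$n_cardiac_phases))
    phi <- array(0, c(n1, n1, acq$n_cardiac_phases))
    for (k in seq_len(acq$n_cardiac_phases)) {
      fr <- matrix(acq$tissue_magnitude + 0i, n1, n1)
      for (j in seq_len(nrow(perf))) {
        fp <- footprints[[j]]
        if (is.null(fp)) next
        contrib <- fp$amp * exp(1i * pi * waveforms[[j]][k] / acq$venc_cm_s)
        fr[fp$rows, fp$cols] <- fr[fp$rows, fp$cols] + contrib
        if (acq$ghost_fraction > 0) {
          grows <- ((fp$rows - 1 + ghost_shift) %% n1) + 1
          fr[grows, fp$cols] <- fr[grows, fp$cols] + acq$ghost_fraction * contrib
        }
      }
      if (acq$noise_sigma > 0) {
        fr <- fr + complex(real = stats::rnorm(n1 * n1, 0, acq$noise_sigma),
                           imaginary = stats::rnorm(n1 * n1, 0, acq$noise_sigma))
      }
      mag[, , k] <- Mod(fr)
      phi[, , k] <- Arg(fr)
    }
    list(mag = mag, phi = phi)
  })

  acq_series <- cine_pc_series(stacks$mag, stacks$phi, dx, acq$venc_cm_s,
                               acq$heart_rate_bpm, grid_kind = "acquired")
  series <- zero_fill_reconstruct(acq_series, acq$recon_spacing_mm)

  roi <- build_roi(roi_spec, series, acq)
  truth <- annotate_truth(perf, waveforms, roi, series, acq)
  list(series = series, roi = roi, truth = truth)
}

build_roi <- function(roi_spec, series, acq) {
  if (inherits(roi_spec, "roi_mask")) return(check_roi(series, roi_spec))
  margin <- (roi_spec$margin_mm %||% 2.5)
  d <- dim(series$magnitude)
  lo <- rep(margin, 4)  # top, bottom, left, right insets (mm)
  if (!is.null(roi_spec$jitter_mm) && roi_spec$jitter_mm > 0) {
    # symmetric edge jitter: a redrawn ROI is as likely larger as smaller
    j <- roi_spec$jitter_mm / 2
    lo <- lo + with_seed(roi_spec$jitter_seed %||% 1L, stats::runif(4, -j, j))
  }
  yc <- (seq_len(d[1]) - 0.5) * series$pixel_spacing_mm[1]
  xc <- (seq_len(d[2]) - 0.5) * series$pixel_spacing_mm[2]
  fov <- d[1:2] * series$pixel_spacing_mm
  m <- outer(yc >= lo[1] & yc <= fov[1] - lo[2],
             xc >= lo[3] & xc <= fov[2] - lo[4], `&`)
  roi_mask(m, label = "synthetic basal-ganglia ROI")
}

annotate_truth <- function(perf, waveforms, roi, series, acq) {
  d <- dim(roi)
  r_idx <- pmin(pmax(ceiling(perf$y_mm / series$pixel_spacing_mm[1]), 1), d[1])
  c_idx <- pmin(pmax(ceiling(perf$x_mm / series$pixel_spacing_mm[2]), 1), d[2])
  inside <- roi[cbind(r_idx, c_idx)]
  circular <- perf$axis_ratio <= 2
  above_noise <- acq$noise_sigma == 0 | perf$signal_gain / max(acq$noise_sigma, 1e-12) >= 5
  # shadowed: a stronger (higher mean-velocity) perforator within 1.2 mm
  shadowed <- vapply(seq_len(nrow(perf)), function(i) {
    dist <- sqrt((perf$x_mm - perf$x_mm[i])^2 + (perf$y_mm - perf$y_mm[i])^2)
    near <- dist < 1.2 & seq_len(nrow(perf)) != i
    any(near & (perf$v_mean_cm_s > perf$v_mean_cm_s[i] |
                  (perf$v_mean_cm_s == perf$v_mean_cm_s[i] &
                     seq_len(nrow(perf)) < i)))
  }, logical(1))
  dplyr::mutate(perf,
    waveform = waveforms,
    in_roi = inside, circular = circular, above_noise = above_noise,
    shadowed = shadowed,
    detectable = inside & circular & above_noise & !shadowed
  )
}

#' Simulate a test-retest scan pair over one ground truth
#'
#' Renders the same planted perforators twice with independent noise
#' realizations. With `repositioning = TRUE` the object is rigidly moved
#' before the second render — a sub-voxel translation (uniform within one
#' acquired pixel) and a small rotation (uniform within 2 degrees) — and the
#' second ROI rectangle is independently jittered, emulating taking the
#' subject out of the scanner and replanning the slice.
#'
#' @inheritParams render_cine
#' @param repositioning Apply a random rigid repositioning before scan 2?
#' @param seed_pair Two distinct integer seeds, one per scan.
#' @return List with `scan1`, `scan2` (each as returned by [render_cine()])
#'   and `transform` (the applied repositioning, or `NULL`).
#' @export
simulate_retest <- function(perforators, acq, repositioning = FALSE,
                            seed_pair, roi_spec = NULL) {
  stopifnot(length(seed_pair) == 2, seed_pair[1] != seed_pair[2])
  scan1 <- render_cine(perforators, acq, roi_spec, seed = seed_pair[1])
  transform <- NULL
  roi2 <- roi_spec
  if (repositioning) {
    s <- acq$acquired_spacing_mm
    transform <- with_seed(seed_pair[2] + 1L, list(
      dx_mm = stats::runif(1, -s, s),
      dy_mm = stats::runif(1, -s, s),
      rot_deg = stats::runif(1, -2, 2)
    ))
    if (!inherits(roi_spec, "roi_mask")) {
      roi2 <- c(roi_spec %||% list(),
                list(jitter_mm = roi_spec$jitter_mm %||% 1,
                     jitter_seed = seed_pair[2] + 2L))
    }
  }
  scan2 <- render_cine(perforators, acq, roi2, transform = transform,
                       seed = seed_pair[2])
  list(scan1 = scan1, scan2 = scan2, transform = transform)
}

#' Standard synthetic validation scene
#'
#' The package's reference scene for exercising the full detection pipeline:
#' circular perforators (velocities and pulsatilities drawn around the
#' physiologic values of basal-ganglia perforators, mean velocity about
#' 6.5 cm/s and vPI about 0.45), oblique decoys (axis ratio 3, which the
#' circularity filter must reject) and "ghost" decoys planted 0.8 mm from a
#' true vessel at lower amplitude and velocity (which the 1.2 mm proximity
#' rule must remove). Vessel peak-signal-to-noise is `snr`.
#'
#' @param n_vessels,n_oblique,n_ghost Scene composition.
#' @param snr Vessel peak magnitude over per-channel noise SD.
#' @param fov_mm Simulated field of view (the detection physics is local, so
#'   a sub-FOV patch keeps rendering cheap without changing resolution,
#'   venc, or any filter threshold).
#' @param n_cardiac_phases Cardiac phases.
#' @param vpi_true If not `NULL`, all vessels share this planted vPI instead
#'   of drawing from the population.
#' @param seed Scene seed (placement, waveforms, and noise).
#' @return List with `perforators`, `acq`, `roi_spec` ready for
#'   [render_cine()].
#' @export
standard_scene <- function(n_vessels = 50, n_oblique = 10, n_ghost = 10,
                           snr = 10, fov_mm = 50, n_cardiac_phases = 12,
                           vpi_true = NULL, seed = 1L) {
  gain <- 25
  margin <- 2.5
  with_seed(seed, {
    n_place <- n_vessels + n_oblique
    pos <- place_min_separation(n_place, lo = margin + 1.5,
                                hi = fov_mm - margin - 1.5, min_sep = 3)
    v_mean <- pmin(pmax(stats::rnorm(n_place, 6.5, 1.0), 4), 9)
    vpi <- if (is.null(vpi_true)) {
      pmin(pmax(stats::rnorm(n_place, 0.45, 0.14), 0.1), 0.9)
    } else rep(vpi_true, n_place)
    peak <- stats::runif(n_place, 0.2, 0.3)
    role <- rep(c("vessel", "oblique"), c(n_vessels, n_oblique))
    ar <- ifelse(role == "vessel", 1, 3)
    orient <- stats::runif(n_place, 0, 180)
    perf <- perforator_table(pos$x, pos$y, v_mean, vpi, peak,
                             diameter_mm = 0.45, axis_ratio = ar,
                             orientation_deg = ifelse(role == "vessel", 0, orient),
                             signal_gain = gain, role = role)
    if (n_ghost > 0) {
      # ghost replicas: a displaced, attenuated copy of the host vessel's
      # complex signal, i.e. same waveform at lower amplitude
      host <- sample(which(perf$role == "vessel"), n_ghost)
      ang <- stats::runif(n_ghost, 0, 2 * pi)
      ghost <- perforator_table(
        perf$x_mm[host] + 1.0 * cos(ang), perf$y_mm[host] + 1.0 * sin(ang),
        perf$v_mean_cm_s[host], perf$vpi_true[host],
        perf$peak_time_frac[host], diameter_mm = 0.45, axis_ratio = 1,
        signal_gain = 0.5 * gain, role = "ghost"
      )
      perf <- dplyr::mutate(dplyr::bind_rows(perf, ghost),
                            id = dplyr::row_number())
    }
    acq <- acquisition_spec(fov_mm = fov_mm, noise_sigma = gain / snr,
                            tissue_magnitude = 2 * gain / snr,
                            n_cardiac_phases = n_cardiac_phases, seed = seed)
    list(perforators = perf, acq = acq, roi_spec = list(margin_mm = margin))
  })
}

# Sequential rejection sampling of points with a minimum pairwise distance.
place_min_separation <- function(n, lo, hi, min_sep, max_tries = 20000L) {
  x <- numeric(0); y <- numeric(0)
  tries <- 0L
  while (length(x) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not place ", n, " points at min separation ", min_sep,
           " mm in the available area", call. = FALSE)
    }
    xn <- stats::runif(1, lo, hi); yn <- stats::runif(1, lo, hi)
    if (!length(x) || all((x - xn)^2 + (y - yn)^2 >= min_sep^2)) {
      x <- c(x, xn); y <- c(y, yn)
    }
  }
  list(x = x, y = y)
}

#' Score detections against planted ground truth
#'
#' Matches each detected vessel to the nearest planted perforator within
#' `tol_mm`, greedily in descending detected velocity. Sensitivity is the
#' fraction of detectable planted vessels recovered; precision the fraction
#' of detections matching a detectable planted vessel.
#'
#' @param vessels A `vessel_set` from [detect_perforators()].
#' @param truth Ground-truth tibble from [render_cine()].
#' @param tol_mm Matching radius, mm.
#' @return A list: `sensitivity`, `precision`, `n_true`, `n_detected`,
#'   `matches` (tibble of detection id vs truth id).
#' @export
score_detection <- function(vessels, truth, tol_mm = 0.7) {
  det_tb <- truth[truth$detectable, ]
  matches <- tibble::tibble(vessel_id = integer(), truth_id = integer())
  taken <- integer(0)
  if (nrow(vessels) > 0 && nrow(det_tb) > 0) {
    ord <- order(-abs(vessels$mean_velocity_cm_s))
    for (i in ord) {
      d2 <- (det_tb$x_mm - vessels$x_mm[i])^2 + (det_tb$y_mm - vessels$y_mm[i])^2
      d2[det_tb$id %in% taken] <- Inf
      j <- which.min(d2)
      if (length(j) && d2[j] <= tol_mm^2) {
        taken <- c(taken, det_tb$id[j])
        matches <- dplyr::bind_rows(matches,
          tibble::tibble(vessel_id = vessels$vessel_id[i], truth_id = det_tb$id[j]))
      }
    }
  }
  list(
    sensitivity = if (nrow(det_tb)) nrow(matches) / nrow(det_tb) else NA_real_,
    precision = if (nrow(vessels)) nrow(matches) / nrow(vessels) else NA_real_,
    n_true = nrow(det_tb), n_detected = nrow(vessels), matches = matches
  )
}
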