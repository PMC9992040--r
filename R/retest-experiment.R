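#' Configuration of an end-to-end test-retest simulation
#'
#' Defines the simulated study: per-subject population distributions for the
#' hemodynamic ground truth, the acquisition geometry and noise, and the
#' detection thresholds. Defaults mirror the target protocol wherever a
#' published value exists (venc 20 cm/s, SNR cutoff 2, axis-ratio cutoff 2,
#' 1.2 mm proximity rule, 1.96 agreement multiplier); the population moments
#' (mean velocity 6.5 +/- 1.0 cm/s, vPI 0.45 +/- 0.14, about 8 +/- 3 vessels,
#' heart rate 68 +/- 10 bpm) describe healthy-control basal-ganglia
#' perforators.
#'
#' @param n_subjects Number of simulated subjects.
#' @param seed Master seed; all per-subject randomness derives from it.
#' @param fov_mm Simulated (sub-)field of view per subject.
#' @param noise_sigma Per-channel complex-noise SD (signal units; vessel peak
#'   signal is `signal_gain`).
#' @param signal_gain Peak blob magnitude of each vessel.
#' @param tissue_magnitude Static-tissue background magnitude (kept above the
#'   noise floor, as in tissue at 3 T).
#' @param repositioning Apply a rigid repositioning plus ROI replanning
#'   between scan 1 and scan 2 (scan 3 always repeats scan 2's geometry
#'   without repositioning).
#' @param v_mean_pop,v_mean_sd Population mean and SD of per-subject mean
#'   velocity (cm/s).
#' @param vpi_pop,vpi_sd Population mean and SD of per-subject vPI
#'   (truncated to (0.05, 1.5)).
#' @param n_perf_pop,n_perf_sd Population mean and SD of the per-subject
#'   number of perforators (rounded, floored at 1).
#' @param heart_rate_pop,heart_rate_sd Heart-rate population (bpm).
#' @param detection A [detection_config()].
#' @return List of class `retest_config`.
#' @export
retest_config <- function(n_subjects = 35, seed = 1L, fov_mm = 22,
                          noise_sigma = 2.5, signal_gain = 25,
                          tissue_magnitude = 5, repositioning = TRUE,
                          v_mean_pop = 6.5, v_mean_sd = 1.0,
                          vpi_pop = 0.45, vpi_sd = 0.14,
                          n_perf_pop = 8, n_perf_sd = 3,
                          heart_rate_pop = 68, heart_rate_sd = 10,
                          detection = detection_config()) {
  stopifnot(n_subjects >= 2, fov_mm > 0, noise_sigma >= 0, signal_gain > 0)
  structure(as.list(environment()), class = "retest_config")
}

# Reconstructed cardiac phases for a heart rate: the cycle is binned into
# roughly 84 ms phases by retrospective gating, clamped to the protocol's
# 8-15 range.
phases_for_heart_rate <- function(hr_bpm) {
  as.integer(pmin(pmax(round(60000 / hr_bpm / 84), 8), 15))
}

simulate_subject <- function(cfg, subject_seed) {
  with_seed(subject_seed, {
    hr <- pmax(stats::rnorm(1, cfg$heart_rate_pop, cfg$heart_rate_sd), 40)
    # truncated at [1, 12]: the simulated patch cannot pack more vessels at
    # the separation real perforators keep
    n_perf <- min(max(1L, as.integer(round(stats::rnorm(1, cfg$n_perf_pop,
                                                        cfg$n_perf_sd)))), 12L)
    margin <- 2.5
    pos <- place_min_separation(n_perf, lo = margin + 1,
                                hi = cfg$fov_mm - margin - 1, min_sep = 2.8)
    subj_v <- pmin(pmax(stats::rnorm(1, cfg$v_mean_pop, cfg$v_mean_sd), 3), 10)
    subj_vpi <- pmin(pmax(stats::rnorm(1, cfg$vpi_pop, cfg$vpi_sd), 0.05), 1.5)
    perf <- perforator_table(
      pos$x, pos$y,
      v_mean_cm_s = pmin(pmax(stats::rnorm(n_perf, subj_v, 0.8), 2.5), 11),
      vpi_true = pmin(pmax(stats::rnorm(n_perf, subj_vpi, 0.08), 0.05), 1.5),
      peak_time_frac = stats::runif(1, 0.2, 0.3),
      signal_gain = cfg$signal_gain
    )
    scan_seeds <- sample.int(.Machine$integer.max - 10L, 3L)
    list(perforators = perf, heart_rate = hr, scan_seeds = scan_seeds)
  })
}

analyze_scan <- function(scene, cfg) {
  vessels <- detect_perforators(scene$series, scene$roi, cfg$detection)
  glance(waveform_stats(scene$series, vessels))
}

#' Run a simulated three-scan test-retest experiment end to end
#'
#' For each simulated subject, three cine phase-contrast scans are rendered
#' over the same planted perforators and pushed through detection and
#' hemodynamic analysis: scan 1 at the initial position, scan 2 after a
#' random rigid repositioning with an independently re-drawn ROI (when
#' `repositioning` is enabled), and scan 3 immediately repeating scan 2
#' without repositioning (independent noise only). Bland-Altman agreement is
#' then computed per outcome for scan 1 vs 2 (test-retest *with*
#' repositioning) and scan 2 vs 3 (*without*).
#'
#' @param config A [retest_config()].
#' @return Object of class `retest_experiment`: list with `subjects`
#'   (per-subject, per-scan tibble of `n_detected`, `v_mean_cm_s`, `vpi`,
#'   `heart_rate_bpm`), `agreement` (one row per outcome x comparison, the
#'   [glance.agreement_report()] fields), `reports` (the underlying
#'   `agreement_report` objects), `config`, and `seed`.
#' @export
run_retest_experiment <- function(config = retest_config()) {
  stopifnot(inherits(config, "retest_config"))
  subject_seeds <- with_seed(config$seed,
                             sample.int(.Machine$integer.max - 10L,
                                        config$n_subjects))
  margin <- 2.5
  subjects <- purrr::map_dfr(seq_len(config$n_subjects), function(i) {
    subj <- simulate_subject(config, subject_seeds[i])
    acq <- acquisition_spec(
      fov_mm = config$fov_mm, noise_sigma = config$noise_sigma,
      tissue_magnitude = config$tissue_magnitude,
      n_cardiac_phases = phases_for_heart_rate(subj$heart_rate),
      heart_rate_bpm = subj$heart_rate, seed = subj$scan_seeds[1]
    )
    transform <- NULL
    roi2 <- list(margin_mm = margin)
    if (config$repositioning) {
      s <- acq$acquired_spacing_mm
      transform <- with_seed(subject_seeds[i] + 7L, list(
        dx_mm = stats::runif(1, -s, s),
        dy_mm = stats::runif(1, -s, s),
        rot_deg = stats::runif(1, -2, 2)
      ))
      roi2 <- list(margin_mm = margin, jitter_mm = 1,
                   jitter_seed = subject_seeds[i] + 8L)
    }
    scans <- list(
      render_cine(subj$perforators, acq, list(margin_mm = margin),
                  seed = subj$scan_seeds[1]),
      render_cine(subj$perforators, acq, roi2, transform = transform,
                  seed = subj$scan_seeds[2]),
      render_cine(subj$perforators, acq, roi2, transform = transform,
                  seed = subj$scan_seeds[3])
    )
    res <- purrr::map_dfr(scans, analyze_scan, cfg = config)
    dplyr::mutate(res, subject = i, scan = dplyr::row_number(), .before = 1)
  })

  comparisons <- list(
    with_repositioning = c(1L, 2L),
    without_repositioning = c(2L, 3L)
  )
  outcomes <- c(n_detected = "n_detected", v_mean_cm_s = "v_mean_cm_s",
                vpi = "vpi")
  reports <- purrr::imap(comparisons, function(pair, cmp) {
    purrr::imap(outcomes, function(col, nm) {
      a <- subjects[[col]][subjects$scan == pair[1]]
      b <- subjects[[col]][subjects$scan == pair[2]]
      bland_altman(a, b, outcome = nm)
    })
  })
  agreement <- purrr::imap_dfr(reports, function(lst, cmp) {
    dplyr::mutate(purrr::map_dfr(lst, glance), comparison = cmp, .before = 1)
  })
  structure(list(subjects = subjects, agreement = agreement,
                 reports = reports, config = config, seed = config$seed),
            class = "retest_experiment")
}

#' @export
print.retest_experiment <- function(x, ...) {
  cat("<retest_experiment> ", x$config$n_subjects,
      " subjects x 3 scans (seed ", x$seed, ")\n", sep = "")
  print(x$agreement, n = Inf)
  invisible(x)
}

#' Write experiment outputs as CSV
#'
#' Emits `subjects.csv` (per-subject, per-scan outcomes), `agreement.csv`
#' (Bland-Altman summaries), and `run_info.yaml` (seed and configuration) in
#' `dir`. Outputs are deterministic for a fixed configuration seed.
#'
#' @param experiment A `retest_experiment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_retest_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "retest_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(experiment$subjects, file.path(dir, "subjects.csv"))
  readr::write_csv(experiment$agreement, file.path(dir, "agreement.csv"))
  cfg <- experiment$config
  cfg$detection <- unclass(cfg$detection)
  yaml::write_yaml(list(seed = experiment$seed, config = unclass(cfg)),
                   file.path(dir, "run_info.yaml"))
  invisible(dir)
}
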