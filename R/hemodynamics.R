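#' Extract per-vessel velocity waveforms
#'
#' Reads the velocity magnitude at each vessel's representative voxel across
#' all cardiac phases. Velocities are taken as absolute values so flow
#' direction does not affect the hemodynamic summaries.
#'
#' @param series A reconstructed [cine_pc_series()].
#' @param vessels A `vessel_set` from [detect_perforators()].
#' @return A tibble in long form: `vessel_id`, `cardiac_phase` (1-based),
#'   `velocity_cm_s` (absolute). Empty (zero rows) when no vessels were
#'   detected, with attribute `no_vessels = TRUE`.
#' @export
extract_waveforms <- function(series, vessels) {
  stopifnot(inherits(series, "cine_pc_series"))
  if (nrow(vessels) == 0) {
    out <- tibble::tibble(vessel_id = integer(), cardiac_phase = integer(),
                          velocity_cm_s = numeric())
    attr(out, "no_vessels") <- TRUE
    return(out)
  }
  vel <- phase_to_velocity(series)
  purrr::map_dfr(seq_len(nrow(vessels)), function(i) {
    tibble::tibble(
      vessel_id = vessels$vessel_id[i],
      cardiac_phase = seq_len(series$n_cardiac_phases),
      velocity_cm_s = abs(vel[vessels$row[i], vessels$col[i], ])
    )
  })
}

# Long waveform tibble (or vessel x phase matrix) -> matrix, with checks.
curves_matrix <- function(curves) {
  if (is.matrix(curves)) {
    m <- curves
  } else if (is.data.frame(curves)) {
    stopifnot(all(c("vessel_id", "cardiac_phase", "velocity_cm_s") %in%
                    names(curves)))
    counts <- table(curves$vessel_id)
    if (length(unique(counts)) > 1) {
      stop("mismatched cardiac-phase counts across vessels", call. = FALSE)
    }
    wide <- tidyr::pivot_wider(curves, id_cols = "vessel_id",
                               names_from = "cardiac_phase",
                               values_from = "velocity_cm_s")
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- wide$vessel_id
  } else if (is.numeric(curves)) {
    m <- matrix(curves, nrow = 1)
  } else {
    stop("`curves` must be a waveform tibble, a vessel x phase matrix, or a ",
         "single numeric curve", call. = FALSE)
  }
  if (anyNA(m)) stop("mismatched cardiac-phase counts across vessels", call. = FALSE)
  if (ncol(m) < 2) stop("each curve needs at least 2 cardiac phases", call. = FALSE)
  if (nrow(m) < 1) stop("at least one curve required", call. = FALSE)
  m
}

#' Scan-level mean velocity
#'
#' `V_mean` is the temporal mean of the average velocity waveform over all
#' vessels.
#'
#' @param curves Waveform tibble from [extract_waveforms()], a vessel x phase
#'   matrix, or a single numeric curve.
#' @return Scalar, cm/s.
#' @export
compute_v_mean <- function(curves) {
  m <- curves_matrix(curves)
  mean(colMeans(m))
}

#' Scan-level velocity pulsatility index
#'
#' Each vessel's velocity curve is first normalized by its own temporal mean,
#' the normalized curves are averaged elementwise over vessels, and
#' `vPI = (V_max - V_min) / V_mean` is evaluated on that mean normalized
#' curve — whose temporal mean is 1 by construction of the normalization.
#' Curves with a nonpositive temporal mean cannot be normalized and are
#' excluded with a warning.
#'
#' @inheritParams compute_v_mean
#' @return Scalar vPI (>= 0).
#' @export
compute_vpi <- function(curves) {
  m <- curves_matrix(curves)
  mu <- rowMeans(m)
  bad <- mu <= 0
  if (any(bad)) {
    warning(sum(bad), " curve(s) with nonpositive temporal mean excluded ",
            "from vPI")
    m <- m[!bad, , drop = FALSE]; mu <- mu[!bad]
    if (nrow(m) == 0) stop("no curves left after exclusion", call. = FALSE)
  }
  navg <- colMeans(m / mu)
  (max(navg) - min(navg)) / mean(navg)
}

#' Full hemodynamic summary of one scan
#'
#' Bundles the per-vessel waveforms with the scan-level outcomes: the number
#' of detected perforators, the mean velocity `V_mean`, and the velocity
#' pulsatility index `vPI` of the mean normalized curve.
#'
#' @param series A reconstructed [cine_pc_series()].
#' @param vessels A `vessel_set` from [detect_perforators()].
#' @return Object of class `waveform_stats`: list with `curves` (long
#'   tibble), `mean_curve`, `normalized_mean_curve`, `n_detected`, `v_mean`,
#'   `v_max`, `v_min`, `vpi`, `heart_rate_bpm`.
#' @export
waveform_stats <- function(series, vessels) {
  curves <- extract_waveforms(series, vessels)
  if (nrow(curves) == 0) {
    return(structure(list(curves = curves, mean_curve = numeric(),
                          normalized_mean_curve = numeric(),
                          n_detected = 0L, v_mean = NA_real_,
                          v_max = NA_real_, v_min = NA_real_, vpi = NA_real_,
                          heart_rate_bpm = series$heart_rate_bpm),
                     class = "waveform_stats"))
  }
  m <- curves_matrix(curves)
  mu <- rowMeans(m)
  keep <- mu > 0
  navg <- colMeans(m[keep, , drop = FALSE] / mu[keep])
  structure(list(
    curves = curves,
    mean_curve = colMeans(m),
    normalized_mean_curve = navg,
    n_detected = n_detected(vessels),
    v_mean = mean(colMeans(m)),
    v_max = max(navg), v_min = min(navg),
    vpi = (max(navg) - min(navg)) / mean(navg),
    heart_rate_bpm = series$heart_rate_bpm
  ), class = "waveform_stats")
}

#' @export
print.waveform_stats <- function(x, ...) {
  cat("<waveform_stats> N_detected =", x$n_detected,
      " V_mean =", signif(x$v_mean, 4), "cm/s",
      " vPI =", signif(x$vpi, 4), "\n")
  invisible(x)
}

#' Tidy a waveform summary
#' @param x A [waveform_stats()] object.
#' @param ... Unused.
#' @return Tibble with `cardiac_phase`, `mean_velocity_cm_s`,
#'   `normalized_velocity`.
#' @exportS3Method generics::tidy
tidy.waveform_stats <- function(x, ...) {
  tibble::tibble(
    cardiac_phase = seq_along(x$mean_curve),
    mean_velocity_cm_s = x$mean_curve,
    normalized_velocity = x$normalized_mean_curve
  )
}

#' One-row summary of a scan's hemodynamics
#' @param x A [waveform_stats()] object.
#' @param ... Unused.
#' @return One-row tibble: `n_detected`, `v_mean_cm_s`, `vpi`, `v_max`,
#'   `v_min`, `heart_rate_bpm`.
#' @exportS3Method generics::glance
glance.waveform_stats <- function(x, ...) {
  tibble::tibble(n_detected = x$n_detected, v_mean_cm_s = x$v_mean,
                 vpi = x$vpi, v_max = x$v_max, v_min = x$v_min,
                 heart_rate_bpm = x$heart_rate_bpm)
}

#' Plot the mean normalized velocity waveform
#' @param object A [waveform_stats()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.waveform_stats <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cardiac_phase,
                                   y = .data$normalized_velocity)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Cardiac phase", y = "Normalized velocity",
                  title = sprintf("Mean normalized waveform (vPI = %.2f)",
                                  object$vpi)) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
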