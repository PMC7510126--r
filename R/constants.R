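#' Observation-time schedule for multi-delay pCASL
#'
#' An observation time (OT) is one (labeling duration, post-labeling delay)
#' combination. The default schedule is the 12-OT design used for choroid
#' plexus perfusion mapping: six OTs with growing labeling duration tau at
#' the minimum delay of 0.7 s (tracking inflow), then six with tau fixed at
#' 4 s and growing delay (tracking washout).
#'
#' @param tau numeric vector of labeling durations, seconds (all > 0).
#' @param w numeric vector of post-labeling delays, seconds (all > 0),
#'   same length as `tau`.
#' @return An object of class `ot_schedule`: a data.frame with columns
#'   `tau` and `w`, one row per OT.
#' @examples
#' sched <- ot_schedule()
#' nrow(sched)  # 12
#' @export
ot_schedule <- function(tau = c(1.5, 2.0, 2.5, 3.0, 3.5, 4.0, 4.0, 4.0, 4.0, 4.0, 4.0, 4.0),
                        w   = c(0.7, 0.7, 0.7, 0.7, 0.7, 0.7, 1.2, 1.7, 2.2, 2.7, 3.2, 3.7)) {
  tau <- as.numeric(tau)
  w <- as.numeric(w)
  if (length(tau) == 0L || length(tau) != length(w)) {
    stop("`tau` and `w` must be non-empty vectors of equal length", call. = FALSE)
  }
  if (!all(is.finite(tau)) || !all(is.finite(w))) {
    stop("schedule entries must be finite", call. = FALSE)
  }
  if (any(tau <= 0) || any(w <= 0)) {
    bad <- which(tau <= 0 | w <= 0)[1L]
    stop(sprintf("schedule row %d has non-positive tau or w", bad), call. = FALSE)
  }
  structure(data.frame(tau = tau, w = w),
            class = c("ot_schedule", "data.frame"))
}

#' Fixed acquisition and tissue constants of the ASL quantification model
#'
#' All physical constants entering the kinetic model, the M0 calibration and
#' the total-flow conversion. Defaults are standard literature values for
#' 3 T pCASL with background suppression.
#'
#' @param alpha1 inversion (labeling) efficiency of the arterial blood,
#'   dimensionless. Default 0.8.
#' @param alpha2 background-suppression efficiency, dimensionless.
#'   Default 0.75. The effective labeling efficiency is
#'   `alpha = alpha1 * alpha2`.
#' @param T1a longitudinal relaxation time of arterial blood, seconds.
#'   Default 1.65.
#' @param lambda_bbp brain-blood partition coefficient, ml/g. Default 0.9;
#'   also used to approximate the (unknown) choroid plexus partition
#'   coefficient.
#' @param Tsat saturation recovery time of the proton-density reference
#'   scan, seconds. Default 2.
#' @param T1g gray-matter longitudinal relaxation time used in the M0
#'   calibration, seconds. Default 1.5.
#' @param rho tissue density, g/ml. Default 1.08 (brain parenchyma; assumed
#'   to hold for choroid plexus).
#' @param voxel_volume analysis-grid voxel volume, ml. Default 0.064
#'   (4 mm isotropic ASL grid); configurable because analysis may run on a
#'   resampled higher-resolution grid.
#' @return An object of class `acq_constants` (named list).
#' @export
acquisition_constants <- function(alpha1 = 0.8, alpha2 = 0.75, T1a = 1.65,
                                  lambda_bbp = 0.9, Tsat = 2, T1g = 1.5,
                                  rho = 1.08, voxel_volume = 0.064) {
  vals <- c(alpha1 = alpha1, alpha2 = alpha2, T1a = T1a,
            lambda_bbp = lambda_bbp, Tsat = Tsat, T1g = T1g,
            rho = rho, voxel_volume = voxel_volume)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all acquisition constants must be finite and strictly positive",
         call. = FALSE)
  }
  if (alpha1 * alpha2 > 1) {
    stop("labeling efficiency alpha1*alpha2 must lie in (0, 1]", call. = FALSE)
  }
  structure(as.list(vals), class = "acq_constants")
}

#' Perfusion parameter triple
#'
#' The three quantities estimated per voxel or region: apparent blood flow
#' `f` (ml/100 g/min), arterial transit time `delta` (seconds), and the
#' tissue longitudinal relaxation time `T1` of the labeled water after
#' exchange into tissue (seconds). When produced by the fitter the triple
#' respects the fit bounds; as simulation ground truth any non-negative
#' values (with `T1 > 0`) are allowed.
#'
#' @param f apparent blood flow, ml/100 g/min (>= 0).
#' @param delta arterial transit time, seconds (>= 0).
#' @param T1 tissue T1, seconds (> 0).
#' @return An object of class `perfusion_params` (named list).
#' @export
perfusion_params <- function(f, delta, T1) {
  if (!all(is.finite(c(f, delta, T1)))) {
    stop("perfusion parameters must be finite", call. = FALSE)
  }
  if (f < 0 || delta < 0 || T1 <= 0) {
    stop("require f >= 0, delta >= 0, T1 > 0", call. = FALSE)
  }
  structure(list(f = f, delta = delta, T1 = T1), class = "perfusion_params")
}

#' Box constraints for the three-parameter fit
#'
#' Lower bounds follow the quantification protocol: apparent flow at least
#' 10 ml/100 g/min, transit time at least the minimum post-labeling delay of
#' 0.7 s, tissue T1 at least 1 s (empirical). Upper bounds are generous
#' physiological ceilings chosen to keep the bounded optimizer stable: flow
#' 300 ml/100 g/min, transit time 4 s (beyond the largest delay plus the
#' shortest labeling duration the transit time is unobservable), T1 5 s
#' (CSF ceiling).
#'
#' @param lower named numeric vector `c(f=, delta=, T1=)` of lower bounds.
#' @param upper named numeric vector of upper bounds, finite,
#'   componentwise greater than `lower`.
#' @return An object of class `fit_bounds`.
#' @export
fit_bounds <- function(lower = c(f = 10, delta = 0.7, T1 = 1),
                       upper = c(f = 300, delta = 4, T1 = 5)) {
  nm <- c("f", "delta", "T1")
  lower <- lower[nm]; upper <- upper[nm]
  if (anyNA(lower) || anyNA(upper)) {
    stop("bounds must be named vectors with entries f, delta, T1", call. = FALSE)
  }
  if (!all(is.finite(lower)) || !all(is.finite(upper))) {
    stop("bounds must be finite", call. = FALSE)
  }
  if (!all(lower < upper)) {
    stop("lower bounds must be strictly below upper bounds", call. = FALSE)
  }
  structure(list(lower = lower, upper = upper), class = "fit_bounds")
}

#' Observed relative ASL signal curve
#'
#' Bundles one relative-signal curve (label-control difference divided by
#' the calibration M0) with its schedule and the M0 used, for provenance.
#' Values may be negative due to noise.
#'
#' @param rel_signal numeric vector of dimensionless relative signals
#'   (delta-M / M0), one per OT; finite or NA.
#' @param schedule an [ot_schedule()] of the same length.
#' @param m0 the calibration M0 in scanner units (> 0).
#' @return An object of class `asl_observation`.
#' @export
asl_observation <- function(rel_signal, schedule = ot_schedule(), m0 = 1) {
  rel_signal <- as.numeric(rel_signal)
  if (length(rel_signal) != nrow(schedule)) {
    stop("rel_signal length must equal the schedule length", call. = FALSE)
  }
  if (any(is.infinite(rel_signal))) {
    stop("rel_signal values must be finite or NA", call. = FALSE)
  }
  if (!is.finite(m0) || m0 <= 0) {
    stop("m0 must be a positive scalar", call. = FALSE)
  }
  structure(list(rel_signal = rel_signal, schedule = schedule, m0 = m0),
            class = "asl_observation")
}

#' @export
print.perfusion_params <- function(x, ...) {
  cat(sprintf("perfusion parameters: f = %.3f ml/100g/min, delta = %.3f s, T1 = %.3f s\n",
              x$f, x$delta, x$T1))
  invisible(x)
}

#' @export
print.acq_constants <- function(x, ...) {
  cat("ASL acquisition constants:\n")
  for (nm in names(x)) cat(sprintf("  %-12s %g\n", nm, x[[nm]]))
  invisible(x)
}
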