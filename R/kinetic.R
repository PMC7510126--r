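#' Relative ASL signal of the single-compartment dynamic model
#'
#' Forward kinetic model for pseudo-continuous ASL: the relative
#' label-control difference signal dM/M0 produced by a bolus of labeled
#' arterial water of duration `tau`, observed after a post-labeling delay
#' `w`, given a tissue with apparent blood flow `f`, arterial transit time
#' `delta`, and tissue relaxation time `T1`:
#'
#'   dM/M0 = 2 alpha f' T1 exp(-delta/T1a)
#'           (exp(-max(w - delta, 0)/T1) - exp(-max(w + tau - delta, 0)/T1))
#'
#' where `alpha = alpha1*alpha2` is the effective labeling efficiency and
#' `f' = f/6000` converts ml/100 g/min to ml/g/s so the result is
#' dimensionless (typical magnitude ~1e-2). Label decays with the arterial
#' T1a until arrival at `delta` and with the tissue T1 thereafter. The
#' signal is zero when no label has arrived (`w + tau <= delta`) and exactly
#' linear in `f`.
#'
#' @param params a [perfusion_params()] triple (f, delta, T1).
#' @param constants an [acquisition_constants()] object.
#' @param tau labeling duration(s), seconds (> 0); vectorized.
#' @param w post-labeling delay(s), seconds (>= 0); recycled against `tau`.
#' @return numeric vector of dimensionless relative signals, >= 0.
#' @seealso [asl_signal_curve()] for evaluation over a schedule.
#' @export
asl_relative_signal <- function(params, constants = acquisition_constants(),
                                tau, w) {
  if (!all(is.finite(tau)) || !all(is.finite(w))) {
    stop("tau and w must be finite", call. = FALSE)
  }
  if (any(tau <= 0) || any(w < 0)) {
    stop("require tau > 0 and w >= 0", call. = FALSE)
  }
  f <- params$f; delta <- params$delta; T1 <- params$T1
  if (!all(is.finite(c(f, delta, T1))) || f < 0 || delta < 0 || T1 <= 0) {
    stop("require finite params with f >= 0, delta >= 0, T1 > 0", call. = FALSE)
  }
  alpha <- constants$alpha1 * constants$alpha2
  fp <- f / 6000  # ml/100g/min -> ml/g/s
  2 * alpha * fp * T1 * exp(-delta / constants$T1a) *
    (exp(-pmax(w - delta, 0) / T1) - exp(-pmax(w + tau - delta, 0) / T1))
}

#' Model signal curve over an observation-time schedule
#'
#' @param params a [perfusion_params()] triple.
#' @param constants an [acquisition_constants()] object.
#' @param schedule an [ot_schedule()].
#' @return numeric vector, one relative signal per schedule row.
#' @export
asl_signal_curve <- function(params, constants = acquisition_constants(),
                             schedule = ot_schedule()) {
  asl_relative_signal(params, constants, schedule$tau, schedule$w)
}

#' Equilibrium magnetization of arterial blood from the proton-density scan
#'
#' The proton-density reference image is acquired with a saturation recovery
#' time `Tsat`; the mean gray-matter signal `m_pd` therefore underestimates
#' the fully relaxed magnetization. M0 is recovered as
#' `m_pd / (lambda * (1 - exp(-Tsat/T1g)))`, using gray matter as the
#' reference tissue with partition coefficient `lambda`.
#'
#' @param m_pd mean proton-density signal over the gray-matter region,
#'   scanner units (> 0).
#' @param constants an [acquisition_constants()] object (uses `lambda_bbp`,
#'   `Tsat`, `T1g`).
#' @return M0 in scanner units; strictly greater than `m_pd / lambda`.
#' @export
compute_m0 <- function(m_pd, constants = acquisition_constants()) {
  if (!is.finite(m_pd) || m_pd <= 0) {
    stop("m_pd must be a positive finite scalar", call. = FALSE)
  }
  m_pd / (constants$lambda_bbp * (1 - exp(-constants$Tsat / constants$T1g)))
}

#' Total blood flow of a region from its mean apparent flow
#'
#' Summing voxelwise apparent flows f_n = w_n * F_n over a region cancels
#' the unknown per-voxel partial-volume fractions w_n, so the region total
#' `F = rho * v * N * mean(f) / 100` (ml/min) is insensitive to partial
#' volume. `mean_apparent_f` is in ml/100 g/min, hence the division by 100
#' once minutes and grams are matched through `rho * v` (g per voxel).
#'
#' @param mean_apparent_f mean apparent blood flow over the region,
#'   ml/100 g/min (>= 0).
#' @param n_voxels number of voxels in the region (>= 1).
#' @param constants an [acquisition_constants()] object (uses `rho`,
#'   `voxel_volume`).
#' @return total blood flow F in ml/min.
#' @export
total_flow <- function(mean_apparent_f, n_voxels,
                       constants = acquisition_constants()) {
  if (!is.finite(n_voxels) || n_voxels < 1) {
    stop("n_voxels must be >= 1", call. = FALSE)
  }
  if (!is.finite(mean_apparent_f) || mean_apparent_f < 0) {
    stop("mean_apparent_f must be finite and >= 0", call. = FALSE)
  }
  constants$rho * constants$voxel_volume * n_voxels * mean_apparent_f / 100
}

#' Weight-corrected specific blood flow of the choroid plexus
#'
#' Converts a measured total flow of the lateral-ventricle choroid plexus
#' (ml/min) to a specific flow per 100 g of choroid plexus tissue, given the
#' whole-organ mass and the fraction of that mass located in the lateral
#' ventricles: `100 * F / (mass * fraction)`.
#'
#' @param F total blood flow, ml/min (>= 0).
#' @param cp_total_mass whole-organ choroid plexus mass, grams (> 0).
#' @param fraction_in_lateral_ventricles fraction of the organ mass in the
#'   lateral ventricles, in (0, 1].
#' @return specific blood flow in ml/100 g/min.
#' @examples
#' weight_corrected_flow(0.80, 2, 0.5)  # 80
#' @export
weight_corrected_flow <- function(F, cp_total_mass,
                                  fraction_in_lateral_ventricles) {
  if (!is.finite(F) || F < 0) stop("F must be finite and >= 0", call. = FALSE)
  if (!is.finite(cp_total_mass) || cp_total_mass <= 0) {
    stop("cp_total_mass must be positive", call. = FALSE)
  }
  fr <- fraction_in_lateral_ventricles
  if (!is.finite(fr) || fr <= 0 || fr > 1) {
    stop("fraction_in_lateral_ventricles must lie in (0, 1]", call. = FALSE)
  }
  100 * F / (cp_total_mass * fr)
}
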