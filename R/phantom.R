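# Tissue class codes used in the phantom label volume.
PHANTOM_CLASSES <- c(background = 0L, gray_matter = 1L, white_matter = 2L,
                     csf = 3L, choroid_plexus = 4L)

#' Specification of a synthetic ASL subject
#'
#' Describes the digital phantom: grid, voxel size, the generating perfusion
#' parameters of gray matter, white matter and choroid plexus, the choroid
#' plexus partial-volume fraction, the noise level and the proton-density
#' signal. Defaults reproduce the group-mean regional values of a healthy
#' adult cohort: gray matter (f = 53.74 ml/100 g/min, delta = 1.31 s,
#' T1 = 1.85 s) and choroid plexus actual flow F = 80 ml/100 g/min
#' (delta = 1.24 s, T1 = 2.33 s) observed at partial-volume fraction 0.5,
#' i.e. an apparent flow of 40 ml/100 g/min. White matter (f = 20,
#' delta = 1.5, T1 = 1.1) exists only to make the geometry realistic.
#'
#' @param grid_shape integer vector of 3 voxel counts (default 48^3).
#' @param voxel_size_mm voxel edge lengths in mm (default 4 mm isotropic,
#'   the native ASL resolution).
#' @param gm_params,wm_params [perfusion_params()] of gray and white matter.
#' @param cp_actual_params [perfusion_params()] of the choroid plexus with
#'   `f` the ACTUAL flow F (ml/100 g/min of choroid plexus tissue).
#' @param cp_pv_fraction partial-volume fraction w of choroid plexus tissue
#'   per choroid plexus voxel, in (0, 1]; the simulated apparent flow is
#'   `w * F`.
#' @param noise_sd Gaussian noise SD on the relative difference signal, in
#'   dM/M0 units. The default 2.5e-4 puts the gray-matter peak signal at a
#'   curve SNR of about 20.
#' @param m_pd_gm proton-density signal of tissue, scanner units.
#' @param seed integer seed for the noise generator.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48L, 48L, 48L),
                         voxel_size_mm = c(4, 4, 4),
                         gm_params = perfusion_params(53.74, 1.31, 1.85),
                         wm_params = perfusion_params(20, 1.5, 1.1),
                         cp_actual_params = perfusion_params(80, 1.24, 2.33),
                         cp_pv_fraction = 0.5,
                         noise_sd = 2.5e-4,
                         m_pd_gm = 1000,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L)) {
    stop("grid_shape must be 3 positive voxel counts", call. = FALSE)
  }
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0)) {
    stop("voxel_size_mm must be 3 positive lengths", call. = FALSE)
  }
  if (!is.finite(cp_pv_fraction) || cp_pv_fraction <= 0 || cp_pv_fraction > 1) {
    stop("cp_pv_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be >= 0", call. = FALSE)
  }
  if (!is.finite(m_pd_gm) || m_pd_gm <= 0) {
    stop("m_pd_gm must be positive", call. = FALSE)
  }
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 gm_params = gm_params, wm_params = wm_params,
                 cp_actual_params = cp_actual_params,
                 cp_pv_fraction = cp_pv_fraction, noise_sd = noise_sd,
                 m_pd_gm = m_pd_gm, seed = as.integer(seed)),
            class = "phantom_spec")
}

# squared ellipsoid coordinate of every voxel: sum_i ((x_i - c_i)/a_i)^2
ellipsoid_r2 <- function(dims, center, semi) {
  x <- (seq_len(dims[1L]) - center[1L]) / semi[1L]
  y <- (seq_len(dims[2L]) - center[2L]) / semi[2L]
  z <- (seq_len(dims[3L]) - center[3L]) / semi[3L]
  outer(outer(x^2, y^2, `+`), z^2, `+`)
}

# logical OR of a mask with its 6-neighborhood shifts
dilate6 <- function(m) {
  d <- dim(m)
  out <- m
  shift <- function(a, axis, by) {
    idx <- rep(list(quote(expr = )), 3L)
    src <- seq_len(d[axis]) - by
    src[src < 1L | src > d[axis]] <- NA
    idx[[axis]] <- src
    r <- do.call(`[`, c(list(a), idx))
    r[is.na(r)] <- FALSE
    array(r, d)
  }
  for (axis in 1:3) for (by in c(-1L, 1L)) out <- out | shift(m, axis, by)
  out
}

#' Build the deterministic phantom geometry
#'
#' Constructs a brain-like label volume on the spec grid: an ellipsoidal
#' cortical gray-matter shell, interior white matter, two ellipsoidal
#' CSF-filled lateral ventricles, and a thin sheet of choroid plexus voxels
#' lining the posterior wall of each ventricle. The gray-matter probability
#' map is 1 on gray matter except for a one-voxel rim at the outer surface
#' set to 0.5 (so a strict > 0.5 threshold selects the interior gray
#' matter), and 0 elsewhere.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_truth`: list with integer
#'   `label_volume` (codes: 0 background, 1 gray matter, 2 white matter,
#'   3 CSF, 4 choroid plexus), `gm_probability_map`, `pv_map` (partial
#'   volume fraction w per voxel), `true_flow_map` (apparent flow
#'   f = w * F), `true_att_map`, `true_t1_map` (NA where flow is zero),
#'   and `classes`, the code table.
#' @export
build_geometry <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  if (any(d < 24L)) {
    stop("grid too small: need at least 24 voxels per axis to contain all structures",
         call. = FALSE)
  }
  ctr <- (d + 1) / 2

  brain_a <- 0.44 * d
  shell_vox <- 2
  outer_r2 <- ellipsoid_r2(d, ctr, brain_a)
  inner_r2 <- ellipsoid_r2(d, ctr, brain_a - shell_vox)
  brain <- outer_r2 <= 1
  wm <- inner_r2 <= 1
  gm <- brain & !wm

  lab <- array(PHANTOM_CLASSES[["background"]], d)
  lab[gm] <- PHANTOM_CLASSES[["gray_matter"]]
  lab[wm] <- PHANTOM_CLASSES[["white_matter"]]

  # lateral ventricles: mirrored ellipsoids elongated along the y
  # (anterior-posterior) axis, inside white matter
  vent_semi <- c(0.09, 0.22, 0.09) * d
  vent_off <- 0.15 * d[1L]
  for (side in c(-1, 1)) {
    vc <- c(ctr[1L] + side * vent_off, ctr[2L], ctr[3L])
    v_r2 <- ellipsoid_r2(d, vc, vent_semi)
    vent <- v_r2 <= 1 & wm
    lab[vent] <- PHANTOM_CLASSES[["csf"]]
    # choroid plexus: sheet along the posterior ventricle wall (inner shell
    # of the ventricle, posterior third)
    ymat <- array(rep(seq_len(d[2L]), each = d[1L]), d)
    cp <- vent & v_r2 >= 0.45 & ymat >= vc[2L] + 0.35 * vent_semi[2L]
    lab[cp] <- PHANTOM_CLASSES[["choroid_plexus"]]
  }

  present <- PHANTOM_CLASSES %in% unique(as.vector(lab))
  if (!all(present)) {
    stop(sprintf("grid too small: tissue class(es) %s not representable",
                 paste(names(PHANTOM_CLASSES)[!present], collapse = ", ")),
         call. = FALSE)
  }

  gm_mask <- lab == PHANTOM_CLASSES[["gray_matter"]]
  rim <- gm_mask & dilate6(!brain)  # outermost gray-matter layer
  gm_prob <- array(0, d)
  gm_prob[gm_mask] <- 1
  gm_prob[rim] <- 0.5

  pv <- array(0, d)
  pv[lab == PHANTOM_CLASSES[["gray_matter"]] |
       lab == PHANTOM_CLASSES[["white_matter"]]] <- 1
  pv[lab == PHANTOM_CLASSES[["choroid_plexus"]]] <- spec$cp_pv_fraction

  flow <- array(0, d)
  att <- array(NA_real_, d)
  t1 <- array(NA_real_, d)
  set_tissue <- function(code, f, delta, T1) {
    m <- lab == PHANTOM_CLASSES[[code]]
    flow[m] <<- f; att[m] <<- delta; t1[m] <<- T1
  }
  set_tissue("gray_matter", spec$gm_params$f, spec$gm_params$delta,
             spec$gm_params$T1)
  set_tissue("white_matter", spec$wm_params$f, spec$wm_params$delta,
             spec$wm_params$T1)
  set_tissue("choroid_plexus",
             spec$cp_pv_fraction * spec$cp_actual_params$f,
             spec$cp_actual_params$delta, spec$cp_actual_params$T1)

  structure(list(label_volume = lab, gm_probability_map = gm_prob,
                 pv_map = pv, true_flow_map = flow, true_att_map = att,
                 true_t1_map = t1, classes = PHANTOM_CLASSES),
            class = "phantom_truth")
}

#' Simulate one synthetic ASL subject
#'
#' Generates per-OT difference volumes and proton-density reference volumes
#' from the phantom geometry via the forward kinetic model. For every voxel
#' the noiseless difference signal is
#' `dM = M0 * asl_relative_signal(true params)`, with
#' `M0 = compute_m0(m_pd_gm)`; CSF and background voxels contribute no ASL
#' signal. The proton-density volume is constant `m_pd_gm` on tissue so the
#' analysis-side M0 calibration reproduces the generating M0 exactly.
#' When `noise_sd > 0`, independent zero-mean Gaussian noise of SD
#' `noise_sd * M0` is added per voxel and OT (seeded, reproducible).
#'
#' @param spec a [phantom_spec()].
#' @param schedule an [ot_schedule()].
#' @param constants an [acquisition_constants()] object; its `voxel_volume`
#'   is ignored in favor of the spec voxel size.
#' @return list with `delta_m` (list of 3-D arrays, one per OT), `pd`
#'   (matching proton-density arrays), `truth` ([build_geometry()] output),
#'   `m0`, `voxel_volume_ml`, `spec` and `schedule`.
#' @export
simulate_subject <- function(spec, schedule = ot_schedule(),
                             constants = acquisition_constants()) {
  stopifnot(inherits(spec, "phantom_spec"))
  truth <- build_geometry(spec)
  lab <- truth$label_volume
  m0 <- compute_m0(spec$m_pd_gm, constants)
  n_ot <- nrow(schedule)

  curves <- list(
    gray_matter = asl_signal_curve(spec$gm_params, constants, schedule),
    white_matter = asl_signal_curve(spec$wm_params, constants, schedule),
    # apparent signal of a partial-volume voxel: linear in f, so w * curve(F)
    choroid_plexus = spec$cp_pv_fraction *
      asl_signal_curve(spec$cp_actual_params, constants, schedule)
  )

  tissue <- lab != PHANTOM_CLASSES[["background"]]
  pd_vol <- array(0, dim(lab))
  pd_vol[tissue] <- spec$m_pd_gm

  masks <- lapply(names(curves), function(nm) lab == PHANTOM_CLASSES[[nm]])
  names(masks) <- names(curves)

  delta_m <- vector("list", n_ot)
  noise <- if (spec$noise_sd > 0) {
    with_seed(spec$seed,
              stats::rnorm(length(lab) * n_ot, 0, spec$noise_sd * m0))
  } else NULL
  for (i in seq_len(n_ot)) {
    vol <- array(0, dim(lab))
    for (nm in names(curves)) vol[masks[[nm]]] <- m0 * curves[[nm]][i]
    if (!is.null(noise)) {
      vol <- vol + array(noise[((i - 1) * length(lab) + 1):(i * length(lab))],
                         dim(lab))
    }
    delta_m[[i]] <- vol
  }

  list(delta_m = delta_m, pd = rep(list(pd_vol), n_ot), truth = truth,
       m0 = m0, voxel_volume_ml = prod(spec$voxel_size_mm) / 1000,
       spec = spec, schedule = schedule)
}

#' Simulate a cohort of synthetic subjects
#'
#' Draws per-subject generating parameters by multiplying the template
#' values by independent log-normal factors with unit mean and coefficient
#' of variation `between_subject_cv` (applied to gray-matter f/delta/T1 and
#' choroid plexus actual F/delta/T1), then simulates each subject. A
#' between-subject CV of 0.25 matches the reported ~25% inter-subject
#' variation of regional flow.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param spec_template a [phantom_spec()]; per-subject specs differ only in
#'   the drawn parameters and the noise seed.
#' @param between_subject_cv coefficient of variation of the log-normal
#'   factors (>= 0; 0 gives identical subjects).
#' @param seed integer master seed; subject seeds are derived from it.
#' @param schedule,constants forwarded to [simulate_subject()].
#' @return list with `subjects` (list of [simulate_subject()] outputs) and
#'   `truth_table`, a data.frame with one row per subject giving the
#'   generating regional parameters (gray matter f/att/T1; choroid plexus
#'   apparent f, actual F, att, T1) in group-table layout.
#' @export
simulate_cohort <- function(n_subjects, spec_template = phantom_spec(),
                            between_subject_cv = 0.25, seed = 1L,
                            schedule = ot_schedule(),
                            constants = acquisition_constants()) {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (between_subject_cv < 0) stop("between_subject_cv must be >= 0", call. = FALSE)
  cv <- between_subject_cv
  sdlog <- sqrt(log(1 + cv^2))
  # unit-mean log-normal factors, 6 per subject
  fac <- with_seed(seed, {
    matrix(stats::rlnorm(6L * n_subjects, meanlog = -sdlog^2 / 2, sdlog = sdlog),
           nrow = n_subjects)
  })
  if (cv == 0) fac[] <- 1

  subjects <- vector("list", n_subjects)
  rows <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    gm <- perfusion_params(spec_template$gm_params$f * fac[i, 1L],
                           spec_template$gm_params$delta * fac[i, 2L],
                           spec_template$gm_params$T1 * fac[i, 3L])
    cp <- perfusion_params(spec_template$cp_actual_params$f * fac[i, 4L],
                           spec_template$cp_actual_params$delta * fac[i, 5L],
                           spec_template$cp_actual_params$T1 * fac[i, 6L])
    sp <- spec_template
    sp$gm_params <- gm
    sp$cp_actual_params <- cp
    sp$seed <- as.integer((abs(seed) %% 10000) * 100000 + i * 101)
    subjects[[i]] <- simulate_subject(sp, schedule, constants)
    rows[[i]] <- data.frame(
      subject = i,
      gm_f = gm$f, gm_att = gm$delta, gm_t1 = gm$T1,
      cp_f_apparent = sp$cp_pv_fraction * cp$f,
      cp_F_actual = cp$f, cp_att = cp$delta, cp_t1 = cp$T1)
  }
  list(subjects = subjects, truth_table = do.call(rbind, rows))
}
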