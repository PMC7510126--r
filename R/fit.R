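# Run code with a private, restored RNG state so fits are deterministic
# without disturbing the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` with the total sum of squares taken about the
#' mean of the observed values. Can be negative for a fit worse than the
#' mean; never exceeds 1.
#'
#' @param observed numeric vector (length >= 2, not all identical).
#' @param predicted numeric vector, same length.
#' @return scalar R-squared.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2) {
    stop("observed and predicted must have equal length >= 2", call. = FALSE)
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop("observed values are all identical: R^2 undefined", call. = FALSE)
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

# Starting points for the multi-start search. The max(.,0) kinks of the
# kinetic model make the residual surface piecewise-smooth in delta, so one
# default start is complemented by restarts spread over the observable delta
# range with seeded jitter on T1. The model is linear in f, so each start's
# f is its closed-form least-squares value at that (delta, T1), clamped to
# the bounds (`init_f` supplied by the caller).
fit_starts <- function(bounds, n_starts, seed, init_f) {
  lo <- bounds$lower; hi <- bounds$upper
  clamp <- function(x) pmin(pmax(x, lo), hi)
  mk <- function(delta, T1) clamp(c(f = init_f(delta, T1), delta = delta, T1 = T1))
  starts <- list(mk(1.0, 1.5))
  if (n_starts > 1) {
    dgrid <- seq(max(lo[["delta"]], 0.7), min(hi[["delta"]], 3.7),
                 length.out = n_starts - 1L)
    jit <- with_seed(seed, exp(stats::rnorm(n_starts - 1L, 0, 0.3)))
    for (i in seq_len(n_starts - 1L)) {
      starts[[i + 1L]] <- mk(dgrid[i], 1.5 * jit[i])
    }
  }
  starts
}

#' Fit the kinetic model to one observed relative-signal curve
#'
#' Constrained nonlinear least squares for the triple (f, delta, T1) of
#' [perfusion_params()], minimizing the unweighted sum of squared residuals
#' between [asl_signal_curve()] and the observed relative signal. Bounded
#' quasi-Newton optimization (`stats::nlminb`, PORT routines) is run from
#' `n_starts` starting points and the lowest-residual converged solution is
#' returned; the multi-start guards against the piecewise-smooth residual
#' surface in delta created by the arrival-time kinks of the model.
#'
#' @param obs an [asl_observation()]; NA entries are dropped (at least 3
#'   usable points are required for the 3 parameters).
#' @param constants an [acquisition_constants()] object.
#' @param bounds a [fit_bounds()] object.
#' @param n_starts number of starting points (>= 1, default 5).
#' @param seed integer seed for the restart jitter; identical inputs and
#'   seed give bitwise-identical results.
#' @return An object of class `asl_fit` with elements `params`
#'   ([perfusion_params()]), `r2`, `residual_norm` (root of the residual sum
#'   of squares), `bound_hit` (named logical, TRUE where the estimate sits
#'   on a bound), `converged`, `n_restarts_used`, `fitted` (model curve on
#'   the full schedule) and `obs`.
#' @export
fit_series <- function(obs, constants = acquisition_constants(),
                       bounds = fit_bounds(), n_starts = 5L, seed = 1L) {
  stopifnot(inherits(obs, "asl_observation"))
  if (n_starts < 1) stop("n_starts must be >= 1", call. = FALSE)
  y <- obs$rel_signal
  use <- is.finite(y)
  if (sum(use) < 3) {
    stop("insufficient data: need at least 3 usable observation times",
         call. = FALSE)
  }
  tau <- obs$schedule$tau[use]; w <- obs$schedule$w[use]; yy <- y[use]
  alpha <- constants$alpha1 * constants$alpha2
  T1a <- constants$T1a

  model <- function(p) {
    2 * alpha * (p[1L] / 6000) * p[3L] * exp(-p[2L] / T1a) *
      (exp(-pmax(w - p[2L], 0) / p[3L]) - exp(-pmax(w + tau - p[2L], 0) / p[3L]))
  }
  objective <- function(p) sum((model(p) - yy)^2)

  lo <- bounds$lower; hi <- bounds$upper
  ctrl <- list(iter.max = 200L, eval.max = 1000L,
               rel.tol = 1e-12, x.tol = 1e-12)
  # closed-form least-squares f at fixed (delta, T1), from linearity in f
  init_f <- function(delta, T1) {
    m1 <- 2 * alpha * (1 / 6000) * T1 * exp(-delta / T1a) *
      (exp(-pmax(w - delta, 0) / T1) - exp(-pmax(w + tau - delta, 0) / T1))
    denom <- sum(m1^2)
    if (denom <= 0) return(50)
    sum(m1 * yy) / denom
  }
  best <- NULL
  n_used <- 0L
  for (start in fit_starts(bounds, n_starts, seed, init_f)) {
    n_used <- n_used + 1L
    res <- tryCatch(
      stats::nlminb(start, objective, lower = lo, upper = hi, control = ctrl),
      error = function(e) NULL)
    if (is.null(res)) next
    res$ok <- res$convergence == 0L || res$objective < .Machine$double.eps
    if (is.null(best) ||
        (res$ok && !best$ok) ||
        (res$ok == best$ok && res$objective < best$objective)) {
      best <- res
    }
  }
  if (is.null(best)) {
    stop("fit_series: no restart produced a usable solution", call. = FALSE)
  }
  p <- unname(best$par)
  scale <- unname(hi - lo)
  lo <- unname(lo); hi <- unname(hi)
  tol <- 1e-6
  bound_hit <- ((p - lo) / scale < tol) | ((hi - p) / scale < tol)
  names(bound_hit) <- c("f", "delta", "T1")
  fitted_full <- asl_relative_signal(
    perfusion_params(p[1L], p[2L], p[3L]), constants,
    obs$schedule$tau, obs$schedule$w)
  r2 <- if (stats::var(yy) > 0) r_squared(yy, model(p)) else NA_real_
  structure(list(
    params = perfusion_params(p[1L], p[2L], p[3L]),
    r2 = r2,
    residual_norm = sqrt(best$objective),
    bound_hit = bound_hit,
    converged = isTRUE(best$ok),
    n_restarts_used = n_used,
    fitted = fitted_full,
    obs = obs
  ), class = "asl_fit")
}

#' @export
print.asl_fit <- function(x, ...) {
  cat(sprintf(
    "ASL kinetic fit: f = %.2f ml/100g/min, delta = %.3f s, T1 = %.3f s (R2 = %s)\n",
    x$params$f, x$params$delta, x$params$T1,
    ifelse(is.na(x$r2), "NA", sprintf("%.4f", x$r2))))
  if (any(x$bound_hit)) {
    cat("  at bound:", paste(names(x$bound_hit)[x$bound_hit], collapse = ", "), "\n")
  }
  invisible(x)
}

# Coerce a mask to logical voxel positions on a reference grid.
as_mask <- function(mask, dim_ref) {
  if (is.logical(mask)) {
    if (!identical(dim(mask), dim_ref)) {
      stop("mask grid does not match the volume grid", call. = FALSE)
    }
    return(mask)
  }
  m <- array(FALSE, dim_ref)
  m[mask] <- TRUE
  m
}

#' Fit the kinetic model to the mean signal of a region
#'
#' Averages the per-OT difference signal over the mask, divides by `m0`,
#' and fits one curve (mean-then-fit). This is the estimator used for
#' regional perfusion: averaging first suppresses voxel noise before the
#' nonlinear fit.
#'
#' @param delta_m_volumes list of 3-D arrays, one per OT, sharing one grid.
#' @param mask logical array on the same grid, or voxel indices; must be
#'   non-empty.
#' @param m0 calibration M0, scanner units.
#' @param constants,bounds,n_starts,seed passed to [fit_series()].
#' @param schedule an [ot_schedule()] matching the volume list.
#' @return An `asl_fit` (see [fit_series()]).
#' @export
fit_roi <- function(delta_m_volumes, mask, m0,
                    constants = acquisition_constants(),
                    bounds = fit_bounds(), schedule = ot_schedule(),
                    n_starts = 5L, seed = 1L) {
  if (length(delta_m_volumes) != nrow(schedule)) {
    stop("need one volume per schedule row", call. = FALSE)
  }
  msk <- as_mask(mask, dim(delta_m_volumes[[1L]]))
  if (!any(msk)) stop("mask is empty", call. = FALSE)
  mean_dm <- vapply(delta_m_volumes,
                    function(v) mean(v[msk], na.rm = TRUE), numeric(1))
  obs <- asl_observation(mean_dm / m0, schedule, m0)
  fit_series(obs, constants, bounds, n_starts = n_starts, seed = seed)
}

#' Voxelwise kinetic-model fitting over a mask
#'
#' Runs an independent [fit_series()] in every mask voxel and assembles
#' parameter maps. Per-voxel failures are recorded as missing values and
#' tallied, never fatal.
#'
#' @inheritParams fit_roi
#' @param verbose log progress every 500 voxels.
#' @return An object of class `voxel_maps`: list with 3-D arrays
#'   `flow_map`, `att_map`, `t1_map`, `r2_map` (NA outside the mask and at
#'   failed voxels), the logical `mask`, and `n_failed`.
#' @export
fit_voxelwise <- function(delta_m_volumes, mask, m0,
                          constants = acquisition_constants(),
                          bounds = fit_bounds(), schedule = ot_schedule(),
                          n_starts = 5L, seed = 1L, verbose = FALSE) {
  if (length(delta_m_volumes) != nrow(schedule)) {
    stop("need one volume per schedule row", call. = FALSE)
  }
  dims <- dim(delta_m_volumes[[1L]])
  msk <- as_mask(mask, dims)
  if (!any(msk)) stop("mask is empty", call. = FALSE)
  idx <- which(msk)
  sig <- vapply(delta_m_volumes, function(v) v[idx],
                numeric(length(idx)))  # voxels x OTs
  if (length(idx) == 1L) sig <- matrix(sig, nrow = 1L)

  empty <- array(NA_real_, dims)
  maps <- list(flow_map = empty, att_map = empty,
               t1_map = empty, r2_map = empty)
  n_failed <- 0L
  for (k in seq_along(idx)) {
    fit <- tryCatch({
      obs <- asl_observation(sig[k, ] / m0, schedule, m0)
      fit_series(obs, constants, bounds, n_starts = n_starts, seed = seed)
    }, error = function(e) NULL)
    if (is.null(fit)) {
      n_failed <- n_failed + 1L
      next
    }
    v <- idx[k]
    maps$flow_map[v] <- fit$params$f
    maps$att_map[v] <- fit$params$delta
    maps$t1_map[v] <- fit$params$T1
    maps$r2_map[v] <- fit$r2
    if (verbose && k %% 500L == 0L) {
      message(sprintf("fit_voxelwise: %d / %d voxels", k, length(idx)))
    }
  }
  structure(c(maps, list(mask = msk, n_failed = n_failed)),
            class = "voxel_maps")
}
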