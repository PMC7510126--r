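cst <- acquisition_constants()
sch <- ot_schedule()
bnds <- fit_bounds()

test_that("r_squared matches an independent two-pass formula", {
  set.seed(5)
  obs <- rnorm(12)
  pred <- obs + rnorm(12, 0, 0.3)
  expect_equal(r_squared(obs, pred), oracle_r2(obs, pred), tolerance = 1e-12)
  expect_identical(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 12)), 0, tolerance = 1e-12)
  expect_error(r_squared(rep(1, 5), rep(1, 5)), "identical")
  expect_error(r_squared(1:3, 1:4), "equal length")
})

test_that("noiseless curves are recovered to optimizer precision", {
  p <- perfusion_params(39.73, 1.35, 2.45)
  obs <- asl_observation(asl_signal_curve(p, cst, sch), sch)
  fit <- fit_series(obs, cst, bnds)
  expect_equal(fit$params$f, p$f, tolerance = 1e-6)
  expect_equal(fit$params$delta, p$delta, tolerance = 1e-6)
  expect_equal(fit$params$T1, p$T1, tolerance = 1e-6)
  expect_gte(fit$r2, 1 - 1e-9)
  expect_true(fit$converged)
  expect_false(any(fit$bound_hit))
})

test_that("parameters exactly at the lower bounds are recovered", {
  p <- perfusion_params(10, 0.7, 1)
  obs <- asl_observation(asl_signal_curve(p, cst, sch), sch)
  fit <- fit_series(obs, cst, bnds)
  expect_equal(fit$params$f, 10, tolerance = 1e-3)
  expect_equal(fit$params$delta, 0.7, tolerance = 1e-3)
  expect_equal(fit$params$T1, 1, tolerance = 1e-3)
})

test_that("all-zero signal terminates at the lower bounds with flags", {
  obs <- asl_observation(rep(0, 12), sch)
  fit <- fit_series(obs, cst, bnds)
  expect_equal(unname(fit$params$f), unname(bnds$lower[["f"]]))
  expect_true(fit$bound_hit[["f"]])
  expect_true(is.na(fit$r2))  # zero variance: R^2 undefined
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(fit_series(asl_observation(c(1, 2, NA, NA, NA, NA, NA, NA,
                                            NA, NA, NA, NA), sch), cst, bnds),
               "insufficient data")
  expect_error(asl_observation(rep(0, 5), sch), "length")
  expect_error(fit_bounds(lower = c(f = 10, delta = 0.7, T1 = 2),
                          upper = c(f = 300, delta = 4, T1 = 1)),
               "strictly below")
})

test_that("noiseless recovery holds for random in-bounds triples", {
  set.seed(101)
  n <- 30  # acceptance runs the full 100; this is the per-module check
  for (k in seq_len(n)) {
    f <- runif(1, 12, 250); d <- runif(1, 0.75, 3.8); T1 <- runif(1, 1.05, 4.8)
    p <- perfusion_params(f, d, T1)
    obs <- asl_observation(asl_signal_curve(p, cst, sch), sch)
    fit <- fit_series(obs, cst, bnds, n_starts = 5, seed = 1)
    expect_lt(abs(fit$params$f - f) / f, 1e-3)
    expect_lt(abs(fit$params$delta - d) / d, 1e-3)
    expect_lt(abs(fit$params$T1 - T1) / T1, 1e-3)
  }
})

test_that("fits are deterministic and invariant to joint dM/M0 rescaling", {
  set.seed(9)
  y <- asl_signal_curve(perfusion_params(45, 1.4, 2.1), cst, sch) +
    rnorm(12, 0, 2e-4)
  f1 <- fit_series(asl_observation(y, sch, m0 = 1000), cst, bnds, seed = 42)
  f2 <- fit_series(asl_observation(y, sch, m0 = 1000), cst, bnds, seed = 42)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$residual_norm, f2$residual_norm)
  # joint rescaling of dM and M0 leaves rel_signal, hence the fit, unchanged
  k <- 3.7
  dm <- y * 1000
  obs_a <- asl_observation(dm / 1000, sch, m0 = 1000)
  obs_b <- asl_observation((k * dm) / (k * 1000), sch, m0 = k * 1000)
  fa <- fit_series(obs_a, cst, bnds, seed = 1)
  fb <- fit_series(obs_b, cst, bnds, seed = 1)
  expect_equal(fa$params$f, fb$params$f, tolerance = 1e-6)
  expect_equal(fa$params$T1, fb$params$T1, tolerance = 1e-6)
})

test_that("ROI fit is mean-then-fit and linear mixing halves the flow", {
  dims <- c(4L, 4L, 2L)
  p <- perfusion_params(60, 1.2, 2.0)
  m0 <- 1500
  curve <- asl_signal_curve(p, cst, sch)
  vols <- lapply(seq_len(12), function(i) array(m0 * curve[i], dims))
  mask <- array(TRUE, dims)
  roi <- fit_roi(vols, mask, m0, cst, bnds, sch)
  single <- fit_series(asl_observation(curve, sch, m0), cst, bnds)
  expect_equal(roi$params$f, single$params$f, tolerance = 1e-9)

  # 50/50 mix of flow f and flow 0, delta >= max(w): signal linear in f,
  # so the mean-curve fit returns f/2
  d_late <- 3.8  # >= max PLD 3.7
  pf <- perfusion_params(80, d_late, 2.0)
  cf <- asl_signal_curve(pf, cst, sch)
  vols2 <- lapply(seq_len(12), function(i) {
    a <- array(0, dims)
    a[1:2, , ] <- m0 * cf[i]  # half the voxels flow, half zero
    a
  })
  roi2 <- fit_roi(vols2, mask, m0, cst, bnds, sch)
  expect_equal(roi2$params$f, 40, tolerance = 40 * 1e-3)
  expect_error(fit_roi(vols, array(FALSE, dims), m0, cst, bnds, sch), "empty")
})

test_that("voxelwise fitting fills maps on the mask and tolerates failures", {
  dims <- c(3L, 3L, 1L)
  m0 <- 1200
  p1 <- perfusion_params(50, 1.1, 1.8)
  p2 <- perfusion_params(30, 1.6, 2.6)
  c1 <- asl_signal_curve(p1, cst, sch); c2 <- asl_signal_curve(p2, cst, sch)
  vols <- lapply(seq_len(12), function(i) {
    a <- array(NA_real_, dims)
    a[1, 1, 1] <- m0 * c1[i]
    a[2, 1, 1] <- m0 * c2[i]
    # voxel [3,1,1] has all-missing data
    a
  })
  mask <- array(FALSE, dims); mask[1:3, 1, 1] <- TRUE
  maps <- fit_voxelwise(vols, mask, m0, cst, bnds, sch)
  expect_equal(maps$flow_map[1, 1, 1], 50, tolerance = 1e-4)
  expect_equal(maps$t1_map[2, 1, 1], 2.6, tolerance = 1e-4)
  expect_true(is.na(maps$flow_map[3, 1, 1]))
  expect_equal(maps$n_failed, 1L)
  expect_true(all(is.na(maps$flow_map[!mask])))

  # single-voxel mask equals fit_series on that voxel
  mask1 <- array(FALSE, dims); mask1[1, 1, 1] <- TRUE
  maps1 <- fit_voxelwise(vols, mask1, m0, cst, bnds, sch)
  direct <- fit_series(asl_observation(c1, sch, m0), cst, bnds)
  expect_equal(maps1$flow_map[1, 1, 1], direct$params$f, tolerance = 1e-9)
  expect_equal(sum(!is.na(maps1$flow_map)), 1L)
})
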