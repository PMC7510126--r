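cst <- acquisition_constants()
sch <- ot_schedule()

test_that("geometry contains all tissue classes and is deterministic", {
  spec <- small_spec()
  tr <- build_geometry(spec)
  counts <- table(tr$label_volume)
  expect_setequal(as.integer(names(counts)), 0:4)
  expect_gt(sum(tr$label_volume == 4), 0)  # choroid plexus present
  tr2 <- build_geometry(spec)
  expect_identical(tr$label_volume, tr2$label_volume)
  expect_identical(tr$true_flow_map, tr2$true_flow_map)
  expect_error(build_geometry(phantom_spec(grid_shape = c(10, 10, 10))),
               "too small")
})

test_that("truth maps satisfy f_n = w_n * F_n and CSF carries no flow", {
  spec <- small_spec(cp_pv_fraction = 0.35)
  tr <- build_geometry(spec)
  cp <- tr$label_volume == tr$classes[["choroid_plexus"]]
  expect_equal(unique(tr$pv_map[cp]), 0.35)
  expect_equal(tr$true_flow_map[cp],
               tr$pv_map[cp] * spec$cp_actual_params$f, tolerance = 1e-12)
  csf <- tr$label_volume == tr$classes[["csf"]]
  expect_true(all(tr$true_flow_map[csf] == 0))
  expect_true(all(tr$true_flow_map[tr$label_volume == 0] == 0))
  # pv fraction 1 means pure choroid plexus voxels
  tr1 <- build_geometry(small_spec(cp_pv_fraction = 1))
  cp1 <- tr1$label_volume == 4
  expect_true(all(tr1$pv_map[cp1] == 1))
})

test_that("gray-matter probability map has a 0.5 rim excluded by the threshold", {
  tr <- build_geometry(small_spec())
  gm_all <- tr$label_volume == tr$classes[["gray_matter"]]
  expect_setequal(unique(as.vector(tr$gm_probability_map)), c(0, 0.5, 1))
  interior <- threshold_mask(tr$gm_probability_map, 0.5)
  expect_true(all(gm_all[interior]))          # mask is inside gray matter
  expect_lt(sum(interior), sum(gm_all))       # rim is excluded
  expect_identical(interior, tr$gm_probability_map == 1)
})

test_that("noiseless simulation is an exact inverse of the generator", {
  sim <- simulate_subject(small_spec(noise_sd = 0), sch, cst)
  tr <- sim$truth
  gm <- threshold_mask(tr$gm_probability_map, 0.5)
  cp <- tr$label_volume == tr$classes[["choroid_plexus"]]
  spec <- sim$spec
  gm_fit <- fit_roi(sim$delta_m, gm, sim$m0, cst, schedule = sch)
  expect_equal(gm_fit$params$f, spec$gm_params$f, tolerance = 1e-3)
  expect_equal(gm_fit$params$delta, spec$gm_params$delta, tolerance = 1e-3)
  expect_equal(gm_fit$params$T1, spec$gm_params$T1, tolerance = 1e-3)
  cp_fit <- fit_roi(sim$delta_m, cp, sim$m0, cst, schedule = sch)
  # apparent parameters: flow is pv * actual F, delta and T1 unchanged
  expect_equal(cp_fit$params$f,
               spec$cp_pv_fraction * spec$cp_actual_params$f,
               tolerance = 1e-3)
  expect_equal(cp_fit$params$T1, spec$cp_actual_params$T1, tolerance = 1e-3)
  # voxelwise on a choroid plexus sub-mask reproduces the truth flow map
  idx <- which(cp)[1:10]
  maps <- fit_voxelwise(sim$delta_m, idx, sim$m0, cst, schedule = sch)
  expect_equal(maps$flow_map[idx], tr$true_flow_map[idx],
               tolerance = 1e-3 * max(tr$true_flow_map[idx]))
})

test_that("analysis-side M0 calibration recovers the generating M0 exactly", {
  sim <- simulate_subject(small_spec(noise_sd = 0), sch, cst)
  gm <- threshold_mask(sim$truth$gm_probability_map, 0.5)
  m_pd <- mean(sim$pd[[1]][gm])
  expect_equal(compute_m0(m_pd, cst), sim$m0, tolerance = 1e-12)
})

test_that("mean apparent CP flow scales linearly with the pv fraction", {
  fits <- vapply(c(0.25, 0.5, 1), function(pv) {
    sim <- simulate_subject(small_spec(noise_sd = 0, cp_pv_fraction = pv),
                            sch, cst)
    cp <- sim$truth$label_volume == 4
    fit_roi(sim$delta_m, cp, sim$m0, cst, schedule = sch)$params$f
  }, numeric(1))
  F_actual <- 80
  expect_equal(fits, c(0.25, 0.5, 1) * F_actual,
               tolerance = 1e-3 * F_actual)
  # slope of apparent flow vs pv is the actual flow
  expect_equal((fits[3] - fits[1]) / 0.75, F_actual, tolerance = 0.1)
})

test_that("total_flow on the noiseless phantom equals the analytic value", {
  sim <- simulate_subject(small_spec(noise_sd = 0), sch, cst)
  cp <- sim$truth$label_volume == 4
  cstv <- acquisition_constants(voxel_volume = sim$voxel_volume_ml)
  fit <- fit_roi(sim$delta_m, cp, sim$m0, cstv, schedule = sch)
  F_meas <- total_flow(fit$params$f, sum(cp), cstv)
  F_true <- cstv$rho * sim$voxel_volume_ml * sum(sim$truth$true_flow_map[cp]) / 100
  expect_equal(F_meas, F_true, tolerance = 1e-3 * F_true)
})

test_that("noise is seeded and reproducible", {
  s1 <- simulate_subject(small_spec(noise_sd = 3e-4, seed = 7L), sch, cst)
  s2 <- simulate_subject(small_spec(noise_sd = 3e-4, seed = 7L), sch, cst)
  expect_identical(s1$delta_m, s2$delta_m)
  s3 <- simulate_subject(small_spec(noise_sd = 3e-4, seed = 8L), sch, cst)
  expect_false(identical(s1$delta_m[[1]], s3$delta_m[[1]]))
})

test_that("cohort generator honors cv = 0, determinism, and the target CV", {
  spec <- small_spec()
  c0 <- simulate_cohort(3, spec, between_subject_cv = 0, seed = 1,
                        schedule = sch, constants = cst)
  expect_equal(c0$truth_table$gm_f, rep(spec$gm_params$f, 3))
  expect_equal(c0$truth_table$cp_F_actual, rep(80, 3))
  ca <- simulate_cohort(2, spec, 0.25, seed = 5, schedule = sch, constants = cst)
  cb <- simulate_cohort(2, spec, 0.25, seed = 5, schedule = sch, constants = cst)
  expect_identical(ca$truth_table, cb$truth_table)
  expect_identical(ca$subjects[[1]]$delta_m, cb$subjects[[1]]$delta_m)
  # Monte-Carlo: empirical CV of drawn CP flows approaches the target
  # (many small cohorts; a cheap noiseless 24^3 grid, only the truth table
  # is used)
  draws <- unlist(lapply(1:100, function(s) {
    simulate_cohort(5, phantom_spec(grid_shape = c(24, 24, 24), noise_sd = 0),
                    0.25, seed = s, schedule = sch,
                    constants = cst)$truth_table$cp_F_actual
  }))
  cv_emp <- sd(draws) / mean(draws)
  expect_equal(cv_emp, 0.25, tolerance = 0.15)  # relative, ~6 sigma of n=500
  expect_equal(mean(draws), 80, tolerance = 0.05)
})
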