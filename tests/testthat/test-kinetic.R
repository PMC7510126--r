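cst <- acquisition_constants()

test_that("default schedule and constants carry the protocol values", {
  sch <- ot_schedule()
  expect_equal(nrow(sch), 12L)
  expect_equal(sch$tau, default_schedule_df()$tau)
  expect_equal(sch$w, default_schedule_df()$w)
  expect_equal(cst$alpha1 * cst$alpha2, 0.6)
  expect_error(ot_schedule(tau = c(1, -1), w = c(0.7, 0.7)), "row 2")
  expect_error(acquisition_constants(T1a = -1), "positive")
})

test_that("relative signal matches the scalar oracle and handles edges", {
  # frozen by hand evaluation of the closed form (subject-1 CP row at t12)
  p <- perfusion_params(39.73, 1.35, 2.45)
  expect_equal(asl_relative_signal(p, cst, tau = 4.0, w = 3.7),
               0.00264843310248, tolerance = 1e-10)
  # no-arrival and zero-flow regimes are exactly zero
  expect_identical(asl_relative_signal(perfusion_params(50, 1.3, 1.85), cst,
                                       tau = 1.0, w = 0.2), 0)
  expect_identical(asl_relative_signal(perfusion_params(0, 1.3, 1.85), cst,
                                       tau = 3, w = 1.5), 0)
  # oracle agreement over a parameter/OT grid
  set.seed(11)
  for (k in 1:25) {
    f <- runif(1, 0, 150); d <- runif(1, 0, 3); T1 <- runif(1, 1, 4)
    tau <- runif(1, 0.5, 4); w <- runif(1, 0, 4)
    expect_equal(
      asl_relative_signal(perfusion_params(f, d, T1), cst, tau, w),
      oracle_signal(f, d, T1, tau, w), tolerance = 1e-12)
  }
  expect_error(asl_relative_signal(p, cst, tau = -1, w = 0.7), "tau")
  expect_error(asl_relative_signal(p, cst, tau = 2, w = Inf), "finite")
  expect_error(asl_relative_signal(p, cst, tau = 2, w = -0.1), "w >= 0")
})

test_that("signal curve vectorizes the scalar model over the schedule", {
  sch <- ot_schedule()
  p <- perfusion_params(53.74, 1.31, 1.85)
  curve <- asl_signal_curve(p, cst, sch)
  scalar <- vapply(seq_len(nrow(sch)), function(i)
    oracle_signal(p$f, p$delta, p$T1, sch$tau[i], sch$w[i]), numeric(1))
  expect_equal(curve, scalar, tolerance = 1e-12)
  # inflow phase grows with tau; washout phase decays with w once w >= delta
  early <- asl_signal_curve(perfusion_params(50, 0.7, 1.85), cst, sch)
  expect_true(all(diff(early[1:6]) > 0))
  expect_true(all(diff(early[7:12]) < 0))
})

test_that("kinetic model invariants hold on a grid", {
  set.seed(3)
  for (k in 1:20) {
    f <- runif(1, 5, 200); d <- runif(1, 0.2, 3.5); T1 <- runif(1, 1, 4)
    tau <- runif(1, 0.5, 4); w <- runif(1, 0, 4)
    p <- perfusion_params(f, d, T1)
    # exact linearity in f
    kf <- runif(1, 0, 3)
    expect_equal(asl_relative_signal(perfusion_params(kf * f, d, T1), cst, tau, w),
                 kf * asl_relative_signal(p, cst, tau, w), tolerance = 1e-12)
    # zero in the no-arrival regime
    if (w + tau <= d) {
      expect_identical(asl_relative_signal(p, cst, tau, w), 0)
    }
    # mono-exponential washout for w >= delta
    if (w >= d) {
      h <- runif(1, 0.1, 1)
      s0 <- asl_relative_signal(p, cst, tau, w)
      s1 <- asl_relative_signal(p, cst, tau, w + h)
      expect_equal(s1 / s0, exp(-h / T1), tolerance = 1e-10)
    }
  }
})

test_that("M0 calibration matches hand evaluation and is homogeneous", {
  # frozen: 1000 / (0.9 * (1 - exp(-2/1.5)))
  expect_equal(compute_m0(1000, cst), 1508.83594921, tolerance = 1e-9)
  expect_gt(compute_m0(1000, cst), 1000 / cst$lambda_bbp)
  # Tsat -> Inf limit gives full recovery m_pd / lambda
  expect_equal(compute_m0(1000, acquisition_constants(Tsat = 1e6)),
               1000 / 0.9, tolerance = 1e-9)
  expect_equal(compute_m0(3000, cst), 3 * compute_m0(1000, cst))
  expect_error(compute_m0(0, cst), "positive")
  expect_error(compute_m0(-5, cst), "positive")
})

test_that("total flow matches per-voxel summation and is linear", {
  flows <- c(20, 40, 60)
  cst4 <- acquisition_constants(voxel_volume = 0.001)
  by_sum <- cst4$rho * cst4$voxel_volume * sum(flows) / 100
  expect_equal(total_flow(mean(flows), length(flows), cst4), by_sum,
               tolerance = 1e-12)
  expect_identical(total_flow(0, 10, cst), 0)
  expect_equal(total_flow(50, 20, cst), 2 * total_flow(50, 10, cst))
  expect_error(total_flow(50, 0, cst), "n_voxels")
})

test_that("weight correction reproduces the published arithmetic exactly", {
  expect_identical(weight_corrected_flow(0.80, 2, 0.5), 80)
  expect_identical(weight_corrected_flow(0, 2, 0.5), 0)
  expect_identical(weight_corrected_flow(1, 1, 1), 100)
  expect_error(weight_corrected_flow(0.8, 0, 0.5), "mass")
  expect_error(weight_corrected_flow(0.8, 2, 0), "fraction")
  expect_error(weight_corrected_flow(0.8, 2, 1.2), "fraction")
})
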