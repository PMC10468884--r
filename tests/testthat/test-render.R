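# Speckle renderer: perfusion-to-correlation-time mapping and both render
# modes against the single-exposure contrast theory.

# independent oracle: invert the closed-form K^2 by scalar root-finding
oracle_tau_for_k2 <- function(k2_target, exposure_time) {
  k2 <- function(tau) {
    x <- tau / exposure_time
    (x / 2) * (2 - x * (1 - exp(-2 / x)))
  }
  uniroot(function(tau) k2(tau) - k2_target,
          c(1e-9, 10), tol = 1e-14)$root
}

test_that("correlation time is capped at zero flow and strictly decreasing", {
  op <- optics_config()
  p <- c(0, 1, 5, 20, 50, 80, 100, 110)
  tau <- perfusion_to_correlation_time(p, op)
  expect_identical(tau[1], op$tau_cap)
  expect_true(all(diff(tau) < 0))
  expect_error(perfusion_to_correlation_time(-1, op), "0, 110")
  expect_error(perfusion_to_correlation_time(111, op), "0, 110")
})

test_that("correlation-time inversion matches scalar root-finding on K^2", {
  op <- optics_config()
  for (p in c(10, 25, 50, 75, 100)) {
    tau <- perfusion_to_correlation_time(p, op)
    # flow index is affine in p by construction; recover the implied K^2
    F0 <- 1 / speckle_contrast_theory(op$tau_cap, op$exposure_time)^2
    F100 <- 1 / op$k_full_flow^2
    k2_target <- 1 / (F0 + (F100 - F0) * p / 100)
    expect_equal(tau, oracle_tau_for_k2(k2_target, op$exposure_time),
                 tolerance = 0.001, info = paste("p =", p))
  }
})

test_that("rendered pixels recover their correlation time within 5 percent", {
  # round trip: render at perfusion p, estimate K over the region, invert
  # with the independent oracle, compare to tau_c(p)
  op <- optics_config()
  for (p in c(20, 60, 100)) {
    K_hat <- region_contrast(p, op, n_frames = 4, seed = 42)
    tau_hat <- oracle_tau_for_k2(K_hat^2, op$exposure_time)
    tau_true <- perfusion_to_correlation_time(p, op)
    expect_equal(tau_hat, tau_true, tolerance = 0.05, info = paste("p =", p))
  }
})

test_that("analytic-mode contrast tracks the closed form over a tau grid", {
  op <- optics_config()
  cal_p <- c(5, 20, 45, 70, 100) # five correlation times via the p mapping
  for (p in cal_p) {
    tau <- perfusion_to_correlation_time(p, op)
    K_theory <- speckle_contrast_theory(tau, op$exposure_time)
    K_hat <- region_contrast(p, op, n_frames = 4, seed = p + 1)
    expect_equal(K_hat, K_theory, tolerance = 0.05, info = paste("p =", p))
  }
})

test_that("dynamic-mode contrast matches theory and the analytic mode", {
  # correlation times several substeps long, where the AR(1) discretization
  # resolves the exposure integral (the renderer warns below that regime)
  op_dyn <- optics_config(mode = "dynamic", substeps_per_frame = 128)
  op_an <- optics_config()
  for (p in c(10, 30, 45)) {
    K_dyn <- region_contrast(p, op_dyn, n_frames = 2, seed = 7)
    tau <- perfusion_to_correlation_time(p, op_dyn)
    K_theory <- speckle_contrast_theory(tau, op_dyn$exposure_time)
    expect_equal(K_dyn, K_theory, tolerance = 0.05, info = paste("p =", p))
    K_an <- region_contrast(p, op_an, n_frames = 2, seed = 7)
    expect_lt(abs(K_dyn - K_an) / K_an, 0.10)
  }
})

test_that("static speckle has unit contrast and fast flow low contrast", {
  op_dyn <- optics_config(mode = "dynamic")
  # zero flow: fully developed quasi-static speckle, sigma/mu ~ 1
  K0 <- region_contrast(0, op_dyn, n_frames = 1, seed = 5, w = 7)
  expect_equal(K0, 1, tolerance = 0.08)
  # very fast flow: exposure averages many decorrelations, contrast is low;
  # tau_c here sits below the substep resolution, which the renderer warns
  # about
  expect_warning(K100 <- region_contrast(100, op_dyn, n_frames = 1, seed = 5),
                 "substeps")
  expect_lt(K100, 0.2)
})

test_that("mean frame intensity is independent of perfusion level", {
  op <- optics_config()
  mu <- vapply(c(0, 30, 70, 100), function(p) {
    v <- render_video(flat_scene(p), op, n_frames = 2, seed = 3)
    mean(v$frames)
  }, numeric(1))
  expect_true(all(abs(mu / op$mean_intensity - 1) < 0.05))
})

test_that("rendering is byte-identical under a fixed seed", {
  sc <- blocks_scene()
  for (mode in c("analytic", "dynamic")) {
    op <- optics_config(mode = mode)
    # dynamic mode warns that the fastest pixels are underresolved at the
    # default substep count; determinism holds regardless
    a <- suppressWarnings(render_video(sc, op, n_frames = 2, seed = 99))
    b <- suppressWarnings(render_video(sc, op, n_frames = 2, seed = 99))
    expect_identical(a$frames, b$frames)
  }
})

test_that("renderer validates inputs and stays within the bit depth", {
  sc <- flat_scene(50)
  expect_error(render_video(sc, optics_config(), n_frames = 0), "n_frames")
  expect_error(optics_config(exposure_time = 0.01, frame_rate = 120),
               "exposure_time")
  expect_error(optics_config(substeps_per_frame = 4), "substeps")
  v8 <- render_video(sc, optics_config(bit_depth = 8, mean_intensity = 40),
                     n_frames = 1, seed = 1)
  expect_true(all(v8$frames >= 0 & v8$frames <= 255))
  expect_true(is.integer(v8$frames))
})
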