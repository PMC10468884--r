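# Single-exposure speckle rendering. The device's proprietary processing is
# not public; a standard published single-exposure speckle-contrast model
# (Lorentzian velocity spectrum, exponential field correlation) stands in for
# it. Because RPU normalization is invariant to affine rescaling of the raw
# flow quantity, the substitution does not affect any relative readout.

#' Optics configuration for speckle rendering
#'
#' @param frame_rate frames per second (default 120, matching the emulated
#'   device).
#' @param exposure_time exposure per frame in seconds; must not exceed the
#'   frame period. Default 5 ms.
#' @param speckle_grain_px speckle grain size in pixels; the default 1.0
#'   reflects a ~1:1 pixel-to-speckle ratio.
#' @param bit_depth detector bit depth, 8 or 16.
#' @param mean_intensity mean detector counts per pixel; keep well below the
#'   bit-depth ceiling so the exponential intensity tail is not clipped.
#' @param mode `"analytic"` (per-pixel gamma-distributed integrated
#'   intensities; fast) or `"dynamic"` (explicit time-evolving complex
#'   speckle field; the physics reference).
#' @param substeps_per_frame temporal substeps per exposure in dynamic mode
#'   (>= 8).
#' @param read_noise_sd additive Gaussian detector read noise (counts;
#'   default 0, off).
#' @param tau_cap correlation time cap in seconds assigned to zero
#'   perfusion (quasi-static speckle).
#' @param k_full_flow speckle contrast at 100 percent perfusion; together
#'   with `tau_cap` this fixes the affine calibration between perfusion and
#'   the flow index 1/K^2.
#' @return A list of class `optics_config`.
#' @export
optics_config <- function(frame_rate = 120,
                          exposure_time = 0.005,
                          speckle_grain_px = 1.0,
                          bit_depth = 16,
                          mean_intensity = 3000,
                          mode = c("analytic", "dynamic"),
                          substeps_per_frame = 40L,
                          read_noise_sd = 0,
                          tau_cap = 1.0,
                          k_full_flow = 0.1) {
  mode <- match.arg(mode)
  assert_that(frame_rate > 0, "frame_rate must be positive")
  assert_that(exposure_time > 0 && exposure_time <= 1 / frame_rate,
              "exposure_time must be positive and at most the frame period 1/frame_rate")
  assert_that(bit_depth %in% c(8, 16), "bit_depth must be 8 or 16")
  assert_that(mean_intensity > 0 && mean_intensity < 2^bit_depth - 1,
              "mean_intensity must fit within the bit depth")
  assert_that(substeps_per_frame >= 8, "substeps_per_frame must be >= 8")
  assert_that(speckle_grain_px >= 1, "speckle_grain_px must be >= 1")
  assert_that(tau_cap > exposure_time, "tau_cap must exceed the exposure time")
  assert_that(k_full_flow > 0 && k_full_flow < 1, "k_full_flow must be in (0, 1)")
  structure(list(frame_rate = frame_rate, exposure_time = exposure_time,
                 speckle_grain_px = speckle_grain_px, bit_depth = bit_depth,
                 mean_intensity = mean_intensity, mode = mode,
                 substeps_per_frame = as.integer(substeps_per_frame),
                 read_noise_sd = read_noise_sd, tau_cap = tau_cap,
                 k_full_flow = k_full_flow),
            class = "optics_config")
}

#' Theoretical single-exposure speckle contrast
#'
#' The closed-form spatial contrast of fully developed speckle integrated
#' over an exposure `T`, for a field with exponential correlation of time
#' constant `tau_c` (Lorentzian velocity spectrum):
#' `K^2 = (x/2) * (2 - x * (1 - exp(-2/x)))` with `x = tau_c / T`.
#' `K` approaches 1 for quasi-static speckle (`tau_c >> T`) and 0 for fast
#' flow (`tau_c << T`).
#'
#' @param tau_c correlation time(s) in seconds.
#' @param exposure_time exposure in seconds.
#' @return Speckle contrast `K` (same length as `tau_c`).
#' @export
speckle_contrast_theory <- function(tau_c, exposure_time) {
  assert_that(all(tau_c >= 0) && exposure_time > 0,
              "tau_c must be >= 0 and exposure_time > 0")
  sqrt(.k2_lorentzian(tau_c / exposure_time))
}

# K^2 as a function of x = tau_c / T; monotone increasing, -> 1 as x -> Inf
.k2_lorentzian <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  xp <- x[pos]
  out[pos] <- (xp / 2) * (2 - xp * (1 - exp(-2 / xp)))
  tiny <- pos & x < 1e-10
  out[tiny] <- x[tiny] # series limit K^2 ~ x - x^2/2
  out
}

# Affine flow-index calibration implied by an optics config: perfusion p in
# [0, 110] maps to flow index F(p) = F0 + (F100 - F0) p / 100, where F0 is
# the flow index of quasi-static speckle (tau_cap) and F100 that of contrast
# k_full_flow. Returns interpolators between p, K^2 and x = tau_c / T.
.flow_calibration <- function(optics) {
  Tt <- optics$exposure_time
  x_cap <- optics$tau_cap / Tt
  k2_full <- optics$k_full_flow^2
  x_full <- uniroot(function(x) .k2_lorentzian(x) - k2_full,
                    c(1e-8, x_cap), tol = 1e-12)$root
  F0 <- 1 / .k2_lorentzian(x_cap)
  F100 <- 1 / k2_full
  # grid covers p up to 110 (flow index beyond F100) with margin
  k2_lo <- 1 / (F0 + (F100 - F0) * 1.2)
  x_lo <- uniroot(function(x) .k2_lorentzian(x) - k2_lo,
                  c(1e-9, x_full), tol = 1e-12)$root
  xs <- exp(seq(log(x_lo), log(x_cap), length.out = 4000))
  k2s <- .k2_lorentzian(xs)
  list(exposure_time = Tt, F0 = F0, F100 = F100, x_cap = x_cap,
       log_xs = log(xs), log_k2s = log(k2s))
}

.p_to_k2 <- function(p, cal) {
  Fi <- cal$F0 + (cal$F100 - cal$F0) * p / 100
  1 / Fi
}

.k2_to_x <- function(k2, cal) {
  x <- exp(approx(cal$log_k2s, cal$log_xs, xout = log(k2), rule = 2)$y)
  pmin(x, cal$x_cap)
}

#' Map perfusion to speckle correlation time
#'
#' Inverts the single-exposure contrast model so that the flow index
#' `1/K^2` is affine in ground-truth perfusion: 0 percent maps to the
#' quasi-static cap `tau_cap` and 100 percent to the correlation time whose
#' contrast is `k_full_flow`. Strictly decreasing in perfusion.
#'
#' @param p perfusion in percent, within `[0, 110]`; vectorized.
#' @param optics an [optics_config()].
#' @return Correlation times in seconds.
#' @export
perfusion_to_correlation_time <- function(p, optics = optics_config()) {
  assert_that(inherits(optics, "optics_config"), "optics must be an optics_config")
  assert_that(all(is.finite(p)) && all(p >= 0 & p <= 110),
              "perfusion must lie in [0, 110] percent")
  cal <- .flow_calibration(optics)
  x <- .k2_to_x(.p_to_k2(p, cal), cal)
  out <- x * optics$exposure_time
  out[p == 0] <- optics$tau_cap
  out
}

# spatially correlated complex-noise component for speckle grain > 1 px:
# box-smoothed white noise renormalized to unit variance
.grain_noise <- function(n1, n2, grain) {
  z <- matrix(rnorm(n1 * n2), n1, n2)
  if (grain <= 1) return(z)
  w <- 2L * as.integer(ceiling((grain - 1) / 2)) + 1L
  s <- box_mean(z, w)
  s / sqrt(mean(s^2))
}

#' Render a speckle video from a perfusion scene
#'
#' In `analytic` mode each pixel's integrated intensity is drawn from a
#' gamma distribution with mean `mean_intensity` and coefficient of
#' variation equal to the theoretical contrast `K(tau_c(p), T)` (the gamma
#' shape `1/K^2` plays the role of effective degrees of freedom). In
#' `dynamic` mode a complex speckle field evolves per substep as a
#' first-order autoregressive process with correlation `exp(-dt/tau_c)`;
#' fully developed speckle intensities (negative-exponential) are averaged
#' over the exposure window to form each frame, and the field decorrelates
#' through the dead time between exposures. Off-mask pixels carry
#' zero perfusion and render as quasi-static speckle.
#'
#' Identical `seed` (and inputs) produces a byte-identical video.
#'
#' @param scene a [perfusion_scene()].
#' @param optics an [optics_config()].
#' @param n_frames number of frames (>= 1).
#' @param seed integer RNG seed.
#' @return An object of class `speckle_video`: list with `frames` (integer
#'   array rows x cols x n_frames, detector counts), `optics`, `scene_id`,
#'   `seed`.
#' @export
render_video <- function(scene, optics = optics_config(), n_frames = 5,
                         seed = 1L) {
  assert_that(inherits(scene, "perfusion_scene"), "scene must be a perfusion_scene")
  assert_that(inherits(optics, "optics_config"), "optics must be an optics_config")
  assert_that(n_frames >= 1, "n_frames must be >= 1")
  set.seed(as.integer(seed))
  cal <- .flow_calibration(optics)
  p <- scene$field
  k2 <- .p_to_k2(p, cal)
  n1 <- nrow(p); n2 <- ncol(p); npx <- n1 * n2
  vmax <- 2^optics$bit_depth - 1
  mu <- optics$mean_intensity

  frames <- array(0L, dim = c(n1, n2, n_frames))
  if (optics$mode == "analytic") {
    shape <- 1 / k2
    for (f in seq_len(n_frames)) {
      I <- rgamma(npx, shape = shape, scale = mu / shape)
      if (optics$read_noise_sd > 0) I <- I + rnorm(npx, 0, optics$read_noise_sd)
      frames[, , f] <- as.integer(round(pmin(pmax(I, 0), vmax)))
    }
  } else {
    ns <- optics$substeps_per_frame
    dt <- optics$exposure_time / ns
    x <- .k2_to_x(k2, cal)
    tau <- x * optics$exposure_time
    if (min(tau) < 2 * dt)
      warning("shortest correlation time (", signif(min(tau), 3),
              " s) is under 2 substeps; dynamic-mode contrast will be ",
              "underresolved -- increase substeps_per_frame", call. = FALSE)
    rho <- exp(-dt / tau)
    gap <- 1 / optics$frame_rate - optics$exposure_time
    rho_gap <- exp(-gap / tau)
    g <- optics$speckle_grain_px
    Er <- .grain_noise(n1, n2, g); Ei <- .grain_noise(n1, n2, g)
    step <- function(E, rho) rho * E + sqrt(1 - rho^2) * .grain_noise(n1, n2, g)
    for (f in seq_len(n_frames)) {
      acc <- matrix(0, n1, n2)
      for (s in seq_len(ns)) {
        acc <- acc + (Er^2 + Ei^2) / 2
        Er <- step(Er, rho); Ei <- step(Ei, rho)
      }
      I <- acc / ns * mu
      if (optics$read_noise_sd > 0) I <- I + rnorm(npx, 0, optics$read_noise_sd)
      frames[, , f] <- as.integer(round(pmin(pmax(I, 0), vmax)))
      if (gap > 0) { Er <- step(Er, rho_gap); Ei <- step(Ei, rho_gap) }
    }
  }
  structure(list(frames = frames, optics = optics, scene_id = scene$scene_id,
                 seed = as.integer(seed)),
            class = "speckle_video")
}

#' @export
print.speckle_video <- function(x, ...) {
  d <- dim(x$frames)
  cat("<speckle_video '", x$scene_id, "'> ", d[1], " x ", d[2], " px, ",
      d[3], " frame(s), ", x$optics$bit_depth, "-bit, ",
      x$optics$mode, " mode, seed ", x$seed, "\n", sep = "")
  invisible(x)
}
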