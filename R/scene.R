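# Synthetic perfusion scenes: ground-truth fields, arcs and landmarks for the
# three porcine bowel experiments (ischemic gradient, occlusion series,
# paired side-to-side anastomoses).

#' Construct a perfusion scene
#'
#' A perfusion scene is the ground truth the imaging pipeline is asked to
#' recover: a per-pixel perfusion field on a 0--100 percent scale, a tissue
#' mask, a physical scale, named arcs (polylines along which profiles are
#' measured) and named landmarks (reference points such as the stapled bowel
#' edge or the Hot/Cold reference centers).
#'
#' @param field numeric matrix of ground-truth perfusion (percent, 0--110;
#'   values above 100 are permitted for locally hyperperfused tissue).
#' @param mask logical matrix, `TRUE` on tissue. Must be `TRUE` wherever
#'   `field > 0`.
#' @param px_per_cm spatial scale, pixels per centimetre (> 0).
#' @param arcs named list of polylines; each a data.frame with columns
#'   `row`, `col` (pixel coordinates, 1-based). Distance along an arc is
#'   measured in cm from its first vertex.
#' @param landmarks named list of length-2 numeric vectors `c(row, col)`.
#' @param scene_id character tag carried into rendered videos.
#' @return An object of class `perfusion_scene`.
#' @export
perfusion_scene <- function(field, mask = field > 0, px_per_cm = 20,
                            arcs = list(), landmarks = list(),
                            scene_id = "scene") {
  assert_that(is.matrix(field) && is.numeric(field), "field must be a numeric matrix")
  assert_that(all(is.finite(field)), "field must be finite")
  assert_that(all(field >= 0 & field <= 110),
              "field values must lie in [0, 110] percent")
  assert_that(is.matrix(mask) && is.logical(mask) && all(dim(mask) == dim(field)),
              "mask must be a logical matrix matching field")
  assert_that(all(mask[field > 0]), "mask must be TRUE wherever field > 0")
  assert_that(is.numeric(px_per_cm) && length(px_per_cm) == 1 && px_per_cm > 0,
              "px_per_cm must be a positive scalar")
  for (nm in names(arcs)) {
    a <- arcs[[nm]]
    assert_that(is.data.frame(a) && all(c("row", "col") %in% names(a)),
                "arc '", nm, "' must be a data.frame with row/col columns")
    ij <- cbind(round(a$row), round(a$col))
    assert_that(all(ij[, 1] >= 1 & ij[, 1] <= nrow(field) &
                    ij[, 2] >= 1 & ij[, 2] <= ncol(field)),
                "arc '", nm, "' leaves the grid")
    assert_that(all(mask[ij]), "arc '", nm, "' leaves the tissue mask")
  }
  structure(list(field = field, mask = mask, px_per_cm = px_per_cm,
                 arcs = arcs, landmarks = landmarks, scene_id = scene_id),
            class = "perfusion_scene")
}

#' @export
print.perfusion_scene <- function(x, ...) {
  cat("<perfusion_scene '", x$scene_id, "'> ", nrow(x$field), " x ",
      ncol(x$field), " px (", round(nrow(x$field) / x$px_per_cm, 1), " x ",
      round(ncol(x$field) / x$px_per_cm, 1), " cm)\n", sep = "")
  cat("  perfusion range:", paste(round(range(x$field[x$mask]), 1), collapse = " - "),
      "% on tissue\n")
  cat("  arcs:", paste(names(x$arcs), collapse = ", "), "\n")
  cat("  landmarks:", paste(names(x$landmarks), collapse = ", "), "\n")
  invisible(x)
}

#' Gradient scene configuration
#'
#' Parameters of the partially devascularized bowel-loop scene: a 10 cm bowel
#' band with a perfused plateau distally, a gentle decline into the watershed
#' zone, a slope break (sharp decline) at `decline_onset_cm`, and an ischemic
#' zone near the stapled edge. The mesenteric border runs hyperperfused
#' relative to the antimesenteric border by `arc_offset` percent in the
#' perfused zone.
#'
#' The default levels are the calibration targets of the porcine experiments
#' this scene emulates: perfused plateau 98.8, watershed 78.3, ischemic 1.9
#' (percent), with decline onset 5 cm and devascularization margin 4 cm from
#' the stapled edge, and a mesenteric-antimesenteric arc difference of 16.6
#' points split asymmetrically so the mesenteric arc sits at 100 and the
#' antimesenteric at 83.4 in the perfused segment while the bowel centerline
#' stays at the plateau level.
#'
#' @param plateau_level,watershed_level,ischemic_level segment perfusion
#'   levels in percent; must satisfy
#'   `0 <= ischemic < watershed < plateau <= 105`.
#' @param decline_onset_cm distance (cm from the stapled edge) at which the
#'   sharp decline begins; in (0, 10).
#' @param devasc_margin_cm devascularization margin landmark (cm).
#' @param arc_offset mesenteric minus antimesenteric perfusion difference
#'   (percent) in the perfused zone.
#' @param arc_offset_split fraction of `arc_offset` placed above the
#'   centerline level (mesenteric side); the remainder is subtracted on the
#'   antimesenteric side.
#' @param length_cm,band_width_cm,margin_cm geometry of the bowel band and
#'   the background margin around it (cm).
#' @param px_per_cm pixels per cm.
#' @param seed integer; scenes are deterministic, the seed is recorded for
#'   provenance of downstream rendering.
#' @return A validated list of class `gradient_scene_config`.
#' @export
gradient_scene_config <- function(plateau_level = 98.8,
                                  watershed_level = 78.3,
                                  ischemic_level = 1.9,
                                  decline_onset_cm = 5,
                                  devasc_margin_cm = 4,
                                  arc_offset = 16.6,
                                  arc_offset_split = 1.2 / 16.6,
                                  length_cm = 10,
                                  band_width_cm = 4,
                                  margin_cm = 1.5,
                                  px_per_cm = 20,
                                  seed = 1L) {
  cfg <- list(plateau_level = plateau_level, watershed_level = watershed_level,
              ischemic_level = ischemic_level,
              decline_onset_cm = decline_onset_cm,
              devasc_margin_cm = devasc_margin_cm,
              arc_offset = arc_offset, arc_offset_split = arc_offset_split,
              length_cm = length_cm, band_width_cm = band_width_cm,
              margin_cm = margin_cm, px_per_cm = px_per_cm,
              seed = as.integer(seed))
  assert_that(ischemic_level >= 0 && ischemic_level < watershed_level &&
              watershed_level < plateau_level && plateau_level <= 105,
              "levels must satisfy 0 <= ischemic < watershed < plateau <= 105")
  assert_that(decline_onset_cm > 0 && decline_onset_cm < length_cm,
              "decline_onset_cm must lie inside the bowel length")
  assert_that(arc_offset >= 0 && arc_offset_split >= 0 && arc_offset_split <= 1,
              "arc_offset must be >= 0 and arc_offset_split in [0, 1]")
  assert_that(px_per_cm > 0 && band_width_cm > 0 && margin_cm > 0,
              "geometry parameters must be positive")
  class(cfg) <- "gradient_scene_config"
  cfg
}

# Axial ground-truth profile v(d): ischemic plateau below 2 cm, steep linear
# rise to the slope break at `onset`, gentle linear rise reaching the perfused
# plateau at 8 cm. `s1` is the gentle (distal) slope in percent per cm.
.axial_profile <- function(d, s1, P, I, onset) {
  v_on <- P - s1 * (8 - onset)
  s2 <- (v_on - I) / (onset - 2)
  v <- ifelse(d >= 8, P,
       ifelse(d >= onset, P - s1 * (8 - d),
       ifelse(d >= 2, v_on - s2 * (onset - d), I)))
  v
}

# Solve the gentle slope so the sampled watershed-segment mean (0.5 cm ROI
# spacing over 4-6 cm, matching the default profile sampling) equals the
# configured watershed level.
.solve_gentle_slope <- function(P, W, I, onset) {
  dd <- seq(4, 6, by = 0.5)
  f <- function(s1) mean(.axial_profile(dd, s1, P, I, onset)) - W
  s_max <- (P - I) / (8 - onset) # gentle slope at which the steep piece vanishes
  assert_that(f(1e-9) > 0 && f(s_max * (1 - 1e-9)) < 0,
              "watershed_level is not attainable for this level/onset geometry")
  uniroot(f, c(1e-9, s_max * (1 - 1e-9)), tol = 1e-10)$root
}

#' Build the ischemic bowel-gradient scene
#'
#' Constructs a rectangular bowel band whose perfusion along the bowel axis is
#' piecewise linear: constant at `ischemic_level` within 2 cm of the stapled
#' edge, a steep rise up to `decline_onset_cm`, a gentle rise reaching
#' `plateau_level` at 8 cm, and constant beyond. The gentle slope is solved so
#' that the watershed-segment mean (ROIs at 0.5 cm spacing over 4--6 cm)
#' equals `watershed_level` exactly in ground truth. Across the bowel the
#' mesenteric arc is offset upwards and the antimesenteric arc downwards; the
#' offsets are constant in a band around each arc (so a region of interest
#' centred on an arc sees a uniform level), taper linearly to zero between
#' 2 cm and the decline onset, and vanish in the ischemic zone.
#'
#' Landmarks include `stapled_edge` (0 cm), `devasc_margin`, `hot_ref` (on the
#' mesenteric arc at 9 cm, the maximally perfused point) and `cold_ref` (on
#' the avascular background beyond the stapled edge, zero flow).
#'
#' @param cfg a [gradient_scene_config()].
#' @return A [perfusion_scene()] with arcs `centerline`, `mesenteric`,
#'   `antimesenteric`.
#' @export
build_gradient_scene <- function(cfg = gradient_scene_config()) {
  assert_that(inherits(cfg, "gradient_scene_config"),
              "cfg must be a gradient_scene_config")
  ppc <- cfg$px_per_cm
  px <- function(cm) as.integer(round(cm * ppc))
  m_px <- px(cfg$margin_cm)
  len_px <- px(cfg$length_cm)
  wid_px <- px(cfg$band_width_cm)
  n_rows <- wid_px + 2L * m_px + 1L
  n_cols <- len_px + 2L * m_px + 1L
  top <- m_px + 1L            # first tissue row
  bot <- top + wid_px         # last tissue row
  x0 <- m_px + 1L             # column of the stapled edge (d = 0)

  row_mes <- top + px(0.75)   # arcs 0.75 cm inside the band edges
  row_am  <- bot - px(0.75)
  row_mid <- as.integer(round((row_mes + row_am) / 2))

  s1 <- .solve_gentle_slope(cfg$plateau_level, cfg$watershed_level,
                            cfg$ischemic_level, cfg$decline_onset_cm)
  d_cm <- (seq_len(n_cols) - x0) / ppc
  v <- .axial_profile(pmax(d_cm, 0), s1, cfg$plateau_level,
                      cfg$ischemic_level, cfg$decline_onset_cm)
  # arc-offset taper: full beyond the decline onset, zero in the ischemic zone
  taper <- pmin(pmax((d_cm - 2) / (cfg$decline_onset_cm - 2), 0), 1)

  u_m  <- cfg$arc_offset * cfg$arc_offset_split        # above centerline
  u_am <- cfg$arc_offset * (1 - cfg$arc_offset_split)  # below centerline
  # cross-bowel offset: flat around each arc and around the centerline so
  # ROI disks (radius ~0.5 cm) sample a uniform level, with short ramps
  flat <- px(0.5)
  knots_r <- c(top, row_mes + flat, row_mid - flat, row_mid + flat,
               row_am - flat, bot)
  knots_v <- c(u_m, u_m, 0, 0, -u_am, -u_am)
  cross <- approx(knots_r, knots_v, xout = seq_len(n_rows), rule = 2)$y

  field <- matrix(0, n_rows, n_cols)
  rows_t <- top:bot
  # the bowel continues distally beyond the 10 cm measurement span; a short
  # overhang keeps regions sampled at the distal end on tissue
  over_px <- min(px(0.75), n_cols - (x0 + len_px))
  cols_t <- x0:(x0 + len_px + over_px)
  ax <- v[cols_t] # axial level on tissue columns
  tp <- taper[cols_t]
  field[rows_t, cols_t] <- outer(cross[rows_t], tp) +
    matrix(ax, length(rows_t), length(cols_t), byrow = TRUE)
  field[rows_t, cols_t] <- pmin(pmax(field[rows_t, cols_t], 0), 110)
  mask <- matrix(FALSE, n_rows, n_cols)
  mask[rows_t, cols_t] <- TRUE

  arc_df <- function(r) data.frame(row = c(r, r), col = c(x0, x0 + len_px))
  arcs <- list(centerline = arc_df(row_mid),
               mesenteric = arc_df(row_mes),
               antimesenteric = arc_df(row_am))
  landmarks <- list(
    stapled_edge = c(row_mid, x0),
    devasc_margin = c(row_mid, x0 + px(cfg$devasc_margin_cm)),
    hot_ref = c(row_mes, x0 + px(9)),
    cold_ref = c(row_mid, x0 - px(0.75)))

  sc <- perfusion_scene(field, mask, ppc, arcs, landmarks,
                        scene_id = "gradient")
  sc$config <- cfg
  sc
}

#' Occlusion configuration
#'
#' Parameters of the progressive-occlusion simulation: mean arterial pressure
#' (MAP) falls linearly with occlusion fraction from `map_baseline` to
#' `map_floor`, and the global perfusion scale factor is linear in MAP with
#' additive Gaussian noise. Venous outflow occlusion is modelled as more
#' pressure-sensitive than arterial inflow occlusion: complete venous
#' occlusion abolishes perfusion after only a modest MAP drop, so the
#' venous slope (perfusion scale per mmHg) is steeper.
#'
#' MAP values are simulation conventions, not measured data: the baseline of
#' 65 mmHg and the kind-specific floors (20 mmHg arterial, 45 mmHg venous)
#' are configurable placeholders on a physiologically plausible scale.
#'
#' @param kind `"arterial"` or `"venous"`.
#' @param map_baseline baseline MAP in mmHg (occlusion fraction 0).
#' @param map_floor MAP at complete occlusion; defaults to 20 (arterial) or
#'   45 (venous) mmHg.
#' @param scale_at_full perfusion scale factor at complete occlusion
#'   (must be <= 0.05).
#' @param noise_sd standard deviation of the Gaussian noise added to the
#'   scale factor at interior steps (scale units; 0.10 corresponds to 10
#'   RPU points on a fully perfused segment). The default was calibrated so
#'   that the MAP-perfusion regression of a default 10-step schedule has a
#'   median R-squared of about 0.96 across seeds (see
#'   `scripts/calibrate_occlusion_noise.R`).
#' @param seed integer seed for the noise draws.
#' @return A list of class `occlusion_config`.
#' @export
occlusion_config <- function(kind = c("arterial", "venous"),
                             map_baseline = 65,
                             map_floor = NULL,
                             scale_at_full = 0.02,
                             noise_sd = 0.10,
                             seed = 1L) {
  kind <- match.arg(kind)
  map_floor <- map_floor %||% switch(kind, arterial = 20, venous = 45)
  assert_that(map_floor < map_baseline, "map_floor must be below map_baseline")
  assert_that(scale_at_full >= 0 && scale_at_full <= 0.05,
              "scale_at_full must lie in [0, 0.05]")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  structure(list(kind = kind, map_baseline = map_baseline,
                 map_floor = map_floor, scale_at_full = scale_at_full,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "occlusion_config")
}

#' Build a progressive occlusion schedule
#'
#' Generates `n_steps` occlusion states from fraction 0 (baseline) to 1
#' (complete occlusion). MAP decreases strictly linearly; the global
#' perfusion scale factor is linear in MAP plus Gaussian noise at interior
#' steps, clamped to `[0, 1]`, forced to 1 at baseline and to at most
#' `scale_at_full` at complete occlusion, and made non-increasing (a running
#' minimum), reflecting that progressive clamping never restores flow.
#'
#' @param kind `"arterial"` or `"venous"`; must match `cfg$kind` if both given.
#' @param n_steps number of occlusion steps (>= 3).
#' @param cfg an [occlusion_config()].
#' @return A data.frame of class `occlusion_schedule` with columns
#'   `occlusion_fraction`, `map_mmHg`, `scale`; attributes `kind`,
#'   `sensitivity` (scale-per-mmHg slope of the noiseless model) and
#'   `noise_sd`.
#' @export
build_occlusion_schedule <- function(kind = c("arterial", "venous"),
                                     n_steps = 10,
                                     cfg = occlusion_config(kind)) {
  kind <- match.arg(kind)
  assert_that(inherits(cfg, "occlusion_config"), "cfg must be an occlusion_config")
  assert_that(identical(cfg$kind, kind),
              "cfg$kind ('", cfg$kind, "') does not match kind ('", kind, "')")
  assert_that(n_steps >= 3, "n_steps must be >= 3")
  frac <- seq(0, 1, length.out = n_steps)
  map <- cfg$map_baseline + frac * (cfg$map_floor - cfg$map_baseline)
  sensitivity <- (1 - cfg$scale_at_full) / (cfg$map_baseline - cfg$map_floor)
  scale_clean <- cfg$scale_at_full + sensitivity * (map - cfg$map_floor)
  set.seed(cfg$seed)
  noise <- rnorm(n_steps, 0, cfg$noise_sd)
  noise[c(1, n_steps)] <- 0 # endpoints pinned: baseline 1, full occlusion floor
  scale <- pmin(pmax(scale_clean + noise, 0), 1)
  scale <- cummin(scale)
  out <- data.frame(occlusion_fraction = frac, map_mmHg = map, scale = scale)
  structure(out, kind = kind, sensitivity = sensitivity,
            noise_sd = cfg$noise_sd, config = cfg,
            class = c("occlusion_schedule", "data.frame"))
}

#' Anastomosis scene configuration
#'
#' Ground-truth perfusion profiles for two side-to-side small-bowel
#' anastomoses measured at 10 matched points spanning 0--4.5 cm. The
#' antimesenteric (AM) anastomosis must exceed the mesenteric (M) one at
#' every matched point; both profiles decline from proximal to distal.
#' The default profiles are linear declines calibrated so the AM profile has
#' mean 54 with SD 18 and the M profile mean 38 with SD 15 (percent).
#'
#' @param am_profile,m_profile numeric length-10 perfusion profiles (percent).
#' @param length_cm span of the 10 matched points (cm).
#' @param band_width_cm width of each anastomosis band (cm).
#' @param gap_cm background gap between the two bands (cm).
#' @param margin_cm background margin (cm).
#' @param px_per_cm pixels per cm.
#' @param seed integer, recorded for downstream rendering provenance.
#' @return A list of class `anastomosis_scene_config`.
#' @export
anastomosis_scene_config <- function(am_profile = seq(82.2, 25.8, length.out = 10),
                                     m_profile = seq(61.5, 14.5, length.out = 10),
                                     length_cm = 4.5,
                                     band_width_cm = 1.5,
                                     gap_cm = 2,
                                     margin_cm = 1.5,
                                     px_per_cm = 20,
                                     seed = 1L) {
  assert_that(length(am_profile) == 10 && length(m_profile) == 10,
              "profiles must have exactly 10 matched points")
  assert_that(all(am_profile > m_profile),
              "AM profile must exceed the M profile at every matched point")
  assert_that(all(diff(am_profile) <= 0) && all(diff(m_profile) <= 0),
              "profiles must decline from proximal (0 cm) to distal")
  assert_that(all(c(am_profile, m_profile) >= 0 & c(am_profile, m_profile) <= 110),
              "profile values must lie in [0, 110]")
  structure(list(am_profile = am_profile, m_profile = m_profile,
                 length_cm = length_cm, band_width_cm = band_width_cm,
                 gap_cm = gap_cm, margin_cm = margin_cm,
                 px_per_cm = px_per_cm, seed = as.integer(seed)),
            class = "anastomosis_scene_config")
}

#' Build the paired-anastomosis scene
#'
#' Two parallel tissue bands (antimesenteric anastomosis on top, mesenteric
#' below) whose perfusion varies along their length by linear interpolation
#' of the 10 configured point values; perfusion is constant across each
#' band's width. A maximally perfused reference patch (`hot_ref`, 100
#' percent, the analogue of a surface capillary) sits in the left margin
#' between the bands and the `cold_ref` landmark sits on avascular
#' background in the right margin.
#'
#' @param cfg an [anastomosis_scene_config()].
#' @return A [perfusion_scene()] with arcs `anastomosis_AM`, `anastomosis_M`
#'   and attribute `sample_points_cm` giving the 10 matched distances.
#' @export
build_anastomosis_scene <- function(cfg = anastomosis_scene_config()) {
  assert_that(inherits(cfg, "anastomosis_scene_config"),
              "cfg must be an anastomosis_scene_config")
  ppc <- cfg$px_per_cm
  px <- function(cm) as.integer(round(cm * ppc))
  m_px <- px(cfg$margin_cm)
  len_px <- px(cfg$length_cm)
  wid_px <- px(cfg$band_width_cm)
  gap_px <- px(cfg$gap_cm)
  n_rows <- 2L * wid_px + gap_px + 2L * m_px + 2L
  n_cols <- len_px + 2L * m_px + 1L
  x0 <- m_px + 1L

  top_am <- m_px + 1L
  bot_am <- top_am + wid_px
  top_m <- bot_am + gap_px
  bot_m <- top_m + wid_px
  row_am <- as.integer(round((top_am + bot_am) / 2))
  row_m <- as.integer(round((top_m + bot_m) / 2))

  d_pts <- seq(0, cfg$length_cm, length.out = 10)
  # bands overhang the measured span on both sides (the bowel loops
  # continue) so endpoint regions stay on tissue; profile values extend
  # flat beyond the first/last matched point
  over_px <- min(px(0.75), m_px %/% 2L)
  cols_t <- (x0 - over_px):(x0 + len_px + over_px)
  d_cm <- (cols_t - x0) / ppc
  am_v <- approx(d_pts, cfg$am_profile, xout = d_cm, rule = 2)$y
  m_v <- approx(d_pts, cfg$m_profile, xout = d_cm, rule = 2)$y

  field <- matrix(0, n_rows, n_cols)
  field[top_am:bot_am, cols_t] <-
    matrix(am_v, bot_am - top_am + 1L, length(cols_t), byrow = TRUE)
  field[top_m:bot_m, cols_t] <-
    matrix(m_v, bot_m - top_m + 1L, length(cols_t), byrow = TRUE)

  # maximally perfused reference patch in the left margin, between the bands
  hot_r <- as.integer(round((bot_am + top_m) / 2))
  hot_c <- as.integer(round(m_px / 2))
  half <- px(0.7)
  field[(hot_r - half):(hot_r + half), max(1L, hot_c - half):(hot_c + half)] <- 100

  mask <- field > 0
  arcs <- list(
    anastomosis_AM = data.frame(row = c(row_am, row_am),
                                col = c(x0, x0 + len_px)),
    anastomosis_M = data.frame(row = c(row_m, row_m),
                               col = c(x0, x0 + len_px)))
  # cold reference on avascular background in the top-right corner, clear
  # of the band overhangs
  landmarks <- list(
    proximal_edge = c(row_am, x0),
    hot_ref = c(hot_r, hot_c),
    cold_ref = c(as.integer(round(m_px / 2)),
                 n_cols - as.integer(round(m_px / 2))))

  sc <- perfusion_scene(field, mask, ppc, arcs, landmarks,
                        scene_id = "anastomosis")
  sc$config <- cfg
  attr(sc, "sample_points_cm") <- d_pts
  sc
}

#' Scale a scene's perfusion field
#'
#' Multiplies the ground-truth field by a global factor (the occlusion scale
#' factor), leaving mask, arcs and landmarks untouched. Used to image the
#' same scene under progressive occlusion.
#'
#' @param scene a [perfusion_scene()].
#' @param scale factor in `[0, 1]`.
#' @return The scaled `perfusion_scene`.
#' @export
scale_scene <- function(scene, scale) {
  assert_that(inherits(scene, "perfusion_scene"), "scene must be a perfusion_scene")
  assert_that(is.numeric(scale) && length(scale) == 1 && scale >= 0 && scale <= 1,
              "scale must be a scalar in [0, 1]")
  scene$field <- scene$field * scale
  scene
}

# -- arc geometry -----------------------------------------------------------

.arc_lookup <- function(scene, arc) {
  assert_that(inherits(scene, "perfusion_scene"), "scene must be a perfusion_scene")
  a <- scene$arcs[[arc]]
  assert_that(!is.null(a), "unknown arc '", arc, "'")
  seg <- sqrt(diff(a$row)^2 + diff(a$col)^2)
  list(poly = a, d_cm = c(0, cumsum(seg)) / scene$px_per_cm)
}

#' Locate a point at a given distance along an arc
#'
#' Distances are measured in cm along the polyline from its first vertex
#' (for bowel arcs, the stapled-edge end).
#'
#' @param scene a [perfusion_scene()].
#' @param arc arc name.
#' @param distance_cm distances along the arc (cm); vectorized.
#' @return A data.frame with columns `distance_cm`, `row`, `col`
#'   (fractional pixel coordinates).
#' @export
arc_point <- function(scene, arc, distance_cm) {
  al <- .arc_lookup(scene, arc)
  assert_that(all(distance_cm >= 0 & distance_cm <= max(al$d_cm) + 1e-9),
              "distance_cm outside arc '", arc, "' (0 to ",
              round(max(al$d_cm), 2), " cm)")
  r <- approx(al$d_cm, al$poly$row, xout = distance_cm, rule = 2)$y
  c_ <- approx(al$d_cm, al$poly$col, xout = distance_cm, rule = 2)$y
  data.frame(distance_cm = distance_cm, row = r, col = c_)
}

#' Arc length in cm
#' @param scene a [perfusion_scene()].
#' @param arc arc name.
#' @return Length of the polyline in cm.
#' @export
arc_length <- function(scene, arc) {
  max(.arc_lookup(scene, arc)$d_cm)
}

#' Query ground-truth perfusion along an arc
#'
#' Bilinear interpolation of the ground-truth field at arbitrary distances
#' along an arc; at grid nodes the interpolated value equals the stored grid
#' value exactly.
#'
#' @inheritParams arc_point
#' @return Numeric vector of ground-truth perfusion values (percent).
#' @export
query_arc <- function(scene, arc, distance_cm) {
  pt <- arc_point(scene, arc, distance_cm)
  bilinear_at(scene$field, pt$row, pt$col)
}

# bilinear interpolation at fractional (row, col); exact at integer nodes
bilinear_at <- function(field, row, col) {
  n1 <- nrow(field); n2 <- ncol(field)
  r0 <- pmin(pmax(floor(row), 1), n1 - 1); c0 <- pmin(pmax(floor(col), 1), n2 - 1)
  fr <- row - r0; fc <- col - c0
  f00 <- field[cbind(r0, c0)]; f10 <- field[cbind(r0 + 1, c0)]
  f01 <- field[cbind(r0, c0 + 1)]; f11 <- field[cbind(r0 + 1, c0 + 1)]
  f00 * (1 - fr) * (1 - fc) + f10 * fr * (1 - fc) +
    f01 * (1 - fr) * fc + f11 * fr * fc
}
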