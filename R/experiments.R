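# End-to-end experiment drivers: scene -> speckle render -> contrast ->
# flow index -> RPU -> statistics, for each of the three scenarios.

#' Flow-index map sequence from a speckle video
#'
#' The default processing chain: per-frame spatial speckle contrast
#' (window `w`), conversion to the flow index `1/max(K, k_floor)^2`, then
#' temporal smoothing by a sliding `smooth_window`-frame average.
#'
#' @param video a `speckle_video`.
#' @param w spatial contrast window (odd, default 7).
#' @param k_floor contrast floor (default 0.05).
#' @param smooth_window temporal smoothing window in frames (default 5).
#' @return List of `flow_index_map`s (length
#'   `n_frames - smooth_window + 1`).
#' @export
video_flow_maps <- function(video, w = 7L, k_floor = 0.05, smooth_window = 5L) {
  assert_that(inherits(video, "speckle_video"), "video must be a speckle_video")
  nf <- dim(video$frames)[3]
  maps <- lapply(seq_len(nf), function(i)
    flow_index(spatial_contrast(video$frames[, , i], w = w, frame_index = i),
               k_floor = k_floor))
  smooth_temporal(maps, window = min(smooth_window, nf))
}

.ref_centers <- function(scene) {
  assert_that(all(c("hot_ref", "cold_ref") %in% names(scene$landmarks)),
              "scene lacks hot_ref/cold_ref landmarks")
  list(hot = scene$landmarks$hot_ref, cold = scene$landmarks$cold_ref)
}

# mean raw reference values over the selector's representative frames
.baseline_reference_pair <- function(maps, refs, n = 5L,
                                     selector = frame_selector_uniform(),
                                     area_px = 317L) {
  idx <- selector(length(maps), n)
  hot <- mean(vapply(idx, function(i)
    extract_region(maps[[i]], refs$hot, area_px, i)$mean_raw, numeric(1)))
  cold <- mean(vapply(idx, function(i)
    extract_region(maps[[i]], refs$cold, area_px, i)$mean_raw, numeric(1)))
  reference_pair(hot, cold)
}

#' Run the ischemic bowel-gradient experiment end to end
#'
#' Builds the gradient scene, renders a speckle video, computes flow-index
#' maps, measures RPU profiles along the centerline, mesenteric and
#' antimesenteric arcs (references at the scene's Hot/Cold landmarks,
#' re-sampled per representative frame), and produces the standard
#' readouts: segment summary with ANOVA, paired arc comparison, and
#' decline-onset estimate.
#'
#' @param cfg a [gradient_scene_config()]; defaults to the calibration
#'   defaults.
#' @param optics an [optics_config()].
#' @param seed integer seed for the speckle render.
#' @param n_frames frames rendered (default 60, one cardiac-cycle window at
#'   120 fps).
#' @param spacing_cm profile sample spacing (default 0.5 cm).
#' @param settings list of processing settings (`spatial_window`,
#'   `smooth_window`, `k_floor`, `area_px`, `n_rep_frames`,
#'   `cardiac_window_frames`, `onset_span_cm`); defaults from
#'   [porcine_defaults()].
#' @return List with `scene`, `profiles` (centerline, mesenteric,
#'   antimesenteric), `segments` (ANOVA `comparison_result`),
#'   `arc_comparison`, `onset` (cm), `reference_report` and `seed`.
#' @export
run_gradient_experiment <- function(cfg = default_gradient_config(),
                                    optics = default_optics(),
                                    seed = 1L,
                                    n_frames = 60L,
                                    spacing_cm = 0.5,
                                    settings = NULL) {
  s <- .experiment_settings(settings)
  scene <- build_gradient_scene(cfg)
  video <- render_video(scene, optics, n_frames = n_frames, seed = seed)
  maps <- video_flow_maps(video, w = s$spatial_window, k_floor = s$k_floor,
                          smooth_window = s$smooth_window)
  refs <- .ref_centers(scene)
  sel <- frame_selector_uniform(s$cardiac_window_frames)
  profiles <- lapply(c(centerline = "centerline", mesenteric = "mesenteric",
                       antimesenteric = "antimesenteric"), function(a)
    arc_profile(maps, scene, a, refs, spacing_cm = spacing_cm,
                n_frames = s$n_rep_frames, selector = sel,
                area_px = s$area_px))
  ref_pair <- .baseline_reference_pair(maps, refs, n = s$n_rep_frames,
                                       selector = sel, area_px = s$area_px)
  ref_report <- suppressWarnings(
    validate_references(ref_pair, maps[[1]], mask = scene$mask))
  list(scene = scene,
       profiles = profiles,
       segments = segment_summary(profiles$centerline),
       arc_comparison = compare_arcs(profiles$mesenteric,
                                     profiles$antimesenteric),
       onset = detect_decline_onset(profiles$centerline,
                                    span = s$onset_span_cm),
       reference_report = ref_report,
       seed = as.integer(seed))
}

.experiment_settings <- function(settings = NULL) {
  pd <- porcine_defaults()
  base <- list(spatial_window = pd$contrast$spatial_window,
               smooth_window = pd$contrast$smooth_window,
               k_floor = pd$rpu$k_floor,
               area_px = pd$rpu$area_px,
               n_rep_frames = pd$rpu$n_frames,
               cardiac_window_frames = pd$rpu$cardiac_window_frames,
               onset_span_cm = unlist(pd$analysis$onset_span_cm))
  if (!is.null(settings)) base <- modifyList(base, settings)
  base
}

#' Run the progressive-occlusion experiment end to end
#'
#' Builds the gradient scene and an occlusion schedule, renders the scene
#' scaled by each step's perfusion factor, and measures the mean RPU of the
#' perfused and watershed segments at each step. Hot/Cold reference raw
#' values are measured once on the baseline (unoccluded) step and held
#' fixed across steps, so the RPU series tracks the global perfusion loss.
#' Finishes with the RPU-on-MAP regression per segment.
#'
#' @param kind `"arterial"` or `"venous"`.
#' @param n_steps occlusion steps (default 10).
#' @param occ_cfg an [occlusion_config()]; its seed drives the schedule
#'   noise.
#' @param scene_cfg gradient scene configuration.
#' @param optics an [optics_config()].
#' @param seed integer; seeds the per-step renders (seed + step) and, if
#'   `occ_cfg` is not supplied, the schedule noise.
#' @param n_frames frames rendered per step (default 15; lighter than the
#'   gradient run since only segment means are needed).
#' @param settings see [run_gradient_experiment()].
#' @return List with `schedule`, `series` (data.frame `occlusion_fraction`,
#'   `map_mmHg`, `scale`, `segment`, `rpu`), `regressions` (per-segment
#'   `regression_result`), `kind`, `seed`.
#' @export
run_occlusion_experiment <- function(kind = c("arterial", "venous"),
                                     n_steps = 10L,
                                     occ_cfg = NULL,
                                     scene_cfg = default_gradient_config(),
                                     optics = default_optics(),
                                     seed = 1L,
                                     n_frames = 15L,
                                     settings = NULL) {
  kind <- match.arg(kind)
  s <- .experiment_settings(settings)
  occ_cfg <- occ_cfg %||% default_occlusion_config(kind, seed = seed)
  schedule <- build_occlusion_schedule(kind, n_steps, occ_cfg)
  scene <- build_gradient_scene(scene_cfg)
  refs <- .ref_centers(scene)
  sel <- frame_selector_uniform(s$cardiac_window_frames)
  bounds <- segment_boundaries()[c("perfused", "watershed")]
  roi_d <- lapply(bounds, function(b) seq(b[1], b[2], by = 0.5))

  series <- list()
  ref_pair <- NULL
  for (i in seq_len(nrow(schedule))) {
    video <- render_video(scale_scene(scene, schedule$scale[i]), optics,
                          n_frames = n_frames, seed = seed + i)
    maps <- video_flow_maps(video, w = s$spatial_window, k_floor = s$k_floor,
                            smooth_window = s$smooth_window)
    if (i == 1L)
      ref_pair <- .baseline_reference_pair(maps, refs, n = s$n_rep_frames,
                                           selector = sel, area_px = s$area_px)
    for (segn in names(roi_d)) {
      pts <- arc_point(scene, "centerline", roi_d[[segn]])
      rpu <- vapply(seq_len(nrow(pts)), function(j)
        rpu_over_frames(maps, ref_pair, c(pts$row[j], pts$col[j]),
                        n = s$n_rep_frames, selector = sel,
                        area_px = s$area_px)$mean_rpu, numeric(1))
      series[[length(series) + 1L]] <- data.frame(
        occlusion_fraction = schedule$occlusion_fraction[i],
        map_mmHg = schedule$map_mmHg[i], scale = schedule$scale[i],
        segment = segn, rpu = mean(rpu))
    }
  }
  series <- do.call(rbind, series)
  regressions <- lapply(split(series, series$segment), map_rpu_regression)
  list(schedule = schedule, series = series,
       regressions = regressions[names(roi_d)], kind = kind,
       seed = as.integer(seed))
}

#' Run the paired-anastomosis experiment end to end
#'
#' Builds the two-anastomosis scene, renders it, measures RPU at the 10
#' matched points along each anastomosis arc, and runs the paired
#' comparison.
#'
#' @param cfg an [anastomosis_scene_config()].
#' @param optics an [optics_config()].
#' @param seed integer render seed.
#' @param n_frames frames rendered (default 60).
#' @param settings see [run_gradient_experiment()].
#' @return List with `scene`, `points` (data.frame `distance_cm`, `am`,
#'   `m`), `comparison` (paired t `comparison_result`), `seed`.
#' @export
run_anastomosis_experiment <- function(cfg = default_anastomosis_config(),
                                       optics = default_optics(),
                                       seed = 1L,
                                       n_frames = 60L,
                                       settings = NULL) {
  s <- .experiment_settings(settings)
  scene <- build_anastomosis_scene(cfg)
  video <- render_video(scene, optics, n_frames = n_frames, seed = seed)
  maps <- video_flow_maps(video, w = s$spatial_window, k_floor = s$k_floor,
                          smooth_window = s$smooth_window)
  refs <- .ref_centers(scene)
  sel <- frame_selector_uniform(s$cardiac_window_frames)
  d_pts <- attr(scene, "sample_points_cm")
  measure_arc <- function(arc) {
    pts <- arc_point(scene, arc, d_pts)
    vapply(seq_len(nrow(pts)), function(j)
      rpu_over_frames(maps, refs, c(pts$row[j], pts$col[j]),
                      n = s$n_rep_frames, selector = sel,
                      area_px = s$area_px)$mean_rpu, numeric(1))
  }
  am <- measure_arc("anastomosis_AM")
  m <- measure_arc("anastomosis_M")
  list(scene = scene,
       points = data.frame(distance_cm = d_pts, am = am, m = m),
       comparison = compare_anastomoses(am, m),
       seed = as.integer(seed))
}
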