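#' Calibration defaults for the porcine bowel scenes
#'
#' Loads the versioned default configuration shipped with the package
#' (`inst/extdata/porcine_defaults.yaml`): the ground-truth perfusion levels
#' each synthetic scene is calibrated to, the occlusion/MAP simulation
#' conventions, default optics, and the RPU/contrast/analysis settings.
#'
#' @return A named list mirroring the YAML structure.
#' @export
porcine_defaults <- function() {
  path <- system.file("extdata", "porcine_defaults.yaml",
                      package = "speckleRPU", mustWork = TRUE)
  yaml::read_yaml(path)
}

#' Default gradient scene configuration from the calibration file
#' @param seed integer seed recorded in the config.
#' @return A [gradient_scene_config()].
#' @export
default_gradient_config <- function(seed = 1L) {
  g <- porcine_defaults()$gradient
  gradient_scene_config(plateau_level = g$plateau_level,
                        watershed_level = g$watershed_level,
                        ischemic_level = g$ischemic_level,
                        decline_onset_cm = g$decline_onset_cm,
                        devasc_margin_cm = g$devasc_margin_cm,
                        arc_offset = g$arc_offset,
                        arc_offset_split = g$arc_offset_split,
                        length_cm = g$length_cm,
                        band_width_cm = g$band_width_cm,
                        margin_cm = g$margin_cm,
                        px_per_cm = g$px_per_cm,
                        seed = seed)
}

#' Default anastomosis scene configuration from the calibration file
#' @param seed integer seed recorded in the config.
#' @return An [anastomosis_scene_config()].
#' @export
default_anastomosis_config <- function(seed = 1L) {
  a <- porcine_defaults()$anastomosis
  anastomosis_scene_config(am_profile = a$am_profile,
                           m_profile = a$m_profile,
                           length_cm = a$length_cm,
                           band_width_cm = a$band_width_cm,
                           gap_cm = a$gap_cm,
                           margin_cm = a$margin_cm,
                           px_per_cm = a$px_per_cm,
                           seed = seed)
}

#' Default occlusion configuration from the calibration file
#' @param kind `"arterial"` or `"venous"`.
#' @param seed integer seed for the schedule noise.
#' @return An [occlusion_config()].
#' @export
default_occlusion_config <- function(kind = c("arterial", "venous"), seed = 1L) {
  kind <- match.arg(kind)
  o <- porcine_defaults()$occlusion[[kind]]
  occlusion_config(kind = kind, map_baseline = o$map_baseline,
                   map_floor = o$map_floor, scale_at_full = o$scale_at_full,
                   noise_sd = o$noise_sd, seed = seed)
}

#' Default optics configuration from the calibration file
#' @param ... overrides passed to [optics_config()].
#' @return An [optics_config()].
#' @export
default_optics <- function(...) {
  o <- porcine_defaults()$optics
  do.call(optics_config, modifyList(o, list(...)))
}
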