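# Calibration defaults for the synthetic porcine bowel experiments.
# Perfusion levels are the RPU calibration targets each scene is built to
# express in ground truth; MAP values are simulation conventions (no
# pressure measurements are bundled with this package).
version: 1
gradient:
  plateau_level: 98.8      # perfused segment mean, percent
  watershed_level: 78.3    # watershed segment mean, percent
  ischemic_level: 1.9      # ischemic segment mean, percent
  decline_onset_cm: 5.0    # sharp-decline onset, cm from stapled edge
  devasc_margin_cm: 4.0    # devascularization margin, cm
  arc_offset: 16.6         # mesenteric - antimesenteric difference, percent
  arc_offset_split: 0.072289156626506 # 1.2/16.6: offset fraction above the centerline
  length_cm: 10
  band_width_cm: 4
  margin_cm: 1.5
  px_per_cm: 20
occlusion:
  arterial:
    map_baseline: 65       # mmHg, simulation convention
    map_floor: 20
    scale_at_full: 0.02
    noise_sd: 0.10         # scale units; see scripts/calibrate_occlusion_noise.R
  venous:
    map_baseline: 65
    map_floor: 45          # smaller MAP drop for the same perfusion loss
    scale_at_full: 0.02
    noise_sd: 0.10
  n_steps: 10
anastomosis:
  am_profile: [82.2, 75.93, 69.67, 63.4, 57.13, 50.87, 44.6, 38.33, 32.07, 25.8]
  m_profile: [61.5, 56.28, 51.06, 45.83, 40.61, 35.39, 30.17, 24.94, 19.72, 14.5]
  length_cm: 4.5
  band_width_cm: 1.5
  gap_cm: 2
  margin_cm: 1.5
  px_per_cm: 20
optics:
  frame_rate: 120
  exposure_time: 0.005
  speckle_grain_px: 1.0
  bit_depth: 16
  mean_intensity: 3000
  mode: analytic
  substeps_per_frame: 40
  tau_cap: 1.0
  k_full_flow: 0.1
rpu:
  area_px: 317             # region area shared by ROIs and references
  area_px_alt: 21          # documented alternate small-region area
  n_frames: 5              # representative frames averaged
  cardiac_window_frames: 60 # 0.5 s at 120 fps
  k_floor: 0.05
contrast:
  spatial_window: 7
  smooth_window: 5
analysis:
  spacing_cm: 0.5
  onset_span_cm: [2, 8]
  segments:
    ischemic: [0, 2]
    watershed: [4, 6]
    perfused: [8, 10]
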