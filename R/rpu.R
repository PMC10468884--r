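# Relative Perfusion Unit quantification: 317-pixel region sampling, Hot/Cold
# reference normalization, and representative-frame averaging.

# Discrete disk of exactly `area_px` pixels nearest the origin; ties broken
# by angle (counter-clockwise from the +col axis) then row-major order.
# Returns an area_px x 2 matrix of (drow, dcol) offsets.
disk_offsets <- function(area_px = 317L) {
  area_px <- as.integer(area_px)
  assert_that(area_px >= 1L, "area_px must be >= 1")
  r_max <- ceiling(sqrt(area_px / pi)) + 2L
  g <- expand.grid(drow = -r_max:r_max, dcol = -r_max:r_max)
  d2 <- g$drow^2 + g$dcol^2
  ang <- atan2(g$drow, g$dcol) %% (2 * pi)
  ord <- order(d2, ang, g$drow, g$dcol)
  as.matrix(g[ord[seq_len(area_px)], c("drow", "dcol")])
}

#' Extract a fixed-area region sample from a map
#'
#' Samples the discrete disk of exactly `area_px` pixels nearest `center`
#' (the default 317 pixels corresponds to a disk of radius about 10 px) and
#' records its mean raw value. All regions used in RPU quantification --
#' ROIs and the Hot and Cold references -- share this area.
#'
#' @param map a `flow_index_map` or numeric matrix.
#' @param center numeric length-2 `c(row, col)`; fractional centers are
#'   rounded to the nearest pixel.
#' @param area_px region area in pixels (default 317; 21 is the documented
#'   alternate small-region area).
#' @param frame_index optional provenance index.
#' @return A `region_sample`: list with `center`, `pixels` (area_px x 2
#'   matrix of coordinates), `mean_raw`, `area_px`, `frame_index`.
#' @export
extract_region <- function(map, center, area_px = 317L, frame_index = NA_integer_) {
  m <- as_map_matrix(map)
  assert_that(length(center) == 2 && all(is.finite(center)),
              "center must be c(row, col)")
  ctr <- as.integer(round(center))
  off <- disk_offsets(area_px)
  px <- cbind(row = ctr[1] + off[, 1], col = ctr[2] + off[, 2])
  if (any(px[, 1] < 1 | px[, 1] > nrow(m) | px[, 2] < 1 | px[, 2] > ncol(m)))
    stop_user("region of ", area_px, " px at center (", ctr[1], ", ", ctr[2],
              ") clips the map border (", nrow(m), " x ", ncol(m), ")")
  vals <- m[px]
  assert_that(all(is.finite(vals)), "region contains non-finite values")
  structure(list(center = ctr, pixels = px, mean_raw = mean(vals),
                 area_px = as.integer(area_px),
                 frame_index = frame_index),
            class = "region_sample")
}

#' Hot/Cold reference pair
#'
#' The Hot reference is a maximally perfused region (highest raw flow, e.g. a
#' surface capillary); the Cold reference a minimally perfused region within
#' the ischemic zone. Their raw means anchor the RPU scale at 100 and 0.
#'
#' @param hot,cold `region_sample`s (or numeric scalar raw values, which are
#'   wrapped for convenience).
#' @return A `reference_pair`; errors if `hot` does not strictly exceed
#'   `cold`.
#' @export
reference_pair <- function(hot, cold) {
  wrap <- function(x, nm) {
    if (inherits(x, "region_sample")) return(x)
    assert_that(is.numeric(x) && length(x) == 1 && is.finite(x),
                nm, " must be a region_sample or a finite scalar")
    structure(list(center = c(NA, NA), pixels = NULL, mean_raw = x,
                   area_px = NA_integer_, frame_index = NA_integer_),
              class = "region_sample")
  }
  hot <- wrap(hot, "hot"); cold <- wrap(cold, "cold")
  if (!(hot$mean_raw > cold$mean_raw))
    stop_user("degenerate references: hot raw (", signif(hot$mean_raw, 6),
              ") must strictly exceed cold raw (", signif(cold$mean_raw, 6), ")")
  structure(list(hot = hot, cold = cold), class = "reference_pair")
}

#' Relative Perfusion Units
#'
#' `RPU = 100 * (ROI_raw - Cold_raw) / (Hot_raw - Cold_raw)`: 0 percent at
#' the Cold reference, 100 at the Hot reference. Values are never clipped;
#' regions brighter than Hot (or darker than Cold) legitimately map slightly
#' above 100 (below 0). The result is invariant to any affine rescaling
#' `a + b*x` (b > 0) applied to all three raw values.
#'
#' @param roi_raw ROI raw value(s): numeric vector or a `region_sample`.
#' @param refs a [reference_pair()].
#' @return RPU in percent (same length as `roi_raw`).
#' @export
compute_rpu <- function(roi_raw, refs) {
  assert_that(inherits(refs, "reference_pair"), "refs must be a reference_pair")
  if (inherits(roi_raw, "region_sample")) roi_raw <- roi_raw$mean_raw
  assert_that(is.numeric(roi_raw) && all(is.finite(roi_raw)),
              "roi_raw must be finite numeric")
  h <- refs$hot$mean_raw; c0 <- refs$cold$mean_raw
  # ratio first: an ROI equal to a reference hits 0 or 100 exactly
  100 * ((roi_raw - c0) / (h - c0))
}

#' Evenly spread representative-frame selector
#'
#' Returns a selector that spreads `n` frames uniformly over a span of
#' `window_frames` frames (default 60, i.e. 0.5 s at 120 fps -- roughly one
#' cardiac cycle), so that systolic and diastolic phases average out. If
#' fewer frames are available the span shrinks to what is available.
#'
#' @param window_frames span in frames over which to spread the selection.
#' @return A function `(n_available, n)` returning `n` distinct frame
#'   indices.
#' @export
frame_selector_uniform <- function(window_frames = 60L) {
  force(window_frames)
  function(n_available, n) {
    span <- min(window_frames, n_available)
    idx <- unique(as.integer(round(seq(1, span, length.out = n))))
    if (length(idx) < n) { # short span: pad with the nearest unused frames
      extra <- setdiff(seq_len(n_available), idx)
      idx <- sort(c(idx, extra[seq_len(n - length(idx))]))
    }
    idx
  }
}

#' RPU of an ROI averaged over representative frames
#'
#' Selects `n` representative frames from the map sequence (default: spread
#' uniformly over a cardiac-cycle-length window), computes the ROI's RPU on
#' each selected frame with the Hot/Cold references re-sampled at fixed
#' coordinates on that same frame, and averages.
#'
#' @param maps list of `flow_index_map`s (or matrices), one per frame.
#' @param refs list with elements `hot` and `cold`, each `c(row, col)`
#'   reference center coordinates; or a [reference_pair()] of fixed raw
#'   values (then references are not re-sampled per frame, as for
#'   cross-time-point series anchored to a baseline).
#' @param roi_center `c(row, col)` ROI center.
#' @param n number of representative frames to average (default 5).
#' @param selector frame selector, see [frame_selector_uniform()].
#' @param area_px region area (default 317).
#' @return An `rpu_measurement`: list with `per_frame` (data.frame `frame`,
#'   `rpu`), `mean_rpu`, `n_frames_averaged`, `roi_center`.
#' @export
rpu_over_frames <- function(maps, refs, roi_center, n = 5L,
                            selector = frame_selector_uniform(),
                            area_px = 317L) {
  assert_that(is.list(maps) || is.matrix(maps), "maps must be a list of maps")
  if (!is.list(maps)) maps <- list(maps)
  assert_that(length(maps) >= n, "need at least n = ", n, " frames, got ",
              length(maps))
  idx <- selector(length(maps), n)
  assert_that(length(idx) == n && all(idx >= 1 & idx <= length(maps)),
              "selector must return n valid frame indices")
  fixed <- inherits(refs, "reference_pair")
  if (!fixed)
    assert_that(is.list(refs) && all(c("hot", "cold") %in% names(refs)),
                "refs must be a list(hot=, cold=) of centers or a reference_pair")
  rpu <- vapply(idx, function(i) {
    roi <- extract_region(maps[[i]], roi_center, area_px, frame_index = i)
    rp <- if (fixed) refs else
      reference_pair(extract_region(maps[[i]], refs$hot, area_px, i),
                     extract_region(maps[[i]], refs$cold, area_px, i))
    compute_rpu(roi, rp)
  }, numeric(1))
  structure(list(per_frame = data.frame(frame = idx, rpu = rpu),
                 mean_rpu = mean(rpu), n_frames_averaged = as.integer(n),
                 roi_center = as.integer(round(roi_center))),
            class = "rpu_measurement")
}

#' @export
print.rpu_measurement <- function(x, ...) {
  cat("<rpu_measurement> ROI at (", x$roi_center[1], ", ", x$roi_center[2],
      "): mean RPU ", round(x$mean_rpu, 2), "% over ",
      x$n_frames_averaged, " frame(s)\n", sep = "")
  invisible(x)
}

#' Advisory validation of a Hot/Cold reference pair
#'
#' Reference regions are selected manually; this check reports how well the
#' chosen pair spans the map. It computes the hot-cold separation, each
#' reference's percentile among on-map values, and warns when the
#' separation falls below `min_separation_frac` of the map's value range.
#'
#' @param refs a [reference_pair()].
#' @param map the `flow_index_map` (or matrix) the references live on.
#' @param min_separation_frac warn when `(hot - cold)` is below this
#'   fraction of the map range (default 0.5).
#' @param mask optional logical matrix restricting the percentile
#'   computation to tissue.
#' @return A `reference_report`: list with `separation`, `hot_percentile`,
#'   `cold_percentile`, `warnings` (character vector, possibly empty).
#' @export
validate_references <- function(refs, map, min_separation_frac = 0.5,
                                mask = NULL) {
  assert_that(inherits(refs, "reference_pair"), "refs must be a reference_pair")
  m <- as_map_matrix(map)
  vals <- if (is.null(mask)) as.vector(m) else m[mask]
  sep <- refs$hot$mean_raw - refs$cold$mean_raw
  rng <- diff(range(vals))
  pct <- ecdf(vals)
  warnings <- character(0)
  if (rng > 0 && sep < min_separation_frac * rng)
    warnings <- c(warnings, sprintf(
      "weak reference separation: hot - cold = %.4g is %.1f%% of the map range",
      sep, 100 * sep / rng))
  rep <- structure(list(separation = sep,
                        hot_percentile = 100 * pct(refs$hot$mean_raw),
                        cold_percentile = 100 * pct(refs$cold$mean_raw),
                        warnings = warnings),
                   class = "reference_report")
  for (w in warnings) warning(w, call. = FALSE)
  rep
}

#' @export
print.reference_report <- function(x, ...) {
  cat("<reference_report> separation ", signif(x$separation, 4),
      "; hot at p", round(x$hot_percentile, 1), ", cold at p",
      round(x$cold_percentile, 1), " of map values\n", sep = "")
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  else cat("  no warnings\n")
  invisible(x)
}
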