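# Stack I/O (multi-frame grayscale TIFF + JSON sidecar) and perfusion
# heatmap rendering.

.sidecar_path <- function(path) paste0(path, ".json")

#' Write a speckle video or flow-map sequence to a multi-frame TIFF
#'
#' Videos are stored as integer TIFF pages at their native bit depth;
#' flow-index maps (or other float maps) as 32-bit float pages normalized by
#' a scale factor recorded in the JSON sidecar (`<path>.json`), which also
#' carries optics, provenance and seed metadata. The round trip through
#' [read_stack()] is lossless for integer videos and float32-exact for maps.
#'
#' @param x a `speckle_video`, a `flow_index_map`, a list of
#'   `flow_index_map`s, or a numeric matrix/list of matrices.
#' @param path output TIFF path.
#' @param metadata optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path, metadata = list()) {
  if (inherits(x, "speckle_video")) {
    bd <- x$optics$bit_depth
    pages <- lapply(seq_len(dim(x$frames)[3]),
                    function(i) x$frames[, , i] / (2^bd - 1))
    side <- c(list(type = "speckle_video", bit_depth = bd,
                   optics = unclass(x$optics), scene_id = x$scene_id,
                   seed = x$seed, n_frames = length(pages)),
              metadata)
    tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bd))
  } else {
    if (inherits(x, "flow_index_map") || is.matrix(x)) x <- list(x)
    assert_that(is.list(x) && length(x) >= 1, "nothing to write")
    mats <- lapply(x, as_map_matrix)
    scale <- max(1e-12, max(vapply(mats, max, numeric(1))))
    pages <- lapply(mats, function(m) m / scale)
    kf <- if (inherits(x[[1]], "flow_index_map")) x[[1]]$k_floor else NULL
    side <- c(list(type = "flow_maps", scale = scale, k_floor = kf,
                   n_frames = length(pages)), metadata)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  jsonlite::write_json(side, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a stack written by [write_stack()]
#'
#' @param path TIFF path (the JSON sidecar `<path>.json` must sit next to
#'   it).
#' @return A `speckle_video`, or a list of `flow_index_map`s, according to
#'   the sidecar's `type`.
#' @export
read_stack <- function(path) {
  assert_that(file.exists(path), "no such file: ", path)
  sp <- .sidecar_path(path)
  assert_that(file.exists(sp), "missing metadata sidecar: ", sp)
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop_user("malformed TIFF '", path,
                                                  "': ", conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  for (i in seq_along(pages))
    if (length(dim(pages[[i]])) != 2)
      stop_user("page ", i, " of '", path, "' is not single-channel grayscale")
  if (identical(side$type, "speckle_video")) {
    bd <- side$bit_depth
    frames <- array(0L, dim = c(dim(pages[[1]]), length(pages)))
    for (i in seq_along(pages))
      frames[, , i] <- as.integer(round(pages[[i]] * (2^bd - 1)))
    optics <- do.call(optics_config, side$optics[setdiff(names(side$optics), NULL)])
    structure(list(frames = frames, optics = optics,
                   scene_id = side$scene_id %||% "unknown",
                   seed = side$seed %||% NA_integer_),
              class = "speckle_video")
  } else if (identical(side$type, "flow_maps")) {
    lapply(pages, function(p)
      structure(list(values = p * side$scale,
                     k_floor = side$k_floor %||% NA_real_,
                     provenance = list(source = path)),
                class = "flow_index_map"))
  } else {
    stop_user("sidecar of '", path, "' has unknown type '", side$type, "'")
  }
}

# warm-cool perfusion palette: blue (low) -> green -> yellow -> red (high)
.perfusion_palette <- function(n = 256) {
  colorRamp(c("#00007F", "#0000FF", "#00BFFF", "#00FF7F", "#BFFF00",
              "#FFFF00", "#FF7F00", "#FF0000", "#7F0000"))(seq(0, 1, length.out = n)) / 255
}

#' Render a perfusion heatmap
#'
#' Linearly maps `clim` onto a warm-cool palette (warm colors = high flow),
#' clamping out-of-range values for display only, and embeds a vertical
#' color scale bar along the right edge.
#'
#' @param map a `flow_index_map`, RPU field, or numeric matrix.
#' @param clim length-2 display range `c(lo, hi)`, `lo < hi`; defaults to
#'   the map range.
#' @param scale_bar_px width of the embedded scale bar (0 disables it).
#' @return A `heatmap_render`: list with `image` (rows x cols x 3 RGB array
#'   in [0,1]), `colormap`, `clim`.
#' @export
render_heatmap <- function(map, clim = NULL, scale_bar_px = 12L) {
  m <- as_map_matrix(map)
  assert_that(all(is.finite(m)), "map must be finite")
  clim <- clim %||% range(m)
  assert_that(length(clim) == 2 && clim[1] < clim[2],
              "clim must be c(lo, hi) with lo < hi")
  pal <- .perfusion_palette()
  n <- nrow(pal)
  idx <- 1 + as.integer(round((n - 1) *
          pmin(pmax((m - clim[1]) / (clim[2] - clim[1]), 0), 1)))
  img <- array(0, dim = c(nrow(m), ncol(m), 3))
  for (ch in 1:3) img[, , ch] <- matrix(pal[idx, ch], nrow(m), ncol(m))
  if (scale_bar_px > 0) {
    bar_idx <- 1 + as.integer(round((n - 1) *
                 seq(1, 0, length.out = nrow(m)))) # warm at top
    bar <- array(0, dim = c(nrow(m), scale_bar_px, 3))
    for (ch in 1:3) bar[, , ch] <- matrix(pal[bar_idx, ch], nrow(m), scale_bar_px)
    gap <- array(1, dim = c(nrow(m), 2L, 3)) # white separator
    out <- array(0, dim = c(nrow(m), ncol(m) + 2L + scale_bar_px, 3))
    out[, seq_len(ncol(m)), ] <- img
    out[, ncol(m) + 1:2, ] <- gap
    out[, (ncol(m) + 3L):dim(out)[2], ] <- bar
    img <- out
  }
  structure(list(image = img, colormap = "warmcool", clim = clim),
            class = "heatmap_render")
}

#' Write a heatmap to PNG
#' @param hm a `heatmap_render` (or map passed through [render_heatmap()]).
#' @param path output PNG path.
#' @param ... passed to [render_heatmap()] when `hm` is a raw map.
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(hm, path, ...) {
  if (!inherits(hm, "heatmap_render")) hm <- render_heatmap(hm, ...)
  png::writePNG(hm$image, path)
  invisible(path)
}

#' Read region/reference coordinates from CSV
#'
#' Expected columns: `name`, `row`, `col`, optionally `area_px` (default
#' 317). Mirrors the manual selection of Hot/Cold references and ROIs.
#'
#' @param path CSV path.
#' @return data.frame with columns `name`, `row`, `col`, `area_px`.
#' @export
read_regions_csv <- function(path) {
  assert_that(file.exists(path), "no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  assert_that(all(c("name", "row", "col") %in% names(df)),
              "regions CSV needs columns name, row, col")
  if (is.null(df$area_px)) df$area_px <- 317L
  df
}
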