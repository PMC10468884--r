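# Speckle contrast estimation and the raw flow-index map that feeds RPU
# quantification.

# sliding-window sum along rows; input must have >= w rows, returns
# nrow - w + 1 rows
.slide_rows <- function(m, w) {
  cs <- rbind(0, apply(m, 2L, cumsum))
  cs[(w + 1):nrow(cs), , drop = FALSE] - cs[1:(nrow(cs) - w), , drop = FALSE]
}

# w x w box mean with reflect padding (mirror about the edge, edge pixel not
# repeated); w odd
box_mean <- function(mat, w) {
  r <- (w - 1L) %/% 2L
  n1 <- nrow(mat); n2 <- ncol(mat)
  assert_that(n1 > r && n2 > r, "matrix too small for window ", w)
  if (r > 0L) {
    ri <- c((r + 1L):2L, seq_len(n1), (n1 - 1L):(n1 - r))
    ci <- c((r + 1L):2L, seq_len(n2), (n2 - 1L):(n2 - r))
    mat <- mat[ri, ci, drop = FALSE]
  }
  s <- .slide_rows(mat, w)
  s <- t(.slide_rows(t(s), w))
  s / (w * w)
}

.new_contrast_map <- function(values, window, frames) {
  n_over <- sum(values > 1.2)
  structure(list(values = values, window = window, frames = frames,
                 n_over_physical = n_over),
            class = "contrast_map")
}

#' Spatial speckle contrast
#'
#' Per-pixel contrast `K = sigma / mu` over a `w x w` neighborhood, using the
#' population (divide-by-n) standard deviation and reflect padding at the
#' image border. Neighborhoods with zero mean yield `K = 0`. Values above
#' 1.2 are physically implausible for fully developed speckle and are
#' counted in the result's `n_over_physical` field.
#'
#' @param frame numeric matrix of intensities (one video frame).
#' @param w odd window size >= 3 (default 7).
#' @param frame_index optional index recorded for provenance.
#' @return A `contrast_map`: list with `values` (matrix of K), `window`,
#'   `frames`, `n_over_physical`.
#' @export
spatial_contrast <- function(frame, w = 7L, frame_index = NA_integer_) {
  if (inherits(frame, "speckle_video")) {
    assert_that(dim(frame$frames)[3] == 1,
                "pass a single frame matrix, or use frames = video$frames[,,i]")
    frame <- frame$frames[, , 1]
  }
  assert_that(is.matrix(frame) && is.numeric(frame) && all(is.finite(frame)),
              "frame must be a finite numeric matrix")
  w <- as.integer(w)
  assert_that(w >= 3L && w %% 2L == 1L, "window size w must be odd and >= 3")
  mu <- box_mean(frame, w)
  m2 <- box_mean(frame^2, w)
  v <- pmax(m2 - mu^2, 0) # population variance; clamp tiny negative rounding
  K <- matrix(0, nrow(frame), ncol(frame))
  nz <- mu != 0
  K[nz] <- sqrt(v[nz]) / mu[nz]
  .new_contrast_map(K, window = list(type = "spatial", w = w),
                    frames = frame_index)
}

#' Temporal speckle contrast
#'
#' Per-pixel contrast over the time axis: `K = sigma_t / mu_t` across the
#' first `n_frames` frames of the stack (population standard deviation;
#' zero-mean pixels yield 0).
#'
#' @param video a `speckle_video` or a rows x cols x frames numeric array.
#' @param n_frames number of frames to use (>= 2, at most the stack length).
#' @return A `contrast_map`.
#' @export
temporal_contrast <- function(video, n_frames) {
  frames <- if (inherits(video, "speckle_video")) video$frames else video
  assert_that(is.array(frames) && length(dim(frames)) == 3,
              "video must be a speckle_video or a 3-d array")
  nf <- dim(frames)[3]
  assert_that(n_frames >= 2, "n_frames must be >= 2")
  assert_that(n_frames <= nf, "n_frames (", n_frames,
              ") exceeds stack length (", nf, ")")
  sub <- frames[, , seq_len(n_frames), drop = FALSE]
  mu <- apply(sub, c(1, 2), mean)
  m2 <- apply(sub^2, c(1, 2), mean)
  v <- pmax(m2 - mu^2, 0)
  K <- matrix(0, nrow(mu), ncol(mu))
  nz <- mu != 0
  K[nz] <- sqrt(v[nz]) / mu[nz]
  .new_contrast_map(K, window = list(type = "temporal", n_frames = n_frames),
                    frames = seq_len(n_frames))
}

#' Flow-index map from a contrast map
#'
#' The raw flow quantity used throughout RPU quantification:
#' `1 / max(K, k_floor)^2`, monotone decreasing in contrast and finite
#' everywhere thanks to the contrast floor. RPU is invariant to affine
#' rescaling of this quantity, so its absolute scale carries no meaning.
#'
#' @param K_map a `contrast_map` or numeric matrix of contrast values.
#' @param k_floor positive contrast floor (default 0.05).
#' @return A `flow_index_map`: list with `values`, `k_floor`, `provenance`.
#' @export
flow_index <- function(K_map, k_floor = 0.05) {
  prov <- NULL
  if (inherits(K_map, "contrast_map")) {
    prov <- K_map[c("window", "frames")]
    K_map <- K_map$values
  }
  assert_that(is.matrix(K_map) && all(is.finite(K_map)) && all(K_map >= 0),
              "contrast values must be finite and >= 0")
  assert_that(is.numeric(k_floor) && k_floor > 0, "k_floor must be > 0")
  structure(list(values = 1 / pmax(K_map, k_floor)^2, k_floor = k_floor,
                 provenance = prov),
            class = "flow_index_map")
}

#' Temporal smoothing of a flow-index map sequence
#'
#' Sliding moving average over `window` consecutive maps. Only full windows
#' are returned, so the output sequence has `length(maps) - window + 1`
#' elements; `window = 1` is the identity.
#'
#' @param maps list of `flow_index_map`s (or numeric matrices) from
#'   consecutive frames.
#' @param window window length in frames (>= 1, at most the sequence length).
#' @return List of `flow_index_map`s.
#' @export
smooth_temporal <- function(maps, window = 5L) {
  assert_that(is.list(maps) && length(maps) >= 1, "maps must be a non-empty list")
  window <- as.integer(window)
  assert_that(window >= 1L && window <= length(maps),
              "window must be between 1 and the sequence length")
  vals <- lapply(maps, function(m) if (inherits(m, "flow_index_map")) m$values else m)
  kf <- if (inherits(maps[[1]], "flow_index_map")) maps[[1]]$k_floor else NA_real_
  n_out <- length(vals) - window + 1L
  out <- vector("list", n_out)
  acc <- Reduce(`+`, vals[seq_len(window)])
  for (i in seq_len(n_out)) {
    if (i > 1) acc <- acc - vals[[i - 1L]] + vals[[i + window - 1L]]
    out[[i]] <- structure(
      list(values = acc / window, k_floor = kf,
           provenance = list(window = list(type = "temporal_smooth",
                                           n_frames = window),
                             frames = i:(i + window - 1L))),
      class = "flow_index_map")
  }
  out
}

# coerce map-like inputs (flow_index_map, contrast_map, matrix) to a matrix
as_map_matrix <- function(x) {
  if (inherits(x, "flow_index_map") || inherits(x, "contrast_map")) return(x$values)
  assert_that(is.matrix(x) && is.numeric(x), "expected a map object or numeric matrix")
  x
}
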