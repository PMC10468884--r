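# Shared fixture builders. Everything is generated in code at test time.

# flat rectangular scene at a single perfusion level, large enough for a
# 317-px region plus the 7x7 contrast window
flat_scene <- function(level, n = 41L) {
  field <- matrix(level, n, n)
  perfusion_scene(field, mask = matrix(TRUE, n, n), px_per_cm = 20,
                  scene_id = "flat")
}

# three-block calibration scene: cold (0) | mid (g) | hot (100) vertical
# bands, each wide enough to hold a centered 317-px region clear of the
# block boundaries
blocks_scene <- function(g = 50, block_w = 41L, n_rows = 41L) {
  field <- cbind(matrix(0, n_rows, block_w),
                 matrix(g, n_rows, block_w),
                 matrix(100, n_rows, block_w))
  perfusion_scene(field, mask = matrix(TRUE, n_rows, 3L * block_w),
                  px_per_cm = 20, scene_id = "blocks")
}

block_centers <- function(block_w = 41L, n_rows = 41L) {
  r <- (n_rows + 1L) %/% 2L
  list(cold = c(r, (block_w + 1L) %/% 2L),
       mid = c(r, block_w + (block_w + 1L) %/% 2L),
       hot = c(r, 2L * block_w + (block_w + 1L) %/% 2L))
}

# region-mean flow index of a rendered flat region, averaged over frames
region_flow <- function(level, optics = optics_config(), n_frames = 3L,
                        seed = 1L, w = 7L) {
  sc <- flat_scene(level)
  v <- render_video(sc, optics, n_frames = n_frames, seed = seed)
  fm <- lapply(seq_len(n_frames), function(i)
    flow_index(spatial_contrast(v$frames[, , i], w = w)))
  mean(vapply(fm, function(m) mean(m$values), numeric(1)))
}

# region-mean spatial contrast of a rendered flat region
region_contrast <- function(level, optics = optics_config(), n_frames = 3L,
                            seed = 1L, w = 7L) {
  sc <- flat_scene(level)
  v <- render_video(sc, optics, n_frames = n_frames, seed = seed)
  mean(vapply(seq_len(n_frames), function(i) {
    K <- spatial_contrast(v$frames[, , i], w = w)$values
    # trim the window-width border so padding does not enter the average
    mean(K[4:(nrow(K) - 3), 4:(ncol(K) - 3)])
  }, numeric(1)))
}

# independent brute-force oracle for windowed sigma/mu with reflect padding
brute_spatial_contrast <- function(frame, w) {
  r <- (w - 1) / 2
  n1 <- nrow(frame); n2 <- ncol(frame)
  reflect <- function(i, n) {
    i <- ifelse(i < 1, 2 - i, i)
    ifelse(i > n, 2 * n - i, i)
  }
  K <- matrix(0, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    vals <- numeric(0)
    for (di in -r:r) for (dj in -r:r)
      vals <- c(vals, frame[reflect(i + di, n1), reflect(j + dj, n2)])
    mu <- mean(vals)
    K[i, j] <- if (mu == 0) 0 else sqrt(mean((vals - mu)^2)) / mu
  }
  K
}
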