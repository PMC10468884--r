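# Statistical readouts over measured RPU profiles: segment classification
# along the ischemic gradient, arc comparisons, decline-onset detection,
# perfusion-pressure regression and paired anastomosis comparison.

#' Default gradient segment boundaries (cm from the stapled edge)
#'
#' Ischemic 0--2, watershed 4--6, perfused 8--10 cm. The 2--4 and 6--8 cm
#' gaps are transition zones excluded from segment summaries (profiles still
#' sample them for decline-onset detection).
#' @return Named list of length-2 numeric ranges.
#' @export
segment_boundaries <- function() {
  list(ischemic = c(0, 2), watershed = c(4, 6), perfused = c(8, 10))
}

#' Measure an RPU profile along an arc
#'
#' Places fixed-area regions at `spacing_cm` steps along the arc, computes
#' each region's representative-frame-averaged RPU (see
#' [rpu_over_frames()]), and returns the ordered distance-RPU profile.
#' Sample positions whose region would clip the map border are dropped with
#' a warning.
#'
#' @param maps list of `flow_index_map`s (one per frame).
#' @param scene the [perfusion_scene()] providing the arc geometry.
#' @param arc arc name in `scene$arcs`.
#' @param refs reference centers `list(hot=, cold=)` or a fixed
#'   [reference_pair()]; passed to [rpu_over_frames()].
#' @param spacing_cm distance between consecutive samples (default 0.5 cm).
#' @param n_frames representative frames averaged per sample (default 5).
#' @param selector frame selector.
#' @param area_px region area (default 317).
#' @return A `gradient_profile`: data.frame with columns `distance_cm`,
#'   `rpu`; attribute `arc`.
#' @export
arc_profile <- function(maps, scene, arc, refs, spacing_cm = 0.5,
                        n_frames = 5L, selector = frame_selector_uniform(),
                        area_px = 317L) {
  assert_that(spacing_cm > 0, "spacing_cm must be positive")
  len <- arc_length(scene, arc)
  dists <- seq(0, len, by = spacing_cm)
  pts <- arc_point(scene, arc, dists)
  keep <- logical(nrow(pts))
  rpu <- rep(NA_real_, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    res <- tryCatch(
      rpu_over_frames(maps, refs, c(pts$row[i], pts$col[i]), n = n_frames,
                      selector = selector, area_px = area_px),
      error = function(e) e)
    if (inherits(res, "error")) next
    keep[i] <- TRUE
    rpu[i] <- res$mean_rpu
  }
  if (!all(keep))
    warning(sum(!keep), " sample(s) dropped along arc '", arc,
            "' (region would clip the map border)", call. = FALSE)
  assert_that(any(keep), "no valid samples along arc '", arc, "'")
  out <- data.frame(distance_cm = dists[keep], rpu = rpu[keep])
  structure(out, arc = arc, class = c("gradient_profile", "data.frame"))
}

#' Make a gradient profile from raw distance/RPU pairs
#'
#' @param distance_cm strictly increasing distances (cm).
#' @param rpu RPU values (percent).
#' @param arc arc name tag.
#' @return A `gradient_profile` data.frame.
#' @export
gradient_profile <- function(distance_cm, rpu, arc = "arc") {
  assert_that(length(distance_cm) == length(rpu) && length(rpu) >= 2,
              "need matching distance/rpu vectors of length >= 2")
  assert_that(all(diff(distance_cm) > 0), "distances must be strictly increasing")
  structure(data.frame(distance_cm = distance_cm, rpu = rpu),
            arc = arc, class = c("gradient_profile", "data.frame"))
}

.assign_segment <- function(d, boundaries) {
  seg <- rep(NA_character_, length(d))
  for (nm in names(boundaries)) {
    b <- boundaries[[nm]]
    seg[d >= b[1] - 1e-9 & d <= b[2] + 1e-9] <- nm
  }
  seg
}

.comparison_result <- function(test, statistic, p_value, groups,
                               paired = FALSE, estimate = NA_real_) {
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 groups = groups, paired = paired, estimate = estimate),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result> ", x$test, if (x$paired) " (paired)", ": ",
      "statistic = ", signif(x$statistic, 4), ", p = ",
      format(x$p_value, digits = 3), "\n", sep = "")
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Per-segment summary and one-way ANOVA across gradient segments
#'
#' Assigns each profile sample to the ischemic / watershed / perfused
#' segment (samples in the transition gaps are excluded), reports each
#' segment's mean and SD, and tests segment separation with a one-way
#' ANOVA.
#'
#' @param profile a `gradient_profile`, or a list of them (pooled).
#' @param boundaries named segment ranges, see [segment_boundaries()].
#' @return A `comparison_result` with `test = "anova"`, the F statistic,
#'   p-value, and a `groups` data.frame (`segment`, `mean`, `sd`, `n`).
#' @export
segment_summary <- function(profile, boundaries = segment_boundaries()) {
  if (inherits(profile, "gradient_profile")) profile <- list(profile)
  df <- do.call(rbind, lapply(profile, function(p)
    data.frame(distance_cm = p$distance_cm, rpu = p$rpu)))
  df$segment <- .assign_segment(df$distance_cm, boundaries)
  df <- df[!is.na(df$segment), ]
  for (nm in names(boundaries)) {
    n_seg <- sum(df$segment == nm)
    assert_that(n_seg >= 2, "segment '", nm, "' has ", n_seg,
                " sample(s); need at least 2")
  }
  df$segment <- factor(df$segment, levels = names(boundaries))
  groups <- do.call(rbind, lapply(split(df$rpu, df$segment), function(v)
    data.frame(mean = mean(v), sd = sd(v), n = length(v))))
  groups <- data.frame(segment = rownames(groups), groups, row.names = NULL)
  if (var(df$rpu) == 0) # all samples identical: no separation at all
    return(.comparison_result("anova", statistic = 0, p_value = 1,
                              groups = groups))
  fit <- anova(lm(rpu ~ segment, data = df))
  .comparison_result("anova", statistic = fit[["F value"]][1],
                     p_value = fit[["Pr(>F)"]][1], groups = groups)
}

#' Paired comparison of mesenteric and antimesenteric arc profiles
#'
#' Matches the two profiles on common distances, restricts to the perfused
#' and watershed segments, and runs a paired two-sided t-test of the
#' mesenteric minus antimesenteric difference.
#'
#' @param profile_mes,profile_antimes `gradient_profile`s of the two arcs.
#' @param boundaries segment ranges; the `watershed` and `perfused` entries
#'   define the comparison window.
#' @return A `comparison_result` (`test = "t"`, paired) with both arcs'
#'   means in `groups` and the mean difference in `estimate`.
#' @export
compare_arcs <- function(profile_mes, profile_antimes,
                         boundaries = segment_boundaries()) {
  d <- intersect(profile_mes$distance_cm, profile_antimes$distance_cm)
  seg <- .assign_segment(d, boundaries)
  d <- d[seg %in% c("watershed", "perfused")]
  assert_that(length(d) >= 3, "need at least 3 matched points in the ",
              "perfused/watershed window; got ", length(d))
  x <- profile_mes$rpu[match(d, profile_mes$distance_cm)]
  y <- profile_antimes$rpu[match(d, profile_antimes$distance_cm)]
  groups <- data.frame(arc = c("mesenteric", "antimesenteric"),
                       mean = c(mean(x), mean(y)), sd = c(sd(x), sd(y)),
                       n = length(d))
  .paired_t(x, y, groups)
}

# paired t with explicit handling of degenerate differences (identical
# profiles -> p = 1; constant non-zero difference -> p = 0)
.paired_t <- function(x, y, groups) {
  d <- x - y
  if (all(d == 0))
    return(.comparison_result("t", statistic = 0, p_value = 1, groups = groups,
                              paired = TRUE, estimate = 0))
  if (sd(d) == 0)
    return(.comparison_result("t", statistic = sign(mean(d)) * Inf,
                              p_value = 0, groups = groups, paired = TRUE,
                              estimate = mean(d)))
  tt <- t.test(x, y, paired = TRUE)
  .comparison_result("t", statistic = unname(tt$statistic),
                     p_value = tt$p.value, groups = groups, paired = TRUE,
                     estimate = unname(tt$estimate))
}

#' Detect the sharp-decline onset in a gradient profile
#'
#' Fits every continuous two-piece linear model whose breakpoint sits at one
#' of the interior sample positions (hinge regression
#' `rpu ~ d + max(d - c, 0)`), selects the breakpoint minimizing the total
#' squared error, and accepts it only when the proximal (toward the stapled
#' edge) slope magnitude exceeds the distal slope magnitude by at least
#' `slope_ratio`. Returns `NA` ("no onset") otherwise -- e.g. for a
#' perfectly linear profile.
#'
#' @param profile a `gradient_profile`.
#' @param span optional `c(lo, hi)` distance window restricting the search
#'   to the declining portion (for the bowel-gradient scene, `c(2, 8)`
#'   excludes the flat ischemic and perfused plateaus); `NULL` uses the full
#'   profile.
#' @param slope_ratio minimum proximal/distal slope-magnitude ratio
#'   (default 2).
#' @return Breakpoint distance in cm, or `NA_real_` when no qualifying
#'   slope break exists. Attributes `slopes` (proximal, distal) and `sse`.
#' @export
detect_decline_onset <- function(profile, span = NULL, slope_ratio = 2) {
  d <- profile$distance_cm; y <- profile$rpu
  if (!is.null(span)) {
    keep <- d >= span[1] - 1e-9 & d <= span[2] + 1e-9
    d <- d[keep]; y <- y[keep]
  }
  assert_that(length(d) >= 6, "need at least 6 samples in the search span")
  # candidates need >= 2 support points strictly on each side
  cand <- d[seq(3, length(d) - 2)]
  best <- NULL
  for (cc in cand) {
    h <- pmax(d - cc, 0)
    fit <- lm(y ~ d + h)
    sse <- sum(fit$residuals^2)
    if (is.null(best) || sse < best$sse - 1e-12)
      best <- list(c = cc, sse = sse, coef = coef(fit))
  }
  slope_prox <- best$coef[["d"]]                 # slope below the breakpoint
  slope_dist <- best$coef[["d"]] + best$coef[["h"]] # slope above it
  if (!is.finite(slope_prox) || !is.finite(slope_dist) ||
      abs(slope_prox) < slope_ratio * abs(slope_dist))
    return(structure(NA_real_, slopes = c(proximal = slope_prox,
                                          distal = slope_dist),
                     sse = best$sse))
  structure(best$c, slopes = c(proximal = slope_prox, distal = slope_dist),
            sse = best$sse)
}

#' Ordinary least squares of mean RPU on mean arterial pressure
#'
#' @param series a data.frame with columns `map_mmHg` and `rpu` (an
#'   occlusion series for one segment), or numeric vectors via `map_mmHg`
#'   and `rpu` columns.
#' @return A `regression_result`: list with `slope` (percent per mmHg),
#'   `intercept`, `r_squared`, `n`.
#' @export
map_rpu_regression <- function(series) {
  assert_that(is.data.frame(series) && all(c("map_mmHg", "rpu") %in% names(series)),
              "series must have columns map_mmHg and rpu")
  assert_that(nrow(series) >= 3, "need at least 3 points")
  assert_that(var(series$map_mmHg) > 0, "MAP has zero variance")
  fit <- lm(rpu ~ map_mmHg, data = series)
  sse <- sum(fit$residuals^2)
  sst <- sum((series$rpu - mean(series$rpu))^2)
  r2 <- if (sst == 0) 1 else 1 - sse / sst
  structure(list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r_squared = r2, n = nrow(series)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat("<regression_result> RPU = ", signif(x$intercept, 4), " + ",
      signif(x$slope, 4), " * MAP;  R^2 = ", round(x$r_squared, 3),
      "  (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Paired comparison of the two anastomoses
#'
#' Paired two-sided t-test of the antimesenteric minus mesenteric RPU
#' difference over the 10 matched measurement points.
#'
#' @param am_points,m_points numeric vectors of matched RPU measurements
#'   (equal length, >= 3; the standard design uses 10 points over
#'   0--4.5 cm).
#' @return A `comparison_result` (`test = "t"`, paired).
#' @export
compare_anastomoses <- function(am_points, m_points) {
  assert_that(length(am_points) == length(m_points),
              "matched point sets differ in length (", length(am_points),
              " vs ", length(m_points), ")")
  assert_that(length(am_points) >= 3, "need at least 3 matched points")
  groups <- data.frame(anastomosis = c("antimesenteric", "mesenteric"),
                       mean = c(mean(am_points), mean(m_points)),
                       sd = c(sd(am_points), sd(m_points)),
                       n = length(am_points))
  .paired_t(am_points, m_points, groups)
}
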