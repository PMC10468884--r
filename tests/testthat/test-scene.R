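# Synthetic scene construction: gradient geometry, occlusion schedules,
# anastomosis profiles.

test_that("gradient config rejects invalid level ordering and geometry", {
  expect_error(gradient_scene_config(plateau_level = 50, watershed_level = 60),
               "levels")
  expect_error(gradient_scene_config(ischemic_level = -1), "levels")
  expect_error(gradient_scene_config(plateau_level = 107), "levels")
  expect_error(gradient_scene_config(decline_onset_cm = 0), "onset")
  expect_error(gradient_scene_config(arc_offset_split = 1.5), "arc_offset")
})

test_that("gradient scene hits the configured anchor levels along its arcs", {
  sc <- build_gradient_scene(default_gradient_config())
  # mesenteric arc in the perfused zone carries the full positive offset
  expect_equal(query_arc(sc, "mesenteric", 9), 100, tolerance = 1e-6)
  # deep ischemic zone is at the ischemic level on every arc
  expect_equal(query_arc(sc, "centerline", 1), 1.9, tolerance = 1e-6)
  expect_equal(query_arc(sc, "antimesenteric", 1), 1.9, tolerance = 1e-6)
  # centerline plateau equals the configured plateau level
  expect_equal(query_arc(sc, "centerline", 9), 98.8, tolerance = 1e-6)
  # antimesenteric perfused level = plateau - (1 - split) * offset
  expect_equal(query_arc(sc, "antimesenteric", 9), 83.4, tolerance = 0.01)
  # ground truth watershed mean at 0.5 cm sampling equals the configured level
  ws <- mean(query_arc(sc, "centerline", seq(4, 6, by = 0.5)))
  expect_equal(ws, 78.3, tolerance = 1e-6)
})

test_that("gradient scene satisfies the perfusion-field invariants", {
  sc <- build_gradient_scene(default_gradient_config())
  expect_true(all(sc$field >= 0 & sc$field <= 110))
  expect_true(all(sc$mask[sc$field > 0]))
  # perfusion is non-increasing toward the stapled edge along every arc
  d <- seq(0, 10, by = 0.1)
  for (arc in c("centerline", "mesenteric", "antimesenteric")) {
    v <- query_arc(sc, arc, d)
    expect_true(all(diff(v) >= -1e-9), info = arc)
  }
})

test_that("gradient scene has a detectable two-piece slope structure", {
  sc <- build_gradient_scene(default_gradient_config())
  slope_on <- function(lo, hi) {
    d <- seq(lo, hi, by = 0.25)
    v <- query_arc(sc, "centerline", d)
    unname(coef(lm(v ~ d))[2])
  }
  steep <- slope_on(3, 5)   # proximal piece, between ischemic zone and onset
  gentle <- slope_on(6, 8)  # distal piece
  expect_gt(abs(steep), 2 * abs(gentle))
})

test_that("scene construction is deterministic and queries are exact at nodes", {
  a <- build_gradient_scene(default_gradient_config())
  b <- build_gradient_scene(default_gradient_config())
  expect_identical(a$field, b$field)
  # interpolation agrees with stored grid values exactly at pixel nodes
  pt <- arc_point(a, "centerline", 3)
  expect_identical(bilinear <- query_arc(a, "centerline", 3),
                   a$field[round(pt$row), round(pt$col)])
})

test_that("perfusion_scene validates its invariants", {
  f <- matrix(50, 10, 10)
  expect_error(perfusion_scene(f, mask = matrix(FALSE, 10, 10)), "mask")
  expect_error(perfusion_scene(matrix(120, 10, 10)), "0, 110")
  expect_error(perfusion_scene(f, px_per_cm = 0), "px_per_cm")
  bad_arc <- list(a = data.frame(row = c(1, 50), col = c(1, 1)))
  expect_error(perfusion_scene(f, arcs = bad_arc), "arc")
})

test_that("occlusion schedules decrease MAP strictly and pin the endpoints", {
  for (kind in c("arterial", "venous")) {
    sch <- build_occlusion_schedule(kind, 10, occlusion_config(kind, seed = 3))
    expect_true(all(diff(sch$map_mmHg) < 0))
    expect_identical(sch$scale[1], 1)          # no occlusion: full perfusion
    expect_lte(sch$scale[10], 0.05)            # complete occlusion: near zero
    expect_true(all(diff(sch$scale) <= 0))     # progressive clamp
    expect_true(all(sch$scale >= 0 & sch$scale <= 1))
  }
  expect_error(build_occlusion_schedule("arterial", 2), "n_steps")
  expect_error(occlusion_config("portal"), "arg")
})

test_that("venous occlusion is more pressure-sensitive than arterial", {
  art <- build_occlusion_schedule("arterial", 10, occlusion_config("arterial"))
  ven <- build_occlusion_schedule("venous", 10, occlusion_config("venous"))
  expect_gt(abs(attr(ven, "sensitivity")), abs(attr(art, "sensitivity")))
})

test_that("MAP and perfusion scale stay strongly correlated at default noise", {
  for (s in 1:10) {
    sch <- build_occlusion_schedule("arterial", 10,
                                    occlusion_config("arterial", seed = s))
    expect_gte(cor(sch$map_mmHg, sch$scale), 0.85)
  }
})

test_that("anastomosis scene reproduces its configured point profiles", {
  cfg <- default_anastomosis_config()
  sc <- build_anastomosis_scene(cfg)
  d <- attr(sc, "sample_points_cm")
  am <- query_arc(sc, "anastomosis_AM", d)
  m <- query_arc(sc, "anastomosis_M", d)
  expect_equal(am, cfg$am_profile, tolerance = 0.02)
  expect_equal(m, cfg$m_profile, tolerance = 0.02)
  expect_true(all(am > m))                       # AM exceeds M at every point
  expect_equal(mean(cfg$am_profile), 54, tolerance = 0.01)
  expect_equal(mean(cfg$m_profile), 38, tolerance = 0.01)
  expect_equal(sd(cfg$am_profile), 18, tolerance = 0.2)
  expect_equal(sd(cfg$m_profile), 15, tolerance = 0.2)
})

test_that("anastomosis config rejects malformed profiles", {
  expect_error(anastomosis_scene_config(am_profile = rep(50, 9)), "10 matched")
  expect_error(anastomosis_scene_config(am_profile = seq(30, 10, length.out = 10),
                                        m_profile = seq(40, 20, length.out = 10)),
               "exceed")
  expect_error(anastomosis_scene_config(am_profile = seq(25, 80, length.out = 10)),
               "exceed|decline")
})

test_that("scaling a scene scales its field and nothing else", {
  sc <- build_gradient_scene(default_gradient_config())
  half <- scale_scene(sc, 0.5)
  expect_equal(half$field, sc$field * 0.5)
  expect_identical(half$mask, sc$mask)
  expect_error(scale_scene(sc, 2), "scale")
})
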