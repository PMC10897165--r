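test_that("path distance handles the elementary cases", {
  stat <- mk_traj(rep(100, 50), rep(100, 50))
  expect_equal(path_distance(stat), 0)
  st <- straight_traj(2, 60)
  expect_equal(path_distance(st, 0, 60), 120, tolerance = 1e-9)
  expect_error(path_distance(st, -1, 60), "outside")
  expect_error(path_distance(st, 30, 10), "t0_s < t1_s")
})

test_that("circle path distance matches the chord-sum closed form", {
  tr <- circle_traj(10, pi / 5, 60, fps = 25)
  expect_equal(path_distance(tr, 0, 60),
               chord_sum_oracle(10, pi / 5, 60, 25),
               tolerance = 1e-9)
  # frozen value: 1500 chords of 2*10*sin(pi*0.04/10)
  expect_equal(path_distance(tr, 0, 60), 376.9753, tolerance = 1e-4)
})

test_that("steps straddling the window are prorated linearly", {
  tr <- straight_traj(25, 1, fps = 1)   # 1 step of 25 mm over [0, 1)
  expect_equal(path_distance(tr, 0, 0.4), 10)
  expect_equal(path_distance(tr, 0.25, 0.75), 12.5)
})

test_that("refining the sampling rate increases chord sums toward arc length", {
  arc <- 10 * pi / 5 * 60                       # true arc length
  d <- vapply(c(5, 10, 25, 100), function(fps)
    path_distance(circle_traj(10, pi / 5, 60, fps = fps)), numeric(1))
  expect_true(all(diff(d) > 0))
  expect_true(all(d < arc))
  expect_equal(d[4], arc, tolerance = 1e-4)
})

test_that("distance is invariant under rigid motions", {
  set.seed(21)
  w <- random_walk_xy(200, 2)
  tr <- mk_traj(w$x, w$y)
  th <- 0.7
  xr <- 300 + cos(th) * (w$x - 500) - sin(th) * (w$y - 500)
  yr <- 400 + sin(th) * (w$x - 500) + cos(th) * (w$y - 500)
  expect_equal(path_distance(mk_traj(xr, yr)), path_distance(tr),
               tolerance = 1e-9)
})

test_that("binned activity pools distance into labelled 1-min bins", {
  sch <- make_pmr_schedule("methods")
  tr <- straight_traj(1 / 60, 4500, fps = 5, dir = c(1, 0))  # 1 mm/min
  b <- bin_activity(tr, sch, 60)
  expect_equal(nrow(b), 75)
  expect_equal(b$distance_mm, rep(1, 75), tolerance = 1e-9)
  expect_equal(sum(b$distance_mm), path_distance(tr, 0, 4500),
               tolerance = 1e-9)
  expect_equal(b$epoch[56], "L1")
  b90 <- bin_activity(tr, sch, 90)
  expect_equal(nrow(b90), 50)
  expect_error(bin_activity(tr, sch, 301), "shortest epoch")
})

test_that("bin sums conserve total distance for irregular motion", {
  set.seed(31)
  sch <- make_open_field_schedule(120)
  w <- random_walk_xy(120 * 25, 1.5)
  tr <- mk_traj(w$x, w$y)
  b <- bin_activity(tr, sch, 60)
  expect_equal(sum(b$distance_mm), path_distance(tr, 0, 120),
               tolerance = 1e-9)
})

test_that("per-minute epoch means behave and fail loudly on empty epochs", {
  sch <- make_open_field_schedule(180, label = "open_field")
  # piecewise speeds: 10, 20, 30 mm/min across the three minutes
  fps <- 5
  sp <- rep(c(10, 20, 30) / 60, each = 180 / 3 * fps)
  x <- 100 + cumsum(c(0, sp / fps))
  tr <- mk_traj(x, rep(100, length(x)), fps = fps)
  b <- bin_activity(tr, sch, 60)
  expect_equal(mean_distance_per_min(b, "open_field"), 20, tolerance = 1e-9)
  expect_error(mean_distance_per_min(b, "L0"), "no bins")
})

test_that("light/dark cycle ratios divide dark by light per-minute means", {
  sch <- light_schedule(data.frame(
    start_s = c(0, 120, 240, 360),
    end_s = c(120, 240, 360, 480),
    condition = c("light", "dark", "light", "dark"),
    label = c("L1", "D1", "L2", "D2"), cycle = c(1L, 1L, 2L, 2L)))
  fps <- 5
  sp <- rep(c(1, 1.5, 2, 2) / 1, c(120, 120, 120, 120) * fps)   # mm/s
  x <- 100 + cumsum(c(0, sp / fps))
  tr <- mk_traj(x, rep(100, length(x)), fps = fps,
                arena = arena_geometry("long", "rectangle", width_mm = 5000,
                                       height_mm = 200, edge_band_mm = 10))
  b <- bin_activity(tr, sch, 60)
  r1 <- light_dark_ratio(b, 1)
  expect_equal(r1$ratio, 1.5, tolerance = 1e-9)
  expect_false(r1$undefined)
  expect_equal(light_dark_ratio(b, 2)$ratio, 1.0, tolerance = 1e-9)
  expect_error(light_dark_ratio(b, 3), "cycle 3")
})

test_that("a zero light-phase mean flags the ratio as undefined", {
  sch <- light_schedule(data.frame(
    start_s = c(0, 60), end_s = c(60, 120),
    condition = c("light", "dark"), label = c("L1", "D1"),
    cycle = c(1L, 1L)))
  x <- c(rep(100, 60 * 5 + 1), 100 + cumsum(rep(0.2, 60 * 5)))
  tr <- mk_traj(x, rep(100, length(x)), fps = 5)
  r <- light_dark_ratio(bin_activity(tr, sch, 60), 1)
  expect_true(r$undefined)
  expect_true(is.na(r$ratio))
})
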