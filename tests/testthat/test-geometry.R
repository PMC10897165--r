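test_that("standard arena presets carry the published dimensions", {
  w <- make_standard_arena("well24_7dpf")
  expect_equal(w$shape, "circle")
  expect_equal(w$radius_mm, 9)

  d <- make_standard_arena("dish35_15dpf")
  expect_equal(d$radius_mm, 17.5)

  t <- make_standard_arena("tank300_open")
  expect_equal(c(t$width_mm, t$height_mm), c(300, 300))

  m <- make_standard_arena("mating_tank")
  expect_equal(c(m$width_mm, m$height_mm), c(210, 100))
  expect_setequal(names(m$regions), c("social", "nonsocial"))
  expect_equal(m$regions$social$params$x0, 140)

  expect_error(make_standard_arena("foo"), "well24_7dpf")
})

test_that("inner zone construction follows the radius fraction", {
  w <- make_standard_arena("well24_7dpf")
  expect_equal(make_inner_zone(w, 0.5)$params$r, 4.5)
  expect_equal(make_inner_zone(make_standard_arena("dish35_15dpf"))$params$r,
               8.75)
  expect_error(make_inner_zone(w, 1.0), "between 0 and 1")
  expect_error(make_inner_zone(make_standard_arena("tank300_open")),
               "circular")
})

test_that("region membership is boundary-inclusive and deterministic", {
  disk <- region("d", "disk", cx = 0, cy = 0, r = 5)
  expect_true(region_contains(disk, 5, 0))          # on the boundary
  expect_true(region_contains(disk, 0, 0))
  expect_false(region_contains(disk, 5.0001, 0))
  ann <- region("a", "annulus", cx = 0, cy = 0, r0 = 2, r1 = 5)
  expect_true(all(region_contains(ann, c(2, 5), c(0, 0))))
  expect_false(region_contains(ann, 1.999, 0))
  rect <- region("r", "rectangle", x0 = 0, x1 = 4, y0 = 0, y1 = 2)
  expect_true(region_contains(rect, 4, 2))
  hp <- region("h", "half_plane", a = 1, b = 0, c = 3)
  expect_true(all(region_contains(hp, c(3, -10), c(7, 0))))
  expect_false(region_contains(hp, 3.001, 0))
})

test_that("region membership agrees with areas on a fine grid", {
  # rasterized membership mass must recover analytic areas
  g <- expand.grid(x = seq(-10, 10, by = 0.1), y = seq(-10, 10, by = 0.1))
  cell <- 0.1^2
  disk <- region("d", "disk", cx = 1, cy = -2, r = 4)
  expect_equal(sum(region_contains(disk, g$x, g$y)) * cell, pi * 16,
               tolerance = 0.01)
  ann <- region("a", "annulus", cx = 0, cy = 0, r0 = 3, r1 = 6)
  expect_equal(sum(region_contains(ann, g$x, g$y)) * cell, pi * (36 - 9),
               tolerance = 0.01)
  # off-lattice bounds so inclusive boundaries do not add a full grid row
  rect <- region("r", "rectangle", x0 = -3.05, x1 = 1.95, y0 = 0.03, y1 = 4.03)
  expect_equal(sum(region_contains(rect, g$x, g$y)) * cell, 20,
               tolerance = 0.01)
})

test_that("photomotor schedules are contiguous and span the stated totals", {
  for (v in c("figure", "methods")) {
    s <- make_pmr_schedule(v)
    expect_true(all(s$end_s > s$start_s))
    expect_equal(s$start_s[1], 0)
    expect_equal(s$start_s[-1], s$end_s[-nrow(s)])   # no gaps
    expect_equal(sum(s$end_s - s$start_s), schedule_span(s))
    expect_true(all(c("L0", "L1", "D1", "L2", "D2") %in% s$label))
  }
  expect_equal(schedule_span(make_pmr_schedule("methods")), 4500)
  expect_equal(schedule_span(make_pmr_schedule("figure")), 4800)
})

test_that("epoch lookup uses left-closed right-open epochs", {
  s <- make_pmr_schedule("methods")
  expect_equal(epoch_at(s, c(0, 3299.9, 3300, 3600)),
               c("L0", "L0", "L1", "D1"))
  expect_equal(epoch_at(s, 3600, "condition"), "dark")
  expect_true(is.na(epoch_at(s, 4500.5)))
})

test_that("arena invariants are enforced", {
  expect_error(arena_geometry("a", "circle", radius_mm = -1, edge_band_mm = 1),
               "radius")
  expect_error(arena_geometry("a", "circle", radius_mm = 5, edge_band_mm = 5),
               "edge_band_mm")
  expect_error(light_schedule(data.frame(start_s = 1, end_s = 2,
                                         condition = "light", label = "L0",
                                         cycle = NA)),
               "start at 0")
})
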