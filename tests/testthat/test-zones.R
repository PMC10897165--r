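test_that("zone occupancy brackets: containment and exclusion", {
  w <- make_standard_arena("well24_7dpf")
  inner <- make_inner_zone(w)
  # fish jittering around the centre: fully inside
  set.seed(2)
  tin <- trajectory("f", w, (0:199) / 25, rnorm(200, 0, 0.5),
                    rnorm(200, 0, 0.5), 25)
  oin <- zone_occupancy(tin, inner)
  expect_equal(oin$time_fraction, 1)
  expect_equal(oin$distance_fraction, 1)
  # fish glued to the wall: fully outside the 4.5 mm inner disk
  th <- seq(0, 4 * pi, length.out = 200)
  twall <- trajectory("f", w, (0:199) / 25, 8.8 * cos(th), 8.8 * sin(th), 25)
  owall <- zone_occupancy(twall, inner)
  expect_equal(owall$time_fraction, 0)
  expect_equal(owall$distance_fraction, 0)
})

test_that("uniform positions give area-proportional dwell", {
  w <- make_standard_arena("well24_7dpf")
  set.seed(7)
  n <- 4000
  r <- 9 * sqrt(runif(n)); a <- runif(n, 0, 2 * pi)
  tr <- trajectory("f", w, (0:(n - 1)) / 25, r * cos(a), r * sin(a), 25)
  tf <- zone_occupancy(tr, make_inner_zone(w))$time_fraction
  expect_lt(abs(tf - 0.25), 3 * sqrt(0.25 * 0.75 / n))
})

test_that("partition closure: complementary zones sum to one", {
  w <- make_standard_arena("well24_7dpf")
  set.seed(8)
  n <- 1000
  r <- 9 * sqrt(runif(n)); a <- runif(n, 0, 2 * pi)
  tr <- trajectory("f", w, (0:(n - 1)) / 25, r * cos(a), r * sin(a), 25)
  oi <- zone_occupancy(tr, make_inner_zone(w))
  oo <- zone_occupancy(tr, make_outer_zone(w))
  expect_equal(oi$time_fraction + oo$time_fraction, 1, tolerance = 1e-9)
  expect_equal(oi$distance_fraction + oo$distance_fraction, 1,
               tolerance = 1e-9)

  m <- make_standard_arena("mating_tank")
  set.seed(9)
  tm <- trajectory("f", m, (0:999) / 25, runif(1000, 1, 209),
                   runif(1000, 1, 99), 25)
  os <- zone_occupancy(tm, m$regions$social)
  on <- zone_occupancy(tm, m$regions$nonsocial)
  expect_equal(os$time_fraction + on$time_fraction, 1, tolerance = 1e-9)
})

test_that("occupancy is invariant to time reversal", {
  w <- make_standard_arena("well24_7dpf")
  set.seed(12)
  n <- 500
  r <- 8.5 * sqrt(runif(n)); a <- runif(n, 0, 2 * pi)
  x <- r * cos(a); y <- r * sin(a)
  tr <- trajectory("f", w, (0:(n - 1)) / 25, x, y, 25)
  rv <- trajectory("f", w, (0:(n - 1)) / 25, rev(x), rev(y), 25)
  o1 <- zone_occupancy(tr, make_inner_zone(w))
  o2 <- zone_occupancy(rv, make_inner_zone(w))
  expect_equal(o1$time_fraction, o2$time_fraction)
  expect_equal(o1$distance_fraction, o2$distance_fraction)
})

test_that("steps are assigned to zones by their midpoints", {
  w <- make_standard_arena("well24_7dpf")
  inner <- make_inner_zone(w)                    # radius 4.5
  # one step from (2,0) to (6,0): midpoint (4,0) inside -> fully inner
  tr <- trajectory("f", w, c(0, 0.04), c(2, 6), c(0, 0), 25)
  expect_equal(zone_occupancy(tr, inner)$distance_fraction, 1)
  # one step from (4,0) to (8,0): midpoint (6,0) outside -> fully outer
  tr2 <- trajectory("f", w, c(0, 0.04), c(4, 8), c(0, 0), 25)
  expect_equal(zone_occupancy(tr2, inner)$distance_fraction, 0)
})

test_that("social preference reports in-region and away fractions", {
  m <- make_standard_arena("mating_tank")
  tr <- trajectory("f", m, (0:99) / 25, runif(100, 150, 205),
                   runif(100, 10, 90), 25)
  sp <- social_preference(tr)
  expect_equal(sp$time_fraction, 1)
  expect_equal(sp$away_distance_fraction, 1 - sp$distance_fraction)
  wt <- trajectory("f", make_standard_arena("tank300_open"),
                   (0:99) / 25, runif(100, 10, 290), runif(100, 10, 290), 25)
  expect_error(social_preference(wt), "social")
})

test_that("heatmaps conserve dwell time and accumulate across fish", {
  m <- make_standard_arena("mating_tank")
  stat <- trajectory("f", m, (0:(60 * 25 - 1)) / 25,
                     rep(30.2, 1500), rep(40.7, 1500), 25)
  hm <- occupancy_heatmap(stat, 5)
  expect_equal(sum(hm$dwell_s > 0), 1)              # single cell
  expect_equal(max(hm$dwell_s), 60, tolerance = 1 / 25)
  set.seed(14)
  two <- lapply(1:2, function(i)
    trajectory(paste0("f", i), m, (0:(30 * 25 - 1)) / 25,
               runif(750, 1, 209), runif(750, 1, 99), 25))
  hm2 <- occupancy_heatmap(two, 5)
  expect_equal(sum(hm2$dwell_s), 60, tolerance = 2 / 25)
  expect_error(occupancy_heatmap(two, 0.5), ">= 1 mm")
})

test_that("heatmap text export round-trips the grid spec", {
  m <- make_standard_arena("mating_tank")
  tr <- trajectory("f", m, (0:99) / 25, runif(100, 1, 209),
                   runif(100, 1, 99), 25)
  hm <- occupancy_heatmap(tr, 5)
  p <- withr::local_tempfile(fileext = ".txt")
  write_heatmap(hm, p)
  lines <- readLines(p)
  expect_match(lines[1], "cell_mm=5")
  expect_equal(length(lines) - 1, nrow(hm$dwell_s))
  vals <- read.table(text = lines[-1])
  expect_equal(sum(as.matrix(vals)), sum(hm$dwell_s), tolerance = 1e-6)
})
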