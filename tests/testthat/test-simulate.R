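test_that("agent parameter validation rejects out-of-range values", {
  expect_error(agent_params(mean_speed_mm_s = 0), "mean_speed")
  expect_error(agent_params(wall_bias = 1.2), "wall_bias")
  expect_error(agent_params(social_weight = -0.1), "social_weight")
  expect_error(agent_params(dark_multiplier = 0), "dark_multiplier")
  expect_error(agent_params(bout_rates = c(nope = 1)), "bout_rates")
})

test_that("identical seeds reproduce identical fish and shoals", {
  a <- make_standard_arena("tank300_open")
  p <- cohort_defaults("repetitive")$mut_params
  s1 <- simulate_fish(p, a, duration_s = 60, seed = 9)
  s2 <- simulate_fish(p, a, duration_s = 60, seed = 9)
  expect_identical(s1$trajectory$x_mm, s2$trajectory$x_mm)
  expect_identical(s1$truth$bouts, s2$truth$bouts)
  s3 <- simulate_fish(p, a, duration_s = 60, seed = 10)
  expect_false(identical(s1$trajectory$x_mm, s3$trajectory$x_mm))
  sh1 <- simulate_shoal(3, p, a, 20, seed = 5)
  sh2 <- simulate_shoal(3, p, a, 20, seed = 5)
  expect_identical(sh1$trajectories[[2]]$y_mm, sh2$trajectories[[2]]$y_mm)
})

test_that("simulated positions stay inside the arena", {
  for (preset in c("well24_7dpf", "tank300_open", "mating_tank")) {
    a <- make_standard_arena(preset)
    p <- agent_params(mean_speed_mm_s = if (preset == "well24_7dpf") 3 else 60,
                      wall_bias = 0.4,
                      social_weight = if (preset == "mating_tank") 0.5 else 0)
    tr <- simulate_fish(p, a, duration_s = 60, seed = 3)$trajectory
    expect_true(all(arena_contains(a, tr$x_mm, tr$y_mm)))
  }
})

test_that("injected ground-truth bouts are disjoint per label and in range", {
  a <- make_standard_arena("tank300_open")
  p <- cohort_defaults("repetitive")$mut_params
  for (seed in c(2, 4, 6)) {
    sim <- simulate_fish(p, a, duration_s = 300, seed = seed)
    b <- sim$truth$bouts
    expect_true(all(b$start_s >= 0 & b$end_s <= 300))
    for (lab in unique(b$label)) {
      bi <- b[b$label == lab, ]
      if (nrow(bi) > 1) {
        bi <- bi[order(bi$start_s), ]
        expect_true(all(bi$start_s[-1] >= bi$end_s[-nrow(bi)] - 1e-9))
      }
    }
  }
})

test_that("empirical speed matches the gamma parameters", {
  a <- arena_geometry("huge", "rectangle", width_mm = 5000, height_mm = 5000,
                      edge_band_mm = 100)
  p <- agent_params(mean_speed_mm_s = 40, speed_shape = 4, wall_bias = 0)
  tr <- simulate_fish(p, a, duration_s = 400, seed = 8)$trajectory  # 1e4 steps
  sp <- sqrt(diff(tr$x_mm)^2 + diff(tr$y_mm)^2) * tr$frame_rate_hz
  n <- length(sp)
  se <- (40 / sqrt(4)) / sqrt(n)
  expect_lt(abs(mean(sp) - 40), 3 * se + 0.2)   # small reflection allowance
})

test_that("dark epochs multiply speed by the dark multiplier", {
  a <- make_standard_arena("well24_7dpf")
  sch <- make_pmr_schedule("figure")
  p <- agent_params(mean_speed_mm_s = 3, speed_shape = 3, turn_sd_rad = 0.7,
                    wall_bias = 0.3, dark_multiplier = 2)
  rs <- unlist(lapply(1:6, function(s) {
    b <- bin_activity(simulate_fish(p, a, sch, seed = 100 + s)$trajectory, sch)
    c(light_dark_ratio(b, 1)$ratio, light_dark_ratio(b, 2)$ratio)
  }))
  expect_equal(mean(rs), 2, tolerance = 0.08)
})

test_that("uncoupled shoal members have uncorrelated turning", {
  a <- make_standard_arena("tank300_open")
  p <- agent_params(mean_speed_mm_s = 60, wall_bias = 0, cohesion = 0)
  sh <- simulate_shoal(2, p, a, 200, seed = 77)$trajectories
  turn_of <- function(tr) {
    h <- atan2(diff(tr$y_mm), diff(tr$x_mm))
    d <- diff(h); ((d + pi) %% (2 * pi)) - pi
  }
  r <- cor(turn_of(sh[[1]]), turn_of(sh[[2]]))
  expect_lt(abs(r), 3 / sqrt(200 * 25 - 2))
})

test_that("cohesion contracts the shoal", {
  a <- make_standard_arena("tank300_open")
  wins <- 0
  for (s in 1:10) {
    hi <- agent_params(mean_speed_mm_s = 60, wall_bias = 0.1, cohesion = 0.9)
    lo <- agent_params(mean_speed_mm_s = 60, wall_bias = 0.1, cohesion = 0)
    ih <- interindividual_distance(
      simulate_shoal(6, hi, a, 90, seed = 400 + s)$trajectories)$mean_mm
    il <- interindividual_distance(
      simulate_shoal(6, lo, a, 90, seed = 400 + s)$trajectories)$mean_mm
    wins <- wins + (ih < il)
  }
  expect_gte(wins, 9)
})

test_that("cohorts write one tracking and one truth file per replicate", {
  dir <- withr::local_tempdir()
  co <- make_cohort(2, assay = "repetitive", seed = 42, dir = dir,
                    duration_s = 30)
  expect_equal(nrow(co$manifest), 4)
  expect_true(all(file.exists(co$manifest$tracking)))
  expect_true(all(file.exists(co$manifest$truth)))
  expect_setequal(co$manifest$group, c("wt", "mut"))
  # reading one back reproduces the simulated trajectory
  tr <- read_tracking(co$manifest$tracking[1], co$arena)
  expect_equal(tr[[1]]$x_mm, co$trajectories[[1]]$x_mm, tolerance = 1e-6)
  expect_error(make_cohort(2, assay = "nope"), "arg")
})

test_that("seeded cohorts are byte-for-byte reproducible", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  make_cohort(2, assay = "shoaling", seed = 7, dir = d1, duration_s = 20)
  make_cohort(2, assay = "shoaling", seed = 7, dir = d2, duration_s = 20)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})
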