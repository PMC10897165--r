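test_that("swim segmentation splits on stops and bridges blips", {
  # always moving -> one interval spanning the recording
  mv <- straight_traj(20, 10)
  iv <- segment_swimming(mv)
  expect_equal(nrow(iv), 1)
  expect_equal(c(iv$start_s, iv$end_s), c(0, 10), tolerance = 0.2)
  # never moving -> none
  expect_equal(nrow(segment_swimming(mk_traj(rep(1, 100), rep(1, 100)))), 0)
  # 10 s swim, 1 s stop, 10 s swim -> two intervals
  fps <- 25
  sp <- c(rep(20, 10 * fps), rep(0, 1 * fps), rep(20, 10 * fps))
  x <- 100 + cumsum(c(0, sp / fps))
  tr <- mk_traj(x, rep(100, length(x)))
  expect_equal(nrow(segment_swimming(tr)), 2)
})

test_that("confined swimming is stereotypic iff long enough", {
  set.seed(41)
  mk_confined <- function(dur) {
    n <- round(dur * 25)
    # jitter swim inside a 5 mm disk at ~10 mm/s
    a <- cumsum(rnorm(n, 0, 1))
    x <- 500 + 2.4 * cos(a)
    y <- 500 + 2.4 * sin(a)
    mk_traj(x, y)
  }
  expect_equal(nrow(detect_stereotypic(mk_confined(10))), 1)
  expect_equal(nrow(detect_stereotypic(mk_confined(4))), 0)
})

test_that("a span crossing 30 mm truncates the bout before the violation", {
  fps <- 25
  # 7 s of tight jitter, then a straight dash away
  set.seed(42)
  n1 <- 7 * fps
  a <- cumsum(rnorm(n1, 0, 1))
  x <- c(500 + 2 * cos(a), 500 + seq(2, 120, by = 2))
  y <- c(500 + 2 * sin(a), rep(500, 60))
  tr <- mk_traj(x, y)
  b <- detect_stereotypic(tr)
  expect_equal(nrow(b), 1)
  expect_lt(b$end_s[1], 8)
  expect_lt(b$max_span_mm[1], 30)
})

test_that("greedy spans match the all-pairs oracle on random walks", {
  win <- data.frame(start_s = 0, end_s = 1e6)
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(100:400, 1)
    w <- random_walk_xy(n - 1, sample(c(0.5, 1.5, 3), 1))
    tr <- mk_traj(w$x, w$y)
    got <- detect_stereotypic(tr, swim = data.frame(start_s = 0,
                                                    end_s = max(tr$t_s)))
    want <- oracle_stereo(tr$t_s, tr$x_mm, tr$y_mm)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start_s, want$start_s)
      expect_equal(got$end_s, want$end_s)
    }
  }
})

test_that("wall-following loops are counted with their orientation", {
  arena <- arena_geometry("disc", "circle", radius_mm = 150, edge_band_mm = 35)
  # 3 ccw revolutions (plus a margin) riding 20 mm inside the wall
  tr <- circle_traj(130, 2 * pi / 10, 31, fps = 25, arena = arena)
  b <- detect_large_circle(tr, arena)
  expect_equal(nrow(b), 3)
  expect_true(all(b$label == "large_circle_ccw"))
  # half a revolution: nothing
  half <- circle_traj(130, 2 * pi / 10, 4.9, fps = 25, arena = arena)
  expect_equal(nrow(detect_large_circle(half, arena)), 0)
  # clockwise
  cw <- circle_traj(130, -2 * pi / 10, 21, fps = 25, arena = arena)
  bc <- detect_large_circle(cw, arena)
  expect_equal(nrow(bc), 2)
  expect_true(all(bc$label == "large_circle_cw"))
})

test_that("noisy wall-following matches the winding-number oracle", {
  arena <- arena_geometry("disc", "circle", radius_mm = 150, edge_band_mm = 35)
  for (seed in 1:10) {
    set.seed(seed)
    n <- 1500
    dth <- 0.022 + rnorm(n, 0, 0.006)      # monotone-on-average rotation
    th <- cumsum(c(runif(1, 0, 2 * pi), dth))
    r <- 128 + rnorm(n + 1, 0, 2)
    tr <- trajectory("f", arena, (0:n) / 25, r * cos(th), r * sin(th), 25)
    loops <- nrow(detect_large_circle(tr, arena))
    expect_equal(loops,
                 floor(abs(winding_total(tr$x_mm, tr$y_mm)) / (2 * pi)))
  }
})

test_that("time reversal swaps loop orientation with equal counts", {
  arena <- arena_geometry("disc", "circle", radius_mm = 150, edge_band_mm = 35)
  tr <- circle_traj(130, 2 * pi / 8, 41, fps = 25, arena = arena)
  rv <- trajectory("f", arena, tr$t_s, rev(tr$x_mm), rev(tr$y_mm), 25)
  fwd <- detect_large_circle(tr, arena)
  bwd <- detect_large_circle(rv, arena)
  expect_equal(nrow(fwd), nrow(bwd))
  expect_true(all(fwd$label == "large_circle_ccw"))
  expect_true(all(bwd$label == "large_circle_cw"))
})

test_that("an out-and-back along one wall is one event", {
  ta <- make_standard_arena("tank300_open")
  # ride 10 mm from the bottom wall: out 100 mm, straight back
  xs <- c(seq(100, 200, by = 2), seq(198, 100, by = -2))
  tr <- mk_traj(xs, rep(10, length(xs)), arena = ta)
  b <- detect_back_and_forth(tr, ta)
  expect_equal(nrow(b), 1)
  expect_equal(b$label, "back_and_forth")
  # a single pass without return: nothing
  one_way <- mk_traj(seq(100, 250, by = 2), rep(10, 76), arena = ta)
  expect_equal(nrow(detect_back_and_forth(one_way, ta)), 0)
})

test_that("adjacent-edge L excursions count; opposite edges never do", {
  ta <- make_standard_arena("tank300_open")
  # L: along the bottom into the corner, up the right wall, and back
  leg1 <- cbind(seq(240, 290, by = 2), rep(10, 26))
  leg2 <- cbind(rep(290, 25), seq(12, 60, by = 2))
  path <- rbind(leg1, leg2, leg2[rev(seq_len(nrow(leg2))), ],
                leg1[rev(seq_len(nrow(leg1))), ])
  tr <- mk_traj(path[, 1], path[, 2], arena = ta)
  expect_equal(nrow(detect_back_and_forth(tr, ta)), 1)
  # full traverse of the bottom wall touching both vertical walls
  m <- make_standard_arena("mating_tank")
  xs <- c(seq(10, 200, by = 2), seq(198, 10, by = -2))
  tr2 <- mk_traj(xs, rep(10, length(xs)), arena = m)
  expect_equal(nrow(detect_back_and_forth(tr2, m)), 0)
  # circular arenas are rejected
  expect_error(detect_back_and_forth(circle_traj(8, 1, 5),
                                     arena_geometry("c", "circle",
                                                    radius_mm = 15,
                                                    edge_band_mm = 3)),
               "rectangular")
})

test_that("bout summaries partition counts and durations by label", {
  s <- summarize_repetitive(empty_bouts_df <- data.frame(
    fish_id = character(), label = character(),
    start_s = numeric(), end_s = numeric()), c(0, 100))
  expect_true(all(s$n_events == 0))
  b <- rbind(
    data.frame(fish_id = "f", label = "stereotypic",
               start_s = c(1, 10, 20), end_s = c(7, 16, 26)),
    data.frame(fish_id = "f", label = "back_and_forth",
               start_s = 40, end_s = 44))
  s2 <- summarize_repetitive(b, c(0, 100))
  expect_equal(s2$n_events[s2$label == "stereotypic"], 3)
  expect_equal(s2$total_duration_s[s2$label == "stereotypic"], 18)
  expect_equal(s2$n_events[s2$label == "back_and_forth"], 1)
  expect_error(summarize_repetitive(b, c(0, 30)), "outside")
})
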