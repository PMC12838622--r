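test_that("count_hits tallies events by hand and bin", {
  expect_equal(count_hits(task_log())$total, c(left = 0, right = 0))

  hit <- data.frame(time = c(1, 2, 3, 4, 5),
                    hand = c("left", "left", "left", "right", "right"),
                    bin = c(2L, 2L, 2L, 13L, 13L))
  h <- count_hits(task_log(hits = hit))
  expect_equal(h$left[3], 3)   # bin 2 is index 3 (0-based bins)
  expect_equal(h$right[14], 2)
  expect_equal(sum(h$left), 3)
  expect_equal(sum(h$right), 2)
  expect_equal(unname(h$total), c(3, 2))
})

test_that("parked paddles outside all lanes collect zero hits", {
  cfg <- object_hit_config(
    duration = 30, objects_per_bin = 30L, n_bins = 2L,
    policy_left = list(reaction_delay = 0.2, max_speed = 0,
                       park = c(-10, -10)),
    policy_right = list(reaction_delay = 0.2, max_speed = 0,
                        park = c(90, -10)))
  log <- simulate_object_hit(cfg, seed = 5)
  expect_equal(nrow(log$hits), 0)
})

test_that("speed and acceleration recover closed-form kinematics", {
  rate <- 200
  t <- seq(0, 5 - 1 / rate, by = 1 / rate)

  still <- hand_speed_accel(timeseries(rep(3, length(t)), rate),
                            timeseries(rep(4, length(t)), rate),
                            smooth_hz = NULL)
  expect_equal(still$mean_speed, 0)
  expect_equal(still$mean_abs_accel, 0)

  lin <- hand_speed_accel(timeseries(12 * t, rate),
                          timeseries(rep(0, length(t)), rate),
                          smooth_hz = NULL)
  core <- 3:(length(t) - 2)
  expect_equal(mean(lin$speed$values[core]), 12, tolerance = 1e-9)
  expect_lt(mean(lin$abs_accel$values[core]), 1e-6)

  # circle r = 5 cm, omega = 2 rad/s: speed 10 cm/s, |accel| 20 cm/s^2
  circ <- hand_speed_accel(timeseries(5 * cos(2 * t), rate),
                           timeseries(5 * sin(2 * t), rate),
                           smooth_hz = NULL)
  expect_equal(mean(circ$speed$values[core]), 10, tolerance = 0.005 * 10)
  expect_equal(mean(circ$abs_accel$values[core]), 20,
               tolerance = 0.005 * 20)
})

test_that("speed is stable under resampling at twice the rate", {
  t1 <- seq(0, 4, by = 1 / 100)
  t2 <- seq(0, 4, by = 1 / 200)
  path <- function(t) list(x = 3 * sin(1.3 * t), y = 2 * cos(0.7 * t))
  p1 <- path(t1); p2 <- path(t2)
  s1 <- hand_speed_accel(timeseries(p1$x, 100), timeseries(p1$y, 100),
                         smooth_hz = NULL)$mean_speed
  s2 <- hand_speed_accel(timeseries(p2$x, 200), timeseries(p2$y, 200),
                         smooth_hz = NULL)$mean_speed
  expect_lt(abs(s2 - s1) / s1, 0.001)
})

test_that("hand_speed_accel validates its inputs", {
  expect_error(hand_speed_accel(timeseries(1:10, 100),
                                timeseries(1:9, 100)),
               "validation error")
  expect_error(hand_speed_accel(timeseries(1:10, 100),
                                timeseries(1:10, 200)),
               "validation error")
})

test_that("space_covered handles point, sweep and diagonal paths", {
  still <- space_covered(timeseries(rep(3.5, 10), 10),
                         timeseries(rep(2.5, 10), 10), 1, c(10, 10))
  expect_equal(still$n_cells, 1)
  expect_equal(still$area, 1)

  xs <- ys <- c()
  for (r in 0:9) { xs <- c(xs, seq(0.5, 9.5, 0.5)); ys <- c(ys, rep(r + 0.5, 19)) }
  sweep <- space_covered(timeseries(xs, 10), timeseries(ys, 10), 1,
                         c(10, 10))
  expect_equal(sweep$area, 100)

  diag <- space_covered(timeseries(c(0.3, 9.7), 1),
                        timeseries(c(0.2, 9.8), 1), 1, c(10, 10))
  expect_equal(sort(which(t(diag$grid) > 0)) - 1L,
               sort(oracle_raster_cells(0.3, 0.2, 9.7, 9.8, 1, 10, 10)))
})

test_that("rasterised cells match the segment-rectangle oracle", {
  set.seed(51)
  for (rep in 1:25) {
    p <- runif(4, 0.05, 9.95)
    got <- space_covered(timeseries(p[c(1, 3)], 1),
                         timeseries(p[c(2, 4)], 1), 1, c(10, 10))
    want <- oracle_raster_cells(p[1], p[2], p[3], p[4], 1, 10, 10)
    expect_equal(sort(which(t(got$grid) > 0)) - 1L, sort(want))
  }
})

test_that("space covered is monotone in extension and reversal-invariant", {
  set.seed(52)
  x <- cumsum(rnorm(200, 0, 0.5)) + 38
  y <- cumsum(rnorm(200, 0, 0.5)) + 22
  x <- pmin(pmax(x, 0.1), 75.9); y <- pmin(pmax(y, 0.1), 43.9)
  a_half <- space_covered(timeseries(x[1:100], 200),
                          timeseries(y[1:100], 200))$area
  a_full <- space_covered(timeseries(x, 200), timeseries(y, 200))$area
  expect_gte(a_full, a_half)
  a_rev <- space_covered(timeseries(rev(x), 200),
                         timeseries(rev(y), 200))$area
  expect_equal(a_rev, a_full)
})

test_that("out-of-workspace samples are clipped with a warning", {
  expect_warning(
    sc <- space_covered(timeseries(c(-5, 5), 1), timeseries(c(2, 2), 1),
                        1, c(10, 10)),
    "clipped")
  expect_equal(sc$n_cells, 6)  # cells x in [0,5] at row y=2
})

test_that("kinematic_summary bundles consistent outcome measures", {
  cfg <- object_hit_config(duration = 30, n_bins = 4L, objects_per_bin = 15L)
  log <- simulate_object_hit(cfg, seed = 6)
  for (hand in c("left", "right")) {
    ks <- kinematic_summary(log, hand)
    expect_equal(ks$hits_total, sum(ks$hits_per_bin))
    expect_gte(ks$mean_speed, 0)
    expect_gte(ks$mean_abs_accel, 0)
    expect_gte(ks$space_covered, 1)
  }
})
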