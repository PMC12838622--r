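test_that("segmentation yields one window per cue with round(rate) samples", {
  sched <- build_cue_schedule(3, 1, 1)
  tr <- timeseries(rnorm(300), rate = 47.75)
  segs <- segment_contractions(tr, sched)
  expect_length(segs, 3)
  expect_true(all(vapply(segs, function(s) length(s$samples$values),
                         integer(1)) == 48L))  # round(47.75 * 1)
  expect_equal(vapply(segs, `[[`, integer(1), "index"), 0:2)

  expect_length(segment_contractions(tr, build_cue_schedule(0, 1, 1)), 0)
  expect_error(segment_contractions(timeseries(rnorm(10), 47.75), sched),
               "bounds error")
})

test_that("a 9-minute 1 s/1 s session segments into 270 contractions", {
  sched <- build_cue_schedule(270, 1, 1)
  tr <- timeseries(rnorm(ceiling(540 * 47.75)), rate = 47.75)
  expect_length(segment_contractions(tr, sched), 270)
})

test_that("fwhm_median matches the exhaustive-scan oracle", {
  # rectangular plateau: median equals the plateau value
  plat <- timeseries(c(rep(0, 20), rep(10, 30), rep(0, 20)), rate = 50)
  expect_equal(fwhm_median(plat)$median_force, 10)

  # symmetric triangle, peak 8, 101 samples
  tri <- triangle_profile(peak = 8, n = 101)
  est <- fwhm_median(tri)
  expect_equal(est$median_force, oracle_fwhm_median(tri$values))
  expect_lt(est$fwhm_start, est$fwhm_end)

  # asymmetric noisy pulses against the oracle
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(60:200, 1)
    v <- pmax(0, dnorm(seq(-3, 3, length.out = n), mean = runif(1, -1, 1),
                       sd = runif(1, 0.3, 1))) * runif(1, 5, 50) +
         rnorm(n, 0, 0.05)
    prof <- timeseries(v, rate = 50)
    expect_equal(fwhm_median(prof)$median_force,
                 oracle_fwhm_median(v))
  }
})

test_that("fwhm_median invariances: time shift and force scaling", {
  tri <- triangle_profile(peak = 8, n = 101)
  shifted <- timeseries(tri$values, rate = tri$rate, t0 = 12.5)
  expect_equal(fwhm_median(shifted)$median_force,
               fwhm_median(tri)$median_force)
  scaled <- timeseries(3.7 * tri$values, rate = tri$rate)
  expect_equal(fwhm_median(scaled)$median_force,
               3.7 * fwhm_median(tri)$median_force)
})

test_that("median force lies within [half-max, max] of the corrected profile", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(50:150, 1)
    v <- pmax(0, sin(seq(0, pi, length.out = n)))^runif(1, 0.5, 3) *
         runif(1, 1, 20)
    est <- fwhm_median(timeseries(v, rate = 50))
    vc_max <- max(v) - est$baseline
    expect_gte(est$median_force - est$baseline, vc_max / 2 - 1e-12)
    expect_lte(est$median_force - est$baseline, vc_max + 1e-12)
  }
})

test_that("fwhm_median rejects profiles without a peak", {
  expect_error(fwhm_median(timeseries(rep(0, 50), 50)), "no-peak")
  expect_error(fwhm_median(timeseries(c(1, NA, 3), 50)), "NA")
})

test_that("best-of-3 MVC keeps the highest of the three medians", {
  profs <- lapply(c(5, 7, 6), function(p)
    timeseries(c(rep(0, 10), rep(p, 20), rep(0, 10)), rate = 50))
  best <- mvc_best_of(profs)
  expect_equal(best$median_force, 7)
  expect_equal(best$all_medians, c(5, 7, 6))
  expect_equal(best$source, "best_of_n")
})

test_that("contraction_auc is the trapezoidal integral", {
  const <- timeseries(rep(2, 48), rate = 47)  # 47 intervals at 1/47 s = 1 s
  expect_equal(contraction_auc(const), 2)
  expect_equal(contraction_auc(timeseries(rep(0, 48), rate = 47)), 0)
  ramp <- timeseries(seq(0, 1, length.out = 48), rate = 47)
  expect_equal(contraction_auc(ramp), 0.5)
  expect_error(contraction_auc(timeseries(c(1, NA), 47)), "NA")
})

test_that("contraction_auc is additive over splits and monotone", {
  set.seed(43)
  v <- runif(101, 0, 5)
  whole <- contraction_auc(timeseries(v, rate = 50))
  left <- contraction_auc(timeseries(v[1:51], rate = 50))
  right <- contraction_auc(timeseries(v[51:101], rate = 50))
  expect_equal(left + right, whole)
  expect_gte(contraction_auc(timeseries(v + 1, rate = 50)), whole)
})

test_that("fatigue_slope recovers an exact linear drift to machine precision", {
  aucs <- 3 - 0.01 * (0:269)
  est <- fatigue_slope(aucs, discard_first = 10)
  expect_equal(est$beta, -0.01, tolerance = 1e-12)
  expect_equal(est$n_points, 260)
  expect_equal(fatigue_slope(rep(4.2, 100))$beta, 0, tolerance = 1e-12)
  expect_error(fatigue_slope(1:10, discard_first = 10), "validation error")
})

test_that("fatigue_slope recovers noisy injected drift within 3 SE", {
  set.seed(44)
  beta_true <- -0.02
  hit <- 0L
  n_rep <- 500L
  for (r in seq_len(n_rep)) {
    aucs <- 5 + beta_true * (0:269) + rnorm(270, 0, 0.1)
    est <- fatigue_slope(aucs)
    if (abs(est$beta - beta_true) <= 3 * est$se_beta) hit <- hit + 1L
  }
  expect_gte(hit / n_rep, 0.99)
})
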