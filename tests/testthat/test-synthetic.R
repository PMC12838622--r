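test_that("force generator matches the protocol structure", {
  s <- gen_force_session(force_gen_config(n_cycles = 270))
  expect_equal(s$schedule$n_cycles, 270)
  expect_equal(s$schedule$task_duration, 540)
  expect_equal(s$trace$rate, 47.75)
  expect_equal(length(s$trace$values), ceiling(540 * 47.75))
})

test_that("noiseless generated sessions return the injected drift exactly", {
  cfg <- force_gen_config(n_cycles = 60, drift_beta = -0.02, noise_sd = 0)
  s <- gen_force_session(cfg)
  fa <- force_ft_analysis(s$trace, s$schedule)
  expect_equal(fa$slope$beta, -0.02, tolerance = 1e-9)
  # measured per-contraction AUCs equal the generator's analytic targets
  expect_equal(fa$aucs, s$auc_targets, tolerance = 1e-9)
})

test_that("noisy drift recovery is unbiased across seeds", {
  cfg0 <- force_gen_config(n_cycles = 120, drift_beta = -0.02)
  amp <- cfg0$target_pct / 100 * cfg0$mvc
  cfg <- force_gen_config(n_cycles = 120, drift_beta = -0.02,
                          noise_sd = 0.1 * amp * 0.85)
  betas <- vapply(1:50, function(sd) {
    s <- gen_force_session(cfg, seed = sd)
    force_ft_analysis(s$trace, s$schedule)$slope$beta
  }, numeric(1))
  mc_se <- sd(betas) / sqrt(length(betas))
  expect_lt(abs(mean(betas) - (-0.02)), 2 * mc_se)
})

test_that("generators are bit-reproducible per seed and validate configs", {
  cfg <- force_gen_config(n_cycles = 20, drift_beta = -0.01, noise_sd = 2)
  expect_identical(gen_force_session(cfg, seed = 7)$trace$values,
                   gen_force_session(cfg, seed = 7)$trace$values)
  expect_false(identical(gen_force_session(cfg, seed = 7)$trace$values,
                         gen_force_session(cfg, seed = 8)$trace$values))
  expect_error(force_gen_config(rise_fall = 0.6), "rise_fall")
  expect_error(force_gen_config(target_pct = 40), "one of")
  # drift that drives the AUC negative is rejected
  expect_error(gen_force_session(force_gen_config(n_cycles = 270,
                                                  target_pct = 5,
                                                  drift_beta = -0.05)),
               "below zero")
})

test_that("EMG generator: gate off everywhere leaves near-zero envelope", {
  sched <- build_cue_schedule(0, 1, 1)
  sched$task_duration <- 4  # rest-only stretch
  e <- gen_emg_session(sched, amp = 1, rest_level = 0, seed = 5)
  on_level <- rms(gen_emg_session(build_cue_schedule(2, 1, 1), amp = 1,
                                  seed = 5)$values)
  expect_lt(rms(e$values), 0.01 * on_level)
})

test_that("EMG drift recovery: null is centred and injected drift is found", {
  sched <- build_cue_schedule(30, 1, 1)
  betas0 <- vapply(1:12, function(sd) {
    e <- gen_emg_session(sched, amp = 1, drift_per_contraction = 0,
                         rate = 1024, seed = sd)
    env <- emg_envelope(bandpass_emg(e, 10, 450, 4))
    emg_ft_slope(env, sched, discard_first = 5)$slope$beta
  }, numeric(1))
  mc_se <- sd(betas0) / sqrt(length(betas0))
  expect_lt(abs(mean(betas0)), 2 * mc_se)

  neg <- vapply(1:12, function(sd) {
    e <- gen_emg_session(sched, amp = 1, drift_per_contraction = -0.01,
                         rate = 1024, seed = sd)
    env <- emg_envelope(bandpass_emg(e, 10, 450, 4))
    emg_ft_slope(env, sched, discard_first = 5)$slope$beta
  }, numeric(1))
  expect_gte(mean(neg < 0), 0.95)
})

test_that("object-hit simulator satisfies the release schedule invariants", {
  cfg <- object_hit_config()
  log <- simulate_object_hit(cfg, seed = 11)
  expect_equal(nrow(log$releases), 480)
  expect_equal(unname(tabulate(log$releases$bin + 1L, 16)), rep(30L, 16))
  expect_true(all(log$releases$speed >= 15 & log$releases$speed <= 30))
  expect_equal(diff(log$releases$time), rep(0.5, 479))
  # every hit references a released bin; each ball hit at most once
  h <- count_hits(log)
  expect_lte(sum(h$total), nrow(log$releases))
  expect_true(all(log$hits$time <= cfg$duration))

  log2 <- simulate_object_hit(cfg, seed = 11)
  expect_identical(log2$hits, log$hits)
  expect_identical(log2$trajectories$left$x$values,
                   log$trajectories$left$x$values)
})

test_that("slowing one hand reduces its hit count", {
  cfg_fast <- object_hit_config(duration = 60, n_bins = 8L,
                                objects_per_bin = 15L)
  cfg_slow <- object_hit_config(duration = 60, n_bins = 8L,
                                objects_per_bin = 15L,
                                policy_right = list(reaction_delay = 0.2,
                                                    max_speed = 8))
  worse <- 0L
  for (sd in 1:10) {
    hr_fast <- count_hits(simulate_object_hit(cfg_fast, sd))$total["right"]
    hr_slow <- count_hits(simulate_object_hit(cfg_slow, sd))$total["right"]
    if (hr_slow < hr_fast) worse <- worse + 1L
  }
  expect_gte(worse, 9L)
})

test_that("infeasible object-hit schedules are rejected", {
  expect_error(object_hit_config(duration = 100), "infeasible")
})

test_that("spatial map generator injects its effect where configured", {
  cfg <- map_gen_config(H = 12, W = 12, n_per_group = 30,
                        effect_rows = 3:5, effect_cols = 7:9,
                        effect_size = 2)
  set <- gen_spatial_maps(cfg, seed = 13)
  g1 <- apply(set$maps[set$labels == "A", , ], c(2, 3), mean)
  g2 <- apply(set$maps[set$labels == "B", , ], c(2, 3), mean)
  dd <- g2 - g1
  expect_gt(mean(dd[3:5, 7:9]), 1.0)   # shifted region
  expect_lt(abs(mean(dd[8:12, 1:5])), 0.5)  # untouched region
  expect_identical(gen_spatial_maps(cfg, seed = 13)$maps, set$maps)
  expect_error(map_gen_config(H = 5, W = 5, effect_rows = 6:7,
                              effect_cols = 1:2, effect_size = 1),
               "outside grid")
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(gen_force_session(force_gen_config(n_cycles = 5, noise_sd = 1),
                              seed = 3))
  invisible(gen_spatial_maps(map_gen_config(H = 4, W = 4, n_per_group = 2),
                             seed = 3))
  expect_identical(.Random.seed, before)
})
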