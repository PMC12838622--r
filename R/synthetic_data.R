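# run expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
            assign(".Random.seed", old_seed, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# trapezoidal contraction pulse: linear rise, plateau, linear fall within the
# cue-on window; u is time since cue onset in [0, on_s]
pulse_shape <- function(u, on_s = 1, rise_fall = 0.15) {
  s <- numeric(length(u))
  inside <- u >= 0 & u <= on_s
  ru <- u[inside]
  s[inside] <- pmin(1, pmin(ru / rise_fall, (on_s - ru) / rise_fall))
  pmax(s, 0)
}

#' Configuration for the synthetic fatiguing-task force generator
#'
#' Defaults encode the study protocol: 270 cycles of 1 s contraction / 1 s
#' rest sampled at 47.75 Hz, targets at 5/50/75% of a baseline MVC, and a
#' trapezoidal pulse (0.15 s rise, 0.7 s plateau, 0.15 s fall).
#'
#' @param mvc baseline MVC in force units.
#' @param target_pct force level, one of 5, 50, 75 (% of MVC).
#' @param n_cycles number of contraction/rest cycles (default 270).
#' @param on_s,off_s contraction/rest durations in seconds (default 1/1).
#' @param rate sampling rate in Hz (default 47.75).
#' @param rise_fall pulse rise and fall time in seconds (default 0.15); must
#'   satisfy `2 * rise_fall <= on_s`.
#' @param drift_beta linear drift of the per-contraction AUC, in AUC units
#'   (force x s) per contraction; negative values emulate fatigue.
#' @param noise_sd additive Gaussian sample noise, force units.
#' @return list of class `"force_gen_config"`.
#' @export
force_gen_config <- function(mvc = 57, target_pct = 50, n_cycles = 270L,
                             on_s = 1, off_s = 1, rate = 47.75,
                             rise_fall = 0.15, drift_beta = 0,
                             noise_sd = 0) {
  if (2 * rise_fall > on_s)
    stop("validation error: rise_fall too long for the contraction window")
  if (!target_pct %in% c(5, 50, 75))
    stop("`target_pct` must be one of 5, 50, 75")
  stopifnot(mvc > 0, n_cycles >= 0, rate > 0, noise_sd >= 0)
  structure(list(mvc = mvc, target_pct = target_pct,
                 n_cycles = as.integer(n_cycles), on_s = on_s, off_s = off_s,
                 rate = rate, rise_fall = rise_fall, drift_beta = drift_beta,
                 noise_sd = noise_sd),
            class = "force_gen_config")
}

#' Generate a synthetic cued handgrip force session
#'
#' Simulates the force trace of one fatiguing task: trapezoidal contraction
#' pulses toward `target_pct/100 * mvc`, with per-contraction amplitude
#' scaled so that the per-contraction AUC (as measured by
#' [contraction_auc()] on the cue-driven segments) drifts exactly linearly
#' with slope `drift_beta`, plus optional i.i.d. Gaussian sample noise.
#' Deterministic given `seed`.
#'
#' @param cfg a [force_gen_config()].
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @return list with `trace` (a [timeseries()] at `cfg$rate`), `schedule`
#'   (the matching [build_cue_schedule()]), and `auc_targets` (the noiseless
#'   per-contraction AUC values).
#' @examples
#' s <- gen_force_session(force_gen_config(n_cycles = 20, drift_beta = -0.02))
#' force_ft_analysis(s$trace, s$schedule, discard_first = 2)$slope$beta
#' @export
gen_force_session <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "force_gen_config"))
  schedule <- build_cue_schedule(cfg$n_cycles, cfg$on_s, cfg$off_s)
  n_samp <- ceiling(schedule$task_duration * cfg$rate)
  if (cfg$n_cycles == 0L) n_samp <- max(n_samp, 1L)
  tt <- (seq_len(n_samp) - 1) / cfg$rate
  values <- numeric(n_samp)
  amp0 <- cfg$target_pct / 100 * cfg$mvc
  area0 <- amp0 * (cfg$on_s - cfg$rise_fall)  # analytic trapezoid area
  auc_targets <- numeric(cfg$n_cycles)
  for (k in seq_len(cfg$n_cycles)) {
    idx <- segment_indices(cfg$rate, 0, schedule, k)
    u <- tt[idx] - schedule$onsets[k]
    shape <- pulse_shape(u, cfg$on_s, cfg$rise_fall)
    t_k <- sum((shape[-1L] + shape[-length(shape)]) / 2) / cfg$rate
    target_auc <- area0 + cfg$drift_beta * (k - 1L)
    if (target_auc <= 0)
      stop("validation error: drift drives per-contraction AUC below zero ",
           "at contraction ", k)
    amp_k <- target_auc / t_k
    # paint the full pulse (rise may start before the first kept sample)
    all_idx <- which(tt >= schedule$onsets[k] &
                     tt <= schedule$onsets[k] + cfg$on_s)
    values[all_idx] <- amp_k * pulse_shape(tt[all_idx] - schedule$onsets[k],
                                           cfg$on_s, cfg$rise_fall)
    auc_targets[k] <- target_auc
  }
  if (cfg$noise_sd > 0)
    values <- values + with_seed(seed, stats::rnorm(n_samp, 0, cfg$noise_sd))
  list(trace = timeseries(values, rate = cfg$rate, units = "force-au",
                          channel = "grip"),
       schedule = schedule, auc_targets = auc_targets)
}

#' Generate a synthetic MVC contraction profile
#'
#' A single maximal-contraction force profile: a trapezoidal pulse of the
#' given peak on a resting baseline, with optional Gaussian noise. Useful for
#' exercising [fwhm_median()] and [mvc_best_of()].
#'
#' @param peak peak force, force units.
#' @param baseline resting force level (default 0).
#' @param duration profile duration in seconds (default 3).
#' @param rate sampling rate in Hz (default 47.75).
#' @param rise_fall rise/fall time in seconds (default 0.5).
#' @param noise_sd additive Gaussian noise, force units.
#' @param seed RNG seed (used when `noise_sd > 0`).
#' @return a [timeseries()].
#' @export
gen_mvc_profile <- function(peak = 57, baseline = 0, duration = 3,
                            rate = 47.75, rise_fall = 0.5, noise_sd = 0,
                            seed = 1L) {
  n <- ceiling(duration * rate)
  tt <- (seq_len(n) - 1) / rate
  # centre the pulse, leaving flat baseline at both ends
  on_s <- duration * 0.6
  u <- tt - duration * 0.2
  v <- baseline + (peak - baseline) * pulse_shape(u, on_s, rise_fall)
  if (noise_sd > 0)
    v <- v + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  timeseries(v, rate = rate, units = "force-au", channel = "mvc")
}

#' Generate a synthetic surface-EMG session for the fatiguing task
#'
#' Simulates EMG as band-limited (20-450 Hz) Gaussian noise amplitude-
#' modulated by the contraction gate: within each cue-on window the carrier
#' is scaled by a trapezoidal gate whose amplitude drifts linearly across
#' contractions (`amp_k = amp * (1 + drift_per_contraction * k)`); between
#' contractions a small tonic floor remains. Sampled at 2048 Hz by default.
#' Deterministic given `seed`.
#'
#' @param schedule a [build_cue_schedule()] result.
#' @param amp contraction-level carrier amplitude (envelope scale), arbitrary
#'   units (default 1).
#' @param drift_per_contraction relative amplitude change per contraction
#'   (e.g. `-0.005` for a 0.5% per-contraction decline).
#' @param rate sampling rate in Hz (default 2048).
#' @param band carrier band in Hz (default `c(20, 450)`, inside the standard
#'   10-500 Hz analysis band).
#' @param rest_level tonic rest amplitude as a fraction of `amp`
#'   (default 0.02).
#' @param rise_fall gate rise/fall time in seconds (default 0.15).
#' @param seed RNG seed.
#' @return a [timeseries()] EMG trace.
#' @export
gen_emg_session <- function(schedule, amp = 1, drift_per_contraction = 0,
                            rate = 2048, band = c(20, 450),
                            rest_level = 0.02, rise_fall = 0.15, seed = 1L) {
  stopifnot(inherits(schedule, "cue_schedule"))
  n <- ceiling(max(schedule$task_duration, 1) * rate)
  carrier <- with_seed(seed, stats::rnorm(n))
  bf <- signal::butter(4, band / (rate / 2), type = "pass")
  carrier <- signal::filtfilt(bf, carrier)
  # normalise the carrier so the gate amplitude is the envelope scale
  carrier <- carrier / stats::sd(carrier)
  tt <- (seq_len(n) - 1) / rate
  gate <- rep(rest_level * amp, n)
  for (k in seq_len(schedule$n_cycles)) {
    amp_k <- amp * (1 + drift_per_contraction * (k - 1L))
    if (amp_k < 0) amp_k <- 0
    idx <- which(tt >= schedule$onsets[k] &
                 tt <= schedule$onsets[k] + schedule$on_s)
    gate[idx] <- pmax(gate[idx],
                      amp_k * pulse_shape(tt[idx] - schedule$onsets[k],
                                          schedule$on_s, rise_fall))
  }
  timeseries(carrier * gate, rate = rate, units = "volts", channel = "emg")
}

#' Configuration for the object-hit task simulator
#'
#' Defaults encode the study task: balls released from 16 evenly spaced bins
#' (30 objects per bin) at 2 balls per second over 4 minutes, falling at
#' 15-30 cm/s through a 76 x 44 cm workspace toward two 1.5 x 0.5 cm paddles
#' deflecting 0.75 cm balls. The schedule must be feasible:
#' `n_bins * objects_per_bin = release_rate * duration`.
#'
#' @param n_bins number of release bins (default 16).
#' @param objects_per_bin releases per bin (default 30).
#' @param speed_range fall-speed range in cm/s (default `c(15, 30)`).
#' @param release_rate releases per second (default 2).
#' @param duration task duration in seconds (default 240).
#' @param workspace `c(width, height)` in cm (default `c(76, 44)`).
#' @param paddle `c(width, height)` of each paddle in cm (default
#'   `c(1.5, 0.5)`).
#' @param ball_diameter ball diameter in cm (default 0.75).
#' @param kin_rate kinematic sampling rate in Hz (default 200).
#' @param policy_left,policy_right per-hand pursuit policy: list with
#'   `reaction_delay` (s), `max_speed` (cm/s), and optionally `park`
#'   (`c(x, y)` to hold position, disabling pursuit).
#' @param defence_y height of the interception line in cm (default 8).
#' @return list of class `"object_hit_config"`.
#' @export
object_hit_config <- function(n_bins = 16L, objects_per_bin = 30L,
                              speed_range = c(15, 30), release_rate = 2,
                              duration = 240, workspace = c(76, 44),
                              paddle = c(1.5, 0.5), ball_diameter = 0.75,
                              kin_rate = 200,
                              policy_left = list(reaction_delay = 0.2,
                                                 max_speed = 60),
                              policy_right = list(reaction_delay = 0.2,
                                                  max_speed = 60),
                              defence_y = 8) {
  n_rel <- n_bins * objects_per_bin
  if (abs(n_rel - release_rate * duration) > 1e-9)
    stop("validation error: infeasible schedule — n_bins * objects_per_bin ",
         "must equal release_rate * duration (", n_rel, " vs ",
         release_rate * duration, ")")
  stopifnot(speed_range[1L] > 0, speed_range[2L] >= speed_range[1L],
            kin_rate > 0, all(workspace > 0))
  structure(list(n_bins = as.integer(n_bins),
                 objects_per_bin = as.integer(objects_per_bin),
                 speed_range = speed_range, release_rate = release_rate,
                 duration = duration, workspace = workspace, paddle = paddle,
                 ball_diameter = ball_diameter, kin_rate = kin_rate,
                 policy_left = policy_left, policy_right = policy_right,
                 defence_y = defence_y),
            class = "object_hit_config")
}

# squared distance from point to an axis-aligned rectangle centred at (cx,cy)
rect_point_dist2 <- function(px, py, cx, cy, hw, hh) {
  dx <- pmax(abs(px - cx) - hw, 0)
  dy <- pmax(abs(py - cy) - hh, 0)
  dx^2 + dy^2
}

#' Simulate one object-hit assessment task
#'
#' Event-driven simulation of the bimanual object-hit task. Balls are
#' released on a quota-constrained pseudorandom bin sequence (every bin
#' releases exactly `objects_per_bin` balls) with uniformly drawn fall
#' speeds, and fall vertically. Each paddle pursues its nearest threat — the
#' active ball in its own half that will reach the defence line soonest —
#' under a bounded speed and a reaction delay, crossing the midline only
#' when its own half is empty. Collisions are detected by rectangle-circle
#' overlap; on a hit the ball's vertical velocity is reflected and a
#' horizontal component proportional to the contact offset is added, and the
#' hit is logged once per ball. Deterministic given `seed`.
#'
#' @param cfg an [object_hit_config()].
#' @param seed RNG seed.
#' @return a [task_log()] with releases, hits and per-hand trajectories at
#'   `cfg$kin_rate`.
#' @export
simulate_object_hit <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "object_hit_config"))
  W <- cfg$workspace[1L]; H <- cfg$workspace[2L]
  n_rel <- cfg$n_bins * cfg$objects_per_bin
  sched <- with_seed(seed, {
    bins <- sample(rep.int(seq_len(cfg$n_bins) - 1L, cfg$objects_per_bin))
    speeds <- stats::runif(n_rel, cfg$speed_range[1L], cfg$speed_range[2L])
    list(bins = bins, speeds = speeds)
  })
  rel_time <- (seq_len(n_rel) - 1) / cfg$release_rate
  bin_x <- (sched$bins + 0.5) * W / cfg$n_bins
  r_ball <- cfg$ball_diameter / 2
  hw <- cfg$paddle[1L] / 2; hh <- cfg$paddle[2L] / 2

  dt <- 1 / cfg$kin_rate
  n_steps <- as.integer(round(cfg$duration * cfg$kin_rate))
  # ball state: x, y, vx, vy, active, was_hit
  bx <- bin_x; by <- rep(H, n_rel)
  bvx <- numeric(n_rel); bvy <- -sched$speeds
  active <- logical(n_rel); was_hit <- logical(n_rel)
  released <- logical(n_rel)

  pads <- list(
    left = list(pos = c(W / 4, cfg$defence_y), policy = cfg$policy_left),
    right = list(pos = c(3 * W / 4, cfg$defence_y), policy = cfg$policy_right))
  traj <- list(left = matrix(NA_real_, n_steps, 2L),
               right = matrix(NA_real_, n_steps, 2L))
  hits <- vector("list", 600L); n_hits <- 0L
  next_rel <- 1L

  for (step in seq_len(n_steps)) {
    t_now <- (step - 1) * dt
    while (next_rel <= n_rel && rel_time[next_rel] <= t_now + 1e-12) {
      active[next_rel] <- TRUE
      released[next_rel] <- TRUE
      next_rel <- next_rel + 1L
    }
    ai <- which(active)
    # advance balls
    if (length(ai)) {
      bx[ai] <- bx[ai] + bvx[ai] * dt
      by[ai] <- by[ai] + bvy[ai] * dt
      gone <- ai[by[ai] < -r_ball | by[ai] > H + r_ball]
      active[gone] <- FALSE
      ai <- which(active)
    }
    # paddle pursuit
    for (hand in c("left", "right")) {
      p <- pads[[hand]]
      if (!is.null(p$policy$park)) {
        pads[[hand]]$pos <- p$policy$park
        traj[[hand]][step, ] <- p$policy$park
        next
      }
      cand <- ai[!was_hit[ai] & bvy[ai] < 0 &
                 t_now - rel_time[ai] >= p$policy$reaction_delay]
      if (length(cand)) {
        own <- if (hand == "left") cand[bx[cand] < W / 2]
               else cand[bx[cand] >= W / 2]
        pool <- if (length(own)) own else cand
        eta <- (by[pool] - cfg$defence_y) / (-bvy[pool])
        tgt <- pool[which.min(eta)]
        goal <- c(bx[tgt], cfg$defence_y)
        dvec <- goal - p$pos
        dist <- sqrt(sum(dvec^2))
        step_len <- min(dist, p$policy$max_speed * dt)
        if (dist > 1e-12)
          pads[[hand]]$pos <- p$pos + dvec / dist * step_len
      }
      traj[[hand]][step, ] <- pads[[hand]]$pos
    }
    # collisions
    if (length(ai)) {
      unhit <- ai[!was_hit[ai]]
      if (length(unhit)) {
        dl <- rect_point_dist2(bx[unhit], by[unhit],
                               pads$left$pos[1L], pads$left$pos[2L], hw, hh)
        dr <- rect_point_dist2(bx[unhit], by[unhit],
                               pads$right$pos[1L], pads$right$pos[2L], hw, hh)
        hit_l <- dl <= r_ball^2
        hit_r <- dr <= r_ball^2
        both <- hit_l & hit_r
        # simultaneous contact goes to the nearer paddle centre
        if (any(both)) {
          cl <- (bx[unhit] - pads$left$pos[1L])^2 +
                (by[unhit] - pads$left$pos[2L])^2
          cr <- (bx[unhit] - pads$right$pos[1L])^2 +
                (by[unhit] - pads$right$pos[2L])^2
          hit_l[both] <- cl[both] <= cr[both]
          hit_r[both] <- !hit_l[both]
        }
        for (hand in c("left", "right")) {
          sel <- unhit[if (hand == "left") hit_l else hit_r]
          for (b in sel) {
            n_hits <- n_hits + 1L
            hits[[n_hits]] <- data.frame(time = t_now, hand = hand,
                                         bin = sched$bins[b])
            was_hit[b] <- TRUE
            px <- pads[[hand]]$pos[1L]
            bvy[b] <- abs(bvy[b])            # specular vertical reflection
            bvx[b] <- (bx[b] - px) / hw * 5  # offset-proportional deflection
          }
        }
      }
    }
  }

  releases <- data.frame(time = rel_time, bin = sched$bins,
                         speed = sched$speeds)
  hits_df <- if (n_hits) do.call(rbind, hits[seq_len(n_hits)]) else NULL
  mk <- function(m, hand) list(
    x = timeseries(m[, 1L], rate = cfg$kin_rate, units = "cm",
                   channel = paste0(hand, "-x")),
    y = timeseries(m[, 2L], rate = cfg$kin_rate, units = "cm",
                   channel = paste0(hand, "-y")))
  task_log(releases, hits_df,
           trajectories = list(left = mk(traj$left, "left"),
                               right = mk(traj$right, "right")),
           n_bins = cfg$n_bins, duration = cfg$duration)
}

#' Configuration for the synthetic spatial-map generator
#'
#' @param H,W grid dimensions (default 30 x 30).
#' @param n_per_group maps per condition (default 20).
#' @param effect_rows,effect_cols integer ranges defining the rectangular
#'   region that carries the group-2 mean shift (default none).
#' @param effect_size mean shift added to the effect region in group 2, in
#'   SD units of the unit-variance cell noise.
#' @return list of class `"map_gen_config"`.
#' @export
map_gen_config <- function(H = 30L, W = 30L, n_per_group = 20L,
                           effect_rows = integer(0),
                           effect_cols = integer(0), effect_size = 0) {
  if (length(effect_rows) && (min(effect_rows) < 1L || max(effect_rows) > H))
    stop("effect_rows outside grid")
  if (length(effect_cols) && (min(effect_cols) < 1L || max(effect_cols) > W))
    stop("effect_cols outside grid")
  structure(list(H = as.integer(H), W = as.integer(W),
                 n_per_group = as.integer(n_per_group),
                 effect_rows = as.integer(effect_rows),
                 effect_cols = as.integer(effect_cols),
                 effect_size = effect_size),
            class = "map_gen_config")
}

#' Generate a two-condition set of synthetic spatial maps
#'
#' Draws i.i.d. standard-normal cells for every map and adds `effect_size`
#' to the configured rectangular region in the second condition's maps —
#' the test harness for the cluster-based permutation test. Deterministic
#' given `seed`.
#'
#' @param cfg a [map_gen_config()].
#' @param seed RNG seed.
#' @return a [spatial_map_set()] with labels `"A"` (null) and `"B"`
#'   (effect-carrying).
#' @export
gen_spatial_maps <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "map_gen_config"))
  n <- 2L * cfg$n_per_group
  maps <- with_seed(seed,
    array(stats::rnorm(n * cfg$H * cfg$W), dim = c(n, cfg$H, cfg$W)))
  if (cfg$effect_size != 0 && length(cfg$effect_rows) &&
      length(cfg$effect_cols)) {
    g2 <- (cfg$n_per_group + 1L):n
    maps[g2, cfg$effect_rows, cfg$effect_cols] <-
      maps[g2, cfg$effect_rows, cfg$effect_cols] + cfg$effect_size
  }
  spatial_map_set(maps, rep(c("A", "B"), each = cfg$n_per_group))
}
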