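# resolve a manifest stream: file path -> loaded object, in-memory -> as-is
resolve_stream <- function(x, kind = c("timeseries", "task_log")) {
  kind <- match.arg(kind)
  if (is.null(x)) return(NULL)
  if (is.character(x))
    return(switch(kind, timeseries = read_timeseries(x),
                  task_log = read_task_log(x)))
  x
}

# tiny rolling hash of a deparsed object, for report provenance
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Default study-analysis configuration
#'
#' Collects every tunable threshold of the full pipeline in one list:
#' cue-schedule shape, familiarisation discard, EMG filter band and envelope
#' method, occupancy cell size, and the permutation-test parameters.
#'
#' @param n_cycles,on_s,off_s fatiguing-task cue schedule (default 270 cycles
#'   of 1 s / 1 s).
#' @param discard_first familiarisation contractions excluded from slopes
#'   (default 10).
#' @param emg_low,emg_high,emg_order EMG bandpass parameters (default
#'   10-500 Hz, order 4).
#' @param envelope_method `"hilbert"` or `"rectify_lowpass"`.
#' @param cell_size occupancy-grid cell size, cm (default 1).
#' @param n_perm,threshold_p,alpha cluster permutation-test parameters
#'   (defaults 5000, 0.01, 0.05).
#' @param seed base RNG seed recorded in reports and used by the
#'   permutation test.
#' @return list of class `"study_config"`.
#' @export
study_config <- function(n_cycles = 270L, on_s = 1, off_s = 1,
                         discard_first = 10L, emg_low = 10, emg_high = 500,
                         emg_order = 4L,
                         envelope_method = "hilbert", cell_size = 1,
                         n_perm = 5000L, threshold_p = 0.01, alpha = 0.05,
                         seed = 1L) {
  structure(as.list(environment()), class = "study_config")
}

# analyse one session manifest into per-session metrics
analyse_session <- function(man, cfg) {
  stopifnot(inherits(man, "session_manifest"))
  schedule <- build_cue_schedule(cfg$n_cycles, cfg$on_s, cfg$off_s)
  out <- list(subject_id = man$subject_id, condition = man$condition,
              round_index = man$round_index, baseline_mvc = man$baseline_mvc)
  force <- resolve_stream(man$streams$force, "timeseries")
  if (!is.null(force)) {
    fa <- force_ft_analysis(force, schedule, cfg$discard_first)
    out$force_slope <- fa$slope$beta
    out$force_n_points <- fa$slope$n_points
  }
  for (mus in c("fcr", "ecr")) {
    emg <- resolve_stream(man$streams[[paste0("emg_", mus)]], "timeseries")
    if (!is.null(emg)) {
      filt <- bandpass_emg(emg, cfg$emg_low, cfg$emg_high, cfg$emg_order)
      env <- emg_envelope(filt, method = cfg$envelope_method)
      out[[paste0(mus, "_slope")]] <-
        emg_ft_slope(env, schedule, cfg$discard_first)$slope$beta
    }
  }
  post <- resolve_stream(man$streams$post_mvc, "timeseries")
  if (!is.null(post)) out$post_mvc <- fwhm_median(post)$median_force
  tl <- resolve_stream(man$streams$task_log, "task_log")
  if (!is.null(tl) && !is.null(tl$trajectories)) {
    for (hand in c("left", "right")) {
      ks <- kinematic_summary(tl, hand, cell_size = cfg$cell_size)
      out[[paste0(hand, "_hits")]] <- ks$hits_total
      out[[paste0(hand, "_mean_speed")]] <- ks$mean_speed
      out[[paste0(hand, "_mean_abs_accel")]] <- ks$mean_abs_accel
      out[[paste0(hand, "_space_covered")]] <- ks$space_covered
      out[[paste0(hand, "_occupancy")]] <- ks$occupancy
    }
  }
  out
}

# subjects x 3 wide matrix of one metric, conditions in fixed order
metric_matrix <- function(sessions, metric) {
  conds <- c("pct5", "pct50", "pct75")
  subs <- unique(vapply(sessions, `[[`, character(1), "subject_id"))
  m <- matrix(NA_real_, length(subs), 3L,
              dimnames = list(subs, conds))
  for (s in sessions) {
    v <- s[[metric]]
    if (!is.null(v)) m[s$subject_id, s$condition] <- v
  }
  if (anyNA(m)) return(NULL)
  m
}

#' Run the full study analysis over a set of session manifests
#'
#' Orchestrates the whole pipeline: per-session fatiguing-task slopes (force
#' and, when EMG streams are present, FCR/ECR envelope slopes), post-task
#' MVC, assessment-task kinematic summaries, then the group-level
#' within-subject statistics (1 x 3 RM-ANOVA on every complete metric, with
#' Bonferroni-corrected paired follow-ups) and, when occupancy maps are
#' available, cluster-based permutation tests of space covered between force
#' levels per hand. The design must be complete: every subject must have a
#' session for each of the three conditions.
#'
#' @param manifests list of [session_manifest()] (3 per subject).
#' @param cfg a [study_config()].
#' @return An object of class `"study_report"`: list with `sessions`
#'   (per-session metrics), `tables` (wide subjects x conditions matrices),
#'   `anova` (per-metric [rm_anova()] tables), `posthoc` (per-metric
#'   [paired_tests()]), `cluster` (per-hand, per-contrast
#'   [permutation_test()] results, if maps present) and `provenance`.
#' @export
run_study <- function(manifests, cfg = study_config()) {
  stopifnot(is.list(manifests), length(manifests) >= 1L)
  key <- vapply(manifests, function(m)
    paste(m$subject_id, m$condition), character(1))
  if (anyDuplicated(key)) stop("duplicate subject x condition sessions")
  tab <- table(vapply(manifests, `[[`, character(1), "subject_id"))
  if (any(tab != 3L)) {
    missing <- names(tab)[tab != 3L]
    stop("incomplete design: subjects without all 3 conditions: ",
         paste(missing, collapse = ", "))
  }
  sessions <- lapply(manifests, analyse_session, cfg = cfg)

  metrics <- c("force_slope", "fcr_slope", "ecr_slope", "post_mvc",
               "left_hits", "right_hits", "left_mean_speed",
               "right_mean_speed", "left_mean_abs_accel",
               "right_mean_abs_accel", "left_space_covered",
               "right_space_covered")
  tables <- list(); anova <- list(); posthoc <- list()
  for (mtr in metrics) {
    m <- metric_matrix(sessions, mtr)
    if (is.null(m)) next
    tables[[mtr]] <- m
    if (nrow(m) >= 2L) {  # group inference needs more than one subject
      anova[[mtr]] <- rm_anova(m)
      posthoc[[mtr]] <- paired_tests(m)
    }
  }

  cluster <- list()
  have_maps <- all(vapply(sessions, function(s)
    !is.null(s$left_occupancy), logical(1)))
  if (have_maps) {
    contrasts <- list(c("pct5", "pct50"), c("pct5", "pct75"),
                      c("pct50", "pct75"))
    for (hand in c("left", "right")) {
      for (ct in contrasts) {
        sel <- Filter(function(s) s$condition %in% ct, sessions)
        maps <- lapply(sel, `[[`, paste0(hand, "_occupancy"))
        labs <- vapply(sel, `[[`, character(1), "condition")
        set <- spatial_map_set(lapply(maps, function(g) (g > 0) * 1), labs)
        nm <- paste(hand, ct[1L], ct[2L], sep = "_")
        cluster[[nm]] <- permutation_test(set, n_perm = cfg$n_perm,
                                          seed = cfg$seed,
                                          threshold_p = cfg$threshold_p,
                                          alpha = cfg$alpha)
      }
    }
  }
  structure(list(sessions = sessions, tables = tables, anova = anova,
                 posthoc = posthoc, cluster = cluster,
                 provenance = list(
                   seed = cfg$seed, config_hash = config_hash(cfg),
                   n_subjects = length(tab),
                   package_version =
                     as.character(utils::packageVersion("fatiguekit")))),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d subjects, %d sessions, %d metric table(s)\n",
              x$provenance$n_subjects, length(x$sessions),
              length(x$tables)))
  if (!is.null(x$anova$force_slope)) {
    a <- x$anova$force_slope
    cat(sprintf("  force-slope RM-ANOVA: F(%d,%d) = %.2f, p = %.4g, ",
                a$df_num[1L], a$df_den[1L], a$F[1L], a$p[1L]))
    cat(sprintf("partial eta^2 = %.2f\n", a$partial_eta_sq[1L]))
  }
  invisible(x)
}

#' Write a study report to JSON
#'
#' Serialises a [run_study()] report (excluding the bulky per-session
#' occupancy grids) to pretty-printed JSON; byte-identical for identical
#' inputs and seed.
#'
#' @param report a `"study_report"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_study_report <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  slim <- report
  slim$sessions <- lapply(slim$sessions, function(s) {
    s$left_occupancy <- NULL; s$right_occupancy <- NULL; s
  })
  slim$cluster <- lapply(slim$cluster, function(cl) {
    list(n_clusters = length(cl$clusters),
         p_values = vapply(cl$clusters, `[[`, numeric(1), "p_value"),
         any_significant = cl$any_significant,
         n_permutations = cl$n_permutations)
  })
  slim$tables <- lapply(slim$tables, function(m)
    as.data.frame(as.table(m)))
  class(slim) <- NULL
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Simulate a complete synthetic study
#'
#' Generates a full within-subject study in memory — every subject performs
#' the fatiguing task at all three force levels — and runs [run_study()] on
#' it. Per-condition fatigue drifts are set by `drift`; each subject's
#' actual drift in a condition is jittered by a Gaussian with
#' `drift_subject_sd` to create realistic between-subject variability, and
#' the force traces carry i.i.d. sample noise. EMG streams are optional (the
#' fatiguing-task EMG pipeline is exercised by its own module tests; at
#' 2048 Hz it dominates runtime).
#'
#' @param n_subjects number of subjects (default 6).
#' @param drift named vector of per-condition AUC drifts
#'   (`pct5`, `pct50`, `pct75`), AUC units per contraction.
#' @param drift_subject_sd SD of the per-subject drift jitter, AUC units
#'   per contraction, identical across conditions so a zero-mean `drift`
#'   yields an exchangeable null. The default keeps every plausible draw
#'   feasible for the weakest condition: a 5% MVC session cannot lose
#'   more output per contraction than it produces, which bounds the
#'   admissible jitter at roughly `0.05 * mvc * 0.85 / n_cycles`.
#' @param noise_sd force sample noise SD, force units.
#' @param mvc baseline MVC given to every subject (force units).
#' @param n_cycles fatiguing-task cycles (default 270).
#' @param include_emg also generate and analyse FCR/ECR EMG streams.
#' @param seed base RNG seed; all session seeds derive from it.
#' @param cfg a [study_config()]; `n_cycles` and `seed` are overridden by
#'   the arguments above.
#' @return the [run_study()] report.
#' @export
simulate_study <- function(n_subjects = 6L,
                           drift = c(pct5 = 0, pct50 = -0.01,
                                     pct75 = -0.03),
                           drift_subject_sd = 5e-4, noise_sd = 1,
                           mvc = 57, n_cycles = 270L, include_emg = FALSE,
                           seed = 1L, cfg = study_config()) {
  stopifnot(all(c("pct5", "pct50", "pct75") %in% names(drift)))
  cfg$n_cycles <- n_cycles
  cfg$seed <- seed
  manifests <- list()
  jit <- with_seed(seed,
    matrix(stats::rnorm(n_subjects * 3L, 0, drift_subject_sd),
           n_subjects, 3L))
  conds <- c("pct5", "pct50", "pct75")
  for (i in seq_len(n_subjects)) {
    for (j in seq_along(conds)) {
      cond <- conds[j]
      sess_seed <- (seed * 1000L + i * 10L + j) %% .Machine$integer.max
      fcfg <- force_gen_config(mvc = mvc, target_pct = condition_pct(cond),
                               n_cycles = n_cycles,
                               drift_beta = drift[[cond]] + jit[i, j],
                               noise_sd = noise_sd)
      fs <- gen_force_session(fcfg, seed = sess_seed)
      streams <- list(force = fs$trace)
      if (include_emg) {
        streams$emg_fcr <- gen_emg_session(
          fs$schedule, amp = 1,
          drift_per_contraction = (drift[[cond]] + jit[i, j]) / 10,
          seed = sess_seed + 1L)
        streams$emg_ecr <- gen_emg_session(
          fs$schedule, amp = 0.8,
          drift_per_contraction = (drift[[cond]] + jit[i, j]) / 20,
          seed = sess_seed + 2L)
      }
      manifests[[length(manifests) + 1L]] <-
        session_manifest(sprintf("S%02d", i), cond, round_index = j,
                         baseline_mvc = mvc, streams = streams)
    }
  }
  run_study(manifests, cfg)
}
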