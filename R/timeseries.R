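#' Uniformly sampled time series
#'
#' Constructs the basic signal container used throughout the package: a
#' uniformly sampled, session-relative time series with an explicit sampling
#' rate, unit label and channel label. Force traces (nominally 47.75 Hz) and
#' surface EMG (2048 Hz) are both carried in this container.
#'
#' @param values numeric vector of samples; must have length >= 1 and contain
#'   no non-finite values other than `NA` (explicitly missing samples).
#' @param rate sampling rate in Hz, > 0.
#' @param t0 session-relative start time of the first sample, in seconds.
#' @param units unit label, e.g. `"force-au"` or `"volts"`.
#' @param channel channel label, e.g. `"grip"`, `"FCR-R"`.
#' @return An object of class `"timeseries"`: a list with fields `values`,
#'   `rate`, `t0`, `units`, `channel`.
#' @examples
#' ts <- timeseries(sin(seq_len(100) / 10), rate = 47.75, units = "force-au")
#' ts_duration(ts)
#' @export
timeseries <- function(values, rate, t0 = 0, units = "au", channel = "") {
  if (!is.numeric(values) || length(values) < 1L)
    stop("`values` must be a numeric vector of length >= 1")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number (Hz)")
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0))
    stop("`t0` must be a single finite number (seconds)")
  bad <- !is.finite(values) & !is.na(values)
  if (any(bad))
    stop("`values` contains non-finite entries (Inf/NaN); use NA for missing")
  structure(
    list(values = as.numeric(values), rate = as.numeric(rate),
         t0 = as.numeric(t0), units = as.character(units)[1L],
         channel = as.character(channel)[1L]),
    class = "timeseries"
  )
}

#' @export
print.timeseries <- function(x, ...) {
  cat(sprintf("<timeseries> %d samples @ %g Hz, t0 = %g s [%s%s]\n",
              length(x$values), x$rate, x$t0, x$units,
              if (nzchar(x$channel)) paste0(", ", x$channel) else ""))
  invisible(x)
}

#' @export
length.timeseries <- function(x) length(x$values)

#' Sample times of a time series
#'
#' @param ts a [timeseries()].
#' @return numeric vector of sample times `t0 + k / rate`, `k = 0, 1, ...`.
#' @export
ts_times <- function(ts) {
  stopifnot(inherits(ts, "timeseries"))
  ts$t0 + (seq_along(ts$values) - 1) / ts$rate
}

#' Duration of a time series in seconds
#'
#' @param ts a [timeseries()].
#' @return time spanned from the first sample to one sample past the last.
#' @export
ts_duration <- function(ts) length(ts$values) / ts$rate

#' Write a time series to CSV with a JSON sidecar
#'
#' The on-disk format is a two-column CSV (`time_s,value`) plus a sidecar JSON
#' file (`<path>.json`) holding `rate`, `units`, `channel` and `t0`. Values
#' round-trip bit-identically through [read_timeseries()] (times are written at
#' full precision and the reader trusts the sidecar rate rather than
#' re-deriving it).
#'
#' @param ts a [timeseries()].
#' @param path CSV output path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "timeseries"))
  df <- data.frame(time_s = ts_times(ts), value = ts$values)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(rate = ts$rate, units = ts$units, channel = ts$channel,
               t0 = ts$t0)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a time series from CSV (+ optional JSON sidecar)
#'
#' Reads the format written by [write_timeseries()]. When the sidecar is
#' absent, `rate` must be supplied (or is inferred from the median time step
#' if `rate = NULL` is kept and a `time_s` column exists).
#'
#' @param path CSV path with columns `time_s,value` (or `value` only when
#'   `rate` is given).
#' @param rate sampling rate override in Hz; defaults to the sidecar value.
#' @param units,channel metadata overrides; default to sidecar values.
#' @return a [timeseries()].
#' @export
read_timeseries <- function(path, rate = NULL, units = NULL, channel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  meta <- list(rate = NULL, units = "au", channel = "", t0 = 0)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    m <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    meta[names(m)] <- m
  }
  if (!is.null(rate)) meta$rate <- rate
  if (!is.null(units)) meta$units <- units
  if (!is.null(channel)) meta$channel <- channel
  if (!("value" %in% names(df)))
    stop("format error: missing `value` column in ", path)
  if ("time_s" %in% names(df) && nrow(df) > 1L) {
    dt <- diff(df$time_s)
    if (any(dt <= 0))
      stop("data error: `time_s` not strictly increasing in ", path)
    if (is.null(meta$rate)) meta$rate <- 1 / stats::median(dt)
    meta$t0 <- df$time_s[1L]
  }
  if (is.null(meta$rate))
    stop("format error: no sidecar and no `rate` given for ", path)
  timeseries(df$value, rate = meta$rate, t0 = meta$t0, units = meta$units,
             channel = meta$channel)
}

#' Cue schedule for a contraction/rest protocol
#'
#' Builds the schedule of cued contraction windows for the fatiguing task:
#' `n_cycles` cycles of `on_s` seconds of contraction followed by `off_s`
#' seconds of rest, starting at time 0. The study protocol is 270 cycles of
#' 1 s on / 1 s off, i.e. a 9-minute task.
#'
#' @param n_cycles number of contraction/rest cycles (>= 0).
#' @param on_s contraction (cue on) duration in seconds, > 0.
#' @param off_s rest duration in seconds, > 0.
#' @return An object of class `"cue_schedule"`: a list with `onsets`,
#'   `offsets` (numeric vectors of window starts/ends in seconds), `on_s`,
#'   `off_s` and `task_duration`.
#' @examples
#' sched <- build_cue_schedule(270, 1, 1)
#' sched$task_duration  # 540 s
#' @export
build_cue_schedule <- function(n_cycles, on_s = 1, off_s = 1) {
  if (!is.numeric(n_cycles) || length(n_cycles) != 1L || n_cycles < 0 ||
      n_cycles != round(n_cycles))
    stop("`n_cycles` must be a non-negative integer")
  if (on_s <= 0 || off_s <= 0)
    stop("`on_s` and `off_s` must be positive")
  n <- as.integer(n_cycles)
  cycle <- on_s + off_s
  starts <- (seq_len(n) - 1) * cycle
  structure(
    list(onsets = starts, offsets = starts + on_s,
         on_s = on_s, off_s = off_s, n_cycles = n,
         task_duration = n * cycle),
    class = "cue_schedule"
  )
}

#' @export
print.cue_schedule <- function(x, ...) {
  cat(sprintf("<cue_schedule> %d cycles of %g s on / %g s off (%g s total)\n",
              x$n_cycles, x$on_s, x$off_s, x$task_duration))
  invisible(x)
}

#' Object-hit task log
#'
#' Container for timestamped events of the bimanual object-hit task:
#' ball releases (time, bin, fall speed), paddle hits (time, hand, bin of the
#' hit ball) and the sampled hand trajectories in workspace coordinates.
#'
#' @param releases data.frame with columns `time` (s), `bin` (0..n_bins-1),
#'   `speed` (cm/s).
#' @param hits data.frame with columns `time` (s), `hand` (`"left"`/`"right"`),
#'   `bin` (0..n_bins-1).
#' @param trajectories named list with elements `left` and `right`, each a
#'   list of two [timeseries()] (`x`, `y`, cm), or `NULL`.
#' @param n_bins number of release bins (16 in the study task).
#' @param duration task duration in seconds (240 in the study task).
#' @return An object of class `"task_log"`.
#' @export
task_log <- function(releases = NULL, hits = NULL, trajectories = NULL,
                     n_bins = 16L, duration = 240) {
  empty_rel <- data.frame(time = numeric(), bin = integer(), speed = numeric())
  empty_hit <- data.frame(time = numeric(), hand = character(),
                          bin = integer())
  if (is.null(releases)) releases <- empty_rel
  if (is.null(hits)) hits <- empty_hit
  stopifnot(all(c("time", "bin", "speed") %in% names(releases)),
            all(c("time", "hand", "bin") %in% names(hits)))
  if (nrow(releases) && (any(releases$bin < 0) ||
                         any(releases$bin >= n_bins)))
    stop("validation error: release bin index outside [0, ", n_bins - 1, "]")
  if (nrow(hits)) {
    if (any(hits$bin < 0) || any(hits$bin >= n_bins))
      stop("validation error: hit bin index outside [0, ", n_bins - 1, "]")
    if (!all(hits$hand %in% c("left", "right")))
      stop("validation error: hand must be 'left' or 'right'")
    if (any(hits$time < 0) || any(hits$time > duration))
      stop("validation error: hit time outside task duration")
  }
  releases <- releases[order(releases$time), , drop = FALSE]
  hits <- hits[order(hits$time), , drop = FALSE]
  rownames(releases) <- rownames(hits) <- NULL
  structure(list(releases = releases, hits = hits,
                 trajectories = trajectories,
                 n_bins = as.integer(n_bins), duration = duration),
            class = "task_log")
}

#' @export
print.task_log <- function(x, ...) {
  cat(sprintf("<task_log> %d releases, %d hits, %d bins, %g s%s\n",
              nrow(x$releases), nrow(x$hits), x$n_bins, x$duration,
              if (is.null(x$trajectories)) "" else ", with trajectories"))
  invisible(x)
}

#' Write an object-hit task log as JSON lines
#'
#' One JSON object per line: `{"ev":"release",...}`, `{"ev":"hit",...}` and,
#' when trajectories are present, `{"ev":"pos",...}` samples for both hands.
#'
#' @param log a [task_log()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_task_log <- function(log, path) {
  stopifnot(inherits(log, "task_log"))
  lines <- character(0)
  hdr <- jsonlite::toJSON(list(ev = "meta", n_bins = log$n_bins,
                               duration = log$duration), auto_unbox = TRUE)
  lines <- c(lines, as.character(hdr))
  if (nrow(log$releases)) {
    r <- log$releases
    lines <- c(lines, vapply(seq_len(nrow(r)), function(i) {
      as.character(jsonlite::toJSON(list(ev = "release", time = r$time[i],
                                         bin = r$bin[i], speed = r$speed[i]),
                                    auto_unbox = TRUE, digits = NA))
    }, character(1)))
  }
  if (nrow(log$hits)) {
    h <- log$hits
    lines <- c(lines, vapply(seq_len(nrow(h)), function(i) {
      as.character(jsonlite::toJSON(list(ev = "hit", time = h$time[i],
                                         hand = h$hand[i], bin = h$bin[i]),
                                    auto_unbox = TRUE, digits = NA))
    }, character(1)))
  }
  if (!is.null(log$trajectories)) {
    for (hand in c("left", "right")) {
      tr <- log$trajectories[[hand]]
      if (is.null(tr)) next
      tt <- ts_times(tr$x)
      lines <- c(lines, vapply(seq_along(tt), function(i) {
        as.character(jsonlite::toJSON(
          list(ev = "pos", time = tt[i], hand = hand,
               x = tr$x$values[i], y = tr$y$values[i], rate = tr$x$rate),
          auto_unbox = TRUE, digits = NA))
      }, character(1)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an object-hit task log from JSON lines
#'
#' Parses the format written by [write_task_log()]. Events are sorted by time;
#' unknown event types raise a format error.
#'
#' @param path JSON-lines file path.
#' @return a [task_log()].
#' @export
read_task_log <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n_bins <- 16L; duration <- 240
  rel <- list(); hit <- list(); pos <- list()
  for (ln in lines) {
    ev <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    if (is.null(ev$ev)) stop("format error: event without `ev` field")
    switch(ev$ev,
      meta = {
        if (!is.null(ev$n_bins)) n_bins <- as.integer(ev$n_bins)
        if (!is.null(ev$duration)) duration <- ev$duration
      },
      release = rel[[length(rel) + 1L]] <-
        data.frame(time = ev$time, bin = as.integer(ev$bin),
                   speed = ev$speed),
      hit = hit[[length(hit) + 1L]] <-
        data.frame(time = ev$time, hand = ev$hand, bin = as.integer(ev$bin)),
      pos = pos[[length(pos) + 1L]] <-
        data.frame(time = ev$time, hand = ev$hand, x = ev$x, y = ev$y,
                   rate = if (is.null(ev$rate)) NA_real_ else ev$rate),
      stop("format error: unknown event type '", ev$ev, "'")
    )
  }
  releases <- if (length(rel)) do.call(rbind, rel) else NULL
  hits <- if (length(hit)) do.call(rbind, hit) else NULL
  trajectories <- NULL
  if (length(pos)) {
    pd <- do.call(rbind, pos)
    trajectories <- list()
    for (hand in unique(pd$hand)) {
      ph <- pd[pd$hand == hand, , drop = FALSE]
      ph <- ph[order(ph$time), , drop = FALSE]
      rate <- if (all(is.na(ph$rate))) 1 / stats::median(diff(ph$time))
              else ph$rate[!is.na(ph$rate)][1L]
      trajectories[[hand]] <- list(
        x = timeseries(ph$x, rate = rate, t0 = ph$time[1L], units = "cm",
                       channel = paste0(hand, "-x")),
        y = timeseries(ph$y, rate = rate, t0 = ph$time[1L], units = "cm",
                       channel = paste0(hand, "-y")))
    }
  }
  task_log(releases, hits, trajectories, n_bins = n_bins,
           duration = duration)
}

#' Session manifest
#'
#' Describes one experimental session: the subject, the fatiguing-task force
#' condition (5%, 50% or 75% of baseline MVC), the round index and the file
#' paths (or in-memory objects) of its data streams.
#'
#' @param subject_id subject label.
#' @param condition one of `"pct5"`, `"pct50"`, `"pct75"`.
#' @param round_index 1..3, position of this condition in the session order.
#' @param baseline_mvc baseline maximum voluntary contraction, force units,
#'   > 0.
#' @param streams named list of file paths or in-memory objects
#'   (e.g. `force`, `emg_fcr`, `emg_ecr`, `task_log`, `post_mvc`).
#' @return An object of class `"session_manifest"`.
#' @export
session_manifest <- function(subject_id, condition, round_index = 1L,
                             baseline_mvc = 1, streams = list()) {
  condition <- match.arg(condition, c("pct5", "pct50", "pct75"))
  if (!round_index %in% 1:3) stop("`round_index` must be 1, 2 or 3")
  if (!is.numeric(baseline_mvc) || baseline_mvc <= 0)
    stop("`baseline_mvc` must be > 0")
  structure(list(subject_id = as.character(subject_id), condition = condition,
                 round_index = as.integer(round_index),
                 baseline_mvc = baseline_mvc, streams = streams),
            class = "session_manifest")
}

#' Target force level as a percentage of baseline MVC
#'
#' @param pct force level, one of 5, 50, 75 (percent of baseline MVC).
#' @param baseline_mvc baseline MVC in force units, > 0.
#' @return list with `pct` and `absolute` (force units).
#' @export
target_force <- function(pct, baseline_mvc) {
  if (!pct %in% c(5, 50, 75))
    stop("`pct` must be one of 5, 50, 75")
  if (baseline_mvc <= 0) stop("`baseline_mvc` must be > 0")
  list(pct = pct, absolute = pct / 100 * baseline_mvc)
}

condition_pct <- function(condition) {
  c(pct5 = 5, pct50 = 50, pct75 = 75)[[condition]]
}
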