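#' Segment a force trace into cued contraction windows
#'
#' Cuts one segment per cue window out of a continuous trace. Segmentation is
#' cue-driven: the window boundaries come from the schedule, matching a
#' visually prompted protocol, not from a force threshold. Each segment holds
#' `round(rate * on_s)` samples starting at the first sample at or after the
#' cue onset.
#'
#' @param trace a [timeseries()] covering all schedule windows.
#' @param schedule a [build_cue_schedule()] result.
#' @return list of `"contraction_segment"` objects, each with `index`
#'   (0-based), `samples` (a [timeseries()] slice) and `onset` (s).
#' @examples
#' sched <- build_cue_schedule(3, 1, 1)
#' tr <- timeseries(rep(1, 300), rate = 47.75)
#' length(segment_contractions(tr, sched))  # 3
#' @export
segment_contractions <- function(trace, schedule) {
  stopifnot(inherits(trace, "timeseries"), inherits(schedule, "cue_schedule"))
  n_per <- round(trace$rate * schedule$on_s)
  out <- vector("list", schedule$n_cycles)
  for (k in seq_len(schedule$n_cycles)) {
    onset <- schedule$onsets[k]
    i0 <- ceiling((onset - trace$t0) * trace$rate - 1e-9) + 1L
    i1 <- i0 + n_per - 1L
    if (i0 < 1L || i1 > length(trace$values))
      stop("bounds error: cue window ", k, " lies outside the trace")
    out[[k]] <- structure(
      list(index = k - 1L,
           samples = timeseries(trace$values[i0:i1], rate = trace$rate,
                                t0 = trace$t0 + (i0 - 1L) / trace$rate,
                                units = trace$units, channel = trace$channel),
           onset = onset),
      class = "contraction_segment")
  }
  out
}

# indices the segmenter will select for cycle k (1-based); shared with the
# synthetic generator so that generated per-contraction AUCs are exact
segment_indices <- function(rate, t0, schedule, k) {
  n_per <- round(rate * schedule$on_s)
  i0 <- ceiling((schedule$onsets[k] - t0) * rate - 1e-9) + 1L
  i0:(i0 + n_per - 1L)
}

#' Median force between the full-width-at-half-maximum points
#'
#' Quantifies a maximum voluntary contraction (MVC) as the median force
#' applied between the FWHM points of the contraction force profile. The
#' profile is baseline-corrected by subtracting the smaller of the medians of
#' its first and last 10% of samples; the half-maximum crossings are located
#' by linear interpolation between the bracketing samples; the median is taken
#' over the raw (uncorrected) samples lying between the two crossings,
#' inclusive of the bracketing inner samples.
#'
#' @param profile a [timeseries()] holding one contraction force profile with
#'   a positive peak above baseline.
#' @return An object of class `"mvc_estimate"`: list with `median_force`
#'   (force units), `fwhm_start`, `fwhm_end` (s, interpolated crossing times),
#'   `peak` and `baseline`.
#' @seealso [mvc_best_of()] for the best-of-3 selection rule.
#' @export
fwhm_median <- function(profile) {
  stopifnot(inherits(profile, "timeseries"))
  v <- profile$values
  if (anyNA(v)) stop("data error: NA samples in MVC profile")
  n <- length(v)
  n_edge <- max(1L, floor(0.1 * n))
  baseline <- min(stats::median(v[seq_len(n_edge)]),
                  stats::median(v[(n - n_edge + 1L):n]))
  vc <- v - baseline
  peak_i <- which.max(vc)
  peak <- vc[peak_i]
  if (peak <= 0) stop("no-peak error: profile has no peak above baseline")
  half <- peak / 2
  above <- vc >= half
  first_above <- which(above)[1L]
  last_above <- which(above)[sum(above)]
  tt <- ts_times(profile)
  # interpolated crossing times (profile may start/end already above half-max)
  if (first_above == 1L) {
    t_start <- tt[1L]
  } else {
    i <- first_above
    frac <- (half - vc[i - 1L]) / (vc[i] - vc[i - 1L])
    t_start <- tt[i - 1L] + frac / profile$rate
  }
  if (last_above == n) {
    t_end <- tt[n]
  } else {
    i <- last_above
    frac <- (vc[i] - half) / (vc[i] - vc[i + 1L])
    t_end <- tt[i] + frac / profile$rate
  }
  med <- stats::median(v[first_above:last_above])
  structure(list(median_force = med, fwhm_start = t_start, fwhm_end = t_end,
                 peak = peak + baseline, baseline = baseline,
                 source = "single"),
            class = "mvc_estimate")
}

#' @export
print.mvc_estimate <- function(x, ...) {
  cat(sprintf("<mvc_estimate> median %.4g over FWHM [%.3f, %.3f] s (%s)\n",
              x$median_force, x$fwhm_start, x$fwhm_end, x$source))
  invisible(x)
}

#' Best-of-n MVC selection
#'
#' Applies [fwhm_median()] to each of several MVC attempt profiles and keeps
#' the attempt with the highest median force — the selection rule used for
#' the baseline "MVC 3x" block, whose winner also defines the target forces
#' of the fatiguing task.
#'
#' @param profiles list of [timeseries()] profiles (typically 3).
#' @return the winning `"mvc_estimate"`, with `source = "best_of_n"` and an
#'   extra field `all_medians`.
#' @export
mvc_best_of <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  ests <- lapply(profiles, fwhm_median)
  meds <- vapply(ests, `[[`, numeric(1), "median_force")
  best <- ests[[which.max(meds)]]
  best$source <- "best_of_n"
  best$all_medians <- meds
  best
}

#' Area under the curve of one contraction window
#'
#' Trapezoidal integral of the raw force over the contraction window, in
#' force x seconds. No baseline correction is applied.
#'
#' @param segment a `"contraction_segment"` from [segment_contractions()], or
#'   a bare [timeseries()].
#' @return numeric scalar, the AUC.
#' @export
contraction_auc <- function(segment) {
  ts <- if (inherits(segment, "contraction_segment")) segment$samples
        else segment
  stopifnot(inherits(ts, "timeseries"))
  v <- ts$values
  if (anyNA(v)) stop("data error: NA samples in contraction window")
  if (length(v) < 2L) stop("data error: contraction window too short")
  sum((v[-1L] + v[-length(v)]) / 2) / ts$rate
}

#' Fatigue slope: linear regression of per-contraction AUC on index
#'
#' The fatigue index of the cued handgrip protocol: ordinary least squares of
#' the per-contraction AUC values on contraction number, after discarding an
#' initial familiarisation period (the first 10 of 270 contractions in the
#' study protocol, leaving 260 points). A negative slope indicates declining
#' force output across the task.
#'
#' @param aucs numeric vector of per-contraction AUC values, in task order.
#' @param discard_first number of initial contractions to exclude as
#'   familiarisation (default 10).
#' @return An object of class `"slope_estimate"`: list with `beta` (AUC units
#'   per contraction), `intercept`, `n_points`, `residual_se` and `se_beta`.
#' @examples
#' aucs <- 3 - 0.01 * (0:269)
#' fatigue_slope(aucs)$beta  # -0.01
#' @export
fatigue_slope <- function(aucs, discard_first = 10L) {
  if (!is.numeric(aucs)) stop("`aucs` must be numeric")
  if (anyNA(aucs)) stop("data error: NA in AUC sequence")
  if (discard_first < 0) stop("`discard_first` must be >= 0")
  if (length(aucs) < discard_first + 2L)
    stop("validation error: need at least ", discard_first + 2L,
         " AUC values (", length(aucs), " given)")
  keep <- aucs[(discard_first + 1L):length(aucs)]
  idx <- seq.int(discard_first + 1L, length(aucs))
  fit <- stats::lm(keep ~ idx)
  cf <- stats::coef(fit)
  n <- length(keep)
  rss <- sum(stats::residuals(fit)^2)
  sigma <- sqrt(rss / (n - 2L))
  sxx <- sum((idx - mean(idx))^2)
  structure(list(beta = unname(cf[2L]), intercept = unname(cf[1L]),
                 n_points = n,
                 residual_se = sigma,
                 se_beta = sigma / sqrt(sxx)),
            class = "slope_estimate")
}

#' @export
print.slope_estimate <- function(x, ...) {
  cat(sprintf("<slope_estimate> beta = %.6g (se %.3g), n = %d\n",
              x$beta, x$se_beta, x$n_points))
  invisible(x)
}

#' Per-contraction AUCs and fatigue slope of a force trace
#'
#' Convenience wrapper chaining [segment_contractions()],
#' [contraction_auc()] and [fatigue_slope()].
#'
#' @inheritParams segment_contractions
#' @inheritParams fatigue_slope
#' @return list with `aucs` (one per cue window) and `slope`
#'   (a `"slope_estimate"`).
#' @export
force_ft_analysis <- function(trace, schedule, discard_first = 10L) {
  segs <- segment_contractions(trace, schedule)
  aucs <- vapply(segs, contraction_auc, numeric(1))
  list(aucs = aucs, slope = fatigue_slope(aucs, discard_first))
}
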