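#' Zero-phase Butterworth bandpass for surface EMG
#'
#' Bandpass filters an EMG trace between `low` and `high` Hz with a
#' Butterworth filter of the stated order, applied forward and backward
#' (zero-phase) so that contraction windows are not misaligned by group
#' delay. Because of the two passes the effective attenuation order doubles;
#' the stated `order` is the design order of each pass.
#'
#' @param trace a [timeseries()]; `rate` must exceed `2 * high`.
#' @param low,high band edges in Hz (defaults 10 and 500).
#' @param order Butterworth design order (default 4).
#' @return filtered [timeseries()] of the same length and rate.
#' @export
bandpass_emg <- function(trace, low = 10, high = 500, order = 4L) {
  stopifnot(inherits(trace, "timeseries"))
  if (anyNA(trace$values)) stop("data error: NA samples in EMG trace")
  if (trace$rate <= 2 * high)
    stop("Nyquist error: sampling rate ", trace$rate,
         " Hz must exceed twice the upper band edge (", 2 * high, " Hz)")
  if (low <= 0 || high <= low) stop("need 0 < low < high")
  # cascade of high-pass and low-pass sections: an order-n bandpass as a
  # single 2n-pole transfer function is numerically fragile at wide bands,
  # while the cascaded sections keep the same band edges and are stable
  hp <- signal::butter(order, low / (trace$rate / 2), type = "high")
  lp <- signal::butter(order, high / (trace$rate / 2), type = "low")
  filtered <- signal::filtfilt(lp, signal::filtfilt(hp, trace$values))
  timeseries(filtered, rate = trace$rate, t0 = trace$t0,
             units = trace$units, channel = trace$channel)
}

# analytic signal via FFT: zero negative frequencies, double positive ones
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' EMG amplitude envelope
#'
#' Extracts the non-negative amplitude envelope of a (bandpassed) EMG trace.
#' The default method is the magnitude of the analytic signal (Hilbert
#' transform); an alternative rectify-and-low-pass estimator (full-wave
#' rectification followed by a zero-phase 2nd-order Butterworth low-pass,
#' default 6 Hz) is available via `method`.
#'
#' @param trace a bandpassed [timeseries()].
#' @param method `"hilbert"` (default) or `"rectify_lowpass"`.
#' @param lowpass_hz low-pass cut-off for the rectification method, Hz.
#' @return An `"envelope_trace"`: a [timeseries()] of non-negative values
#'   with the same rate/length as the input, with attribute `method`.
#' @export
emg_envelope <- function(trace, method = c("hilbert", "rectify_lowpass"),
                         lowpass_hz = 6) {
  stopifnot(inherits(trace, "timeseries"))
  method <- match.arg(method)
  if (anyNA(trace$values)) stop("data error: NA samples in EMG trace")
  env <- switch(method,
    hilbert = Mod(analytic_signal(trace$values)),
    rectify_lowpass = {
      rect <- abs(trace$values)
      bf <- signal::butter(2, lowpass_hz / (trace$rate / 2), type = "low")
      pmax(signal::filtfilt(bf, rect), 0)
    })
  out <- timeseries(env, rate = trace$rate, t0 = trace$t0,
                    units = trace$units, channel = trace$channel)
  class(out) <- c("envelope_trace", class(out))
  attr(out, "method") <- method
  out
}

#' EMG fatigue slope over the fatiguing task
#'
#' Applies the same per-contraction pipeline used for force to the EMG
#' envelope: segment by the cue schedule, discard the familiarisation
#' contractions, compute the AUC of the envelope within each 1 s contraction
#' window, and regress AUC on contraction number.
#'
#' @param envelope an `"envelope_trace"` from [emg_envelope()] (or any
#'   [timeseries()]).
#' @param schedule a [build_cue_schedule()] result.
#' @param discard_first initial contractions excluded (default 10).
#' @return list with `aucs` and `slope` (a `"slope_estimate"`), as
#'   [force_ft_analysis()].
#' @export
emg_ft_slope <- function(envelope, schedule, discard_first = 10L) {
  force_ft_analysis(envelope, schedule, discard_first)
}

#' Median EMG envelope over a task window
#'
#' Summary of muscle activity during the assessment task: the median of the
#' envelope samples between `t_start` and `t_end` (inclusive).
#'
#' @param envelope an `"envelope_trace"` (or [timeseries()]).
#' @param t_start,t_end window bounds in seconds (session clock); default the
#'   full trace.
#' @return numeric scalar, the median envelope value.
#' @export
emg_at_median <- function(envelope, t_start = NULL, t_end = NULL) {
  stopifnot(inherits(envelope, "timeseries"))
  tt <- ts_times(envelope)
  if (is.null(t_start)) t_start <- tt[1L]
  if (is.null(t_end)) t_end <- tt[length(tt)]
  if (t_end <= t_start) stop("validation error: t_end must exceed t_start")
  sel <- tt >= t_start - 1e-9 & tt <= t_end + 1e-9
  if (!any(sel)) stop("validation error: empty envelope window")
  stats::median(envelope$values[sel])
}
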