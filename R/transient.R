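# Transient evoked-response pipeline: peri-onset epoching, grand averaging,
# baseline-referenced peak amplitude and distance-corrected peak latency.

#' Extract peri-onset epochs
#'
#' Cuts one row per burst onset spanning \code{pre_ms} before to
#' \code{post_ms} after the onset (default the 40-ms analysis window: 20 ms
#' either side). The time axis places the onset sample at 0 ms, so the
#' baseline interval is (-pre_ms, 0] and the response interval (0, post_ms].
#' Onsets lacking full context are dropped with a warning.
#'
#' @param neural numeric LFP series, µV.
#' @param onsets sorted burst onset times, s.
#' @param rate_hz sampling rate, Hz.
#' @param pre_ms,post_ms window half-widths, ms.
#' @return an \linkS4class{EpochSet}.
#' @export
extractEpochs <- function(neural, onsets, rate_hz, pre_ms = 20, post_ms = 20) {
  if (!length(onsets)) stop("empty onset list")
  pre_n <- round(pre_ms / 1000 * rate_hz)
  post_n <- round(post_ms / 1000 * rate_hz)
  n <- length(neural)
  i0 <- round(onsets * rate_hz) + 1L          # onset sample (t = 0)
  ok <- (i0 - pre_n) >= 1L & (i0 + post_n) <= n
  if (any(!ok))
    warning(sum(!ok), " onset(s) dropped for lacking full pre/post context")
  i0 <- i0[ok]
  if (!length(i0)) stop("no onset has full pre/post context")
  rel <- seq.int(-pre_n + 1L, post_n)         # (-pre, 0] and (0, post]
  trials <- t(vapply(i0, function(i) neural[i + rel], numeric(length(rel))))
  new("EpochSet", trials = trials, timeMs = rel / rate_hz * 1000,
      rate = rate_hz)
}

#' Grand average of an epoch set
#'
#' @param epochs an \linkS4class{EpochSet} with at least one trial.
#' @return numeric pointwise-mean waveform over the epoch time axis, µV.
#' @export
grandAverage <- function(epochs) {
  if (nTrials(epochs) < 1) stop("need at least one trial")
  colMeans(epochMatrix(epochs))
}

#' Peak latency and amplitude of an averaged evoked response
#'
#' The baseline is the mean over the pre-onset interval (time <= 0). The
#' evoked peak is the post-onset sample (time > 0) with maximum deviation
#' from baseline (absolute deviation by default; restrict with
#' \code{polarity}). Amplitude is the signed peak-minus-baseline value;
#' latency is the raw peak time plus \code{delay_correction_ms}, the
#' speaker-to-animal propagation allowance (default +2 ms for a 70-cm
#' distance; sign and size configurable).
#'
#' @param avg numeric averaged waveform (e.g. from [grandAverage()]).
#' @param time_ms time axis in ms relative to onset, same length as
#'   \code{avg}, spanning negative and positive times.
#' @param delay_correction_ms signed correction added to the raw peak time.
#' @param polarity "both" (default), "positive" or "negative".
#' @return list: \code{latency_ms}, \code{amplitude_uV},
#'   \code{peak_time_raw_ms}, \code{baseline_mean_uV},
#'   \code{delay_correction_ms}.
#' @export
peakMetrics <- function(avg, time_ms, delay_correction_ms = 2.0,
                        polarity = c("both", "positive", "negative")) {
  polarity <- match.arg(polarity)
  stopifnot(length(avg) == length(time_ms))
  base_idx <- time_ms <= 0
  post_idx <- time_ms > 0
  if (!any(base_idx) || !any(post_idx))
    stop("time axis must span the pre- and post-onset intervals")
  baseline <- mean(avg[base_idx])
  dev <- avg[post_idx] - baseline
  if (max(abs(dev)) < .Machine$double.eps * max(1, abs(baseline)))
    stop("no evoked peak: post-onset segment is flat")
  score <- switch(polarity, both = abs(dev), positive = dev, negative = -dev)
  k <- which.max(score)
  peak_raw <- time_ms[post_idx][k]
  list(latency_ms = peak_raw + delay_correction_ms,
       amplitude_uV = dev[k],
       peak_time_raw_ms = peak_raw,
       baseline_mean_uV = baseline,
       delay_correction_ms = delay_correction_ms)
}

#' Latency dispersion (coefficient of variation)
#'
#' 100 x sample SD / mean of a set of peak latencies; the response-jitter
#' summary used to compare groups.
#'
#' @param latencies_ms numeric latencies, ms; at least 2, nonzero mean.
#' @return percent.
#' @export
latencyDispersion <- function(latencies_ms) {
  if (length(latencies_ms) < 2) stop("need at least 2 latencies")
  m <- mean(latencies_ms)
  if (m == 0) stop("mean latency is zero")
  100 * stats::sd(latencies_ms) / m
}

#' Acoustic propagation delay in milliseconds
#'
#' Travel time of sound over a speaker-to-subject distance, the physical
#' basis of the latency correction (70 cm at 343 m/s is ~2.04 ms, i.e. 2 ms
#' to the nearest millisecond).
#'
#' @param distance_m distance, m.
#' @param speed_m_s speed of sound, m/s (default 343, dry air at 20 C).
#' @return delay in ms.
#' @export
propagationDelayMs <- function(distance_m, speed_m_s = 343) {
  if (distance_m < 0 || speed_m_s <= 0) stop("invalid distance or speed")
  1000 * distance_m / speed_m_s
}

#' Transient metrics of a recording session
#'
#' End-to-end convenience: epochs around the session's burst onsets, grand
#' average, and peak metrics.
#'
#' @param session a \linkS4class{RecordingSession} whose protocol contains
#'   burst onsets.
#' @param pre_ms,post_ms epoch half-widths, ms.
#' @param delay_correction_ms signed latency correction, ms.
#' @param polarity peak polarity restriction, see [peakMetrics()].
#' @return one-row data.frame: n_trials, latency_ms, amplitude_uV,
#'   peak_time_raw_ms, baseline_mean_uV.
#' @export
analyzeTransient <- function(session, pre_ms = 20, post_ms = 20,
                             delay_correction_ms = 2.0, polarity = "both") {
  onsets <- burstOnsets(sessionProtocol(session))
  ep <- extractEpochs(neuralTrack(session), onsets, sampleRate(session),
                      pre_ms, post_ms)
  pm <- peakMetrics(grandAverage(ep), epochTimesMs(ep),
                    delay_correction_ms, polarity)
  data.frame(n_trials = nTrials(ep), latency_ms = pm$latency_ms,
             amplitude_uV = pm$amplitude_uV,
             peak_time_raw_ms = pm$peak_time_raw_ms,
             baseline_mean_uV = pm$baseline_mean_uV)
}
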