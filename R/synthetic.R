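# Synthetic two-channel LFP sessions with known ground truth: 1/f-colored
# background with band-limited oscillations, stimulus-entrained sinusoids
# with phase jitter, transient evoked kernels, and movement-artifact bursts.

#' Synthetic session configuration
#'
#' Ground-truth parameters of the LFP simulator. No quantitative signal
#' model is published for the recordings this package emulates; the defaults
#' are realistic midbrain-LFP presets (documented in the methods vignette),
#' not literature claims.
#'
#' @param rate_hz sampling rate, Hz (10000 and 12000 are the two emulated
#'   acquisition protocols).
#' @param duration_s session duration, s.
#' @param noise_sigma_uV standard deviation of the colored background, µV.
#' @param spectral_exponent alpha >= 0; background PSD proportional to
#'   1/f^alpha above 1 Hz.
#' @param band_oscillations data.frame(center_hz, amplitude_uV) of sustained
#'   sinusoidal oscillations added to the background.
#' @param entrain_amp_uV amplitude of the stimulus-entrained component, µV.
#' @param phase_jitter_sd_rad SD of the per-cycle phase random-walk
#'   innovation, rad; 0 gives perfect entrainment.
#' @param evoked_latency_ms evoked-kernel peak latency after burst onset, ms.
#' @param evoked_amp_uV evoked-kernel peak amplitude, µV.
#' @param evoked_width_ms SD of the Gaussian evoked kernel, ms.
#' @param trial_latency_jitter_ms SD of the per-trial latency jitter, ms.
#' @param evoked_polarity +1 or -1.
#' @param artifact_bursts data.frame(start_s, dur_s, amplitude_uV) of
#'   low-frequency movement-artifact bursts.
#' @param seed integer; fully determines the generated session.
#' @return a validated list of class \code{SyntheticConfig}.
#' @export
syntheticConfig <- function(rate_hz = 12000, duration_s = 60,
                            noise_sigma_uV = 20, spectral_exponent = 1,
                            band_oscillations = data.frame(
                              center_hz = c(6, 40),
                              amplitude_uV = c(5, 2)),
                            entrain_amp_uV = 10, phase_jitter_sd_rad = 0.1,
                            evoked_latency_ms = 5, evoked_amp_uV = 80,
                            evoked_width_ms = 2, trial_latency_jitter_ms = 0.2,
                            evoked_polarity = 1,
                            artifact_bursts = data.frame(
                              start_s = numeric(), dur_s = numeric(),
                              amplitude_uV = numeric()),
                            seed = 1L) {
  cfg <- as.list(environment())
  if (rate_hz <= 0 || duration_s <= 0)
    stop("rate_hz and duration_s must be positive")
  if (noise_sigma_uV < 0 || entrain_amp_uV < 0 || evoked_amp_uV < 0)
    stop("amplitudes must be nonnegative")
  if (spectral_exponent < 0) stop("spectral_exponent must be >= 0")
  if (phase_jitter_sd_rad < 0) stop("phase_jitter_sd_rad must be >= 0")
  if (!abs(evoked_polarity) == 1) stop("evoked_polarity must be +1 or -1")
  class(cfg) <- c("SyntheticConfig", "list")
  cfg
}

#' Generate the colored background LFP
#'
#' White Gaussian noise is spectrally shaped in the frequency domain to a
#' PSD proportional to 1/f^alpha above 1 Hz (flat below 1 Hz, zero DC), then
#' rescaled to \code{noise_sigma_uV} SD; the configured band oscillations are
#' added with random phases. Uses the current RNG state; callers wanting
#' reproducibility seed beforehand (as [generateSession()] does).
#'
#' @param cfg a \code{\link{syntheticConfig}}.
#' @param duration_s duration, s (default \code{cfg$duration_s}).
#' @return numeric zero-mean series, µV.
#' @export
generateBackground <- function(cfg, duration_s = cfg$duration_s) {
  if (duration_s <= 0) stop("duration must be positive")
  n <- round(duration_s * cfg$rate_hz)
  w <- stats::rnorm(n)
  f <- c(seq_len(n %/% 2 + 1) - 1, rev(seq_len((n - 1) %/% 2))) *
    cfg$rate_hz / n                       # two-sided frequency magnitudes
  h <- pmax(f, 1)^(-cfg$spectral_exponent / 2)
  h[1] <- 0
  x <- Re(stats::fft(stats::fft(w) * h, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x <- x * (cfg$noise_sigma_uV / s)
  if (nrow(cfg$band_oscillations)) {
    t <- (seq_len(n) - 1) / cfg$rate_hz
    for (i in seq_len(nrow(cfg$band_oscillations))) {
      fc <- cfg$band_oscillations$center_hz[i]
      # ongoing oscillations drift in phase (they are not stimulus-locked):
      # a slow random walk (0.2 rad SD per cycle) keeps them narrowband but
      # incoherent with any periodic stimulus train
      drift <- cumsum(stats::rnorm(n, 0, 0.2 * sqrt(fc / cfg$rate_hz)))
      x <- x + cfg$band_oscillations$amplitude_uV[i] *
        sin(2 * pi * fc * t + stats::runif(1, 0, 2 * pi) + drift)
    }
  }
  x
}

#' Generate a stimulus-entrained sinusoidal component
#'
#' \eqn{A \sin(2\pi f_m t + \phi(t))} where the phase \eqn{\phi} follows a
#' cumulative Gaussian random walk with per-cycle innovation SD
#' \code{phase_jitter_sd_rad}: zero jitter gives a pure sine, increasing
#' jitter degrades coherence with a reference sine while the instantaneous
#' frequency stays near \eqn{f_m}.
#'
#' @param mod_hz modulation (entrainment) frequency, Hz; below rate/2.
#' @param cfg a \code{\link{syntheticConfig}} (uses \code{entrain_amp_uV},
#'   \code{phase_jitter_sd_rad}, \code{rate_hz}).
#' @param dur_s duration, s.
#' @return numeric series, µV.
#' @export
generateEntrainedComponent <- function(mod_hz, cfg, dur_s) {
  if (mod_hz >= cfg$rate_hz / 2) stop("mod_hz must be below rate/2")
  if (cfg$phase_jitter_sd_rad < 0) stop("phase jitter SD must be >= 0")
  n <- round(dur_s * cfg$rate_hz)
  t <- (seq_len(n) - 1) / cfg$rate_hz
  phi <- if (cfg$phase_jitter_sd_rad > 0) {
    # per-sample innovation so that variance accrued per cycle = sd^2
    cumsum(stats::rnorm(n, 0, cfg$phase_jitter_sd_rad *
                             sqrt(mod_hz / cfg$rate_hz)))
  } else 0
  cfg$entrain_amp_uV * sin(2 * pi * mod_hz * t + phi)
}

#' Generate transient evoked components
#'
#' Adds, at each burst onset, a Gaussian-envelope monophasic kernel peaking
#' \code{evoked_latency_ms} (plus per-trial Gaussian jitter of SD
#' \code{trial_latency_jitter_ms}) after the onset, with peak
#' \code{evoked_amp_uV} and envelope SD \code{evoked_width_ms}.
#'
#' @param onsets burst onset times, s; all within \code{duration_s}.
#' @param cfg a \code{\link{syntheticConfig}}.
#' @param duration_s series duration, s.
#' @return list: \code{series} (numeric, µV) and \code{trials}
#'   (data.frame onset_s, latency_ms, amplitude_uV of each realized kernel).
#' @export
generateEvokedComponent <- function(onsets, cfg, duration_s = cfg$duration_s) {
  n <- round(duration_s * cfg$rate_hz)
  x <- numeric(n)
  if (!length(onsets))
    return(list(series = x,
                trials = data.frame(onset_s = numeric(), latency_ms = numeric(),
                                    amplitude_uV = numeric())))
  if (any(onsets < 0 | onsets > duration_s))
    stop("onsets must lie within [0, duration]")
  lat <- cfg$evoked_latency_ms +
    stats::rnorm(length(onsets), 0, cfg$trial_latency_jitter_ms)
  sd_n <- cfg$evoked_width_ms / 1000 * cfg$rate_hz
  half <- ceiling(5 * sd_n)
  for (k in seq_along(onsets)) {
    peak_i <- round((onsets[k] + lat[k] / 1000) * cfg$rate_hz) + 1
    idx <- max(1, peak_i - half):min(n, peak_i + half)
    x[idx] <- x[idx] + cfg$evoked_polarity * cfg$evoked_amp_uV *
      exp(-((idx - peak_i)^2) / (2 * sd_n^2))
  }
  list(series = x,
       trials = data.frame(onset_s = onsets, latency_ms = lat,
                           amplitude_uV = cfg$evoked_amp_uV))
}

#' Inject low-frequency movement-artifact bursts
#'
#' Within each configured interval, adds low-pass (< 10 Hz) Gaussian noise
#' scaled to the configured SD; the series is unchanged outside the bursts.
#' Overlapping bursts simply superpose.
#'
#' @param series numeric sample series, µV.
#' @param cfg a \code{\link{syntheticConfig}} (uses \code{artifact_bursts},
#'   \code{rate_hz}).
#' @return the series with artifacts added.
#' @export
injectArtifactBursts <- function(series, cfg) {
  ab <- cfg$artifact_bursts
  if (!nrow(ab)) return(series)
  n <- length(series)
  dur <- n / cfg$rate_hz
  if (any(ab$start_s < 0 | ab$start_s + ab$dur_s > dur + 1e-9))
    stop("artifact burst intervals must lie within the series duration")
  bf <- signal::butter(4, min(10 / (cfg$rate_hz / 2), 0.99), type = "low")
  for (i in seq_len(nrow(ab))) {
    i0 <- round(ab$start_s[i] * cfg$rate_hz) + 1L
    i1 <- min(n, i0 + round(ab$dur_s[i] * cfg$rate_hz) - 1L)
    m <- i1 - i0 + 1L
    raw <- as.numeric(signal::filtfilt(bf, stats::rnorm(m + 2000)))[1001:(1000 + m)]
    s <- stats::sd(raw)
    if (s > 0) raw <- raw * (ab$amplitude_uV[i] / s)
    series[i0:i1] <- series[i0:i1] + raw
  }
  series
}

#' Generate a full synthetic recording session
#'
#' Assembles neural = background + entrained components (active only during
#' the protocol's AM segments) + evoked kernels (at burst onsets) +
#' artifact bursts, regenerates the reference track from the protocol (unit
#' sines during AM segments, unit square pulses during bursts), and records
#' every true parameter in a ground-truth object. Fully deterministic under
#' \code{cfg$seed}.
#'
#' @param protocol a \linkS4class{StimulusProtocol}.
#' @param cfg a \code{\link{syntheticConfig}}; \code{duration_s} must cover
#'   the last protocol event.
#' @param meta list of provenance tags attached to the session.
#' @return list: \code{session} (\linkS4class{RecordingSession}) and
#'   \code{truth} (list with \code{segments}, \code{trials},
#'   \code{artifacts}, \code{background_var_uV2}).
#' @export
generateSession <- function(protocol, cfg, meta = list()) {
  ev <- protocolEvents(protocol)
  if (nrow(ev) && max(ev$time_s) > cfg$duration_s + 1e-9)
    stop("cfg$duration_s does not cover the protocol (needs >= ",
         max(ev$time_s), " s)")
  set.seed(cfg$seed)
  n <- round(cfg$duration_s * cfg$rate_hz)
  neural <- generateBackground(cfg)
  reference <- numeric(n)

  segs <- amSegments(protocol)
  if (nrow(segs)) {
    for (i in seq_len(nrow(segs))) {
      i0 <- round(segs$start_s[i] * cfg$rate_hz) + 1L
      seg_dur <- segs$end_s[i] - segs$start_s[i]
      comp <- generateEntrainedComponent(segs$freq_hz[i], cfg, seg_dur)
      idx <- i0:(i0 + length(comp) - 1L)
      neural[idx] <- neural[idx] + comp
      tl <- (idx - i0) / cfg$rate_hz
      reference[idx] <- sin(2 * pi * segs$freq_hz[i] * tl)
    }
  }
  segs$entrain_amp_uV <- rep(cfg$entrain_amp_uV, nrow(segs))
  segs$phase_jitter_sd_rad <- rep(cfg$phase_jitter_sd_rad, nrow(segs))

  onsets <- burstOnsets(protocol)
  evk <- generateEvokedComponent(onsets, cfg)
  neural <- neural + evk$series
  if (length(onsets)) {
    offs <- ev$time_s[ev$kind == "burst_offset"]
    for (k in seq_along(onsets)) {
      i0 <- round(onsets[k] * cfg$rate_hz) + 1L
      i1 <- if (length(offs) >= k) round(offs[k] * cfg$rate_hz)
            else i0 + round(0.04 * cfg$rate_hz) - 1L
      reference[i0:min(i1, n)] <- 1
    }
  }

  neural <- injectArtifactBursts(neural, cfg)
  session <- new("RecordingSession", neural = neural, reference = reference,
                 rate = cfg$rate_hz, protocol = protocol, meta = meta)
  truth <- list(segments = segs, trials = evk$trials,
                artifacts = cfg$artifact_bursts,
                background_var_uV2 = cfg$noise_sigma_uV^2)
  list(session = session, truth = truth)
}

#' Protocol of a conditioned-stimulus (AFC-style) session
#'
#' \code{n_cs} presentations of a 30-s AM conditioned stimulus at
#' \code{cs_freq_hz}, each preceded by \code{baseline_s} of silence.
#'
#' @param n_cs number of CS presentations (default 5).
#' @param cs_freq_hz CS modulation frequency, Hz (default 53.7).
#' @param cs_dur_s CS duration, s (default 30).
#' @param baseline_s silence before each CS, s (default 30).
#' @return a \linkS4class{StimulusProtocol}.
#' @export
afcProtocol <- function(n_cs = 5, cs_freq_hz = 53.7, cs_dur_s = 30,
                        baseline_s = 30) {
  ev <- data.frame(kind = character(), time_s = numeric(), freq_hz = numeric())
  t0 <- 0
  for (k in seq_len(n_cs)) {
    ev <- rbind(ev,
                data.frame(kind = "silence_start", time_s = t0,
                           freq_hz = NA_real_),
                data.frame(kind = c("am_segment_start", "am_segment_end"),
                           time_s = c(t0 + baseline_s,
                                      t0 + baseline_s + cs_dur_s),
                           freq_hz = cs_freq_hz))
    t0 <- t0 + baseline_s + cs_dur_s
  }
  StimulusProtocol(ev)
}
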