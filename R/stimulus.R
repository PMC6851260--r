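# Acoustic stimulus synthesis: transient tone-burst trains and
# amplitude-modulated (AM) tones with reference sync tracks.

#' Stimulus specification
#'
#' Parameters of the acoustic stimulation protocol: a train of gated
#' tone bursts (transient stimulus) and/or amplitude-modulated pure tones
#' (steady-state stimulus), rendered together with a reference sync track.
#' Defaults reproduce the recording protocol this package emulates: 120
#' bursts of a 10-kHz carrier, each 40 ms (1-ms linear rise, 38-ms plateau,
#' 1-ms fall) with a 460-ms interpulse interval (two bursts per second over
#' 60 s), and 30-s AM segments at 30/90/150/210 Hz separated by 30-s
#' silences, at 44.1 kHz audio rate.
#'
#' @param carrier_hz carrier frequency, Hz.
#' @param burst_count number of tone bursts in the transient train.
#' @param burst_dur_s burst duration, s.
#' @param rise_s linear rise-ramp duration, s.
#' @param plateau_s plateau duration, s; the fall ramp is
#'   \code{burst_dur_s - rise_s - plateau_s}.
#' @param interpulse_s silent gap between bursts, s.
#' @param am_mod_freqs_hz AM modulation frequencies, Hz.
#' @param am_depth AM modulation depth in [0, 1] (1 = 100\%).
#' @param segment_dur_s duration of each AM segment, s.
#' @param silence_dur_s duration of the silence before each AM segment, s.
#' @param audio_rate_hz audio sampling rate, Hz.
#' @param level_dB_SPL nominal presentation level; metadata only, no
#'   acoustic calibration is modelled.
#' @return a validated list of class \code{StimulusSpec}.
#' @export
stimulusSpec <- function(carrier_hz = 10000, burst_count = 120,
                         burst_dur_s = 0.040, rise_s = 0.001,
                         plateau_s = 0.038, interpulse_s = 0.460,
                         am_mod_freqs_hz = c(30, 90, 150, 210),
                         am_depth = 1.0, segment_dur_s = 30,
                         silence_dur_s = 30, audio_rate_hz = 44100,
                         level_dB_SPL = 80) {
  spec <- list(carrier_hz = carrier_hz, burst_count = burst_count,
               burst_dur_s = burst_dur_s, rise_s = rise_s,
               plateau_s = plateau_s, interpulse_s = interpulse_s,
               am_mod_freqs_hz = am_mod_freqs_hz, am_depth = am_depth,
               segment_dur_s = segment_dur_s, silence_dur_s = silence_dur_s,
               audio_rate_hz = audio_rate_hz, level_dB_SPL = level_dB_SPL)
  fall <- burst_dur_s - rise_s - plateau_s
  if (fall < -1e-12)
    stop("invalid spec: rise_s + plateau_s exceeds burst_dur_s")
  if (interpulse_s < 0)
    stop("invalid spec: interpulse_s must be nonnegative (bursts overlap)")
  if (burst_count < 0) stop("invalid spec: burst_count must be >= 0")
  if (am_depth < 0 || am_depth > 1)
    stop("invalid spec: am_depth must lie in [0, 1]")
  if (audio_rate_hz <= 2 * carrier_hz)
    stop("invalid spec: audio_rate_hz must exceed twice the carrier (Nyquist)")
  class(spec) <- c("StimulusSpec", "list")
  spec
}

# trapezoidal gating envelope of one burst, evaluated at times t (s) from
# burst onset; linear rise over rise_s, plateau, linear fall back to 0
burstEnvelope <- function(t, burst_dur_s, rise_s, plateau_s) {
  fall_s <- burst_dur_s - rise_s - plateau_s
  env <- numeric(length(t))
  inb <- t >= 0 & t < burst_dur_s
  tr <- t[inb]
  e <- rep(1, length(tr))
  e[tr < rise_s] <- tr[tr < rise_s] / rise_s
  f <- tr >= rise_s + plateau_s
  e[f] <- (burst_dur_s - tr[f]) / fall_s
  env[inb] <- e
  env
}

#' Build the transient tone-burst train
#'
#' Renders \code{burst_count} gated carrier bursts, one every
#' \code{burst_dur_s + interpulse_s} seconds, with linear rise/fall ramps and
#' a plateau per the spec. The reference track carries a unit square pulse
#' spanning each burst.
#'
#' @param spec a \code{\link{stimulusSpec}}.
#' @return a \linkS4class{StereoStimulus} spanning
#'   \code{burst_count * (burst_dur_s + interpulse_s)} seconds.
#' @seealso [transientProtocol()] for the analytically known event times.
#' @export
buildTransientTrain <- function(spec = stimulusSpec()) {
  rate <- spec$audio_rate_hz
  period_s <- spec$burst_dur_s + spec$interpulse_s
  n <- round(spec$burst_count * period_s * rate)
  audio <- numeric(n)
  ref <- numeric(n)
  if (spec$burst_count > 0) {
    t <- (seq_len(n) - 1) / rate
    burst_n <- round(spec$burst_dur_s * rate)
    for (k in seq_len(spec$burst_count)) {
      onset_s <- (k - 1) * period_s
      i0 <- round(onset_s * rate) + 1L
      idx <- i0:(i0 + burst_n - 1L)
      tl <- t[idx] - onset_s
      env <- burstEnvelope(tl, spec$burst_dur_s, spec$rise_s, spec$plateau_s)
      audio[idx] <- env * sin(2 * pi * spec$carrier_hz * tl)
      ref[idx] <- 1
    }
  }
  new("StereoStimulus", audio = audio, reference = ref, rate = rate)
}

#' Analytic event times of the transient train
#'
#' @param spec a \code{\link{stimulusSpec}}.
#' @return a \linkS4class{StimulusProtocol} with one burst_onset and
#'   burst_offset per burst.
#' @export
transientProtocol <- function(spec = stimulusSpec()) {
  if (spec$burst_count == 0) return(StimulusProtocol())
  period_s <- spec$burst_dur_s + spec$interpulse_s
  onsets <- (seq_len(spec$burst_count) - 1) * period_s
  StimulusProtocol(data.frame(
    kind = rep(c("burst_onset", "burst_offset"), spec$burst_count),
    time_s = as.vector(rbind(onsets, onsets + spec$burst_dur_s)),
    freq_hz = NA_real_))
}

#' Build an amplitude-modulated tone with a reference sine track
#'
#' Standard double-sideband AM: the audio is
#' \eqn{[1 + m \sin(2\pi f_m t)] \sin(2\pi f_c t) / (1 + m)}, scaled so the
#' peak never exceeds 1 at any depth; the reference track is a unit sine at
#' the modulation frequency.
#'
#' @param carrier_hz carrier frequency, Hz.
#' @param mod_hz modulation frequency, Hz (< carrier_hz).
#' @param depth modulation depth in [0, 1].
#' @param dur_s duration, s.
#' @param rate_hz sampling rate, Hz.
#' @return a \linkS4class{StereoStimulus}.
#' @export
buildAmTone <- function(carrier_hz = 10000, mod_hz = 53.7, depth = 1.0,
                        dur_s = 30, rate_hz = 44100) {
  if (depth < 0 || depth > 1) stop("depth must lie in [0, 1]")
  if (mod_hz >= carrier_hz) stop("mod_hz must be below carrier_hz")
  if (carrier_hz + mod_hz >= rate_hz / 2)
    stop("Nyquist violation: carrier_hz + mod_hz must be below rate_hz/2")
  n <- round(dur_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  audio <- (1 + depth * sin(2 * pi * mod_hz * t)) *
    sin(2 * pi * carrier_hz * t) / (1 + depth)
  new("StereoStimulus", audio = audio,
      reference = sin(2 * pi * mod_hz * t), rate = rate_hz)
}

#' Build the steady-state (ASSR) stimulus sequence
#'
#' Concatenates one AM segment per modulation frequency, each preceded by a
#' silence of \code{silence_dur_s} (set 0 to omit). Optionally prepends the
#' transient burst train. The returned protocol lists every segment boundary
#' with its modulation frequency.
#'
#' @param spec a \code{\link{stimulusSpec}}.
#' @param include_transient prepend the transient train (followed by its own
#'   leading silence before the first AM segment).
#' @return list with elements \code{stimulus} (\linkS4class{StereoStimulus})
#'   and \code{protocol} (\linkS4class{StimulusProtocol}).
#' @export
buildAssrSequence <- function(spec = stimulusSpec(), include_transient = FALSE) {
  if (!length(spec$am_mod_freqs_hz)) stop("am_mod_freqs_hz must be nonempty")
  rate <- spec$audio_rate_hz
  audio <- list(); ref <- list()
  ev <- data.frame(kind = character(), time_s = numeric(), freq_hz = numeric())
  t0 <- 0
  if (include_transient) {
    train <- buildTransientTrain(spec)
    audio <- c(audio, list(train@audio)); ref <- c(ref, list(train@reference))
    ev <- rbind(ev, protocolEvents(transientProtocol(spec)))
    t0 <- signalDuration(train)
  }
  sil_n <- round(spec$silence_dur_s * rate)
  for (fm in spec$am_mod_freqs_hz) {
    if (sil_n > 0) {
      audio <- c(audio, list(numeric(sil_n)))
      ref <- c(ref, list(numeric(sil_n)))
      ev <- rbind(ev, data.frame(kind = "silence_start", time_s = t0,
                                 freq_hz = NA_real_))
      t0 <- t0 + sil_n / rate
    }
    seg <- buildAmTone(spec$carrier_hz, fm, spec$am_depth,
                       spec$segment_dur_s, rate)
    audio <- c(audio, list(seg@audio)); ref <- c(ref, list(seg@reference))
    seg_dur <- length(seg@audio) / rate
    ev <- rbind(ev,
                data.frame(kind = c("am_segment_start", "am_segment_end"),
                           time_s = c(t0, t0 + seg_dur), freq_hz = fm))
    t0 <- t0 + seg_dur
  }
  list(stimulus = new("StereoStimulus", audio = unlist(audio),
                      reference = unlist(ref), rate = rate),
       protocol = StimulusProtocol(ev))
}

#' Export a protocol as JSON
#'
#' @param protocol a \linkS4class{StimulusProtocol}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
exportProtocolJson <- function(protocol, path) {
  jsonlite::write_json(protocolEvents(protocol), path, digits = NA, na = "null")
  invisible(path)
}

#' Read a protocol from JSON
#'
#' @param path path to a JSON file written by [exportProtocolJson()].
#' @return a \linkS4class{StimulusProtocol}.
#' @export
readProtocolJson <- function(path) {
  ev <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!nrow(ev)) return(StimulusProtocol())
  ev$freq_hz <- as.numeric(ev$freq_hz)
  StimulusProtocol(ev)
}
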