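EVENT_KINDS <- c("burst_onset", "burst_offset",
                 "am_segment_start", "am_segment_end", "silence_start")

#' StereoStimulus: audio plus reference sync track
#'
#' Two equally long sample series at a common rate: the acoustic stimulus
#' waveform (dimensionless, in [-1, 1]) and the reference synchronization
#' track (square pulses at transient burst onsets and/or unit reference sines
#' at the AM modulation frequencies). This is the payload of the stereo WAV
#' files used to drive and synchronize the recordings.
#'
#' @slot audio numeric, audio samples in [-1, 1].
#' @slot reference numeric, sync-track samples in [-1, 1].
#' @slot rate numeric(1), sampling rate in Hz.
#' @export
setClass("StereoStimulus",
  representation(audio = "numeric", reference = "numeric", rate = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@rate) != 1L || object@rate <= 0)
      msg <- c(msg, "rate must be a single positive number")
    if (length(object@audio) != length(object@reference))
      msg <- c(msg, "audio and reference tracks must have equal length")
    if (length(object@audio) && max(abs(object@audio)) > 1 + 1e-9)
      msg <- c(msg, "audio samples must lie in [-1, 1] (no clipping)")
    if (length(object@reference) && max(abs(object@reference)) > 1 + 1e-9)
      msg <- c(msg, "reference samples must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
  })

#' StimulusProtocol: timed stimulus events
#'
#' An ordered table of stimulus events: transient burst onsets/offsets, AM
#' segment boundaries (with their modulation frequency) and silence starts.
#' Protocols are produced by the stimulus builders and recovered from
#' recorded reference tracks by [detectReferenceEvents()].
#'
#' @slot events data.frame with columns \code{kind} (character),
#'   \code{time_s} (numeric, nondecreasing), \code{freq_hz} (numeric, NA
#'   except for AM segment events).
#' @export
setClass("StimulusProtocol",
  representation(events = "data.frame"),
  validity = function(object) {
    ev <- object@events
    msg <- character()
    need <- c("kind", "time_s", "freq_hz")
    if (!all(need %in% names(ev)))
      return(sprintf("events must have columns %s", paste(need, collapse = ", ")))
    if (nrow(ev)) {
      if (!all(ev$kind %in% EVENT_KINDS))
        msg <- c(msg, sprintf("unknown event kind(s): %s",
                              paste(setdiff(ev$kind, EVENT_KINDS), collapse = ", ")))
      if (is.unsorted(ev$time_s))
        msg <- c(msg, "event times must be nondecreasing")
      am <- ev$kind %in% c("am_segment_start", "am_segment_end")
      if (any(am & !is.finite(ev$freq_hz)))
        msg <- c(msg, "AM segment events must carry freq_hz")
      if (any(!am & is.finite(ev$freq_hz)))
        msg <- c(msg, "freq_hz must be NA for non-AM events")
      if (sum(ev$kind == "am_segment_start") != sum(ev$kind == "am_segment_end"))
        msg <- c(msg, "every am_segment_start needs a matching am_segment_end")
    }
    if (length(msg)) msg else TRUE
  })

#' RecordingSession: a two-channel LFP recording
#'
#' Continuous neural LFP (µV) plus the simultaneously recorded reference
#' sync track, the common sampling rate, the stimulus protocol, and free-form
#' provenance metadata (strain/drug labels carried as tags only).
#'
#' @slot neural numeric, LFP samples in µV.
#' @slot reference numeric, reference-track samples.
#' @slot rate numeric(1), sampling rate in Hz (10 or 12 kHz in the
#'   emulated acquisition protocols).
#' @slot protocol a \linkS4class{StimulusProtocol}.
#' @slot meta list of provenance tags.
#' @export
setClass("RecordingSession",
  representation(neural = "numeric", reference = "numeric", rate = "numeric",
                 protocol = "StimulusProtocol", meta = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@rate) != 1L || object@rate <= 0)
      msg <- c(msg, "rate must be a single positive number")
    if (length(object@neural) != length(object@reference))
      msg <- c(msg, "neural and reference tracks must have equal length")
    ev <- object@protocol@events
    dur <- length(object@neural) / object@rate
    if (nrow(ev) && (min(ev$time_s) < -1e-9 || max(ev$time_s) > dur + 1e-9))
      msg <- c(msg, "protocol event times must lie within [0, duration]")
    if (length(msg)) msg else TRUE
  })

#' SpectralEstimate: a one-sided Welch power spectral density
#'
#' @slot freqs numeric frequency grid in Hz, spanning [0, rate/2].
#' @slot psd numeric, nonnegative density (input-units^2/Hz) per bin.
#' @slot params list: window_s, overlap, taper, rate_hz, n_segments.
#' @export
setClass("SpectralEstimate",
  representation(freqs = "numeric", psd = "numeric", params = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@freqs) != length(object@psd))
      msg <- c(msg, "freqs and psd must have equal length")
    if (any(object@psd < 0))
      msg <- c(msg, "psd must be nonnegative")
    if (is.unsorted(object@freqs))
      msg <- c(msg, "freqs must be increasing")
    if (length(msg)) msg else TRUE
  })

#' CoherenceEstimate: magnitude-squared coherence on a frequency grid
#'
#' @slot freqs numeric frequency grid in Hz.
#' @slot msc numeric in [0, 1] per bin.
#' @slot nSegments integer, number of averaged segments (>= 2).
#' @slot params list: window_s, overlap, taper, rate_hz.
#' @export
setClass("CoherenceEstimate",
  representation(freqs = "numeric", msc = "numeric", nSegments = "integer",
                 params = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@freqs) != length(object@msc))
      msg <- c(msg, "freqs and msc must have equal length")
    if (any(object@msc < -1e-12 | object@msc > 1 + 1e-12))
      msg <- c(msg, "msc must lie in [0, 1]")
    if (object@nSegments < 1L)
      msg <- c(msg, "nSegments must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' EpochSet: peri-onset trial matrix
#'
#' Trials (rows) by time (columns) matrix of LFP segments extracted around
#' stimulus onsets, with the time axis in ms relative to onset.
#'
#' @slot trials numeric matrix, trial x time, µV.
#' @slot timeMs numeric, time axis in ms relative to onset.
#' @slot rate numeric(1), sampling rate in Hz.
#' @export
setClass("EpochSet",
  representation(trials = "matrix", timeMs = "numeric", rate = "numeric"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@trials) != length(object@timeMs))
      msg <- c(msg, "time axis length must equal trial column count")
    if (length(object@rate) != 1L || object@rate <= 0)
      msg <- c(msg, "rate must be a single positive number")
    if (length(msg)) msg else TRUE
  })

## -- accessors ---------------------------------------------------------------

#' @rdname sampleRate
#' @export
setMethod("sampleRate", "StereoStimulus", function(x) x@rate)
#' @rdname sampleRate
#' @export
setMethod("sampleRate", "RecordingSession", function(x) x@rate)
#' @rdname sampleRate
#' @export
setMethod("sampleRate", "EpochSet", function(x) x@rate)

#' @rdname signalDuration
#' @export
setMethod("signalDuration", "StereoStimulus",
          function(x) length(x@audio) / x@rate)
#' @rdname signalDuration
#' @export
setMethod("signalDuration", "RecordingSession",
          function(x) length(x@neural) / x@rate)

#' @rdname audioTrack
#' @export
setMethod("audioTrack", "StereoStimulus", function(x) x@audio)

#' @rdname referenceTrack
#' @export
setMethod("referenceTrack", "StereoStimulus", function(x) x@reference)
#' @rdname referenceTrack
#' @export
setMethod("referenceTrack", "RecordingSession", function(x) x@reference)

#' @rdname neuralTrack
#' @export
setMethod("neuralTrack", "RecordingSession", function(x) x@neural)

#' @rdname protocolEvents
#' @export
setMethod("protocolEvents", "StimulusProtocol", function(x) x@events)
#' @rdname protocolEvents
#' @export
setMethod("protocolEvents", "RecordingSession", function(x) x@protocol@events)

#' @rdname frequencies
#' @export
setMethod("frequencies", "SpectralEstimate", function(x) x@freqs)
#' @rdname frequencies
#' @export
setMethod("frequencies", "CoherenceEstimate", function(x) x@freqs)

#' @rdname psdValues
#' @export
setMethod("psdValues", "SpectralEstimate", function(x) x@psd)

#' @rdname mscValues
#' @export
setMethod("mscValues", "CoherenceEstimate", function(x) x@msc)

#' @rdname nTrials
#' @export
setMethod("nTrials", "EpochSet", function(x) nrow(x@trials))

#' Epoch time axis (ms relative to onset)
#'
#' @param x an \linkS4class{EpochSet}.
#' @return numeric vector of per-sample times in ms.
#' @export
epochTimesMs <- function(x) {
  stopifnot(is(x, "EpochSet"))
  x@timeMs
}

#' Epoch trial matrix
#'
#' @param x an \linkS4class{EpochSet}.
#' @return numeric matrix, trial x time.
#' @export
epochMatrix <- function(x) {
  stopifnot(is(x, "EpochSet"))
  x@trials
}

#' Session protocol accessor
#'
#' @param x a \linkS4class{RecordingSession}.
#' @return the session's \linkS4class{StimulusProtocol}.
#' @export
sessionProtocol <- function(x) {
  stopifnot(is(x, "RecordingSession"))
  x@protocol
}

#' Session metadata accessor
#'
#' @param x a \linkS4class{RecordingSession}.
#' @return list of provenance tags.
#' @export
sessionMeta <- function(x) {
  stopifnot(is(x, "RecordingSession"))
  x@meta
}

#' Construct a stimulus protocol from an event table
#'
#' @param events data.frame with columns \code{kind}, \code{time_s} and
#'   optionally \code{freq_hz} (NA where absent).
#' @return a \linkS4class{StimulusProtocol}.
#' @export
StimulusProtocol <- function(events = data.frame(kind = character(),
                                                 time_s = numeric(),
                                                 freq_hz = numeric())) {
  if (!"freq_hz" %in% names(events)) events$freq_hz <- NA_real_
  events <- events[order(events$time_s), c("kind", "time_s", "freq_hz")]
  rownames(events) <- NULL
  new("StimulusProtocol", events = events)
}

#' Burst onset times of a protocol
#'
#' @param protocol a \linkS4class{StimulusProtocol}.
#' @return numeric vector of burst onset times in seconds.
#' @export
burstOnsets <- function(protocol) {
  ev <- protocolEvents(protocol)
  ev$time_s[ev$kind == "burst_onset"]
}

#' AM segments of a protocol
#'
#' @param protocol a \linkS4class{StimulusProtocol}.
#' @return data.frame with columns \code{start_s}, \code{end_s},
#'   \code{freq_hz}, one row per AM segment.
#' @export
amSegments <- function(protocol) {
  ev <- protocolEvents(protocol)
  st <- ev[ev$kind == "am_segment_start", ]
  en <- ev[ev$kind == "am_segment_end", ]
  stopifnot(nrow(st) == nrow(en))
  data.frame(start_s = st$time_s, end_s = en$time_s, freq_hz = st$freq_hz)
}

## -- show methods ------------------------------------------------------------

setMethod("show", "StereoStimulus", function(object) {
  cat(sprintf("StereoStimulus: %.3f s at %g Hz (%d samples/channel)\n",
              signalDuration(object), object@rate, length(object@audio)))
})

setMethod("show", "StimulusProtocol", function(object) {
  ev <- object@events
  cat(sprintf("StimulusProtocol: %d events (%d burst onsets, %d AM segments)\n",
              nrow(ev), sum(ev$kind == "burst_onset"),
              sum(ev$kind == "am_segment_start")))
})

setMethod("show", "RecordingSession", function(object) {
  cat(sprintf("RecordingSession: %.1f s at %g Hz; %d protocol events\n",
              signalDuration(object), object@rate, nrow(object@protocol@events)))
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), unlist(lapply(object@meta, format)),
                         sep = "=", collapse = ", "), "\n")
})

setMethod("show", "SpectralEstimate", function(object) {
  cat(sprintf("SpectralEstimate: %d bins, %.3g-%.4g Hz (df = %.4g Hz, %d segments)\n",
              length(object@freqs), min(object@freqs), max(object@freqs),
              if (length(object@freqs) > 1) diff(object@freqs[1:2]) else NA,
              object@params$n_segments))
})

setMethod("show", "CoherenceEstimate", function(object) {
  cat(sprintf("CoherenceEstimate: %d bins, %d segments (window %.3g s, overlap %g%%)\n",
              length(object@freqs), object@nSegments,
              object@params$window_s, 100 * object@params$overlap))
})

setMethod("show", "EpochSet", function(object) {
  cat(sprintf("EpochSet: %d trials x %d samples (%g to %g ms at %g Hz)\n",
              nrow(object@trials), ncol(object@trials),
              min(object@timeMs), max(object@timeMs), object@rate))
})
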