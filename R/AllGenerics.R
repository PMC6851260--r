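#' @import methods
NULL

#' Sample rate of a signal object
#'
#' @param x a \linkS4class{StereoStimulus}, \linkS4class{RecordingSession},
#'   or \linkS4class{EpochSet}.
#' @return sampling rate in Hz.
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' Duration of a signal object in seconds
#'
#' @param x a signal-bearing object.
#' @return duration in seconds.
#' @export
setGeneric("signalDuration", function(x) standardGeneric("signalDuration"))

#' Audio track accessor
#'
#' @param x a \linkS4class{StereoStimulus}.
#' @return numeric vector of audio samples in [-1, 1].
#' @export
setGeneric("audioTrack", function(x) standardGeneric("audioTrack"))

#' Reference (sync) track accessor
#'
#' @param x a \linkS4class{StereoStimulus} or \linkS4class{RecordingSession}.
#' @return numeric vector of reference samples.
#' @export
setGeneric("referenceTrack", function(x) standardGeneric("referenceTrack"))

#' Neural track accessor
#'
#' @param x a \linkS4class{RecordingSession}.
#' @return numeric vector of neural samples (µV).
#' @export
setGeneric("neuralTrack", function(x) standardGeneric("neuralTrack"))

#' Protocol events accessor
#'
#' @param x a \linkS4class{StimulusProtocol} or \linkS4class{RecordingSession}.
#' @return data.frame with columns \code{kind}, \code{time_s}, \code{freq_hz}.
#' @export
setGeneric("protocolEvents", function(x) standardGeneric("protocolEvents"))

#' Frequency grid accessor
#'
#' @param x a \linkS4class{SpectralEstimate} or \linkS4class{CoherenceEstimate}.
#' @return numeric vector of frequencies in Hz.
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' Power spectral density values
#'
#' @param x a \linkS4class{SpectralEstimate}.
#' @return numeric vector, input-units^2/Hz per frequency bin.
#' @export
setGeneric("psdValues", function(x) standardGeneric("psdValues"))

#' Magnitude-squared coherence values
#'
#' @param x a \linkS4class{CoherenceEstimate}.
#' @return numeric vector in [0, 1] per frequency bin.
#' @export
setGeneric("mscValues", function(x) standardGeneric("mscValues"))

#' Number of trials in an epoch set
#'
#' @param x an \linkS4class{EpochSet}.
#' @return integer trial count.
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
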