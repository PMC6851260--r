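# Session serialization as a WAV-pair + JSON sidecar: both channels go into
# one stereo WAV (neural in channel 1, reference in channel 2), each scaled
# to [-1, 1]; the scale factors, rate, protocol and metadata live in JSON.

#' Write a recording session to disk
#'
#' Creates \code{<base>.wav} (16-bit stereo: scaled neural + reference) and
#' \code{<base>.json} (scale factors in µV per full-scale unit, rate,
#' protocol events, metadata).
#'
#' @param session a \linkS4class{RecordingSession}.
#' @param base output path without extension.
#' @return \code{base}, invisibly.
#' @export
writeSession <- function(session, base) {
  neu <- neuralTrack(session)
  ref <- referenceTrack(session)
  neu_scale <- max(abs(neu), 1e-12)
  ref_scale <- max(abs(ref), 1e-12)
  writeStereoWav(new("StereoStimulus", audio = neu / neu_scale,
                     reference = ref / ref_scale,
                     rate = sampleRate(session)),
                 paste0(base, ".wav"))
  jsonlite::write_json(
    list(rate_hz = sampleRate(session), neural_scale_uV = neu_scale,
         reference_scale = ref_scale,
         protocol = protocolEvents(session), meta = sessionMeta(session)),
    paste0(base, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(base)
}

#' Read a recording session written by [writeSession()]
#'
#' @param base path without extension.
#' @return a \linkS4class{RecordingSession}.
#' @export
readSession <- function(base) {
  meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  wav <- readStereoWav(paste0(base, ".wav"))
  ev <- as.data.frame(meta$protocol)
  if (nrow(ev)) ev$freq_hz <- as.numeric(ev$freq_hz)
  new("RecordingSession",
      neural = audioTrack(wav) * meta$neural_scale_uV,
      reference = referenceTrack(wav) * meta$reference_scale,
      rate = meta$rate_hz,
      protocol = if (nrow(ev)) StimulusProtocol(ev) else StimulusProtocol(),
      meta = if (length(meta$meta)) as.list(meta$meta) else list())
}
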