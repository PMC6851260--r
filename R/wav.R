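# Minimal RIFF/WAVE PCM 16-bit stereo I/O. Audio in channel 1, reference
# sync track in channel 2, matching how the stimulus files are laid out.

#' Write a StereoStimulus to a 16-bit PCM stereo WAV file
#'
#' Channel 1 carries the audio, channel 2 the reference sync track. Samples
#' must already lie in [-1, 1]; they are quantized to 16-bit signed PCM.
#'
#' @param stimulus a \linkS4class{StereoStimulus}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeStereoWav <- function(stimulus, path) {
  stopifnot(is(stimulus, "StereoStimulus"))
  audio <- stimulus@audio
  ref <- stimulus@reference
  if (length(audio) && max(abs(audio), abs(ref)) > 1 + 1e-12)
    stop("samples must lie in [-1, 1] before writing")
  n <- length(audio)
  rate <- as.integer(round(stimulus@rate))
  # interleave and quantize; clamp +1.0 to the top 16-bit code
  inter <- numeric(2L * n)
  inter[seq(1L, by = 2L, length.out = n)] <- audio
  inter[seq(2L, by = 2L, length.out = n)] <- ref
  pcm <- as.integer(pmin(pmax(round(inter * 32768), -32768), 32767))

  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(2L, con, size = 2, endian = "little")           # channels
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(rate * 4L, con, size = 4, endian = "little")    # byte rate
  writeBin(4L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM stereo WAV file as a StereoStimulus
#'
#' @param path path to a 2-channel 16-bit PCM WAV file.
#' @return a \linkS4class{StereoStimulus}; samples rescaled to [-1, 1].
#' @export
readStereoWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)

  fmt <- NULL
  pcm <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        format = readBin(con, integer(), size = 2, endian = "little"),
        channels = readBin(con, integer(), size = 2, endian = "little"),
        rate = readBin(con, integer(), size = 4, endian = "little"),
        byte_rate = readBin(con, integer(), size = 4, endian = "little"),
        block_align = readBin(con, integer(), size = 2, endian = "little"),
        bits = readBin(con, integer(), size = 2, endian = "little"))
      if (sz > 16L) readBin(con, raw(), n = sz - 16L)
    } else if (id == "data") {
      pcm <- readBin(con, integer(), n = sz %/% 2L, size = 2,
                     endian = "little", signed = TRUE)
    } else {
      readBin(con, raw(), n = sz + sz %% 2L)
    }
    if (!is.null(fmt) && !is.null(pcm)) break
  }
  if (is.null(fmt) || is.null(pcm)) stop("malformed WAV file: ", path)
  if (fmt$format != 1L) stop("unsupported WAV encoding (need PCM): ", path)
  if (fmt$bits != 16L) stop("unsupported bit depth (need 16-bit): ", path)
  if (fmt$channels != 2L)
    stop("need a 2-channel WAV (audio + reference), got ", fmt$channels,
         " channel(s): ", path)
  n <- length(pcm) %/% 2L
  new("StereoStimulus",
      audio = pcm[seq(1L, by = 2L, length.out = n)] / 32768,
      reference = pcm[seq(2L, by = 2L, length.out = n)] / 32768,
      rate = as.numeric(fmt$rate))
}
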