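# Spectral core: Welch PSD, magnitude-squared coherence, STFT spectrogram,
# and band/narrowband power. Hamming taper throughout; one-sided density
# normalization so the PSD integral approximates the series variance.

# segment start indices for Welch-style framing; final partial frame dropped
welchStarts <- function(n, seg_n, overlap) {
  hop <- max(1L, seg_n - floor(overlap * seg_n))
  if (n < seg_n) return(integer())
  seq.int(1L, n - seg_n + 1L, by = hop)
}

# per-segment one-sided scaled FFTs: matrix bins x segments
segmentFFT <- function(x, starts, seg_n) {
  w <- signal::hamming(seg_n)
  nb <- seg_n %/% 2L + 1L
  out <- matrix(0 + 0i, nb, length(starts))
  for (j in seq_along(starts)) {
    seg <- x[starts[j]:(starts[j] + seg_n - 1L)] * w
    out[, j] <- stats::fft(seg)[seq_len(nb)]
  }
  out
}

# one-sided doubling factors (DC and, for even seg_n, Nyquist not doubled)
onesidedScale <- function(seg_n) {
  nb <- seg_n %/% 2L + 1L
  sc <- rep(2, nb)
  sc[1] <- 1
  if (seg_n %% 2L == 0L) sc[nb] <- 1
  sc
}

#' Welch power spectral density
#'
#' Averaged Hamming-tapered periodograms over (possibly overlapping) segments
#' of \code{window_s} seconds; the final partial segment is discarded. The
#' one-sided density is normalized so its integral over frequency
#' approximates the series variance (Parseval).
#'
#' @param x numeric sample series.
#' @param rate_hz sampling rate, Hz.
#' @param window_s segment length, s (default 1).
#' @param overlap overlap fraction in [0, 1) (default 0, no overlap).
#' @return a \linkS4class{SpectralEstimate}; bin spacing \code{1/window_s}.
#' @export
welchPsd <- function(x, rate_hz, window_s = 1.0, overlap = 0.0) {
  seg_n <- round(window_s * rate_hz)
  if (length(x) < seg_n)
    stop("series shorter than one window (", seg_n, " samples)")
  starts <- welchStarts(length(x), seg_n, overlap)
  X <- segmentFFT(x, starts, seg_n)
  U <- sum(signal::hamming(seg_n)^2)
  psd <- rowMeans(Mod(X)^2) * onesidedScale(seg_n) / (rate_hz * U)
  new("SpectralEstimate",
      freqs = (seq_len(nrow(X)) - 1) * rate_hz / seg_n,
      psd = psd,
      params = list(window_s = window_s, overlap = overlap,
                    taper = "hamming", rate_hz = rate_hz,
                    n_segments = length(starts)))
}

#' Magnitude-squared coherence
#'
#' Segment-averaged cross- and auto-spectra with a Hamming taper:
#' \eqn{C_{xy}(f) = |P_{xy}|^2 / (P_{xx} P_{yy})} per frequency bin.
#' Requires at least two segments (single-segment coherence is identically 1
#' and is rejected). Bins where either auto-spectrum is zero get msc 0.
#'
#' @param x,y equally long numeric sample series.
#' @param rate_hz sampling rate, Hz.
#' @param window_s segment length, s.
#' @param overlap overlap fraction in [0, 1).
#' @return a \linkS4class{CoherenceEstimate}.
#' @export
msCoherence <- function(x, y, rate_hz, window_s = 1.34, overlap = 0.5) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  seg_n <- round(window_s * rate_hz)
  starts <- welchStarts(length(x), seg_n, overlap)
  if (length(starts) < 2L)
    stop("need at least 2 segments for coherence (got ", length(starts), ")")
  X <- segmentFFT(x, starts, seg_n)
  Y <- segmentFFT(y, starts, seg_n)
  Pxx <- rowSums(Mod(X)^2)
  Pyy <- rowSums(Mod(Y)^2)
  Pxy <- rowSums(X * Conj(Y))
  den <- Pxx * Pyy
  msc <- ifelse(den > 0, Mod(Pxy)^2 / pmax(den, .Machine$double.xmin), 0)
  msc <- pmin(msc, 1)  # guard rounding at perfectly coherent bins
  new("CoherenceEstimate",
      freqs = (seq_len(nrow(X)) - 1) * rate_hz / seg_n,
      msc = as.numeric(msc), nSegments = length(starts),
      params = list(window_s = window_s, overlap = overlap,
                    taper = "hamming", rate_hz = rate_hz))
}

#' Short-time Fourier transform spectrogram
#'
#' Frame-by-frame Hamming-tapered magnitude-squared spectra with the same
#' one-sided density scaling as [welchPsd()]; bin spacing
#' \code{rate_hz/nfft} (0.366 Hz for the default 32768 points at 12 kHz).
#'
#' @param x numeric sample series, at least \code{nfft} samples.
#' @param rate_hz sampling rate, Hz.
#' @param nfft frame length in points (default 32768).
#' @param hop hop between frame starts in samples (default \code{nfft/2},
#'   50\% overlap).
#' @return list of class \code{icassr_stft}: \code{freqs} (Hz), \code{times}
#'   (frame centers, s), \code{power} (bins x frames, units^2/Hz),
#'   \code{params}.
#' @export
stftSpectrogram <- function(x, rate_hz, nfft = 32768, hop = nfft %/% 2) {
  if (length(x) < nfft)
    stop("series shorter than one frame (", nfft, " samples)")
  starts <- seq.int(1L, length(x) - nfft + 1L, by = hop)
  X <- segmentFFT(x, starts, nfft)
  U <- sum(signal::hamming(nfft)^2)
  power <- Mod(X)^2 * onesidedScale(nfft) / (rate_hz * U)
  structure(list(freqs = (seq_len(nrow(X)) - 1) * rate_hz / nfft,
                 times = (starts - 1 + nfft / 2) / rate_hz,
                 power = power,
                 params = list(nfft = nfft, hop = hop, taper = "hamming",
                               rate_hz = rate_hz, n_frames = length(starts))),
            class = "icassr_stft")
}

#' Canonical frequency band definitions
#'
#' theta 4-12 Hz, beta 12-30 Hz, gamma 30-80 Hz.
#'
#' @return data.frame with columns \code{name}, \code{lo_hz}, \code{hi_hz}.
#' @export
bandDefinitions <- function() {
  data.frame(name = c("theta", "beta", "gamma"),
             lo_hz = c(4, 12, 30), hi_hz = c(12, 30, 80))
}

#' Band power from a spectral estimate
#'
#' Integrates the PSD over the half-open band [lo, hi): bins with
#' \code{lo <= f < hi} contribute \code{psd * df}, so adjacent bands never
#' double-count a bin.
#'
#' @param est a \linkS4class{SpectralEstimate}.
#' @param lo_hz,hi_hz band edges, Hz (lo < hi, within the estimate range).
#' @return band power in input-units^2.
#' @export
bandPower <- function(est, lo_hz, hi_hz) {
  f <- frequencies(est)
  if (lo_hz >= hi_hz) stop("empty band: lo_hz must be below hi_hz")
  if (lo_hz < min(f) - 1e-9 || hi_hz > max(f) + 1e-9)
    stop("band outside the estimate's frequency range")
  df <- f[2] - f[1]
  sel <- f >= lo_hz - 1e-9 & f < hi_hz - 1e-9
  sum(psdValues(est)[sel]) * df
}

#' Narrowband power around a target frequency
#'
#' Integrates the PSD over the closed interval [f0 - half_bw, f0 + half_bw],
#' the convention used for power at a stimulation modulation frequency
#' (e.g. f0 +/- 1.0 Hz, or 53.71 +/- 0.6 Hz).
#'
#' @param est a \linkS4class{SpectralEstimate}.
#' @param f0_hz center frequency, Hz.
#' @param half_bw_hz half bandwidth, Hz.
#' @return narrowband power in input-units^2.
#' @export
narrowbandPower <- function(est, f0_hz, half_bw_hz = 1.0) {
  f <- frequencies(est)
  if (f0_hz - half_bw_hz < min(f) - 1e-9 || f0_hz + half_bw_hz > max(f) + 1e-9)
    stop("narrowband interval outside the estimate's frequency range")
  df <- f[2] - f[1]
  sel <- f >= f0_hz - half_bw_hz - 1e-9 & f <= f0_hz + half_bw_hz + 1e-9
  sum(psdValues(est)[sel]) * df
}

# mean PSD in a closed band across STFT frames (units^2, integrated over f)
stftBandMean <- function(stft, f0_hz, half_bw_hz) {
  f <- stft$freqs
  df <- f[2] - f[1]
  sel <- f >= f0_hz - half_bw_hz - 1e-9 & f <= f0_hz + half_bw_hz + 1e-9
  mean(colSums(stft$power[sel, , drop = FALSE])) * df
}

#' Write a spectral or coherence estimate to CSV
#'
#' Two columns (freq_hz, value); parameters go to a JSON sidecar with the
#' same basename.
#'
#' @param est a \linkS4class{SpectralEstimate} or
#'   \linkS4class{CoherenceEstimate}.
#' @param path CSV output path.
#' @return the path, invisibly.
#' @export
writeEstimateCsv <- function(est, path) {
  value <- if (is(est, "SpectralEstimate")) psdValues(est) else mscValues(est)
  utils::write.csv(data.frame(freq_hz = frequencies(est), value = value),
                   path, row.names = FALSE)
  jsonlite::write_json(est@params, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
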