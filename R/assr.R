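# Steady-state (ASSR) pipeline: minimum-variance analysis-window election,
# narrowband power and coherence per modulation frequency, CS-locked
# baseline-normalized power, and silent-period band-power profiling.

#' Analysis configuration presets
#'
#' Two presets ship, matching the two recording protocols this package
#' emulates: \code{"sound-processing"} (Welch/coherence with 1-s windows, no
#' overlap, narrowband f0 +/- 1.0 Hz, modulation frequencies 30/90/150/210
#' Hz) and \code{"afc"} (coherence with 1.34-s windows and 50\% overlap,
#' narrowband 53.71 +/- 0.6 Hz, 32768-point STFT for CS-normalized power).
#' Any field can be overridden.
#'
#' @param preset "sound-processing" or "afc".
#' @param ... overrides for individual fields: \code{window_dur_s},
#'   \code{hop_s}, \code{coh_window_s}, \code{coh_overlap},
#'   \code{psd_window_s}, \code{narrowband_half_bw_hz}, \code{stft_points},
#'   \code{bands}, \code{mod_freqs_hz}, \code{delay_correction_ms},
#'   \code{total_band_hz}, \code{ideal_reference}.
#' @return a list of class \code{AnalysisConfig}.
#' @export
analysisConfig <- function(preset = c("sound-processing", "afc"), ...) {
  preset <- match.arg(preset)
  cfg <- list(window_dur_s = 10, hop_s = 0.5, coh_window_s = 1.0,
              coh_overlap = 0.0, psd_window_s = 1.0,
              narrowband_half_bw_hz = 1.0, stft_points = 32768,
              bands = bandDefinitions(),
              mod_freqs_hz = c(30, 90, 150, 210),
              delay_correction_ms = 2.0,
              total_band_hz = c(1, NA),   # NA upper edge = Nyquist
              ideal_reference = FALSE, preset = preset)
  if (preset == "afc") {
    cfg$coh_window_s <- 1.34
    cfg$coh_overlap <- 0.5
    cfg$narrowband_half_bw_hz <- 0.6
    cfg$mod_freqs_hz <- 53.71
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown analysis config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$narrowband_half_bw_hz <= 0) stop("narrowband_half_bw_hz must be > 0")
  class(cfg) <- c("AnalysisConfig", "list")
  cfg
}

#' Elect the minimum-variance analysis window
#'
#' Scans candidate windows of \code{window_dur_s} seconds across a segment
#' at stride \code{hop_s} and returns the start of the one with the lowest
#' sample variance — the automatic election used to avoid movement
#' artifacts. Ties go to the earliest window.
#'
#' @param x numeric sample series.
#' @param rate_hz sampling rate, Hz.
#' @param segment numeric c(start_s, end_s); must be at least
#'   \code{window_dur_s} long.
#' @param window_dur_s analysis-window length, s (default 10).
#' @param hop_s candidate stride, s (default 0.5; set \code{1/rate_hz} for an
#'   exhaustive per-sample scan).
#' @return elected window start time, s.
#' @export
selectMinVarianceWindow <- function(x, rate_hz, segment, window_dur_s = 10,
                                    hop_s = 0.5) {
  seg_i0 <- round(segment[1] * rate_hz) + 1L
  seg_i1 <- min(length(x), round(segment[2] * rate_hz))
  win_n <- round(window_dur_s * rate_hz)
  if (seg_i1 - seg_i0 + 1L < win_n)
    stop("segment shorter than the analysis window")
  hop_n <- max(1L, round(hop_s * rate_hz))
  starts <- seq.int(seg_i0, seg_i1 - win_n + 1L, by = hop_n)
  # O(1) per-candidate variance via cumulative sums
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  s1 <- cs[starts + win_n] - cs[starts]
  s2 <- cs2[starts + win_n] - cs2[starts]
  v <- (s2 - s1^2 / win_n) / (win_n - 1)
  (starts[which.min(v)] - 1L) / rate_hz
}

# slice [start_s, start_s + dur_s) out of a series
sliceSeconds <- function(x, rate_hz, start_s, dur_s) {
  i0 <- round(start_s * rate_hz) + 1L
  x[i0:(i0 + round(dur_s * rate_hz) - 1L)]
}

#' Steady-state metrics of one AM segment
#'
#' Elects the minimum-variance window inside the segment, then computes the
#' narrowband LFP power at the modulation frequency (Welch PSD,
#' \code{psd_window_s} windows) and the magnitude-squared coherence between
#' the neural track and the reference (averaged over f_m +/-
#' \code{narrowband_half_bw_hz}). If the protocol has a silence immediately
#' before the segment, the same-length minimum-variance baseline window
#' yields a baseline-normalized power; otherwise normalized power is NA.
#'
#' @param session a \linkS4class{RecordingSession}.
#' @param segment one row of [amSegments()] (list/data.frame with
#'   \code{start_s}, \code{end_s}, \code{freq_hz}).
#' @param cfg an \code{\link{analysisConfig}}.
#' @param segment_id identifier carried into the result row.
#' @return one-row data.frame: segment_id, mod_freq_hz, window_start_s,
#'   raw_power, normalized_power, coherence_at_fm.
#' @export
assrSegmentMetrics <- function(session, segment, cfg = analysisConfig(),
                               segment_id = 1L) {
  rate <- sampleRate(session)
  fm <- segment$freq_hz
  win0 <- selectMinVarianceWindow(neuralTrack(session), rate,
                                  c(segment$start_s, segment$end_s),
                                  cfg$window_dur_s, cfg$hop_s)
  neu <- sliceSeconds(neuralTrack(session), rate, win0, cfg$window_dur_s)
  ref <- if (cfg$ideal_reference) {
    sin(2 * pi * fm * (seq_along(neu) - 1) / rate)
  } else {
    sliceSeconds(referenceTrack(session), rate, win0, cfg$window_dur_s)
  }
  if (max(abs(ref)) == 0)
    stop("reference track is silent during the elected window")

  psd <- welchPsd(neu, rate, cfg$psd_window_s, 0)
  raw_power <- narrowbandPower(psd, fm, cfg$narrowband_half_bw_hz)

  coh <- msCoherence(neu, ref, rate, cfg$coh_window_s, cfg$coh_overlap)
  sel <- frequencies(coh) >= fm - cfg$narrowband_half_bw_hz - 1e-9 &
    frequencies(coh) <= fm + cfg$narrowband_half_bw_hz + 1e-9
  coherence_at_fm <- mean(mscValues(coh)[sel])

  # baseline-normalized power when a pre-segment silence exists
  normalized_power <- NA_real_
  ev <- protocolEvents(session)
  sil <- ev$time_s[ev$kind == "silence_start" & ev$time_s < segment$start_s]
  if (length(sil)) {
    sil0 <- max(sil)
    if (segment$start_s - sil0 >= cfg$window_dur_s) {
      b0 <- selectMinVarianceWindow(neuralTrack(session), rate,
                                    c(sil0, segment$start_s),
                                    cfg$window_dur_s, cfg$hop_s)
      bpsd <- welchPsd(sliceSeconds(neuralTrack(session), rate, b0,
                                    cfg$window_dur_s),
                       rate, cfg$psd_window_s, 0)
      bpow <- narrowbandPower(bpsd, fm, cfg$narrowband_half_bw_hz)
      if (bpow > 0) normalized_power <- raw_power / bpow
    }
  }
  data.frame(segment_id = segment_id, mod_freq_hz = fm,
             window_start_s = win0, raw_power = raw_power,
             normalized_power = normalized_power,
             coherence_at_fm = coherence_at_fm)
}

#' Steady-state metrics for every AM segment of a session
#'
#' @param session a \linkS4class{RecordingSession}.
#' @param cfg an \code{\link{analysisConfig}}.
#' @return data.frame, one row per AM segment (see [assrSegmentMetrics()]).
#' @export
analyzeAssr <- function(session, cfg = analysisConfig()) {
  segs <- amSegments(sessionProtocol(session))
  if (!nrow(segs)) stop("session protocol has no AM segments")
  do.call(rbind, lapply(seq_len(nrow(segs)), function(i)
    assrSegmentMetrics(session, segs[i, ], cfg, segment_id = i)))
}

#' Conditioned-stimulus baseline-normalized power
#'
#' For each CS presentation: mean STFT power in the modulation band
#' (f_m +/- \code{narrowband_half_bw_hz}) across frames within the CS,
#' divided by the same quantity over the \code{baseline_s} seconds
#' immediately preceding that CS. The session value is the arithmetic mean
#' across presentations.
#'
#' @param session a \linkS4class{RecordingSession} (nominal 12 kHz AFC
#'   recording).
#' @param cfg an \code{\link{analysisConfig}}, normally
#'   \code{analysisConfig("afc")}.
#' @param cs_events data.frame of CS intervals (default: the session
#'   protocol's AM segments).
#' @param baseline_s baseline length before each CS, s (default the CS
#'   duration).
#' @return list: \code{per_cs} (data.frame cs_id, start_s, cs_power,
#'   baseline_power, normalized_power) and \code{session_value} (mean
#'   normalized power).
#' @export
csNormalizedPower <- function(session, cfg = analysisConfig("afc"),
                              cs_events = amSegments(sessionProtocol(session)),
                              baseline_s = NULL) {
  if (!nrow(cs_events)) stop("no CS events")
  rate <- sampleRate(session)
  rows <- NULL
  for (i in seq_len(nrow(cs_events))) {
    cs0 <- cs_events$start_s[i]
    cs_dur <- cs_events$end_s[i] - cs_events$start_s[i]
    b_dur <- if (is.null(baseline_s)) cs_dur else baseline_s
    fm <- if ("freq_hz" %in% names(cs_events) &&
              is.finite(cs_events$freq_hz[i]))
      cs_events$freq_hz[i] else cfg$mod_freqs_hz[1]
    if (cs0 - b_dur < -1e-9)
      stop("CS ", i, " lacks ", b_dur, " s of pre-CS baseline")
    if (i > 1 && cs0 - b_dur < cs_events$end_s[i - 1] - 1e-9)
      stop("baseline of CS ", i, " overlaps the previous CS")
    cs_x <- sliceSeconds(neuralTrack(session), rate, cs0, cs_dur)
    bl_x <- sliceSeconds(neuralTrack(session), rate, cs0 - b_dur, b_dur)
    cs_p <- stftBandMean(stftSpectrogram(cs_x, rate, cfg$stft_points),
                         fm, cfg$narrowband_half_bw_hz)
    bl_p <- stftBandMean(stftSpectrogram(bl_x, rate, cfg$stft_points),
                         fm, cfg$narrowband_half_bw_hz)
    rows <- rbind(rows, data.frame(cs_id = i, start_s = cs0, cs_power = cs_p,
                                   baseline_power = bl_p,
                                   normalized_power = cs_p / bl_p))
  }
  list(per_cs = rows, session_value = mean(rows$normalized_power))
}

#' Baseline (silent-period) band-power profile
#'
#' Elects the minimum-variance window inside a silent segment and computes
#' total power over the whole spectrum (default 1 Hz to Nyquist, the
#' hardware passband floor) plus each configured band power.
#'
#' @param session a \linkS4class{RecordingSession}.
#' @param silent_segment numeric c(start_s, end_s) of the silent period.
#' @param cfg an \code{\link{analysisConfig}}.
#' @return one-row data.frame: window_start_s, total_power, then one column
#'   per band (theta/beta/gamma by default), units^2.
#' @export
baselineProfile <- function(session, silent_segment, cfg = analysisConfig()) {
  rate <- sampleRate(session)
  win0 <- selectMinVarianceWindow(neuralTrack(session), rate, silent_segment,
                                  cfg$window_dur_s, cfg$hop_s)
  psd <- welchPsd(sliceSeconds(neuralTrack(session), rate, win0,
                               cfg$window_dur_s),
                  rate, cfg$psd_window_s, 0)
  hi <- if (is.na(cfg$total_band_hz[2])) max(frequencies(psd))
        else cfg$total_band_hz[2]
  out <- data.frame(window_start_s = win0,
                    total_power = bandPower(psd, cfg$total_band_hz[1], hi))
  for (i in seq_len(nrow(cfg$bands)))
    out[[cfg$bands$name[i]]] <- bandPower(psd, cfg$bands$lo_hz[i],
                                          cfg$bands$hi_hz[i])
  out
}

#' Tidy session report
#'
#' Binds per-analysis result tables into one long table with a stable
#' schema: session_id, analysis, segment_id, metric, value, plus any group
#' labels passed in \code{meta}.
#'
#' @param results named list of data.frames (names label the analysis, e.g.
#'   \code{assr}, \code{transient}, \code{baseline}, \code{afc}).
#' @param session_id session identifier.
#' @param meta named list of group labels to carry as columns.
#' @return data.frame in long format.
#' @export
sessionReport <- function(results, session_id = "session1", meta = list()) {
  if (!length(results)) stop("empty results list")
  if (is.null(names(results)) || any(!nzchar(names(results))))
    stop("results must be a named list")
  rows <- NULL
  for (an in names(results)) {
    df <- as.data.frame(results[[an]])
    seg <- if ("segment_id" %in% names(df)) df$segment_id else seq_len(nrow(df))
    for (col in setdiff(names(df), "segment_id")) {
      if (!is.numeric(df[[col]])) next
      rows <- rbind(rows, data.frame(session_id = session_id, analysis = an,
                                     segment_id = seg, metric = col,
                                     value = df[[col]]))
    }
  }
  for (nm in names(meta)) rows[[nm]] <- meta[[nm]]
  rownames(rows) <- NULL
  rows
}
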