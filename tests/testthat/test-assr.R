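test_that("minimum-variance election matches the exhaustive oracle", {
  rate <- 500
  # constant signal: tie broken to the segment start
  expect_equal(selectMinVarianceWindow(rep(1, 30 * rate), rate, c(0, 30), 10),
               0)

  # a 10x artifact burst at 12-14 s is excluded from the elected window
  set.seed(41)
  x <- rnorm(30 * rate)
  x[(12 * rate):(14 * rate)] <- x[(12 * rate):(14 * rate)] * 10
  w <- selectMinVarianceWindow(x, rate, c(0, 30), 10, 0.5)
  expect_true(w + 10 <= 12 || w >= 14)
  expect_equal(w, oracleMinVarWindow(x, rate, c(0, 30), 10, 0.5))

  # agreement with the naive scan on random segments
  for (r in 1:10) {
    set.seed(500 + r)
    xs <- rnorm(25 * rate) * (1 + 3 * sin(2 * pi * runif(1, 0.02, 0.1) *
                                            seq_len(25 * rate) / rate))
    expect_equal(selectMinVarianceWindow(xs, rate, c(0, 25), 10, 0.5),
                 oracleMinVarWindow(xs, rate, c(0, 25), 10, 0.5))
  }

  # near-exhaustive hop barely improves the elected variance on smooth signals
  set.seed(43)
  xs <- cumsum(rnorm(30 * rate)) / 50
  vOf <- function(w) stats::var(xs[(w * rate + 1):((w + 10) * rate)])
  v_coarse <- vOf(selectMinVarianceWindow(xs, rate, c(0, 30), 10, 0.5))
  v_fine <- vOf(selectMinVarianceWindow(xs, rate, c(0, 30), 10, 1 / rate))
  expect_lte(v_fine, v_coarse)
  expect_lt((v_coarse - v_fine) / v_fine, 0.01)

  expect_error(selectMinVarianceWindow(rnorm(rate), rate, c(0, 1), 10),
               "shorter")
})

test_that("ASSR segment metrics recover entrainment signatures end-to-end", {
  mkSession <- function(amp, jitter, seed, fm = 90) {
    prot <- StimulusProtocol(data.frame(
      kind = c("silence_start", "am_segment_start", "am_segment_end"),
      time_s = c(0, 10, 20), freq_hz = c(NA, fm, fm)))
    cfg <- syntheticConfig(rate_hz = 12000, duration_s = 20, noise_sigma_uV = 20,
                           entrain_amp_uV = amp, phase_jitter_sd_rad = jitter,
                           seed = seed)
    generateSession(prot, cfg)$session
  }

  # noiseless-entrainment limit: coherence ~ 1 at each modulation frequency
  for (fm in c(30, 90, 150, 210)) {
    prot <- StimulusProtocol(data.frame(
      kind = c("am_segment_start", "am_segment_end"),
      time_s = c(0, 10), freq_hz = fm))
    cfg <- syntheticConfig(rate_hz = 12000, duration_s = 10, noise_sigma_uV = 0,
                           band_oscillations = data.frame(center_hz = numeric(),
                                                          amplitude_uV = numeric()),
                           entrain_amp_uV = 10, phase_jitter_sd_rad = 0,
                           seed = 1)
    s <- generateSession(prot, cfg)$session
    res <- assrSegmentMetrics(s, amSegments(sessionProtocol(s))[1, ],
                              analysisConfig(mod_freqs_hz = fm))
    expect_gte(res$coherence_at_fm, 0.99)
  }

  # amplitude ladder with the noise floor well below the weakest signal:
  # raw narrowband power scales as amplitude^2
  mkQuiet <- function(amp, seed) {
    prot <- afcProtocol(1, 90, 10, 10)
    cfg <- syntheticConfig(rate_hz = 12000, duration_s = 20, noise_sigma_uV = 1,
                           entrain_amp_uV = amp, phase_jitter_sd_rad = 0,
                           seed = seed)
    generateSession(prot, cfg)$session
  }
  pows <- sapply(c(1, 2, 4), function(a)
    assrSegmentMetrics(mkQuiet(a, seed = 55),
                       amSegments(afcProtocol(1, 90, 10, 10))[1, ],
                       analysisConfig())$raw_power)
  expect_equal(pows[2] / pows[1], 4, tolerance = 0.1)
  expect_equal(pows[3] / pows[1], 16, tolerance = 0.1)

  # jitter ladder: median coherence decreasing where above the chance floor
  med <- sapply(c(0, 0.15, 0.5), function(j)
    stats::median(sapply(1:20, function(r)
      assrSegmentMetrics(mkSession(10, j, seed = 7000 + 1000 * j + r),
                         amSegments(afcProtocol(1, 90, 10, 10))[1, ],
                         analysisConfig())$coherence_at_fm)))
  expect_true(all(diff(med) < 0))
  expect_gt(med[1] - med[3], 0.2)
})

test_that("normalized power is a scale-free ratio and null-calibrated", {
  prot <- afcProtocol(n_cs = 1, cs_freq_hz = 53.7, cs_dur_s = 10,
                      baseline_s = 10)
  cfg <- syntheticConfig(rate_hz = 12000, duration_s = 20, entrain_amp_uV = 8,
                         phase_jitter_sd_rad = 0.1, seed = 61)
  s <- generateSession(prot, cfg)$session
  res <- assrSegmentMetrics(s, amSegments(sessionProtocol(s))[1, ],
                            analysisConfig("afc", mod_freqs_hz = 53.7))
  expect_gt(res$normalized_power, 1)

  # global amplitude rescaling leaves the ratio untouched
  s2 <- new("RecordingSession", neural = 3.7 * neuralTrack(s),
            reference = referenceTrack(s), rate = sampleRate(s),
            protocol = sessionProtocol(s), meta = list())
  res2 <- assrSegmentMetrics(s2, amSegments(sessionProtocol(s2))[1, ],
                             analysisConfig("afc", mod_freqs_hz = 53.7))
  expect_equal(res2$normalized_power, res$normalized_power, tolerance = 1e-9)
  expect_equal(res2$coherence_at_fm, res$coherence_at_fm, tolerance = 1e-9)
})

test_that("CS-normalized STFT power rises with entrainment and doubles per the square law", {
  mkAfc <- function(amp, seed) {
    prot <- afcProtocol(n_cs = 2, cs_dur_s = 10, baseline_s = 10)
    cfg <- syntheticConfig(rate_hz = 12000, duration_s = 40, noise_sigma_uV = 10,
                           entrain_amp_uV = amp, phase_jitter_sd_rad = 0,
                           seed = seed)
    generateSession(prot, cfg)$session
  }
  cfgA <- analysisConfig("afc", stft_points = 8192, mod_freqs_hz = 53.7)
  r1 <- csNormalizedPower(mkAfc(4, 71), cfgA)
  r2 <- csNormalizedPower(mkAfc(8, 71), cfgA)
  expect_gt(r1$session_value, 1)
  # doubling the amplitude quadruples the above-baseline excess
  expect_equal((r2$session_value - 1) / (r1$session_value - 1), 4,
               tolerance = 0.15)
  expect_equal(nrow(r1$per_cs), 2)

  # overlapping baseline is rejected
  bad <- amSegments(sessionProtocol(mkAfc(1, 72)))
  bad$start_s[2] <- bad$end_s[1] + 2
  expect_error(csNormalizedPower(mkAfc(1, 72), cfgA, cs_events = bad),
               "overlaps")
})

test_that("baseline profile splits power by band like a flat/peaked spectrum", {
  # white noise: band powers proportional to bandwidths 8:18:50
  prot <- StimulusProtocol(data.frame(kind = "silence_start", time_s = 0,
                                      freq_hz = NA_real_))
  # a 10-s window gives ~8% sampling error per band, so average 5 sessions
  bps <- lapply(1:5, function(s) {
    cfg <- syntheticConfig(rate_hz = 2000, duration_s = 15, noise_sigma_uV = 5,
                           spectral_exponent = 0,
                           band_oscillations = data.frame(center_hz = numeric(),
                                                          amplitude_uV = numeric()),
                           seed = 80 + s)
    baselineProfile(generateSession(prot, cfg)$session, c(0, 15),
                    analysisConfig())
  })
  bp <- do.call(rbind, bps)
  expect_equal(mean(bp$theta) / mean(bp$beta), 8 / 18,
               tolerance = 0.1 * 8 / 18)
  expect_equal(mean(bp$theta) / mean(bp$gamma), 8 / 50,
               tolerance = 0.1 * 8 / 50)
  expect_true(all(bp$theta + bp$beta + bp$gamma <= bp$total_power))

  # a pure 6-Hz oscillation lands almost entirely in theta
  cfg6 <- syntheticConfig(rate_hz = 2000, duration_s = 15, noise_sigma_uV = 0.01,
                          band_oscillations = data.frame(center_hz = 6,
                                                         amplitude_uV = 10),
                          seed = 82)
  s6 <- generateSession(prot, cfg6)$session
  bp6 <- baselineProfile(s6, c(0, 15), analysisConfig())
  in4to80 <- bp6$theta + bp6$beta + bp6$gamma
  expect_gte(bp6$theta / in4to80, 0.95)
})

test_that("session reports are tidy and round-trip through CSV", {
  prot <- buildAssrSequence(stimulusSpec(segment_dur_s = 12, silence_dur_s = 12,
                                         am_mod_freqs_hz = c(30, 90, 150, 210),
                                         audio_rate_hz = 44100))$protocol
  cfg <- syntheticConfig(rate_hz = 2000, duration_s = 100, seed = 91)
  s <- generateSession(prot, cfg)$session
  assr <- analyzeAssr(s, analysisConfig())
  expect_equal(nrow(assr), 4)
  expect_equal(assr$mod_freq_hz, c(30, 90, 150, 210))
  expect_true(all(assr$coherence_at_fm >= 0 & assr$coherence_at_fm <= 1))
  expect_true(all(assr$window_start_s >= amSegments(sessionProtocol(s))$start_s))

  rep <- sessionReport(list(assr = assr), session_id = "s1",
                       meta = list(strain = "WAR"))
  expect_equal(unique(rep$analysis), "assr")
  expect_true(all(c("session_id", "segment_id", "metric", "value") %in%
                    names(rep)))
  path <- tempfile(fileext = ".csv")
  write.csv(rep, path, row.names = FALSE)
  back <- read.csv(path)
  expect_equal(back$value, rep$value)
  expect_equal(back$metric, rep$metric)
  expect_error(sessionReport(list()), "empty")
})
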