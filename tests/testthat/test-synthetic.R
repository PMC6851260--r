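test_that("background has the configured spectral slope and is deterministic", {
  fitSlope <- function(x, rate) {
    est <- welchPsd(x, rate, 1, 0)
    sel <- frequencies(est) >= 1 & frequencies(est) <= 100
    stats::coef(stats::lm(log10(psdValues(est)[sel]) ~
                            log10(frequencies(est)[sel])))[2]
  }
  cfg0 <- syntheticConfig(rate_hz = 1000, duration_s = 60,
                          spectral_exponent = 0,
                          band_oscillations = data.frame(center_hz = numeric(),
                                                         amplitude_uV = numeric()),
                          seed = 21)
  set.seed(21)
  expect_equal(unname(fitSlope(generateBackground(cfg0), 1000)), 0,
               tolerance = 0.15)

  cfg1 <- syntheticConfig(rate_hz = 1000, duration_s = 60,
                          spectral_exponent = 1,
                          band_oscillations = data.frame(center_hz = numeric(),
                                                         amplitude_uV = numeric()),
                          seed = 21)
  set.seed(21)
  expect_equal(unname(fitSlope(generateBackground(cfg1), 1000)), -1,
               tolerance = 0.15)

  # variance scales with noise_sigma^2
  set.seed(5); a <- generateBackground(cfg1)
  expect_equal(stats::sd(a), 20, tolerance = 1e-9)

  # determinism: same seed, bit-identical output
  set.seed(99); b1 <- generateBackground(cfg1)
  set.seed(99); b2 <- generateBackground(cfg1)
  expect_identical(b1, b2)
  expect_error(generateBackground(cfg1, duration_s = -1), "positive")
})

test_that("entrained component: pure sine limit and jitter monotonicity", {
  cfg <- syntheticConfig(rate_hz = 2000, duration_s = 10, entrain_amp_uV = 4,
                         phase_jitter_sd_rad = 0, seed = 1)
  x <- generateEntrainedComponent(50, cfg, 10)
  expect_equal(mean(x^2), 4^2 / 2, tolerance = 0.01 * 8)

  ref <- sin(2 * pi * 50 * (seq_along(x) - 1) / 2000)
  coh <- msCoherence(x, ref, 2000, 1, 0)
  at50 <- mscValues(coh)[which.min(abs(frequencies(coh) - 50))]
  expect_gte(at50, 0.99)

  # coherence degrades monotonically with phase-jitter SD (20 replicates);
  # beyond ~0.3 rad/cycle it saturates at the chance floor ~1/K, where
  # medians are statistical ties — pairs below the 2/K chance ceiling are
  # accepted as ties, and a pooled rank test covers the whole ladder
  jitters <- c(0, 0.1, 0.3, 1.0)
  reps <- sapply(jitters, function(j) {
    cj <- syntheticConfig(rate_hz = 2000, duration_s = 10,
                          phase_jitter_sd_rad = j, entrain_amp_uV = 4)
    sapply(1:20, function(r) {
      set.seed(1000 + r)
      xr <- generateEntrainedComponent(50, cj, 10)
      c <- msCoherence(xr, ref, 2000, 1, 0)
      mscValues(c)[which.min(abs(frequencies(c) - 50))]
    })
  })
  med <- apply(reps, 2, stats::median)
  chance_ceiling <- 2 / 10                    # K = 10 one-second segments
  ties <- pmax(med[-1], med[-length(med)]) <= chance_ceiling
  expect_true(all(diff(med) <= 0 | ties))
  rk <- suppressWarnings(stats::cor.test(rep(jitters, each = 20), c(reps),
                                         method = "spearman"))
  expect_lt(rk$estimate, -0.5)
  expect_lt(rk$p.value, 0.01)
  expect_error(generateEntrainedComponent(1500, cfg, 1), "rate/2")
})

test_that("evoked kernels peak where and how tall the config says", {
  cfg <- syntheticConfig(rate_hz = 10000, duration_s = 2, evoked_latency_ms = 5,
                         evoked_amp_uV = 80, trial_latency_jitter_ms = 0,
                         seed = 2)
  out <- generateEvokedComponent(1.0, cfg, 2)
  peak_i <- which.max(out$series)
  expect_equal((peak_i - 1) / 10000, 1.005)    # onset + latency
  expect_equal(max(out$series), 80)

  # averaging jittered trials attenuates the peak, more so for larger jitter:
  # the mean of jittered kernels converges to kernel * Gaussian(jitter)
  avgPeak <- function(jit) {
    cj <- syntheticConfig(rate_hz = 10000, duration_s = 70,
                          evoked_latency_ms = 5, evoked_amp_uV = 80,
                          evoked_width_ms = 2, trial_latency_jitter_ms = jit,
                          seed = 3)
    onsets <- seq(0.5, 60, by = 0.5)[1:120]
    set.seed(42)
    o <- generateEvokedComponent(onsets, cj, 70)
    ep <- extractEpochs(o$series, onsets, 10000)
    max(grandAverage(ep))
  }
  p0 <- avgPeak(0); p2 <- avgPeak(2); p5 <- avgPeak(5)
  expect_equal(p0, 80, tolerance = 1e-6)
  expect_true(p2 < p0 && p5 < p2)
  # convolution oracle: peak shrinks by width/sqrt(width^2 + jitter^2)
  expect_equal(p2 / p0, 2 / sqrt(2^2 + 2^2), tolerance = 0.1)

  expect_equal(generateEvokedComponent(numeric(), cfg, 2)$series, numeric(20000))
  expect_error(generateEvokedComponent(5, cfg, 2), "within")
})

test_that("artifact bursts are confined to their intervals and recoverable", {
  cfg <- syntheticConfig(rate_hz = 1000, duration_s = 30, noise_sigma_uV = 1,
                         artifact_bursts = data.frame(start_s = 12, dur_s = 2,
                                                      amplitude_uV = 10),
                         seed = 4)
  set.seed(4)
  base <- rnorm(30000)
  withArt <- injectArtifactBursts(base, cfg)
  inside <- 12001:14000
  expect_gte(stats::var(withArt[inside]) / stats::var(withArt[-inside]), 10)
  expect_identical(withArt[-inside], base[-inside])

  # no bursts -> identity
  cfg0 <- syntheticConfig(rate_hz = 1000, duration_s = 30)
  expect_identical(injectArtifactBursts(base, cfg0), base)

  # burst location recoverable as argmax of sliding-window variance
  win <- 2000
  v <- sapply(seq(1, 28001, by = 500),
              function(i) stats::var(withArt[i:(i + win - 1)]))
  best <- seq(1, 28001, by = 500)[which.max(v)]
  expect_lt(abs((best - 1) / 1000 - 12), 2)
  cfgBad <- syntheticConfig(rate_hz = 1000, duration_s = 30,
                            artifact_bursts = data.frame(start_s = 29,
                                                         dur_s = 5,
                                                         amplitude_uV = 1))
  expect_error(injectArtifactBursts(base, cfgBad), "within")
})

test_that("full sessions assemble components exactly as configured", {
  # AFC-style: entrained energy only during the CS intervals
  prot <- afcProtocol(n_cs = 2, cs_dur_s = 10, baseline_s = 10)
  cfg <- syntheticConfig(rate_hz = 2000, duration_s = 40, noise_sigma_uV = 2,
                         entrain_amp_uV = 10, phase_jitter_sd_rad = 0,
                         seed = 5)
  sim <- generateSession(prot, cfg)
  nbp <- function(seg) {
    idx <- (seg[1] * 2000 + 1):(seg[2] * 2000)
    narrowbandPower(welchPsd(neuralTrack(sim$session)[idx], 2000), 53.7, 1)
  }
  expect_gte(nbp(c(10, 20)) / nbp(c(0, 10)), 5)
  expect_gte(nbp(c(30, 40)) / nbp(c(20, 30)), 5)

  # all amplitudes zero -> session equals the pure background
  cfg0 <- syntheticConfig(rate_hz = 2000, duration_s = 40, noise_sigma_uV = 2,
                          entrain_amp_uV = 0, evoked_amp_uV = 0,
                          band_oscillations = data.frame(center_hz = numeric(),
                                                         amplitude_uV = numeric()),
                          seed = 6)
  sim0 <- generateSession(prot, cfg0)
  set.seed(6)
  expect_identical(neuralTrack(sim0$session), generateBackground(cfg0))

  # ground truth: one entry per segment and per burst; determinism
  tprot <- transientProtocol(stimulusSpec(burst_count = 20))
  cfgT <- syntheticConfig(rate_hz = 2000, duration_s = 11, seed = 7)
  simT <- generateSession(tprot, cfgT)
  expect_equal(nrow(simT$truth$trials), 20)
  expect_equal(nrow(sim$truth$segments), 2)
  simT2 <- generateSession(tprot, cfgT)
  expect_identical(neuralTrack(simT$session), neuralTrack(simT2$session))
  expect_error(generateSession(prot, syntheticConfig(duration_s = 10)),
               "does not cover")
})

test_that("sessions round-trip through the WAV-pair serialization", {
  prot <- afcProtocol(n_cs = 1, cs_dur_s = 2, baseline_s = 2)
  cfg <- syntheticConfig(rate_hz = 2000, duration_s = 4, seed = 8)
  sim <- generateSession(prot, cfg, meta = list(strain = "WAR", drug = "DZP"))
  base <- tempfile()
  writeSession(sim$session, base)
  back <- readSession(base)
  expect_equal(sampleRate(back), 2000)
  expect_lt(max(abs(neuralTrack(back) - neuralTrack(sim$session))),
            2^-14 * max(abs(neuralTrack(sim$session))))
  expect_equal(protocolEvents(back), protocolEvents(sim$session))
  expect_equal(sessionMeta(back)$strain, "WAR")
})
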