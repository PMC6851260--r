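# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# sample-wise trapezoidal envelope, coded independently of burstEnvelope()
oracleEnvelope <- function(t_s, dur = 0.040, rise = 0.001, plateau = 0.038) {
  fall <- dur - rise - plateau
  sapply(t_s, function(t) {
    if (t < 0 || t >= dur) 0
    else if (t < rise) t / rise
    else if (t < rise + plateau) 1
    else (dur - t) / fall
  })
}

# naive exhaustive minimum-variance window scan (loop + var())
oracleMinVarWindow <- function(x, rate, seg, win_s, hop_s) {
  win_n <- round(win_s * rate)
  i0 <- round(seg[1] * rate) + 1
  i1 <- min(length(x), round(seg[2] * rate))
  starts <- seq(i0, i1 - win_n + 1, by = max(1, round(hop_s * rate)))
  vs <- sapply(starts, function(s) stats::var(x[s:(s + win_n - 1)]))
  (starts[which.min(vs)] - 1) / rate
}

# brute-force freezing percentage: scan every sample run by hand
oracleFreezingPeriod <- function(immobile, rate, min_bout_s = 3) {
  min_n <- round(min_bout_s * rate)
  count <- 0; run <- 0
  for (v in c(immobile, FALSE)) {
    if (v) run <- run + 1
    else { if (run >= min_n) count <- count + run; run <- 0 }
  }
  100 * count / length(immobile)
}

oracleFreezingCs <- function(immobile, rate, window_s = 30, epoch_s = 5,
                             min_s = 3) {
  n_ep <- window_s / epoch_s
  ep_n <- round(epoch_s * rate)
  frozen <- 0
  for (e in seq_len(n_ep)) {
    seg <- immobile[((e - 1) * ep_n + 1):(e * ep_n)]
    best <- 0; run <- 0
    for (v in c(seg, FALSE)) {
      if (v) run <- run + 1 else { best <- max(best, run); run <- 0 }
    }
    if (best >= round(min_s * rate)) frozen <- frozen + 1
  }
  100 * frozen / n_ep
}

# single-segment periodogram band mass via direct FFT (rectangular window)
oracleSineFreqZeroCross <- function(x, rate) {
  s <- sign(x)
  cross <- which(s[-1] * s[-length(s)] < 0)
  (length(cross) - 1) / 2 / ((cross[length(cross)] - cross[1]) / rate)
}
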