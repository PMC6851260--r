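# Freezing-behavior scoring on binary immobility traces. Freezing is
# immobility except breathing; the input here is already a boolean
# immobile/mobile series (video-to-immobility conversion is out of scope).

# lengths and start indices of TRUE runs
immobileRuns <- function(immobile) {
  r <- rle(as.logical(immobile))
  ends <- cumsum(r$lengths)
  data.frame(start = (ends - r$lengths + 1L)[r$values],
             len = r$lengths[r$values])
}

#' Score freezing within a conditioned-stimulus window, per 5-s epochs
#'
#' The CS window is divided into \code{cs_window_s / epoch_s} epochs; an
#' epoch counts as freezing iff it contains a contiguous immobile run of at
#' least \code{min_immobile_s} (boundary inclusive: exactly 3 s counts). A
#' bout spanning an epoch boundary counts in any epoch where its
#' within-epoch portion reaches the minimum. Returns the percentage of
#' freezing epochs, quantized to multiples of 100/n_epochs.
#'
#' @param immobile logical (or 0/1) immobility series covering the CS window.
#' @param rate_hz sampling rate of the trace, Hz.
#' @param cs_window_s CS window length, s (default 30).
#' @param epoch_s epoch length, s (default 5; must divide the window).
#' @param min_immobile_s minimum contiguous immobility per epoch, s
#'   (default 3).
#' @return percent of epochs scored as freezing.
#' @export
scoreFreezingCs <- function(immobile, rate_hz, cs_window_s = 30, epoch_s = 5,
                            min_immobile_s = 3) {
  n_epochs <- cs_window_s / epoch_s
  if (abs(n_epochs - round(n_epochs)) > 1e-9)
    stop("cs_window_s must be a multiple of epoch_s")
  n_epochs <- round(n_epochs)
  need <- round(cs_window_s * rate_hz)
  if (length(immobile) < need)
    stop("trace shorter than the CS window")
  immobile <- as.logical(immobile[seq_len(need)])
  ep_n <- round(epoch_s * rate_hz)
  min_n <- round(min_immobile_s * rate_hz)
  frozen <- vapply(seq_len(n_epochs), function(e) {
    seg <- immobile[((e - 1L) * ep_n + 1L):(e * ep_n)]
    runs <- immobileRuns(seg)
    nrow(runs) > 0 && max(runs$len) >= min_n
  }, logical(1))
  100 * sum(frozen) / n_epochs
}

#' Score freezing over a whole period as percent time
#'
#' Total time spent inside immobile bouts of at least \code{min_bout_s},
#' divided by the trace duration, times 100.
#'
#' @param immobile logical (or 0/1) immobility series.
#' @param rate_hz sampling rate, Hz.
#' @param min_bout_s minimum bout length to count, s (default 3).
#' @return percent of time frozen.
#' @export
scoreFreezingPeriod <- function(immobile, rate_hz, min_bout_s = 3) {
  if (!length(immobile)) stop("empty trace")
  runs <- immobileRuns(as.logical(immobile))
  min_n <- round(min_bout_s * rate_hz)
  100 * sum(runs$len[runs$len >= min_n]) / length(immobile)
}

#' Read a movement trace from CSV
#'
#' Expects columns \code{time} (s) and \code{immobile} (0/1); the rate is
#' inferred from the time column.
#'
#' @param path CSV path.
#' @return list: \code{immobile} (logical), \code{rate_hz},
#'   \code{duration_s}.
#' @export
readMovementTrace <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time", "immobile") %in% names(df)))
    stop("movement trace CSV needs columns 'time' and 'immobile'")
  dt <- stats::median(diff(df$time))
  list(immobile = as.logical(df$immobile), rate_hz = 1 / dt,
       duration_s = nrow(df) * dt)
}
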