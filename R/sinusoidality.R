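#' Rise/decay-time diagnostic for non-sinusoidal oscillations
#'
#' Sawtooth-like (non-sinusoidal) low-frequency oscillations generate
#' spurious phase-amplitude coupling through their phase harmonics. Waveform
#' asymmetry can be quantified per cycle by the time from trough to peak
#' (rise time), the time from peak to trough (decay time), and their ratio:
#' a sinusoid has ratio 1, a slowly-rising sawtooth > 1, a slowly-decaying
#' sawtooth < 1.
#'
#' Cycle landmarks come from the narrowband (+/- `phase_half_bw` Hz) phase:
#' a peak where the instantaneous phase crosses 0 upward, a trough where it
#' wraps at +/- pi. Because extrema of a narrowband signal are sinusoidal by
#' construction, the landmark times are then refined to the extrema of a
#' lightly low-passed (`broadband_cutoff` Hz) copy of the raw signal within
#' each half-cycle.
#'
#' @param trials a [trial_series()].
#' @param phase_freqs phase centre frequencies to scan, Hz.
#' @param phase_half_bw half-bandwidth of the narrow phase band, Hz.
#' @param broadband_cutoff low-pass cutoff (Hz) of the copy used to time
#'   the extrema.
#' @param trim edge trim in seconds (see [extract_analytic()]).
#' @return An object of class `sinusoidality`: list with `freqs`, `rise`
#'   and `decay` (mean seconds per frequency), `ratio`, and
#'   `trial_ratios` (trials x frequencies matrix for condition comparison).
#' @examples
#' t <- (0:5499) / 1000
#' ts <- trial_series(matrix(sin(2 * pi * 10 * t), 1), fs = 1000, pad = 0.5)
#' rise_decay_ratio(ts, phase_freqs = 10)$ratio  # ~1
#' @seealso [compare_sinusoidality()]
#' @export
rise_decay_ratio <- function(trials, phase_freqs = 7:13, phase_half_bw = 1,
                             broadband_cutoff = 40,
                             trim = if (trials$pad > 0) trials$pad else 0.5) {
  stopifnot(inherits(trials, "trial_series"))
  fs <- trials$fs
  dur <- ncol(trials$data) / fs - 2 * trim
  if (dur < 3 / min(phase_freqs))
    stop(sprintf(
      "trials leave %.3g s after trimming; need at least 3 cycles at %g Hz",
      dur, min(phase_freqs)), call. = FALSE)
  ktrim <- round(trim * fs)
  keep <- (ktrim + 1):(ncol(trials$data) - ktrim)
  lp <- butter_sos(4, broadband_cutoff, fs, "low")
  broad <- sos_filtfilt_rows(lp, trials$data)[, keep, drop = FALSE]
  ntr <- nrow(trials$data)
  nf <- length(phase_freqs)
  rise <- decay <- matrix(NA_real_, ntr, nf)
  for (fi in seq_len(nf)) {
    an <- extract_analytic(trials, design_phase_band(phase_freqs[fi]),
                           trim = trim)
    for (i in seq_len(ntr)) {
      rd <- cycle_rise_decay(an$phase[i, ], broad[i, ], fs)
      if (!is.null(rd)) {
        rise[i, fi] <- rd$rise
        decay[i, fi] <- rd$decay
      }
    }
  }
  ratio_trials <- rise / decay
  structure(
    list(freqs = phase_freqs,
         rise = colMeans(rise, na.rm = TRUE),
         decay = colMeans(decay, na.rm = TRUE),
         ratio = colMeans(ratio_trials, na.rm = TRUE),
         trial_ratios = ratio_trials,
         condition = trials$condition),
    class = "sinusoidality"
  )
}

# Mean rise (trough -> peak) and decay (peak -> trough) time of one trial.
# phase: narrowband instantaneous phase; broad: low-passed raw signal.
cycle_rise_decay <- function(phase, broad, fs) {
  n <- length(phase)
  dphi <- diff(phase)
  # peaks: upward crossing of phase 0; troughs: wrap from +pi to -pi
  peaks <- which(phase[-n] < 0 & phase[-1] >= 0 & dphi > 0 & dphi < pi)
  troughs <- which(dphi < -pi)
  if (length(peaks) < 2 || length(troughs) < 2) return(NULL)
  # refine to extrema of the broadband copy between adjacent landmarks
  refine <- function(at, lo, hi, fun) {
    win <- max(1, lo):min(n, hi)
    win[fun(broad[win])]
  }
  events <- sort(c(stats::setNames(peaks, rep("p", length(peaks))),
                   stats::setNames(troughs, rep("t", length(troughs)))))
  kinds <- names(events)
  # drop leading events so the sequence starts at a trough
  first_t <- match("t", kinds)
  if (is.na(first_t)) return(NULL)
  events <- events[first_t:length(events)]
  kinds <- names(events)
  rises <- decays <- numeric(0)
  for (k in seq_len(length(events) - 1)) {
    a <- events[k]; b <- events[k + 1]
    if (kinds[k] == "t" && kinds[k + 1] == "p") {
      ta <- refine(a, a, b, which.min)
      tb <- refine(b, a, b, which.max)
      if (tb > ta) rises <- c(rises, (tb - ta) / fs)
    } else if (kinds[k] == "p" && kinds[k + 1] == "t") {
      ta <- refine(a, a, b, which.max)
      tb <- refine(b, a, b, which.min)
      if (tb > ta) decays <- c(decays, (tb - ta) / fs)
    }
  }
  if (length(rises) == 0 || length(decays) == 0) return(NULL)
  list(rise = mean(rises), decay = mean(decays))
}

#' @export
print.sinusoidality <- function(x, ...) {
  cat("Rise/decay asymmetry (condition \"", x$condition, "\"):\n", sep = "")
  df <- data.frame(freq = x$freqs, rise_s = round(x$rise, 4),
                   decay_s = round(x$decay, 4), ratio = round(x$ratio, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Compare waveform asymmetry between two conditions
#'
#' Paired t test (over trials) of the rise/decay ratio at every phase
#' frequency, with the p values of all frequencies reported. A significant
#' difference warns that an observed change in phase-amplitude coupling
#' may be driven by a change in waveform shape rather than genuine coupling.
#'
#' @param a,b `sinusoidality` results for the two conditions, computed on
#'   matching trial sets (equal trial counts, same frequencies).
#' @return data.frame with columns `freq`, `t`, `df`, `p`.
#' @export
compare_sinusoidality <- function(a, b) {
  stopifnot(inherits(a, "sinusoidality"), inherits(b, "sinusoidality"))
  if (!identical(a$freqs, b$freqs))
    stop("conditions were scanned at different frequencies", call. = FALSE)
  if (nrow(a$trial_ratios) != nrow(b$trial_ratios))
    stop("conditions have different trial counts; paired comparison undefined",
         call. = FALSE)
  res <- lapply(seq_along(a$freqs), function(fi) {
    ok <- stats::complete.cases(a$trial_ratios[, fi], b$trial_ratios[, fi])
    tt <- paired_t(a$trial_ratios[ok, fi], b$trial_ratios[ok, fi])
    data.frame(freq = a$freqs[fi], t = tt$t, df = tt$df, p = tt$p)
  })
  do.call(rbind, res)
}
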