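#' Trial-epoched single-channel time series
#'
#' Container for an epoched single-channel recording: a numeric matrix with
#' one row per trial and one column per sample, together with the sampling
#' rate, the time of the first sample relative to the event of interest, a
#' condition label, and the amount of padding present at each end of every
#' trial. Padding is extra recorded (or simulated) signal around the epoch
#' of interest; it is consumed by the edge trimming performed after
#' filtering and the Hilbert transform (see [extract_analytic()]).
#'
#' @param data numeric matrix, trials x samples. A vector is treated as a
#'   single trial.
#' @param fs sampling rate in Hz (> 0).
#' @param t0 time of the first sample relative to the event, in seconds.
#' @param condition condition label (single string).
#' @param pad padding duration at each end of the trial, in seconds.
#'   `pad * fs` must be a whole number of samples.
#' @return An object of class `trial_series`.
#' @examples
#' x <- trial_series(matrix(rnorm(2000), nrow = 2), fs = 1000, t0 = -0.5)
#' x
#' @seealso [simulate_pac_trials()], [read_trials()], [extract_analytic()]
#' @export
trial_series <- function(data, fs, t0 = 0, condition = "unlabelled", pad = 0) {
  if (is.vector(data) && is.numeric(data)) data <- matrix(data, nrow = 1)
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (trials x samples)", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  if (!is.numeric(pad) || length(pad) != 1 || pad < 0)
    stop("`pad` must be a single non-negative number (s)", call. = FALSE)
  if (abs(pad * fs - round(pad * fs)) > 1e-8)
    stop("`pad` must correspond to a whole number of samples (pad * fs integer)",
         call. = FALSE)
  structure(
    list(data = data, fs = fs, t0 = t0,
         condition = as.character(condition)[1], pad = pad),
    class = "trial_series"
  )
}

#' @export
print.trial_series <- function(x, ...) {
  cat("Trial series:", nrow(x$data), "trials x", ncol(x$data), "samples\n")
  cat(sprintf("  fs = %g Hz, t0 = %g s, pad = %g s, condition = \"%s\"\n",
              x$fs, x$t0, x$pad, x$condition))
  cat(sprintf("  duration = %g s per trial (%g s excluding padding)\n",
              ncol(x$data) / x$fs, ncol(x$data) / x$fs - 2 * x$pad))
  invisible(x)
}

#' @export
dim.trial_series <- function(x) dim(x$data)

#' Sample times of a trial series
#'
#' @param x a [trial_series()].
#' @return numeric vector of sample times (s) relative to the event.
#' @export
trial_times <- function(x) {
  stopifnot(inherits(x, "trial_series"))
  x$t0 + (seq_len(ncol(x$data)) - 1) / x$fs
}

n_trials <- function(x) nrow(x$data)
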