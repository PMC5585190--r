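#' Modulation-index estimators
#'
#' Four estimators of phase-amplitude coupling strength between a
#' low-frequency instantaneous phase series and a high-frequency amplitude
#' envelope sampled at the same instants:
#'
#' * `mvl_canolty()` — mean vector length: the modulus of the average of
#'   the complex-valued signal `amp * exp(1i * phase)`. Sensitive to the
#'   absolute amplitude scale (it doubles when the envelope doubles), a
#'   documented confound: raw values partly reflect high-frequency power.
#' * `mvl_ozkurt()` — mean vector length with an amplitude-power
#'   normalisation, `|sum(amp e^{i phase})| / (sqrt(N) * sqrt(sum(amp^2)))`,
#'   which removes the scale dependence and is better suited to noisy
#'   recordings such as MEG.
#' * `plv_cohen()` — phase-locking value between the low-frequency phase
#'   and the phase of the (demeaned) amplitude envelope: if coupling is
#'   present the envelope oscillates at the phase frequency.
#' * `kl_tort()` — Kullback-Leibler divergence of the phase-binned mean
#'   amplitude distribution from uniform, normalised by `log(n_bins)` so
#'   the value lies in `[0, 1]`.
#'
#' All four return an object of class `mi_estimate`.
#'
#' @param phase numeric vector of phases in radians, wrapped to `[-pi, pi)`.
#' @param amp numeric vector of envelope values (>= 0), same length.
#' @param n_bins number of phase bins for the Kullback-Leibler estimator.
#' @param phase_center,amp_center optional band centre frequencies (Hz)
#'   recorded in the result for bookkeeping.
#' @return An `mi_estimate`: list with `method`, `value`, `phase_center`,
#'   `amp_center`, `n_samples`.
#' @examples
#' ph <- c(0, pi / 2, -pi, -pi / 2)
#' mvl_canolty(ph, c(2, 0, 0, 0))$value  # 0.5
#' mvl_ozkurt(ph, c(2, 0, 0, 0))$value   # 0.5
#' @name modulation_index
NULL

mi_estimate <- function(method, value, n, phase_center = NA_real_,
                        amp_center = NA_real_) {
  structure(
    list(method = method, value = value, phase_center = phase_center,
         amp_center = amp_center, n_samples = n),
    class = "mi_estimate"
  )
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(sprintf("MI (%s): %.6g  [N = %d", x$method, x$value, x$n_samples))
  if (!is.na(x$phase_center))
    cat(sprintf(", phase %g Hz, amplitude %g Hz", x$phase_center, x$amp_center))
  cat("]\n")
  invisible(x)
}

check_phase_amp <- function(phase, amp) {
  if (length(phase) != length(amp))
    stop("`phase` and `amp` must have equal length", call. = FALSE)
  if (length(phase) < 2)
    stop("need at least 2 samples", call. = FALSE)
}

#' @rdname modulation_index
#' @export
mvl_canolty <- function(phase, amp, phase_center = NA_real_,
                        amp_center = NA_real_) {
  check_phase_amp(phase, amp)
  n <- length(phase)
  value <- Mod(sum(amp * exp(1i * phase))) / n
  mi_estimate("mvl_canolty", value, n, phase_center, amp_center)
}

#' @rdname modulation_index
#' @export
mvl_ozkurt <- function(phase, amp, phase_center = NA_real_,
                       amp_center = NA_real_) {
  check_phase_amp(phase, amp)
  ss <- sum(amp^2)
  if (ss <= 0)
    stop("degenerate input: amplitude is identically zero", call. = FALSE)
  n <- length(phase)
  value <- Mod(sum(amp * exp(1i * phase))) / (sqrt(n) * sqrt(ss))
  mi_estimate("mvl_ozkurt", value, n, phase_center, amp_center)
}

#' @rdname modulation_index
#' @export
plv_cohen <- function(phase, amp, phase_center = NA_real_,
                      amp_center = NA_real_) {
  check_phase_amp(phase, amp)
  if (max(amp) - min(amp) < .Machine$double.eps * 4 * max(abs(amp), 1))
    stop("degenerate input: envelope is constant, its phase is undefined",
         call. = FALSE)
  env_phase <- wrap_phase(Arg(analytic_signal(amp - mean(amp))))
  n <- length(phase)
  value <- Mod(sum(exp(1i * (phase - env_phase)))) / n
  mi_estimate("plv_cohen", value, n, phase_center, amp_center)
}

#' Phase-binned amplitude distribution
#'
#' Partitions `[-pi, pi)` into `n_bins` equal-width bins (left-closed,
#' right-open; a phase of exactly `pi` falls in the last bin), computes the
#' mean amplitude within each bin, and normalises the means to sum to one.
#' This is the distribution `P` compared against the uniform reference `Q`
#' by [kl_tort()].
#'
#' @inheritParams modulation_index
#' @return An object of class `phase_amplitude_distribution`: list with
#'   `n_bins`, `bin_edges` (length `n_bins + 1`), `P`, `Q`, `counts`.
#' @examples
#' ph <- seq(-pi, pi - 1e-6, length.out = 1000)
#' phase_amplitude_histogram(ph, rep(1, 1000))$P  # all 1/18
#' @export
phase_amplitude_histogram <- function(phase, amp, n_bins = 18) {
  check_phase_amp(phase, amp)
  idx <- phase_bin_index(phase, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  if (any(counts == 0)) {
    empty <- which(counts == 0)
    stop(sprintf(
      "empty phase bin(s) %s of %d: too few samples to cover the phase cycle; use longer trials or fewer bins",
      paste(empty, collapse = ", "), n_bins), call. = FALSE)
  }
  sums <- as.numeric(rowsum(amp, idx))
  means <- sums / counts
  structure(
    list(n_bins = as.integer(n_bins),
         bin_edges = seq(-pi, pi, length.out = n_bins + 1),
         P = means / sum(means), Q = rep(1 / n_bins, n_bins),
         counts = counts),
    class = "phase_amplitude_distribution"
  )
}

# Left-closed, right-open bins over [-pi, pi); phase == pi -> last bin.
phase_bin_index <- function(phase, n_bins) {
  idx <- floor((phase + pi) / (2 * pi / n_bins)) + 1L
  idx[idx > n_bins] <- n_bins
  idx[idx < 1L] <- 1L
  as.integer(idx)
}

#' @export
print.phase_amplitude_distribution <- function(x, ...) {
  cat(sprintf("Phase-amplitude distribution over %d bins (sum P = %g)\n",
              x$n_bins, sum(x$P)))
  print(round(x$P, 4))
  invisible(x)
}

#' @rdname modulation_index
#' @export
kl_tort <- function(phase, amp, n_bins = 18, phase_center = NA_real_,
                    amp_center = NA_real_) {
  h <- phase_amplitude_histogram(phase, amp, n_bins)
  value <- kl_mi_from_p(h$P)
  mi_estimate("kl_tort", value, length(phase), phase_center, amp_center)
}

# D(P, Q)/log(n_bins) for uniform Q, natural log, 0*log(0) == 0.
kl_mi_from_p <- function(P) {
  n_bins <- length(P)
  nz <- P > 0
  sum(P[nz] * log(P[nz] * n_bins)) / log(n_bins)
}

# ---- fast internal paths used by the comodulogram sweep ------------------
# These operate on whole vectors/matrices without constructing mi_estimate
# objects; the exported estimators above are the reference implementations
# and the test suite checks the two paths agree.

mi_methods <- c("mvl_canolty", "mvl_ozkurt", "plv_cohen", "kl_tort")

#' @rdname modulation_index
#' @param method estimator to dispatch to: one of `"mvl_canolty"`,
#'   `"mvl_ozkurt"`, `"plv_cohen"`, `"kl_tort"`.
#' @param ... passed through to the estimator.
#' @export
modulation_index <- function(method = mi_methods, phase, amp, ...) {
  method <- match.arg(method)
  switch(method,
         mvl_canolty = mvl_canolty(phase, amp, ...),
         mvl_ozkurt = mvl_ozkurt(phase, amp, ...),
         plv_cohen = plv_cohen(phase, amp, ...),
         kl_tort = kl_tort(phase, amp, ...))
}
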