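#' Band-pass filter specification
#'
#' Describes one analysis band: a centre frequency, a half-bandwidth, and
#' the Butterworth order / number of passes used to realise it. Two passes
#' (forward and reverse) give zero net phase shift, so filtered landmarks
#' keep their sample positions.
#'
#' @param center centre frequency, Hz.
#' @param half_bw half-bandwidth, Hz; the band is
#'   `[center - half_bw, center + half_bw]`.
#' @param order Butterworth order per pass.
#' @param passes 1 (forward only) or 2 (forward + reverse, zero phase).
#' @return An object of class `band_filter_spec` with fields `center`,
#'   `half_bw`, `lo_edge`, `hi_edge`, `order`, `passes`.
#' @seealso [design_phase_band()], [design_amplitude_band()]
#' @export
band_filter_spec <- function(center, half_bw, order = 4, passes = 2) {
  if (!is.numeric(center) || length(center) != 1 ||
      !is.numeric(half_bw) || length(half_bw) != 1 || half_bw <= 0)
    stop("`center` and `half_bw` must be single numbers with half_bw > 0",
         call. = FALSE)
  lo <- center - half_bw
  hi <- center + half_bw
  if (lo <= 0)
    stop(sprintf(
      "invalid band: lower edge %g Hz is not positive (center %g, half_bw %g)",
      lo, center, half_bw), call. = FALSE)
  if (!passes %in% c(1, 2)) stop("`passes` must be 1 or 2", call. = FALSE)
  structure(
    list(center = center, half_bw = half_bw, lo_edge = lo, hi_edge = hi,
         order = as.integer(order), passes = as.integer(passes)),
    class = "band_filter_spec"
  )
}

#' @export
print.band_filter_spec <- function(x, ...) {
  cat(sprintf("Band %g Hz +/- %g Hz -> [%g, %g] Hz (Butterworth order %d, %d-pass)\n",
              x$center, x$half_bw, x$lo_edge, x$hi_edge, x$order, x$passes))
  invisible(x)
}

#' Design the narrow phase-frequency band
#'
#' The band used to extract low-frequency phase is kept narrow, at +/- 1 Hz
#' around the centre frequency, so that the filtered waveform is close to
#' sinusoidal and its instantaneous phase is well defined.
#'
#' @param center phase centre frequency, Hz; must be >= 2 so the lower band
#'   edge stays positive.
#' @return a [band_filter_spec()] with `half_bw = 1`, order 4, two passes.
#' @examples
#' design_phase_band(10)  # [9, 11] Hz
#' @export
design_phase_band <- function(center) {
  if (!is.numeric(center) || length(center) != 1 || center < 2)
    stop(sprintf(
      "invalid band: phase center %s Hz gives a non-positive lower edge (need center >= 2)",
      format(center)), call. = FALSE)
  band_filter_spec(center, half_bw = 1, order = 4, passes = 2)
}

#' Design the scaled amplitude-frequency band
#'
#' The band used to extract the high-frequency amplitude envelope must be
#' wide enough to contain the modulation sidebands `center +/- f_phase`;
#' otherwise coupling cannot be detected even when present. A bandwidth
#' proportional to the centre frequency (default +/- 0.4 x centre) realises
#' this for the usual alpha/gamma ranges: e.g. a 60 Hz centre gives
#' \[36, 84\] Hz, covering sidebands of phase frequencies up to 24 Hz.
#'
#' @param center amplitude centre frequency, Hz (> 0).
#' @param scale half-bandwidth as a fraction of `center`, in (0, 1).
#' @return a [band_filter_spec()] with `half_bw = scale * center`.
#' @examples
#' design_amplitude_band(60)        # [36, 84] Hz
#' design_amplitude_band(60, 13/60) # minimal band for 13 Hz phase: [47, 73]
#' @export
design_amplitude_band <- function(center, scale = 0.4) {
  if (!is.numeric(center) || length(center) != 1 || center <= 0)
    stop("`center` must be a single positive frequency (Hz)", call. = FALSE)
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0 || scale >= 1)
    stop("`scale` must lie strictly between 0 and 1", call. = FALSE)
  band_filter_spec(center, half_bw = scale * center, order = 4, passes = 2)
}

#' Smallest admissible amplitude centre frequency
#'
#' On a regular amplitude-frequency grid, finds the lowest centre frequency
#' whose scaled bandwidth still covers the sidebands of the highest phase
#' frequency of interest, i.e. the smallest multiple of `amp_grid_step`
#' with `scale * f >= max_phase`.
#'
#' @param max_phase highest phase frequency to be detected, Hz.
#' @param scale amplitude bandwidth scale (see [design_amplitude_band()]).
#' @param amp_grid_step spacing of the amplitude grid, Hz.
#' @return the smallest admissible centre frequency, Hz.
#' @examples
#' min_amplitude_center(13, 0.4, 2)  # 34 Hz
#' @export
min_amplitude_center <- function(max_phase, scale = 0.4, amp_grid_step = 2) {
  if (!is.numeric(max_phase) || length(max_phase) != 1 || max_phase <= 0)
    stop("`max_phase` must be a single positive frequency (Hz)", call. = FALSE)
  amp_grid_step * ceiling(max_phase / (scale * amp_grid_step))
}

# ---- Butterworth band-pass via second-order sections --------------------
#
# The 2 Hz-wide phase bands at typical MEG sampling rates put the digital
# poles so close to the unit circle that the expanded transfer-function
# form is numerically unstable; the filter is therefore designed in
# zero-pole-gain form (analog prototype -> band transform -> bilinear) and
# applied as a cascade of biquads.

butter_zpk <- function(order, edges_hz, fs, type = c("pass", "low")) {
  type <- match.arg(type)
  n <- as.integer(order)
  fs2 <- 2 * fs
  w <- fs2 * tan(pi * edges_hz / fs)      # prewarped analog edges, rad/s
  k <- seq_len(n)
  theta <- pi * (2 * k - 1) / (2 * n)
  p <- complex(real = -sin(theta), imaginary = cos(theta))  # LHP prototype
  if (type == "low") {
    p <- p * w[1]
    z <- complex(0)
    gain <- w[1]^n
  } else {
    wo <- sqrt(w[1] * w[2])
    bw <- w[2] - w[1]
    plp <- p * bw / 2
    p <- c(plp + sqrt(plp^2 - wo^2), plp - sqrt(plp^2 - wo^2))
    z <- rep(complex(real = 0), n)
    gain <- bw^n
  }
  # bilinear transform
  degree <- length(p) - length(z)
  gain <- gain * Re(prod(fs2 - z) / prod(fs2 - p))
  z <- (fs2 + z) / (fs2 - z)
  p <- (fs2 + p) / (fs2 - p)
  z <- c(z, rep(complex(real = -1), degree))
  list(z = z, p = p, k = gain)
}

# Pair conjugate poles with nearest zeros into biquad sections.
# Returns a sections x 6 matrix with rows (b0, b1, b2, 1, a1, a2); the
# overall gain is folded into the first section.
zpk_to_sos <- function(z, p, k) {
  stopifnot(length(z) == length(p), length(p) %% 2 == 0)
  take_conj_pairs <- function(v) {
    pairs <- list()
    v <- v[order(-abs(Im(v)), Re(v))]
    while (length(v) > 0) {
      if (abs(Im(v[1])) > 1e-12) {
        j <- which.min(Mod(v[-1] - Conj(v[1]))) + 1L
      } else {
        re <- which(abs(Im(v)) <= 1e-12)
        j <- if (length(re) > 1) re[re != 1][1] else 2L
      }
      pairs[[length(pairs) + 1L]] <- c(v[1], v[j])
      v <- v[-c(1L, j)]
    }
    pairs
  }
  ppairs <- take_conj_pairs(p)
  # process pole pairs closest to the unit circle first
  ppairs <- ppairs[order(-vapply(ppairs, function(q) max(Mod(q)), 0))]
  zleft <- z
  sos <- matrix(0, length(ppairs), 6)
  for (i in seq_along(ppairs)) {
    pp <- ppairs[[i]]
    j1 <- which.min(Mod(zleft - pp[1]))
    z1 <- zleft[j1]; zleft <- zleft[-j1]
    j2 <- which.min(Mod(zleft - Conj(z1)))
    z2 <- zleft[j2]; zleft <- zleft[-j2]
    sos[i, 1:3] <- Re(c(1, -(z1 + z2), z1 * z2))
    sos[i, 4:6] <- Re(c(1, -(pp[1] + pp[2]), pp[1] * pp[2]))
  }
  sos[1, 1:3] <- sos[1, 1:3] * k
  sos
}

butter_sos <- function(order, edges_hz, fs, type = c("pass", "low")) {
  zpk <- butter_zpk(order, edges_hz, fs, type)
  zpk_to_sos(zpk$z, zpk$p, zpk$k)
}

sos_filter <- function(sos, x) {
  drop(.sos_filter_mat(sos, matrix(x, nrow = 1)))
}

# Zero-phase filtering: forward + reverse pass over an even (symmetric)
# reflection extension of the signal. Full-length reflection is used
# because the narrow phase bands ring for hundreds of milliseconds and
# short pads leave visible envelope droop well inside the epoch.
sos_filtfilt <- function(sos, x) {
  n <- length(x)
  if (n < 4) stop("signal too short to filter", call. = FALSE)
  drop(.sos_filtfilt_mat(sos, matrix(x, nrow = 1), n - 1L))
}

# Row-wise zero-phase filtering of a trials x samples matrix.
sos_filtfilt_rows <- function(sos, X) {
  if (ncol(X) < 4) stop("signal too short to filter", call. = FALSE)
  .sos_filtfilt_mat(sos, X, ncol(X) - 1L)
}

band_sos <- function(band, fs) {
  if (band$lo_edge <= 0 || band$hi_edge >= fs / 2)
    stop(sprintf(
      "invalid band: [%g, %g] Hz must lie strictly inside (0, %g) Hz at fs = %g Hz",
      band$lo_edge, band$hi_edge, fs / 2, fs), call. = FALSE)
  butter_sos(band$order, c(band$lo_edge, band$hi_edge), fs, "pass")
}

#' Apply a band filter to a signal
#'
#' Filters a numeric vector with the Butterworth band described by a
#' [band_filter_spec()]. Two passes give zero net phase shift.
#'
#' @param x numeric vector.
#' @param band a [band_filter_spec()].
#' @param fs sampling rate, Hz.
#' @return filtered numeric vector, same length as `x`.
#' @export
band_filter <- function(x, band, fs) {
  sos <- band_sos(band, fs)
  if (band$passes == 2) sos_filtfilt(sos, x) else sos_filter(sos, x)
}

# ---- Hilbert analytic signal --------------------------------------------

#' Analytic signal via the Hilbert transform
#'
#' Computes the complex analytic extension of a real signal using the FFT
#' half-spectrum method; `Mod()` of the result is the amplitude envelope and
#' `Arg()` the instantaneous phase.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# wrap Arg() output (-pi, pi] to the [-pi, pi) convention
wrap_phase <- function(ph) {
  ph[ph >= pi] <- ph[ph >= pi] - 2 * pi
  ph
}

# ---- Phase / amplitude extraction ---------------------------------------

#' Extract instantaneous phase and amplitude for a band
#'
#' Band-pass filters every trial (zero phase, two passes), takes the Hilbert
#' analytic signal, and then trims `trim` seconds from both ends of every
#' trial. Trimming after the transform removes both the filter edge
#' transients and the Hilbert edge artifacts in one step; sharp edges left
#' in place are a classic source of spurious coupling.
#'
#' Trials that are identically zero (dead channels) yield zero amplitude and
#' a defined but meaningless phase; they are flagged in `degenerate` rather
#' than raising an error so that batch runs survive them.
#'
#' @param trials a [trial_series()].
#' @param band a [band_filter_spec()].
#' @param trim seconds discarded from each end of every trial after
#'   filtering and the Hilbert transform. Defaults to the padding recorded
#'   in `trials` if positive, otherwise 0.5 s.
#' @return An object of class `analytic_series`: list with `phase` and
#'   `amplitude` matrices (trials x remaining samples, phase in
#'   `[-pi, pi)`, amplitude >= 0), `n_samples`, `band`, `fs`, `t0` (time of
#'   the first retained sample), and logical `degenerate` per trial.
#' @examples
#' ts <- trial_series(matrix(cos(2 * pi * 10 * (0:2199) / 1000), 1),
#'                    fs = 1000, t0 = -0.5, pad = 0.5)
#' a <- extract_analytic(ts, design_phase_band(10))
#' range(a$amplitude)
#' @export
extract_analytic <- function(trials, band,
                             trim = if (trials$pad > 0) trials$pad else 0.5) {
  stopifnot(inherits(trials, "trial_series"), inherits(band, "band_filter_spec"))
  fs <- trials$fs
  nsamp <- ncol(trials$data)
  ktrim <- round(trim * fs)
  if (nsamp <= 2 * ktrim)
    stop(sprintf(
      "trials of %g s are too short to trim %g s from each end",
      nsamp / fs, trim), call. = FALSE)
  sos <- band_sos(band, fs)
  keep <- (ktrim + 1):(nsamp - ktrim)
  ntr <- nrow(trials$data)
  ph <- matrix(0, ntr, length(keep))
  am <- matrix(0, ntr, length(keep))
  degen <- apply(trials$data, 1, function(x)
    all(abs(x - x[1]) < .Machine$double.eps * 4))
  Y <- sos_filtfilt_rows(sos, trials$data)
  Y[degen, ] <- 0
  for (i in seq_len(ntr)) {
    z <- analytic_signal(Y[i, ])[keep]
    ph[i, ] <- wrap_phase(Arg(z))
    am[i, ] <- Mod(z)
  }
  structure(
    list(phase = ph, amplitude = am, n_samples = length(keep),
         band = band, fs = fs, t0 = trials$t0 + ktrim / fs,
         trim = ktrim / fs, degenerate = degen),
    class = "analytic_series"
  )
}

#' @export
print.analytic_series <- function(x, ...) {
  cat(sprintf(
    "Analytic series: %d trials x %d samples, band [%g, %g] Hz, fs %g Hz, trim %g s\n",
    nrow(x$phase), x$n_samples, x$band$lo_edge, x$band$hi_edge, x$fs, x$trim))
  if (any(x$degenerate))
    cat("  degenerate (flat) trials:", paste(which(x$degenerate), collapse = ", "), "\n")
  invisible(x)
}
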