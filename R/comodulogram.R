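#' Comodulogram grid specification
#'
#' Defines the phase-frequency x amplitude-frequency sweep: the two centre
#' grids, the bandwidth rules (narrow +/- `phase_half_bw` Hz for phase,
#' +/- `amp_scale` x centre for amplitude), the analysis window, the edge
#' trim, and which modulation-index estimators to run. The defaults cover
#' alpha phase 7-13 Hz in 1 Hz steps against amplitudes 34-100 Hz in 2 Hz
#' steps; 34 Hz is the smallest even centre whose scaled bandwidth still
#' contains the sidebands of a 13 Hz modulating phase (see
#' [min_amplitude_center()]). Cells whose amplitude bandwidth does not cover
#' the sidebands of the highest phase centre are kept but flagged
#' inadmissible in `admissible`.
#'
#' @param phase_centers phase centre frequencies, Hz, strictly increasing.
#' @param amp_centers amplitude centre frequencies, Hz, strictly increasing.
#' @param phase_half_bw half-bandwidth of the phase bands, Hz.
#' @param amp_scale amplitude half-bandwidth as a fraction of the centre.
#' @param window optional `c(start, end)` in seconds relative to the event;
#'   modulation indices are computed on samples inside this window (after
#'   trimming). `NULL` uses the whole trimmed trial.
#' @param methods character vector of estimators to run (see
#'   [modulation_index()]).
#' @param n_bins phase bins for the Kullback-Leibler estimator.
#' @param trim edge trim passed to [extract_analytic()]; `NULL` uses that
#'   function's default (the series' padding).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(phase_centers = 7:13,
                      amp_centers = seq(34, 100, by = 2),
                      phase_half_bw = 1, amp_scale = 0.4,
                      window = NULL, methods = mi_methods,
                      n_bins = 18, trim = NULL) {
  if (is.unsorted(phase_centers, strictly = TRUE) ||
      is.unsorted(amp_centers, strictly = TRUE))
    stop("centre grids must be strictly increasing", call. = FALSE)
  methods <- match.arg(methods, mi_methods, several.ok = TRUE)
  if (!is.null(window) && (length(window) != 2 || window[1] >= window[2]))
    stop("`window` must be c(start, end) with start < end", call. = FALSE)
  admissible <- outer(rep(TRUE, length(phase_centers)),
                      amp_scale * amp_centers >= max(phase_centers), `&`)
  dimnames(admissible) <- list(phase_centers, amp_centers)
  structure(
    list(phase_centers = phase_centers, amp_centers = amp_centers,
         phase_half_bw = phase_half_bw, amp_scale = amp_scale,
         window = window, methods = methods, n_bins = as.integer(n_bins),
         trim = trim, admissible = admissible),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "Comodulogram grid: %d phase centres (%g-%g Hz) x %d amplitude centres (%g-%g Hz)\n",
    length(x$phase_centers), min(x$phase_centers), max(x$phase_centers),
    length(x$amp_centers), min(x$amp_centers), max(x$amp_centers)))
  cat(sprintf("  phase bands +/- %g Hz, amplitude bands +/- %g x centre\n",
              x$phase_half_bw, x$amp_scale))
  if (!is.null(x$window))
    cat(sprintf("  analysis window %g to %g s\n", x$window[1], x$window[2]))
  cat("  methods:", paste(x$methods, collapse = ", "), "\n")
  if (!all(x$admissible))
    cat("  NOTE:", sum(!x$admissible), "cells flagged sideband-inadmissible\n")
  invisible(x)
}

# ---- analytic cache -------------------------------------------------------
# Everything the sweep needs, extracted once per trial series: per phase
# centre the unit phasors exp(1i * phase) and the phase-bin indices, per
# amplitude centre the envelope, its per-trial sum of squares, and the unit
# phasors of the demeaned envelope's own phase (for the PLV estimator).

analytic_cache <- function(trials, grid) {
  fs <- trials$fs
  trim <- grid$trim
  a0 <- extract_analytic(trials, design_phase_band(grid$phase_centers[1]),
                         trim = if (is.null(trim)) (if (trials$pad > 0) trials$pad else 0.5) else trim)
  trim_used <- a0$trim
  times <- a0$t0 + (seq_len(a0$n_samples) - 1) / fs
  win <- if (is.null(grid$window)) c(-Inf, Inf) else grid$window
  keep <- which(times >= win[1] & times <= win[2])
  if (length(keep) < 2)
    stop("analysis window contains fewer than 2 samples of the trimmed trial",
         call. = FALSE)

  need_plv <- "plv_cohen" %in% grid$methods
  need_kl <- "kl_tort" %in% grid$methods

  E_phase <- vector("list", length(grid$phase_centers))
  bin_idx <- if (need_kl) vector("list", length(grid$phase_centers)) else NULL
  for (p in seq_along(grid$phase_centers)) {
    a <- if (p == 1) a0 else
      extract_analytic(trials,
                       band_filter_spec(grid$phase_centers[p], grid$phase_half_bw),
                       trim = trim_used)
    ph <- a$phase[, keep, drop = FALSE]
    E_phase[[p]] <- exp(1i * ph)
    if (need_kl) bin_idx[[p]] <- matrix(phase_bin_index(ph, grid$n_bins),
                                        nrow = nrow(ph))
  }

  A <- vector("list", length(grid$amp_centers))
  ssqA <- vector("list", length(grid$amp_centers))
  E_env <- if (need_plv) vector("list", length(grid$amp_centers)) else NULL
  for (q in seq_along(grid$amp_centers)) {
    a <- extract_analytic(trials,
                          design_amplitude_band(grid$amp_centers[q], grid$amp_scale),
                          trim = trim_used)
    amp_full <- a$amplitude
    A[[q]] <- amp_full[, keep, drop = FALSE]
    ssqA[[q]] <- rowSums(A[[q]]^2)
    if (need_plv) {
      # envelope phase from the whole trimmed envelope (per trial, no
      # cross-trial concatenation), then restricted to the window
      ep <- t(apply(amp_full, 1, function(v)
        wrap_phase(Arg(analytic_signal(v - mean(v))))))
      E_env[[q]] <- exp(1i * ep[, keep, drop = FALSE])
    }
  }
  list(E_phase = E_phase, bin_idx = bin_idx, A = A, ssqA = ssqA,
       E_env = E_env, n = length(keep), n_trials = nrow(trials$data),
       trim = trim_used)
}

# per-trial KL MI for one cell given bin indices (trials x n) and amplitudes
kl_per_trial <- function(bins, amp, n_bins) {
  ntr <- nrow(bins)
  grp <- as.vector(bins) + n_bins * (rep(seq_len(ntr), times = ncol(bins)) - 1L)
  counts <- matrix(tabulate(grp, nbins = n_bins * ntr), n_bins, ntr)
  sums <- matrix(0, n_bins, ntr)
  rs <- rowsum(as.vector(amp), grp)
  sums[as.integer(rownames(rs))] <- rs
  ok <- colSums(counts == 0) == 0
  mi <- rep(NA_real_, ntr)
  if (any(ok)) {
    means <- sums[, ok, drop = FALSE] / counts[, ok, drop = FALSE]
    P <- sweep(means, 2, colSums(means), `/`)
    Pl <- ifelse(P > 0, P * log(P * n_bins), 0)
    mi[ok] <- colSums(Pl) / log(n_bins)
  }
  mi
}

#' Compute a phase-amplitude comodulogram
#'
#' Sweeps every (phase centre, amplitude centre) cell of the grid: extracts
#' the instantaneous phase for the narrow phase band and the amplitude
#' envelope for the scaled amplitude band, computes the modulation index of
#' every trial separately, and averages across trials to one value per cell
#' and estimator. Kullback-Leibler cells where a trial leaves a phase bin
#' empty contribute `NA` for that trial and are dropped from the average.
#'
#' @param trials a [trial_series()].
#' @param grid a [grid_spec()].
#' @param keep_trials if `TRUE`, the per-trial MI layers are returned in
#'   `per_trial` (trials x phase x amplitude array per method).
#' @param cache internal: a precomputed analytic cache, so
#'   [generate_surrogates()] can share the filtered series.
#' @return An object of class `comodulogram`: list with `mi` (named list of
#'   phase x amplitude matrices, one per method), optional `per_trial`,
#'   `grid`, `n_trials`, `condition`, `normalized = FALSE`.
#' @examples
#' \donttest{
#' ts <- simulate_pac_trials(simulation_spec(n_trials = 8, seed = 1))
#' cm <- compute_comodulogram(ts, grid_spec(phase_centers = 9:11,
#'                                          amp_centers = seq(50, 70, 10)))
#' summary(cm)
#' }
#' @export
compute_comodulogram <- function(trials, grid = grid_spec(),
                                 keep_trials = FALSE, cache = NULL) {
  stopifnot(inherits(trials, "trial_series"), inherits(grid, "grid_spec"))
  cc <- if (is.null(cache)) analytic_cache(trials, grid) else cache
  np <- length(grid$phase_centers)
  na <- length(grid$amp_centers)
  ntr <- cc$n_trials
  nw <- cc$n
  dn <- list(grid$phase_centers, grid$amp_centers)

  mi <- lapply(grid$methods, function(m)
    matrix(NA_real_, np, na, dimnames = dn))
  names(mi) <- grid$methods
  per_trial <- if (keep_trials)
    lapply(mi, function(m) array(NA_real_, c(ntr, np, na))) else NULL

  need_mvl <- any(c("mvl_canolty", "mvl_ozkurt") %in% grid$methods)
  for (p in seq_len(np)) {
    E <- cc$E_phase[[p]]
    for (q in seq_len(na)) {
      A <- cc$A[[q]]
      vals <- list()
      if (need_mvl) {
        S <- rowSums(A * E)
        if ("mvl_canolty" %in% grid$methods)
          vals$mvl_canolty <- Mod(S) / nw
        if ("mvl_ozkurt" %in% grid$methods)
          vals$mvl_ozkurt <- Mod(S) / (sqrt(nw) * sqrt(cc$ssqA[[q]]))
      }
      if ("plv_cohen" %in% grid$methods)
        vals$plv_cohen <- Mod(rowSums(E * Conj(cc$E_env[[q]]))) / nw
      if ("kl_tort" %in% grid$methods)
        vals$kl_tort <- kl_per_trial(cc$bin_idx[[p]], A, grid$n_bins)
      for (m in names(vals)) {
        mi[[m]][p, q] <- mean(vals[[m]], na.rm = TRUE)
        if (keep_trials) per_trial[[m]][, p, q] <- vals[[m]]
      }
    }
  }
  structure(
    list(mi = mi, per_trial = per_trial, grid = grid, n_trials = ntr,
         condition = trials$condition, normalized = FALSE),
    class = "comodulogram"
  )
}

#' @export
print.comodulogram <- function(x, ...) {
  cat(sprintf("%s comodulogram: %d x %d grid, %d trials, condition \"%s\"\n",
              if (x$normalized) "Surrogate-normalized" else "Raw",
              length(x$grid$phase_centers), length(x$grid$amp_centers),
              x$n_trials, x$condition))
  cat("  methods:", paste(names(x$mi), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.comodulogram <- function(object, ...) {
  print(object)
  for (m in names(object$mi)) {
    pk <- comodulogram_peak(object, m)
    cat(sprintf("  %s: peak %.4g at phase %g Hz, amplitude %g Hz\n",
                m, pk$value, pk$phase, pk$amp))
  }
  invisible(object)
}

#' Location of the comodulogram maximum
#'
#' @param x a `comodulogram`.
#' @param method which estimator's grid to inspect (default: first).
#' @return list with `phase`, `amp` (Hz) and `value` at the grid maximum.
#' @export
comodulogram_peak <- function(x, method = names(x$mi)[1]) {
  m <- x$mi[[method]]
  ij <- which(m == max(m, na.rm = TRUE), arr.ind = TRUE)[1, ]
  list(phase = x$grid$phase_centers[ij[1]],
       amp = x$grid$amp_centers[ij[2]],
       value = m[ij[1], ij[2]])
}

#' @export
plot.comodulogram <- function(x, methods = names(x$mi),
                              col = grDevices::hcl.colors(64, "viridis"),
                              ...) {
  old <- graphics::par(mfrow = c(1, length(methods)), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(old))
  for (m in methods) {
    graphics::image(x$grid$phase_centers, x$grid$amp_centers, x$mi[[m]],
                    col = col, xlab = "phase frequency (Hz)",
                    ylab = "amplitude frequency (Hz)", main = m, ...)
  }
  invisible(x)
}

# ---- surrogates -----------------------------------------------------------

# random derangement (permutation with no fixed point) by rejection
rderangement <- function(n) {
  if (n < 2) stop("cannot shuffle fewer than 2 trials", call. = FALSE)
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

#' Trial-shuffled surrogate ensemble
#'
#' Destroys the within-trial pairing of phase and amplitude by reassigning
#' the phase series across trials with a random derangement (no trial keeps
#' its own phase), recomputing the trial-averaged modulation index for every
#' grid cell, and repeating `n` times. The ensemble mean and standard
#' deviation per cell form the null reference used by [normalize_mi()].
#'
#' Internally the MI of every (amplitude trial i, phase trial j) pairing is
#' computed once per cell, so the 200 draws are indexing operations.
#'
#' @inheritParams compute_comodulogram
#' @param n number of surrogates.
#' @param seed RNG seed for reproducible draws (`NULL`: leave RNG alone).
#' @return An object of class `surrogate_ensemble`: list with `values`
#'   (named list per method of n x phase x amplitude arrays), `mean`, `sd`
#'   (named lists of matrices), `n_surrogates`, `seed`, `grid`.
#' @export
generate_surrogates <- function(trials, grid = grid_spec(), n = 200,
                                seed = NULL, cache = NULL) {
  stopifnot(inherits(trials, "trial_series"), inherits(grid, "grid_spec"))
  cc <- if (is.null(cache)) analytic_cache(trials, grid) else cache
  ntr <- cc$n_trials
  if (ntr < 2) stop("cannot shuffle fewer than 2 trials", call. = FALSE)
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  perms <- with_seed(seed,
                     t(vapply(seq_len(n), function(i) rderangement(ntr),
                              integer(ntr))))
  np <- length(grid$phase_centers)
  na <- length(grid$amp_centers)
  nw <- cc$n
  dn <- list(grid$phase_centers, grid$amp_centers)
  values <- lapply(grid$methods, function(m) array(NA_real_, c(n, np, na)))
  names(values) <- grid$methods
  pick <- cbind(rep(seq_len(ntr), n),
                as.vector(t(perms)),
                deparse.level = 0)
  surr_of <- function(pair_mi) {
    # pair_mi[i, j]: MI of amplitude trial i paired with phase trial j
    v <- matrix(pair_mi[pick], ntr, n)
    colMeans(v, na.rm = TRUE)
  }
  need_mvl <- any(c("mvl_canolty", "mvl_ozkurt") %in% grid$methods)
  need_kl <- "kl_tort" %in% grid$methods
  if (need_kl) {
    ind_big <- lapply(seq_len(np), function(p) {
      bins <- cc$bin_idx[[p]]
      Matrix::sparseMatrix(
        i = rep(seq_len(nw), each = ntr),
        j = as.vector(bins) + grid$n_bins * (rep(seq_len(ntr), times = nw) - 1L),
        x = 1,
        dims = c(nw, grid$n_bins * ntr))
    })
    # bins is trials x nw: as.vector goes down columns (trial fastest), so
    # row index of ind_big must advance with the sample index
  }
  for (p in seq_len(np)) {
    E <- cc$E_phase[[p]]
    tE <- t(E)
    if (need_kl) {
      IB <- ind_big[[p]]
      counts <- matrix(Matrix::colSums(IB), grid$n_bins, ntr)
      ok_j <- colSums(counts == 0) == 0
    }
    for (q in seq_len(na)) {
      A <- cc$A[[q]]
      if (need_mvl) {
        M <- Mod(A %*% tE)
        if ("mvl_canolty" %in% grid$methods)
          values$mvl_canolty[, p, q] <- surr_of(M / nw)
        if ("mvl_ozkurt" %in% grid$methods)
          values$mvl_ozkurt[, p, q] <-
            surr_of(M / (sqrt(nw) * sqrt(cc$ssqA[[q]])))
      }
      if ("plv_cohen" %in% grid$methods) {
        Mp <- Mod(Conj(cc$E_env[[q]]) %*% tE)
        values$plv_cohen[, p, q] <- surr_of(Mp / nw)
      }
      if (need_kl) {
        G <- as.matrix(A %*% IB)             # ntr x (n_bins * ntr) sums
        kl_pair <- matrix(NA_real_, ntr, ntr)
        for (j in which(ok_j)) {
          cols <- (j - 1L) * grid$n_bins + seq_len(grid$n_bins)
          means <- t(G[, cols, drop = FALSE]) / counts[, j]  # bins x i
          P <- sweep(means, 2, colSums(means), `/`)
          Pl <- ifelse(P > 0, P * log(P * grid$n_bins), 0)
          kl_pair[, j] <- colSums(Pl) / log(grid$n_bins)
        }
        values$kl_tort[, p, q] <- surr_of(kl_pair)
      }
    }
  }
  means <- lapply(values, function(v)
    matrix(apply(v, c(2, 3), mean), np, na, dimnames = dn))
  sds <- lapply(values, function(v)
    matrix(apply(v, c(2, 3), stats::sd), np, na, dimnames = dn))
  structure(
    list(values = values, mean = means, sd = sds, n_surrogates = n,
         seed = seed, grid = grid),
    class = "surrogate_ensemble"
  )
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf("Surrogate ensemble: %d trial-shuffled draws on a %d x %d grid\n",
              x$n_surrogates, length(x$grid$phase_centers),
              length(x$grid$amp_centers)))
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Normalize a comodulogram against its surrogate ensemble
#'
#' Converts each cell to a standardized score,
#' `(observed - surrogate mean) / surrogate sd`. Cells with zero surrogate
#' spread are undefined and returned as `NA` (with a warning).
#'
#' @param observed a `comodulogram` from [compute_comodulogram()].
#' @param surr a `surrogate_ensemble` from [generate_surrogates()] on the
#'   same grid.
#' @return a `comodulogram` with `normalized = TRUE`.
#' @export
normalize_mi <- function(observed, surr) {
  stopifnot(inherits(observed, "comodulogram"),
            inherits(surr, "surrogate_ensemble"))
  if (!identical(dim(observed$mi[[1]]), dim(surr$mean[[1]])))
    stop("observed and surrogate grids do not match", call. = FALSE)
  methods <- intersect(names(observed$mi), names(surr$mean))
  if (length(methods) == 0)
    stop("no common methods between observed and surrogate grids", call. = FALSE)
  out <- observed
  out$mi <- lapply(methods, function(m) {
    z <- (observed$mi[[m]] - surr$mean[[m]]) / surr$sd[[m]]
    bad <- surr$sd[[m]] == 0
    if (any(bad)) {
      warning(sum(bad), " cell(s) with zero surrogate spread set to NA")
      z[bad] <- NA_real_
    }
    z
  })
  names(out$mi) <- methods
  out$per_trial <- NULL
  out$normalized <- TRUE
  out
}
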