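# shared fixture builders for the suite

fs_default <- 1000

cosine_trials <- function(freq = 10, dur = 2.2, fs = fs_default, n_trials = 1,
                          amp = 1, pad = 0.5) {
  t <- (seq_len(round(dur * fs)) - 1) / fs
  trial_series(matrix(rep(amp * cos(2 * pi * freq * t), n_trials),
                      nrow = n_trials, byrow = TRUE),
               fs = fs, t0 = -pad, pad = pad)
}

# envelope-modulated carrier: carrier at f_c whose amplitude is `modulator`
modulated_trials <- function(modulator, f_c = 60, fs = fs_default, pad = 0.5) {
  t <- (seq_along(modulator) - 1) / fs
  trial_series(matrix(modulator * cos(2 * pi * f_c * t), 1),
               fs = fs, t0 = -pad, pad = pad)
}

noise_trials <- function(n_trials = 8, dur = 2.2, fs = fs_default, pad = 0.5,
                         seed = 1) {
  set.seed(seed)
  trial_series(matrix(rnorm(n_trials * round(dur * fs)), n_trials),
               fs = fs, t0 = -pad, pad = pad)
}

# dense uniform phases over full cycles, open at pi
uniform_phases <- function(n = 3600) seq(-pi, pi - 2 * pi / n, length.out = n)

# sawtooth oscillation: rising = slow ramp up, sharp drop
sawtooth_wave <- function(freq, dur, fs = fs_default, rising = TRUE) {
  t <- (seq_len(round(dur * fs)) - 1) / fs
  x <- 2 * ((t * freq) %% 1) - 1
  if (rising) x else -x
}
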