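#' Run configuration
#'
#' A single structured file (YAML) collects every tunable of a pipeline
#' run: the simulator specification, the comodulogram grid, surrogate and
#' permutation counts, significance levels, the seed and the output
#' directory. Unknown keys are rejected by name so a typo cannot silently
#' fall back to a default, and a config written with [write_run_config()]
#' reads back identically.
#'
#' @param path YAML file path.
#' @return `default_run_config()` and `read_run_config()` return a named
#'   list of class `run_config`.
#' @name run_config
NULL

config_template <- function() {
  list(
    seed = 1L,
    out_dir = ".",
    verbose = TRUE,
    simulation = list(fs = 1000, trial_len = 1.2, n_trials = 64L, fp = 10,
                      amp_band = c(50, 70), coupling = 1, snr_db = NULL,
                      alpha_amp = 1, gamma_amp = 0.5, pad = 0.5),
    grid = list(phase_centers = 7:13, amp_centers = seq(34, 100, 2),
                phase_half_bw = 1, amp_scale = 0.4,
                window = NULL, methods = mi_methods, n_bins = 18L,
                trim = NULL),
    surrogates = list(n = 200L),
    stats = list(n_perm = 1000L, cluster_alpha = 0.05, alpha = 0.05,
                 stat = "max_t"),
    power = list(freqs = c(1, 100), window = 0.5, step = 0.02, smoothing = 8),
    sinusoidality = list(phase_freqs = 7:13, broadband_cutoff = 40),
    study = list(lengths = c(0.1, 10, 0.1), n_seeds = 20L)
  )
}

#' @rdname run_config
#' @export
default_run_config <- function() {
  structure(config_template(), class = "run_config")
}

check_config_keys <- function(cfg, tmpl = config_template(), where = "") {
  unknown <- setdiff(names(cfg), names(tmpl))
  if (length(unknown) > 0)
    stop(sprintf("unknown config key%s%s: %s",
                 if (length(unknown) > 1) "s" else "",
                 if (nzchar(where)) paste0(" under \"", where, "\"") else "",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  for (k in names(cfg)) {
    if (is.list(tmpl[[k]]) && !is.null(names(tmpl[[k]])) && is.list(cfg[[k]]))
      check_config_keys(cfg[[k]], tmpl[[k]],
                        if (nzchar(where)) paste(where, k, sep = ".") else k)
  }
  invisible(cfg)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config file is not a YAML mapping", call. = FALSE)
  check_config_keys(cfg)
  merged <- utils::modifyList(config_template(), cfg)
  # modifyList drops NULL values; restore explicit NULL-able fields
  for (f in c("snr_db")) if (is.null(cfg$simulation[[f]]))
    merged$simulation[f] <- list(NULL)
  if (is.null(cfg$grid$window)) merged$grid["window"] <- list(NULL)
  if (is.null(cfg$grid$trim)) merged$grid["trim"] <- list(NULL)
  structure(merged, class = "run_config")
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_simulation_spec <- function(cfg) {
  s <- cfg$simulation
  simulation_spec(fs = s$fs, trial_len = s$trial_len, n_trials = s$n_trials,
                  fp = s$fp, amp_band = s$amp_band, coupling = s$coupling,
                  snr_db = s$snr_db, alpha_amp = s$alpha_amp,
                  gamma_amp = s$gamma_amp, pad = s$pad, seed = cfg$seed)
}

config_grid_spec <- function(cfg) {
  g <- cfg$grid
  grid_spec(phase_centers = g$phase_centers, amp_centers = g$amp_centers,
            phase_half_bw = g$phase_half_bw, amp_scale = g$amp_scale,
            window = g$window, methods = g$methods, n_bins = g$n_bins,
            trim = g$trim)
}
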