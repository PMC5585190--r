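#' Read and write trial series as delimited text
#'
#' The on-disk dialect is a plain delimited text file (tab or comma
#' separated) with one row per trial and a comment header carrying the
#' metadata:
#'
#' ```
#' # phaseamp trial series
#' # fs: 1000
#' # t0: -0.5
#' # condition: simulated
#' # pad: 0.5
#' ```
#'
#' The round trip is lossless: data to full double precision (17
#' significant digits), metadata exactly.
#'
#' @param path file path.
#' @param sep field separator: `"\t"` (default, `.tsv`) or `","` (`.csv`).
#' @return `read_trials()` returns a [trial_series()]; `write_trials()`
#'   returns `path` invisibly.
#' @examples
#' ts <- trial_series(matrix(rnorm(40), 4), fs = 100, t0 = -0.05, pad = 0.05)
#' f <- tempfile(fileext = ".tsv")
#' write_trials(ts, f)
#' all.equal(read_trials(f)$data, ts$data)
#' @name trials_io
NULL

#' @rdname trials_io
#' @param trials a [trial_series()].
#' @export
write_trials <- function(trials, path, sep = "\t") {
  stopifnot(inherits(trials, "trial_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# phaseamp trial series",
               sprintf("# fs: %.17g", trials$fs),
               sprintf("# t0: %.17g", trials$t0),
               sprintf("# condition: %s", trials$condition),
               sprintf("# pad: %.17g", trials$pad)), con)
  utils::write.table(format(trials$data, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, sep = sep, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname trials_io
#' @export
read_trials <- function(path, sep = "\t") {
  if (!file.exists(path))
    stop(sprintf("trial file not found: %s", path), call. = FALSE)
  lines <- readLines(path, n = 64)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(name, required = TRUE) {
    m <- grep(sprintf("^#\\s*%s:", name), hdr, value = TRUE)
    if (length(m) == 0) {
      if (required)
        stop(sprintf("malformed trial file %s: missing header field \"%s\"",
                     path, name), call. = FALSE)
      return(NULL)
    }
    sub(sprintf("^#\\s*%s:\\s*", name), "", m[1])
  }
  fs <- as.numeric(get_field("fs"))
  if (is.na(fs)) stop(sprintf("malformed trial file %s: field \"fs\" is not numeric",
                              path), call. = FALSE)
  t0 <- as.numeric(get_field("t0"))
  condition <- get_field("condition")
  pad <- as.numeric(get_field("pad"))
  data <- as.matrix(utils::read.table(path, sep = sep, comment.char = "#",
                                      header = FALSE))
  dimnames(data) <- NULL
  trial_series(data, fs = fs, t0 = t0, condition = condition, pad = pad)
}

#' Write a comodulogram as TSV plus a JSON sidecar
#'
#' Each method's grid goes to `<path stem>_<method>.tsv` (phase centres as
#' rows, amplitude centres as columns) and the run parameters (methods,
#' window, trial count, bandwidth rules, normalization flag, optional
#' surrogate count and seed) to `<path stem>.json`, so any published grid
#' is reproducible from its sidecar.
#'
#' @param x a `comodulogram`.
#' @param stem output path without extension.
#' @param extra named list merged into the JSON sidecar (e.g. surrogate
#'   parameters).
#' @return invisibly, the paths written.
#' @export
write_comodulogram <- function(x, stem, extra = list()) {
  stopifnot(inherits(x, "comodulogram"))
  paths <- character(0)
  for (m in names(x$mi)) {
    p <- paste0(stem, "_", m, ".tsv")
    utils::write.table(x$mi[[m]], p, sep = "\t", quote = FALSE,
                       row.names = x$grid$phase_centers,
                       col.names = x$grid$amp_centers)
    paths <- c(paths, p)
  }
  meta <- c(list(
    methods = names(x$mi),
    phase_centers = x$grid$phase_centers,
    amp_centers = x$grid$amp_centers,
    phase_half_bw = x$grid$phase_half_bw,
    amp_scale = x$grid$amp_scale,
    window = x$grid$window,
    n_trials = x$n_trials,
    condition = x$condition,
    normalized = x$normalized
  ), extra)
  jp <- paste0(stem, ".json")
  jsonlite::write_json(meta, jp, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, jp))
}

#' Read back one method grid written by [write_comodulogram()]
#' @param path a `_<method>.tsv` file.
#' @return numeric matrix with phase centres as rownames, amplitude centres
#'   as colnames.
#' @export
read_comodulogram_grid <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                              check.names = FALSE, row.names = 1))
}

#' Write a cluster test result as JSON
#'
#' Clusters are stored as column-major cell-index lists along with their
#' statistics, p values, the permutation parameters and seed; the t map is
#' included as a matrix.
#'
#' @param x a `cluster_test`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_cluster_result <- function(x, path) {
  stopifnot(inherits(x, "cluster_test"))
  out <- list(
    t_map = x$t_map,
    clusters = x$clusters,
    cluster_signs = x$cluster_signs,
    cluster_stats = x$cluster_stats,
    p_values = x$p_values,
    sig_mask = x$sig_mask,
    n_perm = x$n_perm,
    cluster_alpha = x$cluster_alpha,
    alpha = x$alpha,
    stat = x$stat,
    n_subjects = x$n_subjects,
    seed = x$seed
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' Write a trial-length study summary as TSV
#'
#' @param x a `trial_length_study`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_study <- function(x, path) {
  stopifnot(inherits(x, "trial_length_study"))
  utils::write.table(x$summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
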