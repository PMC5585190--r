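#' Paired (dependent-samples) t statistic
#'
#' Standard paired t test of two equal-length per-subject vectors, two
#' tailed. A difference vector with zero variance has no defined t
#' statistic; the result is then flagged (`flag = "zero_variance"`) with
#' `t = Inf` (or 0 when the differences are identically zero) and `p = NA`
#' rather than raising an error, so grid sweeps survive degenerate cells.
#'
#' @param a,b numeric vectors of per-subject values, equal length >= 2.
#' @return list with `t`, `df`, `p`, `mean_diff`, `flag` (`"ok"` or
#'   `"zero_variance"`).
#' @examples
#' paired_t(c(1, 2, 3, 4, 6), c(0, 1, 1, 2, 4))
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b))
    stop("`a` and `b` must have equal length", call. = FALSE)
  n <- length(a)
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  d <- a - b
  v <- stats::var(d)
  m <- mean(d)
  # variance at floating-point rounding scale counts as zero
  if (v <= (.Machine$double.eps * (abs(m) + 1))^2 * n) v <- 0
  if (v == 0) {
    return(list(t = if (m == 0) 0 else Inf * sign(m), df = n - 1, p = NA_real_,
                mean_diff = m, flag = "zero_variance"))
  }
  t <- m / sqrt(v / n)
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1),
       mean_diff = m, flag = "ok")
}

# vectorized paired t over columns of a subjects x cells difference matrix;
# zero-variance cells get t = 0 (they carry no evidence either way)
t_map <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  v <- (colSums(D^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  t <- ifelse(v == 0, 0, m / sqrt(v / n))
  t
}

# Connected components of supra-threshold cells on a np x na grid under
# 4-neighbour adjacency; positive and negative cells cluster separately.
# Returns a list of integer vectors of cell indices (column-major).
grid_clusters <- function(tmat, threshold) {
  np <- nrow(tmat)
  na <- ncol(tmat)
  state <- matrix(0L, np, na)
  state[tmat >= threshold] <- 1L
  state[tmat <= -threshold] <- -1L
  visited <- matrix(FALSE, np, na)
  clusters <- list()
  for (j in seq_len(na)) {
    for (i in seq_len(np)) {
      if (state[i, j] == 0L || visited[i, j]) next
      sgn <- state[i, j]
      stack <- list(c(i, j))
      visited[i, j] <- TRUE
      members <- integer(0)
      while (length(stack) > 0) {
        cur <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        members <- c(members, (cur[2] - 1L) * np + cur[1])
        for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
          ni <- cur[1] + d[1]; nj <- cur[2] + d[2]
          if (ni >= 1 && ni <= np && nj >= 1 && nj <= na &&
              !visited[ni, nj] && state[ni, nj] == sgn) {
            visited[ni, nj] <- TRUE
            stack[[length(stack) + 1L]] <- c(ni, nj)
          }
        }
      }
      clusters[[length(clusters) + 1L]] <- sort(members)
    }
  }
  clusters
}

cluster_statistic <- function(tvec, members, stat = c("max_t", "mass")) {
  stat <- match.arg(stat)
  if (stat == "max_t") max(abs(tvec[members])) else abs(sum(tvec[members]))
}

#' Cluster-based permutation comparison of comodulograms
#'
#' Compares two conditions across subjects with the non-parametric
#' cluster-level procedure of Maris & Oostenveld: a dependent-samples t
#' statistic per grid cell, grouping of cells exceeding the two-tailed
#' `cluster_alpha` t quantile into clusters of 4-adjacent same-sign cells,
#' a per-cluster statistic (by default the maximum absolute t within the
#' cluster; `"mass"` selects the summed-t alternative), and a null
#' distribution of the largest cluster statistic obtained by randomly
#' swapping condition labels within subjects (equivalently sign-flipping
#' the paired differences) `n_perm` times. A cluster's p value is the
#' proportion of permutations whose largest statistic is at least as large.
#'
#' @param grids_a,grids_b lists of per-subject comodulograms (either
#'   `comodulogram` objects with a single method or plain phase x amplitude
#'   matrices), equal length, matching dimensions.
#' @param n_perm number of label permutations.
#' @param cluster_alpha two-tailed significance level forming clusters.
#' @param alpha cluster-level significance threshold.
#' @param stat `"max_t"` (default) or `"mass"` cluster statistic.
#' @param seed RNG seed for the permutation draws.
#' @return An object of class `cluster_test`: list with `t_map`, `clusters`
#'   (list of cell-index vectors, column-major), `cluster_signs`,
#'   `cluster_stats`, `p_values`, `null_distribution`, `sig_mask` (logical
#'   matrix), and the parameters.
#' @examples
#' \donttest{
#' a <- replicate(8, matrix(rnorm(12), 3), simplify = FALSE)
#' b <- replicate(8, matrix(rnorm(12), 3), simplify = FALSE)
#' cluster_permutation_test(a, b, n_perm = 200, seed = 1)
#' }
#' @export
cluster_permutation_test <- function(grids_a, grids_b, n_perm = 1000,
                                     cluster_alpha = 0.05, alpha = 0.05,
                                     stat = c("max_t", "mass"), seed = NULL) {
  stat <- match.arg(stat)
  as_mat <- function(g) {
    if (inherits(g, "comodulogram")) {
      if (length(g$mi) != 1)
        stop("per-subject comodulograms must carry exactly one method; subset `$mi` first",
             call. = FALSE)
      g$mi[[1]]
    } else as.matrix(g)
  }
  A <- lapply(grids_a, as_mat)
  B <- lapply(grids_b, as_mat)
  if (length(A) != length(B))
    stop("conditions have different subject counts", call. = FALSE)
  ns <- length(A)
  if (ns < 2) stop("need at least 2 subjects", call. = FALSE)
  dm <- dim(A[[1]])
  if (!all(vapply(c(A, B), function(m) identical(dim(m), dm), TRUE)))
    stop("all per-subject grids must share dimensions", call. = FALSE)
  if (n_perm < 1) stop("`n_perm` must be at least 1", call. = FALSE)

  D <- t(vapply(seq_len(ns), function(s) as.vector(A[[s]] - B[[s]]),
                numeric(prod(dm))))
  tobs <- t_map(D)
  tmat <- matrix(tobs, dm[1], dm[2])
  tcrit <- stats::qt(1 - cluster_alpha / 2, df = ns - 1)
  clusters <- grid_clusters(tmat, tcrit)
  signs <- vapply(clusters, function(mb) sign(tobs[mb[1]]), 0)
  stats_obs <- vapply(clusters, function(mb)
    cluster_statistic(tobs, mb, stat), 0)

  # permutation null: largest cluster statistic under per-subject sign flips
  S <- with_seed(seed,
                 matrix(sample(c(-1, 1), n_perm * ns, replace = TRUE),
                        n_perm, ns))
  Mperm <- (S %*% D) / ns
  css <- colSums(D^2)
  null <- numeric(n_perm)
  for (k in seq_len(n_perm)) {
    mk <- Mperm[k, ]
    vk <- (css - ns * mk^2) / (ns - 1)
    vk[vk < 0] <- 0
    tk <- ifelse(vk == 0, 0, mk / sqrt(vk / ns))
    if (!any(abs(tk) >= tcrit)) next
    cl <- grid_clusters(matrix(tk, dm[1], dm[2]), tcrit)
    null[k] <- max(vapply(cl, function(mb)
      cluster_statistic(tk, mb, stat), 0))
  }

  p <- vapply(stats_obs, function(s) mean(null >= s), 0)
  sig <- matrix(FALSE, dm[1], dm[2])
  for (ci in which(p < alpha)) sig[clusters[[ci]]] <- TRUE
  dimnames(sig) <- dimnames(A[[1]])

  structure(
    list(t_map = tmat, clusters = clusters, cluster_signs = signs,
         cluster_stats = stats_obs, p_values = p, null_distribution = null,
         sig_mask = sig, n_perm = n_perm, cluster_alpha = cluster_alpha,
         alpha = alpha, stat = stat, n_subjects = ns, seed = seed),
    class = "cluster_test"
  )
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf(
    "Cluster permutation test: %d subjects, %d permutations, cluster-forming alpha %g\n",
    x$n_subjects, x$n_perm, x$cluster_alpha))
  if (length(x$clusters) == 0) {
    cat("  no supra-threshold clusters\n")
  } else {
    for (i in seq_along(x$clusters)) {
      cat(sprintf("  cluster %d: %d cells, sign %+d, %s = %.3f, p = %.4f%s\n",
                  i, length(x$clusters[[i]]), x$cluster_signs[i], x$stat,
                  x$cluster_stats[i], x$p_values[i],
                  if (x$p_values[i] < x$alpha) " *" else ""))
    }
  }
  invisible(x)
}
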