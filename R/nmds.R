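#' Weighted isotonic regression (pool-adjacent-violators)
#'
#' Least-squares monotone (non-decreasing) fit to a sequence: the classical
#' PAVA algorithm. This is the monotone-regression subroutine of [nmds()].
#'
#' @param y Numeric sequence to fit.
#' @param w Positive weights (default equal).
#' @return Numeric vector of the isotonic fit, same length as `y`.
#' @export
isotonic_fit <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (n == 0) return(numeric(0))
  if (length(w) != n || any(w <= 0)) stop("weights must be positive, length n")
  ## blocks as (value, weight, size) stacks
  val <- numeric(n); wt <- numeric(n); sz <- integer(n)
  m <- 0L
  for (i in seq_len(n)) {
    m <- m + 1L
    val[m] <- y[i]; wt[m] <- w[i]; sz[m] <- 1L
    while (m > 1L && val[m - 1L] > val[m]) {
      val[m - 1L] <- (wt[m - 1L] * val[m - 1L] + wt[m] * val[m]) /
        (wt[m - 1L] + wt[m])
      wt[m - 1L] <- wt[m - 1L] + wt[m]
      sz[m - 1L] <- sz[m - 1L] + sz[m]
      m <- m - 1L
    }
  }
  rep(val[seq_len(m)], sz[seq_len(m)])
}

## internal: lower-triangle vector of pairwise Euclidean distances
lower_dist <- function(conf) as.numeric(stats::dist(conf))

#' Kruskal stress-1 of a configuration against a dissimilarity matrix
#'
#' Recomputes `sqrt(sum((dhat - d)^2) / sum(d^2))` where `d` are the
#' configuration's Euclidean distances and `dhat` their isotonic fit in the
#' rank order of the dissimilarities (primary treatment of ties: within tied
#' dissimilarities, distances are taken in ascending order).
#'
#' @param coordinates Configuration matrix (samples x k).
#' @param D Dissimilarity matrix or `dist` object.
#' @return Scalar stress-1 in \[0, 1\].
#' @export
nmds_stress <- function(coordinates, D) {
  dvec <- as.numeric(stats::as.dist(D))
  d <- lower_dist(as.matrix(coordinates))
  ord <- order(dvec, d)
  dhat <- numeric(length(d))
  dhat[ord] <- isotonic_fit(d[ord])
  sqrt(sum((dhat - d)^2) / sum(d^2))
}

#' Nonmetric multidimensional scaling
#'
#' Kruskal's rank-based embedding, minimizing stress-1 by alternating monotone
#' regression (PAVA, primary tie treatment) of the configuration distances
#' onto the dissimilarity ranks with Guttman-transform configuration updates
#' (nonmetric SMACOF). The first restart starts from the classical
#' metric-scaling (principal coordinates) solution; further restarts start
#' from random Gaussian configurations. The best-of-restarts configuration is
#' returned, with the recorded stress trace non-increasing within the winning
#' restart.
#'
#' @param D Dissimilarity matrix or `dist` object.
#' @param k Embedding dimension (default 2).
#' @param max_iter Iterations per restart (default 300).
#' @param n_restarts Number of restarts including the metric start
#'   (default 20).
#' @param seed Optional integer seed for the random restarts.
#' @param tol Relative stress-change convergence tolerance (default 1e-6).
#' @return An object of class `nmds_config`: `coordinates` (samples x k),
#'   `stress`, `converged`, `n_restarts_used`, `stress_trace` of the winning
#'   restart.
#' @export
nmds <- function(D, k = 2L, max_iter = 300L, n_restarts = 20L, seed = NULL,
                 tol = 1e-6) {
  Dm <- as.matrix(stats::as.dist(D))
  n <- nrow(Dm)
  if (k < 1L) stop("k must be >= 1")
  if (n < k + 2L) stop("too few points for a ", k, "-dimensional embedding")
  dvec <- as.numeric(stats::as.dist(Dm))
  if (all(dvec == 0)) stop("degenerate dissimilarity matrix (all zero)")

  run_restart <- function(conf) {
    conf <- scale(conf, center = TRUE, scale = FALSE)
    trace <- numeric(0)
    converged <- FALSE
    prev_conf <- conf
    prev_stress <- Inf
    for (it in seq_len(max_iter)) {
      d <- lower_dist(conf)
      if (all(d == 0)) break
      ord <- order(dvec, d)
      dhat <- numeric(length(d))
      dhat[ord] <- isotonic_fit(d[ord])
      stress <- sqrt(sum((dhat - d)^2) / sum(d^2))
      if (stress > prev_stress + 1e-12) break  # keep the trace monotone
      trace <- c(trace, stress)
      if (is.finite(prev_stress) &&
          (prev_stress - stress) < tol * max(prev_stress, 1e-12)) {
        converged <- TRUE
        prev_conf <- conf
        prev_stress <- stress
        break
      }
      prev_conf <- conf
      prev_stress <- stress
      if (stress < 1e-12) { converged <- TRUE; break }
      ## Guttman transform with dhat as target distances
      ratio <- matrix(0, n, n)
      dm <- as.matrix(stats::dist(conf))
      hm <- matrix(0, n, n)
      hm[lower.tri(hm)] <- dhat
      hm <- hm + t(hm)
      nz <- dm > 0
      ratio[nz] <- hm[nz] / dm[nz]
      B <- -ratio
      diag(B) <- -rowSums(B)
      conf <- (B %*% conf) / n
      conf <- scale(conf, center = TRUE, scale = FALSE)
    }
    list(coordinates = prev_conf, stress = prev_stress, converged = converged,
         trace = trace)
  }

  metric_start <- suppressWarnings(stats::cmdscale(Dm, k = k))
  if (ncol(metric_start) < k) {
    metric_start <- cbind(metric_start,
                          matrix(0, n, k - ncol(metric_start)))
  }
  best <- NULL
  with_seed(if (is.null(seed)) 1L else seed, {
    for (r in seq_len(max(1L, n_restarts))) {
      start <- if (r == 1L) metric_start else
        matrix(stats::rnorm(n * k, sd = stats::sd(dvec) + 1e-9), n, k)
      res <- run_restart(start)
      if (is.null(best) || (is.finite(res$stress) && res$stress < best$stress)) {
        best <- res
      }
    }
  })
  rownames(best$coordinates) <- rownames(Dm)
  structure(
    list(coordinates = best$coordinates[, seq_len(k), drop = FALSE],
         stress = best$stress, converged = best$converged,
         n_restarts_used = as.integer(max(1L, n_restarts)),
         stress_trace = best$trace),
    class = "nmds_config"
  )
}

#' @export
print.nmds_config <- function(x, ...) {
  cat(sprintf("<nmds_config> %d points in %d dimensions, stress-1 %.4f%s (%d restarts)\n",
              nrow(x$coordinates), ncol(x$coordinates), x$stress,
              if (x$converged) "" else " [not converged]",
              x$n_restarts_used))
  invisible(x)
}
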