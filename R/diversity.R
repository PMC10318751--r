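#' Shannon and inverse Simpson diversity of one sample
#'
#' `shannon()` returns `H' = -sum(p_i * log(p_i))` over the positive
#' proportions `p_i = x_i / sum(x)` (natural log); `inv_simpson()` returns
#' `1 / sum(p_i^2)`. Both require at least one positive entry.
#'
#' @param abundances Non-negative abundance vector of one sample.
#' @return Scalar index value.
#' @export
shannon <- function(abundances) {
  p <- diversity_proportions(abundances)
  -sum(p * log(p))
}

#' @rdname shannon
#' @export
inv_simpson <- function(abundances) {
  p <- diversity_proportions(abundances)
  1 / sum(p^2)
}

diversity_proportions <- function(abundances) {
  x <- as.numeric(abundances)
  if (any(!is.finite(x)) || any(x < 0)) stop("abundances must be non-negative")
  tot <- sum(x)
  if (tot <= 0) stop("all-zero abundance vector")
  x[x > 0] / tot
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum U with midrank ties. When both groups have at most 8 observations
#' the p-value is exact, by full enumeration of all allocations of the pooled
#' (mid)ranks; otherwise the normal approximation with tie and continuity
#' correction is used. `U` is reported for the first group and satisfies
#' `U_a + U_b = n_a * n_b`.
#'
#' @param group_a,group_b Numeric value vectors, both non-empty.
#' @return A list with `U`, `p_value` and `method` (`"exact"` or
#'   `"normal_approx"`).
#' @export
mann_whitney_u <- function(group_a, group_b) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  na <- length(a); nb <- length(b)
  if (na < 1 || nb < 1) stop("both groups must be non-empty")
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  n <- na + nb
  if (na <= 8 && nb <= 8) {
    ## exact null distribution of U over all C(n, na) allocations of the
    ## observed (mid)ranks
    combs <- utils::combn(n, na)
    u_all <- colSums(matrix(r[combs], nrow = na)) - na * (na + 1) / 2
    eps <- 1e-9
    p_le <- mean(u_all <= U + eps)
    p_ge <- mean(u_all >= U - eps)
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(U = U, p_value = p, method = "exact"))
  }
  mu <- na * nb / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma <- sqrt(na * nb / 12 * ((n + 1) - tie_term))
  if (sigma == 0) return(list(U = U, p_value = 1, method = "normal_approx"))
  z <- U - mu
  z <- sign(z) * max(0, abs(z) - 0.5) / sigma  # continuity correction
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(U = U, p_value = p, method = "normal_approx")
}

#' Per-sample alpha diversity with a between-group rank test
#'
#' Computes the chosen index for every row of an abundance matrix and compares
#' the two populations with a two-sided Mann-Whitney U test.
#'
#' @param X Non-negative matrix, samples x features (counts or proportions).
#' @param population Two-level group labels per sample.
#' @param index `"shannon"` or `"inv_simpson"`.
#' @return An object of class `alpha_result`: `per_sample_index` (named),
#'   `index_name`, `group_test_statistic` (U), `group_test_pvalue`.
#' @export
alpha_diversity <- function(X, population, index = c("shannon", "inv_simpson")) {
  index <- match.arg(index)
  X <- as.matrix(X)
  population <- factor(as.character(population))
  stopifnot(nlevels(population) == 2L, nrow(X) == length(population))
  f <- if (index == "shannon") shannon else inv_simpson
  vals <- apply(X, 1, f)
  names(vals) <- rownames(X)
  lv <- levels(population)
  mw <- mann_whitney_u(vals[population == lv[1]], vals[population == lv[2]])
  structure(
    list(per_sample_index = vals, index_name = index,
         group_test_statistic = mw$U, group_test_pvalue = mw$p_value),
    class = "alpha_result"
  )
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(a, b) = sum(|x_a - x_b|) / sum(x_a + x_b)` between sample rows;
#' symmetric with zero diagonal, entries in \[0, 1\]. Bray-Curtis is not a
#' metric (the triangle inequality can fail).
#'
#' @param X Non-negative matrix, samples x features; no all-zero rows.
#' @return A [stats::dist] object.
#' @export
bray_curtis <- function(X) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("negative entries are not allowed")
  if (any(rowSums(X) == 0)) stop("all-zero sample row")
  n <- nrow(X)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (jj in (i + 1):n) {
      d[i, jj] <- d[jj, i] <- sum(abs(X[i, ] - X[jj, ])) /
        sum(X[i, ] + X[jj, ])
    }
  }
  rownames(d) <- colnames(d) <- rownames(X)
  stats::as.dist(d)
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Partitions the total sum of squared dissimilarities into between- and
#' within-group components (the Gower identity `SS = sum(d^2)/n` per block)
#' and reports the pseudo-F statistic
#' `F = (SS_between/(g-1)) / (SS_within/(n-g))` with a permutation p-value
#' `(1 + #{F_perm >= F_obs}) / (1 + n_permutations)` obtained by relabeling
#' samples. With a coordinate matrix as input, Euclidean distances are used
#' (the usual way to test group separation on the first two ordination
#' dimensions); a `dist` object (e.g. Bray-Curtis) is used as-is.
#'
#' @param x A `dist` object or a numeric coordinate matrix (samples x k).
#' @param labels Two-level group labels.
#' @param n_permutations Number of random permutations (default 999); a
#'   warning is issued under 99.
#' @param seed Optional integer seed for the permutation stream.
#' @param exhaustive If `TRUE`, enumerate all distinct label assignments
#'   instead of sampling (feasible for small n); the p-value is then exact.
#' @return An object of class `permanova_result`: `pseudo_f`, `p_value`,
#'   `n_permutations`, `ss_between`, `ss_within`, `df`.
#' @export
permanova <- function(x, labels, n_permutations = 999L, seed = NULL,
                      exhaustive = FALSE) {
  labels <- factor(as.character(labels))
  if (nlevels(labels) != 2L) stop("two groups required")
  if (any(table(labels) < 2L)) stop("need at least 2 samples per group")
  D2 <- if (inherits(x, "dist")) as.matrix(x)^2 else
    as.matrix(stats::dist(as.matrix(x)))^2
  n <- nrow(D2)
  if (n != length(labels)) stop("labels must match the number of samples")
  if (!exhaustive && n_permutations < 99) {
    warning("fewer than 99 permutations gives poor p-value resolution")
  }
  n1 <- sum(labels == levels(labels)[1]); n2 <- n - n1
  tot <- sum(D2)
  ss_total <- tot / (2 * n)

  ## SS_within for group-1 membership indicator z (0/1 vector)
  ss_within_of <- function(z) {
    q1 <- as.numeric(t(z) %*% D2 %*% z)          # 2 * sum_{i<j in g1} d^2
    u <- sum(D2 %*% z)                           # 1' D2 z
    q2 <- tot - 2 * u + q1
    q1 / (2 * n1) + q2 / (2 * n2)
  }
  z_obs <- as.numeric(labels == levels(labels)[1])
  ssw <- ss_within_of(z_obs)
  ssb <- ss_total - ssw
  f_of <- function(ssw) {
    if (ssw <= .Machine$double.eps * tot || tot == 0) return(NA_real_)
    ((ss_total - ssw) / 1) / (ssw / (n - 2))
  }
  f_obs <- f_of(ssw)
  if (!is.finite(f_obs)) {
    ## degenerate: no within-group variation (or no variation at all)
    f_obs <- if (ss_total <= .Machine$double.eps) 0 else Inf
  }
  if (ss_total <= .Machine$double.eps) {
    return(structure(list(pseudo_f = 0, p_value = 1,
                          n_permutations = 0L, ss_between = 0, ss_within = 0,
                          df = c(between = 1L, within = n - 2L)),
                     class = "permanova_result"))
  }

  if (exhaustive) {
    combs <- utils::combn(n, n1)
    Z <- matrix(0, n, ncol(combs))
    Z[cbind(as.vector(combs), rep(seq_len(ncol(combs)), each = n1))] <- 1
  } else {
    Z <- with_seed(if (is.null(seed)) stats::runif(1, 1, 2^31 - 2) else seed, {
      vapply(seq_len(n_permutations), function(i) sample(z_obs),
             numeric(n))
    })
  }
  ## vectorized within-group sums over all permutations
  DZ <- D2 %*% Z
  q1 <- colSums(DZ * Z)
  u <- colSums(DZ)
  q2 <- tot - 2 * u + q1
  ssw_perm <- q1 / (2 * n1) + q2 / (2 * n2)
  f_perm <- ifelse(ssw_perm <= .Machine$double.eps * tot, Inf,
                   (ss_total - ssw_perm) / (ssw_perm / (n - 2)))
  if (exhaustive) {
    p <- mean(f_perm >= f_obs - 1e-12)
  } else {
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + length(f_perm))
  }
  structure(
    list(pseudo_f = f_obs, p_value = p,
         n_permutations = as.integer(ncol(Z)), ss_between = ssb,
         ss_within = ssw, df = c(between = 1L, within = n - 2L)),
    class = "permanova_result"
  )
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("<permanova_result> pseudo-F %.3f, p = %.4g (%d permutations)\n",
              x$pseudo_f, x$p_value, x$n_permutations))
  invisible(x)
}
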