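# Fixtures and independent oracles shared across the suite.

# Scaled feature matrix with planted group differences, built directly from
# normals (bypassing the compositional machinery) for fast PLS-DA/Bayes tests.
# Planted columns 1..n_diff carry a raw group-mean difference of `effect`
# within-group SDs; columns are then auto-scaled like pipeline input.
make_scaled_matrix <- function(n1 = 34, n2 = 28, p = 200, n_diff = 30,
                               effect = 1, seed = 1) {
  set.seed(seed)
  n <- n1 + n2
  X <- matrix(rnorm(n * p), n, p)
  if (n_diff > 0) {
    sgn <- rep_len(c(1, -1), n_diff)
    X[seq_len(n1), seq_len(n_diff)] <- X[seq_len(n1), seq_len(n_diff)] +
      matrix(effect * sgn, n1, n_diff, byrow = TRUE)
  }
  colnames(X) <- sprintf("V%03d", seq_len(p))
  X <- scale(X)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  list(X = X, y = factor(rep(c("pop1", "pop2"), c(n1, n2))),
       planted = colnames(X)[seq_len(n_diff)])
}

# Right-inverse via SVD, to map score-space points back to feature space.
MASS_less_ginv <- function(m) {
  s <- svd(m)
  s$v %*% diag(1 / s$d, length(s$d)) %*% t(s$u)
}

# Reorder a count table's feature columns (keeps metadata in sync).
subset_ct_for_test <- function(tab, perm) {
  count_table(tab$counts[, perm], tab$population,
              feature_ids = tab$feature_ids[perm])
}

# Closed-form flat-prior posterior of the group difference:
# delta | y ~ t_{n-4}(center = ybar1 - ybar2,
#                     scale^2 = SSE/(n-4) * (1/n1 + 1/n2)).
analytic_delta_posterior <- function(y, z) {
  n <- length(y); n1 <- sum(z); n2 <- n - n1
  center <- mean(y[z == 1]) - mean(y[z == 0])
  fit <- stats::lm(y ~ z)
  sse <- sum(stats::resid(fit)^2)
  df <- n - 4
  scale <- sqrt(sse / df * (1 / n1 + 1 / n2))
  list(center = center, scale = scale, df = df,
       post_sd = scale * sqrt(df / (df - 2)),
       p_positive = stats::pt(center / scale, df))
}

# Brute-force isotonic regression oracle: enumerate all partitions of 1..n
# into consecutive blocks, fit blockwise means, keep the feasible
# (non-decreasing) fit with minimal weighted SSE. Valid for small n.
brute_isotonic <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  best <- NULL; best_sse <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    fit <- numeric(n)
    for (b in seq_len(length(bounds) - 1)) {
      idx <- (bounds[b] + 1):bounds[b + 1]
      fit[idx] <- sum(w[idx] * y[idx]) / sum(w[idx])
    }
    if (is.unsorted(fit)) next
    sse <- sum(w * (y - fit)^2)
    if (sse < best_sse - 1e-12) { best_sse <- sse; best <- fit }
  }
  best
}

# Brute-force two-group PERMANOVA oracle on a small coordinate matrix:
# classical ANOVA sums of squares per label split, exhaustive p-value.
brute_permanova <- function(coords, labels) {
  coords <- as.matrix(coords)
  labels <- factor(labels)
  n <- nrow(coords); n1 <- sum(labels == levels(labels)[1])
  f_of <- function(lab) {
    ssw <- 0
    for (lv in unique(lab)) {
      sub <- coords[lab == lv, , drop = FALSE]
      ssw <- ssw + sum(sweep(sub, 2, colMeans(sub))^2)
    }
    sst <- sum(sweep(coords, 2, colMeans(coords))^2)
    ((sst - ssw) / 1) / (ssw / (n - 2))
  }
  f_obs <- f_of(as.character(labels))
  combs <- utils::combn(n, n1)
  f_all <- apply(combs, 2, function(idx) {
    lab <- rep("b", n); lab[idx] <- "a"; f_of(lab)
  })
  list(f = f_obs, p = mean(f_all >= f_obs - 1e-12))
}
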