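#' MCMC settings for the two-group Gibbs sampler
#'
#' Defaults follow the protocol the package implements: four chains of 50,000
#' iterations with a thinning lag of 10 and a burn-in of 1,000 iterations,
#' under flat priors. Tests and the pipeline scale the chain length down; the
#' convergence bound (split R-hat < 1.05) is checked regardless.
#'
#' @param chains Number of chains (>= 2, required by R-hat).
#' @param iterations Iterations per chain.
#' @param thinning_lag Keep every `thinning_lag`-th post-burn-in draw.
#' @param burn_in Discarded initial iterations per chain.
#' @param seed Integer seed.
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(chains = 4L, iterations = 50000L, thinning_lag = 10L,
                          burn_in = 1000L, seed = 1L) {
  s <- structure(
    list(chains = as.integer(chains), iterations = as.integer(iterations),
         thinning_lag = as.integer(thinning_lag),
         burn_in = as.integer(burn_in), seed = as.integer(seed)),
    class = "mcmc_settings"
  )
  stopifnot(s$chains >= 2, s$thinning_lag >= 1, s$burn_in >= 0,
            s$burn_in < s$iterations)
  s
}

#' Gibbs sampler for a flat-prior two-group normal comparison
#'
#' Model: `y_i = mu + delta * I(group_i == level1) + e_i`, `e_i ~ N(0,
#' sigma^2)`, with improper uniform priors on `(mu, delta)` and a flat prior
#' on `sigma^2` (the full conditionals are proper for n >= 5). Per iteration,
#' `(mu, delta)` are drawn jointly from their bivariate-normal full
#' conditional and `sigma^2` from its inverse-gamma full conditional; `delta`
#' is the difference (group level 1 minus level 2). Under these priors the
#' marginal posterior of `delta` is a Student-t with `n - 4` degrees of
#' freedom centered at the difference of group means — the closed form the
#' test suite checks the sampler against.
#'
#' @param y Numeric per-sample values of one feature.
#' @param labels Two-level group labels (level order of `factor(labels)`
#'   defines the sign of `delta`).
#' @param settings An [mcmc_settings()] object.
#' @return An object of class `gibbs_chains`: a list of per-chain matrices of
#'   thinned post-burn-in draws with columns `mu`, `delta`, `sigma2`, plus the
#'   settings and group levels.
#' @export
gibbs_two_group <- function(y, labels, settings = mcmc_settings()) {
  y <- as.numeric(y)
  labels <- factor(as.character(labels))
  if (nlevels(labels) != 2L) stop("two groups required")
  if (any(table(labels) < 2L)) stop("need at least 2 samples per group")
  n <- length(y)
  if (n < 5L) stop("need n >= 5 for proper full conditionals")
  z <- as.numeric(labels == levels(labels)[1])
  n1 <- sum(z)
  ## fixed regression quantities: X = [1, z]
  XtX <- matrix(c(n, n1, n1, n1), 2, 2)
  XtXinv <- solve(XtX)
  L <- t(chol(XtXinv))
  beta_hat <- XtXinv %*% c(sum(y), sum(y * z))
  sum_y2 <- sum(y^2); sum_y <- sum(y); sum_yz <- sum(y * z)

  C <- settings$chains
  keep_idx <- seq(settings$burn_in + settings$thinning_lag,
                  settings$iterations, by = settings$thinning_lag)
  n_keep <- length(keep_idx)
  if (n_keep < 2L) stop("settings keep fewer than 2 draws per chain")
  out <- array(NA_real_, c(n_keep, 3, C),
               dimnames = list(NULL, c("mu", "delta", "sigma2"), NULL))

  with_seed(settings$seed, {
    ## overdispersed starts around the data scale
    mu <- rep(mean(y), C) + stats::rnorm(C, 0, stats::sd(y) + 1e-8)
    delta <- stats::rnorm(C, 0, stats::sd(y) + 1e-8)
    sigma2 <- stats::var(y) * stats::runif(C, 0.5, 2)
    krow <- rep(0L, C)
    for (it in seq_len(settings$iterations)) {
      ## (mu, delta) | sigma2: N(beta_hat, sigma2 * (X'X)^-1), all chains
      z1 <- stats::rnorm(C); z2 <- stats::rnorm(C)
      s <- sqrt(sigma2)
      mu <- beta_hat[1] + s * (L[1, 1] * z1)
      delta <- beta_hat[2] + s * (L[2, 1] * z1 + L[2, 2] * z2)
      ## sigma2 | mu, delta: flat prior on sigma2 -> IG(n/2 - 1, SSE/2)
      sse <- sum_y2 - 2 * (mu * sum_y + delta * sum_yz) + n * mu^2 +
        2 * mu * delta * n1 + delta^2 * n1
      sigma2 <- sse / (2 * stats::rgamma(C, shape = n / 2 - 1, rate = 1))
      if (it > settings$burn_in &&
          (it - settings$burn_in) %% settings$thinning_lag == 0L) {
        krow <- krow + 1L
        for (cc in seq_len(C)) {
          out[krow[cc], , cc] <- c(mu[cc], delta[cc], sigma2[cc])
        }
      }
    }
  })
  structure(
    list(chains = lapply(seq_len(C), function(cc) out[, , cc]),
         settings = settings, group_levels = levels(labels),
         n = c(n1 = n1, n2 = n - n1)),
    class = "gibbs_chains"
  )
}

#' @export
print.gibbs_chains <- function(x, ...) {
  cat("<gibbs_chains>", length(x$chains), "chains x", nrow(x$chains[[1]]),
      "thinned draws (delta =", x$group_levels[1], "-", x$group_levels[2],
      ")\n")
  invisible(x)
}

#' Split-chain potential scale reduction factor (R-hat)
#'
#' Each chain is split in half (dropping the last draw of odd-length chains),
#' then the classical between/within-chain variance ratio is computed over the
#' split chains: `R-hat = sqrt(((m-1)/m * W + B/m) / W)` with `m` the split
#' length. Values near 1 indicate between-chain agreement; the conventional
#' convergence bound used throughout the package is 1.05.
#'
#' @param chains A numeric matrix (draws x chains), a list of equal-length
#'   numeric vectors, or a `gibbs_chains` object (then `parameter` selects the
#'   column).
#' @param parameter Parameter name for `gibbs_chains` input (default
#'   `"delta"`).
#' @return Scalar R-hat.
#' @export
rhat <- function(chains, parameter = "delta") {
  if (inherits(chains, "gibbs_chains")) {
    chains <- vapply(chains$chains, function(m) m[, parameter],
                     numeric(nrow(chains$chains[[1]])))
  }
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  if (ncol(chains) < 2L) stop("R-hat needs at least 2 chains")
  n <- nrow(chains)
  if (n < 10L) stop("chains too short for a split R-hat (need >= 10 draws)")
  half <- floor(n / 2)
  split <- cbind(chains[seq_len(half), , drop = FALSE],
                 chains[half + seq_len(half), , drop = FALSE])
  m <- ncol(split)
  W <- mean(apply(split, 2, stats::var))
  if (!is.finite(W) || W <= 0) {
    stop("zero within-chain variance: R-hat undefined (degenerate chains)")
  }
  B <- half * stats::var(colMeans(split))
  var_plus <- (half - 1) / half * W + B / half
  sqrt(var_plus / W)
}

## internal: narrowest interval containing `prob` of the draws
hpd_interval <- function(draws, prob = 0.95) {
  s <- sort(draws)
  k <- length(s)
  m <- max(1L, ceiling(prob * k))
  if (m >= k) return(c(lower = s[1], upper = s[k]))
  starts <- seq_len(k - m)
  widths <- s[starts + m] - s[starts]
  i <- which.min(widths)
  c(lower = s[i], upper = s[i + m])
}

#' Summarize a posterior of the group difference
#'
#' Produces the reporting quantities of the screen: posterior mean difference
#' in units of the feature's SD, `P0` — the posterior probability that the
#' difference is greater than zero if its mean is positive, or less than zero
#' if negative — the narrowest 95% highest-posterior-density interval, and the
#' relevance flag `|mean| > sd_threshold & P0 > p0_threshold`.
#'
#' @param samples Numeric vector of posterior draws of the difference, or a
#'   `gibbs_chains` object (pooled `delta` draws are used).
#' @param feature_sd The feature's SD used to express the difference in SD
#'   units; 1 for auto-scaled input (the pipeline's case).
#' @param sd_threshold,p0_threshold Relevance cutoffs (defaults 0.5 and 0.9).
#' @param feature_id Optional identifier carried into the summary.
#' @return An object of class `posterior_summary`: `feature_id`,
#'   `mean_diff_sd_units`, `p0` (in \[0.5, 1\]), `hpd95` (length-2 vector, on
#'   the SD-unit scale), `relevant`.
#' @export
summarize_posterior <- function(samples, feature_sd = 1, sd_threshold = 0.5,
                                p0_threshold = 0.9, feature_id = NA_character_) {
  if (inherits(samples, "gibbs_chains")) {
    samples <- unlist(lapply(samples$chains, function(m) m[, "delta"]))
  }
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("empty sample set")
  if (!is.finite(feature_sd) || feature_sd <= 0) stop("feature_sd must be > 0")
  d <- samples / feature_sd
  mean_diff <- mean(d)
  p_pos <- mean(d > 0)
  p0 <- max(p_pos, 1 - p_pos)
  structure(
    list(feature_id = feature_id, mean_diff_sd_units = mean_diff, p0 = p0,
         hpd95 = hpd_interval(d, 0.95),
         relevant = abs(mean_diff) > sd_threshold && p0 > p0_threshold),
    class = "posterior_summary"
  )
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("<posterior_summary> %s: meanDiff %.3f SD, P0 %.3f, HPD95 [%.3f, %.3f]%s\n",
              x$feature_id, x$mean_diff_sd_units, x$p0, x$hpd95[1], x$hpd95[2],
              if (x$relevant) " *relevant*" else ""))
  invisible(x)
}

#' Bayesian relevance screen over a selected feature set
#'
#' Runs the flat-prior Gibbs comparison feature by feature on the columns of a
#' (typically PLS-selected, auto-scaled) matrix, checks split R-hat
#' convergence of the difference parameter, and summarizes each posterior.
#' Features with R-hat at or above `rhat_limit` are flagged non-converged and
#' excluded from the relevant set; a failure in one feature does not abort the
#' screen. Output is sorted by decreasing `|mean_diff_sd_units|`.
#'
#' @param X Numeric matrix (samples x features) of auto-scaled values.
#' @param labels Two-level group labels (difference = level 1 minus level 2).
#' @param settings [mcmc_settings()]; per-feature chains get distinct seeds
#'   derived from `settings$seed`.
#' @param sd_threshold,p0_threshold Relevance cutoffs (defaults 0.5, 0.9).
#' @param rhat_limit Convergence bound (default 1.05).
#' @param feature_sds Optional per-feature SDs for unscaled input (default 1).
#' @return A data frame of class `bayes_screen` with columns `feature_id`,
#'   `mean_diff_sd_units`, `p0`, `hpd95_lower`, `hpd95_upper`, `rhat`,
#'   `converged`, `relevant`.
#' @export
run_bayes_screen <- function(X, labels, settings = mcmc_settings(),
                             sd_threshold = 0.5, p0_threshold = 0.9,
                             rhat_limit = 1.05, feature_sds = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (is.null(feature_sds)) feature_sds <- rep(1, ncol(X))
  rows <- lapply(seq_len(ncol(X)), function(jf) {
    st <- settings
    st$seed <- derive_seed(settings$seed, jf)
    res <- tryCatch({
      g <- gibbs_two_group(X[, jf], labels, st)
      r <- rhat(g, "delta")
      s <- summarize_posterior(g, feature_sd = feature_sds[jf],
                               sd_threshold = sd_threshold,
                               p0_threshold = p0_threshold,
                               feature_id = colnames(X)[jf])
      conv <- r < rhat_limit
      data.frame(feature_id = s$feature_id,
                 mean_diff_sd_units = s$mean_diff_sd_units, p0 = s$p0,
                 hpd95_lower = s$hpd95[1], hpd95_upper = s$hpd95[2],
                 rhat = r, converged = conv,
                 relevant = s$relevant && conv)
    }, error = function(e) {
      warning("feature ", colnames(X)[jf], " failed: ", conditionMessage(e))
      data.frame(feature_id = colnames(X)[jf],
                 mean_diff_sd_units = NA_real_, p0 = NA_real_,
                 hpd95_lower = NA_real_, hpd95_upper = NA_real_,
                 rhat = NA_real_, converged = FALSE, relevant = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$mean_diff_sd_units)), ]
  rownames(out) <- NULL
  class(out) <- c("bayes_screen", "data.frame")
  out
}

## internal: derive a child seed from a root seed, staying inside 32-bit range
derive_seed <- function(root, index) {
  as.integer((as.numeric(root) * 48271 + as.numeric(index) * 7919) %%
               2147483647)
}
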