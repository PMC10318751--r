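test_that("PLS factorization identities hold on random fits", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 30; p <- 12
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("V", 1:p)))
    y <- rep(c("a", "b"), c(16, 14))
    fit <- fit_plsda(X, y, 5)
    # scores T = Xc W (P'W)^-1 reproduces stored scores
    Xc <- sweep(X, 2, fit$x_means)
    expect_equal(unname(Xc %*% fit$rotation), unname(fit$x_scores),
                 tolerance = 1e-8)
    # successive score vectors mutually orthogonal
    g <- crossprod(fit$x_scores)
    expect_lt(max(abs(g[upper.tri(g)])) / max(diag(g)), 1e-8)
    expect_true(all(fit$explained_y_variance >= 0))
  }
})

test_that("full-rank PLS-DA reproduces least-squares dummy regression", {
  set.seed(4)
  n <- 20; p <- 6
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("V", 1:p)))
  y <- rep(c("a", "b"), each = 10)
  fit <- fit_plsda(X, y, p)
  expect_equal(fit$n_components, p)
  # cumulative Y-hat from the PLS factorization
  yhat_pls <- fit$x_scores %*% t(fit$y_loadings)
  Yc <- scale(cbind(y == "a", y == "b"), scale = FALSE)
  yhat_ls <- stats::lm.fit(scale(X, scale = FALSE), Yc)$fitted.values
  expect_equal(unname(yhat_pls), unname(yhat_ls), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("separable clouds classify perfectly with one component", {
  set.seed(2)
  X <- rbind(matrix(rnorm(40, mean = 0, sd = 0.3), 20, 2),
             matrix(rnorm(40, mean = 5, sd = 0.3), 20, 2))
  colnames(X) <- c("f1", "f2")
  y <- rep(c("a", "b"), each = 20)
  fit <- fit_plsda(X, y, 1)
  expect_equal(balanced_error_rate(y, predict(fit, X)), 0)
})

test_that("label-independent y gives a null-level fit", {
  # oracle values frozen from a 30-replicate Monte-Carlo run of this exact
  # generator: mean training accuracy 0.544 (range 0.51-0.59), mean explained
  # Y variance of component 1 below 0.01
  set.seed(10)
  accs <- replicate(10, {
    X <- matrix(rnorm(500 * 5), 500, 5, dimnames = list(NULL, paste0("V", 1:5)))
    y <- sample(rep(c("a", "b"), 250))
    fit <- fit_plsda(X, y, 3)
    c(mean(predict(fit, X) == y), fit$explained_y_variance[1])
  })
  expect_gt(mean(accs[1, ]), 0.45)
  expect_lt(mean(accs[1, ]), 0.62)
  expect_lt(max(accs[2, ]), 0.05)
})

test_that("prediction is Mahalanobis nearest-centroid with sorted-order ties", {
  set.seed(6)
  X <- rbind(matrix(rnorm(30, 0), 15, 2), matrix(rnorm(30, 3), 15, 2))
  colnames(X) <- c("f1", "f2")
  y <- rep(c("a", "b"), each = 15)
  fit <- fit_plsda(X, y, 2)
  # a training sample placed exactly at each centroid classifies to its class
  mh <- microdiscrim:::score_mahalanobis_model(fit, 2)
  inv_rot <- MASS_less_ginv(fit$rotation)
  for (k in 1:2) {
    x_at <- matrix(mh$centroids[k, ], 1, 2) %*% inv_rot + fit$x_means
    expect_equal(as.character(predict(fit, x_at)), fit$classes[k])
  }
  # exactly equidistant point: tie goes to the first class in sorted order
  mid <- matrix(colMeans(mh$centroids), 1) %*% inv_rot + fit$x_means
  expect_equal(as.character(predict(fit, mid)), "a")
})

test_that("with identity score covariance prediction is nearest-centroid", {
  # craft a fit whose pooled within-class score covariance is the identity:
  # orthonormalized within-class scores
  set.seed(7)
  n_per <- 20; k <- 3
  make_block <- function(center) {
    Z <- matrix(rnorm(n_per * k), n_per, k)
    Z <- scale(Z, scale = FALSE)
    Z <- Z %*% solve(chol(crossprod(Z) / (n_per - 1)))
    sweep(Z, 2, center, "+")
  }
  c1 <- c(1, 0, 0); c2 <- c(-1, 0.5, 0)
  scores <- rbind(make_block(c1), make_block(c2))
  y <- factor(rep(c("a", "b"), each = n_per))
  fit <- structure(
    list(n_components = k, x_scores = scores, y = y, classes = c("a", "b"),
         rotation = diag(k), x_means = rep(0, k),
         feature_ids = paste0("V", 1:k)),
    class = "plsda_fit")
  mh <- microdiscrim:::score_mahalanobis_model(fit, k)
  # pooled covariance is (2(n-1)I)/(2n-2) = I by construction
  expect_equal(unname(mh$cov), diag(k), tolerance = 1e-10)
  Xnew <- matrix(rnorm(100 * k), 100, k)
  pred <- predict(fit, Xnew)
  cent <- mh$centroids
  euclid <- apply(Xnew, 1, function(x) {
    which.min(c(sum((x - cent[1, ])^2), sum((x - cent[2, ])^2)))
  })
  expect_equal(as.character(pred), c("a", "b")[euclid])
})

test_that("balanced error rate matches hand-computed confusion tables", {
  expect_equal(balanced_error_rate(c("a", "a", "b", "b"),
                                   c("a", "a", "b", "b")), 0)
  expect_equal(balanced_error_rate(rep(c("a", "b"), each = 10),
                                   rep("a", 20)), 0.5)
  truth <- rep(c("a", "b"), c(10, 40))
  pred <- truth
  pred[1] <- "b"            # 1 error in 10
  pred[11:14] <- "a"        # 4 errors in 40
  expect_equal(balanced_error_rate(truth, pred), 0.1)
  expect_error(balanced_error_rate(rep("a", 4), rep("a", 4)), "both classes")
  expect_error(balanced_error_rate(c("a", "b"), "a"), "equal length")
})

test_that("cross-validation is deterministic and tracks signal strength", {
  null_case <- make_scaled_matrix(20, 20, p = 10, n_diff = 0, seed = 1)
  cv1 <- cross_validate(null_case$X, null_case$y, max_components = 3,
                        repeats = 30, seed = 5)
  cv2 <- cross_validate(null_case$X, null_case$y, max_components = 3,
                        repeats = 30, seed = 5)
  expect_identical(cv1, cv2)
  expect_true(all(cv1$ber_by_component >= 0.35 & cv1$ber_by_component <= 0.65))

  strong <- make_scaled_matrix(31, 31, p = 50, n_diff = 10, effect = 2,
                               seed = 2)
  cv3 <- cross_validate(strong$X, strong$y, max_components = 5, repeats = 20,
                        seed = 3)
  expect_lt(cv3$min_ber, 0.1)
  expect_lte(cv3$chosen_components, 5L)
  expect_equal(cv3$min_ber, min(cv3$ber_by_component))

  expect_error(cross_validate(strong$X, rep(c("a", "b", "b", "b"), 15)[1:62],
                              folds = 40), "stratification")
})

test_that("VIP matches its formula and normalization", {
  # 1-component toy with weights (2,1,0): VIP = (sqrt(12/5), sqrt(3/5), 0)
  toy <- structure(
    list(x_weights = matrix(c(2, 1, 0), 3, 1), ssy = 4.2,
         feature_ids = c("a", "b", "c")),
    class = "plsda_fit")
  expect_equal(unname(vip(toy)), c(sqrt(12 / 5), sqrt(3 / 5), 0))

  # equal |weights| on all features -> all VIP = 1
  uni <- structure(
    list(x_weights = matrix(c(1, -1, 1, -1) / 2, 4, 1), ssy = 1,
         feature_ids = letters[1:4]),
    class = "plsda_fit")
  expect_equal(unname(vip(uni)), rep(1, 4))

  # sum(VIP^2) = p on arbitrary fits
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(rnorm(40 * 15), 40, 15, dimnames = list(NULL, paste0("V", 1:15)))
    fit <- fit_plsda(X, rep(c("a", "b"), each = 20), 4)
    expect_equal(sum(vip(fit)^2), 15, tolerance = 1e-8)
  }

  bad <- structure(list(x_weights = matrix(1, 2, 1), ssy = 0,
                        feature_ids = c("a", "b")), class = "plsda_fit")
  expect_error(vip(bad), "zero total")
})

test_that("iterative selection recovers planted features and terminates", {
  hits <- vapply(1:3, function(seed) {
    sim <- make_scaled_matrix(34, 28, p = 200, n_diff = 30, effect = 2,
                              seed = seed)
    sel <- iterative_selection(sim$X, sim$y, repeats = 15, seed = seed)
    expect_true(all(diff(sel$iteration_log$n_features) <= 0))
    expect_lte(sel$chosen_components, 10L)
    mean(sel$selected_feature_ids %in% sim$planted)
  }, numeric(1))
  expect_gte(min(hits), 0.8)  # retained sets are enriched for planted truth

  # pure noise: the loop terminates by the no-improvement rule. The terminal
  # BER sits well above 0 but below the 0.5 chance level (0.20-0.30 over
  # seeds) because VIP selection on the full data leaks into the next CV
  # round -- an optimism intrinsic to the select-then-cross-validate protocol.
  noise <- make_scaled_matrix(20, 20, p = 40, n_diff = 0, seed = 9)
  sel <- iterative_selection(noise$X, noise$y, repeats = 10, seed = 1)
  expect_gt(sel$final_ber, 0.15)
  expect_lte(nrow(sel$iteration_log), 10)
  expect_gt(sel$iteration_log$ber[1], 0.35)  # the honest first-pass BER
})

test_that("confusion matrices behave on separable data and under permutation", {
  sim <- make_scaled_matrix(18, 14, p = 20, n_diff = 10, effect = 4, seed = 3)
  conf <- confusion_matrix_cv(sim$X, sim$y, n_components = 2, repeats = 25,
                              seed = 2, positive_class = "pop1")
  expect_equal(conf$accuracy, 1)
  expect_equal(conf$precision, 1)
  expect_true(all(conf$matrix >= 0))
  # mean matrix rows sum to the true class counts (permutation-invariant)
  expect_equal(unname(rowSums(conf$matrix)), c(18, 14))

  perm <- permuted_confusion(sim$X, sim$y, n_components = 2, repeats = 40,
                             permutation_seed = 11, positive_class = "pop1")
  perm2 <- permuted_confusion(sim$X, sim$y, n_components = 2, repeats = 40,
                              permutation_seed = 11, positive_class = "pop1")
  expect_identical(perm, perm2)                       # determinism
  expect_equal(unname(rowSums(perm$matrix)), c(18, 14))  # counts preserved
  expect_true(perm$accuracy >= 0 && perm$accuracy <= 1)
  # permuted labels destroy the (perfect) signal
  expect_lt(perm$classification_rate[["pop1"]], 0.75)
})
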