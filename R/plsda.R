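#' Fit a two-class PLS-DA model by NIPALS
#'
#' Dummy-codes the two-level response (one centered indicator column per
#' class) and extracts latent components with the iterative NIPALS algorithm:
#' per component, the dominant covariance direction between X and Y is found
#' by power iteration, scores and loadings are computed, and X and Y are
#' deflated. Training-class centroids and the pooled within-class covariance
#' of the scores are stored for Mahalanobis-distance classification, and the
#' per-component Y variance captured is recorded for VIP scoring.
#'
#' X is centered internally (training-fold centering); it is expected to be
#' column-scaled upstream (auto-scaled ALR values).
#'
#' @param X Numeric matrix, samples x features, with column names.
#' @param y Two-level class labels, one per row of X.
#' @param n_components Number of latent components to extract; silently capped
#'   at `min(nrow(X) - 1, ncol(X))`, and reduced further (with a warning) if X
#'   runs out of rank.
#' @return An object of class `plsda_fit` with elements `x_weights`,
#'   `x_scores`, `x_loadings`, `y_loadings`, `rotation` (projection matrix for
#'   new data), `explained_y_variance`, `ssy` (raw per-component Y sum of
#'   squares captured), `classes`, `y`, `x_means`, `feature_ids`,
#'   `n_components`, `class_centroids`, `within_class_score_covariance`.
#' @export
fit_plsda <- function(X, y, n_components = 10L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- factor(as.character(y))
  if (nlevels(y) != 2L) stop("PLS-DA here is two-class; got ", nlevels(y))
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  classes <- sort(levels(y))
  n <- nrow(X); p <- ncol(X)
  A <- min(as.integer(n_components), n - 1L, p)
  if (A < 1L) stop("cannot extract any component")

  Ymat <- cbind(as.numeric(y == classes[1]), as.numeric(y == classes[2]))
  y_means <- colMeans(Ymat)
  Yc <- sweep(Ymat, 2, y_means)
  x_means <- colMeans(X)
  Xc <- sweep(X, 2, x_means)
  ssy_total <- sum(Yc^2)

  W <- matrix(0, p, A); P <- matrix(0, p, A); Q <- matrix(0, 2, A)
  Tm <- matrix(0, n, A); ssy <- numeric(A)
  Xh <- Xc; Yh <- Yc
  a <- 0L
  for (h in seq_len(A)) {
    u <- Yh[, 1]
    if (sum(u^2) < 1e-12) u <- Yh[, 2]
    w <- NULL
    for (iter in 1:200) {
      w <- crossprod(Xh, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-12) break
      w <- w / nw
      tt <- Xh %*% w
      q <- crossprod(Yh, tt) / sum(tt^2)
      u_new <- (Yh %*% q) / sum(q^2)
      if (sum((u_new - u)^2) < 1e-14 * max(sum(u_new^2), 1e-300)) {
        u <- u_new; break
      }
      u <- u_new
    }
    tt <- Xh %*% w
    tsq <- sum(tt^2)
    if (!is.finite(tsq) || tsq < 1e-10) {
      warning("rank deficiency: stopping at ", h - 1L, " of ", A,
              " requested components")
      break
    }
    pvec <- crossprod(Xh, tt) / tsq
    qvec <- crossprod(Yh, tt) / tsq
    W[, h] <- w; P[, h] <- pvec; Q[, h] <- qvec; Tm[, h] <- tt
    ssy[h] <- tsq * sum(qvec^2)
    Xh <- Xh - tcrossprod(tt, pvec)
    Yh <- Yh - tcrossprod(tt, qvec)
    a <- h
  }
  if (a == 0L) stop("no usable PLS component could be extracted")
  W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
  Q <- Q[, seq_len(a), drop = FALSE]; Tm <- Tm[, seq_len(a), drop = FALSE]
  ssy <- ssy[seq_len(a)]
  rotation <- W %*% solve(crossprod(P, W))
  dimnames(rotation) <- list(colnames(X), paste0("comp", seq_len(a)))
  colnames(Tm) <- paste0("comp", seq_len(a))

  fit <- structure(
    list(n_components = a, x_weights = W, x_scores = Tm, x_loadings = P,
         y_loadings = Q, rotation = rotation,
         explained_y_variance = ssy / ssy_total, ssy = ssy,
         classes = classes, y = y, x_means = x_means,
         feature_ids = colnames(X)),
    class = "plsda_fit"
  )
  mh <- score_mahalanobis_model(fit, a)
  fit$class_centroids <- mh$centroids
  fit$within_class_score_covariance <- mh$cov
  fit
}

#' @export
print.plsda_fit <- function(x, ...) {
  cat("<plsda_fit> ", x$n_components, " components, ",
      length(x$feature_ids), " features, classes: ",
      paste(x$classes, collapse = " / "), "\n", sep = "")
  cat("explained Y variance:",
      paste(signif(x$explained_y_variance, 3), collapse = " "), "\n")
  invisible(x)
}

## internal: class centroids and pooled within-class covariance of the first
## h training score dimensions, ridge-regularized when near-singular
score_mahalanobis_model <- function(fit, h) {
  Tm <- fit$x_scores[, seq_len(h), drop = FALSE]
  g <- fit$classes
  centroids <- do.call(rbind, lapply(g, function(cl) {
    colMeans(Tm[fit$y == cl, , drop = FALSE])
  }))
  rownames(centroids) <- g
  Sw <- matrix(0, h, h)
  for (cl in g) {
    Tc <- Tm[fit$y == cl, , drop = FALSE]
    Tc <- sweep(Tc, 2, colMeans(Tc))
    Sw <- Sw + crossprod(Tc)
  }
  Sw <- Sw / (nrow(Tm) - length(g))
  ok <- tryCatch({ solve(Sw); TRUE }, error = function(e) FALSE)
  if (!ok || kappa(Sw) > 1e10) {
    Sw <- Sw + diag(1e-8 * sum(diag(Sw)) / h, h)
  }
  list(centroids = centroids, cov = Sw, cov_inv = solve(Sw))
}

#' Classify new samples with a fitted PLS-DA model
#'
#' Projects new rows into the latent score space and assigns each to the class
#' whose training centroid is nearest in Mahalanobis distance under the pooled
#' within-class score covariance. Ties break deterministically to the first
#' class in sorted label order.
#'
#' @param object A [fit_plsda()] result.
#' @param newdata Matrix with the training features (same columns, same scale
#'   state).
#' @param n_components Number of components to use (default: all fitted).
#' @param ... Unused.
#' @return Factor of predicted class labels.
#' @export
predict.plsda_fit <- function(object, newdata, n_components = NULL, ...) {
  h <- if (is.null(n_components)) object$n_components else
    min(as.integer(n_components), object$n_components)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$feature_ids)) {
    stop("newdata must have the ", length(object$feature_ids),
         " training features")
  }
  Tn <- sweep(newdata, 2, object$x_means) %*%
    object$rotation[, seq_len(h), drop = FALSE]
  mh <- score_mahalanobis_model(object, h)
  d2 <- vapply(seq_along(object$classes), function(k) {
    dev <- sweep(Tn, 2, mh$centroids[k, ])
    rowSums((dev %*% mh$cov_inv) * dev)
  }, numeric(nrow(Tn)))
  d2 <- matrix(d2, nrow = nrow(Tn))
  factor(object$classes[apply(d2, 1, which.min)], levels = object$classes)
}

#' Balanced error rate
#'
#' Mean over the two classes of each class's misclassification proportion;
#' insensitive to class imbalance.
#'
#' @param true_labels,predicted_labels Equal-length two-class label vectors;
#'   both classes must appear in `true_labels`.
#' @return A proportion in \[0, 1\].
#' @export
balanced_error_rate <- function(true_labels, predicted_labels) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors must have equal length")
  }
  classes <- sort(unique(true_labels))
  if (length(classes) != 2L) {
    stop("both classes must be present in true_labels")
  }
  mean(vapply(classes, function(cl) {
    idx <- true_labels == cl
    mean(predicted_labels[idx] != cl)
  }, numeric(1)))
}

## internal: stratified fold labels (1..folds) using the current RNG stream
stratified_folds <- function(y, folds) {
  counts <- table(y)
  if (any(counts < folds)) {
    stop("stratification impossible: a class has fewer samples than folds")
  }
  assignment <- integer(length(y))
  for (cl in names(counts)) {
    idx <- which(y == cl)
    assignment[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  assignment
}

#' Tune the PLS-DA component count by repeated stratified cross-validation
#'
#' For every candidate component count `1..max_components`, the mean balanced
#' error rate (Mahalanobis-distance classification) over `folds x repeats`
#' held-out folds is computed, refitting the model inside each training fold;
#' the count with minimal mean BER is chosen, ties going to fewer components.
#' Fold splits are stratified and re-drawn each repeat from `seed`.
#'
#' @param X Scaled feature matrix (samples x features).
#' @param y Two-level labels.
#' @param max_components Ceiling on the component count (default 10).
#' @param folds,repeats Cross-validation geometry (defaults 4 and 100).
#' @param seed Integer seed making the whole procedure deterministic.
#' @return An object of class `cv_result`: `ber_by_component`,
#'   `chosen_components`, `min_ber`, `per_class_classification_rate` (at the
#'   chosen count), `fold_count`, `repeat_count`, `seed`.
#' @export
cross_validate <- function(X, y, max_components = 10L, folds = 4L,
                           repeats = 100L, seed = 1L) {
  X <- as.matrix(X)
  y <- factor(as.character(y))
  if (nlevels(y) != 2L) stop("two classes required")
  if (folds < 2L) stop("folds must be >= 2")
  classes <- sort(levels(y))
  A <- min(as.integer(max_components), ncol(X),
           nrow(X) - ceiling(nrow(X) / folds) - 1L)
  A <- max(A, 1L)
  ber_sum <- numeric(A); ber_n <- numeric(A)
  correct <- matrix(0, A, 2, dimnames = list(NULL, classes))
  totals <- matrix(0, A, 2, dimnames = list(NULL, classes))
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      fold_id <- stratified_folds(y, folds)
      for (k in seq_len(folds)) {
        tr <- fold_id != k; te <- !tr
        fit <- fit_plsda(X[tr, , drop = FALSE], y[tr], A)
        for (h in seq_len(fit$n_components)) {
          pred <- predict(fit, X[te, , drop = FALSE], n_components = h)
          ber_sum[h] <- ber_sum[h] + balanced_error_rate(y[te], pred)
          ber_n[h] <- ber_n[h] + 1
          for (ci in 1:2) {
            idx <- y[te] == classes[ci]
            correct[h, ci] <- correct[h, ci] + sum(pred[idx] == classes[ci])
            totals[h, ci] <- totals[h, ci] + sum(idx)
          }
        }
      }
    }
  })
  ber <- ifelse(ber_n > 0, ber_sum / ber_n, NA_real_)
  chosen <- which.min(ber)  # first minimum = fewer components on ties
  structure(
    list(ber_by_component = ber, chosen_components = as.integer(chosen),
         min_ber = ber[chosen],
         per_class_classification_rate = correct[chosen, ] / totals[chosen, ],
         fold_count = as.integer(folds), repeat_count = as.integer(repeats),
         seed = as.integer(seed)),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> chosen components:", x$chosen_components,
      " mean BER:", signif(x$min_ber, 4), "\n")
  cat("BER by component:", paste(signif(x$ber_by_component, 3),
                                 collapse = " "), "\n")
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt(p * sum_h(SS_h * (w_jh / ||w_h||)^2) / sum_h(SS_h))`, where
#' `p` is the feature count, `w_h` the component-h X-weights and `SS_h` the Y
#' sum of squares captured by component h. Satisfies `sum(VIP^2) = p` for any
#' fit.
#'
#' @param fit A [fit_plsda()] result with at least one component.
#' @return Named numeric vector of per-feature VIP scores.
#' @export
vip <- function(fit) {
  stopifnot(inherits(fit, "plsda_fit"))
  ssy <- fit$ssy
  if (sum(ssy) <= 0) stop("zero total explained Y variance; VIP undefined")
  W <- fit$x_weights
  wn2 <- sweep(W^2, 2, colSums(W^2), "/")
  p <- nrow(W)
  stats::setNames(sqrt(p * as.numeric(wn2 %*% ssy) / sum(ssy)),
                  fit$feature_ids)
}

#' Iterative VIP-based PLS-DA feature selection
#'
#' The selection protocol: fit with up to `max_components` components, choose
#' the component count by cross-validated BER, compute VIP on the chosen fit,
#' retain features with VIP above `vip_threshold`, refit on the reduced
#' matrix, and repeat. The loop stops when the cross-validated BER of a
#' reduced model drops below `ber_target` (at least one VIP reduction is
#' always applied, so an immediately well-separated full model still gets
#' pruned), when the BER fails to improve over the previous iteration, or
#' when the selected feature set stops changing; the iteration with the best
#' (lowest) BER is returned. The retained feature count is non-increasing
#' across iterations.
#'
#' Because VIP selection is computed on the full data before the next round
#' of cross-validation (the protocol's order), iterated BER estimates carry a
#' selection-bias optimism; on pure-noise data the loop therefore terminates
#' by the no-improvement rule at a BER below the 0.5 chance level.
#'
#' @inheritParams cross_validate
#' @param ber_target Stop once the cross-validated BER is below this value
#'   (default 0.02).
#' @param vip_threshold Features with VIP above this value are retained each
#'   iteration (default 1).
#' @return A list with `fit` (final [fit_plsda()] on the full data at the
#'   chosen component count), `selected_feature_ids`, `final_ber`,
#'   `chosen_components` and `iteration_log` (data frame: iteration,
#'   n_features, components, ber).
#' @export
iterative_selection <- function(X, y, ber_target = 0.02, max_components = 10L,
                                folds = 4L, repeats = 100L, seed = 1L,
                                vip_threshold = 1) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  stopifnot(ber_target >= 0, ber_target < 1)
  features <- colnames(X)
  log_rows <- list()
  best <- NULL
  prev_ber <- Inf
  it <- 0L
  repeat {
    it <- it + 1L
    cv <- cross_validate(X[, features, drop = FALSE], y,
                         max_components = max_components, folds = folds,
                         repeats = repeats, seed = seed + it)
    fit <- fit_plsda(X[, features, drop = FALSE], y, cv$chosen_components)
    cur <- list(fit = fit, features = features, ber = cv$min_ber,
                components = cv$chosen_components)
    log_rows[[it]] <- data.frame(iteration = it,
                                 n_features = length(features),
                                 components = cv$chosen_components,
                                 ber = cv$min_ber)
    if (is.null(best) || cur$ber < best$ber) best <- cur
    ## the target stop applies to reduced models: a first-pass full model
    ## below target still undergoes one VIP reduction
    if (it > 1L && cur$ber < ber_target) { best <- cur; break }
    if (it > 1L && cur$ber >= prev_ber) break  # no improvement
    sel <- tryCatch(vip(fit), error = function(e) NULL)
    if (is.null(sel)) break
    keep <- names(sel)[sel > vip_threshold]
    if (length(keep) == 0L) {
      warning("VIP selection emptied the feature set; ",
              "returning the previous iteration's model")
      break
    }
    if (setequal(keep, features)) break  # selected set unchanged
    prev_ber <- cur$ber
    features <- keep
  }
  list(fit = best$fit, selected_feature_ids = best$features,
       final_ber = best$ber, chosen_components = best$components,
       iteration_log = do.call(rbind, log_rows))
}

## internal: shared engine of the two confusion-matrix validations
cv_confusion <- function(X, y, n_components, folds, repeats, seed,
                         positive_class, permute) {
  X <- as.matrix(X)
  y <- factor(as.character(y))
  classes <- sort(levels(y))
  if (is.null(positive_class)) positive_class <- classes[1]
  if (!positive_class %in% classes) stop("unknown positive class")
  neg <- setdiff(classes, positive_class)
  conf_sum <- matrix(0, 2, 2, dimnames = list(true = classes,
                                              predicted = classes))
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      yr <- if (permute) factor(sample(as.character(y)), levels = classes)
            else y
      fold_id <- stratified_folds(yr, folds)
      pred <- factor(rep(classes[1], length(yr)), levels = classes)
      for (k in seq_len(folds)) {
        tr <- fold_id != k
        fit <- fit_plsda(X[tr, , drop = FALSE], yr[tr], n_components)
        pred[!tr] <- predict(fit, X[!tr, , drop = FALSE])
      }
      conf_sum <- conf_sum + table(yr, pred)
    }
  })
  m <- conf_sum / repeats
  tp <- m[positive_class, positive_class]; fp <- m[neg, positive_class]
  fn <- m[positive_class, neg]; tn <- m[neg, neg]
  structure(
    list(matrix = m, accuracy = (tp + tn) / sum(m),
         precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         classification_rate = stats::setNames(
           c(tp / (tp + fn), tn / (tn + fp)), c(positive_class, neg)),
         true_positive_class = positive_class,
         repeats = as.integer(repeats), permuted = permute),
    class = "confusion_summary"
  )
}

#' Cross-validated confusion matrix of a PLS-DA model
#'
#' Accumulates out-of-fold predictions over repeated stratified
#' cross-validation (the model is refit inside every training fold at the
#' given component count) and reports the mean 2x2 confusion matrix, accuracy
#' `(TP+TN)/total`, precision `TP/(TP+FP)` and per-class classification rates,
#' with the designated class as positive.
#'
#' @inheritParams cross_validate
#' @param n_components Component count of the validated model.
#' @param positive_class Class treated as the true positive (default: first in
#'   sorted order).
#' @return An object of class `confusion_summary`.
#' @export
confusion_matrix_cv <- function(X, y, n_components, folds = 4L,
                                repeats = 10000L, seed = 1L,
                                positive_class = NULL) {
  cv_confusion(X, y, n_components, folds, repeats, seed, positive_class,
               permute = FALSE)
}

#' Permuted-confusion matrix (spuriousness check)
#'
#' Identical to [confusion_matrix_cv()] except that the class-label vector is
#' permuted uniformly at random once per repeat before the fold split. A
#' non-spurious model yields a true-positive percentage near the two-class
#' chance level of 50%.
#'
#' @inheritParams confusion_matrix_cv
#' @param permutation_seed Seed of the permutation + CV stream.
#' @return An object of class `confusion_summary` with `permuted = TRUE`.
#' @export
permuted_confusion <- function(X, y, n_components, folds = 4L,
                               repeats = 10000L, permutation_seed = 1L,
                               positive_class = NULL) {
  cv_confusion(X, y, n_components, folds, repeats, permutation_seed,
               positive_class, permute = TRUE)
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("<confusion_summary>", if (x$permuted) "(label-permuted)", "mean over",
      x$repeats, "repeats\n")
  print(round(x$matrix, 2))
  cat(sprintf("accuracy %.3f  precision %.3f  (positive: %s)\n", x$accuracy,
              x$precision, x$true_positive_class))
  cat(sprintf("classification rate: %s\n",
              paste(sprintf("%s %.1f%%", names(x$classification_rate),
                            100 * x$classification_rate), collapse = ", ")))
  invisible(x)
}
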