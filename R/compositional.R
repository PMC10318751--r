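#' Zero-based feature filtering
#'
#' Removes a feature when its zero fraction is at or above
#' `zero_fraction_threshold` within either population or overall — unless the
#' absolute difference in zero fraction between the two populations exceeds
#' `zero_diff_threshold`, in which case the feature is retained as
#' presence/absence-informative (its zeros are themselves the group signal).
#'
#' @param table A [count_table].
#' @param zero_fraction_threshold Proportion in \[0, 1\]; default 0.2.
#' @param zero_diff_threshold Proportion in \[0, 1\]; default 0.5.
#' @return A [count_table] with the surviving features, original order
#'   preserved.
#' @export
filter_features <- function(table, zero_fraction_threshold = 0.2,
                            zero_diff_threshold = 0.5) {
  stopifnot(inherits(table, "count_table"),
            zero_fraction_threshold >= 0, zero_fraction_threshold <= 1,
            zero_diff_threshold >= 0, zero_diff_threshold <= 1)
  z <- table$counts == 0
  pops <- levels(table$population)
  f1 <- colMeans(z[table$population == pops[1], , drop = FALSE])
  f2 <- colMeans(z[table$population == pops[2], , drop = FALSE])
  ftot <- colMeans(z)
  over <- f1 >= zero_fraction_threshold | f2 >= zero_fraction_threshold |
    ftot >= zero_fraction_threshold
  informative <- abs(f1 - f2) > zero_diff_threshold
  keep <- !(over & !informative)
  if (!any(keep)) stop("zero filtering removed all features")
  subset_count_table(table, features = which(keep))
}

#' Add a pseudocount to every entry
#'
#' @param table A [count_table].
#' @param c Integer pseudocount, at least 1 (default 1, the conventional single
#'   count added to deal with remaining zeros before log-ratio analysis).
#' @return A [count_table] with `counts + c`; no zeros remain.
#' @export
add_pseudocount <- function(table, c = 1L) {
  stopifnot(inherits(table, "count_table"), c >= 1)
  out <- table
  out$counts <- table$counts + as.integer(c)
  out
}

## internal: PCA scores on log1p counts, outliers relative to own-population
## centroid on the first two components
flag_pca_outliers <- function(mat, population, sd_multiplier) {
  sc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)$x
  k <- min(2L, ncol(sc))
  flagged <- logical(nrow(mat))
  for (pop in levels(population)) {
    idx <- which(population == pop)
    for (comp in seq_len(k)) {
      s <- sc[idx, comp]
      dev <- abs(s - mean(s))
      sds <- stats::sd(s)
      if (is.finite(sds) && sds > 0) flagged[idx[dev > sd_multiplier * sds]] <- TRUE
    }
  }
  flagged
}

#' PCA-based outlier sample removal
#'
#' Computes principal components of the log-transformed, centered count matrix
#' and flags samples whose score on either of the first two components lies
#' more than `sd_multiplier` standard deviations from their own population's
#' centroid. Flagged samples are removed and the screen is repeated once.
#'
#' @param table A [count_table] with at least 3 samples per population.
#' @param sd_multiplier Outlyingness cutoff in SD units (default 3).
#' @return A list with `table` (the cleaned [count_table]) and
#'   `removed_sample_ids`.
#' @export
pca_outlier_removal <- function(table, sd_multiplier = 3) {
  stopifnot(inherits(table, "count_table"), sd_multiplier > 0)
  if (any(table(table$population) < 3)) {
    stop("need at least 3 samples per population")
  }
  cur <- table
  removed <- character(0)
  for (pass in 1:2) {
    flagged <- flag_pca_outliers(log1p(cur$counts), cur$population,
                                 sd_multiplier)
    if (!any(flagged)) break
    left <- table(cur$population[!flagged])
    if (length(left) < 2 || any(left < 3)) {
      stop("outlier removal would leave fewer than 3 samples in a population (",
           sum(flagged), " samples flagged)")
    }
    removed <- c(removed, cur$sample_ids[flagged])
    cur <- subset_count_table(cur, samples = which(!flagged))
  }
  list(table = cur, removed_sample_ids = removed)
}

#' Procrustes correlation between two point configurations
#'
#' After optimal translation, orthogonal rotation and scaling of one
#' configuration onto the other (classical Procrustes superposition minimizing
#' the residual sum of squares), returns `sqrt(1 - m2)` where `m2` is the
#' normalized Procrustes residual. Equal to 1 for perfectly isometric
#' configurations; symmetric in its arguments. Configurations with different
#' numbers of columns are padded with zero columns.
#'
#' @param config_a,config_b Numeric matrices with the same number of rows
#'   (points).
#' @return A value in \[0, 1\].
#' @export
procrustes_correlation <- function(config_a, config_b) {
  a <- as.matrix(config_a); b <- as.matrix(config_b)
  if (nrow(a) != nrow(b)) stop("configurations must have equal numbers of points")
  k <- max(ncol(a), ncol(b))
  pad <- function(m) cbind(m, matrix(0, nrow(m), k - ncol(m)))
  a <- scale(pad(a), center = TRUE, scale = FALSE)
  b <- scale(pad(b), center = TRUE, scale = FALSE)
  ssa <- sum(a^2); ssb <- sum(b^2)
  if (ssa <= .Machine$double.eps || ssb <= .Machine$double.eps) {
    stop("degenerate configuration: all points identical")
  }
  d <- svd(crossprod(a, b))$d
  r <- sum(d) / sqrt(ssa * ssb)
  min(1, max(0, r))
}

## internal: centered log-ratio matrix of a zero-free count matrix
clr_matrix <- function(counts) {
  lg <- log(counts)
  lg - rowMeans(lg)
}

## internal: principal-coordinate configuration of a real matrix under
## Euclidean distance (= PCA scores, all non-null dimensions). Isometric to
## the original rows, so Procrustes statistics are unchanged while the
## configuration has at most n columns — cheap even for 10^4 features.
pc_config <- function(m) {
  m <- scale(m, center = TRUE, scale = FALSE)
  s <- svd(m, nu = min(dim(m)), nv = 0)
  s$u %*% diag(s$d[seq_len(ncol(s$u))], ncol(s$u))
}

#' Select an ALR reference feature by the Greenacre criteria
#'
#' Among features whose total abundance exceeds the `abundance_quantile` of
#' the per-feature total-abundance distribution, candidates are ranked by
#' ascending coefficient of variation of their log counts; the best-ranked
#' candidate whose ALR geometry has Procrustes correlation above
#' `procrustes_min` with the full (centered) log-ratio geometry of the same
#' data is selected. A caller may instead force a named reference (mirroring
#' fixed choices such as the recA gene for functional features).
#'
#' @param table A [count_table] with no zeros (apply [add_pseudocount()]
#'   first).
#' @param abundance_quantile High-abundance cutoff as a quantile of total
#'   abundance (default 0.75).
#' @param procrustes_min Minimum acceptable Procrustes correlation
#'   (default 0.9).
#' @param reference_id Optional feature identifier to force as reference;
#'   diagnostics are still computed for it.
#' @return A list with `reference_id` and `diagnostics`, a data frame (one row
#'   per candidate examined, sorted by ascending CV) with columns
#'   `candidate_id`, `cv_log_abundance`, `total_abundance`,
#'   `procrustes_correlation` (NA when not evaluated because an earlier
#'   candidate already passed).
#' @export
select_reference <- function(table, abundance_quantile = 0.75,
                             procrustes_min = 0.9, reference_id = NULL) {
  stopifnot(inherits(table, "count_table"))
  if (any(table$counts == 0)) {
    stop("reference selection requires a zero-free table; run add_pseudocount() first")
  }
  lg <- log(table$counts)
  cvs <- apply(lg, 2, stats::sd) / colMeans(lg)
  tot <- colSums(table$counts)
  clr_cfg <- pc_config(clr_matrix(table$counts))

  pc_of <- function(ref_id) {
    alr <- lg[, setdiff(table$feature_ids, ref_id), drop = FALSE] -
      lg[, ref_id]
    procrustes_correlation(clr_cfg, pc_config(alr))
  }

  if (!is.null(reference_id)) {
    if (!reference_id %in% table$feature_ids) {
      stop("forced reference '", reference_id, "' not in table")
    }
    diag <- data.frame(candidate_id = reference_id,
                       cv_log_abundance = cvs[[reference_id]],
                       total_abundance = tot[[reference_id]],
                       procrustes_correlation = pc_of(reference_id))
    return(list(reference_id = reference_id, diagnostics = diag))
  }

  cand <- table$feature_ids[tot >= stats::quantile(tot, abundance_quantile)]
  cand <- cand[order(cvs[cand])]
  pcor <- rep(NA_real_, length(cand))
  chosen <- NULL
  for (i in seq_along(cand)) {
    pcor[i] <- pc_of(cand[i])
    if (pcor[i] > procrustes_min) { chosen <- cand[i]; break }
  }
  diag <- data.frame(candidate_id = cand, cv_log_abundance = cvs[cand],
                     total_abundance = tot[cand],
                     procrustes_correlation = pcor, row.names = NULL)
  if (is.null(chosen)) {
    stop("no high-abundance candidate reached Procrustes correlation > ",
         procrustes_min, "; best achieved ",
         signif(max(pcor, na.rm = TRUE), 4))
  }
  list(reference_id = chosen, diagnostics = diag)
}

#' Additive log-ratio transform
#'
#' `values[i, j] = log(counts[i, j]) - log(counts[i, ref])` (natural log); the
#' reference column is dropped, so a table with j features yields j - 1 ALR
#' coordinates. ALR rows are invariant to per-sample rescaling of the counts.
#'
#' @param table A zero-free [count_table].
#' @param reference_id Feature identifier of the reference (denominator).
#' @return An object of class `alr_table`: `values` (samples x (j-1) matrix),
#'   `sample_ids`, `feature_ids` (reference excluded), `reference_id`,
#'   `population`, `scaled = FALSE`.
#' @export
alr_transform <- function(table, reference_id) {
  stopifnot(inherits(table, "count_table"))
  if (!reference_id %in% table$feature_ids) stop("reference not in table")
  if (any(table$counts == 0)) {
    stop("zero count encountered; apply add_pseudocount() before the ALR transform")
  }
  lg <- log(table$counts)
  keep <- setdiff(table$feature_ids, reference_id)
  values <- lg[, keep, drop = FALSE] - lg[, reference_id]
  structure(
    list(values = values, sample_ids = table$sample_ids, feature_ids = keep,
         reference_id = reference_id, population = table$population,
         scaled = FALSE, scale_means = NULL, scale_sds = NULL),
    class = "alr_table"
  )
}

#' @export
print.alr_table <- function(x, ...) {
  cat("<alr_table> ", nrow(x$values), " samples x ", ncol(x$values),
      " log-ratios (reference: ", x$reference_id, ", ",
      if (x$scaled) "auto-scaled" else "unscaled", ")\n", sep = "")
  invisible(x)
}

#' Auto-scale an ALR table to column mean 0 and SD 1
#'
#' Records the original per-column means and SDs so the scaling can be applied
#' to new data or inverted with [unscale()].
#'
#' @param table An unscaled `alr_table`.
#' @param means,sds Optional pre-recorded statistics to apply instead of the
#'   table's own (for projecting held-out samples onto a training scale).
#' @return The `alr_table` with scaled values, `scaled = TRUE`, and
#'   `scale_means`/`scale_sds` filled in.
#' @export
autoscale <- function(table, means = NULL, sds = NULL) {
  stopifnot(inherits(table, "alr_table"))
  if (isTRUE(table$scaled)) stop("table is already auto-scaled")
  if (is.null(means)) means <- colMeans(table$values)
  if (is.null(sds)) sds <- apply(table$values, 2, stats::sd)
  if (any(!is.finite(sds) | sds <= 0)) {
    bad <- table$feature_ids[which(!is.finite(sds) | sds <= 0)[1]]
    stop("zero-SD column cannot be auto-scaled: ", bad)
  }
  out <- table
  out$values <- sweep(sweep(table$values, 2, means), 2, sds, "/")
  out$scaled <- TRUE
  out$scale_means <- means
  out$scale_sds <- sds
  out
}

#' @rdname autoscale
#' @export
unscale <- function(table) {
  stopifnot(inherits(table, "alr_table"), isTRUE(table$scaled))
  out <- table
  out$values <- sweep(sweep(table$values, 2, table$scale_sds, "*"), 2,
                      table$scale_means, "+")
  out$scaled <- FALSE
  out$scale_means <- NULL
  out$scale_sds <- NULL
  out
}

#' Write / read an ALR matrix as tab-delimited text
#'
#' @param x An `alr_table`.
#' @param values_file Path for the matrix (sample id in the first column).
#' @param provenance_file Optional JSON sidecar recording the reference
#'   feature and scaling state.
#' @export
write_alr_table <- function(x, values_file, provenance_file = NULL) {
  df <- data.frame(sample_id = x$sample_ids, x$values, check.names = FALSE)
  utils::write.table(df, values_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(provenance_file)) {
    jsonlite::write_json(
      list(reference_id = x$reference_id, scaled = x$scaled,
           population = as.list(stats::setNames(as.character(x$population),
                                                x$sample_ids)),
           scale_means = x$scale_means, scale_sds = x$scale_sds),
      provenance_file, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(values_file)
}

#' @rdname write_alr_table
#' @export
read_alr_table <- function(values_file, provenance_file) {
  df <- utils::read.delim(values_file, check.names = FALSE)
  prov <- jsonlite::read_json(provenance_file, simplifyVector = TRUE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  structure(
    list(values = m, sample_ids = df[[1]], feature_ids = colnames(m),
         reference_id = prov$reference_id,
         population = factor(unlist(prov$population)[df[[1]]]),
         scaled = isTRUE(prov$scaled),
         scale_means = if (is.null(prov$scale_means)) NULL else
           stats::setNames(as.numeric(prov$scale_means), colnames(m)),
         scale_sds = if (is.null(prov$scale_sds)) NULL else
           stats::setNames(as.numeric(prov$scale_sds), colnames(m))),
    class = "alr_table"
  )
}
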