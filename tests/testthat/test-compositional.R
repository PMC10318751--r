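# Hand-built 20-sample toy table: 10 samples per population, feature zero
# patterns chosen to hit each branch of the zero rule.
toy_zero_table <- function() {
  n <- 20
  pop <- rep(c("A", "B"), each = 10)
  cnt <- cbind(
    clean    = rep(5L, n),                     # 0% zeros -> retained
    both30   = rep(c(0L, 0L, 0L, 5L, 5L, 5L, 5L, 5L, 5L, 5L), 2),  # 30%/30%
    skewed   = c(rep(0L, 6), rep(4L, 4),       # 60% zeros in A
                 rep(3L, 10)),                 #  0% in B: diff 0.6 > 0.5
    atbound  = c(rep(0L, 6), rep(4L, 4),       # 60% zeros in A
                 0L, rep(3L, 9)),              # 10% in B: diff exactly 0.5
    totonly  = c(rep(0L, 3), rep(2L, 7),       # 30% in A
                 rep(0L, 3), rep(2L, 7))       # 30% in B, 30% total
  )
  count_table(cnt, pop)
}

test_that("zero filtering follows the 20%-with-exception rule", {
  tab <- toy_zero_table()
  kept <- filter_features(tab, 0.2, 0.5)$feature_ids
  expect_true("clean" %in% kept)       # no zeros
  expect_false("both30" %in% kept)     # 30% in both populations, diff 0
  expect_true("skewed" %in% kept)      # diff 0.6 > 0.5: zeros ARE the signal
  expect_false("atbound" %in% kept)    # diff exactly 0.5 is not > 0.5
  expect_false("totonly" %in% kept)
})

test_that("filtering is order-independent and can empty out", {
  d <- simulation_design(n_features = 50, zero_inflation = 0.3,
                         library_size_mean = 2e4, seed = 4)
  tab <- generate_counts(d)$table
  perm <- sample(seq_along(tab$feature_ids))
  a <- filter_features(subset_ct_for_test(tab, perm))
  b <- filter_features(tab)
  expect_setequal(a$feature_ids, b$feature_ids)

  allzero <- count_table(matrix(0L, 10, 3), rep(c("A", "B"), each = 5))
  expect_error(filter_features(allzero), "removed all features")
})

test_that("pseudocount removes zeros and increments everything", {
  tab <- toy_zero_table()
  out <- add_pseudocount(tab, 1L)
  expect_equal(out$counts, tab$counts + 1L)
  expect_gte(min(out$counts), 1)
  expect_error(add_pseudocount(tab, 0), "c >= 1")
})

test_that("PCA outlier screen removes a displaced sample, spares clusters", {
  set.seed(9)
  cnt <- matrix(rpois(40 * 30, exp(rnorm(40 * 30, 5, 1))), 40, 30)
  tab <- count_table(cnt, rep(c("A", "B"), each = 20))
  # displace sample 3 by a huge factor on many features
  tab2 <- tab
  tab2$counts[3, 1:15] <- tab2$counts[3, 1:15] * 1000L
  out <- pca_outlier_removal(tab2, 3)
  expect_true(tab2$sample_ids[3] %in% out$removed_sample_ids)

  # homogeneous clusters: removal rate stays within the 3-SD normal-tail bound
  set.seed(2)
  tot <- 0; rem <- 0
  for (i in 1:60) {
    cnt <- matrix(rpois(40 * 30, exp(rnorm(40 * 30, 5, 1))), 40, 30)
    tb <- count_table(cnt, rep(c("A", "B"), each = 20))
    rem <- rem + length(pca_outlier_removal(tb, 3)$removed_sample_ids)
    tot <- tot + 40
  }
  expect_lte(rem / tot, 0.02)

  tiny <- count_table(matrix(rpois(12, 50), 4, 3), rep(c("A", "B"), each = 2))
  expect_error(pca_outlier_removal(tiny), "at least 3 samples")
})

test_that("procrustes correlation: superposition, symmetry, null level", {
  set.seed(5)
  a <- matrix(rnorm(60), 30, 2)
  th <- 0.7; rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  b <- 3.2 * a %*% rot + 5
  expect_equal(procrustes_correlation(a, b), 1, tolerance = 1e-10)
  expect_equal(procrustes_correlation(a, a), 1, tolerance = 1e-12)

  x <- matrix(rnorm(80), 40, 2); y <- matrix(rnorm(120), 40, 3)
  expect_equal(procrustes_correlation(x, y), procrustes_correlation(y, x),
               tolerance = 1e-8)

  # independent random configurations, n = 100: small correlation
  # (null oracle: 200-replicate Monte-Carlo put the 95th percentile at 0.17)
  set.seed(1)
  r <- replicate(50, procrustes_correlation(matrix(rnorm(200), 100, 2),
                                            matrix(rnorm(200), 100, 2)))
  expect_gte(mean(r < 0.35), 0.95)

  expect_error(procrustes_correlation(matrix(1, 5, 2), matrix(rnorm(10), 5, 2)),
               "degenerate")
})

test_that("procrustes correlation agrees with the vegan oracle", {
  library(vegan)
  set.seed(8)
  x <- matrix(rnorm(60), 30, 2)
  y <- x + matrix(rnorm(60, sd = 0.4), 30, 2)
  ours <- procrustes_correlation(x, y)
  theirs <- vegan::protest(x, y, permutations = 2)$t0
  expect_equal(ours, unname(theirs), tolerance = 1e-8)
})

test_that("reference selection honours CV ranking and the isometry gate", {
  # two-feature toy: constant feature has CV(log) = 0 and passes Procrustes
  cnt <- cbind(const = rep(100L, 12),
               vary = as.integer(round(exp(rnorm(12, 4, 0.5)))))
  tab <- count_table(cnt, rep(c("A", "B"), each = 6))
  sel <- select_reference(tab, abundance_quantile = 0)
  expect_identical(sel$reference_id, "const")

  d <- simulation_design(n_features = 150, n_differential = 20,
                         library_size_mean = 2e5, seed = 21)
  sim <- generate_counts(d)
  tab <- add_pseudocount(filter_features(sim$table))
  sel <- select_reference(tab)
  diag <- sel$diagnostics
  # diagnostics sorted ascending by CV; chosen passes the gate
  expect_false(is.unsorted(diag$cv_log_abundance))
  pc <- diag$procrustes_correlation[diag$candidate_id == sel$reference_id]
  expect_gt(pc, 0.9)
  # chosen has the lowest CV among high-abundance candidates, or the
  # designated reference-like feature itself
  ref_cv <- diag$cv_log_abundance[diag$candidate_id == sel$reference_id]
  truth_cv <- diag$cv_log_abundance[diag$candidate_id ==
                                      sim$truth$reference_feature_id]
  expect_true(sel$reference_id == sim$truth$reference_feature_id ||
                ref_cv <= truth_cv)

  forced <- select_reference(tab, reference_id = sim$truth$reference_feature_id)
  expect_identical(forced$reference_id, sim$truth$reference_feature_id)
  expect_error(select_reference(tab, reference_id = "nope"), "not in table")
  expect_error(select_reference(sim$table), "zero-free")
})

test_that("ALR transform matches its defining identity", {
  cnt <- cbind(a = c(100L, 50L), b = c(10L, 50L), ref = c(10L, 5L))
  tab <- count_table(cnt, c("A", "B", "A", "B")[1:2])
  alr <- alr_transform(tab, "ref")
  expect_equal(ncol(alr$values), 2L)  # j - 1 columns
  expect_equal(alr$values[1, "a"], log(10))       # ln(100/10)
  expect_equal(alr$values[2, "b"], log(10))
  expect_equal(alr$values[2, "a"], log(10))
  expect_false("ref" %in% alr$feature_ids)

  withz <- count_table(cbind(a = c(0L, 1L), b = c(1L, 1L)), c("A", "B"))
  expect_error(alr_transform(withz, "b"), "pseudocount")
})

test_that("ALR is scale-invariant and reconstructs the composition", {
  d <- simulation_design(n_features = 40, n_differential = 5,
                         library_size_mean = 5e4, seed = 13)
  tab <- add_pseudocount(generate_counts(d)$table)
  ref <- tab$feature_ids[10]
  alr1 <- alr_transform(tab, ref)
  tab2 <- tab
  tab2$counts[4, ] <- tab2$counts[4, ] * 7L
  alr2 <- alr_transform(tab2, ref)
  expect_equal(alr1$values[4, ], alr2$values[4, ], tolerance = 1e-10)

  # exp(ALR), reinsert reference at 1, close -> sample proportions
  w <- cbind(exp(alr1$values), 1)
  colnames(w) <- c(alr1$feature_ids, ref)
  recon <- w / rowSums(w)
  props <- tab$counts / rowSums(tab$counts)
  expect_equal(recon[, colnames(props)], props, tolerance = 1e-12)
})

test_that("autoscale centers, scales, inverts, and validates", {
  d <- simulation_design(n_features = 30, n_differential = 5,
                         library_size_mean = 5e4, seed = 6)
  tab <- add_pseudocount(generate_counts(d)$table)
  alr <- alr_transform(tab, tab$feature_ids[1])
  sc <- autoscale(alr)
  expect_lt(max(abs(colMeans(sc$values))), 1e-10)
  expect_lt(max(abs(apply(sc$values, 2, sd) - 1)), 1e-10)
  expect_error(autoscale(sc), "already")

  back <- unscale(sc)
  expect_equal(back$values, alr$values, tolerance = 1e-10)

  resc <- autoscale(back, means = sc$scale_means, sds = sc$scale_sds)
  expect_equal(resc$values, sc$values, tolerance = 1e-10)

  degen <- alr
  degen$values[, 2] <- 3.14
  expect_error(autoscale(degen), "zero-SD")
})

test_that("ALR tables round-trip through text with provenance", {
  d <- simulation_design(n_features = 20, n_differential = 3,
                         library_size_mean = 2e4, seed = 31)
  tab <- add_pseudocount(generate_counts(d)$table)
  alr <- autoscale(alr_transform(tab, tab$feature_ids[2]))
  dir <- withr::local_tempdir()
  write_alr_table(alr, file.path(dir, "alr.tsv"), file.path(dir, "prov.json"))
  back <- read_alr_table(file.path(dir, "alr.tsv"), file.path(dir, "prov.json"))
  expect_equal(unname(back$values), unname(alr$values), tolerance = 1e-12)
  expect_identical(back$reference_id, alr$reference_id)
  expect_true(back$scaled)
  expect_equal(as.character(back$population), as.character(alr$population))
})
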