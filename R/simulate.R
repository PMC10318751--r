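#' Design of a synthetic two-population metagenome experiment
#'
#' Describes the world the generator draws from: two populations of fixed
#' sizes, a log-normal abundance spectrum over `n_features` features, a subset
#' of planted differential features whose log-abundance shifts between the
#' populations, overdispersed library sizes and structural zero inflation of
#' low-abundance features. The defaults emulate the study structure the
#' package targets: 34 + 28 cecal samples, a couple of hundred features at a
#' taxonomic rank, planted shifts of about one within-feature SD, and shotgun
#' library sizes of a few million reads.
#'
#' @param n_pop1,n_pop2 Sample counts of the two populations (default 34/28).
#' @param n_features Number of compositional features.
#' @param n_differential Number of planted differential features.
#' @param effect_sizes Signed per-planted-feature shifts in units of the
#'   within-group log-abundance SD of that feature; recycled to
#'   `n_differential`.
#' @param library_size_mean Expected total counts per sample.
#' @param library_size_dispersion Dimensionless overdispersion of library
#'   sizes; 0 means fixed sizes, otherwise sizes are negative binomial with
#'   `size = 1/dispersion`.
#' @param zero_inflation Probability in \[0, 1\] that a count of a
#'   low-abundance feature (bottom quartile of baseline abundance) is replaced
#'   by a structural zero.
#' @param seed Integer RNG seed; generation is deterministic given the design.
#' @return An object of class `simulation_design`.
#' @seealso [generate_counts()]
#' @export
simulation_design <- function(n_pop1 = 34L, n_pop2 = 28L, n_features = 200L,
                              n_differential = 30L, effect_sizes = 1,
                              library_size_mean = 2e6,
                              library_size_dispersion = 0.3,
                              zero_inflation = 0.05, seed = 1L) {
  d <- structure(
    list(n_pop1 = as.integer(n_pop1), n_pop2 = as.integer(n_pop2),
         n_features = as.integer(n_features),
         n_differential = as.integer(n_differential),
         effect_sizes = as.numeric(effect_sizes),
         library_size_mean = as.numeric(library_size_mean),
         library_size_dispersion = as.numeric(library_size_dispersion),
         zero_inflation = as.numeric(zero_inflation),
         seed = as.integer(seed)),
    class = "simulation_design"
  )
  validate_design(d)
  d
}

validate_design <- function(d) {
  stopifnot(inherits(d, "simulation_design"))
  ok <- function(cond, msg) if (!cond) stop("invalid design: ", msg)
  ok(d$n_pop1 >= 1 && d$n_pop2 >= 1, "population sizes must be >= 1")
  ok(d$n_features >= 2, "need at least two features")
  ok(d$n_differential >= 0 && d$n_differential <= d$n_features - 1,
     "n_differential must be between 0 and n_features - 1 (one feature is reserved as reference-like)")
  ok(all(is.finite(d$effect_sizes)), "effect sizes must be finite")
  ok(d$library_size_mean >= 1, "library_size_mean must be >= 1")
  ok(d$library_size_dispersion >= 0, "library_size_dispersion must be >= 0")
  ok(d$zero_inflation >= 0 && d$zero_inflation <= 1,
     "zero_inflation must be in [0, 1]")
  ok(length(d$seed) == 1 && is.finite(d$seed), "seed must be a scalar integer")
  invisible(TRUE)
}

#' Generate a two-population compositional count table with planted truth
#'
#' Logistic-normal-multinomial generative model. Per-feature baseline
#' log-abundances are drawn from a normal spectrum with a long right tail of a
#' few dominant features (a log-normal abundance spectrum on the count scale).
#' Each feature has its own within-group log-SD, drawn uniformly from
#' \[0.5, 1.5\]. Planted features receive an additive group shift of
#' `effect_size * sd_j` on the log scale in population 1. One designated
#' "reference-like" feature is always generated with high abundance, a tiny
#' log-SD (0.05) and no shift, so that downstream ALR reference selection has a
#' valid target. Sample compositions are the closure of the exponentiated
#' per-sample log-abundances; counts are multinomial draws with
#' negative-binomial library sizes; structural zeros are applied to
#' bottom-quartile features at rate `zero_inflation`.
#'
#' The planted shift survives the ALR transform exactly (the closure constant
#' cancels against any reference), which is what makes the truth record usable
#' as ground truth for the full pipeline.
#'
#' @param design A [simulation_design()].
#' @return A list with elements `table` (a [count_table] with
#'   `feature_kind = "synthetic"`, populations `"pop1"`/`"pop2"`) and `truth`
#'   (class `simulation_truth`: `differential_feature_ids`, `true_shifts` —
#'   full-length signed log-scale shifts, exactly 0 off the planted set —
#'   `compositions` — the closed generative per-sample proportions the
#'   multinomial draws target — `effect_sd_units`, `baseline_log_abundances`,
#'   `feature_sds`, `reference_feature_id`).
#' @export
generate_counts <- function(design) {
  validate_design(design)
  with_seed(design$seed, {
    j <- design$n_features
    n1 <- design$n_pop1; n2 <- design$n_pop2
    n <- n1 + n2
    feature_ids <- sprintf("F%03d", seq_len(j))
    sample_ids <- sprintf("S%02d", seq_len(n))
    population <- rep(c("pop1", "pop2"), c(n1, n2))

    ## abundance spectrum: normal on the log scale + a few dominant features
    baseline <- stats::rnorm(j, mean = 0, sd = 1.5)
    n_dom <- max(1L, round(0.02 * j))
    dom <- sample.int(j, n_dom)
    baseline[dom] <- baseline[dom] + stats::rexp(n_dom, rate = 0.5)
    sds <- stats::runif(j, 0.5, 1.5)

    ## reference-like feature: high abundance, minimal variation, no shift
    ref_idx <- which.max(baseline)
    baseline[ref_idx] <- max(baseline) + 0.5
    sds[ref_idx] <- 0.05

    diff_idx <- integer(0)
    shifts <- numeric(j)
    effects <- numeric(j)
    if (design$n_differential > 0) {
      diff_idx <- sort(sample(setdiff(seq_len(j), ref_idx),
                              design$n_differential))
      effects[diff_idx] <- rep_len(design$effect_sizes, design$n_differential)
      shifts[diff_idx] <- effects[diff_idx] * sds[diff_idx]
    }

    ## per-sample log abundances and closed compositions
    lam <- matrix(baseline, n, j, byrow = TRUE) +
      outer(as.numeric(population == "pop1"), shifts) +
      matrix(stats::rnorm(n * j), n, j) * matrix(sds, n, j, byrow = TRUE)
    w <- exp(lam)
    p <- w / rowSums(w)

    libs <- if (design$library_size_dispersion > 0) {
      pmax(1, stats::rnbinom(n, mu = design$library_size_mean,
                             size = 1 / design$library_size_dispersion))
    } else {
      rep(round(design$library_size_mean), n)
    }
    counts <- t(vapply(seq_len(n),
                       function(i) stats::rmultinom(1, libs[i], p[i, ])[, 1],
                       numeric(j)))

    ## structural zeros on the low-abundance quartile (never the reference)
    if (design$zero_inflation > 0) {
      low <- setdiff(which(baseline <= stats::quantile(baseline, 0.25)),
                     ref_idx)
      if (length(low)) {
        drop <- matrix(stats::runif(n * length(low)) < design$zero_inflation,
                       n, length(low))
        counts[, low][drop] <- 0
      }
    }

    tab <- count_table(counts, population = population,
                       feature_kind = "synthetic",
                       sample_ids = sample_ids, feature_ids = feature_ids)
    dimnames(p) <- list(sample_ids, feature_ids)
    truth <- structure(
      list(differential_feature_ids = feature_ids[diff_idx],
           true_shifts = stats::setNames(shifts, feature_ids),
           compositions = p,
           effect_sd_units = stats::setNames(effects, feature_ids),
           baseline_log_abundances = stats::setNames(baseline, feature_ids),
           feature_sds = stats::setNames(sds, feature_ids),
           reference_feature_id = feature_ids[ref_idx]),
      class = "simulation_truth"
    )
    list(table = tab, truth = truth)
  })
}

#' Write a simulation truth record as delimited text
#'
#' @param truth A `simulation_truth` record from [generate_counts()].
#' @param file Output path (tab-delimited: feature id, true log-scale shift,
#'   effect in SD units, differential flag).
#' @export
write_simulation_truth <- function(truth, file) {
  df <- data.frame(feature_id = names(truth$true_shifts),
                   true_shift = as.numeric(truth$true_shifts),
                   effect_sd_units = as.numeric(truth$effect_sd_units),
                   differential = names(truth$true_shifts) %in%
                     truth$differential_feature_ids)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
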