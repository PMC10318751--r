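#' Pipeline configuration with protocol defaults
#'
#' Bundles every stage parameter of the end-to-end workflow with the
#' protocol's default values: zero-filter threshold 0.2 (retain when the
#' between-population zero-fraction difference exceeds 0.5), pseudocount 1,
#' PLS-DA ceiling of 10 components with fourfold cross-validation repeated 100
#' times for tuning and 10,000 times for the confusion matrix, BER target
#' 0.02, VIP threshold 1, four Gibbs chains of 50,000 iterations with lag 10
#' and burn-in 1,000, R-hat limit 1.05, relevance thresholds 0.5 SD and P0
#' 0.9, and a 0.05 alpha-test level. Either a simulation design or a pair of
#' input files must be supplied.
#'
#' @param design Optional [simulation_design()] to generate inputs.
#' @param counts_file,metadata_file Optional input files (see
#'   [read_count_table()]); ignored when `design` is given.
#' @param feature_kind Feature kind tag for file input.
#' @param zero_fraction_threshold,zero_diff_threshold See [filter_features()].
#' @param pseudocount See [add_pseudocount()].
#' @param abundance_quantile,procrustes_min,reference_id See
#'   [select_reference()]; `reference_id` forces a named reference.
#' @param sd_multiplier,outlier_first PCA outlier screen cutoff and placement:
#'   `outlier_first = TRUE` (default, the protocol's text order) screens raw
#'   log counts before filtering; `FALSE` screens the scaled ALR values after
#'   the transform.
#' @param max_components,folds,tuning_repeats,confusion_repeats,ber_target,vip_threshold
#'   PLS-DA stage parameters.
#' @param positive_class Class treated as true positive (default: first
#'   population level in sorted order).
#' @param chains,iterations,thinning_lag,burn_in,rhat_limit,sd_threshold,p0_threshold
#'   Bayesian stage parameters.
#' @param alpha_level,n_permutations,nmds_restarts,permanova_on_distance
#'   Diversity stage parameters; `permanova_on_distance = TRUE` additionally
#'   runs PERMANOVA directly on the Bray-Curtis matrix.
#' @param seed Root seed; each stage derives its own child seed from it by a
#'   fixed documented scheme, so a run is fully reproducible.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(design = NULL, counts_file = NULL,
                            metadata_file = NULL, feature_kind = "synthetic",
                            zero_fraction_threshold = 0.2,
                            zero_diff_threshold = 0.5, pseudocount = 1L,
                            abundance_quantile = 0.75, procrustes_min = 0.9,
                            reference_id = NULL, sd_multiplier = 3,
                            outlier_first = TRUE, max_components = 10L,
                            folds = 4L, tuning_repeats = 100L,
                            confusion_repeats = 10000L, ber_target = 0.02,
                            vip_threshold = 1, positive_class = NULL,
                            chains = 4L, iterations = 50000L,
                            thinning_lag = 10L, burn_in = 1000L,
                            rhat_limit = 1.05, sd_threshold = 0.5,
                            p0_threshold = 0.9, alpha_level = 0.05,
                            n_permutations = 999L, nmds_restarts = 20L,
                            permanova_on_distance = FALSE, seed = 1L) {
  cfg <- structure(
    list(design = design, counts_file = counts_file,
         metadata_file = metadata_file, feature_kind = feature_kind,
         zero_fraction_threshold = zero_fraction_threshold,
         zero_diff_threshold = zero_diff_threshold,
         pseudocount = as.integer(pseudocount),
         abundance_quantile = abundance_quantile,
         procrustes_min = procrustes_min, reference_id = reference_id,
         sd_multiplier = sd_multiplier, outlier_first = isTRUE(outlier_first),
         max_components = as.integer(max_components),
         folds = as.integer(folds),
         tuning_repeats = as.integer(tuning_repeats),
         confusion_repeats = as.integer(confusion_repeats),
         ber_target = ber_target, vip_threshold = vip_threshold,
         positive_class = positive_class, chains = as.integer(chains),
         iterations = as.integer(iterations),
         thinning_lag = as.integer(thinning_lag),
         burn_in = as.integer(burn_in), rhat_limit = rhat_limit,
         sd_threshold = sd_threshold, p0_threshold = p0_threshold,
         alpha_level = alpha_level,
         n_permutations = as.integer(n_permutations),
         nmds_restarts = as.integer(nmds_restarts),
         permanova_on_distance = isTRUE(permanova_on_distance),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  ok <- function(cond, msg) if (!cond) stop("invalid config: ", msg)
  ok(!is.null(cfg$design) ||
       (!is.null(cfg$counts_file) && !is.null(cfg$metadata_file)),
     "either a simulation design or counts/metadata files are required")
  if (!is.null(cfg$design)) validate_design(cfg$design)
  ok(cfg$zero_fraction_threshold >= 0 && cfg$zero_fraction_threshold <= 1,
     "zero_fraction_threshold in [0,1]")
  ok(cfg$zero_diff_threshold >= 0 && cfg$zero_diff_threshold <= 1,
     "zero_diff_threshold in [0,1]")
  ok(cfg$pseudocount >= 1, "pseudocount >= 1")
  ok(cfg$ber_target > 0 || cfg$ber_target == 0, "ber_target >= 0")
  ok(cfg$ber_target < 1, "ber_target < 1")
  ok(cfg$folds >= 2, "folds >= 2")
  ok(cfg$chains >= 2, "chains >= 2")
  ok(cfg$burn_in < cfg$iterations, "burn_in < iterations")
  ok(cfg$p0_threshold >= 0.5 && cfg$p0_threshold <= 1, "p0_threshold in [0.5,1]")
  ok(cfg$alpha_level > 0 && cfg$alpha_level < 1, "alpha_level in (0,1)")
  invisible(TRUE)
}

#' Serialize / deserialize a pipeline configuration as JSON
#'
#' The default configuration round-trips byte-identically
#' (write, read, write).
#'
#' @param cfg A [pipeline_config()].
#' @param file JSON path.
#' @export
write_pipeline_config <- function(cfg, file) {
  x <- unclass(cfg)
  x$design <- if (is.null(cfg$design)) NULL else unclass(cfg$design)
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(file)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!is.null(x$design)) x$design <- do.call(simulation_design, x$design)
  do.call(pipeline_config, x)
}

## child seeds per stage, derived from the root seed (documented scheme)
stage_seed <- function(cfg, stage) {
  offsets <- c(simulate = 11L, plsda = 71L, confusion = 72L,
               permutation = 73L, bayes = 74L, nmds = 75L, permanova = 76L)
  derive_seed(cfg$seed, offsets[[stage]])
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

## ---------------------------------------------------------------------------
## Stage functions. Each takes (config, dir, state); when `state` lacks its
## inputs they are reloaded from `dir`, so any stage can be re-entered from
## the files a previous run left behind.

stage_input <- function(cfg, dir = NULL, state = list()) {
  if (!is.null(cfg$design)) {
    sim <- generate_counts(cfg$design)
    state$table <- sim$table
    state$truth <- sim$truth
  } else {
    state$table <- read_count_table(cfg$counts_file, cfg$metadata_file,
                                    cfg$feature_kind)
    state$truth <- NULL
  }
  if (!is.null(dir)) {
    write_count_table(state$table, file.path(dir, "counts.tsv"),
                      file.path(dir, "metadata.tsv"))
    if (!is.null(state$truth)) {
      write_simulation_truth(state$truth, file.path(dir, "truth.tsv"))
    }
  }
  state
}

stage_transform <- function(cfg, dir = NULL, state = list()) {
  if (is.null(state$table)) {
    cf <- file.path(dir, "counts.tsv")
    if (file.exists(cf)) {
      state$table <- read_count_table(cf, file.path(dir, "metadata.tsv"),
                                      cfg$feature_kind)
    } else {
      state <- stage_input(cfg, NULL, state)
    }
  }
  tab <- state$table
  removed <- character(0)
  if (cfg$outlier_first) {
    outl <- pca_outlier_removal(tab, cfg$sd_multiplier)
    tab <- outl$table
    removed <- outl$removed_sample_ids
  }
  tab <- filter_features(tab, cfg$zero_fraction_threshold,
                         cfg$zero_diff_threshold)
  tab <- add_pseudocount(tab, cfg$pseudocount)
  ref <- select_reference(tab, cfg$abundance_quantile, cfg$procrustes_min,
                          reference_id = cfg$reference_id)
  alr <- alr_transform(tab, ref$reference_id)
  alr <- autoscale(alr)
  if (!cfg$outlier_first) {
    flagged <- flag_pca_outliers(alr$values, alr$population,
                                 cfg$sd_multiplier)
    if (any(flagged)) {
      removed <- alr$sample_ids[flagged]
      tab <- subset_count_table(tab, samples = which(!flagged))
      alr <- autoscale(alr_transform(tab, ref$reference_id))
    }
  }
  state$filtered_table <- tab
  state$reference <- ref
  state$alr <- alr
  state$removed_sample_ids <- removed
  if (!is.null(dir)) {
    write_count_table(tab, file.path(dir, "counts_filtered.tsv"),
                      file.path(dir, "metadata_filtered.tsv"))
    write_alr_table(alr, file.path(dir, "alr_scaled.tsv"),
                    file.path(dir, "alr_provenance.json"))
    write_tsv(ref$diagnostics, file.path(dir, "reference_diagnostics.tsv"))
    jsonlite::write_json(
      list(reference_id = ref$reference_id, removed_sample_ids = removed,
           n_features_after_filter = length(tab$feature_ids)),
      file.path(dir, "transform.json"), auto_unbox = TRUE, digits = NA)
  }
  state
}

load_alr <- function(cfg, dir, state) {
  if (is.null(state$alr)) {
    state$alr <- read_alr_table(file.path(dir, "alr_scaled.tsv"),
                                file.path(dir, "alr_provenance.json"))
  }
  state
}

stage_plsda <- function(cfg, dir = NULL, state = list()) {
  state <- load_alr(cfg, dir, state)
  alr <- state$alr
  sel <- iterative_selection(alr$values, alr$population,
                             ber_target = cfg$ber_target,
                             max_components = cfg$max_components,
                             folds = cfg$folds, repeats = cfg$tuning_repeats,
                             seed = stage_seed(cfg, "plsda"),
                             vip_threshold = cfg$vip_threshold)
  pos <- if (is.null(cfg$positive_class)) sort(levels(alr$population))[1] else
    cfg$positive_class
  Xsel <- alr$values[, sel$selected_feature_ids, drop = FALSE]
  conf <- confusion_matrix_cv(Xsel, alr$population, sel$chosen_components,
                              folds = cfg$folds,
                              repeats = cfg$confusion_repeats,
                              seed = stage_seed(cfg, "confusion"),
                              positive_class = pos)
  perm <- permuted_confusion(Xsel, alr$population, sel$chosen_components,
                             folds = cfg$folds,
                             repeats = cfg$confusion_repeats,
                             permutation_seed = stage_seed(cfg, "permutation"),
                             positive_class = pos)
  state$selection <- sel
  state$confusion <- conf
  state$permuted_confusion <- perm
  if (!is.null(dir)) {
    writeLines(sel$selected_feature_ids,
               file.path(dir, "selected_features.txt"))
    write_tsv(sel$iteration_log, file.path(dir, "iteration_log.tsv"))
    for (nm in c("confusion", "permuted_confusion")) {
      cs <- state[[nm]]
      jsonlite::write_json(
        list(matrix = as.data.frame(unclass(cs$matrix)),
             accuracy = cs$accuracy, precision = cs$precision,
             classification_rate = as.list(cs$classification_rate),
             true_positive_class = cs$true_positive_class,
             repeats = cs$repeats, permuted = cs$permuted),
        file.path(dir, paste0(nm, ".json")), auto_unbox = TRUE, digits = NA)
    }
  }
  state
}

stage_bayes <- function(cfg, dir = NULL, state = list()) {
  state <- load_alr(cfg, dir, state)
  if (is.null(state$selection)) {
    state$selection <- list(selected_feature_ids = readLines(
      file.path(dir, "selected_features.txt")))
  }
  alr <- state$alr
  X <- alr$values[, state$selection$selected_feature_ids, drop = FALSE]
  st <- mcmc_settings(cfg$chains, cfg$iterations, cfg$thinning_lag,
                      cfg$burn_in, seed = stage_seed(cfg, "bayes"))
  screen <- run_bayes_screen(X, alr$population, st,
                             sd_threshold = cfg$sd_threshold,
                             p0_threshold = cfg$p0_threshold,
                             rhat_limit = cfg$rhat_limit)
  state$bayes <- screen
  if (!is.null(dir)) write_tsv(screen, file.path(dir, "bayes_screen.tsv"))
  state
}

stage_diversity <- function(cfg, dir = NULL, state = list()) {
  if (is.null(state$filtered_table)) {
    state$filtered_table <- read_count_table(
      file.path(dir, "counts_filtered.tsv"),
      file.path(dir, "metadata_filtered.tsv"), cfg$feature_kind)
  }
  tab <- state$filtered_table
  props <- tab$counts / rowSums(tab$counts)
  alpha <- lapply(c("shannon", "inv_simpson"), function(ix) {
    alpha_diversity(props, tab$population, ix)
  })
  names(alpha) <- c("shannon", "inv_simpson")
  bc <- bray_curtis(props)
  nm <- nmds(bc, k = 2, n_restarts = cfg$nmds_restarts,
             seed = stage_seed(cfg, "nmds"))
  pm <- permanova(nm$coordinates, tab$population,
                  n_permutations = cfg$n_permutations,
                  seed = stage_seed(cfg, "permanova"))
  state$diversity <- list(alpha = alpha, bray_curtis = bc, nmds = nm,
                          permanova = pm)
  if (cfg$permanova_on_distance) {
    state$diversity$permanova_distance <-
      permanova(bc, tab$population, n_permutations = cfg$n_permutations,
                seed = stage_seed(cfg, "permanova"))
  }
  if (!is.null(dir)) {
    adf <- data.frame(sample_id = tab$sample_ids,
                      population = as.character(tab$population),
                      shannon = unname(alpha$shannon$per_sample_index),
                      inv_simpson = unname(alpha$inv_simpson$per_sample_index))
    write_tsv(adf, file.path(dir, "alpha_diversity.tsv"))
    cdf <- data.frame(sample_id = tab$sample_ids, nm$coordinates)
    colnames(cdf) <- c("sample_id", "NMDS1", "NMDS2")
    write_tsv(cdf, file.path(dir, "nmds_coordinates.tsv"))
    jsonlite::write_json(
      list(shannon_p = alpha$shannon$group_test_pvalue,
           inv_simpson_p = alpha$inv_simpson$group_test_pvalue,
           nmds_stress = nm$stress, permanova_pseudo_f = pm$pseudo_f,
           permanova_p = pm$p_value),
      file.path(dir, "diversity.json"), auto_unbox = TRUE, digits = NA)
  }
  state
}

#' Run the full discrimination pipeline
#'
#' Executes the protocol stages in order: input (simulation or file ingest),
#' PCA outlier removal, zero filtering, pseudocount, reference selection, ALR
#' transform, auto-scaling, iterative PLS-DA feature selection with confusion
#' and permuted-confusion validation, the per-feature Bayesian relevance
#' screen, and alpha/beta diversity. Fully deterministic given the config's
#' root seed (each stage derives a fixed child seed). If `output_dir` is
#' given, every stage writes its delimited-text outputs there, sufficient to
#' re-enter any downstream stage without recomputation.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory for stage outputs (created if
#'   missing).
#' @param verbose Print stage progress.
#' @return An object of class `run_report`: the config, per-stage parameter
#'   and outcome records, and the final relevant-feature table.
#' @export
run_pipeline <- function(config, output_dir = NULL, verbose = FALSE) {
  validate_config(config)
  if (!is.null(output_dir) && !dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
  }
  say <- function(...) if (verbose) message(...)
  state <- list()
  stages <- list()

  say("stage: input")
  state <- stage_input(config, output_dir, state)
  stages$input <- list(
    n_samples = nrow(state$table$counts),
    n_features = ncol(state$table$counts),
    source = if (is.null(config$design)) "files" else "simulation")

  say("stage: transform")
  state <- stage_transform(config, output_dir, state)
  stages$transform <- list(
    removed_sample_ids = state$removed_sample_ids,
    n_samples = nrow(state$alr$values),
    n_features_after_filter = length(state$filtered_table$feature_ids),
    reference_id = state$reference$reference_id,
    reference_procrustes = state$reference$diagnostics$procrustes_correlation[
      match(state$reference$reference_id,
            state$reference$diagnostics$candidate_id)])

  say("stage: plsda")
  state <- stage_plsda(config, output_dir, state)
  stages$plsda <- list(
    n_selected = length(state$selection$selected_feature_ids),
    components = state$selection$chosen_components,
    final_ber = state$selection$final_ber,
    iteration_log = state$selection$iteration_log,
    accuracy = state$confusion$accuracy,
    precision = state$confusion$precision,
    classification_rate = state$confusion$classification_rate,
    permuted_classification_rate = state$permuted_confusion$classification_rate)

  say("stage: bayes")
  state <- stage_bayes(config, output_dir, state)
  stages$bayes <- list(
    n_screened = nrow(state$bayes),
    n_converged = sum(state$bayes$converged),
    n_relevant = sum(state$bayes$relevant))

  say("stage: diversity")
  state <- stage_diversity(config, output_dir, state)
  stages$diversity <- list(
    shannon_p = state$diversity$alpha$shannon$group_test_pvalue,
    inv_simpson_p = state$diversity$alpha$inv_simpson$group_test_pvalue,
    nmds_stress = state$diversity$nmds$stress,
    permanova_pseudo_f = state$diversity$permanova$pseudo_f,
    permanova_p = state$diversity$permanova$p_value)

  report <- structure(
    list(config = config, stages = stages,
         relevant_features = state$bayes[state$bayes$relevant, , drop = FALSE],
         bayes_screen = state$bayes, truth = state$truth,
         selection = state$selection, diversity = state$diversity,
         confusion = state$confusion,
         permuted_confusion = state$permuted_confusion),
    class = "run_report"
  )
  if (!is.null(output_dir)) {
    jsonlite::write_json(
      list(stages = stages[c("input", "transform", "bayes", "diversity")],
           n_relevant = nrow(report$relevant_features),
           relevant_feature_ids = report$relevant_features$feature_id),
      file.path(output_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  s <- x$stages
  cat("<run_report>\n")
  cat(sprintf("  input:     %d samples x %d features (%s)\n",
              s$input$n_samples, s$input$n_features, s$input$source))
  cat(sprintf("  transform: %d features kept, reference %s, %d sample(s) removed\n",
              s$transform$n_features_after_filter, s$transform$reference_id,
              length(s$transform$removed_sample_ids)))
  cat(sprintf("  plsda:     %d features, %d components, CV-BER %.4f, accuracy %.3f, precision %.3f\n",
              s$plsda$n_selected, s$plsda$components, s$plsda$final_ber,
              s$plsda$accuracy, s$plsda$precision))
  cat(sprintf("  permuted classification rate: %s\n",
              paste(sprintf("%.1f%%", 100 * s$plsda$permuted_classification_rate),
                    collapse = " / ")))
  cat(sprintf("  bayes:     %d screened, %d converged, %d relevant\n",
              s$bayes$n_screened, s$bayes$n_converged, s$bayes$n_relevant))
  cat(sprintf("  diversity: Shannon p %.3f, invSimpson p %.3f, NMDS stress %.3f, PERMANOVA p %.3g\n",
              s$diversity$shannon_p, s$diversity$inv_simpson_p,
              s$diversity$nmds_stress, s$diversity$permanova_p))
  invisible(x)
}
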