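#' Two-population feature count table
#'
#' The basic container of the workflow: a samples x features matrix of
#' non-negative integer counts, a two-level population label per sample, and a
#' tag saying what kind of feature the columns are (taxa at one rank, KEGG or
#' COG gene families, or synthetic).
#'
#' @param counts Numeric matrix, samples in rows and features in columns, with
#'   non-negative integer entries. Row and column names are used as sample and
#'   feature identifiers when `sample_ids`/`feature_ids` are not given.
#' @param population Vector of per-sample population labels; exactly two
#'   distinct levels must be present.
#' @param feature_kind One of `"KEGG"`, `"COG"`, `"phylum"`, `"family"`,
#'   `"genus"`, `"species"`, `"synthetic"`.
#' @param sample_ids,feature_ids Optional identifier vectors overriding the
#'   dimnames of `counts`.
#'
#' @return An object of class `count_table`: a list with elements `counts`,
#'   `sample_ids`, `feature_ids`, `population` (factor with two levels) and
#'   `feature_kind`.
#' @export
count_table <- function(counts, population,
                        feature_kind = c("synthetic", "KEGG", "COG", "phylum",
                                         "family", "genus", "species"),
                        sample_ids = NULL, feature_ids = NULL) {
  feature_kind <- match.arg(feature_kind)
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("`counts` must be a numeric matrix")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("`counts` must contain finite non-negative values")
  }
  if (max(abs(counts - round(counts))) > 1e-8) {
    stop("`counts` must contain integer values")
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(counts)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(counts)))
  }
  if (is.null(feature_ids)) {
    feature_ids <- colnames(counts)
    if (is.null(feature_ids)) feature_ids <- paste0("F", seq_len(ncol(counts)))
  }
  if (length(sample_ids) != nrow(counts)) stop("sample id / row mismatch")
  if (length(feature_ids) != ncol(counts)) stop("feature id / column mismatch")
  if (anyDuplicated(feature_ids)) stop("feature ids must be unique")
  if (length(population) != nrow(counts)) {
    stop("`population` must have one label per sample")
  }
  population <- factor(as.character(population))
  if (nlevels(population) != 2L) {
    stop("exactly two population levels are required, got ",
         nlevels(population))
  }
  dimnames(counts) <- list(sample_ids, feature_ids)
  structure(
    list(counts = counts, sample_ids = sample_ids, feature_ids = feature_ids,
         population = population, feature_kind = feature_kind),
    class = "count_table"
  )
}

#' @export
print.count_table <- function(x, ...) {
  cat("<count_table> ", nrow(x$counts), " samples x ", ncol(x$counts),
      " features (", x$feature_kind, ")\n", sep = "")
  cat("populations: ",
      paste(sprintf("%s=%d", levels(x$population), table(x$population)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

## internal: subset samples/features, keeping metadata in sync
subset_count_table <- function(x, samples = NULL, features = NULL) {
  keep_s <- if (is.null(samples)) seq_along(x$sample_ids) else samples
  keep_f <- if (is.null(features)) seq_along(x$feature_ids) else features
  count_table(x$counts[keep_s, keep_f, drop = FALSE],
              population = x$population[keep_s],
              feature_kind = x$feature_kind,
              sample_ids = x$sample_ids[keep_s],
              feature_ids = x$feature_ids[keep_f])
}

#' Read and write count tables as delimited text
#'
#' The on-disk format is two tab-delimited files: a counts file with a header
#' row of feature identifiers and the sample identifier in the first column,
#' and a two-column metadata file (`sample_id`, `population`).
#'
#' @param x A [count_table].
#' @param counts_file,metadata_file Paths of the two files.
#' @param feature_kind Feature kind to tag the table read from disk.
#' @return `write_count_table` returns the paths invisibly;
#'   `read_count_table` returns a [count_table].
#' @export
write_count_table <- function(x, counts_file, metadata_file) {
  df <- data.frame(sample_id = x$sample_ids, x$counts, check.names = FALSE)
  utils::write.table(df, counts_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  md <- data.frame(sample_id = x$sample_ids,
                   population = as.character(x$population))
  utils::write.table(md, metadata_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts_file, metadata_file))
}

#' @rdname write_count_table
#' @export
read_count_table <- function(counts_file, metadata_file,
                             feature_kind = "synthetic") {
  df <- utils::read.delim(counts_file, check.names = FALSE,
                          stringsAsFactors = FALSE)
  md <- utils::read.delim(metadata_file, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  pop <- md$population[match(df[[1]], md$sample_id)]
  if (anyNA(pop)) stop("metadata is missing samples present in the count file")
  count_table(m, population = pop, feature_kind = feature_kind)
}
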