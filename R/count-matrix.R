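#' Construct a developmental count matrix
#'
#' Bundles a non-negative integer feature x sample count matrix with the
#' sample sheet (time-point, replicate) and feature sheet (class,
#' conservation) that every downstream expression analysis needs.
#'
#' @param counts integer matrix, features in rows, samples in columns.
#'   Row and column names are required and must match the sheets.
#' @param samples data.frame with columns `sample_id`, `time_point`
#'   (integer 1..T), `replicate`.
#' @param features data.frame with columns `feature_id`, `class`
#'   (`"mirna"`, `"mrna"` or `"lncrna"`), `conservation` (`"conserved"` or
#'   `"novel"`).
#' @return an object of class `mw_counts`
#' @examples
#' m <- matrix(1:12, 3, 4, dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
#' cm <- mw_counts(m,
#'   samples = data.frame(sample_id = paste0("s", 1:4),
#'                        time_point = c(1, 1, 2, 2), replicate = c(1, 2, 1, 2)),
#'   features = data.frame(feature_id = paste0("f", 1:3), class = "mirna",
#'                         conservation = "novel"))
#' @export
mw_counts <- function(counts, samples, features) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have row (feature) and column (sample) names")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  stopifnot(all(c("sample_id", "time_point", "replicate") %in% names(samples)),
            all(c("feature_id", "class", "conservation") %in% names(features)))
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  features <- features[match(rownames(counts), features$feature_id), , drop = FALSE]
  if (anyNA(samples$sample_id)) stop("sample sheet does not cover all columns")
  if (anyNA(features$feature_id)) stop("feature sheet does not cover all rows")
  if (anyDuplicated(features$feature_id)) stop("feature ids must be unique")
  structure(list(counts = counts, samples = samples, features = features),
            class = "mw_counts")
}

#' @export
print.mw_counts <- function(x, ...) {
  cat(sprintf("mw_counts: %d features x %d samples (%d time-points)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$samples$time_point))))
  cat("classes:", paste(unique(x$features$class), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.mw_counts <- function(x) dim(x$counts)

#' Average sample-level values into per-time-point means
#'
#' Replicate columns are averaged within each time-point, after whatever
#' normalization the caller applied. Column order follows increasing
#' time-point.
#'
#' @param mat numeric matrix with columns matching `samples$sample_id`
#' @param samples sample sheet (see [mw_counts()])
#' @return features x time-points matrix; columns named `T<t>`
#' @export
timepoint_means <- function(mat, samples) {
  samples <- samples[match(colnames(mat), samples$sample_id), , drop = FALSE]
  tps <- sort(unique(samples$time_point))
  out <- vapply(tps, function(tp) {
    cols <- samples$sample_id[samples$time_point == tp]
    rowMeans(mat[, cols, drop = FALSE])
  }, numeric(nrow(mat)))
  out <- matrix(out, nrow = nrow(mat),
                dimnames = list(rownames(mat), paste0("T", tps)))
  out
}

#' Write/read a count matrix as TSV (feature_id first column)
#' @param x `mw_counts` object
#' @param counts_path,samples_path,features_path output TSV paths
#' @return invisibly, `counts_path`
#' @export
write_counts_tsv <- function(x, counts_path, samples_path = NULL,
                             features_path = NULL) {
  df <- data.frame(feature_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(samples_path))
    write.table(x$samples, samples_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(features_path))
    write.table(x$features, features_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(counts_path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(counts_path, samples_path, features_path) {
  df <- read.delim(counts_path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  mw_counts(m, read.delim(samples_path), read.delim(features_path))
}
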