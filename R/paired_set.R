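#' Paired expression set
#'
#' The unit of data all pipeline stages consume: a non-negative feature x
#' sample matrix (RNA-Seq counts or array signals) together with the paired
#' design -- every subject contributes exactly one carcinoma and one normal
#' sample.
#'
#' @param values numeric matrix, features in rows (rownames = gene symbols or
#'   miRNA names), samples in columns (colnames = sample IDs). All values must
#'   be non-negative and feature IDs unique.
#' @param subject character vector, one entry per column of `values`, mapping
#'   each sample to its subject.
#' @param tissue character vector, one entry per column, each `"carcinoma"` or
#'   `"normal"`.
#' @return An object of class `PairedExpressionSet`: a list with elements
#'   `values`, `subject`, `tissue`.
#' @examples
#' m <- matrix(rpois(8, 10), 2, 4,
#'             dimnames = list(c("G1", "G2"), paste0("s", 1:4)))
#' ps <- paired_set(m, subject = c("a", "a", "b", "b"),
#'                  tissue = c("carcinoma", "normal", "carcinoma", "normal"))
#' @export
paired_set <- function(values, subject, tissue) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature IDs")
  if (any(values < 0)) stop("negative expression values")
  ns <- ncol(values)
  if (length(subject) != ns || length(tissue) != ns)
    stop("'subject' and 'tissue' must have one entry per sample")
  tissue <- as.character(tissue)
  if (!all(tissue %in% c("carcinoma", "normal")))
    stop("tissue labels must be 'carcinoma' or 'normal'")
  subject <- as.character(subject)
  tab <- table(subject, tissue)
  if (!all(dim(tab) == c(length(unique(subject)), 2L)) || !all(tab == 1L))
    stop("every subject must have exactly one carcinoma and one normal sample")
  structure(list(values = values, subject = subject, tissue = tissue),
            class = "PairedExpressionSet")
}

#' @export
print.PairedExpressionSet <- function(x, ...) {
  cat(sprintf("PairedExpressionSet: %d features x %d samples (%d subjects)\n",
              nrow(x$values), ncol(x$values), length(unique(x$subject))))
  if (!is.null(x$normalization))
    cat(sprintf("  normalization: %s\n", x$normalization))
  invisible(x)
}

#' @export
dim.PairedExpressionSet <- function(x) dim(x$values)

#' Subjects of a paired set
#' @param x a `PairedExpressionSet`.
#' @return Character vector of unique subject IDs, in first-appearance order.
#' @export
subjects <- function(x) unique(x$subject)

#' Sample index for one tissue, ordered by subject
#'
#' @param x a `PairedExpressionSet`.
#' @param tissue `"carcinoma"` or `"normal"`.
#' @param subj subject ordering; defaults to [subjects()] of `x`.
#' @return Integer vector of column indices, one per subject.
#' @export
tissue_columns <- function(x, tissue, subj = subjects(x)) {
  idx <- which(x$tissue == tissue)
  idx[match(subj, x$subject[idx])]
}

#' Restrict a paired set to a feature subset
#' @param x a `PairedExpressionSet`.
#' @param features character vector of feature IDs (order preserved from `x`).
#' @return A `PairedExpressionSet` with only the requested features.
#' @export
subset_features <- function(x, features) {
  keep <- rownames(x$values)[rownames(x$values) %in% features]
  out <- x
  out$values <- x$values[keep, , drop = FALSE]
  out
}

#' Restrict a paired set to a subject subset
#' @param x a `PairedExpressionSet`.
#' @param keep character vector of subject IDs to retain.
#' @return A `PairedExpressionSet` containing only samples of those subjects.
#' @export
subset_subjects <- function(x, keep) {
  cols <- x$subject %in% keep
  out <- x
  out$values <- x$values[, cols, drop = FALSE]
  out$subject <- x$subject[cols]
  out$tissue <- x$tissue[cols]
  if (!is.null(out$scale_factors)) out$scale_factors <- out$scale_factors[cols]
  out
}

#' Write / read a paired set as TSV
#'
#' The matrix is written with a `feature` first column and sample IDs as the
#' header; the design (subject, tissue per sample) goes to a companion
#' metadata TSV via [write_metadata_tsv()].
#'
#' @param x a `PairedExpressionSet`.
#' @param file path of the TSV to write.
#' @return `write_pes_tsv` returns `file` invisibly.
#' @export
write_pes_tsv <- function(x, file) {
  df <- data.frame(feature = rownames(x$values), x$values,
                   check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_pes_tsv
#' @param meta data frame with columns `sample`, `subject`, `tissue` (as
#'   written by [write_metadata_tsv()]) describing the samples in `file`.
#' @return `read_pes_tsv` returns a `PairedExpressionSet`.
#' @export
read_pes_tsv <- function(file, meta) {
  df <- utils::read.delim(file, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  meta <- meta[match(colnames(m), meta$sample), ]
  paired_set(m, subject = meta$subject, tissue = meta$tissue)
}

#' Write / read a sample metadata table
#'
#' @param meta data frame with one row per sample (columns `sample`,
#'   `subject`, `tissue`, and optional covariates such as `age`, `sex`,
#'   `msi`).
#' @param file TSV path.
#' @export
write_metadata_tsv <- function(meta, file) {
  utils::write.table(meta, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_metadata_tsv
#' @export
read_metadata_tsv <- function(file) {
  utils::read.delim(file, check.names = FALSE,
                    colClasses = c(sample = "character",
                                   subject = "character"))
}
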