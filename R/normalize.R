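#' RPMPCG normalization for RNA-Seq counts
#'
#' Reads per million protein-coding genes: each count is divided by the
#' sample's total count over all protein-coding genes and multiplied by 1e6.
#' The denominator is always computed over the full protein-coding table, even
#' when the returned set is restricted to a pathway subset, so pathway-level
#' values remain on the cohort scale.
#'
#' @param counts a [paired_set()] of counts. If the generator attached
#'   `lib_sizes` (the simulated protein-coding totals standing in for the full
#'   17,461-gene table), those are used as denominators; otherwise column sums
#'   over `protein_coding_ids` are used.
#' @param protein_coding_ids character vector of protein-coding feature IDs
#'   (must be a subset of the count table's features when denominators are
#'   computed from it).
#' @param subset optional character vector: restrict the returned set to these
#'   features (denominator unaffected).
#' @return A `PairedExpressionSet` with `normalization = "RPMPCG"` and
#'   per-sample `scale_factors` (1e6 / denominator).
#' @export
rpmpcg_normalize <- function(counts, protein_coding_ids = NULL,
                             subset = NULL) {
  stopifnot(inherits(counts, "PairedExpressionSet"))
  if (!is.null(counts$lib_sizes)) {
    denom <- counts$lib_sizes[colnames(counts$values)]
  } else {
    if (is.null(protein_coding_ids))
      stop("protein_coding_ids required when no library sizes are attached")
    missing <- setdiff(protein_coding_ids, rownames(counts$values))
    if (length(missing) > 0)
      stop("protein-coding IDs absent from the count table: ",
           paste(utils::head(missing, 5), collapse = ", "))
    denom <- colSums(counts$values[protein_coding_ids, , drop = FALSE])
  }
  zero <- denom <= 0
  if (any(zero))
    stop("zero protein-coding denominator in sample(s): ",
         paste(colnames(counts$values)[zero], collapse = ", "))
  out <- counts
  out$values <- sweep(counts$values, 2, denom, "/") * 1e6
  if (!is.null(subset))
    out$values <- out$values[rownames(out$values) %in% subset, ,
                             drop = FALSE]
  out$normalization <- "RPMPCG"
  out$scale_factors <- 1e6 / denom
  out
}

#' 75th-percentile scaling for miRNA array signals
#'
#' Each sample is multiplied by a scaling factor: the median of the 75th
#' percentiles of all samples divided by that sample's own 75th percentile.
#' After scaling, the median of per-sample 75th percentiles equals the
#' pre-scaling median. Idempotent: a second application yields factors of 1.
#'
#' @param signals a [paired_set()] of non-negative array signals.
#' @param probs percentile used (default 0.75).
#' @param type quantile interpolation type passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @param detected_only if `TRUE`, percentiles are computed over detected
#'   (value > 0) probes only; default `FALSE` (all probes).
#' @return A `PairedExpressionSet` with `normalization = "Q75"` and the
#'   per-sample `scale_factors` applied.
#' @export
q75_scale <- function(signals, probs = 0.75, type = 7, detected_only = FALSE) {
  stopifnot(inherits(signals, "PairedExpressionSet"))
  p75 <- apply(signals$values, 2, function(v) {
    if (detected_only) v <- v[v > 0]
    if (length(v) == 0) return(0)
    stats::quantile(v, probs = probs, type = type, names = FALSE)
  })
  if (any(p75 <= 0))
    stop("zero 75th percentile in sample(s): ",
         paste(colnames(signals$values)[p75 <= 0], collapse = ", "))
  factors <- stats::median(p75) / p75
  out <- signals
  out$values <- sweep(signals$values, 2, factors, "*")
  out$normalization <- "Q75"
  out$scale_factors <- factors
  out
}

#' Expression-prevalence filter
#'
#' Retains features expressed (strictly > 0) in strictly more than
#' `min_fraction` of the reference samples. Defaults follow the pipeline's
#' conventions: miRNAs require > 20% of normal-mucosa samples
#' (`reference = "normal_only"`); mRNAs require presence in the majority of
#' all samples (`min_fraction = 0.5`, `reference = "all"`).
#'
#' @param data a `PairedExpressionSet` (raw or normalized).
#' @param min_fraction fraction in (0, 1]; features at exactly this prevalence
#'   are dropped (strict inequality).
#' @param reference `"normal_only"` or `"all"`.
#' @return The set restricted to retained features (order preserved). An
#'   empty result triggers a warning, not an error.
#' @export
prevalence_filter <- function(data, min_fraction = 0.20,
                              reference = c("normal_only", "all")) {
  stopifnot(inherits(data, "PairedExpressionSet"))
  reference <- match.arg(reference)
  if (min_fraction <= 0 || min_fraction > 1)
    stop("min_fraction must be in (0, 1]")
  cols <- if (reference == "normal_only") which(data$tissue == "normal")
          else seq_len(ncol(data$values))
  frac <- rowMeans(data$values[, cols, drop = FALSE] > 0)
  keep <- frac > min_fraction
  if (!any(keep)) warning("prevalence filter removed every feature")
  out <- data
  out$values <- data$values[keep, , drop = FALSE]
  out
}
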