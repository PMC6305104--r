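#' Subject-level differential expression
#'
#' For each feature and subject: expression in the carcinoma sample minus
#' expression in the normal-mucosa sample.
#'
#' @param normalized a normalized `PairedExpressionSet`.
#' @return Numeric matrix, features x subjects.
#' @export
differentials <- function(normalized) {
  stopifnot(inherits(normalized, "PairedExpressionSet"))
  subj <- subjects(normalized)
  cc <- tissue_columns(normalized, "carcinoma", subj)
  nc <- tissue_columns(normalized, "normal", subj)
  d <- normalized$values[, cc, drop = FALSE] -
    normalized$values[, nc, drop = FALSE]
  colnames(d) <- subj
  d
}

#' Covariate-adjusted association between two differential profiles
#'
#' Least-squares fit of `d_mrna ~ d_mirna + age + sex` against the null model
#' omitting `d_mirna`; the test statistic is the extra-sum-of-squares F with
#' one numerator degree of freedom. The primary reported slope is
#' standardized (slope of z-scored d_mrna on z-scored d_mirna, a
#' correlation-like scale); the raw-scale slope is also returned.
#'
#' @param d_mrna,d_mirna numeric vectors, one entry per subject (aligned).
#' @param age,sex covariates per subject (sex coded 0/1). `NULL` omits them.
#' @return List with `beta` (standardized), `beta_raw`, `f_stat`, `df2`,
#'   `rss_full`, `rss_null`, and the QR decompositions reused by
#'   [bootstrap_f_pvalue()]. A constant `d_mirna` yields `skipped = TRUE`.
#' @export
fit_association <- function(d_mrna, d_mirna, age = NULL, sex = NULL) {
  n <- length(d_mrna)
  stopifnot(length(d_mirna) == n)
  if (n < 5) stop("need at least 5 subjects")
  if (stats::sd(d_mirna) == 0)
    return(list(skipped = TRUE, beta = NA_real_, f_stat = NA_real_))
  covs <- cbind(intercept = rep(1, n))
  if (!is.null(age)) covs <- cbind(covs, age = age)
  if (!is.null(sex)) covs <- cbind(covs, sex = sex)
  X0 <- covs
  X1 <- cbind(covs, d_mirna = d_mirna)
  qr0 <- qr(X0)
  qr1 <- qr(X1)
  r0 <- qr.resid(qr0, d_mrna)
  r1 <- qr.resid(qr1, d_mrna)
  rss0 <- sum(r0^2)
  rss1 <- sum(r1^2)
  df2 <- n - ncol(X1)
  f <- if (rss1 <= .Machine$double.eps * rss0 || rss1 == 0) Inf
       else (rss0 - rss1) / (rss1 / df2)
  b_raw <- qr.coef(qr1, d_mrna)[["d_mirna"]]
  b_std <- b_raw * stats::sd(d_mirna) / stats::sd(d_mrna)
  list(skipped = FALSE, beta = b_std, beta_raw = b_raw, f_stat = f,
       df2 = df2, rss_full = rss1, rss_null = rss0,
       qr_full = qr1, qr_null = qr0, y = d_mrna,
       fitted_null = d_mrna - r0, resid_null = r0)
}

#' Residual-bootstrap p-value for the association F-test
#'
#' Resamples the null-model residuals with replacement, adds them to the
#' null fitted values, refits full and null models on each pseudo-response
#' and records the F statistic; the p-value is
#' `(1 + #\{F* >= F_obs\}) / (B + 1)` (ties count toward the numerator, and
#' the add-one rule keeps p >= 1/(B+1)). The null model retains the age/sex
#' covariates, so only the miRNA term is resampled away. Refits reuse the
#' observed design's QR decomposition; results are identical to naive
#' refitting.
#'
#' @param fit result of [fit_association()].
#' @param B number of bootstrap resamples (default 10000).
#' @param seed integer seed; the draw is deterministic given it.
#' @return List with `p_raw`, `B`, `f_obs`.
#' @export
bootstrap_f_pvalue <- function(fit, B = 10000, seed = 1L) {
  if (isTRUE(fit$skipped)) stop("association fit was skipped")
  if (B < 1) stop("B must be >= 1")
  n <- length(fit$y)
  with_seed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
    Ystar <- fit$fitted_null + matrix(fit$resid_null[idx], n, B)
    rss0 <- colSums(qr.resid(fit$qr_null, Ystar)^2)
    rss1 <- colSums(qr.resid(fit$qr_full, Ystar)^2)
    fstar <- ifelse(rss1 <= .Machine$double.eps * pmax(rss0, 1), Inf,
                    (rss0 - rss1) / (rss1 / fit$df2))
    p <- (1 + sum(fstar >= fit$f_stat)) / (B + 1)
    list(p_raw = p, B = as.integer(B), f_obs = fit$f_stat)
  })
}

#' Gene-level BH adjustment
#'
#' BH applied separately within each gene's family of miRNA tests
#' (permutation-invariant within a gene).
#'
#' @param records data frame with columns `gene` and `p_raw`.
#' @param p_col name of the p-value column (default `"p_raw"`).
#' @return `records` with a `q` column appended.
#' @export
gene_level_fdr <- function(records, p_col = "p_raw") {
  stopifnot(all(c("gene", p_col) %in% names(records)))
  records$q <- stats::ave(records[[p_col]], records$gene,
                          FUN = function(p) bh_adjust(p))
  records
}

# Deterministic 31-adic hash of the (gene, miRNA) identity, so per-pair
# bootstrap seeds do not depend on iteration order.
pair_hash <- function(gene, mirna) {
  h <- 17
  for (c in utf8ToInt(paste(gene, mirna, sep = "|")))
    h <- (h * 31 + c) %% 2147483629
  h
}

#' Association scan over gated gene and miRNA sets
#'
#' Tests every (gene, miRNA) combination of the supplied differential
#' matrices with [fit_association()] + [bootstrap_f_pvalue()], then applies
#' gene-level BH. Per-pair bootstrap seeds are derived deterministically from
#' `seed` and the pair's (gene, miRNA) identity, so results do not depend on
#' iteration order. Subjects missing from either profile or from the
#' covariates are dropped with a warning.
#'
#' @param d_mrna_mat,d_mirna_mat differential matrices from
#'   [differentials()] (features x subjects; already restricted to the
#'   features to be tested).
#' @param covariates data frame with one row per subject: columns `subject`,
#'   `age`, `sex` -- or `NULL` for unadjusted fits.
#' @param B bootstrap resamples per test (default 10000).
#' @param seed root seed.
#' @return Data frame with one row per tested pair: `gene`, `mirna`, `beta`,
#'   `beta_raw`, `f_stat`, `p_raw`, `q`, `n_subjects`, `bootstrap_reps`,
#'   `seed`.
#' @export
run_association <- function(d_mrna_mat, d_mirna_mat, covariates = NULL,
                            B = 10000, seed = 1L) {
  subj <- intersect(colnames(d_mrna_mat), colnames(d_mirna_mat))
  if (!is.null(covariates)) subj <- intersect(subj, covariates$subject)
  dropped <- setdiff(union(colnames(d_mrna_mat), colnames(d_mirna_mat)), subj)
  if (length(dropped) > 0)
    warning(length(dropped), " subject(s) dropped (incomplete profiles)")
  age <- sex <- NULL
  if (!is.null(covariates)) {
    cv <- covariates[match(subj, covariates$subject), ]
    age <- cv$age
    sex <- cv$sex
  }
  genes <- rownames(d_mrna_mat)
  mirnas <- rownames(d_mirna_mat)
  rows <- vector("list", length(genes) * length(mirnas))
  k <- 0L
  for (gi in seq_along(genes)) {
    for (mi in seq_along(mirnas)) {
      k <- k + 1L
      fit <- fit_association(d_mrna_mat[genes[gi], subj],
                             d_mirna_mat[mirnas[mi], subj],
                             age = age, sex = sex)
      if (isTRUE(fit$skipped)) {
        warning("constant miRNA differential; test skipped for ",
                mirnas[mi])
        rows[[k]] <- data.frame(gene = genes[gi], mirna = mirnas[mi],
                                beta = NA_real_, beta_raw = NA_real_,
                                f_stat = NA_real_, p_raw = NA_real_,
                                n_subjects = length(subj),
                                bootstrap_reps = as.integer(B),
                                seed = NA_integer_)
        next
      }
      pair_seed <- sub_seed(seed, pair_hash(genes[gi], mirnas[mi]))
      bt <- bootstrap_f_pvalue(fit, B = B, seed = pair_seed)
      rows[[k]] <- data.frame(gene = genes[gi], mirna = mirnas[mi],
                              beta = fit$beta, beta_raw = fit$beta_raw,
                              f_stat = fit$f_stat, p_raw = bt$p_raw,
                              n_subjects = length(subj),
                              bootstrap_reps = bt$B, seed = pair_seed)
    }
  }
  res <- do.call(rbind, rows)
  tested <- !is.na(res$p_raw)
  res$q <- NA_real_
  if (any(tested)) {
    adj <- gene_level_fdr(res[tested, , drop = FALSE])
    res$q[tested] <- adj$q
  }
  rownames(res) <- NULL
  res
}

#' Write an association table as TSV
#'
#' Mirrors the conventional layout: per-feature means and fold changes of
#' both members, the standardized beta, raw and gene-level adjusted
#' p-values, and the bootstrap provenance (n, B, seed).
#'
#' @param assoc data frame from [run_association()].
#' @param mrna_norm,mirna_norm normalized sets used to annotate means and
#'   fold changes (optional; columns omitted when `NULL`).
#' @param file output path.
#' @export
write_association_tsv <- function(assoc, file, mrna_norm = NULL,
                                  mirna_norm = NULL) {
  out <- assoc
  annotate <- function(out, pes, feat_col, prefix) {
    fc <- t(vapply(out[[feat_col]], function(f) {
      x <- fold_change(pes, f)
      c(x$mean_carcinoma, x$mean_normal, x$fc)
    }, numeric(3)))
    colnames(fc) <- paste0(prefix, c("_carcinoma", "_normal", "_fc"))
    cbind(out, round(fc, 2))
  }
  if (!is.null(mrna_norm)) out <- annotate(out, mrna_norm, "gene", "gene")
  if (!is.null(mirna_norm)) out <- annotate(out, mirna_norm, "mirna", "mirna")
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
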