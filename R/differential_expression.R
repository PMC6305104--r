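#' Paired negative-binomial fit for one gene
#'
#' Fits count ~ NB(mean = exp(b0 + b_t * \[carcinoma\] + u_i + offset),
#' size = theta) to one gene's paired counts, where u_i is a per-subject
#' effect and the offset is the log of the sample's protein-coding total. Two
#' subject-effect implementations are provided: a random intercept fitted by
#' Laplace ML (`method = "random"`, via glmmTMB) and per-subject fixed
#' intercepts (`method = "fixed"`, via MASS::glm.nb) -- the documented
#' fallback for small data; the two agree closely in simulation. The test of
#' b_t = 0 is a likelihood-ratio test by default (more stable than Wald at
#' low counts), with Wald available.
#'
#' @param y integer counts, one per sample.
#' @param subject subject ID per sample.
#' @param tissue `"carcinoma"`/`"normal"` per sample.
#' @param offset_log log protein-coding total per sample.
#' @param method `"random"` (NB GLMM random intercept) or `"fixed"`
#'   (per-subject fixed intercepts).
#' @param test `"LRT"` or `"Wald"`.
#' @return List with `beta` (log fold-change estimate b_t), `se`, `p_raw`,
#'   `theta`, `converged`, `all_zero`. An all-zero gene returns `p_raw = 1`
#'   flagged `all_zero = TRUE`; non-convergence is flagged via
#'   `converged = FALSE`.
#' @export
fit_paired_nb <- function(y, subject, tissue, offset_log,
                          method = c("random", "fixed"),
                          test = c("LRT", "Wald")) {
  method <- match.arg(method)
  test <- match.arg(test)
  if (length(unique(subject)) < 3) stop("need at least 3 complete pairs")
  if (all(y == 0))
    return(list(beta = NA_real_, se = NA_real_, p_raw = 1, theta = NA_real_,
                converged = FALSE, all_zero = TRUE))
  dat <- data.frame(y = y, subject = factor(subject),
                    carcinoma = as.numeric(tissue == "carcinoma"),
                    off = offset_log)
  res <- tryCatch({
    if (method == "random") {
      full <- suppressWarnings(
        glmmTMB::glmmTMB(y ~ carcinoma + (1 | subject) + offset(off),
                         family = glmmTMB::nbinom2, data = dat))
      co <- summary(full)$coefficients$cond["carcinoma", ]
      theta <- glmmTMB::sigma(full)
      # nlminb soft codes (e.g. false convergence at the Poisson boundary
      # theta -> Inf) still give usable estimates when the Hessian is PD
      conv <- isTRUE(full$fit$convergence == 0) ||
        isTRUE(full$sdr$pdHess)
      if (test == "LRT") {
        null <- suppressWarnings(
          glmmTMB::glmmTMB(y ~ 1 + (1 | subject) + offset(off),
                           family = glmmTMB::nbinom2, data = dat))
        lr <- 2 * (as.numeric(stats::logLik(full)) -
                   as.numeric(stats::logLik(null)))
        p <- stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
      } else {
        p <- co[["Pr(>|z|)"]]
      }
      list(beta = co[["Estimate"]], se = co[["Std. Error"]], p_raw = p,
           theta = theta, converged = conv, all_zero = FALSE)
    } else {
      # NB ML with theta -> Inf (no overdispersion) breaks the theta
      # iteration; the boundary fit is exactly Poisson, so fall back to it
      fit_one <- function(formula) {
        tryCatch(suppressWarnings(MASS::glm.nb(formula, data = dat)),
                 error = function(e)
                   stats::glm(formula, family = stats::poisson, data = dat))
      }
      full <- fit_one(y ~ carcinoma + subject + offset(off))
      co <- summary(full)$coefficients["carcinoma", ]
      if (test == "LRT") {
        null <- fit_one(y ~ subject + offset(off))
        lr <- 2 * (as.numeric(stats::logLik(full)) -
                   as.numeric(stats::logLik(null)))
        p <- stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
      } else {
        p <- co[[4L]]
      }
      list(beta = co[["Estimate"]], se = co[["Std. Error"]], p_raw = p,
           theta = if (is.null(full$theta)) Inf else full$theta,
           converged = full$converged, all_zero = FALSE)
    }
  }, error = function(e) {
    list(beta = NA_real_, se = NA_real_, p_raw = NA_real_, theta = NA_real_,
         converged = FALSE, all_zero = FALSE)
  })
  res
}

#' Fold change of normalized means
#'
#' Arithmetic means of normalized (RPMPCG) values over carcinoma and normal
#' samples, and their ratio. The reported fold change is this ratio of means
#' (not exp of the model coefficient); output tables round it to two
#' decimals while full precision is retained internally.
#'
#' @param normalized a normalized `PairedExpressionSet`.
#' @param gene feature ID.
#' @return List with `mean_carcinoma`, `mean_normal`, `fc` (`NA` flagged when
#'   the normal mean is zero).
#' @export
fold_change <- function(normalized, gene) {
  stopifnot(inherits(normalized, "PairedExpressionSet"))
  if (!gene %in% rownames(normalized$values)) stop("gene not present: ", gene)
  v <- normalized$values[gene, ]
  mc <- mean(v[normalized$tissue == "carcinoma"])
  mn <- mean(v[normalized$tissue == "normal"])
  list(mean_carcinoma = mc, mean_normal = mn,
       fc = if (mn > 0) mc / mn else NA_real_)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH with monotonicity enforcement, order-preserving with
#' the input (thin validated wrapper over [stats::p.adjust()]).
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, elementwise >= the raw values.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Fold-change and FDR gate
#'
#' Keeps genes with adjusted p below `fdr` and fold change strictly above
#' `high` or strictly below `low`. Inequalities are strict at the precision
#' of the supplied `fc` values (a printed table gated at two decimals
#' excludes a printed 1.50).
#'
#' @param records data frame with columns `gene`, `fc`, `p_adj`.
#' @param low,high fold-change bounds (defaults 0.67 and 1.50).
#' @param fdr FDR threshold (default 0.05).
#' @return Character vector of passing gene IDs, in input order.
#' @export
fc_gate <- function(records, low = 0.67, high = 1.50, fdr = 0.05) {
  stopifnot(all(c("gene", "fc", "p_adj") %in% names(records)))
  pass <- !is.na(records$fc) & !is.na(records$p_adj) &
    records$p_adj < fdr & (records$fc > high | records$fc < low)
  records$gene[pass]
}

#' Genes unique to a stratum
#'
#' Set difference: genes passing the gate in a stratum-specific analysis
#' (MSS-only or MSI-only) but not in the overall analysis.
#'
#' @param overall_pass,stratum_pass character vectors of gated gene IDs.
#' @return `stratum_pass` minus `overall_pass`.
#' @export
stratum_unique <- function(overall_pass, stratum_pass) {
  setdiff(stratum_pass, overall_pass)
}

#' Paired differential expression over a gene set
#'
#' Runs [fit_paired_nb()] per gene on raw counts (offsets = log
#' protein-coding totals), attaches RPMPCG means and fold changes, and
#' BH-adjusts raw p-values within the analysis. Non-convergent genes are
#' excluded from the FDR family with a warning and carry `p_adj = NA`.
#'
#' @param counts a [paired_set()] of raw counts with `lib_sizes` attached (or
#'   supply `offsets`).
#' @param normalized the matching RPMPCG-normalized set.
#' @param genes genes to analyze (default: all features of `normalized`).
#' @param offsets optional log-denominator per sample.
#' @param stratum label stored on the output (`"overall"`, `"MSS"`, `"MSI"`).
#' @param method,test passed to [fit_paired_nb()].
#' @return Data frame of per-gene records: `gene`, `mean_carcinoma`,
#'   `mean_normal`, `fc`, `beta`, `p_raw`, `p_adj`, `converged`,
#'   `passes_fc_gate`, `stratum`.
#' @export
run_differential_expression <- function(counts, normalized,
                                        genes = rownames(normalized$values),
                                        offsets = NULL,
                                        stratum = "overall",
                                        method = "random", test = "LRT") {
  stopifnot(inherits(counts, "PairedExpressionSet"))
  if (is.null(offsets)) {
    if (is.null(counts$lib_sizes))
      stop("no library sizes attached; supply 'offsets'")
    offsets <- log(counts$lib_sizes[colnames(counts$values)])
  }
  rows <- lapply(genes, function(g) {
    fit <- fit_paired_nb(counts$values[g, ], counts$subject, counts$tissue,
                         offsets, method = method, test = test)
    fcs <- fold_change(normalized, g)
    data.frame(gene = g, mean_carcinoma = fcs$mean_carcinoma,
               mean_normal = fcs$mean_normal, fc = fcs$fc,
               beta = fit$beta, p_raw = fit$p_raw,
               converged = fit$converged, all_zero = fit$all_zero)
  })
  de <- do.call(rbind, rows)
  family <- (de$converged | de$all_zero) & !is.na(de$p_raw)
  if (any(!family))
    warning(sum(!family), " gene(s) excluded from the FDR family ",
            "(non-convergent fit)")
  de$p_adj <- NA_real_
  de$p_adj[family] <- bh_adjust(de$p_raw[family])
  de$passes_fc_gate <- de$gene %in% fc_gate(de)
  de$stratum <- stratum
  rownames(de) <- NULL
  de
}

#' Write a differential-expression table as TSV
#' @param de data frame from [run_differential_expression()].
#' @param file output path.
#' @param digits decimals used for means and fold change (default 2,
#'   mirroring the conventional presentation).
#' @export
write_de_tsv <- function(de, file, digits = 2) {
  out <- de
  for (cn in c("mean_carcinoma", "mean_normal", "fc"))
    out[[cn]] <- round(out[[cn]], digits)
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
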