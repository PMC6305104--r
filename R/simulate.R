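#' Simulation configuration for a paired tumor/normal cohort
#'
#' Defines the data-generating conditions for the synthetic cohort: paired
#' negative-binomial RNA-Seq counts with a per-subject random intercept and a
#' library-size offset, miRNA array signals with per-sample multiplicative
#' scale distortions, planted miRNA-mRNA couplings on the subject-level
#' differential scale, and planted 3' UTR seed sites.
#'
#' Defaults mirror the cohort the pipeline was designed around: 217 subjects,
#' 122 pathway genes, age ~ Normal(64.8, 10.1), 54.4% male, 13.4% MSI.
#' Quantities with no reported counterpart (dispersion, library sizes, subject
#' SD, array distortion range) are fixed at values typical of bulk FFPE
#' RNA-Seq and array data; see the methods vignette.
#'
#' @param n_subjects number of subjects (each yields one carcinoma and one
#'   normal sample).
#' @param n_genes,n_mirnas numbers of genes and miRNAs.
#' @param baseline_log_mean per-gene log relative abundance (log scale,
#'   relative to the library-size offset). Scalar recycled; `NULL` draws
#'   log-uniform abundances spanning roughly 2--300 RPMPCG.
#' @param tumor_log_fc per-gene natural-log fold change (carcinoma vs normal).
#'   Scalar recycled.
#' @param dispersion per-gene NB size parameter theta (> 0). Scalar recycled.
#' @param library_size_range ordered pair: range of per-sample protein-coding
#'   totals (uniform draw).
#' @param subject_sd SD of the per-subject random intercept on the log scale.
#' @param array_scale_range pair of positive reals: per-sample multiplicative
#'   array distortion, drawn log-uniformly. `c(1, 1)` disables distortion.
#' @param mirna_log_fc per-miRNA natural-log carcinoma/normal fold change of
#'   the array signal (scalar recycled; default 0 = no dysregulation).
#' @param planted_associations `NULL`, or a data frame with columns `gene`,
#'   `mirna` (1-based indices) and `beta` (target standardized slope of the
#'   mRNA-differential on the miRNA-differential).
#' @param noise_sd SD of the unit-scale Gaussian noise added to planted miRNA
#'   differentials (the planted signal has unit scale, so `noise_sd = 1`
#'   yields standardized slopes near `beta / sqrt(beta^2 + 1)`).
#' @param planted_sites `NULL`, or a data frame with columns `gene`, `mirna`
#'   (1-based indices) and `site_type`; `NULL` derives one site per planted
#'   association using `site_type_default`.
#' @param utr_length length of each simulated 3' UTR (nt).
#' @param gc_content background UTR GC fraction.
#' @param seed_mode seed convention used when planting sites: `"literal"`
#'   (seed = miRNA positions 1..k) or `"canonical"` (positions 2..k+1 with
#'   A1-anchored variants).
#' @param site_type_default site type planted for derived sites (`"p1-7"` for
#'   literal mode; use e.g. `"8mer"` with canonical mode).
#' @param age_mean,age_sd,male_prop,msi_prop subject covariate distributions.
#' @param seed integer root RNG seed; each generator operation uses a
#'   deterministic substream derived from it.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_subjects = 217, n_genes = 122, n_mirnas = 50,
                       baseline_log_mean = NULL, tumor_log_fc = 0,
                       dispersion = 10,
                       library_size_range = c(5e5, 2e6),
                       subject_sd = 0.3,
                       array_scale_range = c(0.5, 2),
                       mirna_log_fc = 0,
                       planted_associations = NULL,
                       noise_sd = 1,
                       planted_sites = NULL,
                       utr_length = 2000, gc_content = 0.5,
                       seed_mode = c("literal", "canonical"),
                       site_type_default = "p1-7",
                       age_mean = 64.8, age_sd = 10.1,
                       male_prop = 0.544, msi_prop = 0.134,
                       seed = 1L) {
  seed_mode <- match.arg(seed_mode)
  if (n_subjects < 1 || n_genes < 1 || n_mirnas < 1)
    stop("dimensions must be positive")
  if (any(dispersion <= 0)) stop("dispersion must be > 0")
  if (length(library_size_range) != 2 || diff(library_size_range) < 0 ||
      library_size_range[1] <= 0)
    stop("library_size_range must be an ordered pair of positive values")
  if (any(array_scale_range <= 0) || diff(array_scale_range) < 0)
    stop("array_scale_range must be an ordered pair of positive values")
  if (subject_sd < 0) stop("subject_sd must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (utr_length < 1) stop("utr_length must be positive")
  if (is.null(baseline_log_mean)) {
    baseline_log_mean <- with_seed(sub_seed(seed, 0L),
                                   stats::runif(n_genes, log(2e-6), log(3e-4)))
  }
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_genes = as.integer(n_genes),
    n_mirnas = as.integer(n_mirnas),
    baseline_log_mean = rep_len(baseline_log_mean, n_genes),
    tumor_log_fc = rep_len(tumor_log_fc, n_genes),
    dispersion = rep_len(dispersion, n_genes),
    library_size_range = library_size_range, subject_sd = subject_sd,
    array_scale_range = array_scale_range,
    mirna_log_fc = rep_len(mirna_log_fc, n_mirnas),
    planted_associations = planted_associations, noise_sd = noise_sd,
    planted_sites = planted_sites,
    utr_length = as.integer(utr_length), gc_content = gc_content,
    seed_mode = seed_mode, site_type_default = site_type_default,
    age_mean = age_mean, age_sd = age_sd, male_prop = male_prop,
    msi_prop = msi_prop, seed = as.integer(seed))
  for (pl in list(cfg$planted_associations, cfg$planted_sites)) {
    if (!is.null(pl)) {
      if (any(pl$gene < 1 | pl$gene > n_genes) ||
          any(pl$mirna < 1 | pl$mirna > n_mirnas))
        stop("planted pair references a gene or miRNA index out of range")
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic substream seed for one generator operation.
sub_seed <- function(seed, k)
  as.integer((abs(as.numeric(seed)) + as.numeric(k) * 1000003) %% 2147483629)

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  code
}

gene_ids <- function(n) sprintf("gene_%03d", seq_len(n))
mirna_ids <- function(n) sprintf("hsa-miR-sim-%03d", seq_len(n))

#' Simulate paired RNA-Seq counts
#'
#' For subject i with random intercept u_i ~ Normal(0, `subject_sd`) and
#' sample library size L, the count of gene g in tissue t is drawn
#' NB(mean = exp(baseline_g + tumor_log_fc_g * \[t = carcinoma\] + u_i +
#' log L), size = theta_g).
#'
#' @param config a [sim_config()].
#' @return A list with `counts` (a [paired_set()] of integer counts, with
#'   per-sample `lib_sizes` attached as element `lib_sizes`) and `truth`
#'   (ground truth: `true_de_genes`, `true_log_fc`, `planted_associations`,
#'   `planted_sites`).
#' @export
simulate_paired_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(sub_seed(config$seed, 1L), {
    n <- config$n_subjects
    g <- config$n_genes
    subj <- sprintf("subj_%03d", seq_len(n))
    samples <- c(paste0(subj, "_C"), paste0(subj, "_N"))
    tissue <- rep(c("carcinoma", "normal"), each = n)
    subject <- rep(subj, 2L)
    u <- stats::rnorm(n, 0, config$subject_sd)
    lib <- round(stats::runif(2L * n, config$library_size_range[1],
                              config$library_size_range[2]))
    is_carc <- tissue == "carcinoma"
    log_mu <- outer(config$baseline_log_mean, rep(u, 2L), "+") +
      outer(config$tumor_log_fc, as.numeric(is_carc)) +
      matrix(log(lib), g, 2L * n, byrow = TRUE)
    counts <- matrix(
      stats::rnbinom(g * 2L * n, mu = exp(log_mu),
                     size = rep(config$dispersion, 2L * n)),
      g, 2L * n, dimnames = list(gene_ids(g), samples))
    pes <- paired_set(counts, subject = subject, tissue = tissue)
    pes$lib_sizes <- stats::setNames(lib, samples)
    truth <- list(
      true_log_fc = stats::setNames(config$tumor_log_fc, gene_ids(g)),
      true_de_genes = gene_ids(g)[config$tumor_log_fc != 0],
      subject_effects = stats::setNames(u, subj),
      planted_associations = config$planted_associations,
      planted_sites = NULL)
    list(counts = pes, truth = truth)
  })
}

#' Simulate a mature miRNA catalog
#'
#' Random 22-nt mature sequences over the RNA alphabet with miRBase-style
#' names.
#'
#' @param config a [sim_config()].
#' @return Named character vector of RNA sequences (5' to 3').
#' @export
simulate_mirna_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(sub_seed(config$seed, 5L), {
    seqs <- vapply(seq_len(config$n_mirnas), function(i)
      paste(sample(c("A", "C", "G", "U"), 22, replace = TRUE), collapse = ""),
      "")
    # redraw until the 6-nt seed windows at offsets 0/1/2 are pairwise
    # distinct across miRNAs; otherwise one miRNA's seed core can be fully
    # contained in another's planted site, which clean-mode backgrounds
    # could never separate
    windows <- function(s) c(substr(s, 1, 6), substr(s, 2, 7),
                             substr(s, 3, 8))
    for (it in 1:1000) {
      used <- character(0)
      bad <- logical(length(seqs))
      for (i in seq_along(seqs)) {
        w <- windows(seqs[i])
        bad[i] <- any(w %in% used)
        if (!bad[i]) used <- c(used, unique(w))
      }
      if (!any(bad)) break
      seqs[bad] <- vapply(which(bad), function(i)
        paste(sample(c("A", "C", "G", "U"), 22, replace = TRUE),
              collapse = ""), "")
    }
    if (it == 1000L)
      warning("catalog seed regions are not all distinct")
    stats::setNames(seqs, mirna_ids(config$n_mirnas))
  })
}

#' Simulate miRNA array signals with planted couplings
#'
#' Subject-level miRNA differentials are generated directly (the association
#' stage operates on differentials, so ground truth is cleanest there) and
#' back-allocated to carcinoma/normal signals. For a planted pair the miRNA
#' differential is `beta * z + noise_sd * e` on a unit scale, where `z` is the
#' z-scored library-size-normalized mRNA differential of the planted gene and
#' `e` is standard normal; unplanted miRNAs get independent noise. A miRNA's
#' own dysregulation (`mirna_log_fc`) multiplies its carcinoma values, so the
#' carcinoma/normal fold change of means is near `exp(mirna_log_fc)`. Every
#' sample is then multiplied by a distortion drawn log-uniformly from
#' `array_scale_range` (the distortion [q75_scale()] is designed to remove).
#'
#' @param config a [sim_config()].
#' @param truth ground truth from [simulate_paired_counts()].
#' @param counts the simulated count set (used to form mRNA differentials for
#'   planted couplings).
#' @return A list with `signals` (a [paired_set()] of non-negative reals,
#'   sample design identical to `counts`) and `truth` with element
#'   `array_scale` (the planted per-sample distortions) added.
#' @export
simulate_mirna_signals <- function(config, truth, counts) {
  stopifnot(inherits(config, "sim_config"),
            inherits(counts, "PairedExpressionSet"))
  with_seed(sub_seed(config$seed, 2L), {
    n <- config$n_subjects
    m <- config$n_mirnas
    subj <- subjects(counts)
    cc <- tissue_columns(counts, "carcinoma", subj)
    nc <- tissue_columns(counts, "normal", subj)
    lib <- counts$lib_sizes
    norm_counts <- 1e6 * sweep(counts$values, 2, lib, "/")
    d_mrna <- norm_counts[, cc, drop = FALSE] - norm_counts[, nc, drop = FALSE]

    base <- 10^stats::runif(m, 0.5, 2.5)
    normal_sig <- base * exp(matrix(stats::rnorm(m * n, 0, 0.1), m, n))
    d_std <- matrix(stats::rnorm(m * n), m, n)
    pa <- config$planted_associations
    if (!is.null(pa) && nrow(pa) > 0) {
      first <- !duplicated(pa$mirna)
      if (any(!first))
        warning("multiple planted genes per miRNA; only the first is used")
      pa <- pa[first, , drop = FALSE]
      for (r in seq_len(nrow(pa))) {
        z <- as.numeric(scale(d_mrna[pa$gene[r], ]))
        d_std[pa$mirna[r], ] <- pa$beta[r] * z +
          config$noise_sd * stats::rnorm(n)
      }
    }
    # differential noise scales with the lower-expressed tissue so strongly
    # down-regulated miRNAs are not pushed below zero
    d <- d_std * (0.3 * base * pmin(1, exp(config$mirna_log_fc)))
    carc_sig <- pmax(normal_sig * exp(config$mirna_log_fc) + d, 0)

    sig <- matrix(0, m, 2L * n,
                  dimnames = list(mirna_ids(m), colnames(counts$values)))
    sig[, cc] <- carc_sig
    sig[, nc] <- normal_sig
    scale_f <- exp(stats::runif(2L * n, log(config$array_scale_range[1]),
                                log(config$array_scale_range[2])))
    sig <- sweep(sig, 2, scale_f, "*")
    pes <- paired_set(sig, subject = counts$subject, tissue = counts$tissue)
    truth$array_scale <- stats::setNames(scale_f, colnames(sig))
    list(signals = pes, truth = truth)
  })
}

#' Simulate 3' UTR sequences with planted seed sites
#'
#' Random-background DNA UTRs (one isoform per gene) with, for each planted
#' (gene, miRNA) pair, the exact seed-site string of the configured
#' convention inserted at a recorded position. In clean mode the background is
#' resampled so that no unplanted exact site for any catalog miRNA remains
#' (O(catalog x length); off by default).
#'
#' @param config a [sim_config()].
#' @param truth ground truth list (planted site positions are appended as
#'   element `planted_sites`).
#' @param mirna_seqs named RNA sequences from [simulate_mirna_catalog()].
#' @param clean logical; if `TRUE`, scrub unplanted background sites.
#' @return A list with `utrs` (a data frame of [utr_records()]) and updated
#'   `truth`; `truth$planted_sites` has columns `gene`, `mirna`,
#'   `utr_position` (0-based) and `site_type`.
#' @export
simulate_utrs <- function(config, truth, mirna_seqs, clean = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(sub_seed(config$seed, 3L), {
    g <- config$n_genes
    L <- config$utr_length
    gids <- gene_ids(g)
    gc <- config$gc_content
    probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    draw_bg <- function(len)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = probs),
            collapse = "")
    seqs <- vapply(seq_len(g), function(i) draw_bg(L), "")
    names(seqs) <- gids

    sites <- config$planted_sites
    if (is.null(sites) && !is.null(config$planted_associations))
      sites <- data.frame(gene = config$planted_associations$gene,
                          mirna = config$planted_associations$mirna,
                          site_type = config$site_type_default)
    planted <- NULL
    if (!is.null(sites) && nrow(sites) > 0) {
      occupied <- vector("list", g)  # planted intervals per gene
      recs <- vector("list", nrow(sites))
      for (r in seq_len(nrow(sites))) {
        gi <- sites$gene[r]
        pat <- site_pattern(mirna_seqs[[sites$mirna[r]]], sites$site_type[r])
        w <- nchar(pat)
        if (L < w) stop("UTR too short for site insertion")
        ok <- FALSE
        for (try in 1:200) {
          pos <- sample.int(L - w + 1L, 1L) - 1L  # 0-based
          iv <- c(pos, pos + w)
          clash <- any(vapply(occupied[[gi]], function(o)
            iv[1] < o[2] && o[1] < iv[2], TRUE))
          if (!clash) { ok <- TRUE; break }
        }
        if (!ok) stop("could not place planted site without overlap")
        substr(seqs[gi], pos + 1L, pos + w) <- pat
        occupied[[gi]] <- c(occupied[[gi]], list(iv))
        recs[[r]] <- data.frame(gene = gids[gi],
                                mirna = names(mirna_seqs)[sites$mirna[r]],
                                utr_position = pos,
                                site_type = sites$site_type[r])
      }
      planted <- do.call(rbind, recs)
    }

    if (clean) {
      # 0-based half-open planted intervals per gene; mutations must stay
      # outside them so scrubbing never destroys a planted site
      protected <- lapply(gids, function(gid) {
        if (is.null(planted)) return(NULL)
        pl <- planted[planted$gene == gid, , drop = FALSE]
        lapply(seq_len(nrow(pl)), function(r) {
          w <- nchar(site_pattern(mirna_seqs[[pl$mirna[r]]],
                                  pl$site_type[r]))
          c(pl$utr_position[r], pl$utr_position[r] + w)
        })
      })
      names(protected) <- gids
      is_protected <- function(gid, pos)  # pos 0-based
        any(vapply(protected[[gid]], function(iv)
          pos >= iv[1] && pos < iv[2], TRUE))
      for (pass in 1:100) {
        dirty <- FALSE
        utr_df <- utr_records(gids, seqs)
        for (gi in seq_len(g)) {
          rec <- utr_df[gi, ]
          for (mi in seq_along(mirna_seqs)) {
            hits <- find_seed_matches(rec, mirna_seqs[mi],
                                      mode = config$seed_mode)
            if (nrow(hits) == 0) next
            pl <- planted[planted$gene == gids[gi] &
                            planted$mirna == names(mirna_seqs)[mi], ,
                          drop = FALSE]
            extra <- hits[!(hits$utr_start %in% pl$utr_position), ,
                          drop = FALSE]
            for (hr in seq_len(nrow(extra))) {
              cand <- setdiff(seq(extra$utr_start[hr],
                                  extra$utr_end[hr] - 1L),
                              Filter(function(p) is_protected(gids[gi], p),
                                     seq(extra$utr_start[hr],
                                         extra$utr_end[hr] - 1L)))
              if (length(cand) == 0) next  # site inseparable from planted
              p <- cand[1] + 1L            # 1-based for substr
              old <- substr(seqs[gi], p, p)
              substr(seqs[gi], p, p) <-
                sample(setdiff(c("A", "C", "G", "T"), old), 1L)
              dirty <- TRUE
            }
          }
        }
        if (!dirty) break
      }
      if (dirty) warning("clean mode did not converge; residual sites remain")
    }

    truth$planted_sites <- planted
    list(utrs = utr_records(gids, seqs), truth = truth)
  })
}

#' Simulate a sample metadata table
#'
#' One row per sample; subject-level covariates (age ~ Normal, sex and MSI
#' status Bernoulli) are repeated across a subject's two samples.
#'
#' @param config a [sim_config()].
#' @return Data frame with columns `sample`, `subject`, `tissue`, `age`,
#'   `sex` (0 = female, 1 = male), `msi` ("MSS"/"MSI").
#' @export
simulate_metadata <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(sub_seed(config$seed, 4L), {
    n <- config$n_subjects
    subj <- sprintf("subj_%03d", seq_len(n))
    age <- round(stats::rnorm(n, config$age_mean, config$age_sd), 1)
    sex <- stats::rbinom(n, 1, config$male_prop)
    msi <- ifelse(stats::rbinom(n, 1, config$msi_prop) == 1, "MSI", "MSS")
    data.frame(
      sample = c(paste0(subj, "_C"), paste0(subj, "_N")),
      subject = rep(subj, 2L),
      tissue = rep(c("carcinoma", "normal"), each = n),
      age = rep(age, 2L), sex = rep(sex, 2L), msi = rep(msi, 2L))
  })
}

#' Write ground truth as JSON
#' @param truth ground-truth list from the simulators.
#' @param file output path.
#' @export
write_truth_json <- function(truth, file) {
  jsonlite::write_json(truth, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(file)
}
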