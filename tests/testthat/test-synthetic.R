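test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(n_subjects = 10, n_genes = 15, n_mirnas = 6,
                    planted_associations = data.frame(gene = 2, mirna = 3,
                                                      beta = -0.4),
                    seed = 99)
  a <- simulate_paired_counts(cfg)
  b <- simulate_paired_counts(cfg)
  expect_identical(a$counts$values, b$counts$values)
  sa <- simulate_mirna_signals(cfg, a$truth, a$counts)
  sb <- simulate_mirna_signals(cfg, b$truth, b$counts)
  expect_identical(sa$signals$values, sb$signals$values)
  cat1 <- simulate_mirna_catalog(cfg)
  expect_identical(cat1, simulate_mirna_catalog(cfg))
  u1 <- simulate_utrs(cfg, sa$truth, cat1)
  u2 <- simulate_utrs(cfg, sb$truth, cat1)
  expect_identical(u1$utrs$sequence, u2$utrs$sequence)
  expect_identical(u1$truth$planted_sites, u2$truth$planted_sites)
  # metadata is byte-identical on disk
  f1 <- tempfile(); f2 <- tempfile()
  write_metadata_tsv(simulate_metadata(cfg), f1)
  write_metadata_tsv(simulate_metadata(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("config validation rejects impossible conditions", {
  expect_error(sim_config(n_subjects = 0), "positive")
  expect_error(sim_config(dispersion = -1), "dispersion")
  expect_error(sim_config(library_size_range = c(10, 5)), "ordered")
  expect_error(
    sim_config(n_genes = 3, n_mirnas = 2,
               planted_associations = data.frame(gene = 9, mirna = 1,
                                                 beta = 0.3)),
    "out of range")
})

test_that("null simulation gives symmetric carcinoma/normal means", {
  cfg <- sim_config(n_subjects = 50, n_genes = 200, tumor_log_fc = 0,
                    seed = 5)
  sim <- simulate_paired_counts(cfg)
  norm <- rpmpcg_normalize(sim$counts)
  ratios <- vapply(rownames(norm$values),
                   function(g) fold_change(norm, g)$fc, 0)
  expect_gte(mean(ratios > 0.8 & ratios < 1.25), 0.95)
})

test_that("counts approach the Poisson limit as dispersion grows", {
  # 10,000 draws of one gene at constant mean: variance ~ mean
  cfg <- sim_config(n_subjects = 5000, n_genes = 1, n_mirnas = 1,
                    baseline_log_mean = log(5e-5), tumor_log_fc = 0,
                    dispersion = 1e6, subject_sd = 0,
                    library_size_range = c(1e6, 1e6), seed = 8)
  sim <- simulate_paired_counts(cfg)
  y <- as.numeric(sim$counts$values)
  expect_equal(stats::var(y) / mean(y), 1, tolerance = 0.05)
  # and at theta = 2 the same moment estimate shows clear overdispersion
  cfg2 <- sim_config(n_subjects = 5000, n_genes = 1, n_mirnas = 1,
                     baseline_log_mean = log(5e-5), tumor_log_fc = 0,
                     dispersion = 2, subject_sd = 0,
                     library_size_range = c(1e6, 1e6), seed = 8)
  y2 <- as.numeric(simulate_paired_counts(cfg2)$counts$values)
  expect_equal(stats::var(y2) / mean(y2), 1 + mean(y2) / 2, tolerance = 0.1)
})

test_that("array distortions are planted as configured", {
  cfg <- sim_config(n_subjects = 12, n_genes = 5, n_mirnas = 10,
                    array_scale_range = c(1, 1), seed = 3)
  sim <- simulate_paired_counts(cfg)
  sig <- simulate_mirna_signals(cfg, sim$truth, sim$counts)
  expect_true(all(sig$truth$array_scale == 1))
  cfg2 <- sim_config(n_subjects = 12, n_genes = 5, n_mirnas = 10,
                     array_scale_range = c(0.5, 2), seed = 3)
  sig2 <- simulate_mirna_signals(cfg2, sim$truth, sim$counts)
  expect_true(all(sig2$truth$array_scale >= 0.5 &
                    sig2$truth$array_scale <= 2))
  expect_true(all(sig2$signals$values >= 0))
})

test_that("planted couplings surface as strong negative correlations", {
  # catalog of 30+ miRNAs so the Q75 factors are stably estimable
  cfg <- sim_config(n_subjects = 100, n_genes = 10, n_mirnas = 30,
                    planted_associations = data.frame(gene = 1:5,
                                                      mirna = 1:5,
                                                      beta = -0.8),
                    noise_sd = 0.2, seed = 21)
  sim <- simulate_paired_counts(cfg)
  sig <- simulate_mirna_signals(cfg, sim$truth, sim$counts)
  dm <- differentials(rpmpcg_normalize(sim$counts))
  ds <- differentials(q75_scale(sig$signals))
  for (i in 1:5)
    expect_lt(cor(dm[i, ], ds[i, ]), -0.5)
  # unplanted pairs stay near zero
  expect_lt(abs(cor(dm[6, ], ds[6, ])), 0.35)
  expect_lt(abs(cor(dm[6, ], ds[20, ])), 0.35)
})

test_that("planted UTR sites are recoverable by exact string search", {
  cfg <- sim_config(n_subjects = 5, n_genes = 30, n_mirnas = 10,
                    planted_sites = data.frame(gene = rep(1:15, 2),
                                               mirna = rep(1:10, 3),
                                               site_type = "p1-7"),
                    utr_length = 500, seed = 13)
  mir <- simulate_mirna_catalog(cfg)
  truth <- list()
  res <- simulate_utrs(cfg, truth, mir)
  ps <- res$truth$planted_sites
  expect_equal(nrow(ps), 30L)
  for (r in seq_len(nrow(ps))) {
    seq <- res$utrs$sequence[res$utrs$gene == toupper(ps$gene[r])]
    pat <- pairmir:::site_pattern(mir[[ps$mirna[r]]], ps$site_type[r])
    found <- substr(seq, ps$utr_position[r] + 1,
                    ps$utr_position[r] + nchar(pat))
    expect_identical(found, pat)
  }
  # too-short UTR errors
  cfg_short <- sim_config(n_subjects = 5, n_genes = 2, n_mirnas = 1,
                          planted_sites = data.frame(gene = 1, mirna = 1,
                                                     site_type = "p1-8"),
                          utr_length = 5, seed = 1)
  expect_error(simulate_utrs(cfg_short, list(), mir[1]), "too short")
})

test_that("clean mode leaves no unplanted catalog sites", {
  cfg <- sim_config(n_subjects = 5, n_genes = 10, n_mirnas = 5,
                    planted_sites = data.frame(gene = 1:5, mirna = 1:5,
                                               site_type = "p1-7"),
                    utr_length = 800, seed = 17)
  mir <- simulate_mirna_catalog(cfg)
  res <- simulate_utrs(cfg, list(), mir, clean = TRUE)
  hits <- scan_seed_matches(res$utrs, mir, mode = "literal")
  ps <- res$truth$planted_sites
  key_hit <- paste(hits$gene, hits$mirna, hits$utr_start)
  key_planted <- paste(toupper(ps$gene), ps$mirna, ps$utr_position)
  expect_setequal(key_hit, key_planted)
})

test_that("metadata mirrors the configured cohort composition", {
  cfg <- sim_config(n_subjects = 217, n_genes = 2, n_mirnas = 2, seed = 30)
  md <- simulate_metadata(cfg)
  expect_equal(nrow(md), 434L)
  subj <- md[!duplicated(md$subject), ]
  n_msi <- sum(subj$msi == "MSI")
  # expected 217 * 0.134 = 29.1; assert within the central 99% binomial band
  band <- qbinom(c(0.005, 0.995), 217, 0.134)
  expect_gte(n_msi, band[1])
  expect_lte(n_msi, band[2])
  cfg0 <- sim_config(n_subjects = 40, n_genes = 2, n_mirnas = 2,
                     msi_prop = 0, seed = 30)
  expect_true(all(simulate_metadata(cfg0)$msi == "MSS"))
})
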