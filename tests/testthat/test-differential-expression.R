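make_pairs <- function(normal_counts, fc = 1) {
  n <- length(normal_counts)
  subj <- sprintf("s%02d", seq_len(n))
  y <- c(round(normal_counts * fc), normal_counts)
  list(y = y, subject = rep(subj, 2),
       tissue = rep(c("carcinoma", "normal"), each = n),
       offset = rep(log(1e6), 2 * n))
}

test_that("paired NB fit recovers a deterministic two-fold difference", {
  set.seed(10)
  d <- make_pairs(rpois(30, 50), fc = 2)
  for (method in c("random", "fixed")) {
    fit <- fit_paired_nb(d$y, d$subject, d$tissue, d$offset, method = method)
    expect_true(exp(fit$beta) > 1.8 && exp(fit$beta) < 2.2)
    expect_lt(fit$p_raw, 1e-6)
  }
})

test_that("identical tissues give a null fit and all-zero genes are flagged", {
  set.seed(11)
  d <- make_pairs(rpois(30, 50), fc = 1)  # carcinoma == normal exactly
  fit <- fit_paired_nb(d$y, d$subject, d$tissue, d$offset, method = "fixed")
  expect_lt(abs(fit$beta), 0.05)
  expect_gt(fit$p_raw, 0.5)
  z <- fit_paired_nb(rep(0, 20), rep(sprintf("s%d", 1:10), 2),
                     rep(c("carcinoma", "normal"), each = 10),
                     rep(log(1e6), 20))
  expect_equal(z$p_raw, 1)
  expect_true(z$all_zero)
  expect_error(fit_paired_nb(1:4, c("a", "b", "a", "b"),
                             rep(c("carcinoma", "normal"), each = 2),
                             rep(0, 4)),
               "3 complete pairs")
})

test_that("subject-effect implementations agree on the effect estimate", {
  cfg <- sim_config(n_subjects = 40, n_genes = 6,
                    tumor_log_fc = rep(c(0, log(2), log(0.5)), 2),
                    baseline_log_mean = log(5e-5), seed = 14)
  sim <- simulate_paired_counts(cfg)
  off <- log(sim$counts$lib_sizes)
  for (g in 1:6) {
    fr <- fit_paired_nb(sim$counts$values[g, ], sim$counts$subject,
                        sim$counts$tissue, off, method = "random",
                        test = "Wald")
    ff <- fit_paired_nb(sim$counts$values[g, ], sim$counts$subject,
                        sim$counts$tissue, off, method = "fixed",
                        test = "Wald")
    expect_lt(abs(fr$beta - ff$beta), 0.05)
  }
})

test_that("type-I error of the paired NB test is near nominal", {
  cfg <- sim_config(n_subjects = 30, n_genes = 300, tumor_log_fc = 0,
                    baseline_log_mean = log(5e-5), seed = 15)
  sim <- simulate_paired_counts(cfg)
  off <- log(sim$counts$lib_sizes)
  p <- vapply(seq_len(300), function(g)
    fit_paired_nb(sim$counts$values[g, ], sim$counts$subject,
                  sim$counts$tissue, off, method = "random",
                  test = "Wald")$p_raw, 0)
  rate <- mean(p < 0.05, na.rm = TRUE)
  # central 99% binomial band around 0.05 for 300 draws
  expect_gte(rate, qbinom(0.005, 300, 0.05) / 300)
  expect_lte(rate, qbinom(0.995, 300, 0.05) / 300)
})

test_that("power increases with effect size at fixed n", {
  effects <- c(log(1.2), log(1.8), log(3))
  rates <- vapply(seq_along(effects), function(i) {
    cfg <- sim_config(n_subjects = 25, n_genes = 40,
                      tumor_log_fc = effects[i],
                      baseline_log_mean = log(5e-5), seed = 100 + i)
    sim <- simulate_paired_counts(cfg)
    off <- log(sim$counts$lib_sizes)
    p <- vapply(seq_len(40), function(g)
      fit_paired_nb(sim$counts$values[g, ], sim$counts$subject,
                    sim$counts$tissue, off, method = "fixed",
                    test = "Wald")$p_raw, 0)
    mean(p < 0.05)
  }, 0)
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], 0.9)
})

test_that("fold change is the ratio of normalized tissue means", {
  # means engineered to the MYC- and LIFR-like printed values
  myc <- toy_from_blocks(cbind(c(181.11, 13.28), c(181.11, 13.28)),
                         cbind(c(49.00, 59.86), c(49.00, 59.86)))
  rownames(myc$values) <- c("gA", "gB")
  fa <- fold_change(myc, "gA")
  expect_equal(round(fa$fc, 2), 3.70)
  fb <- fold_change(myc, "gB")
  expect_equal(round(fb$fc, 2), 0.22)
  same <- toy_from_blocks(cbind(c(7, 7)), cbind(c(7, 7)))
  rownames(same$values) <- c("x", "y")
  expect_equal(fold_change(same, "x")$fc, 1.0)
  zero <- toy_from_blocks(cbind(c(3, 1)), cbind(c(0, 1)))
  rownames(zero$values) <- c("z1", "z2")
  expect_true(is.na(fold_change(zero, "z1")$fc))
  expect_error(fold_change(same, "missing"), "not present")
})

test_that("BH adjustment is step-up with monotonicity", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(16)
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the FC gate is strict at both bounds", {
  rec <- data.frame(gene = c("hras_like", "tslp_like", "up", "null"),
                    fc = c(1.50, 0.66, 1.51, 1.00),
                    p_adj = c(0.001, 0.047, 0.001, 0.9))
  expect_equal(fc_gate(rec), c("tslp_like", "up"))
  rec2 <- data.frame(gene = "g", fc = 0.67, p_adj = 0.001)
  expect_equal(fc_gate(rec2), character(0))
})

test_that("stratum-unique genes are the set difference after gating", {
  expect_equal(stratum_unique(c("A", "B"), c("B", "C")), "C")
  expect_equal(stratum_unique(c("A", "B"), c("A")), character(0))
  # planted MSI-only effect: moderate FC in MSI pairs only
  set.seed(17)
  n <- 40
  msi <- rep(c(TRUE, FALSE), each = n / 2)
  subj <- sprintf("s%02d", 1:n)
  norm_cts <- matrix(rpois(2 * n, 60), 2, n)
  carc_cts <- norm_cts
  carc_cts[1, msi] <- rpois(sum(msi), 60 * 1.9)  # gene 1: MSI-only effect
  m <- cbind(carc_cts, norm_cts)
  dimnames(m) <- list(c("msi_gene", "null_gene"),
                      c(paste0(subj, "_C"), paste0(subj, "_N")))
  ps <- paired_set(m, subject = rep(subj, 2),
                   tissue = rep(c("carcinoma", "normal"), each = n))
  ps$lib_sizes <- setNames(rep(1e6, 2 * n), colnames(m))
  nrm <- rpmpcg_normalize(ps)
  de_all <- run_differential_expression(ps, nrm, method = "fixed",
                                        test = "Wald")
  msi_subj <- subj[msi]
  ps_msi <- subset_subjects(ps, msi_subj)
  de_msi <- run_differential_expression(ps_msi, subset_subjects(nrm, msi_subj),
                                        method = "fixed", test = "Wald",
                                        stratum = "MSI")
  uniq <- stratum_unique(fc_gate(de_all), fc_gate(de_msi))
  expect_equal(uniq, "msi_gene")
})

test_that("the DE driver assembles records, FDR family and gate flags", {
  cfg <- sim_config(n_subjects = 25, n_genes = 12,
                    tumor_log_fc = c(rep(log(3), 3), rep(0, 9)),
                    baseline_log_mean = log(5e-5), seed = 18)
  sim <- simulate_paired_counts(cfg)
  nrm <- rpmpcg_normalize(sim$counts)
  de <- run_differential_expression(sim$counts, nrm, method = "fixed",
                                    test = "Wald")
  expect_equal(nrow(de), 12L)
  expect_true(all(de$p_adj >= de$p_raw, na.rm = TRUE))
  expect_setequal(de$gene[de$passes_fc_gate], sprintf("gene_%03d", 1:3))
  f <- tempfile(fileext = ".tsv")
  write_de_tsv(de, f)
  back <- read.delim(f)
  expect_equal(back$fc, round(de$fc, 2))
})
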