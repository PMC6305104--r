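# pairmir

Integration analysis of messenger-RNA and microRNA expression in **paired
tumor/normal designs**, where every subject contributes one carcinoma and one
normal-tissue sample. The package is written for transcriptomics analysts
who want to ask, for a pathway gene set: *which miRNAs plausibly regulate
which dysregulated transcripts?* — and to answer it with calibrated
statistics rather than correlation screenshots. Its stages were built around
a colorectal-carcinoma JAK-STAT study design (217 pairs, 122 pathway genes,
RNA-Seq + miRNA arrays) and ship with that study's printed result tables as
validation fixtures.

## The model

**Normalization.** RNA-Seq counts become RPMPCG (reads per million
protein-coding genes): `x[g,s] = 1e6 * count[g,s] / N_s`, with `N_s` the
sample's total count over all protein-coding genes. Array signals are scaled
per sample by `median_s'(P75_s') / P75_s`.

**Paired differential expression.** Counts of gene *g* follow a negative
binomial mixed model

    log E[y_is] = b0 + b_t * [tissue = carcinoma] + u_i + log N_s,
    y_is ~ NB(mean, theta_g),   u_i ~ Normal(0, sigma_u^2)

with a Wald or likelihood-ratio test of `b_t = 0`, BH FDR across the gene
set, and a fold-change gate (ratio of mean RPMPCG values > 1.50 or < 0.67,
FDR < 0.05). MSS/MSI tumor strata are rerun identically; stratum-unique
genes are set differences against the overall pass list.

**Association.** Subject-level differentials `d = x_carcinoma - x_normal`
enter `d_mRNA ~ d_miRNA + age + sex`; the extra-sum-of-squares F of the
miRNA term is referred to a residual-bootstrap null distribution
(B = 10,000; `p = (1 + #{F* >= F_obs}) / (B + 1)`), then BH-adjusted within
each gene's family of miRNA tests.

**Seed matching and classification.** Exact Watson-Crick complements of the
miRNA seed (literal positions 1-6/7/8 or canonical
6mer/7mer-m8/7mer-A1/8mer) are scanned in 3' UTRs across isoforms and
assemblies. Significant associations are classified by slope sign x seed
flag; negative slope with a seed match is canonical miRNA-mediated
repression.

## Worked example

A five-gene synthetic cohort with one planted fold change (3.70) and one
planted repressive miRNA coupling:

```r
library(pairmir)

cfg <- sim_config(n_subjects = 50, n_genes = 5, n_mirnas = 40,
                  tumor_log_fc = c(log(3.7), rep(0, 4)),
                  planted_associations = data.frame(gene = 1, mirna = 1,
                                                    beta = -0.5),
                  noise_sd = 0.5, seed = 7)
sim <- simulate_paired_counts(cfg)
sig <- simulate_mirna_signals(cfg, sim$truth, sim$counts)
md  <- simulate_metadata(cfg)

norm <- rpmpcg_normalize(sim$counts)
fold_change(norm, "gene_001")
#> mean_carcinoma 1050.13, mean_normal 298.04, fc 3.52

fit <- fit_paired_nb(sim$counts$values["gene_001", ], sim$counts$subject,
                     sim$counts$tissue, log(sim$counts$lib_sizes))
exp(fit$beta); fit$p_raw
#> 3.55        5.3e-28

cov <- unique(md[, c("subject", "age", "sex")])
dm <- differentials(norm)
ds <- differentials(q75_scale(sig$signals))
cv <- cov[match(colnames(dm), cov$subject), ]
af <- fit_association(dm["gene_001", ], ds["hsa-miR-sim-001", ],
                      cv$age, cv$sex)
af$beta
#> -0.53
bootstrap_f_pvalue(af, B = 9999, seed = 7)$p_raw
#> 2e-04
classify(af$beta, TRUE)
#> "repression"
```

The planted fold change (3.70) comes back as 3.52 on the normalized scale
and 3.55 from the model; the planted standardized slope (-0.5) comes back as
-0.53 with a bootstrap p of 2x10^-4, and the pair lands in the canonical
repression category.

The packaged reference tables reproduce the published result structure
exactly:

```r
length(fc_gate(load_de_reference()))
#> 42                      # dysregulated genes passing FC gate + FDR
ar <- load_association_reference()
ar$category <- classify(ar$beta, ar$seed_match)
summarize_interactions(ar)
#> 116 interactions, 46 miRNAs, 17 genes, 87 positive / 29 negative,
#> 69 seed matches; categories 20 / 9 / 38 / 49
```

## The analysis workflow

Numbered drivers under `analysis/` run the full pipeline on a synthetic
217-subject cohort with planted ground truth and write their tables under
`results/`:

    analysis/01_simulate.R                # cohort + ground truth
    analysis/02_normalize.R               # RPMPCG, Q75, prevalence filters
    analysis/03_differential_expression.R # paired NB, gate, MSS/MSI strata
    analysis/04_association.R             # bootstrap F-tests, gene-level BH
    analysis/05_seed_match.R              # UTR scan, site table, flags
    analysis/06_classify.R                # categories, summary, SIF/GraphML

Each script prints what it found (planted DE genes recovered, planted
couplings significant, planted sites recovered) so a run is self-auditing.

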