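#!/usr/bin/env Rscript
# Association between subject-level differential expressions: for every
# (gated mRNA, retained miRNA) pair, a least-squares model of the mRNA
# differential on the miRNA differential adjusted for age and sex; p-values
# from the residual bootstrap of the null model's F distribution; BH FDR at
# the gene level.

source("analysis/00_config.R")
meta <- read_metadata_tsv(file.path(DATA_DIR, "metadata.tsv"))

mrna_norm <- read_pes_tsv(file.path(RESULTS, "mrna_rpmpcg.tsv"), meta)
mirna_norm <- read_pes_tsv(file.path(RESULTS, "mirna_q75.tsv"), meta)
gated <- readLines(file.path(RESULTS, "gated_genes.txt"))

d_mrna <- differentials(subset_features(mrna_norm, gated))
d_mirna <- differentials(mirna_norm)
covariates <- unique(meta[, c("subject", "age", "sex")])

assoc <- run_association(d_mrna, d_mirna, covariates,
                         B = BOOTSTRAP_B, seed = ROOT_SEED)
write_association_tsv(assoc, file.path(RESULTS, "associations.tsv"),
                      mrna_norm = mrna_norm, mirna_norm = mirna_norm)

sig <- assoc[!is.na(assoc$q) & assoc$q < 0.05, ]
cat(sprintf("tested %d pairs (%d genes x %d miRNAs), %d significant at q < 0.05\n",
            nrow(assoc), nrow(d_mrna), nrow(d_mirna), nrow(sig)))
pl <- cohort_config$planted_associations
pl_key <- paste(sprintf("gene_%03d", pl$gene),
                sprintf("hsa-miR-sim-%03d", pl$mirna))
cat(sprintf("planted couplings significant: %d / %d\n",
            sum(pl_key %in% paste(sig$gene, sig$mirna)), nrow(pl)))
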