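#!/usr/bin/env Rscript
# Normalize: RPMPCG for counts (denominator = per-sample protein-coding
# totals), median-of-75th-percentiles scaling for array signals, then the
# prevalence filters (miRNA: expressed in > 20% of normal mucosa;
# mRNA: expressed in > 50% of all samples).

source("analysis/00_config.R")
meta <- read_metadata_tsv(file.path(DATA_DIR, "metadata.tsv"))

counts <- read_pes_tsv(file.path(DATA_DIR, "counts.tsv"), meta)
counts$lib_sizes <- setNames(
  as.numeric(readLines(file.path(DATA_DIR, "protein_coding_totals.txt"))),
  colnames(counts$values))
signals <- read_pes_tsv(file.path(DATA_DIR, "mirna_signals.tsv"), meta)

mrna_norm <- rpmpcg_normalize(counts)
mrna_norm <- prevalence_filter(mrna_norm, 0.50, "all")
mirna_norm <- q75_scale(signals)
mirna_norm <- prevalence_filter(mirna_norm, 0.20, "normal_only")

write_pes_tsv(mrna_norm, file.path(RESULTS, "mrna_rpmpcg.tsv"))
write_pes_tsv(mirna_norm, file.path(RESULTS, "mirna_q75.tsv"))

cat(sprintf("mRNA retained: %d / %d\n", nrow(mrna_norm$values),
            nrow(counts$values)))
cat(sprintf("miRNA retained: %d / %d\n", nrow(mirna_norm$values),
            nrow(signals$values)))
cat(sprintf("Q75 scale factors span %.2f-%.2f\n",
            min(mirna_norm$scale_factors), max(mirna_norm$scale_factors)))
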