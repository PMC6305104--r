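#!/usr/bin/env Rscript
# Generate the synthetic paired cohort: RNA-Seq counts, miRNA array signals,
# sample metadata, mature miRNA catalog, 3' UTRs with planted seed sites,
# and the ground-truth record. Everything downstream reads these files.

source("analysis/00_config.R")
dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)

sim <- simulate_paired_counts(cohort_config)
sig <- simulate_mirna_signals(cohort_config, sim$truth, sim$counts)
mirnas <- simulate_mirna_catalog(cohort_config)
utr <- simulate_utrs(cohort_config, sig$truth, mirnas)
meta <- simulate_metadata(cohort_config)

write_pes_tsv(sim$counts, file.path(DATA_DIR, "counts.tsv"))
writeLines(as.character(sim$counts$lib_sizes),
           file.path(DATA_DIR, "protein_coding_totals.txt"))
write_pes_tsv(sig$signals, file.path(DATA_DIR, "mirna_signals.tsv"))
write_metadata_tsv(meta, file.path(DATA_DIR, "metadata.tsv"))
write_mirna_fasta(mirnas, file.path(DATA_DIR, "mirnas_synthetic.fa"))
write_utr_fasta(utr$utrs, file.path(DATA_DIR, "utrs_synthetic.fa"))
write_truth_json(utr$truth, file.path(DATA_DIR, "ground_truth.json"))

cat(sprintf("cohort: %d subjects, %d genes, %d miRNAs\n",
            cohort_config$n_subjects, cohort_config$n_genes,
            cohort_config$n_mirnas))
cat(sprintf("planted: %d DE genes, %d associations, %d UTR sites\n",
            sum(cohort_config$tumor_log_fc != 0),
            nrow(cohort_config$planted_associations),
            nrow(utr$truth$planted_sites)))
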