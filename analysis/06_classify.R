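#!/usr/bin/env Rscript
# Classification and network export: join significant associations with the
# gene-level seed flags, assign each interaction to one of the four
# beta-sign x seed-match categories, summarize, and export SIF + GraphML.

source("analysis/00_config.R")
meta <- read_metadata_tsv(file.path(DATA_DIR, "metadata.tsv"))

assoc <- read.delim(file.path(RESULTS, "associations.tsv"))
utrs <- read_utr_fasta(file.path(DATA_DIR, "utrs_synthetic.fa"))
mirnas <- read_mirna_fasta(file.path(DATA_DIR, "mirnas_synthetic.fa"))
mirna_norm <- read_pes_tsv(file.path(RESULTS, "mirna_q75.tsv"), meta)
mrna_norm <- read_pes_tsv(file.path(RESULTS, "mrna_rpmpcg.tsv"), meta)

sig <- assoc[!is.na(assoc$q) & assoc$q < 0.05, ]
flags <- seed_match_flags(unique(sig[, c("gene", "mirna")]),
                          utr_records(utrs$gene, utrs$sequence,
                                      utrs$isoform, utrs$assembly),
                          mirnas, mode = "literal")
mirna_fc <- vapply(rownames(mirna_norm$values),
                   function(m) fold_change(mirna_norm, m)$fc, 0)
gene_fc <- vapply(unique(sig$gene),
                  function(g) fold_change(mrna_norm, g)$fc, 0)

# genes live upper-cased in the UTR db; align the association table
flags$gene <- toupper(flags$gene)
sig$gene_uc <- toupper(sig$gene)
ints <- build_interactions(
  transform(sig, gene = gene_uc), flags,
  q_threshold = 0.05, mirna_fc = mirna_fc)
write.table(ints[, c("gene", "mirna", "beta", "q", "seed_match", "category")],
            file.path(RESULTS, "interactions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

summ <- summarize_interactions(ints)
jsonlite::write_json(summ, file.path(RESULTS, "interaction_summary.json"),
                     auto_unbox = TRUE, digits = NA)
names(gene_fc) <- toupper(names(gene_fc))
export_network(ints, file.path(RESULTS, "network.sif"), "SIF")
export_network(ints, file.path(RESULTS, "network.graphml"), "GraphML",
               gene_fc = gene_fc, mirna_fc = mirna_fc)

cat(sprintf("interactions: %d (%d genes, %d miRNAs)\n",
            summ$n_interactions, summ$n_unique_genes, summ$n_unique_mirnas))
cat(sprintf("categories: repression %d | negative no-seed %d | positive no-seed %d | positive with-seed %d\n",
            summ$categories["repression"],
            summ$categories["negative_no_seed"],
            summ$categories["positive_no_seed"],
            summ$categories["positive_with_seed"]))
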