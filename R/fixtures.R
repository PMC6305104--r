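#' Packaged reference tables
#'
#' Two tab-delimited reference tables ship with the package under
#' `inst/extdata`: the per-gene paired differential-expression table for the
#' 122 analyzed JAK-STAT signaling genes (`jakstat_de_table.tsv`: RPMPCG
#' means in carcinoma and normal mucosa, fold change, raw and BH-adjusted
#' p-values) and the significant miRNA-mRNA association table
#' (`jakstat_mirna_assoc_table.tsv`: 116 interactions with per-feature means
#' and fold changes, standardized beta, raw and gene-level adjusted p-values,
#' a seed-match flag, and the analysis stratum). P-values printed as censored
#' (`"<0.001"`, `"<.0001"`) are parsed to half the bound, with the printed
#' string retained in a `*_printed` column.
#'
#' @return Data frame; `load_de_reference` has columns `gene`,
#'   `mean_carcinoma`, `mean_normal`, `fc`, `p_raw`, `p_adj` (+ `_printed`);
#'   `load_association_reference` additionally carries `mirna`, miRNA means
#'   and fold change, `beta`, `seed_match` (logical) and `stratum`.
#' @export
load_de_reference <- function() {
  f <- system.file("extdata", "jakstat_de_table.tsv", package = "pairmir",
                   mustWork = TRUE)
  df <- utils::read.delim(f, check.names = FALSE,
                          colClasses = c(p_raw = "character", p_adj = "character"))
  out <- data.frame(gene = df$gene, mean_carcinoma = df$mean_carcinoma,
                    mean_normal = df$mean_normal, fc = df$fold_change,
                    p_raw = parse_printed_p(df$p_raw),
                    p_adj = parse_printed_p(df$p_adj),
                    p_raw_printed = df$p_raw, p_adj_printed = df$p_adj)
  out
}

#' @rdname load_de_reference
#' @export
load_association_reference <- function() {
  f <- system.file("extdata", "jakstat_mirna_assoc_table.tsv",
                   package = "pairmir", mustWork = TRUE)
  df <- utils::read.delim(f, check.names = FALSE,
                          colClasses = c(p_raw = "character", p_adj = "character"))
  df$seed_match <- df$seed_match == 1
  df$p_raw_printed <- df$p_raw
  df$p_raw <- parse_printed_p(df$p_raw_printed)
  df$p_adj_printed <- df$p_adj
  df$p_adj <- parse_printed_p(df$p_adj_printed)
  df
}

# "<0.001" / "<.0001" -> half the bound; plain numbers pass through.
parse_printed_p <- function(x) {
  cens <- grepl("^<", x)
  val <- as.numeric(sub("^<", "", x))
  ifelse(cens, val / 2, val)
}
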