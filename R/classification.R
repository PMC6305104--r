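#' Classify a miRNA-mRNA interaction
#'
#' Four categories from the sign of the association beta and the seed-match
#' flag: a negative beta with a seed match is consistent with canonical
#' miRNA-mediated repression of the transcript; the other combinations
#' indicate indirect or downstream effects (or, for positive beta with a seed
#' match, a possible feedback loop). A beta of exactly zero (impossible with
#' continuous data but guarded) is bucketed separately as `"no_effect"`.
#'
#' @param beta numeric vector of association slopes.
#' @param seed_match logical vector.
#' @return Character vector: `"repression"`, `"negative_no_seed"`,
#'   `"positive_no_seed"`, `"positive_with_seed"`, or `"no_effect"`.
#' @examples
#' classify(-0.27, TRUE)   # repression
#' classify(0.31, TRUE)    # positive_with_seed
#' @export
classify <- function(beta, seed_match) {
  stopifnot(length(beta) == length(seed_match))
  ifelse(beta == 0, "no_effect",
  ifelse(beta < 0 & seed_match, "repression",
  ifelse(beta < 0, "negative_no_seed",
  ifelse(seed_match, "positive_with_seed", "positive_no_seed"))))
}

#' Assemble the significant-interaction table
#'
#' Joins association records with gene-level seed flags, admits records with
#' gene-level q below `q_threshold`, applies the miRNA fold-change reporting
#' filter (the association test itself is run before this filter so FDR
#' families are unaffected), and attaches categories.
#'
#' @param assoc data frame from [run_association()] (columns `gene`, `mirna`,
#'   `beta`, `q`).
#' @param seed_flags data frame with columns `gene`, `mirna`, `seed_match`
#'   (e.g. from [seed_match_flags()]).
#' @param q_threshold admission threshold on gene-level q (default 0.05).
#' @param mirna_fc optional named vector of miRNA fold changes; when
#'   supplied, only interactions whose miRNA has fc > `fc_high` or
#'   < `fc_low` are reported.
#' @param fc_low,fc_high miRNA fold-change reporting bounds.
#' @return Data frame of interactions with `category` attached.
#' @export
build_interactions <- function(assoc, seed_flags, q_threshold = 0.05,
                               mirna_fc = NULL, fc_low = 0.67,
                               fc_high = 1.50) {
  keep <- !is.na(assoc$q) & assoc$q < q_threshold
  out <- assoc[keep, , drop = FALSE]
  if (!is.null(mirna_fc)) {
    fc <- mirna_fc[out$mirna]
    out <- out[!is.na(fc) & (fc > fc_high | fc < fc_low), , drop = FALSE]
  }
  key <- paste(out$gene, out$mirna)
  fkey <- paste(seed_flags$gene, seed_flags$mirna)
  out$seed_match <- seed_flags$seed_match[match(key, fkey)]
  out$seed_match[is.na(out$seed_match)] <- FALSE
  out$category <- classify(out$beta, out$seed_match)
  rownames(out) <- NULL
  out
}

#' Summarize an interaction set
#'
#' Counts per category plus distinct-feature totals. Duplicate (gene, miRNA)
#' rows violate the uniqueness invariant and raise an error.
#'
#' @param interactions data frame with columns `gene`, `mirna`, `beta`,
#'   `seed_match`, `category`.
#' @return List with `n_interactions`, `n_unique_mirnas`, `n_unique_genes`,
#'   `n_positive_beta`, `n_negative_beta`, `n_seed_matches`, and `categories`
#'   (named counts over the four categories).
#' @export
summarize_interactions <- function(interactions) {
  if (anyDuplicated(interactions[c("gene", "mirna")]))
    stop("duplicated (gene, miRNA) interaction rows")
  cats <- c("repression", "negative_no_seed", "positive_no_seed",
            "positive_with_seed")
  counts <- vapply(cats, function(k) sum(interactions$category == k), 0L)
  list(n_interactions = nrow(interactions),
       n_unique_mirnas = length(unique(interactions$mirna)),
       n_unique_genes = length(unique(interactions$gene)),
       n_positive_beta = sum(interactions$beta > 0),
       n_negative_beta = sum(interactions$beta < 0),
       n_seed_matches = sum(interactions$seed_match),
       categories = counts)
}

#' Export the interaction network
#'
#' Bipartite gene/miRNA graph with node attributes (`type`, `fc`, `direction`
#' up/down) and edge attributes (`beta`, `q`, `seed_match`, `category`).
#' Nodes and edges are emitted in sorted order, so re-export is
#' byte-identical. Formats: `"SIF"` (simple interaction format: source,
#' category, target) and `"GraphML"` (via igraph).
#'
#' @param interactions data frame from [build_interactions()].
#' @param file output path.
#' @param format `"SIF"` or `"GraphML"`.
#' @param gene_fc,mirna_fc optional named fold-change vectors for node
#'   attributes.
#' @return `file`, invisibly.
#' @export
export_network <- function(interactions, file,
                           format = c("SIF", "GraphML"),
                           gene_fc = NULL, mirna_fc = NULL) {
  format <- match.arg(format)
  ints <- interactions[order(interactions$gene, interactions$mirna), ,
                       drop = FALSE]
  if (format == "SIF") {
    lines <- sprintf("%s\t%s\t%s", ints$gene, ints$category, ints$mirna)
    writeLines(lines, file)
    return(invisible(file))
  }
  genes <- sort(unique(ints$gene))
  mirnas <- sort(unique(ints$mirna))
  nodes <- data.frame(
    name = c(genes, mirnas),
    type = rep(c("gene", "mirna"), c(length(genes), length(mirnas))))
  fc <- c(if (is.null(gene_fc)) rep(NA_real_, length(genes))
          else unname(gene_fc[genes]),
          if (is.null(mirna_fc)) rep(NA_real_, length(mirnas))
          else unname(mirna_fc[mirnas]))
  nodes$fc <- fc
  nodes$direction <- ifelse(is.na(fc), "unknown",
                            ifelse(fc > 1, "up", "down"))
  edges <- data.frame(from = ints$gene, to = ints$mirna, beta = ints$beta,
                      q = ints$q, seed_match = ints$seed_match,
                      category = ints$category)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
}
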