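# Naive all-offsets seed-scan oracle: checks every UTR offset against every
# full site pattern by direct substring comparison, then keeps the highest
# tier at each 6-nt core anchor. Independent of the anchored scanner in the
# package (which classifies by flanking bases instead of matching full
# patterns).
naive_seed_scan <- function(utr_seq, mirna_seq, mirna_name, gene,
                            mode = "literal") {
  s <- toupper(utr_seq)
  L <- nchar(s)
  tiers <- if (mode == "canonical") {
    list(c("8mer", 1L), c("7mer-m8", 1L), c("7mer-A1", 0L), c("6mer", 0L))
  } else {
    list(c("p1-8", 2L), c("p1-7", 1L), c("p1-6", 0L))
  }
  hits <- list()
  seen_anchor <- integer(0)
  for (t in tiers) {
    pat <- pairmir:::site_pattern(mirna_seq, t[[1]])
    w <- nchar(pat)
    if (L < w) next
    idx <- seq_len(L - w + 1L)
    at <- idx[substring(s, idx, idx + w - 1L) == pat]  # every offset checked
    anchor <- at - 1L + as.integer(t[[2]])             # 0-based core anchor
    new <- !(anchor %in% seen_anchor)
    seen_anchor <- c(seen_anchor, anchor[new])
    if (any(new))
      hits[[length(hits) + 1L]] <- data.frame(
        mirna = mirna_name, gene = gene, site_type = t[[1]],
        utr_start = at[new] - 1L, utr_end = at[new] - 1L + w)
  }
  out <- do.call(rbind, hits)
  if (is.null(out))
    return(data.frame(mirna = character(0), gene = character(0),
                      site_type = character(0), utr_start = integer(0),
                      utr_end = integer(0)))
  out[order(out$utr_start), , drop = FALSE]
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "")
}

random_rna <- function(n, len = 22) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = ""),
    "")
}
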