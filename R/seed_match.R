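#' Extract a miRNA seed sequence
#'
#' The seed is the 5'-proximal stretch of the mature miRNA whose Watson-Crick
#' complement in an mRNA 3' UTR predicts direct targeting. Two conventions are
#' supported: `"literal"` takes the first `k` nucleotides (positions 1..k);
#' `"canonical"` takes positions 2..(k+1), the core used by the
#' 6mer/7mer-m8/7mer-A1/8mer site-type hierarchy (A1-anchored variants are
#' handled in [find_seed_matches()]).
#'
#' @param mirna_seq mature miRNA sequence, RNA alphabet, 5' to 3'. `T` is
#'   accepted and converted to `U` with a warning.
#' @param k seed length, one of 6, 7, 8.
#' @param mode `"literal"` or `"canonical"`.
#' @return RNA seed string.
#' @examples
#' extract_seed("AGUGGUUAAC", 6, "literal")    # "AGUGGU"
#' extract_seed("AGUGGUUAAC", 6, "canonical")  # "GUGGUU"
#' @export
extract_seed <- function(mirna_seq, k, mode = c("literal", "canonical")) {
  mode <- match.arg(mode)
  mirna_seq <- check_rna(mirna_seq)
  if (!k %in% c(6L, 7L, 8L)) stop("seed length k must be 6, 7 or 8")
  start <- if (mode == "literal") 1L else 2L
  if (nchar(mirna_seq) < start + k - 1L) stop("miRNA sequence too short")
  substr(mirna_seq, start, start + k - 1L)
}

check_rna <- function(x) {
  x <- toupper(x)
  if (grepl("T", x)) {
    warning("DNA alphabet in miRNA sequence; converting T -> U")
    x <- gsub("T", "U", x)
  }
  if (!grepl("^[ACGU]+$", x)) stop("invalid symbol in RNA sequence")
  x
}

#' Seed site: reverse complement of a seed on the UTR strand
#'
#' Watson-Crick reverse complement (U->A, A->T, G->C, C->G), returned 5' to 3'
#' on the mRNA (DNA alphabet) so it can be searched directly in a 3' UTR.
#'
#' @param seed RNA seed string.
#' @return DNA string.
#' @examples
#' seed_site("GUGGUU")  # "AACCAC"
#' @export
seed_site <- function(seed) {
  seed <- check_rna(seed)
  rc <- Biostrings::reverseComplement(Biostrings::RNAString(seed))
  as.character(Biostrings::DNAString(rc))
}

# DNA site string for one site type of one miRNA (used for planting and
# matching). Literal tiers p1-6/p1-7/p1-8; canonical tiers
# 6mer/7mer-m8/7mer-A1/8mer.
site_pattern <- function(mirna_seq, site_type) {
  mirna_seq <- check_rna(mirna_seq)
  switch(site_type,
    "p1-6" = seed_site(substr(mirna_seq, 1, 6)),
    "p1-7" = seed_site(substr(mirna_seq, 1, 7)),
    "p1-8" = seed_site(substr(mirna_seq, 1, 8)),
    "6mer" = seed_site(substr(mirna_seq, 2, 7)),
    "7mer-m8" = seed_site(substr(mirna_seq, 2, 8)),
    "7mer-A1" = paste0(seed_site(substr(mirna_seq, 2, 7)), "A"),
    "8mer" = paste0(seed_site(substr(mirna_seq, 2, 8)), "A"),
    stop("unknown site type: ", site_type))
}

#' UTR record table
#'
#' @param gene character vector of gene symbols (upper-cased on input).
#' @param sequence DNA sequences, 5' to 3'. `N` is allowed and never matches.
#' @param isoform isoform identifiers.
#' @param assembly assembly tag (e.g. "GRCh37").
#' @return Data frame of class `utr_records` with columns `gene`, `isoform`,
#'   `assembly`, `sequence`.
#' @export
utr_records <- function(gene, sequence, isoform = "iso1", assembly = "sim") {
  if (any(!nzchar(sequence))) stop("empty UTR sequence")
  sequence <- toupper(sequence)
  if (!all(grepl("^[ACGTN]+$", sequence)))
    stop("invalid symbol in UTR sequence")
  df <- data.frame(gene = toupper(gene), isoform = isoform,
                   assembly = assembly, sequence = sequence)
  class(df) <- c("utr_records", "data.frame")
  df
}

#' Read UTR records from FASTA
#'
#' Headers are parsed with `header_regex`, whose first three capture groups
#' are gene symbol, isoform and assembly (the default accepts
#' `>SYMBOL|isoform|assembly`, with missing trailing fields tolerated).
#'
#' @param file FASTA path.
#' @param header_regex regular expression with up to three capture groups.
#' @return A [utr_records()] data frame.
#' @export
read_utr_fasta <- function(file,
                           header_regex = "^([^|]+)\\|?([^|]*)\\|?(.*)$") {
  ss <- Biostrings::readDNAStringSet(file)
  hd <- names(ss)
  m <- regmatches(hd, regexec(header_regex, hd))
  gene <- vapply(m, `[`, "", 2L)
  iso <- vapply(m, `[`, "", 3L)
  asm <- vapply(m, `[`, "", 4L)
  iso[!nzchar(iso)] <- "iso1"
  asm[!nzchar(asm)] <- "NA"
  utr_records(gene, as.character(ss), iso, asm)
}

#' Write UTR records to FASTA
#' @param utrs a [utr_records()] data frame.
#' @param file output path.
#' @export
write_utr_fasta <- function(utrs, file) {
  ss <- Biostrings::DNAStringSet(utrs$sequence)
  names(ss) <- paste(utrs$gene, utrs$isoform, utrs$assembly, sep = "|")
  Biostrings::writeXStringSet(ss, file)
  invisible(file)
}

#' Read / write a mature miRNA FASTA (miRBase-style)
#' @param file FASTA path.
#' @return Named character vector of RNA sequences; the first whitespace
#'   token of each header is the miRNA name.
#' @export
read_mirna_fasta <- function(file) {
  ss <- Biostrings::readRNAStringSet(file)
  nm <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
  stats::setNames(as.character(ss), nm)
}

#' @rdname read_mirna_fasta
#' @param seqs named RNA sequences.
#' @export
write_mirna_fasta <- function(seqs, file) {
  ss <- Biostrings::RNAStringSet(unname(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, file)
  invisible(file)
}

# All 0-based start positions of fixed pattern `pat` in `subject`,
# including overlapping occurrences (which regex scans would merge).
fixed_starts <- function(subject, pat) {
  m <- Biostrings::matchPattern(pat, Biostrings::DNAString(subject))
  as.integer(Biostrings::start(m)) - 1L
}

#' Find all seed matches of one miRNA in one UTR
#'
#' Exact (Watson-Crick, no wobble, no mismatch) occurrences of each site
#' pattern on the UTR sense strand. Every site type of either convention
#' contains the reverse complement of the 6-nt seed core as a substring, so
#' matches are anchored on that core and classified by the flanking bases;
#' only the highest tier at each anchor is reported (canonical precedence
#' 8mer > 7mer-m8 > 7mer-A1 > 6mer; literal precedence p1-8 > p1-7 > p1-6).
#'
#' @param utr one row of a [utr_records()] data frame (or a one-row data
#'   frame).
#' @param mirna named length-1 character vector (or single string plus
#'   `mirna_name`) holding the mature RNA sequence.
#' @param mode `"literal"` or `"canonical"`.
#' @param mirna_name miRNA name; defaults to `names(mirna)`.
#' @return Data frame with columns `mirna`, `gene`, `isoform`, `assembly`,
#'   `site_type`, `utr_start`, `utr_end` (0-based half-open on the UTR),
#'   sorted by position.
#' @export
find_seed_matches <- function(utr, mirna, mode = c("literal", "canonical"),
                              mirna_name = names(mirna)) {
  mode <- match.arg(mode)
  if (is.data.frame(utr)) {
    stopifnot(nrow(utr) == 1L)
    utr <- as.list(utr)
  }
  if (is.null(mirna_name)) mirna_name <- "miRNA"
  seq <- check_rna(as.character(mirna[[1]]))
  s <- toupper(utr$sequence)
  L <- nchar(s)

  core <- site_pattern(seq, if (mode == "canonical") "6mer" else "p1-6")
  anchors <- fixed_starts(s, core)
  if (length(anchors) == 0)
    return(empty_matches())

  char_at <- function(pos) ifelse(pos >= 0 & pos < L,
                                  substring(s, pos + 1L, pos + 1L), "")
  if (mode == "canonical") {
    # 7mer-m8 = [c(p8)][core]; 7mer-A1 = [core]A; 8mer = [c(p8)][core]A
    c8 <- substr(site_pattern(seq, "7mer-m8"), 1L, 1L)
    m8 <- char_at(anchors - 1L) == c8
    a1 <- char_at(anchors + nchar(core)) == "A"
    type <- ifelse(m8 & a1, "8mer",
            ifelse(m8, "7mer-m8", ifelse(a1, "7mer-A1", "6mer")))
    start <- anchors - ifelse(m8, 1L, 0L)
    end <- anchors + nchar(core) + ifelse(a1, 1L, 0L)
  } else {
    # p1-7 = [c(p7)][core]; p1-8 = [c(p8)][c(p7)][core]
    c7 <- substr(site_pattern(seq, "p1-7"), 1L, 1L)
    c8 <- substr(site_pattern(seq, "p1-8"), 1L, 1L)
    p7 <- char_at(anchors - 1L) == c7
    p8 <- p7 & char_at(anchors - 2L) == c8
    type <- ifelse(p8, "p1-8", ifelse(p7, "p1-7", "p1-6"))
    start <- anchors - ifelse(p8, 2L, ifelse(p7, 1L, 0L))
    end <- anchors + nchar(core)
  }
  out <- data.frame(mirna = mirna_name, gene = utr$gene,
                    isoform = utr$isoform, assembly = utr$assembly,
                    site_type = type, utr_start = start, utr_end = end)
  out[order(out$utr_start), , drop = FALSE]
}

empty_matches <- function() {
  data.frame(mirna = character(0), gene = character(0),
             isoform = character(0), assembly = character(0),
             site_type = character(0), utr_start = integer(0),
             utr_end = integer(0))
}

#' Scan a UTR catalog against a miRNA catalog
#'
#' @param utrs a [utr_records()] data frame (any number of isoforms and
#'   assemblies per gene).
#' @param mirna_seqs named RNA sequences.
#' @param mode seed convention, `"literal"` (default) or `"canonical"`.
#' @return Data frame of all seed matches, sorted by (gene, miRNA, position).
#' @export
scan_seed_matches <- function(utrs, mirna_seqs,
                              mode = c("literal", "canonical")) {
  mode <- match.arg(mode)
  res <- vector("list", nrow(utrs) * length(mirna_seqs))
  k <- 0L
  for (i in seq_len(nrow(utrs))) {
    for (j in seq_along(mirna_seqs)) {
      k <- k + 1L
      res[[k]] <- find_seed_matches(utrs[i, ], mirna_seqs[j], mode = mode)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0) return(empty_matches())
  out <- out[order(out$gene, out$mirna, out$utr_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-level seed-match flag
#'
#' `TRUE` iff any isoform of the gene, in any assembly, carries at least one
#' seed match of any admitted site type for the miRNA. A gene absent from the
#' UTR catalog yields `FALSE` with a warning ("no UTR available").
#'
#' @param mirna_name miRNA name present in `mirna_seqs`.
#' @param gene gene symbol.
#' @param utrs a [utr_records()] data frame.
#' @param mirna_seqs named RNA sequences.
#' @param mode seed convention.
#' @return Logical flag.
#' @export
has_seed_match <- function(mirna_name, gene, utrs, mirna_seqs,
                           mode = c("literal", "canonical")) {
  mode <- match.arg(mode)
  gene <- toupper(gene)
  rows <- which(utrs$gene == gene)
  if (length(rows) == 0) {
    warning("no UTR available for gene ", gene)
    return(FALSE)
  }
  for (i in rows) {
    hits <- find_seed_matches(utrs[i, ], mirna_seqs[mirna_name], mode = mode)
    if (nrow(hits) > 0) return(TRUE)
  }
  FALSE
}

#' Seed-match flag matrix for many pairs
#'
#' @param pairs data frame with columns `gene`, `mirna`.
#' @inheritParams has_seed_match
#' @return `pairs` with a logical `seed_match` column appended.
#' @export
seed_match_flags <- function(pairs, utrs, mirna_seqs,
                             mode = c("literal", "canonical")) {
  mode <- match.arg(mode)
  flags <- logical(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    flags[r] <- suppressWarnings(
      has_seed_match(pairs$mirna[r], pairs$gene[r], utrs, mirna_seqs,
                     mode = mode))
  }
  pairs$seed_match <- flags
  pairs
}

#' Write seed matches as a BED-like TSV
#'
#' Columns: gene, isoform, start, end, strand ("." -- UTR coordinates carry
#' no genomic strand), miRNA, site_type.
#'
#' @param matches output of [scan_seed_matches()].
#' @param file output path.
#' @export
write_sites_tsv <- function(matches, file) {
  bed <- data.frame(gene = matches$gene, isoform = matches$isoform,
                    start = matches$utr_start, end = matches$utr_end,
                    strand = ".", mirna = matches$mirna,
                    site_type = matches$site_type)
  utils::write.table(bed, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
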