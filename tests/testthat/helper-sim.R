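# Small paired set built by hand: values chosen per test, canonical design.
toy_paired_set <- function(values) {
  ns <- ncol(values)
  stopifnot(ns %% 2 == 0)
  n <- ns / 2
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%02d", seq_len(nrow(values)))
  subj <- sprintf("s%02d", seq_len(n))
  colnames(values) <- c(paste0(subj, "_C"), paste0(subj, "_N"))
  paired_set(values, subject = rep(subj, 2),
             tissue = rep(c("carcinoma", "normal"), each = n))
}

# Paired set with prescribed carcinoma/normal column blocks.
toy_from_blocks <- function(carc, norm) {
  toy_paired_set(cbind(carc, norm))
}
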