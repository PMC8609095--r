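# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: interval classification by direct case
# analysis, span merging by residue masks, alignment scoring via
# Biostrings' established implementation.

STD_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
            "M", "F", "P", "S", "T", "W", "Y", "V")

random_seq <- function(n, alphabet = STD_AA) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Case-analysis classifier: containment first (equal intervals count as
# CONTAINS), then overlap length against the inclusive partial threshold.
oracle_classify <- function(as, ae, bs, be, partial_threshold = 10L) {
  ov <- pmax(0L, pmin(ae, be) - pmax(as, bs) + 1L)
  cls <- ifelse(bs >= as & be <= ae, "CONTAINS",
         ifelse(as >= bs & ae <= be, "CONTAINED_IN",
         ifelse(ov >= partial_threshold, "PARTIAL",
         ifelse(ov >= 1L, "MARGINAL", "NONE"))))
  list(class = cls, overlap_len = ov)
}

# Merge spans by marking residues on a mask and reading off runs.
oracle_merge <- function(starts, ends) {
  mask <- logical(max(ends))
  for (i in seq_along(starts)) mask[starts[i]:ends[i]] <- TRUE
  r <- rle(mask)
  stop_at <- cumsum(r$lengths)
  start_at <- stop_at - r$lengths + 1L
  keep <- r$values
  data.frame(start = start_at[keep], end = stop_at[keep])
}

biostrings_local_score <- function(q, s) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(s), type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1
  )
  Biostrings::score(pa)
}
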