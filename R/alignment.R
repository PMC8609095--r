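#' Read an NCBI-format substitution matrix
#'
#' Parses the plain-text matrix layout used by blastp (`#` comments, a
#' header row of residue letters, one scored row per residue).
#'
#' @param path Path to a matrix file.
#' @return An integer matrix with residue letters as dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  letters <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(ln) strsplit(trimws(ln), "\\s+")[[1]])
  m <- matrix(NA_integer_, length(rows), length(letters),
              dimnames = list(vapply(rows, `[`, "", 1), letters))
  for (i in seq_along(rows)) {
    m[i, ] <- as.integer(rows[[i]][-1])
  }
  if (!identical(rownames(m), colnames(m))) {
    rlang::abort("matrix file is not square in the same residue order")
  }
  m
}

.pkg_cache <- new.env(parent = emptyenv())

#' The bundled BLOSUM62 matrix
#'
#' The default blastp scoring matrix, read from the NCBI-format file shipped
#' with the package. A `U` (selenocysteine) row/column scoring as `C` is
#' included so that every letter of the accepted alphabet has a matrix row.
#'
#' @return An integer substitution matrix.
#' @export
blosum62 <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    path <- system.file("extdata", "BLOSUM62.txt", package = "mimicscreen",
                        mustWork = TRUE)
    .pkg_cache$blosum62 <- read_score_matrix(path)
  }
  .pkg_cache$blosum62
}

#' Scoring parameters for the local aligner
#'
#' Defaults pin the "standard parameters" of blastp: BLOSUM62 with gap open
#' 11 / extend 1 and the gapped Karlin-Altschul constants
#' \eqn{\lambda = 0.267}, \eqn{K = 0.041}. `db_residues` is the total
#' residue count of the search catalog (the `n` of
#' \eqn{E = K m n e^{-\lambda S}}); when `NA` it is taken from the subject
#' at alignment time.
#'
#' @param matrix Integer substitution matrix with residue dimnames.
#' @param gap_open,gap_extend Positive integer gap penalties; a gap of
#'   length L costs `gap_open + L * gap_extend`.
#' @param lambda_gapped,K_gapped Karlin-Altschul constants for the gapped
#'   score distribution.
#' @param e_cutoff Segments with E-value at or above this are discarded
#'   (the screen's "E < 10" gate).
#' @param db_residues Total residues in the searched catalog, or `NA`.
#' @return A `scoring_params` list.
#' @export
scoring_params <- function(matrix = blosum62(), gap_open = 11L,
                           gap_extend = 1L, lambda_gapped = 0.267,
                           K_gapped = 0.041, e_cutoff = 10,
                           db_residues = NA_real_) {
  stopifnot(gap_open > 0, gap_extend > 0)
  if (gap_extend > gap_open) {
    rlang::abort("gap_extend must not exceed gap_open")
  }
  if (lambda_gapped <= 0 || K_gapped <= 0 || e_cutoff <= 0) {
    rlang::abort("lambda_gapped, K_gapped and e_cutoff must be positive")
  }
  structure(
    list(matrix = matrix, gap_open = as.integer(gap_open),
         gap_extend = as.integer(gap_extend),
         lambda_gapped = lambda_gapped, K_gapped = K_gapped,
         e_cutoff = e_cutoff, db_residues = db_residues),
    class = "scoring_params"
  )
}

encode_seq <- function(sequence, matrix) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  idx <- match(chars, rownames(matrix))
  if (anyNA(idx)) {
    rlang::abort(paste0("illegal residue character(s): ",
                        paste(unique(chars[is.na(idx)]), collapse = ", ")))
  }
  idx - 1L
}

# Smallest raw score whose E-value is below the cutoff.
min_raw_score <- function(query_len, db_residues, params) {
  s <- log(params$K_gapped * query_len * db_residues / params$e_cutoff) /
    params$lambda_gapped
  if (!is.finite(s)) return(1L)  # e.g. an infinite cutoff gates nothing
  max(1L, as.integer(ceiling(s)))
}

#' Locally align two protein sequences
#'
#' Smith-Waterman with affine gaps. Up to `max_segments` locally optimal,
#' mutually non-overlapping (on both sequences) alignments are found by
#' iteratively masking the residues of each reported segment and re-running
#' the dynamic program. Only segments with E-value below
#' `params$e_cutoff` are returned, in descending raw-score order.
#'
#' @param query,subject Amino-acid strings.
#' @param params A [scoring_params()] object.
#' @param max_segments Maximum number of segments to report (>= 1).
#' @param query_id,subject_id Identifiers carried into the result.
#' @return A tibble of homology segments with columns `query_id`,
#'   `subject_id`, `q_start`, `q_end`, `s_start`, `s_end`, `identity_pct`,
#'   `positive_pct`, `raw_score`, `evalue`, `aligned_length`, `q_aln`,
#'   `s_aln`.
#' @export
local_align <- function(query, subject, params = scoring_params(),
                        max_segments = 25L, query_id = "query",
                        subject_id = "subject") {
  if (!nzchar(query) || !nzchar(subject)) {
    rlang::abort("query and subject must be non-empty sequences")
  }
  if (max_segments < 1) rlang::abort("max_segments must be >= 1")
  qi <- encode_seq(query, params$matrix)
  si <- encode_seq(subject, params$matrix)
  n_db <- if (is.na(params$db_residues)) length(si) else params$db_residues
  smin <- min_raw_score(length(qi), n_db, params)
  hits <- sw_align_masked(qi, si, params$matrix, params$gap_open,
                          params$gap_extend, as.integer(max_segments), smin)
  if (length(hits) == 0) return(empty_segments())
  qchr <- strsplit(toupper(query), "")[[1]]
  schr <- strsplit(toupper(subject), "")[[1]]
  rows <- purrr::map(hits, function(h) {
    q_aln <- paste(ifelse(h$q_pos == 0, "-", qchr[pmax(h$q_pos, 1)]),
                   collapse = "")
    s_aln <- paste(ifelse(h$s_pos == 0, "-", schr[pmax(h$s_pos, 1)]),
                   collapse = "")
    st <- hsp_stats(q_aln, s_aln, params$matrix)
    tibble::tibble(
      query_id = query_id, subject_id = subject_id,
      q_start = h$q_start, q_end = h$q_end,
      s_start = h$s_start, s_end = h$s_end,
      identity_pct = st$identity_pct, positive_pct = st$positive_pct,
      raw_score = h$raw_score,
      evalue = evalue(h$raw_score, length(qi), params, db_residues = n_db),
      aligned_length = st$aligned_length,
      q_aln = q_aln, s_aln = s_aln
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- out[out$evalue < params$e_cutoff, , drop = FALSE]
  dplyr::arrange(out, dplyr::desc(.data$raw_score), .data$s_start)
}

empty_segments <- function() {
  tibble::tibble(
    query_id = character(), subject_id = character(),
    q_start = integer(), q_end = integer(),
    s_start = integer(), s_end = integer(),
    identity_pct = double(), positive_pct = double(),
    raw_score = integer(), evalue = double(),
    aligned_length = integer(), q_aln = character(), s_aln = character()
  )
}

round_half_away <- function(x) trunc(x + 0.5 * sign(x))

#' Identity and positive percentages of an alignment
#'
#' `identity_pct` is the fraction of columns with identical residues;
#' `positive_pct` ("overall homology", identical plus similar residues) is
#' the fraction of columns whose residue pair scores positively in the
#' substitution matrix, with identities always counting as positives. Both
#' are percentages of the full aligned length including gap columns,
#' rounded to the nearest integer (ties away from zero), as printed in
#' screen reports.
#'
#' @param q_aln,s_aln Aligned strings of equal length; `-` marks a gap.
#' @param matrix Substitution matrix.
#' @return A list with `identity_pct`, `positive_pct`, `aligned_length`,
#'   `n_identical`, `n_positive`.
#' @export
hsp_stats <- function(q_aln, s_aln, matrix = blosum62()) {
  qc <- strsplit(toupper(q_aln), "")[[1]]
  sc <- strsplit(toupper(s_aln), "")[[1]]
  if (length(qc) != length(sc)) {
    rlang::abort("aligned strings must have equal length")
  }
  if (length(qc) == 0) rlang::abort("zero-length alignment")
  paired <- qc != "-" & sc != "-"
  ident <- paired & qc == sc
  pos <- paired
  pos[paired] <- matrix[cbind(qc[paired], sc[paired])] > 0
  pos <- pos | ident
  list(
    identity_pct = round_half_away(100 * sum(ident) / length(qc)),
    positive_pct = round_half_away(100 * sum(pos) / length(qc)),
    aligned_length = length(qc),
    n_identical = sum(ident),
    n_positive = sum(pos)
  )
}

#' Karlin-Altschul E-value of a raw alignment score
#'
#' \eqn{E = K \cdot m \cdot n \cdot e^{-\lambda S}} with `m` the query
#' length and `n` the total database residue count. No effective-length
#' edge correction is applied.
#'
#' @param raw_score Non-negative integer alignment score.
#' @param query_len Query length in residues (positive).
#' @param params A [scoring_params()] object supplying `lambda_gapped`,
#'   `K_gapped` and (by default) `db_residues`.
#' @param db_residues Override for the database size `n`.
#' @return The expected number of chance alignments scoring at least
#'   `raw_score`.
#' @export
evalue <- function(raw_score, query_len, params = scoring_params(),
                   db_residues = params$db_residues) {
  if (any(raw_score < 0)) rlang::abort("raw_score must be >= 0")
  if (any(query_len <= 0) || any(is.na(db_residues)) ||
      any(db_residues <= 0)) {
    rlang::abort("query_len and db_residues must be positive")
  }
  params$K_gapped * query_len * db_residues *
    exp(-params$lambda_gapped * raw_score)
}

#' Write homology segments as a BLAST-tabular-like TSV
#'
#' Columns: query id, subject id, q_start, q_end, s_start, s_end,
#' % identity, % positives, raw score, E-value.
#'
#' @param segments A segment tibble from [local_align()] or a screen.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segment_tsv <- function(segments, path) {
  cols <- c("query_id", "subject_id", "q_start", "q_end", "s_start",
            "s_end", "identity_pct", "positive_pct", "raw_score", "evalue")
  utils::write.table(segments[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
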