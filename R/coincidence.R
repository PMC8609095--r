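#' Overlap classes, from most to least specific
#' @export
OVERLAP_CLASSES <- c("CONTAINS", "CONTAINED_IN", "PARTIAL", "MARGINAL",
                     "NONE")

#' Construct an interval table
#'
#' Intervals are 1-based inclusive residue spans on a named protein — the
#' universal currency of the coincidence analysis.
#'
#' @param start,end Integer vectors, `1 <= start <= end`.
#' @param protein_id Optional protein identifier(s).
#' @return A tibble with columns `protein_id`, `start`, `end`.
#' @export
interval <- function(start, end, protein_id = NA_character_) {
  if (any(start < 1) || any(start > end)) {
    rlang::abort("invalid interval: need 1 <= start <= end")
  }
  tibble::tibble(protein_id = protein_id, start = as.integer(start),
                 end = as.integer(end))
}

check_same_protein <- function(a, b) {
  pa <- if ("protein_id" %in% names(a)) a[["protein_id"]] else NULL
  pb <- if ("protein_id" %in% names(b)) b[["protein_id"]] else NULL
  if (!is.null(pa) && !is.null(pb)) {
    ok <- is.na(pa) | is.na(pb) | pa == pb
    if (!all(ok)) {
      rlang::abort("intervals lie on different proteins")
    }
  }
  invisible(NULL)
}

recycle_pair <- function(a, b) {
  if (nrow(a) == nrow(b)) return(list(a = a, b = b))
  if (nrow(a) == 1) return(list(a = a[rep(1, nrow(b)), ], b = b))
  if (nrow(b) == 1) return(list(a = a, b = b[rep(1, nrow(a)), ]))
  rlang::abort("interval tables must have equal length or length 1")
}

#' Length of the overlap between two intervals
#'
#' `max(0, min(a_end, b_end) - max(a_start, b_start) + 1)`, vectorised over
#' rows (with length-1 recycling). Errors if the intervals carry different
#' protein ids.
#'
#' @param a,b Interval tibbles (see [interval()]).
#' @return Integer vector of overlap lengths in residues.
#' @export
overlap_length <- function(a, b) {
  p <- recycle_pair(a, b)
  check_same_protein(p$a, p$b)
  pmax(0L, pmin(p$a$end, p$b$end) - pmax(p$a$start, p$b$start) + 1L)
}

#' Classify the overlap between two intervals
#'
#' Classes, in precedence order: `CONTAINS` if `b` lies inside `a` (equal
#' intervals classify `CONTAINS`); `CONTAINED_IN` if `a` lies inside `b`;
#' `PARTIAL` if the overlap reaches `partial_threshold` residues;
#' `MARGINAL` for any smaller positive overlap; otherwise `NONE`. The
#' default threshold of 10 residues reproduces the published
#' "partial overlap of more than 10 residues" tallies (see the methods
#' vignette for why the threshold is inclusive).
#'
#' @param a,b Interval tibbles; `a` is the table-segment perspective.
#' @param partial_threshold Minimum overlap, in residues, for `PARTIAL`.
#' @return A tibble with columns `class` (ordered factor, `NONE` <
#'   `MARGINAL` < `PARTIAL` < `CONTAINED_IN` < `CONTAINS`) and
#'   `overlap_len`.
#' @export
classify_overlap <- function(a, b, partial_threshold = 10L) {
  p <- recycle_pair(a, b)
  ov <- overlap_length(p$a, p$b)
  contains <- p$a$start <= p$b$start & p$a$end >= p$b$end
  contained <- !contains & p$b$start <= p$a$start & p$b$end >= p$a$end
  cls <- dplyr::case_when(
    contains ~ "CONTAINS",
    contained ~ "CONTAINED_IN",
    ov >= partial_threshold ~ "PARTIAL",
    ov >= 1L ~ "MARGINAL",
    TRUE ~ "NONE"
  )
  tibble::tibble(
    class = factor(cls, levels = rev(OVERLAP_CLASSES), ordered = TRUE),
    overlap_len = ov
  )
}

cross_classify <- function(segments, refs, partial_threshold) {
  n_s <- nrow(segments)
  n_r <- nrow(refs)
  if (n_s == 0 || n_r == 0) {
    return(tibble::tibble(seg = integer(), ref = integer(),
                          class = factor(character(),
                                         levels = rev(OVERLAP_CLASSES),
                                         ordered = TRUE),
                          overlap_len = integer()))
  }
  idx <- expand.grid(seg = seq_len(n_s), ref = seq_len(n_r))
  cl <- classify_overlap(segments[idx$seg, , drop = FALSE],
                         refs[idx$ref, , drop = FALSE],
                         partial_threshold = partial_threshold)
  dplyr::bind_cols(tibble::as_tibble(idx), cl)
}

#' Count coincidences between homology segments and reference segments
#'
#' Tallies, over autoantigen-axis interval pairs, how often a table segment
#' fully contains a reference segment, is fully contained in one, or
#' partially overlaps one by at least `partial_threshold` residues.
#' The default `"pairs"` convention counts every ordered (table segment,
#' reference) pair with multiplicity — the paper-style "with some multiple
#' matches" tallies; `"per_segment"` counts each table segment once, by its
#' most specific class.
#'
#' @param table_segments Interval tibble of homology segments on one
#'   autoantigen.
#' @param refs Interval tibble of reference segments (spans on the same
#'   autoantigen previously shown homologous to alpha-enolase, AKRIAI or
#'   DDAHI).
#' @param partial_threshold Minimum overlap for a partial coincidence.
#' @param convention `"pairs"` or `"per_segment"`.
#' @return A one-row `coincidence_counts` tibble with columns `contains`,
#'   `contained_in`, `partial`, `partial_threshold`, `convention`.
#' @export
count_coincidences <- function(table_segments, refs, partial_threshold = 10L,
                               convention = c("pairs", "per_segment")) {
  convention <- match.arg(convention)
  get_ids <- function(x) {
    if ("protein_id" %in% names(x)) x[["protein_id"]] else character()
  }
  all_ids <- c(get_ids(table_segments), get_ids(refs))
  all_ids <- unique(all_ids[!is.na(all_ids)])
  if (length(all_ids) > 1) {
    rlang::abort(paste0("intervals from more than one autoantigen: ",
                        paste(all_ids, collapse = ", ")))
  }
  cc <- cross_classify(table_segments, refs, partial_threshold)
  if (convention == "per_segment" && nrow(cc) > 0) {
    cc <- cc |>
      dplyr::group_by(.data$seg) |>
      dplyr::slice_max(.data$class, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  out <- tibble::tibble(
    contains = sum(cc$class == "CONTAINS"),
    contained_in = sum(cc$class == "CONTAINED_IN"),
    partial = sum(cc$class == "PARTIAL"),
    partial_threshold = as.integer(partial_threshold),
    convention = convention
  )
  class(out) <- c("coincidence_counts", class(out))
  out
}

#' Derive "coincidences with" flags for an autoantigen span
#'
#' For each span on the autoantigen axis, returns the set of
#' encephalopathy-autoantigen sources (`Eno`, `AKRIAI`, `DDAHI`) whose
#' reference segments it coincides with. A source flags when some reference
#' of that source is contained in the span, contains it, or overlaps it by
#' at least `min_partial` residues; smaller overlaps do not flag. The
#' default of 21 residues is calibrated on the printed flag columns (see
#' the methods vignette).
#'
#' @param spans Interval tibble on the autoantigen axis.
#' @param refs Reference-segment tibble with columns `start`, `end`,
#'   `source`.
#' @param min_partial Minimum non-containment overlap that flags.
#' @return A list (one element per span row) of character vectors drawn
#'   from `Eno`, `AKRIAI`, `DDAHI`, in that canonical order.
#' @export
derive_flags <- function(spans, refs, min_partial = 21L) {
  source_order <- c("Eno", "AKRIAI", "DDAHI")
  purrr::map(seq_len(nrow(spans)), function(i) {
    cl <- classify_overlap(spans[i, , drop = FALSE],
                           refs[, c("start", "end")],
                           partial_threshold = min_partial)
    hit <- cl$class %in% c("CONTAINS", "CONTAINED_IN", "PARTIAL")
    src <- unique(refs$source[hit])
    source_order[source_order %in% src]
  })
}

#' Collapse flag sets to display strings
#'
#' @param flags A list of character vectors as returned by
#'   [derive_flags()].
#' @param sep Separator.
#' @return Character vector (`""` for an empty set).
#' @export
flags_chr <- function(flags, sep = ",") {
  vapply(flags, paste, "", collapse = sep)
}

#' Per-segment epitope overlap report
#'
#' For each homology segment, finds the most specific overlap class over
#' all published epitopes of the protein (`CONTAINS` > `CONTAINED_IN` >
#' `PARTIAL` > `MARGINAL` > `NONE`), breaking ties by overlap length. The
#' attached summary counts segments with any epitope overlap, with at least
#' a partial overlap, with full containment, and with a "significant"
#' overlap — more than `marginal_threshold` residues or containment, the
#' paper-style insignificance band ("6 or less amino acids of overlap").
#'
#' @param segments Interval tibble of homology segments on one protein.
#' @param epitopes Interval tibble of epitopes on the same protein
#'   (columns `start`, `end`, optionally `modification`).
#' @param partial_threshold Minimum overlap for `PARTIAL`.
#' @param marginal_threshold Overlaps of at most this many residues are
#'   insignificant.
#' @return An `epitope_report` tibble: one row per segment with `start`,
#'   `end`, `best_class`, `overlap_len`, `epitope_start`, `epitope_end`;
#'   summary counts in `attr(, "summary")` (also via [glance()]).
#' @export
epitope_report <- function(segments, epitopes, partial_threshold = 10L,
                           marginal_threshold = 6L) {
  n <- nrow(segments)
  if (nrow(epitopes) == 0) {
    out <- tibble::tibble(
      start = segments$start, end = segments$end,
      best_class = factor(rep("NONE", n), levels = rev(OVERLAP_CLASSES),
                          ordered = TRUE),
      overlap_len = rep(0L, n),
      epitope_start = rep(NA_integer_, n),
      epitope_end = rep(NA_integer_, n)
    )
  } else {
    cc <- cross_classify(segments, epitopes, partial_threshold)
    best <- cc |>
      dplyr::group_by(.data$seg) |>
      dplyr::arrange(dplyr::desc(.data$class), dplyr::desc(.data$overlap_len),
                     .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$seg)
    out <- tibble::tibble(
      start = segments$start, end = segments$end,
      best_class = best$class,
      overlap_len = best$overlap_len,
      epitope_start = ifelse(best$class == "NONE", NA_integer_,
                             epitopes$start[best$ref]),
      epitope_end = ifelse(best$class == "NONE", NA_integer_,
                           epitopes$end[best$ref])
    )
  }
  contain <- out$best_class %in% c("CONTAINS", "CONTAINED_IN")
  attr(out, "summary") <- tibble::tibble(
    n_segments = n,
    n_overlap = sum(out$best_class != "NONE"),
    n_partial = sum(out$best_class >= "PARTIAL"),
    n_contains = sum(out$best_class == "CONTAINS"),
    n_significant = sum(contain | out$overlap_len > marginal_threshold),
    marginal_threshold = as.integer(marginal_threshold)
  )
  class(out) <- c("epitope_report", class(out))
  out
}

#' @rdname epitope_report
#' @param x An `epitope_report`.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::glance
glance.epitope_report <- function(x, ...) {
  attr(x, "summary")
}
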