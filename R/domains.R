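#' Map a homology segment onto named structural domains
#'
#' Lists every domain annotation of the protein that the segment overlaps
#' by at least one residue, sorted by decreasing overlap length (ties by
#' domain name). Annotations may nest or overlap (e.g. the autoantigen's
#' C-peptide lies inside its hinge region).
#'
#' @param segments Interval tibble of homology segments.
#' @param annotations Domain annotation tibble with columns `protein_id`
#'   (optional), `name`, `start`, `end`.
#' @return A tibble with one row per (segment, overlapping domain):
#'   segment `start`/`end`, `domain`, `domain_start`, `domain_end`,
#'   `overlap_len`.
#' @export
assign_domains <- function(segments, annotations) {
  if (nrow(segments) == 0 || nrow(annotations) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          domain = character(), domain_start = integer(),
                          domain_end = integer(), overlap_len = integer()))
  }
  idx <- expand.grid(seg = seq_len(nrow(segments)),
                     dom = seq_len(nrow(annotations)))
  ov <- overlap_length(
    segments[idx$seg, c("start", "end")],
    annotations[idx$dom, c("start", "end")]
  )
  out <- tibble::tibble(
    start = segments$start[idx$seg],
    end = segments$end[idx$seg],
    domain = annotations$name[idx$dom],
    domain_start = annotations$start[idx$dom],
    domain_end = annotations$end[idx$dom],
    overlap_len = ov
  )
  out |>
    dplyr::filter(.data$overlap_len >= 1L) |>
    dplyr::arrange(.data$start, dplyr::desc(.data$overlap_len),
                   .data$domain)
}

#' Per-residue coverage profile of a screened protein
#'
#' For every residue position of the protein, counts how many homology
#' groups (subject proteins) have at least one segment covering it. The
#' profile underlies track figures and exposes unmatched stretches.
#'
#' @param segments Tibble with span columns (`start`, `end` by default) and
#'   a grouping column naming the protein each segment belongs to.
#' @param protein_length Length of the profiled protein.
#' @param group Name of the grouping column; `NULL` treats every row as its
#'   own group.
#' @param start,end Names of the span columns.
#' @return A tibble with columns `position` (1..`protein_length`) and
#'   `count`.
#' @export
coverage_profile <- function(segments, protein_length, group = "subject_id",
                             start = "start", end = "end") {
  st <- segments[[start]]
  en <- segments[[end]]
  if (length(st) && (any(st < 1) || any(en > protein_length))) {
    rlang::abort("segment outside 1..protein_length")
  }
  grp <- if (is.null(group)) seq_along(st) else segments[[group]]
  counts <- integer(protein_length)
  for (g in unique(grp)) {
    mask <- logical(protein_length)
    sel <- which(grp == g)
    for (i in sel) mask[st[i]:en[i]] <- TRUE
    counts <- counts + mask
  }
  tibble::tibble(position = seq_len(protein_length), count = counts)
}

#' Write a coverage profile as wiggle-like text
#'
#' Two tab-separated columns: position, count.
#'
#' @param profile A tibble from [coverage_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
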