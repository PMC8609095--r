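#' Merge overlapping or touching intervals
#'
#' Returns the minimal sorted set of disjoint intervals with the same union
#' as the input; touching intervals (`end + 1 == next start`) are merged.
#' This is the "cumulative span" used to draw multiple overlapping
#' homologous segments of one protein as a single gray bar.
#'
#' @param intervals Interval tibble with columns `start`, `end` (optional
#'   `protein_id`, which must be unique).
#' @return An interval tibble of disjoint merged spans, sorted by `start`.
#' @export
merge_spans <- function(intervals) {
  if (any(intervals$start > intervals$end)) {
    rlang::abort("invalid interval: start > end")
  }
  pid <- unique(intervals$protein_id %||% NA_character_)
  pid <- pid[!is.na(pid)]
  if (length(pid) > 1) {
    rlang::abort("intervals must lie on a single axis")
  }
  if (nrow(intervals) == 0) {
    return(interval(integer(), integer()))
  }
  r <- IRanges::reduce(IRanges::IRanges(start = intervals$start,
                                        end = intervals$end))
  interval(IRanges::start(r), IRanges::end(r),
           protein_id = if (length(pid)) pid else NA_character_)
}

#' Screen a whole catalog against one autoantigen
#'
#' Aligns the autoantigen (query) against every catalog protein (subject)
#' and keeps, for each protein, the locally optimal non-overlapping
#' segments passing the E-value gate. One homology group is formed per
#' protein with at least one surviving segment; groups are ordered by best
#' (lowest) E-value, ties broken by subject id, and segments within a group
#' run from the most N-terminal to the most C-terminal subject position.
#'
#' @param autoantigen A one-row `protein_catalog` (or list with `id` and
#'   `sequence`) for the probe autoantigen.
#' @param catalog A `protein_catalog` to search. A record with the
#'   autoantigen's own id is dropped (self-hit guard).
#' @param params A [scoring_params()] object; `db_residues`, when `NA`, is
#'   set to the catalog's total residue count.
#' @param max_segments Per-protein cap on reported segments.
#' @return A `mimicry_screen` object: the segment tibble (see
#'   [local_align()]) with attributes `autoantigen_id`, `db_residues` and
#'   `params`. Use [tidy()], [glance()] and [homology_groups()] on it.
#' @export
scan_autoantigen <- function(autoantigen, catalog,
                             params = scoring_params(),
                             max_segments = 25L) {
  ag_id <- autoantigen$id[[1]]
  ag_seq <- autoantigen$sequence[[1]]
  if (any(catalog$id == ag_id)) {
    rlang::warn(paste0("dropping catalog record matching the autoantigen id ",
                       ag_id, " (self-hit guard)"))
    catalog <- catalog[catalog$id != ag_id, , drop = FALSE]
  }
  n_db <- sum(nchar(catalog$sequence))
  if (is.na(params$db_residues)) params$db_residues <- n_db
  segs <- purrr::map(seq_len(nrow(catalog)), function(i) {
    local_align(ag_seq, catalog$sequence[i], params = params,
                max_segments = max_segments, query_id = ag_id,
                subject_id = catalog$id[i])
  })
  segs <- dplyr::bind_rows(segs)
  if (nrow(segs) == 0) segs <- empty_segments()
  ord <- segs |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(best_evalue = suppressWarnings(min(.data$evalue)),
                     .groups = "drop") |>
    dplyr::arrange(.data$best_evalue, .data$subject_id)
  segs <- segs |>
    dplyr::mutate(subject_id = factor(.data$subject_id,
                                      levels = ord$subject_id)) |>
    dplyr::arrange(.data$subject_id, .data$s_start) |>
    dplyr::mutate(subject_id = as.character(.data$subject_id))
  structure(segs,
            class = c("mimicry_screen", class(segs)),
            autoantigen_id = ag_id,
            db_residues = params$db_residues,
            params = params)
}

#' Homology groups of a screen
#'
#' Collapses screen segments into one row per subject protein, with merged
#' cumulative spans on both the subject and the autoantigen axis, ordered
#' by best E-value.
#'
#' @param screen A `mimicry_screen` or a compatible segment tibble.
#' @return A tibble with columns `subject_id`, `n_segments`, `best_evalue`
#'   and list-columns `merged_s_spans`, `merged_q_spans`.
#' @export
homology_groups <- function(screen) {
  tibble::as_tibble(screen) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      n_segments = dplyr::n(),
      best_evalue = min(.data$evalue),
      merged_s_spans = list(merge_spans(interval(.data$s_start, .data$s_end))),
      merged_q_spans = list(merge_spans(interval(.data$q_start, .data$q_end))),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$best_evalue, .data$subject_id)
}

#' @export
print.mimicry_screen <- function(x, ...) {
  cat(sprintf("<mimicry_screen> autoantigen %s: %d segment(s) in %d protein(s), db %s residues\n",
              attr(x, "autoantigen_id"), nrow(x),
              length(unique(x$subject_id)),
              format(attr(x, "db_residues"), big.mark = ",")))
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mimicry screen into its segment table
#'
#' @param x A `mimicry_screen`.
#' @param ... Unused.
#' @return The plain segment tibble.
#' @export
#' @exportS3Method generics::tidy
tidy.mimicry_screen <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "mimicry_screen")
  out
}

#' One-row summary of a mimicry screen
#'
#' @param x A `mimicry_screen`.
#' @param ... Unused.
#' @return A tibble with the autoantigen id, subject/segment counts, best
#'   E-value and database size used.
#' @export
#' @exportS3Method generics::glance
glance.mimicry_screen <- function(x, ...) {
  tibble::tibble(
    autoantigen_id = attr(x, "autoantigen_id"),
    n_subjects = length(unique(x$subject_id)),
    n_segments = nrow(x),
    best_evalue = if (nrow(x)) min(x$evalue) else NA_real_,
    db_residues = attr(x, "db_residues")
  )
}
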