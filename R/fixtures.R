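#' Path to a bundled fixture file
#'
#' @param file File name under the package's `extdata/` directory; empty
#'   for the directory itself.
#' @return Absolute path.
#' @export
fixture_path <- function(file = "") {
  system.file("extdata", file, package = "mimicscreen", mustWork = TRUE)
}

read_fixture_tsv <- function(file) {
  tibble::as_tibble(utils::read.delim(
    fixture_path(file), comment.char = "#", stringsAsFactors = FALSE,
    na.strings = character(), check.names = FALSE
  ))
}

#' Load the bundled screen fixtures
#'
#' The published screen results and annotations, transcribed once into
#' read-only tab-separated files and checksummed:
#'
#' * `tables` — per-autoantigen homology tables (`TSHR`, `TG`, `TPO`): one
#'   row per homology segment with subject-protein span, autoantigen span,
#'   printed identity/overall-homology percentages, E-value and printed
#'   coincidence flags;
#' * `reference_segments` — autoantigen spans previously shown homologous
#'   to the encephalopathy autoantigens alpha-enolase (`Eno`), `AKRIAI`
#'   and `DDAHI`, with their counterpart spans;
#' * `epitopes` — published linear epitopes on the autoantigens and on the
#'   homologous CNS proteins, with modification notes;
#' * `domains` — structural-domain bounds of the three autoantigens;
#' * `areas` — CNS areas reported abnormal at neuroimaging in
#'   HE/SREAT, used by the expression cross-reference.
#'
#' @param check Verify fixture MD5 checksums against the bundled manifest
#'   (default `TRUE`); a mismatch is an error.
#' @return A named list of tibbles (see above); `segments` binds the three
#'   tables into one tibble.
#' @export
load_fixtures <- function(check = TRUE) {
  if (check) {
    manifest <- utils::read.delim(fixture_path("manifest.tsv"),
                                  stringsAsFactors = FALSE)
    sums <- tools::md5sum(vapply(manifest$file, fixture_path, ""))
    bad <- manifest$file[unname(sums) != manifest$md5]
    if (length(bad)) {
      rlang::abort(paste0("fixture checksum mismatch: ",
                          paste(bad, collapse = ", ")))
    }
  }
  tables <- list(
    TSHR = read_fixture_tsv("table_tshr.tsv"),
    TG = read_fixture_tsv("table_tg.tsv"),
    TPO = read_fixture_tsv("table_tpo.tsv")
  )
  list(
    tables = tables,
    segments = dplyr::bind_rows(tables),
    reference_segments = read_fixture_tsv("reference_segments.tsv"),
    epitopes = read_fixture_tsv("epitopes.tsv"),
    domains = read_fixture_tsv("domains.tsv"),
    areas = read_term_file(fixture_path("areas_of_interest.txt"))
  )
}

#' Flag sets of a fixture table
#'
#' Converts the printed flag strings (comma-separated source names) into
#' the list-of-character-vector form used by [derive_flags()].
#'
#' @param flags Character vector from a fixture table's `flags` column.
#' @return List of character vectors.
#' @export
parse_flags <- function(flags) {
  out <- strsplit(flags, ",", fixed = TRUE)
  lapply(out, function(x) x[nzchar(x)])
}
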