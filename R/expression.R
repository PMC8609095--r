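#' Read a tissue-expression table
#'
#' Tab-separated, one row per protein; the first column names the protein
#' and the remaining columns are tissue/CNS-area abundance values. A first
#' line of the form `#cutoff=<value>` records the expression cutoff used
#' when the table was exported (e.g. from an expression atlas); it can be
#' overridden by the `cutoff` argument.
#'
#' @param path Path to the TSV file.
#' @param cutoff Optional numeric cutoff overriding the file header.
#' @return An `expression_table` tibble with attributes `cutoff` and
#'   `source`.
#' @export
read_expression_table <- function(path, cutoff = NULL) {
  first <- readLines(path, n = 1L)
  file_cutoff <- NA_real_
  if (grepl("^#\\s*cutoff\\s*=", first)) {
    file_cutoff <- as.numeric(sub("^#\\s*cutoff\\s*=\\s*", "", first))
  }
  x <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                         stringsAsFactors = FALSE)
  names(x)[1] <- "protein_id"
  if (anyDuplicated(names(x))) {
    rlang::abort("expression table column names must be unique")
  }
  out <- tibble::as_tibble(x)
  attr(out, "cutoff") <- cutoff %||% file_cutoff
  attr(out, "source") <- path
  class(out) <- c("expression_table", class(out))
  out
}

#' Count screen-hit proteins expressed per CNS area
#'
#' For each area of interest, counts how many of the hit proteins have an
#' expression value at or above the cutoff. Hit proteins absent from the
#' table are counted as not expressed and reported in the
#' `unknown_proteins` attribute — matching expression databases that simply
#' provide no detail for some proteins.
#'
#' @param hit_proteins Character vector of protein identifiers from a
#'   screen.
#' @param table An [read_expression_table()] tibble (or compatible tibble
#'   with a `protein_id` column).
#' @param areas_of_interest Column names to tally; must exist in `table`.
#' @param cutoff Expression cutoff; defaults to the table's own.
#' @return A tibble with columns `area`, `n_expressed`; unknown proteins in
#'   `attr(, "unknown_proteins")`.
#' @export
area_counts <- function(hit_proteins, table, areas_of_interest,
                        cutoff = NULL) {
  missing_areas <- setdiff(areas_of_interest, names(table))
  if (length(missing_areas)) {
    rlang::abort(paste0("unknown area(s): ",
                        paste(missing_areas, collapse = ", ")))
  }
  cutoff <- cutoff %||% attr(table, "cutoff")
  if (is.null(cutoff) || is.na(cutoff)) {
    rlang::abort("no expression cutoff given and none recorded in the table")
  }
  unknown <- setdiff(hit_proteins, table$protein_id)
  rows <- table[table$protein_id %in% hit_proteins, , drop = FALSE]
  n <- vapply(areas_of_interest, function(a) {
    v <- rows[[a]]
    sum(!is.na(v) & v >= cutoff)
  }, integer(1))
  out <- tibble::tibble(area = areas_of_interest, n_expressed = unname(n))
  attr(out, "unknown_proteins") <- unknown
  attr(out, "cutoff") <- cutoff
  out
}
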