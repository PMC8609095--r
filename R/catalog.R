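#' @importFrom rlang abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Amino-acid alphabet accepted throughout the package: the 20 standard
# residues plus the ambiguity/selenocysteine codes found in real database
# records.
AA_ALPHABET <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M", "F",
  "P", "S", "T", "W", "Y", "V", "B", "Z", "X", "U"
)

#' Build a protein catalog
#'
#' A protein catalog is a tibble with one row per protein record and columns
#' `id`, `accession`, `description`, `sequence` and `tags`, plus a
#' `provenance` attribute recording its origin and every filter applied to
#' it. It is the searchable stand-in for a "brain" / "central nervous
#' system" subset of a protein databank.
#'
#' @param id Character vector of unique record identifiers.
#' @param sequence Character vector of amino-acid sequences (standard 20
#'   letters plus `X`, `B`, `Z`, `U`; case-insensitive).
#' @param accession External accession strings (may be empty).
#' @param description Free-text record annotations.
#' @param tags Free-text source labels (e.g. `"synthetic"`); multiple tags
#'   are separated by `";"`.
#' @param provenance Character vector describing where the records came
#'   from.
#' @return A `protein_catalog` tibble.
#' @export
protein_catalog <- function(id, sequence, accession = "", description = "",
                            tags = "", provenance = "constructed in R") {
  x <- tibble(
    id = as.character(id),
    accession = as.character(accession),
    description = as.character(description),
    sequence = toupper(as.character(sequence)),
    tags = as.character(tags)
  )
  validate_catalog(x)
  new_protein_catalog(x, provenance = provenance)
}

new_protein_catalog <- function(x, provenance = character()) {
  x <- as_tibble(x)
  class(x) <- c("protein_catalog", class(x))
  attr(x, "provenance") <- provenance
  x
}

validate_catalog <- function(x) {
  if (anyDuplicated(x$id)) {
    abort(paste0("duplicate record id(s): ",
                 paste(unique(x$id[duplicated(x$id)]), collapse = ", ")))
  }
  if (any(!nzchar(x$sequence))) {
    abort("every record must have a non-empty sequence")
  }
  bad <- !grepl(sprintf("^[%s]+$", paste(AA_ALPHABET, collapse = "")),
                x$sequence)
  if (any(bad)) {
    abort(paste0("illegal residue character in record(s): ",
                 paste(x$id[bad], collapse = ", ")))
  }
  invisible(x)
}

#' Catalog provenance
#'
#' Every filter appends a line to the catalog's provenance; the history is
#' never overwritten.
#'
#' @param catalog A `protein_catalog`.
#' @return Character vector, one entry per provenance event.
#' @export
provenance <- function(catalog) {
  attr(catalog, "provenance") %||% character()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

append_provenance <- function(catalog, line) {
  attr(catalog, "provenance") <- c(provenance(catalog), line)
  catalog
}

#' @export
print.protein_catalog <- function(x, ...) {
  cat(sprintf("<protein_catalog> %d record(s), %d residues\n",
              nrow(x), sum(nchar(x$sequence))))
  for (p in provenance(x)) cat(" -", p, "\n")
  NextMethod()
}

#' Read a protein catalog from a FASTA file
#'
#' One record is created per FASTA entry: the `id` is the first token of the
#' header, the `description` is the remainder of the header line. Record
#' order is preserved. An empty file yields an empty catalog.
#'
#' @param path Path to a FASTA file.
#' @param tags Tag string attached to every record read.
#' @return A `protein_catalog`.
#' @export
read_fasta <- function(path, tags = "") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) {
    return(new_protein_catalog(
      tibble(id = character(), accession = character(),
             description = character(), sequence = character(),
             tags = character()),
      provenance = paste0("read 0 records from ", path)
    ))
  }
  first <- which(keep)[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    abort(sprintf("malformed FASTA: line %d does not start a record header",
                  first))
  }
  seq_re <- sprintf("^[%s%s]+$", paste(AA_ALPHABET, collapse = ""),
                    paste(tolower(AA_ALPHABET), collapse = ""))
  for (i in which(keep)) {
    ln <- trimws(lines[i])
    if (!startsWith(ln, ">") && !grepl(seq_re, ln)) {
      abort(sprintf("illegal residue character at line %d", i))
    }
  }
  set <- Biostrings::readAAStringSet(path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  x <- tibble(
    id = id, accession = id, description = desc,
    sequence = unname(toupper(as.character(set))), tags = tags
  )
  validate_catalog(x)
  new_protein_catalog(
    x, provenance = sprintf("read %d records from %s", nrow(x), path)
  )
}

#' Write a protein catalog to a FASTA file
#'
#' Headers are `>id description`; sequence lines are wrapped at 80 columns.
#' `write_fasta()` followed by [read_fasta()] round-trips ids, descriptions
#' and sequences exactly.
#'
#' @param catalog A `protein_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(catalog, path) {
  set <- Biostrings::AAStringSet(catalog$sequence)
  names(set) <- ifelse(nzchar(catalog$description),
                       paste(catalog$id, catalog$description),
                       catalog$id)
  Biostrings::writeXStringSet(set, path, width = 80)
  invisible(path)
}

#' Filter a catalog by description keywords
#'
#' Keeps records whose description or tags contain at least one of
#' `include_terms` and none of `exclude_terms`. Matching is case-insensitive
#' plain substring (no tokenization), mimicking a free-text database field
#' hit. This is how the paper-style "brain" / "central nervous system"
#' subset is carved out and how "incomplete" / "hypothetical" records are
#' dropped.
#'
#' @param catalog A `protein_catalog`.
#' @param include_terms Character vector, at least one term.
#' @param exclude_terms Character vector (may be empty).
#' @return The filtered `protein_catalog`; its provenance records both term
#'   lists.
#' @export
filter_by_keywords <- function(catalog, include_terms,
                               exclude_terms = character()) {
  if (length(include_terms) == 0 || all(!nzchar(include_terms))) {
    abort("include_terms must contain at least one non-empty term")
  }
  hay <- tolower(paste(catalog$description, catalog$tags))
  match_any <- function(terms) {
    if (length(terms) == 0) return(rep(FALSE, length(hay)))
    Reduce(`|`, lapply(tolower(terms),
                       function(t) grepl(t, hay, fixed = TRUE)))
  }
  keep <- match_any(include_terms) & !match_any(exclude_terms)
  out <- new_protein_catalog(catalog[keep, , drop = FALSE],
                             provenance = provenance(catalog))
  append_provenance(out, sprintf(
    "keyword filter: include [%s]; exclude [%s]; kept %d/%d",
    paste(include_terms, collapse = ", "),
    paste(exclude_terms, collapse = ", "),
    nrow(out), nrow(catalog)
  ))
}

#' Remove records by identifier deny-list
#'
#' Records whose `id` or `accession` appears in `deny_list` are removed.
#' This is the declarative replacement for the manual curation step that
#' excluded known autoantigens (alpha-enolase, AKRIAI, DDAHI) and records
#' not actually expressed in the CNS.
#'
#' @param catalog A `protein_catalog`.
#' @param deny_list Character vector of identifiers or accessions.
#' @return The filtered `protein_catalog`; the number of removals is logged
#'   in its provenance.
#' @export
exclude_ids <- function(catalog, deny_list) {
  drop <- catalog$id %in% deny_list | catalog$accession %in% deny_list
  out <- new_protein_catalog(catalog[!drop, , drop = FALSE],
                             provenance = provenance(catalog))
  append_provenance(out, sprintf("deny-list: removed %d record(s)",
                                 sum(drop)))
}

#' Read a term or deny-list file
#'
#' One entry per line; blank lines and `#` comments are ignored.
#'
#' @param path File path.
#' @return Character vector of entries.
#' @export
read_term_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}
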