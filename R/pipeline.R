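#' Pipeline configuration
#'
#' Validates and assembles everything [run_pipeline()] needs. Two
#' execution modes exist: `"fixture"` analyses the bundled published
#' homology tables (no alignment — the fully reproducible mode), while
#' `"full"` aligns a user-supplied catalog against user-supplied
#' autoantigen sequences and feeds the resulting segments into the very
#' same downstream coincidence/domain/expression code path.
#'
#' @param out_dir Output directory (created if missing).
#' @param mode `"fixture"` or `"full"`.
#' @param autoantigen_fasta,catalog_fasta FASTA paths (`full` mode).
#' @param include_terms,exclude_terms Keyword filters applied to the
#'   catalog in `full` mode.
#' @param deny_list Identifiers removed from the catalog in `full` mode.
#' @param expression_tsv Optional expression table path for the CNS-area
#'   cross-reference.
#' @param params A [scoring_params()] object (`full` mode); its `e_cutoff`
#'   is the screen's E-value gate.
#' @param partial_threshold Minimum overlap for a partial coincidence.
#' @param flag_min_partial Minimum non-containment overlap that sets a
#'   coincidence flag.
#' @param marginal_threshold Insignificance band for epitope overlaps.
#' @param convention Coincidence counting convention (see
#'   [count_coincidences()]).
#' @param seed Integer seed fixed at the start of the run.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, mode = c("fixture", "full"),
                            autoantigen_fasta = NULL, catalog_fasta = NULL,
                            include_terms = c("brain",
                                              "central nervous system"),
                            exclude_terms = c("incomplete", "hypothetical"),
                            deny_list = character(),
                            expression_tsv = NULL,
                            params = scoring_params(),
                            partial_threshold = 10L,
                            flag_min_partial = 21L,
                            marginal_threshold = 6L,
                            convention = c("pairs", "per_segment"),
                            seed = 1L) {
  mode <- match.arg(mode)
  convention <- match.arg(convention)
  if (mode == "full") {
    ok <- function(p) !is.null(p) && file.exists(p)
    if (!ok(autoantigen_fasta) || !ok(catalog_fasta)) {
      rlang::abort(
        "full mode needs existing autoantigen_fasta and catalog_fasta")
    }
  }
  if (!is.null(expression_tsv) && !file.exists(expression_tsv)) {
    rlang::abort(paste0("expression_tsv not found: ", expression_tsv))
  }
  stopifnot(partial_threshold > 0, flag_min_partial > 0,
            marginal_threshold > 0)
  structure(list(
    out_dir = out_dir, mode = mode,
    autoantigen_fasta = autoantigen_fasta, catalog_fasta = catalog_fasta,
    include_terms = include_terms, exclude_terms = exclude_terms,
    deny_list = deny_list, expression_tsv = expression_tsv,
    params = params, partial_threshold = as.integer(partial_threshold),
    flag_min_partial = as.integer(flag_min_partial),
    marginal_threshold = as.integer(marginal_threshold),
    convention = convention, seed = as.integer(seed)
  ), class = "pipeline_config")
}

# One shared implementation of the downstream interval analysis, used by
# both execution modes.
coincidence_report <- function(spans, refs, partial_threshold,
                               flag_min_partial, convention) {
  counts <- count_coincidences(spans, refs,
                               partial_threshold = partial_threshold,
                               convention = convention)
  flags <- derive_flags(spans, refs, min_partial = flag_min_partial)
  list(counts = counts, flags = flags)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)))
  })
}

#' Run the mimicry screen pipeline
#'
#' Orchestrates catalog preparation, homology screening (full mode),
#' interval-coincidence analysis, flag derivation, domain mapping and the
#' optional expression cross-reference, writing per-autoantigen segment
#' tables (TSV), a coincidence-count JSON, domain assignments, area counts
#' and a run log into `config$out_dir`. Identical configurations produce
#' identical outputs; on failure the stage name is reported and files
#' created by the failed run are removed.
#'
#' @param config A [pipeline_config()].
#' @return The report bundle, invisibly: a list with per-autoantigen
#'   segment tibbles, coincidence counts, flags, domain assignments and
#'   (if requested) area counts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  on_fail <- function(e) {
    unlink(written)
    rlang::abort(conditionMessage(e))
  }
  tryCatch({
    fx <- pipeline_stage("fixtures", load_fixtures())
    report <- list(mode = config$mode, seed = config$seed,
                   autoantigens = list())

    if (config$mode == "fixture") {
      per_ag <- purrr::map(names(fx$tables), function(ag) {
        tab <- fx$tables[[ag]]
        spans <- interval(tab$a_start, tab$a_end, protein_id = ag)
        list(autoantigen = ag, table = tab, spans = spans)
      })
    } else {
      ags <- pipeline_stage("catalog", read_fasta(config$autoantigen_fasta))
      cat <- pipeline_stage("catalog", {
        x <- read_fasta(config$catalog_fasta)
        x <- filter_by_keywords(x, config$include_terms,
                                config$exclude_terms)
        exclude_ids(x, config$deny_list)
      })
      per_ag <- purrr::map(seq_len(nrow(ags)), function(i) {
        scr <- pipeline_stage("screen",
                              scan_autoantigen(ags[i, ], cat,
                                               params = config$params))
        tab <- tidy(scr) |>
          dplyr::transmute(
            autoantigen = ags$id[i], protein = .data$subject_id,
            accession = .data$subject_id,
            p_start = .data$s_start, p_end = .data$s_end,
            a_start = .data$q_start, a_end = .data$q_end,
            identity_pct = .data$identity_pct,
            homology_pct = .data$positive_pct,
            evalue = .data$evalue, flags = ""
          )
        list(autoantigen = ags$id[i], table = tab,
             spans = interval(tab$a_start, tab$a_end,
                              protein_id = ags$id[i]))
      })
    }

    names(per_ag) <- vapply(per_ag, `[[`, "", "autoantigen")
    counts_json <- list()
    for (ag in names(per_ag)) {
      x <- per_ag[[ag]]
      refs_ag <- fx$reference_segments |>
        dplyr::filter(.data$autoantigen == ag)
      refs_iv <- dplyr::bind_cols(
        interval(refs_ag$start, refs_ag$end, protein_id = ag),
        tibble::tibble(source = refs_ag$source)
      )
      cr <- pipeline_stage("coincidence", coincidence_report(
        x$spans, refs_iv, config$partial_threshold,
        config$flag_min_partial, config$convention))
      counts_json[[ag]] <- as.list(cr$counts[, c("contains", "contained_in",
                                                 "partial")])
      tab_out <- x$table
      tab_out$derived_flags <- flags_chr(cr$flags)
      f <- file.path(config$out_dir,
                     sprintf("segments_%s.tsv", tolower(ag)))
      utils::write.table(tab_out, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      written <- c(written, f)

      dom_ag <- fx$domains |> dplyr::filter(.data$protein_id == ag)
      doms <- pipeline_stage("domains", assign_domains(x$spans, dom_ag))
      f <- file.path(config$out_dir, sprintf("domains_%s.tsv", tolower(ag)))
      utils::write.table(doms, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      written <- c(written, f)

      report$autoantigens[[ag]] <- list(table = tab_out, counts = cr$counts,
                                        flags = cr$flags, domains = doms)
    }
    f <- file.path(config$out_dir, "coincidence.json")
    jsonlite::write_json(counts_json, f, auto_unbox = TRUE)
    written <- c(written, f)

    if (!is.null(config$expression_tsv)) {
      expr <- pipeline_stage("expression",
                             read_expression_table(config$expression_tsv))
      hits <- unique(unlist(lapply(report$autoantigens,
                                   function(a) a$table$accession)))
      ac <- pipeline_stage("expression",
                           area_counts(hits, expr, fx$areas))
      f <- file.path(config$out_dir, "area_counts.tsv")
      utils::write.table(ac, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      written <- c(written, f)
      report$area_counts <- ac
    }

    log <- c(
      sprintf("mimicscreen %s",
              as.character(utils::packageVersion("mimicscreen"))),
      sprintf("R %s", getRversion()),
      sprintf("mode=%s seed=%d", config$mode, config$seed),
      sprintf("partial_threshold=%d flag_min_partial=%d marginal_threshold=%d",
              config$partial_threshold, config$flag_min_partial,
              config$marginal_threshold),
      sprintf("convention=%s e_cutoff=%g", config$convention,
              config$params$e_cutoff)
    )
    f <- file.path(config$out_dir, "run_log.txt")
    writeLines(log, f)
    written <- c(written, f)
    invisible(report)
  }, error = on_fail)
}
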