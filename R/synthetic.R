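#' Average background amino-acid frequencies
#'
#' Robinson-Robinson style average protein composition, normalised to sum
#' exactly to one. Used as the background distribution of the synthetic
#' catalog generator.
#'
#' @return A named numeric vector over the 20 standard residues.
#' @export
robinson_frequencies <- function() {
  f <- c(
    A = 0.0780, R = 0.0512, N = 0.0448, D = 0.0536, C = 0.0192,
    Q = 0.0426, E = 0.0627, G = 0.0738, H = 0.0219, I = 0.0514,
    L = 0.0901, K = 0.0574, M = 0.0224, F = 0.0385, P = 0.0520,
    S = 0.0711, T = 0.0568, W = 0.0132, Y = 0.0321, V = 0.0644
  )
  f / sum(f)
}

.tissue_pool <- c("liver", "kidney", "spleen", "heart", "lung", "muscle")
.cns_terms <- c("brain", "central nervous system")

#' Generate a synthetic protein catalog
#'
#' Emulates the statistical backdrop of a protein databank: unrelated
#' random sequences drawn from a background residue distribution, with
#' free-text descriptions that mention "brain" or "central nervous system"
#' for a configurable fraction of records (so keyword filters are
#' exercised) and a fraction labelled "hypothetical protein" (so exclusion
#' terms are exercised). Fully reproducible: the same seed yields a
#' byte-identical catalog. Base R's default Mersenne-Twister generator is
#' used throughout.
#'
#' @param n_proteins Number of records.
#' @param length_range Integer range of sequence lengths, inclusive.
#' @param residue_frequencies Named 20-vector summing to 1 (within 1e-9).
#' @param seed Integer RNG seed.
#' @param cns_fraction Fraction of records whose description mentions a CNS
#'   term.
#' @param hypothetical_fraction Fraction of records labelled
#'   "hypothetical protein".
#' @return A `protein_catalog` tagged `"synthetic"`.
#' @export
generate_catalog <- function(n_proteins, length_range = c(200L, 600L),
                             residue_frequencies = robinson_frequencies(),
                             seed = 1L, cns_fraction = 0.6,
                             hypothetical_fraction = 0.1) {
  if (abs(sum(residue_frequencies) - 1) > 1e-9) {
    rlang::abort("residue_frequencies must sum to 1 (within 1e-9)")
  }
  if (is.null(names(residue_frequencies)) ||
      !all(names(residue_frequencies) %in% AA_ALPHABET)) {
    rlang::abort("residue_frequencies must be named with residue letters")
  }
  if (n_proteins == 0) {
    return(new_protein_catalog(
      tibble::tibble(id = character(), accession = character(),
                     description = character(), sequence = character(),
                     tags = character()),
      provenance = "synthetic catalog (empty)"
    ))
  }
  withr::with_seed(seed, {
    lens <- sample(seq(length_range[1], length_range[2]), n_proteins,
                   replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(names(residue_frequencies), L, replace = TRUE,
                   prob = residue_frequencies), collapse = "")
    }, "")
    cns <- stats::runif(n_proteins) < cns_fraction
    hypo <- stats::runif(n_proteins) < hypothetical_fraction
    tissue <- ifelse(cns,
                     sample(.cns_terms, n_proteins, replace = TRUE),
                     sample(.tissue_pool, n_proteins, replace = TRUE))
    desc <- sprintf("Homo sapiens %s%s protein %d",
                    ifelse(hypo, "hypothetical ", ""), tissue,
                    seq_len(n_proteins))
    cat <- protein_catalog(
      id = sprintf("SYN%05d", seq_len(n_proteins)),
      sequence = seqs,
      accession = sprintf("SYN%05d", seq_len(n_proteins)),
      description = desc,
      tags = "synthetic",
      provenance = sprintf(
        "synthetic catalog: n=%d, lengths %d-%d, seed=%d, cns_fraction=%g",
        n_proteins, length_range[1], length_range[2], seed, cns_fraction)
    )
    cat
  })
}

#' Specification of a planted homologous segment
#'
#' @param subject_id Catalog record to host the planted segment.
#' @param a_start,a_end Autoantigen span to copy (1-based inclusive,
#'   length >= 10).
#' @param target_identity Target fraction of identical positions, in
#'   (0, 1].
#' @param target_positive Target fraction of positive-scoring positions,
#'   `>= target_identity` (defaults to it).
#' @param seed Integer RNG seed for the edit process.
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(subject_id, a_start, a_end, target_identity,
                       target_positive = target_identity, seed = 1L) {
  if (a_end - a_start + 1 < 10) rlang::abort("planted span must be >= 10 residues")
  if (target_identity <= 0 || target_identity > 1 ||
      target_positive < target_identity || target_positive > 1) {
    rlang::abort("need 0 < target_identity <= target_positive <= 1")
  }
  structure(list(subject_id = subject_id, a_start = as.integer(a_start),
                 a_end = as.integer(a_end),
                 target_identity = target_identity,
                 target_positive = target_positive, seed = as.integer(seed)),
            class = "plant_spec")
}

#' Plant a homologous segment into a catalog record
#'
#' Copies the requested autoantigen span into the subject sequence at a
#' random position, editing each copied position independently: with
#' probability `1 - target_identity` the residue is substituted, and a
#' substituted residue is drawn from the positive-scoring residues of the
#' substitution matrix with probability
#' `(target_positive - target_identity) / (1 - target_identity)`,
#' otherwise uniformly from the other residues. This emulates a locally
#' homologous segment embedded in unrelated sequence — the structure the
#' screen assumes.
#'
#' @param catalog A `protein_catalog`.
#' @param autoantigen One-row catalog (or list with `sequence`) providing
#'   the donor span.
#' @param spec A [plant_spec()].
#' @param matrix Substitution matrix used to choose positive-scoring
#'   substitutions.
#' @return A list with the modified `catalog` and a one-row `truth` tibble
#'   (`subject_id`, `s_start`, `s_end`, `a_start`, `a_end`,
#'   `realized_identity`).
#' @export
plant_homologous_segment <- function(catalog, autoantigen, spec,
                                     matrix = blosum62()) {
  ag_seq <- strsplit(toupper(autoantigen$sequence[[1]]), "")[[1]]
  if (spec$a_end > length(ag_seq)) {
    rlang::abort("planted span lies outside the autoantigen")
  }
  row <- which(catalog$id == spec$subject_id)
  if (length(row) != 1) {
    rlang::abort(paste0("subject_id not in catalog: ", spec$subject_id))
  }
  donor <- ag_seq[spec$a_start:spec$a_end]
  L <- length(donor)
  subj <- strsplit(catalog$sequence[row], "")[[1]]
  if (length(subj) < L) {
    rlang::abort("subject too short to host the planted segment")
  }
  std <- names(robinson_frequencies())
  p_pos <- if (spec$target_identity < 1) {
    (spec$target_positive - spec$target_identity) /
      (1 - spec$target_identity)
  } else 0
  withr::with_seed(spec$seed, {
    s_start <- sample(length(subj) - L + 1L, 1L)
    insert <- donor
    sub_mask <- stats::runif(L) >= spec$target_identity
    for (i in which(sub_mask)) {
      orig <- donor[i]
      if (stats::runif(1) < p_pos) {
        pool <- std[matrix[orig, std] > 0 & std != orig]
        if (length(pool) == 0) pool <- setdiff(std, orig)
      } else {
        pool <- setdiff(std, orig)
      }
      insert[i] <- pool[sample.int(length(pool), 1L)]
    }
    subj[s_start:(s_start + L - 1L)] <- insert
  })
  catalog$sequence[row] <- paste(subj, collapse = "")
  validate_catalog(catalog)
  truth <- tibble::tibble(
    subject_id = spec$subject_id,
    s_start = s_start, s_end = s_start + L - 1L,
    a_start = spec$a_start, a_end = spec$a_end,
    realized_identity = mean(insert == donor)
  )
  list(
    catalog = append_provenance(catalog, sprintf(
      "planted %d-residue segment (target identity %.2f) into %s",
      L, spec$target_identity, spec$subject_id)),
    truth = truth
  )
}
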