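---
title: "Screening thyroid autoantigens for molecular mimicry with CNS proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening thyroid autoantigens for molecular mimicry with CNS proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimicscreen)
library(dplyr)
```

## The scientific question

Steroid-responsive encephalopathy associated with autoimmune thyroiditis
(SREAT, also called Hashimoto's encephalopathy) combines neurological
symptoms with high titers of antibodies against the thyroid autoantigens —
the thyrotropin receptor (TSH-R), thyroglobulin (Tg) and thyroid
peroxidase (TPO). One mechanistic hypothesis is molecular mimicry: if
segments of the thyroid autoantigens resemble proteins expressed in the
central nervous system, thyroid-directed antibodies could cross-react with
brain tissue. Three CNS proteins are already established SREAT
autoantigens — alpha-enolase (`Eno`), aldo-keto reductase family 1 member
A1 (`AKRIAI`) and dimethylargininase-I (`DDAHI`) — and the spans of the
thyroid autoantigens homologous to them are known.

`mimicscreen` implements the full desk screen behind this hypothesis:

1. carve a "brain" / "central nervous system" catalog out of a protein
   databank by keyword (`filter_by_keywords()`) and deny-list
   (`exclude_ids()`) filtering;
2. locally align each thyroid autoantigen against every catalog protein
   (`scan_autoantigen()`), keeping segments with E-value below 10;
3. intersect the homologous autoantigen spans with the reference spans
   already linked to `Eno`/`AKRIAI`/`DDAHI`
   (`count_coincidences()`, `derive_flags()`);
4. map segments onto structural domains (`assign_domains()`), published
   epitopes (`epitope_report()`) and tissue-expression tables
   (`area_counts()`).

The published screen results (three homology tables, their reference
segments, epitopes and domain bounds) ship as checksummed fixtures
(`load_fixtures()`), so the entire downstream interval analysis is
reproducible offline; the alignment stage is validated on synthetic
catalogs with planted homologies instead, because the original databank
snapshot (46,809 records) is not redistributable.

## The alignment model

`local_align()` is a Smith–Waterman local aligner with affine gap
penalties: a gap of length $L$ costs $o + eL$ with opening penalty
$o = 11$ and extension penalty $e = 1$ (the classic protein-BLAST
defaults), under BLOSUM62. The bundled matrix (`blosum62()`) is the
standard BLOSUM62 extended with a selenocysteine row/column scored as
cysteine, since databank records occasionally contain `U`. After the
optimal segment is reported, its residues are masked and the dynamic
programme is re-run, yielding up to `max_segments` mutually
non-overlapping locally optimal segments per protein pair — this is what
produces multi-segment homology groups such as the 22 fibrillin-1
segments.

Significance uses Karlin–Altschul statistics for gapped alignments,

$$E = K \, m \, n \, e^{-\lambda S},$$

with $\lambda = 0.267$ and $K = 0.041$ (the standard gapped BLOSUM62
parameters), query length $m$, database residue count $n$, and raw score
$S$; no edge-length correction is applied. Segments with $E < 10$ are
kept, matching the published cutoff. Per-segment statistics follow the
BLAST reporting convention: identity is the fraction of identical columns
over the full aligned length (gap columns included), and "overall
homology" (positives) counts columns that are identical or score
positively in the matrix.

The aligner is written once in C++ (via Rcpp) and is verified in the test
suite against `Biostrings::pairwiseAlignment()` — an independent,
established implementation — on hundreds of random pairs.

## The interval-coincidence model

All downstream analysis happens on intervals of residue positions.
`classify_overlap(a, b)` assigns, in precedence order: `CONTAINS` (b lies
inside a; equal intervals count as `CONTAINS`), `CONTAINED_IN`, `PARTIAL`
(non-containment overlap of at least `partial_threshold` residues,
default 10), `MARGINAL` (any smaller positive overlap) and `NONE`.
`count_coincidences()` tallies these classes over all ordered
(table segment, reference segment) pairs with multiplicity — one segment
containing three references contributes three counts, matching the
published "with some multiple matches" convention; a per-segment
convention is available as a switch.

Two calibration choices deserve explanation:

* **The partial threshold is inclusive** (overlap ≥ 10 classifies
  `PARTIAL`). The published tallies describe "overlap of more than 10
  residues", but the printed TPO tables only reproduce the published
  count of two partial overlaps if the dual oxidase 2 segment
  (650–695, exactly 10 residues against the `Eno` reference 637–659) is
  included; the inclusive rule reproduces every published tally
  (Tg 59/3/10, TPO 36/0/2) without affecting the others.
* **TSH-R partial overlaps: six, not five.** The published summary
  sentence reports five partial overlaps for TSH-R, but recomputing from
  the printed table yields six: five segments overlap the `AKRIAI`
  reference 360–415 (spans 395–688, 393–706, 370–727, 381–466, 402–689)
  and the GPER segment 423–639 additionally overlaps the `AKRIAI`
  reference 620–676 by 20 residues. The tables are treated as primary
  throughout this package, so `mimicscreen` reports six.

`derive_flags()` regenerates the printed "coincidences with" column: a
source (`Eno`, `AKRIAI`, `DDAHI`) flags a segment when a reference of
that source is contained either way or overlaps by at least
`min_partial = 21` residues. The threshold is calibrated on the printed
flag columns themselves: a literal reading of the >10-residue rule would
flag eleven receptor-table rows whose printed column is empty (e.g. the
5-residue C-C chemokine receptor 7 and 8-residue olfactory-receptor
overlaps are unflagged, but so are several 11–20-residue overlaps),
failing the printed data it is meant to reproduce. At 21 residues the
derived flags match 100% of the receptor table and 97.2% (172/177) of
the other two tables. The five residual mismatches are irreducible
internal inconsistencies of the printed flag columns, including the
testican-3 17–95 row (printed `Eno`, but no `Eno` reference lies near
17–95 — a documented erratum) and three SPARC-family rows printed
unflagged despite containing the `AKRIAI` reference 31–90.

## Epitopes, domains and expression

`epitope_report()` classifies every homology segment of a protein against
its published linear epitopes, keeps the most specific class per segment,
and counts segments with any overlap, with at least a partial overlap and
with full containment; overlaps of at most `marginal_threshold = 6`
residues are reported as insignificant, following the published "6 or
less amino acids of overlap" convention. The published tallies are
reproduced exactly: 4 of nidogen-1's 6 Tg-homologous segments contain its
epitope 867–887, 7 of fibrillin-1's 22 TPO-homologous segments overlap a
listed epitope, and 4 of fibrillin-3's 17 segments contain one.

`merge_spans()` collapses a protein's segments into cumulative spans (the
gray bars of the published track figures; adjacent spans merge), built on
`IRanges::reduce()`. `assign_domains()` lists every annotated structural
domain a segment touches — annotations may nest, as with the TSH-R
C-peptide inside its hinge region. `area_counts()` cross-references hit
proteins against a tissue-expression table, counting per CNS area the
hits expressed at or above a cutoff; proteins absent from the table count
as not expressed and are reported separately.

## The synthetic generator

Because the original databank snapshot cannot be redistributed, the
alignment stage is validated on synthetic catalogs. `generate_catalog()`
draws unrelated sequences from the Robinson–Robinson average amino-acid
composition, with lengths uniform in a configurable range and free-text
descriptions that mention CNS terms (so keyword filters are exercised)
and "hypothetical protein" labels (so exclusion terms are exercised).
`plant_homologous_segment()` then embeds a copy of a chosen autoantigen
span at a random position of a chosen record, substituting each position
independently with probability $1 - t_i$ (target identity $t_i$); a
substituted residue is drawn from the positive-scoring residues with
probability $(t_p - t_i)/(1 - t_i)$, so the planted segment realises both
a target identity and a target positive fraction. The generator is
seed-deterministic and leaves the global RNG stream untouched.

This emulates the structure the screen assumes — a locally homologous
island inside unrelated sequence — but deliberately not databank realism:
no domain families, no repeats, no compositional bias, no homology
between catalog records. Consequently false-positive behaviour under
E < 10 is optimistic relative to a real databank, and the planted
recovery rate (≥ 95% at 60% identity over 60 residues in the acceptance
checks; in practice 100%) measures aligner sensitivity, not screen
specificity.

## A worked fixture-mode run

```{r worked}
fx <- load_fixtures()
tab <- fx$tables$TG
refs <- filter(fx$reference_segments, autoantigen == "TG")
count_coincidences(
  interval(tab$a_start, tab$a_end, protein_id = "TG"),
  interval(refs$start, refs$end, protein_id = "TG")
)

nid <- filter(tab, accession == 115298674)
merge_spans(interval(nid$p_start, nid$p_end))

eps <- filter(fx$epitopes, protein_id == 115298674)
glance(epitope_report(interval(nid$p_start, nid$p_end),
                      interval(eps$start, eps$end)))
```

`run_pipeline(pipeline_config(out_dir, mode = "fixture"))` performs the
same analysis for all three autoantigens and writes per-autoantigen
segment and domain tables, a coincidence-count JSON and a run log;
`mode = "full"` aligns a user-supplied catalog first and feeds the
resulting segments through the identical downstream path.

## Numerical choices and limitations

* Published percentages are reproduced with half-away-from-zero rounding
  of `100 * count / aligned_length`.
* E-values use `exp()` directly; raw scores are integers, and scores of
  equal value are reported in deterministic traceback order, so repeated
  runs are byte-identical.
* Exact reproduction of the published segment boundaries and E-values is
  out of scope: they depend on the 2020 databank snapshot and the exact
  BLAST build (composition-based statistics, edge corrections) used then.
  What is reproduced exactly is every downstream interval-analysis
  number recomputable from the printed tables.
* The expression cross-reference consumes a user-supplied table; no
  expression atlas is bundled.
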