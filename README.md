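# mimicscreen

Molecular-mimicry screening of the three classical thyroid autoantigens —
the thyrotropin receptor (TSH-R), thyroglobulin (Tg) and thyroid
peroxidase (TPO) — against proteins expressed in the brain or central
nervous system.

## The scientific problem

Steroid-responsive encephalopathy associated with autoimmune thyroiditis
(SREAT, Hashimoto's encephalopathy) pairs neurological disease with
anti-thyroid antibodies. If segments of the thyroid autoantigens are
locally homologous to CNS-expressed proteins, thyroid-directed antibodies
could cross-react with brain tissue (molecular mimicry). Three CNS
proteins are already established SREAT autoantigens — alpha-enolase
(`Eno`), aldo-keto reductase 1A1 (`AKRIAI`) and dimethylargininase-I
(`DDAHI`) — and the thyroid-autoantigen spans homologous to them are
known reference segments.

`mimicscreen` implements the whole desk screen:

* **catalog** — FASTA-backed protein catalogs with keyword
  ("brain" / "central nervous system") and deny-list filtering, with a
  full provenance trail;
* **alignment** — an in-house Smith–Waterman local aligner (C++ via Rcpp)
  with affine gaps (open 11, extend 1), BLOSUM62 (selenocysteine scored
  as cysteine), iterative masking for multiple non-overlapping segments
  per pair, and Karlin–Altschul E-values (λ = 0.267, K = 0.041, E < 10);
* **coincidence** — interval classification (`CONTAINS`, `CONTAINED_IN`,
  `PARTIAL`, `MARGINAL`, `NONE`), the published coincidence tallies and
  regeneration of the printed `Eno`/`AKRIAI`/`DDAHI` flag columns;
* **domains / epitopes / expression** — structural-domain mapping,
  per-segment epitope reports and CNS-area expression cross-references;
* **synthetic** — a seed-deterministic catalog generator with planted
  homologous segments for end-to-end validation;
* **pipeline** — `run_pipeline()` in a fully reproducible `fixture` mode
  (the bundled published tables) or a `full` mode (align your own
  catalog, then the identical downstream path).

The published screen results ship as checksummed text fixtures
(`load_fixtures()`): the three homology tables (47 + 62 + 115 segments),
29 reference segments, 37 epitopes, domain bounds and the CNS areas of
interest.

## Worked example

Recompute the thyroglobulin coincidence tallies from the bundled tables:

```r
library(mimicscreen)
library(dplyr)

fx <- load_fixtures()
tab <- fx$tables$TG
refs <- filter(fx$reference_segments, autoantigen == "TG")
count_coincidences(interval(tab$a_start, tab$a_end, protein_id = "TG"),
                   interval(refs$start, refs$end, protein_id = "TG"))
#> # A tibble: 1 × 5
#>   contains contained_in partial partial_threshold convention
#>      <int>        <int>   <int>             <int> <chr>
#> 1       59            3      10                10 pairs

nid <- filter(tab, accession == 115298674)   # nidogen-1
merge_spans(interval(nid$p_start, nid$p_end))
#> # A tibble: 1 × 3
#>   protein_id start   end
#> 1 <NA>         847   925

eps <- filter(fx$epitopes, protein_id == 115298674)
glance(epitope_report(interval(nid$p_start, nid$p_end),
                      interval(eps$start, eps$end)))
#> # A tibble: 1 × 6
#>   n_segments n_overlap n_partial n_contains n_significant marginal_threshold
#> 1          6         6         5          4             6                  6
```

Plant a 70%-identity segment into a synthetic catalog and screen for it:

```r
set.seed(10)
aa <- names(robinson_frequencies())
ag <- protein_catalog("AG1",
        paste(sample(aa, 400, TRUE, robinson_frequencies()), collapse = ""))
cat1 <- generate_catalog(5, length_range = c(200L, 300L), seed = 3)
pl <- plant_homologous_segment(cat1, ag,
        plant_spec(cat1$id[2], 100, 179, target_identity = 0.7, seed = 4))
scan_autoantigen(ag, pl$catalog)
#> <mimicry_screen> autoantigen AG1: 6 segment(s) in 5 protein(s), db 1,164 residues
#> # A tibble: 6 × 13
#>   query_id subject_id q_start q_end s_start s_end identity_pct positive_pct
#> 1 AG1      SYN00002        83   177      58   152           54           55
#> 2 AG1      SYN00001       316   341      17    42           35           42
#> ...
```

The top hit recovers the planted segment (truth: `SYN00002` 75–154
against autoantigen 100–179). Use `tidy()`, `glance()`,
`homology_groups()` and `autoplot()` on screen objects.

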