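test_that("classify_overlap equals the exhaustive small-universe oracle", {
  # every interval pair within 1..30, at two thresholds
  iv <- expand.grid(s = 1:30, e = 1:30)
  iv <- iv[iv$s <= iv$e, ]
  pairs <- expand.grid(a = seq_len(nrow(iv)), b = seq_len(nrow(iv)))
  a <- interval(iv$s[pairs$a], iv$e[pairs$a])
  b <- interval(iv$s[pairs$b], iv$e[pairs$b])
  for (thr in c(3L, 10L)) {
    got <- classify_overlap(a, b, partial_threshold = thr)
    want <- oracle_classify(a$start, a$end, b$start, b$end, thr)
    expect_identical(as.character(got$class), want$class)
    expect_identical(got$overlap_len, want$overlap_len)
  }
})

test_that("classification is dual under argument exchange", {
  withr::with_seed(81, {
    a <- interval(s <- sample(1:200, 300, TRUE), s + sample(0:80, 300, TRUE))
    b <- interval(s2 <- sample(1:200, 300, TRUE), s2 + sample(0:80, 300, TRUE))
    ab <- classify_overlap(a, b)
    ba <- classify_overlap(b, a)
    expect_identical(ab$overlap_len, ba$overlap_len)
    flip <- c(CONTAINS = "CONTAINED_IN", CONTAINED_IN = "CONTAINS",
              PARTIAL = "PARTIAL", MARGINAL = "MARGINAL", NONE = "NONE")
    # equal intervals classify CONTAINS from both sides by the precedence
    # rule, so exempt them from the flip expectation
    eq <- a$start == b$start & a$end == b$end
    expect_identical(as.character(ab$class)[!eq],
                     unname(flip[as.character(ba$class)])[!eq])
    expect_true(all(ab$class[eq] == "CONTAINS" & ba$class[eq] == "CONTAINS"))
  })
})

test_that("documented interval examples classify as published", {
  # equal intervals take the CONTAINS branch
  expect_equal(as.character(classify_overlap(interval(5, 9),
                                             interval(5, 9))$class),
               "CONTAINS")
  # chemokine-receptor span vs reference 620-676: 5 residues, marginal
  cl <- classify_overlap(interval(672, 725), interval(620, 676))
  expect_equal(as.character(cl$class), "MARGINAL")
  expect_equal(cl$overlap_len, 5L)
  # nidogen-1 segment 874-919 vs its epitope 867-887: 14-residue partial
  cl2 <- classify_overlap(interval(874, 919), interval(867, 887))
  expect_equal(as.character(cl2$class), "PARTIAL")
  expect_equal(cl2$overlap_len, 14L)
  expect_error(interval(10, 5), "start")
  expect_error(overlap_length(interval(1, 5, "p1"), interval(2, 6, "p2")),
               "different proteins")
})

test_that("count_coincidences counts ordered pairs and validates inputs", {
  segs <- interval(c(10, 100, 300), c(60, 180, 320), protein_id = "AG")
  refs <- interval(c(20, 55, 150), c(40, 120, 162), protein_id = "AG")
  cc <- count_coincidences(segs, refs, partial_threshold = 10L)
  # 10-60 contains 20-40; 10-60 vs 55-120 overlap 6 (marginal);
  # 100-180 contains 150-162; 100-180 vs 55-120 overlap 21 (partial)
  expect_equal(cc$contains, 2L)
  expect_equal(cc$contained_in, 0L)
  expect_equal(cc$partial, 1L)
  # per-segment convention collapses multiple matches of one segment
  segs2 <- interval(c(10, 10), c(200, 200), protein_id = "AG")
  cc_pairs <- count_coincidences(segs2, refs)
  cc_seg <- count_coincidences(segs2, refs, convention = "per_segment")
  expect_equal(cc_pairs$contains, 6L)
  expect_equal(cc_seg$contains, 2L)
  # shuffling rows never changes the tallies
  withr::with_seed(91, {
    cc2 <- count_coincidences(segs[sample(3), ], refs[sample(3), ])
    expect_equal(cc2$contains, cc$contains)
    expect_equal(cc2$partial, cc$partial)
  })
  expect_error(count_coincidences(segs, interval(1, 5, "OTHER")),
               "more than one autoantigen")
})

test_that("derive_flags reproduces the published flag logic", {
  refs <- tibble::tibble(
    start = c(149, 560, 360, 396, 555, 620, 141, 263),
    end = c(161, 575, 415, 402, 563, 676, 148, 292),
    source = c("Eno", "Eno", "AKRIAI", "AKRIAI", "AKRIAI", "AKRIAI",
               "DDAHI", "DDAHI")
  )
  spans <- interval(c(395, 672, 381, 20), c(688, 725, 466, 252))
  fl <- derive_flags(spans, refs)
  # 395-688 contains Eno 560-575 and three AKRIAI references
  expect_identical(fl[[1]], c("Eno", "AKRIAI"))
  # 672-725 only touches 620-676 by 5 residues: unflagged
  expect_identical(fl[[2]], character(0))
  # 381-466 contains AKRIAI 396-402 (its 35-residue partial also flags)
  expect_identical(fl[[3]], "AKRIAI")
  # 20-252 contains Eno 149-161 and DDAHI 141-148, in canonical order
  expect_identical(fl[[4]], c("Eno", "DDAHI"))
  expect_identical(flags_chr(fl), c("Eno,AKRIAI", "", "AKRIAI", "Eno,DDAHI"))
  expect_identical(parse_flags(flags_chr(fl)), fl)
})

test_that("epitope_report picks the most specific class per segment", {
  segs <- interval(c(847, 874, 880, 10), c(919, 919, 919, 20))
  eps <- interval(867, 887)
  rep1 <- epitope_report(segs, eps)
  expect_identical(as.character(rep1$best_class),
                   c("CONTAINS", "PARTIAL", "MARGINAL", "NONE"))
  s <- attr(rep1, "summary")
  expect_equal(s$n_segments, 4L)
  expect_equal(s$n_overlap, 3L)
  expect_equal(s$n_partial, 2L)
  expect_equal(s$n_contains, 1L)
  # 8-residue marginal overlap exceeds the 6-residue insignificance band
  expect_equal(s$n_significant, 3L)
  expect_identical(glance(rep1), s)
  # no epitopes: everything NONE
  rep0 <- epitope_report(segs, interval(integer(), integer()))
  expect_true(all(rep0$best_class == "NONE"))
})
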