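test_that("merge_spans matches the residue-mask oracle", {
  withr::with_seed(101, {
    for (i in 1:25) {
      n <- sample(1:12, 1)
      st <- sample(1:150, n, TRUE)
      en <- st + sample(0:40, n, TRUE)
      got <- merge_spans(interval(st, en))
      want <- oracle_merge(st, en)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  })
  # adjacent spans merge; disjoint ones do not
  adj <- merge_spans(interval(c(1, 6), c(5, 9)))
  expect_equal(adj$start, 1L)
  expect_equal(adj$end, 9L)
  dis <- merge_spans(interval(c(1, 7), c(5, 9)))
  expect_equal(nrow(dis), 2)
  expect_error(merge_spans(tibble::tibble(start = 9L, end = 3L)), "start")
})

test_that("an exact planted copy is recovered at full identity", {
  withr::with_seed(111, {
    ag <- protein_catalog("AG", random_seq(300),
                          description = "autoantigen under study")
    cat1 <- generate_catalog(4, length_range = c(150L, 250L), seed = 77)
    sp <- plant_spec(cat1$id[2], a_start = 50, a_end = 149,
                     target_identity = 1, seed = 5)
    pl <- plant_homologous_segment(cat1, ag, sp)
    scr <- scan_autoantigen(ag, pl$catalog)
    top <- tidy(scr)[1, ]
    expect_equal(top$subject_id, pl$truth$subject_id)
    # the exact copy may gain a few chance-matching flank columns, so
    # identity stays near (not exactly at) 100
    expect_gte(top$identity_pct, 95)
    # the reported segment covers the full planted span on both axes
    expect_lte(top$q_start, pl$truth$a_start)
    expect_gte(top$q_end, pl$truth$a_end)
    expect_lte(top$s_start, pl$truth$s_start)
    expect_gte(top$s_end, pl$truth$s_end)
  })
})

test_that("unrelated random sequences yield no hits at a tight cutoff", {
  ag <- withr::with_seed(121, protein_catalog("AG", random_seq(300)))
  cat1 <- generate_catalog(6, length_range = c(150L, 250L), seed = 31)
  scr <- scan_autoantigen(ag, cat1, params = scoring_params(e_cutoff = 1e-6))
  expect_equal(nrow(scr), 0)
  g <- glance(scr)
  expect_equal(g$n_subjects, 0L)
  expect_true(is.na(g$best_evalue))
})

test_that("the screen drops the autoantigen's own catalog record", {
  ag <- withr::with_seed(131, protein_catalog("AG", random_seq(120)))
  cat1 <- protein_catalog(c("AG", "other"),
                          c(ag$sequence, random_seq(100)))
  expect_warning(scr <- scan_autoantigen(ag, cat1), "self")
  expect_false("AG" %in% tidy(scr)$subject_id)
})

test_that("screen results are grouped by subject, ordered by significance", {
  withr::with_seed(141, {
    ag <- protein_catalog("AG", random_seq(400))
    cat1 <- generate_catalog(5, length_range = c(200L, 300L), seed = 9)
    pl1 <- plant_homologous_segment(
      cat1, ag, plant_spec(cat1$id[4], 30, 109, 0.9, seed = 1))
    pl2 <- plant_homologous_segment(
      pl1$catalog, ag, plant_spec(cat1$id[1], 200, 259, 0.7, seed = 2))
    scr <- scan_autoantigen(ag, pl2$catalog)
    tt <- tidy(scr)
    # the better plant leads; each subject's rows are contiguous
    expect_equal(tt$subject_id[1], cat1$id[4])
    expect_true(all(rle(tt$subject_id)$lengths ==
                      table(tt$subject_id)[rle(tt$subject_id)$values]))
    hg <- homology_groups(scr)
    expect_setequal(hg$subject_id, unique(tt$subject_id))
    expect_equal(sum(hg$n_segments), nrow(tt))
    g <- glance(scr)
    expect_equal(g$n_segments, nrow(tt))
    expect_equal(g$db_residues, sum(nchar(pl2$catalog$sequence)))
  })
})

test_that("tidy() strips the screen class but keeps every column", {
  ag <- withr::with_seed(151, protein_catalog("AG", random_seq(150)))
  cat1 <- generate_catalog(3, length_range = c(100L, 150L), seed = 13)
  scr <- scan_autoantigen(ag, cat1, params = scoring_params(e_cutoff = 1e6))
  tt <- tidy(scr)
  expect_false(inherits(tt, "mimicry_screen"))
  expect_true(all(c("query_id", "subject_id", "q_start", "q_end", "s_start",
                    "s_end", "identity_pct", "positive_pct", "raw_score",
                    "evalue") %in% names(tt)))
})
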