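test_that("bundled score matrix agrees with Biostrings BLOSUM62", {
  m <- blosum62()
  data("BLOSUM62", package = "Biostrings", envir = environment())
  shared <- intersect(rownames(m), rownames(BLOSUM62))
  expect_true(all(c(STD_AA, "B", "Z", "X", "*") %in% shared))
  expect_identical(m[shared, shared], BLOSUM62[shared, shared])
  # selenocysteine is scored as cysteine
  expect_identical(m["U", STD_AA], m["C", STD_AA])
  expect_identical(m[, "U"], m["U", ])
  expect_true(isSymmetric(unname(m)))
})

test_that("self-alignment is a single full-length 100/100 segment", {
  withr::with_seed(21, {
    for (len in c(30, 77, 140)) {
      q <- random_seq(len)
      hits <- local_align(q, q, scoring_params(), query_id = "q",
                          subject_id = "q")
      expect_equal(nrow(hits), 1)
      expect_equal(hits$q_start, 1L)
      expect_equal(hits$q_end, len)
      expect_equal(hits$s_start, 1L)
      expect_equal(hits$s_end, len)
      expect_equal(hits$identity_pct, 100)
      expect_equal(hits$positive_pct, 100)
      m <- blosum62()
      chars <- strsplit(q, "")[[1]]
      expect_equal(hits$raw_score, sum(m[cbind(chars, chars)]))
    }
  })
})

test_that("top raw score matches the Biostrings local-alignment oracle", {
  withr::with_seed(31, {
    for (i in 1:30) {
      q <- random_seq(sample(15:40, 1))
      s <- random_seq(sample(15:40, 1))
      hits <- local_align(q, s, scoring_params(e_cutoff = Inf))
      expect_gte(nrow(hits), 1)
      expect_equal(hits$raw_score[1], biostrings_local_score(q, s),
                   info = paste(q, s))
    }
  })
})

test_that("alignment score is symmetric in query and subject", {
  withr::with_seed(41, {
    for (i in 1:10) {
      q <- random_seq(60)
      s <- random_seq(60)
      a <- local_align(q, s, scoring_params(e_cutoff = Inf))
      b <- local_align(s, q, scoring_params(e_cutoff = Inf))
      expect_equal(a$raw_score[1], b$raw_score[1])
    }
  })
})

test_that("reported segments are mutually non-overlapping on both axes", {
  withr::with_seed(51, {
    core <- random_seq(40)
    q <- paste0(random_seq(30), core, random_seq(50), core, random_seq(20))
    s <- paste0(random_seq(10), core, random_seq(60))
    hits <- local_align(q, s, scoring_params(e_cutoff = Inf),
                        max_segments = 10L)
    expect_gte(nrow(hits), 2)
    if (nrow(hits) > 1) {
      for (i in seq_len(nrow(hits) - 1)) {
        for (j in seq(i + 1, nrow(hits))) {
          q_ov <- min(hits$q_end[i], hits$q_end[j]) -
            max(hits$q_start[i], hits$q_start[j]) + 1
          s_ov <- min(hits$s_end[i], hits$s_end[j]) -
            max(hits$s_start[i], hits$s_start[j]) + 1
          expect_lte(q_ov, 0)
          expect_lte(s_ov, 0)
        }
      }
    }
    # scores are reported best-first
    expect_true(all(diff(hits$raw_score) <= 0))
  })
})

test_that("hsp_stats matches a direct column tally, gaps included", {
  st <- hsp_stats("ACD-EFG", "ACDWEYG")
  # 7 columns; identical: A,C,D,E,G = 5; positive adds F:Y (score 3)
  expect_equal(st$aligned_length, 7L)
  expect_equal(st$n_identical, 5L)
  expect_equal(st$n_positive, 6L)
  expect_equal(st$identity_pct, round(100 * 5 / 7))
  expect_equal(st$positive_pct, round(100 * 6 / 7))
  # X/X scores -1 in the matrix but is identical, so it counts as positive
  st2 <- hsp_stats("XX", "XA")
  expect_equal(st2$n_identical, 1L)
  expect_equal(st2$n_positive, 1L)
  expect_error(hsp_stats("AC", "ACD"), "length")
  # random alignments against an independent tally
  m <- blosum62()
  withr::with_seed(61, {
    for (i in 1:20) {
      n <- sample(10:50, 1)
      qc <- sample(c(STD_AA, "-"), n, TRUE)
      sc <- sample(c(STD_AA, "-"), n, TRUE)
      sc[qc == "-" & sc == "-"] <- "A"
      st3 <- hsp_stats(paste(qc, collapse = ""), paste(sc, collapse = ""))
      ident <- sum(qc == sc & qc != "-")
      pos <- sum(vapply(seq_len(n), function(k) {
        if (qc[k] == "-" || sc[k] == "-") return(FALSE)
        qc[k] == sc[k] || m[qc[k], sc[k]] > 0
      }, logical(1)))
      expect_equal(st3$n_identical, ident)
      expect_equal(st3$n_positive, pos)
      expect_equal(st3$identity_pct, trunc(100 * ident / n + 0.5))
    }
  })
})

test_that("E-values follow the Karlin-Altschul formula", {
  p <- scoring_params(db_residues = 1e6)
  s <- c(30, 40, 50, 60)
  e <- evalue(s, query_len = 500, p)
  expect_equal(e, p$K_gapped * 500 * 1e6 * exp(-p$lambda_gapped * s))
  # monotone decreasing in score, linear in search-space size
  expect_true(all(diff(e) < 0))
  expect_equal(evalue(40, 1000, p), 2 * evalue(40, 500, p))
  expect_equal(evalue(40, 500, p, db_residues = 2e6),
               2 * evalue(40, 500, p))
  expect_error(evalue(-1, 500, p), "raw_score")
})

test_that("min_raw_score is the smallest score passing the E cutoff", {
  p <- scoring_params(db_residues = 5e5)
  for (qlen in c(100, 764, 2768)) {
    s <- min_raw_score(qlen, p$db_residues, p)
    expect_lt(evalue(s, qlen, p), p$e_cutoff)
    if (s > 1) expect_gte(evalue(s - 1, qlen, p), p$e_cutoff)
  }
})

test_that("local_align gates on the E-value cutoff", {
  withr::with_seed(71, {
    q <- random_seq(80)
    s <- random_seq(80)
    all_hits <- local_align(q, s, scoring_params(e_cutoff = Inf,
                                                 db_residues = 1e7))
    tight <- local_align(q, s, scoring_params(e_cutoff = 1e-6,
                                              db_residues = 1e7))
    expect_true(all(tight$raw_score %in% all_hits$raw_score))
    expect_true(all(tight$evalue < 1e-6))
    expect_equal(nrow(tight), 0)
  })
})

test_that("read_score_matrix parses NCBI-format text", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "   A  R", "A  4 -1", "R -1  5"), path)
  m <- read_score_matrix(path)
  expect_identical(dimnames(m), list(c("A", "R"), c("A", "R")))
  expect_equal(m["A", "A"], 4)
  expect_equal(m["A", "R"], -1)
})
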