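test_that("a query equal to a contig translation yields one full hit", {
  lx <- make_locus(fixture_spec(seed = 41, n_exons = 1,
                                exon_len = c(150, 150), intron_len = c(40, 80),
                                flank_len = 200))
  h <- find_seed_hits(lx$protein, lx$contig)
  top <- h[1, ]
  expect_identical(top$q_start, 1L)
  expect_identical(top$q_end, nchar(lx$protein))
  expect_identical(top$g_start, lx$truth$exons$start[1])
  expect_identical(top$g_end, lx$truth$exons$end[1])
  expect_identical(top$strand, "+")
})

test_that("a reverse-strand twin scores the same as its forward original", {
  lx <- make_locus(fixture_spec(seed = 42, n_exons = 1,
                                exon_len = c(120, 120), intron_len = c(40, 80),
                                flank_len = 150))
  hf <- find_seed_hits(lx$protein, lx$contig)
  hr <- find_seed_hits(lx$protein, reverse_complement(lx$contig))
  expect_identical(hr$strand[1], "-")
  expect_identical(hr$score[1], hf$score[1])
  expect_identical(hr$g_start[1],
                   nchar(lx$contig) - lx$truth$exons$end[1])
})

test_that("unrelated random sequences produce no full-length hits", {
  set.seed(43)
  full <- 0L
  for (i in 1:100) {
    q <- paste0(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 60,
                       replace = TRUE), collapse = "")
    contig <- paste0(sample(c("A", "C", "G", "T"), 1200, replace = TRUE),
                     collapse = "")
    h <- tryCatch(find_seed_hits(q, contig), error = function(e) NULL)
    if (!is.null(h) && nrow(h) &&
        any(h$q_end - h$q_start + 1L >= 60L)) full <- full + 1L
  }
  expect_identical(full, 0L)
})

test_that("chain DP equals the exhaustive subset oracle on small instances", {
  params <- reconstruction_params()
  checked <- 0L
  for (s in 1:10) {
    lx <- make_locus(fixture_spec(seed = 50 + s, n_exons = sample(2:5, 1),
                                  exon_len = c(60, 150),
                                  intron_len = c(40, 400), flank_len = 150))
    h <- find_seed_hits(lx$protein, lx$contig, params)
    for (strand in unique(h$strand)) {
      hs <- h[h$strand == strand, , drop = FALSE]
      if (nrow(hs) < 1 || nrow(hs) > 12) next
      ch <- chain_exons(hs, params)
      expect_equal(ch$score, brute_force_chain_score(hs, params),
                   tolerance = 1e-9)
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 5L)
})

test_that("hits overlapping in the query are never co-selected untrimmed", {
  params <- reconstruction_params()
  for (s in 1:5) {
    lx <- make_locus(fixture_spec(seed = 60 + s, n_exons = 4,
                                  exon_len = c(60, 150),
                                  intron_len = c(40, 400), flank_len = 150))
    h <- find_seed_hits(lx$protein, lx$contig, params)
    ch <- chain_exons(h[h$strand == "+", ], params)
    hh <- ch$hits
    if (nrow(hh) > 1) {
      expect_true(all(diff(hh$q_start) > 0))
      expect_true(all(hh$q_start[-1] > hh$q_end[-nrow(hh)]))
      expect_true(all(diff(hh$w_start) > 0))
    }
  }
})
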