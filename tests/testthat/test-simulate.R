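test_that("fixtures are pure functions of their spec", {
  a <- make_locus(fixture_spec(seed = 1))
  b <- make_locus(fixture_spec(seed = 1))
  expect_identical(a$contig, b$contig)
  expect_identical(a$protein, b$protein)
  expect_identical(a$truth$exons, b$truth$exons)
  c <- make_locus(fixture_spec(seed = 2))
  expect_false(identical(a$contig, c$contig))
  # EST sets are deterministic too
  e1 <- make_ests(a$truth, a$contig, n_consistent = 3, noise = 0.02, seed = 7)
  e2 <- make_ests(a$truth, a$contig, n_consistent = 3, noise = 0.02, seed = 7)
  expect_identical(e1$ests, e2$ests)
})

test_that("generated truth satisfies the gene-model invariants", {
  for (s in 1:6) {
    lx <- make_locus(fixture_spec(seed = 200 + s,
                                  n_exons = sample(2:10, 1)))
    expect_identical(nrow(validate_gene(lx$truth, lx$contig)), 0L)
    expect_identical(unname(extract_seqs(lx$truth, lx$contig, "translation")),
                     lx$protein)
    expect_true(all(lx$truth$introns$canonical))
  }
})

test_that("infeasible specs are rejected", {
  expect_error(fixture_spec(n_exons = 0))
  expect_error(fixture_spec(intron_len = c(5, 10)))
  expect_error(make_ests(make_locus(fixture_spec(seed = 1, n_exons = 2))$truth,
                         make_locus(fixture_spec(seed = 1, n_exons = 2))$contig,
                         events = tibble::tibble(type = "exon_skipping",
                                                 anchor = 1L, shift = NA,
                                                 novel_len = NA)),
               "terminal")
})

test_that("planted EST truth tables match the requested events", {
  lx <- make_locus(fixture_spec(seed = 207, n_exons = 6,
                                exon_len = c(90, 200),
                                intron_len = c(200, 500)))
  ev <- tibble::tibble(type = "alt_5prime_splice_site", anchor = 3L,
                       shift = 12L, novel_len = NA)
  es <- make_ests(lx$truth, lx$contig, events = ev, n_consistent = 1,
                  n_per_event = 3, seed = 2)
  tr <- es$truth_events
  expect_identical(sum(tr$type == "alt_5prime_splice_site"), 3L)
  expect_identical(unique(tr$anchor_index[tr$type != "consistent"]), 3L)
  # the planted donor shift has a GT at the shifted position
  it <- lx$truth$introns[3, ]
  expect_identical(substr(es$contig, it$start + 12L + 1L, it$start + 12L + 2L),
                   "GT")
})

test_that("the identity dial of planted copies is faithful", {
  lx <- make_locus(fixture_spec(seed = 208, n_exons = 5,
                                exon_len = c(120, 200),
                                intron_len = c(400, 700)))
  pm <- plant_mxe(lx$truth, lx$contig, exon_index = 2, intron_index = 2,
                  identity = 0.9, seed = 3)
  sim <- score_similarity(substr(pm$contig, pm$mxe$start + 1L, pm$mxe$end),
                          genestructr:::gs_exon_seq(pm$truth, pm$contig, 2),
                          pm$truth$exons$phase[2])
  expect_lt(abs(sim - pm$mxe$realized_identity), 0.02)
  expect_lt(abs(pm$mxe$realized_identity - 0.9), 0.1)
  expect_identical(nrow(validate_gene(pm$truth, pm$contig)), 0L)
})
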