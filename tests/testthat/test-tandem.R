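tandem_locus <- function(seed = 41) {
  make_locus(fixture_spec(seed = seed, n_exons = 5, exon_len = c(90, 250),
                          intron_len = c(60, 300), flank_len = 4000))
}

test_that("an exact downstream copy yields a one_to_one duplicate", {
  lx <- tandem_locus()
  pd <- plant_duplicate(lx$truth, lx$contig, side = "down", distance = 500,
                        identity = 1.0, strand = "+", seed = 1)
  sc <- scan_duplicates(pd$truth, pd$contig, 4000, 4000)
  expect_identical(nrow(sc$duplicates), 1L)
  d <- sc$duplicates[1, ]
  expect_identical(d$dup_start, pd$duplicate$start)
  expect_identical(d$dup_end, pd$duplicate$end)
  expect_identical(d$dup_strand, "+")
  expect_identical(d$side, "downstream")
  hm <- sc$homologies
  expect_true(all(hm$relation == "one_to_one"))
  expect_identical(nrow(hm), nrow(lx$truth$exons))
  expect_true(all(hm$similarity == 1))
})

test_that("an inverted upstream copy is found on the minus strand", {
  lx <- tandem_locus(42)
  pd <- plant_duplicate(lx$truth, lx$contig, side = "up", distance = 700,
                        identity = 1.0, strand = "-", seed = 2)
  sc <- scan_duplicates(pd$truth, pd$contig, 4000, 4000)
  expect_identical(nrow(sc$duplicates), 1L)
  expect_identical(sc$duplicates$dup_strand[1], "-")
  expect_identical(sc$duplicates$side[1], "upstream")
  expect_identical(sc$duplicates$dup_start[1], pd$duplicate$start)
})

test_that("detection degrades gracefully with divergence", {
  lx <- tandem_locus(43)
  pd85 <- plant_duplicate(lx$truth, lx$contig, side = "down",
                          distance = 500, identity = 0.85, seed = 3)
  sc85 <- scan_duplicates(pd85$truth, pd85$contig, 4000, 4000)
  expect_identical(nrow(sc85$duplicates), 1L)
  expect_lt(abs(sc85$duplicates$identity[1] - 0.85), 0.06)
  pd50 <- plant_duplicate(lx$truth, lx$contig, side = "down",
                          distance = 500, identity = 0.50, seed = 3)
  sc50 <- scan_duplicates(pd50$truth, pd50$contig, 4000, 4000)
  expect_identical(nrow(sc50$duplicates), 0L)
})

test_that("a deleted intron flips the homology to fused, an inserted one to split", {
  lx <- tandem_locus(44)
  pf <- plant_duplicate(lx$truth, lx$contig, side = "down", distance = 400,
                        identity = 0.9, fuse_intron = 2, seed = 4)
  scf <- scan_duplicates(pf$truth, pf$contig, 4000, 4000)
  hf <- scf$homologies
  expect_identical(sum(hf$relation == "fused"), 1L)
  expect_identical(hf$query_exons[hf$relation == "fused"], "2,3")
  expect_identical(sum(hf$relation == "one_to_one"), nrow(lx$truth$exons) - 2L)

  ps <- plant_duplicate(lx$truth, lx$contig, side = "down", distance = 400,
                        identity = 0.9, split_exon = 1, seed = 5)
  scs <- scan_duplicates(ps$truth, ps$contig, 4000, 4000)
  hs <- scs$homologies
  expect_identical(sum(hs$relation == "split"), 1L)
  expect_identical(hs$query_exons[hs$relation == "split"], "1")
  expect_identical(length(strsplit(hs$dup_exons[hs$relation == "split"],
                                   ",")[[1]]), 2L)
})

test_that("every duplicate exon joins exactly one homology", {
  lx <- tandem_locus(45)
  pd <- plant_duplicate(lx$truth, lx$contig, side = "down", distance = 600,
                        identity = 0.9, fuse_intron = 3, seed = 6)
  sc <- scan_duplicates(pd$truth, pd$contig, 4000, 4000)
  hm <- sc$homologies
  dup_idx <- unlist(strsplit(hm$dup_exons, ","))
  expect_identical(anyDuplicated(dup_idx), 0L)
  expect_identical(length(dup_idx), sc$duplicates$n_exons[1])
  q_idx <- unlist(strsplit(hm$query_exons, ","))
  expect_identical(anyDuplicated(q_idx), 0L)
})
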