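rand_seq <- function(n, alpha = c("A", "C", "G", "T"))
  paste0(sample(alpha, n, replace = TRUE), collapse = "")

test_that("local alignment scores match an independent Smith-Waterman", {
  set.seed(17)
  for (i in 1:12) {
    a <- rand_seq(sample(40:220, 1))
    b <- rand_seq(sample(40:220, 1))
    # plant a shared segment so there is something to find
    seg <- rand_seq(30)
    a <- paste0(substr(a, 1, 20), seg, substr(a, 21, nchar(a)))
    b <- paste0(substr(b, 1, 35), seg, substr(b, 36, nchar(b)))
    mine <- align_pair(a, b, type = "dna", mode = "local",
                       gap_open = 12, gap_ext = 2)
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 5, mismatch = -4, baseOnly = TRUE),
      gapOpening = 12, gapExtension = 2)
    expect_identical(mine$score, as.integer(Biostrings::score(ref)))
  }
})

test_that("protein local alignment agrees with the BLOSUM62 reference", {
  set.seed(23)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:8) {
    a <- rand_seq(sample(30:120, 1), aas)
    b <- a
    v <- strsplit(b, "")[[1]]
    hit <- sample(length(v), ceiling(length(v) / 6))
    for (k in hit) v[k] <- sample(setdiff(aas, v[k]), 1)
    b <- paste0(v, collapse = "")
    mine <- align_pair(a, b, type = "protein", mode = "local",
                       gap_open = 11, gap_ext = 1)
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1)
    expect_identical(mine$score, as.integer(Biostrings::score(ref)))
  }
})

test_that("global alignment of equal-length near-identical sequences is sane", {
  a <- "ACGTACGTACGTACGTACGT"
  b <- "ACGTACGAACGTACGTACGT"
  al <- align_pair(a, b, type = "dna", mode = "global")
  expect_identical(nrow(al$blocks), 1L)
  expect_identical(al$blocks$n_mismatch, 1L)
  expect_equal(al$identity, 19 / 20)
  expect_identical(al$mismatches$a_pos, 7L)
})

test_that("alignment blocks partition the aligned region", {
  set.seed(31)
  for (i in 1:6) {
    a <- rand_seq(120)
    b <- paste0(substr(a, 1, 50), rand_seq(15), substr(a, 61, 120))
    al <- align_pair(a, b, type = "dna", mode = "local")
    bl <- al$blocks
    expect_true(all(bl$a_end > bl$a_start))
    if (nrow(bl) > 1)
      expect_true(all(diff(bl$a_start) > 0) && all(diff(bl$b_start) > 0))
    expect_identical(sum(bl$a_end - bl$a_start), sum(bl$b_end - bl$b_start))
  }
})
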