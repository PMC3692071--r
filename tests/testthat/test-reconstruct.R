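test_that("reconstruction is exact on clean synthetic loci", {
  set.seed(71)
  for (s in 1:8) {
    lx <- make_locus(fixture_spec(seed = 70 + s, n_exons = sample(3:9, 1),
                                  exon_len = c(60, 300),
                                  intron_len = c(30, 1200)))
    res <- reconstruct(lx$protein, c(contig_1 = lx$contig))
    expect_exact_reconstruction(res, lx$truth)
  }
})

test_that("a minus-strand gene is recovered as the mirror structure", {
  lx <- make_locus(fixture_spec(seed = 81, n_exons = 5, exon_len = c(60, 250),
                                intron_len = c(40, 600)))
  L <- nchar(lx$contig)
  rc <- reverse_complement(lx$contig)
  res <- reconstruct(lx$protein, c(contig_1 = rc))
  g <- res$gene
  expect_identical(g$strand, "-")
  expect_identical(g$exons$start, L - lx$truth$exons$end)
  expect_identical(g$exons$end, L - lx$truth$exons$start)
  expect_identical(unname(extract_seqs(g, rc, "cds")),
                   unname(extract_seqs(lx$truth, lx$contig, "cds")))
  expect_identical(nrow(g$discrepancies), 0L)
})

test_that("split codons across introns are reconstructed exactly", {
  found <- FALSE
  for (s in 1:6) {
    lx <- make_locus(fixture_spec(seed = 90 + s, n_exons = 5,
                                  exon_len = c(61, 299),
                                  intron_len = c(40, 400)))
    if (any(lx$truth$exons$phase != 0)) {
      found <- TRUE
      res <- reconstruct(lx$protein, c(contig_1 = lx$contig))
      expect_exact_reconstruction(res, lx$truth)
    }
  }
  expect_true(found)
})

test_that("planted discrepancies are typed and positioned correctly", {
  for (s in 1:4) {
    lx <- make_locus(fixture_spec(seed = 100 + s, n_exons = 5,
                                  exon_len = c(90, 300),
                                  intron_len = c(40, 600)))
    pl <- plant_discrepancies(lx, n_mismatch = 2, n_stop = 1, n_ins = 1,
                              n_del = 1, seed = s)
    res <- reconstruct(lx$protein, c(contig_1 = pl$contig),
                       reconstruction_params(min_identity = 0.8))
    g <- expect_exact_reconstruction(
      res, pl$truth, allow_kinds = c("mismatch", "inframe_stop",
                                     "sequence_shift"))
    for (k in seq_len(nrow(pl$events))) {
      ev <- pl$events[k, ]
      # the attachment point of a 1-2 nt indel is only defined up to the
      # local repeat run, so shifts may land a couple of residues away
      tol <- if (ev$kind == "sequence_shift") 2L else 0L
      d <- g$discrepancies[
        g$discrepancies$kind == ev$kind &
          g$discrepancies$protein_start <= ev$protein_pos + tol &
          g$discrepancies$protein_end >= ev$protein_pos - tol, ]
      expect_identical(nrow(d), 1L)
    }
    expect_identical(nrow(g$discrepancies), nrow(pl$events))
  }
})

test_that("micro-exons are recovered by exhaustive placement", {
  # N-terminal 2-residue exon planted far upstream of the first seedable
  # exon, plus a run of very short internal exons
  lx <- make_locus(fixture_spec(seed = 111, n_exons = 6,
                                exon_lens = c(6, 9, 12, 210, 180, 240),
                                intron_len = c(40, 200),
                                codon_aligned = TRUE))
  res <- reconstruct(lx$protein, c(contig_1 = lx$contig))
  expect_exact_reconstruction(res, lx$truth)
  # single short internal exon
  lx2 <- make_locus(fixture_spec(seed = 112, n_exons = 3,
                                 exon_lens = c(150, 9, 210),
                                 intron_len = c(60, 300),
                                 codon_aligned = TRUE))
  res2 <- reconstruct(lx2$protein, c(contig_1 = lx2$contig))
  expect_exact_reconstruction(res2, lx2$truth)
})

test_that("unplaceable residues stay annotated as unmatched", {
  lx <- make_locus(fixture_spec(seed = 115, n_exons = 2,
                                exon_lens = c(210, 240),
                                intron_len = c(200, 400),
                                codon_aligned = TRUE))
  # query with 8 extra invented N-terminal residues that are nowhere in the
  # contig
  q <- paste0("WWHHWWHH", lx$protein)
  res <- reconstruct(q, c(contig_1 = lx$contig),
                     reconstruction_params(min_identity = 0.8,
                                           min_coverage = 0.8))
  g <- res$gene
  expect_false(is.null(g))
  un <- g$discrepancies[g$discrepancies$kind == "unmatched", ]
  expect_identical(nrow(un), 1L)
  expect_identical(un$protein_start, 1L)
  expect_identical(un$protein_end, 8L)
  expect_identical(g$exons$start, lx$truth$exons$start)
})

test_that("cross-species queries keep exact boundaries down to ~0.85", {
  p <- reconstruction_params(min_identity = 0.8)
  for (s in 1:4) {
    lx <- make_locus(fixture_spec(seed = 120 + s, n_exons = 6,
                                  exon_len = c(60, 300),
                                  intron_len = c(30, 1200)))
    av <- junction_residues(lx$truth, 2)
    q85 <- mutate_protein(lx$protein, 0.85, seed = s, avoid = av)
    res <- reconstruct(q85, c(contig_1 = lx$contig), p)
    expect_exact_reconstruction(res, lx$truth, allow_kinds = "mismatch")
    # below the working envelope the tool fails with a diagnostic
    q55 <- mutate_protein(lx$protein, 0.55, seed = s, avoid = av)
    res2 <- reconstruct(q55, c(contig_1 = lx$contig), p)
    expect_null(res2$gene)
    expect_match(res2$diagnostics, "identity|coverage")
  }
})

test_that("relaxing the identity floor never loses reconstructed loci", {
  loci <- lapply(1:5, function(s)
    make_locus(fixture_spec(seed = 130 + s, n_exons = 4,
                            exon_len = c(60, 200), intron_len = c(40, 500))))
  recovered <- function(minid) {
    p <- reconstruction_params(min_identity = minid)
    vapply(loci, function(lx) {
      q <- mutate_protein(lx$protein, 0.9, seed = 1,
                          avoid = junction_residues(lx$truth, 2))
      !is.null(reconstruct(q, c(contig_1 = lx$contig), p)$gene)
    }, logical(1))
  }
  strict <- recovered(0.95)
  relaxed <- recovered(0.7)
  expect_true(all(relaxed[strict]))
  expect_gte(sum(relaxed), sum(strict))
})
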