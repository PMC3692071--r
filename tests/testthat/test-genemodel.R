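simple_gene <- function(seed = 1, n_exons = 3) {
  make_locus(fixture_spec(seed = seed, n_exons = n_exons,
                          exon_len = c(60, 150), intron_len = c(40, 200),
                          flank_len = 120))
}

test_that("a well-formed synthetic gene satisfies every invariant", {
  lx <- simple_gene()
  expect_identical(nrow(validate_gene(lx$truth, lx$contig)), 0L)
  g <- lx$truth
  expect_identical(nrow(g$introns), nrow(g$exons) - 1L)
  # offsets chain
  lens <- g$exons$end - g$exons$start
  expect_identical(g$exons$cds_offset,
                   as.integer(cumsum(c(0L, lens))[seq_len(nrow(g$exons))]))
})

test_that("validation reports shifted exons and tiling violations as data", {
  lx <- simple_gene(seed = 2)
  g <- lx$truth
  bad <- g
  bad$exons$start[2] <- bad$exons$start[2] + 1L   # 1-nt shift
  v <- validate_gene(bad, lx$contig)
  expect_gt(nrow(v), 0L)
  expect_true(any(v$invariant %in% c("tiling", "translation", "cds_offsets")))
  bad2 <- g
  bad2$exons$end[1] <- bad2$exons$start[2] + 10L  # overlap into exon 2
  v2 <- validate_gene(bad2, lx$contig)
  expect_true(any(v2$invariant == "tiling"))
})

test_that("protein positions map to codon intervals, split codons included", {
  # single-exon gene planted at position 100
  contig <- paste0(strrep("T", 100),
                   "ATGGAAGAAGAAGAAGAATAG", strrep("T", 60))
  g <- gene_structure("q", translate_cds("ATGGAAGAAGAAGAAGAA"), "c", "+",
                      tibble::tibble(start = 100L, end = 118L),
                      contig = contig)
  iv <- protein_to_genomic(g, 1)
  expect_identical(iv$start, 100L)
  expect_identical(iv$end, 103L)
  # codon split 2|1 across an intron
  lx <- simple_gene(seed = 3, n_exons = 4)
  g2 <- lx$truth
  split_p <- which(g2$exons$phase != 0)
  for (i in split_p) {
    p <- g2$exons$cds_offset[i] %/% 3L + 1L   # residue split at boundary i-1
    iv <- protein_to_genomic(g2, p)
    expect_identical(nrow(iv), 2L)
    expect_identical(sum(iv$end - iv$start), 3L)
  }
})

test_that("coordinate conversion round-trips on random loci", {
  for (s in 1:5) {
    lx <- simple_gene(seed = 10 + s, n_exons = 4)
    g <- lx$truth
    cds_len <- sum(g$exons$end - g$exons$start)
    set.seed(s)
    for (p in sample(nchar(g$query), 25)) {
      iv <- protein_to_genomic(g, p)
      for (k in seq_len(nrow(iv)))
        for (pos in seq.int(iv$start[k], iv$end[k] - 1L)) {
          cp <- genomic_to_cds(g, pos)
          expect_identical(cp %/% 3L + 1L, p)
        }
    }
    # brute-force per-base map built by a linear scan, independent of the
    # interval algebra
    walk <- unlist(lapply(seq_len(nrow(g$exons)), function(i)
      seq.int(g$exons$start[i], g$exons$end[i] - 1L)))
    for (c0 in sample(cds_len, 20) - 1L) {
      iv <- cds_to_genomic(g, c0, c0 + 1L)
      expect_identical(iv$start, walk[c0 + 1L])
    }
  }
})

test_that("strand symmetry: the mirrored gene yields identical CDS", {
  lx <- simple_gene(seed = 21, n_exons = 3)
  g <- lx$truth
  L <- nchar(lx$contig)
  rc <- reverse_complement(lx$contig)
  gm <- gene_structure(g$query_id, g$query, g$contig_id, "-",
                       tibble::tibble(start = L - g$exons$end,
                                      end = L - g$exons$start),
                       contig = rc)
  expect_identical(unname(extract_seqs(gm, rc, "cds")),
                   unname(extract_seqs(g, lx$contig, "cds")))
  expect_identical(unname(extract_seqs(gm, rc, "translation")), g$query)
  expect_identical(nrow(validate_gene(gm, rc)), 0L)
})

test_that("sequence extraction is consistent with the structure", {
  lx <- simple_gene(seed = 4, n_exons = 2)
  g <- lx$truth
  exs <- extract_seqs(g, lx$contig, "exons")
  cds <- extract_seqs(g, lx$contig, "cds")
  expect_identical(unname(cds), paste0(exs, collapse = ""))
  expect_identical(nchar(unname(extract_seqs(g, lx$contig, "translation"))),
                   nchar(cds[[1]]) %/% 3L)
  gen <- extract_seqs(g, lx$contig, "genomic")
  expect_identical(nchar(unname(gen)),
                   sum(g$exons$end - g$exons$start) +
                     sum(g$introns$end - g$introns$start))
  # 1-exon gene has no introns
  one <- gene_structure("q", "MK", "c", "+",
                        tibble::tibble(start = 0L, end = 6L),
                        contig = "ATGAAA")
  expect_length(extract_seqs(one, "ATGAAA", "introns"), 0L)
  expect_error(extract_seqs(g, lx$contig, "nonsense"))
})

test_that("tidy and glance summarise a gene structure", {
  lx <- simple_gene(seed = 6)
  td <- tidy(lx$truth)
  expect_s3_class(td, "tbl_df")
  expect_identical(sum(td$feature == "exon"), nrow(lx$truth$exons))
  gl <- glance(lx$truth)
  expect_identical(gl$n_exons, nrow(lx$truth$exons))
  expect_identical(gl$cds_length, sum(lx$truth$exons$end -
                                        lx$truth$exons$start))
})
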