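mxe_locus <- function(seed = 31) {
  make_locus(fixture_spec(seed = seed, n_exons = 5, exon_len = c(90, 200),
                          intron_len = c(400, 900)))
}

test_that("an exact intronic exon copy is found with similarity 1", {
  lx <- mxe_locus()
  pm <- plant_mxe(lx$truth, lx$contig, exon_index = 3, intron_index = 3,
                  identity = 1.0, seed = 1)
  cands <- enumerate_candidates(pm$truth, pm$contig, 3)
  expect_gte(nrow(cands), 1L)
  top <- cands[1, ]
  expect_identical(top$start, pm$mxe$start)
  expect_identical(top$end, pm$mxe$end)
  expect_equal(top$similarity, 1.0)
  expect_identical(top$donor %in% c("GT", "GC"), TRUE)
  expect_identical(top$acceptor, "AG")
})

test_that("length-constraint arithmetic rejects out-of-band candidates", {
  lx <- mxe_locus(32)
  # copy longer than the source by ~30% of its length: outside the default
  # 20% band, inside a 40% band
  src_len <- lx$truth$exons$end[3] - lx$truth$exons$start[3]
  delta_codons <- ceiling(0.3 * src_len / 3)
  pm <- plant_mxe(lx$truth, lx$contig, exon_index = 3, intron_index = 3,
                  identity = 1.0, codon_delta = delta_codons, seed = 2)
  strict <- enumerate_candidates(pm$truth, pm$contig, 3,
                                 mxe_params(max_length_difference = 0.20))
  wide <- enumerate_candidates(pm$truth, pm$contig, 3,
                               mxe_params(max_length_difference = 0.45,
                                          min_similarity = 0.5))
  expect_false(any(strict$start == pm$mxe$start & strict$end == pm$mxe$end))
  expect_true(any(wide$start == pm$mxe$start & wide$end == pm$mxe$end))
})

test_that("candidate enumeration equals a brute-force window scan", {
  lx <- make_locus(fixture_spec(seed = 33, n_exons = 3,
                                exon_len = c(90, 120),
                                intron_len = c(600, 900), flank_len = 100))
  pm <- plant_mxe(lx$truth, lx$contig, exon_index = 2, intron_index = 1,
                  identity = 0.95, seed = 3)
  g <- pm$truth; contig <- pm$contig
  params <- mxe_params(min_similarity = 0.3)
  cands <- enumerate_candidates(g, contig, 2, params)
  # oracle: scan every AG..GT/GC window in the adjacent introns directly
  oracle <- list()
  for (ii in 1:2) {
    it <- g$introns[ii, ]
    iseq <- substr(contig, it$start + 1L, it$end)
    L <- g$exons$end[2] - g$exons$start[2]
    for (a in seq_len(nchar(iseq) - 2L)) {
      if (substr(iseq, a, a + 1L) != "AG") next
      a0 <- a + 1L
      for (b0 in seq.int(a0 + 3L, nchar(iseq) - 2L)) {
        if (!substr(iseq, b0 + 1L, b0 + 2L) %in% c("GT", "GC")) next
        len <- b0 - a0
        if (abs(len - L) > 0.2 * L || len %% 3L != L %% 3L) next
        if (a0 < params$margin || nchar(iseq) - b0 < params$margin) next
        sim <- score_similarity(substr(iseq, a0 + 1L, b0),
                                genestructr:::gs_exon_seq(g, contig, 2),
                                g$exons$phase[2], g$codon_table)
        if (sim >= params$min_similarity)
          oracle[[length(oracle) + 1L]] <- c(it$start + a0, it$start + b0)
      }
    }
  }
  oracle_keys <- vapply(oracle, paste, "", collapse = "-")
  # every reported candidate is in the oracle set and the best oracle
  # window is reported (greedy non-overlap may drop shadowed windows)
  expect_true(all(paste(cands$start, cands$end, sep = "-") %in% oracle_keys))
  expect_true(paste(pm$mxe$start, pm$mxe$end, sep = "-") %in%
                paste(cands$start, cands$end, sep = "-"))
})

test_that("similarity is symmetric and tracks the planted identity dial", {
  lx <- mxe_locus(34)
  set.seed(4)
  for (i in 1:6) {
    e2 <- genestructr:::gs_exon_seq(lx$truth, lx$contig, 2)
    e3 <- genestructr:::gs_exon_seq(lx$truth, lx$contig, 3)
    expect_equal(as.numeric(score_similarity(e2, e3, 0)),
                 as.numeric(score_similarity(e3, e2, 0)))
  }
  for (dial in c(0.7, 0.8, 0.9, 1.0)) {
    pm <- plant_mxe(lx$truth, lx$contig, exon_index = 2, intron_index = 2,
                    identity = dial, seed = round(100 * dial))
    cands <- enumerate_candidates(pm$truth, pm$contig, 2,
                                  mxe_params(min_similarity = 0.4))
    hit <- cands[cands$start == pm$mxe$start & cands$end == pm$mxe$end, ]
    expect_identical(nrow(hit), 1L)
    expect_lt(abs(hit$similarity - pm$mxe$realized_identity), 0.02)
    expect_lt(abs(pm$mxe$realized_identity - dial), 0.12)
  }
})

test_that("untranslatable windows score zero and are flagged", {
  s <- score_similarity("TAATAATAATAATAA", "ATGGAAGAAGAAGAA", 0)
  expect_identical(as.numeric(s), 0)
  expect_true(isTRUE(attr(s, "flagged")))
})

test_that("thresholds are monotone and clusters obey the invariants", {
  lx <- mxe_locus(35)
  pm <- plant_mxe(lx$truth, lx$contig, exon_index = 2, intron_index = 1,
                  identity = 0.9, seed = 5)
  pm2 <- plant_mxe(pm$truth, pm$contig, exon_index = 3, intron_index = 3,
                   identity = 0.75, seed = 6)
  g <- pm2$truth; contig <- pm2$contig
  sims <- c(0.2, 0.4, 0.6, 0.8, 0.95)
  lds <- c(0.05, 0.1, 0.2, 0.3, 0.4)
  prev_by_sim <- NULL
  for (sim in sims) {
    cl <- build_clusters(g, contig, mxe_params(min_similarity = sim))
    keys <- paste(cl$start, cl$end)
    if (!is.null(prev_by_sim)) expect_true(all(keys %in% prev_by_sim))
    prev_by_sim <- keys
  }
  prev <- NULL
  for (ld in rev(lds)) {   # shrinking the band never adds candidates
    cl <- build_clusters(g, contig,
                         mxe_params(max_length_difference = ld,
                                    min_similarity = 0.3))
    keys <- paste(cl$start, cl$end)
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
  cl <- build_clusters(g, contig, mxe_params(min_similarity = 0.3))
  # frame preservation and no overlap with annotated exons
  for (k in seq_len(nrow(cl))) {
    src_len <- g$exons$end[cl$source_exon[k]] - g$exons$start[cl$source_exon[k]]
    expect_identical(cl$length[k] %% 3L, src_len %% 3L)
    ov <- pmin(g$exons$end, cl$end[k]) - pmax(g$exons$start, cl$start[k])
    expect_true(all(ov <= 0L))
  }
  # members of a cluster are mutually non-overlapping
  for (se in unique(cl$source_exon)) {
    mem <- cl[cl$source_exon == se, ]
    if (nrow(mem) > 1) {
      mem <- mem[order(mem$start), ]
      expect_true(all(mem$start[-1] >= mem$end[-nrow(mem)]))
    }
  }
})

test_that("a candidate of a candidate is only found in recursive mode", {
  lx <- mxe_locus(36)
  pm <- plant_mxe(lx$truth, lx$contig, exon_index = 3, intron_index = 2,
                  identity = 0.55, seed = 7)
  # second hop: a diverged copy of the first candidate, planted in another
  # intron; similar to the first candidate but not to the source exon
  cand_seq <- substr(pm$contig, pm$mxe$start + 1L, pm$mxe$end)
  set.seed(8)
  cand_seq <- genestructr:::mutate_coding_fragment(
    cand_seq, pm$truth$exons$phase[3], 0.55, 1,
    genestructr:::rev_codon_table(1))
  g1 <- pm$truth
  it <- g1$introns[3, ]
  pos <- it$start + (it$end - it$start) %/% 2L
  block <- paste0("AG", cand_seq, "GT")
  contig2 <- paste0(substr(pm$contig, 1, pos), block,
                    substr(pm$contig, pos + 1L, nchar(pm$contig)))
  g2 <- genestructr:::shift_gene_coords(g1, pos, nchar(block), contig2)
  hop2 <- c(pos + 2L, pos + 2L + nchar(cand_seq))
  params_flat <- mxe_params(min_similarity = 0.4)
  params_rec <- mxe_params(min_similarity = 0.4, recursive = TRUE)
  flat <- build_clusters(g2, contig2, params_flat)
  rec <- build_clusters(g2, contig2, params_rec)
  overlaps_hop2 <- function(tb) tb$start < hop2[2] & tb$end > hop2[1]
  expect_false(any(overlaps_hop2(flat)))
  expect_true(any(overlaps_hop2(rec)))
  expect_true(all(rec$generation[overlaps_hop2(rec)] >= 2L))
})
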