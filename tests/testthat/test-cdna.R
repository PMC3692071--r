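cdna_locus <- function(seed = 21) {
  make_locus(fixture_spec(seed = seed, n_exons = 7, exon_len = c(90, 300),
                          intron_len = c(200, 800)))
}

test_that("step 1 retains an exact CDS copy with full coverage", {
  lx <- cdna_locus()
  cds <- unname(extract_seqs(lx$truth, lx$contig, "cds"))
  hits <- map_step1(tibble::tibble(id = "c1", seq = cds), lx$truth, lx$contig)
  expect_length(hits, 1L)
  h <- hits[[1]]
  expect_identical(h$cdna_id, "c1")
  expect_identical(nrow(h$blocks), 1L)
  expect_identical(h$blocks$n_mismatch, 0L)
  expect_identical(h$blocks$a_end - h$blocks$a_start, nchar(cds))
  expect_identical(nrow(h$unmatched), 0L)
})

test_that("an intron-only cDNA is filtered in cds space, kept in genomic", {
  lx <- cdna_locus(22)
  it <- lx$truth$introns[1, ]
  inside <- substr(lx$contig, it$start + 40L, it$start + 240L)
  cdnas <- tibble::tibble(id = "intronic", seq = inside)
  expect_length(map_step1(cdnas, lx$truth, lx$contig, "cds"), 0L)
  expect_length(map_step1(cdnas, lx$truth, lx$contig, "genomic"), 1L)
})

test_that("translated mode rescues cross-species cDNA", {
  lx <- cdna_locus(23)
  # a cDNA from a related species: ~75% protein identity, every codon
  # re-drawn, so nucleotide-level identity is far below the dna floor but
  # the translation still aligns well
  prot <- mutate_protein(
    unname(extract_seqs(lx$truth, lx$contig, "translation")), 0.75, seed = 1)
  set.seed(1)
  rct <- genestructr:::rev_codon_table(1)
  far <- paste0(vapply(strsplit(prot, "")[[1]], function(a) {
    cs <- rct[[a]]
    cs[sample.int(length(cs), 1)]
  }, ""), collapse = "")
  cdnas <- tibble::tibble(id = "xspecies", seq = far)
  expect_length(map_step1(cdnas, lx$truth, lx$contig, "cds"), 0L)
  expect_length(map_step1(cdnas, lx$truth, lx$contig, "translated_cds"), 1L)
})

test_that("step-1 scoring equals a full Smith-Waterman oracle", {
  lx <- make_locus(fixture_spec(seed = 24, n_exons = 3, exon_len = c(60, 150),
                                intron_len = c(60, 200), flank_len = 100))
  cds <- unname(extract_seqs(lx$truth, lx$contig, "cds"))
  set.seed(2)
  for (i in 1:5) {
    frag <- substr(cds, 30 + i * 7, 30 + i * 7 + 180)
    v <- strsplit(frag, "")[[1]]
    for (k in sample(length(v), 4))
      v[k] <- sample(setdiff(c("A", "C", "G", "T"), v[k]), 1)
    frag <- paste0(v, collapse = "")
    h <- map_step1(tibble::tibble(id = "f", seq = frag), lx$truth, lx$contig)
    ref <- Biostrings::pairwiseAlignment(
      frag, cds, type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 5, mismatch = -4, baseOnly = TRUE),
      gapOpening = 12, gapExtension = 2)
    expect_identical(h[[1]]$score, as.integer(Biostrings::score(ref)))
  }
})

test_that("step 2 reproduces the exon structure for a spliced cDNA", {
  lx <- cdna_locus(25)
  es <- make_ests(lx$truth, lx$contig, n_consistent = 0, seed = 1)
  cds <- unname(extract_seqs(lx$truth, lx$contig, "cds"))
  cdnas <- tibble::tibble(id = "full", seq = cds)
  s1 <- map_step1(cdnas, lx$truth, lx$contig)
  s2 <- map_step2(s1, cdnas, lx$truth, lx$contig)
  expect_length(s2, 1L)
  sh <- s2[[1]]
  gf <- genestructr:::gene_space_features(lx$truth)
  expect_identical(nrow(sh$blocks), nrow(lx$truth$exons))
  expect_identical(sh$blocks$g_start, gf$exons$gs)
  expect_identical(sh$blocks$g_end, gf$exons$ge)
  expect_identical(sh$junctions$g_end_left, gf$introns$gs)
  expect_identical(sh$junctions$g_start_right, gf$introns$ge)
  expect_true(all(sh$junctions$canonical))
})

test_that("a retained intron maps as one block spanning its flanks", {
  lx <- cdna_locus(26)
  ex <- lx$truth$exons; it <- lx$truth$introns[2, ]
  read <- substr(lx$contig, ex$start[2] + 1L, ex$end[3])  # exon2+intron2+exon3
  cdnas <- tibble::tibble(id = "ret", seq = read)
  s1 <- map_step1(cdnas, lx$truth, lx$contig)
  s2 <- map_step2(s1, cdnas, lx$truth, lx$contig)
  sh <- s2[[1]]
  expect_identical(nrow(sh$blocks), 1L)
  ev <- classify_events(convert_coordinates(sh, lx$truth), lx$truth)
  expect_identical(ev$type, "intron_retention")
  expect_identical(ev$anchor_index, 2L)
})

test_that("coordinate conversion labels blocks and round-trips", {
  lx <- cdna_locus(27)
  cds <- unname(extract_seqs(lx$truth, lx$contig, "cds"))
  cdnas <- tibble::tibble(id = "full", seq = cds)
  sh <- map_step2(map_step1(cdnas, lx$truth, lx$contig), cdnas, lx$truth,
                  lx$contig)[[1]]
  sh <- convert_coordinates(sh, lx$truth)
  # block i is exactly exon i
  for (i in seq_len(nrow(sh$blocks))) {
    lab <- sh$labels[sh$labels$block == i, ]
    expect_identical(lab$feature, "exon")
    expect_identical(lab$index, i)
    pr <- sh$cds_projection[sh$cds_projection$block == i, ]
    expect_identical(pr$cds_start, lx$truth$exons$cds_offset[i])
    # lossless: gene-space coordinates are retained on the object
    expect_identical(pr$cds_end - pr$cds_start,
                     sh$blocks$g_end[i] - sh$blocks$g_start[i])
  }
})

test_that("all five planted event types classify with correct anchors", {
  lx <- cdna_locus(28)
  es <- make_ests(lx$truth, lx$contig, events = five_event_table(),
                  n_consistent = 3, n_per_event = 2, noise = 0, seed = 4)
  res <- map_cdnas(es$ests, lx$truth, es$contig)
  ok <- event_recovery(res, es$truth_events)
  expect_identical(sum(ok), nrow(es$truth_events))
  # consistent reads yield exactly one consistent event and nothing else
  cons <- es$truth_events$est_id[es$truth_events$type == "consistent"]
  for (id in cons) {
    ev <- res$events[res$events$cdna_id == id, ]
    expect_identical(ev$type, "consistent")
  }
})

test_that("intron-overlapping deviations are never silently dropped", {
  lx <- cdna_locus(29)
  # an exon extension that is too short to classify (< 3 nt) must surface
  # as an unclassifiable diagnostic, not disappear
  ex <- lx$truth$exons; it <- lx$truth$introns
  read <- paste0(substr(lx$contig, ex$start[2] + 1L, ex$end[2] + 2L),
                 substr(lx$contig, ex$start[3] + 1L, ex$end[3]))
  cdnas <- tibble::tibble(id = "tiny_ext", seq = read)
  s1 <- map_step1(cdnas, lx$truth, lx$contig)
  s2 <- map_cdnas(cdnas, lx$truth, lx$contig)
  ev <- s2$events
  expect_true(nrow(ev) >= 1L)
  # either refined away onto the annotated junction (consistent) or
  # reported with a diagnostic; never an invented alt-site call
  expect_false(any(ev$type %in% c("alt_5prime_splice_site",
                                  "alt_3prime_splice_site"), na.rm = TRUE))
})

test_that("substitution effects agree with a translate-both-codons oracle", {
  expect_identical(
    call_substitutions_effect_oracle("GAA", "GAG"), "synonymous")
  expect_identical(
    call_substitutions_effect_oracle("GAA", "GTA"), "nonsynonymous")
  lx <- cdna_locus(30)
  cds <- unname(extract_seqs(lx$truth, lx$contig, "cds"))
  set.seed(9)
  n_checked <- 0L
  for (rep in 1:4) {
    v <- strsplit(cds, "")[[1]]
    pos <- sample(length(v), 40)
    for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    read <- paste0(v, collapse = "")
    cdnas <- tibble::tibble(id = sprintf("mut%d", rep), seq = read)
    sh <- map_step2(map_step1(cdnas, lx$truth, lx$contig,
                              params = cdna_params(min_identity = 0.8)),
                    cdnas, lx$truth, lx$contig)[[1]]
    sh <- convert_coordinates(sh, lx$truth)
    subs <- call_substitutions(sh, lx$truth, lx$contig, read)
    full <- subs[!is.na(subs$effect), ]
    for (k in seq_len(nrow(full))) {
      expect_identical(full$effect[k],
                       call_substitutions_effect_oracle(full$ref_codon[k],
                                                        full$alt_codon[k]))
      n_checked <- n_checked + 1L
    }
    # every exonic mismatch in a full codon yields exactly one record
    expect_identical(nrow(subs), length(unique(subs$cds_pos)))
  }
  expect_gte(n_checked, 100L)
})

test_that("merged coverage equals the per-base union oracle", {
  lx <- cdna_locus(31)
  cds <- unname(extract_seqs(lx$truth, lx$contig, "cds"))
  # no hits -> zero coverage
  cov0 <- merge_coverage(list(), lx$truth, lx$contig)
  expect_identical(cov0$fraction, 0)
  # overlapping fragments
  frags <- tibble::tibble(
    id = c("a", "b", "c"),
    seq = c(substr(cds, 1, 400), substr(cds, 300, 800),
            substr(cds, 700, nchar(cds))))
  s2 <- map_step2(map_step1(frags, lx$truth, lx$contig), frags, lx$truth,
                  lx$contig)
  s2 <- lapply(s2, convert_coordinates, g = lx$truth)
  cov <- merge_coverage(s2, lx$truth, lx$contig)
  expect_equal(cov$fraction, brute_force_coverage(s2, nchar(cds)))
  expect_equal(cov$fraction, 1)
})

test_that("step-2 hits never contradict their step-1 CDS alignment", {
  lx <- cdna_locus(32)
  es <- make_ests(lx$truth, lx$contig, events = five_event_table(),
                  n_consistent = 3, n_per_event = 2, noise = 0.01,
                  adapter_prob = 0.3, seed = 6)
  res <- map_cdnas(es$ests, lx$truth, es$contig)
  cds <- unname(extract_seqs(lx$truth, es$contig, "cds"))
  for (sh in res$hits) {
    sq <- es$ests$seq[match(sh$cdna_id, es$ests$id)]
    if (sh$orientation == "-") sq <- reverse_complement(sq)
    pr <- sh$cds_projection
    for (i in seq_len(nrow(pr))) {
      if (pr$cds_end[i] - pr$cds_start[i] < 30) next
      a <- substr(sq, pr$c_start[i] + 1L, pr$c_end[i])
      b <- substr(cds, pr$cds_start[i] + 1L, pr$cds_end[i])
      mism <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
      expect_lte(mism / nchar(a), 0.1)
    }
  }
})
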