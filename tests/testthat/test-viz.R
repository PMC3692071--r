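viz_doc <- function(seed = 51) {
  lx <- make_locus(fixture_spec(seed = seed, n_exons = 5,
                                exon_len = c(90, 200),
                                intron_len = c(200, 600)))
  es <- make_ests(lx$truth, lx$contig, events = five_event_table()[1:2, ],
                  n_consistent = 2, n_per_event = 1, seed = 1)
  res <- map_cdnas(es$ests, lx$truth, es$contig)
  doc <- result_document(gene = lx$truth, splice_events = res$events)
  list(doc = doc, hits = res$hits, coverage = res$coverage, lx = lx)
}

count_pat <- function(svg, pat) {
  m <- gregexpr(pat, svg, fixed = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

test_that("rendering is a pure function of the document", {
  v <- viz_doc()
  s1 <- render_svg(v$doc, hits = v$hits, coverage = v$coverage)
  s2 <- render_svg(v$doc, hits = v$hits, coverage = v$coverage)
  expect_identical(s1, s2)
})

test_that("MXE opacity equals the similarity, clamped from below", {
  lx <- make_locus(fixture_spec(seed = 52, n_exons = 3,
                                exon_len = c(90, 150),
                                intron_len = c(300, 500)))
  mk <- function(sim) tibble::tibble(
    source_exon = 2L, region = "intron_1",
    start = lx$truth$introns$start[1] + 50L,
    end = lx$truth$introns$start[1] + 140L, length = 90L,
    similarity = sim, donor = "GT", acceptor = "AG", flagged = FALSE,
    generation = 1L, parent_similarity = sim)
  svg1 <- render_svg(result_document(gene = lx$truth, mxe_clusters = mk(1.0)))
  expect_match(svg1, "class=\"mxe\"[^/>]*fill-opacity=\"1.00\"")
  svg05 <- render_svg(result_document(gene = lx$truth, mxe_clusters = mk(0.5)))
  expect_match(svg05, "class=\"mxe\"[^/>]*fill-opacity=\"0.50\"")
  svg_lo <- render_svg(result_document(gene = lx$truth,
                                       mxe_clusters = mk(0.05)))
  expect_match(svg_lo, "class=\"mxe\"[^/>]*fill-opacity=\"0.15\"")
})

test_that("the element count matches the document contents", {
  v <- viz_doc(53)
  svg <- render_svg(v$doc, hits = v$hits, coverage = v$coverage)
  g <- v$doc$gene
  expect_identical(count_pat(svg, "class=\"exon\""), nrow(g$exons))
  expect_identical(count_pat(svg, "class=\"intron\""), nrow(g$introns))
  n_blocks <- sum(vapply(v$hits, function(h) nrow(h$blocks), 0L))
  expect_identical(count_pat(svg, "class=\"hit-block\""), n_blocks)
  n_unmatched <- sum(vapply(v$hits, function(h) nrow(h$unmatched), 0L))
  expect_identical(count_pat(svg, "class=\"hit-unmatched\""), n_unmatched)
  # every classified event surfaces as a tooltip title on a hit block
  for (ty in unique(v$doc$splice_events$type[!is.na(v$doc$splice_events$type) &
                                       v$doc$splice_events$type != "consistent"]))
    expect_match(svg, ty, fixed = TRUE)
})

test_that("degenerate documents are rejected", {
  expect_error(render_svg(result_document(gene = NULL)), "no gene")
})

test_that("autoplot returns a ggplot of the feature table", {
  lx <- make_locus(fixture_spec(seed = 54, n_exons = 3,
                                exon_len = c(60, 120),
                                intron_len = c(60, 150), flank_len = 80))
  p <- autoplot(lx$truth)
  expect_s3_class(p, "ggplot")
})
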