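# shared test helpers: independent oracles and fixture shortcuts

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_exact_reconstruction <- function(res, truth, allow_kinds = character(0)) {
  g <- res$gene
  expect_false(is.null(g))
  expect_identical(g$exons$start, truth$exons$start)
  expect_identical(g$exons$end, truth$exons$end)
  if (!length(allow_kinds)) {
    expect_identical(nrow(g$discrepancies), 0L)
  } else {
    expect_true(all(g$discrepancies$kind %in% allow_kinds))
  }
  invisible(g)
}

# independent brute-force chaining oracle: enumerates every subset of hits
# (in query order) and scores feasible colinear chains with the same gap
# model the chain DP declares, written out from first principles
brute_force_chain_score <- function(hits, params) {
  h <- hits[order(hits$q_start, hits$w_start), ]
  n <- nrow(h)
  best <- -Inf
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (!length(idx)) next
    score <- h$score[idx[1]]
    feasible <- TRUE
    if (length(idx) > 1L) for (k in 2:length(idx)) {
      i <- idx[k - 1L]; j <- idx[k]
      if (h$q_start[i] >= h$q_start[j] || h$q_end[i] >= h$q_end[j] ||
          h$w_start[i] >= h$w_start[j] || h$w_end[i] >= h$w_end[j]) {
        feasible <- FALSE; break
      }
      o <- max(0L, h$q_end[i] - h$q_start[j] + 1L)
      if (o > params$max_chain_protein_overlap) { feasible <- FALSE; break }
      qs <- h$q_start[j] + o; ws <- h$w_start[j] + 3L * o
      if (qs > h$q_end[j]) { feasible <- FALSE; break }
      m <- qs - h$q_end[i] - 1L
      if (m < 0L) { feasible <- FALSE; break }
      G <- ws - h$w_end[i]
      delta <- G - 3L * m
      if (delta >= params$min_intron_len && delta <= params$max_intron_len) {
        pen <- params$intron_open + params$intron_scale * log(delta)
      } else if (abs(delta) <= 2L && G >= -2L) {
        pen <- 2 + 6 * abs(delta) + 0.5 * m
      } else { feasible <- FALSE; break }
      score <- score + h$score[j] - pen - 5 * o
    }
    if (feasible && score > best) best <- score
  }
  best
}

# per-base coverage oracle
brute_force_coverage <- function(hits, cds_len) {
  cov <- rep(FALSE, cds_len)
  for (sh in hits) {
    pr <- sh$cds_projection
    if (is.null(pr)) next
    for (i in seq_len(nrow(pr)))
      for (p in seq.int(pr$cds_start[i] + 1L, pr$cds_end[i])) cov[p] <- TRUE
  }
  mean(cov)
}

# independent effect oracle: translate both codons with Biostrings
call_substitutions_effect_oracle <- function(ref, alt) {
  tr <- function(cod) as.character(
    Biostrings::translate(Biostrings::DNAString(cod), no.init.codon = TRUE))
  if (tr(ref) == tr(alt)) "synonymous" else "nonsynonymous"
}

# standard five-event fixture for cDNA tests
five_event_table <- function() {
  tibble::tibble(
    type = c("alt_5prime_splice_site", "alt_3prime_splice_site",
             "exon_skipping", "intron_retention", "novel_exon"),
    anchor = c(2L, 4L, 3L, 5L, 1L),
    shift = c(12L, 15L, NA, NA, NA),
    novel_len = c(NA, NA, NA, NA, 63L))
}

event_recovery <- function(res, truth_events) {
  vapply(seq_len(nrow(truth_events)), function(i) {
    tr <- truth_events[i, ]
    e <- res$events[res$events$cdna_id == tr$est_id &
                      !is.na(res$events$type) &
                      res$events$type == tr$type, , drop = FALSE]
    nrow(e) > 0 &&
      (is.na(tr$anchor_index) || any(e$anchor_index == tr$anchor_index))
  }, logical(1))
}
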