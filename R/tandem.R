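# Tandemly arrayed gene duplicates: the query protein is reconstructed in
# user-defined up/downstream windows on both strands with relaxed
# acceptance floors; exon homologies between query and duplicate are read
# off the shared CDS coordinate system, which directly exposes fused exons
# (a query intron absent from the duplicate) and split exons (an extra
# intron inside the duplicate).

#' Scan the flanks of a gene for tandem duplicates
#'
#' @param g a `gene_structure`.
#' @param contig contig sequence.
#' @param upstream_nt,downstream_nt window sizes on each side of the gene
#'   span.
#' @param params a [tandem_params()] list.
#' @param recon_params reconstruction parameters for the duplicate search;
#'   identity/coverage floors are taken from `params`.
#' @return list with `duplicates` (one row per duplicate: `duplicate_id`,
#'   `dup_start`, `dup_end`, `dup_strand`, `identity`, `coverage`,
#'   `n_exons`, `mean_similarity`, `side`) and `homologies` (one row per
#'   exon homology: `duplicate_id`, `relation`, `query_exons`,
#'   `dup_exons`, `similarity`).
#' @export
scan_duplicates <- function(g, contig, upstream_nt = 20000L,
                            downstream_nt = 20000L,
                            params = tandem_params(),
                            recon_params = reconstruction_params()) {
  sp <- gene_span(g)
  recon_params$min_identity <- params$min_identity
  recon_params$min_coverage <- params$min_coverage
  recon_params$codon_table <- g$codon_table
  windows <- list(
    list(side = "upstream", start = max(0L, sp[1] - upstream_nt),
         end = sp[1]),
    list(side = "downstream", start = sp[2],
         end = min(nchar(contig), sp[2] + downstream_nt)))
  dups <- list(); homs <- list(); did <- 0L
  for (wd in windows) {
    if (wd$end - wd$start < 100L) next
    wseq <- subseq0(contig, wd$start, wd$end)
    res <- reconstruct(setNames(g$query, g$query_id),
                       setNames(wseq, "window"), recon_params)
    dg <- res$gene
    if (is.null(dg)) next
    did <- did + 1L
    hm <- map_exon_homology(dg, g, wseq, contig, params)
    dsp <- gene_span(dg)
    dups[[length(dups) + 1L]] <- tibble(
      duplicate_id = did,
      dup_start = as.integer(wd$start + dsp[1]),
      dup_end = as.integer(wd$start + dsp[2]),
      dup_strand = dg$strand,
      identity = res$stats$identity, coverage = res$stats$coverage,
      n_exons = nrow(dg$exons),
      mean_similarity = if (nrow(hm)) mean(hm$similarity) else NA_real_,
      side = wd$side)
    if (nrow(hm)) {
      hm$duplicate_id <- did
      homs[[length(homs) + 1L]] <- hm
    }
  }
  list(
    duplicates = if (length(dups)) arrange(bind_rows(dups), dup_start)
                 else tibble(duplicate_id = integer(), dup_start = integer(),
                             dup_end = integer(), dup_strand = character(),
                             identity = numeric(), coverage = numeric(),
                             n_exons = integer(), mean_similarity = numeric(),
                             side = character()),
    homologies = if (length(homs)) bind_rows(homs)
                 else tibble(duplicate_id = integer(), relation = character(),
                             query_exons = character(), dup_exons = character(),
                             similarity = numeric()))
}

#' Map exon homologies between a duplicate and the query gene
#'
#' Both gene structures describe the same protein, so their exons share one
#' CDS coordinate system. A duplicate exon whose CDS span covers two or
#' more query exons (their shared intron is absent) is a `fused` homology;
#' two or more duplicate exons inside one query exon (an extra intron) are
#' `split`; otherwise `one_to_one`. Overlaps up to `boundary_tolerance` nt
#' are ignored as alignment jitter. Per-homology similarity is the
#' identity of the aligned translations over the shared CDS range.
#'
#' @param dup a `gene_structure` of the duplicate (on its own window).
#' @param g the query `gene_structure`.
#' @param dup_contig,query_contig the sequences each structure lives on.
#' @param params a [tandem_params()] list.
#' @return tibble: `relation`, `query_exons`, `dup_exons` (comma-separated
#'   index lists), `similarity`.
#' @export
map_exon_homology <- function(dup, g, dup_contig, query_contig,
                              params = tandem_params()) {
  tol <- params$boundary_tolerance
  qiv <- lapply(seq_len(nrow(g$exons)), function(i)
    c(g$exons$cds_offset[i], g$exons$cds_offset[i] + gs_exon_cds_len(g, i)))
  div <- lapply(seq_len(nrow(dup$exons)), function(i)
    c(dup$exons$cds_offset[i],
      dup$exons$cds_offset[i] + gs_exon_cds_len(dup, i)))
  nq <- length(qiv); nd <- length(div)
  # bipartite overlap graph (overlaps > tol)
  adj <- matrix(FALSE, nq, nd)
  for (i in seq_len(nq)) for (j in seq_len(nd))
    adj[i, j] <- min(qiv[[i]][2], div[[j]][2]) -
      max(qiv[[i]][1], div[[j]][1]) > tol
  seen_q <- rep(FALSE, nq); seen_d <- rep(FALSE, nd)
  qcds <- unname(gs_cds(g, query_contig))
  dcds <- unname(gs_cds(dup, dup_contig))
  gc <- codon_table(g$codon_table)
  rows <- list()
  for (i in seq_len(nq)) {
    if (seen_q[i] || !any(adj[i, ])) next
    qs <- i; ds <- integer(0)
    repeat {
      ds2 <- sort(unique(c(ds, which(apply(adj[qs, , drop = FALSE], 2, any)))))
      qs2 <- sort(unique(c(qs, which(apply(adj[, ds2, drop = FALSE], 1, any)))))
      if (identical(ds2, ds) && identical(qs2, qs)) break
      ds <- ds2; qs <- qs2
    }
    seen_q[qs] <- TRUE; seen_d[ds] <- TRUE
    relation <- if (length(qs) == 1L && length(ds) == 1L) "one_to_one"
                else if (length(qs) >= 2L && length(ds) == 1L) "fused"
                else if (length(qs) == 1L && length(ds) >= 2L) "split"
                else "complex"
    lo <- max(min(vapply(qiv[qs], `[`, 0, 1)),
              min(vapply(div[ds], `[`, 0, 1)))
    hi <- min(max(vapply(qiv[qs], `[`, 0, 2)),
              max(vapply(div[ds], `[`, 0, 2)))
    lo3 <- (lo %/% 3L) * 3L + 3L * (lo %% 3L > 0L)
    hi3 <- (hi %/% 3L) * 3L
    sim <- if (hi3 - lo3 >= 9L) {
      aq <- fast_translate(substr(qcds, lo3 + 1L, hi3), gc)
      ad <- fast_translate(substr(dcds, lo3 + 1L, hi3), gc)
      al <- align_pair(aq, ad, type = "protein", mode = "global")
      n_id <- sum((al$blocks$a_end - al$blocks$a_start) - al$blocks$n_mismatch)
      n_id / max(al$n_columns, 1L)
    } else NA_real_
    rows[[length(rows) + 1L]] <- tibble(
      relation = relation,
      query_exons = paste(qs, collapse = ","),
      dup_exons = paste(ds, collapse = ","),
      similarity = sim)
  }
  if (length(rows)) bind_rows(rows)
  else tibble(relation = character(), query_exons = character(),
              dup_exons = character(), similarity = numeric())
}
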