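# Mutually exclusive exon (MXE) candidate prediction: enumerate
# acceptor..donor-flanked intronic windows that preserve the reading-frame
# contribution of a source exon, score their translated similarity, and
# group accepted candidates into per-exon clusters; an optional recursive
# mode re-runs the search with accepted candidates as new sources.

# translation of a coding fragment in the frame implied by `phase`
# (= cds_offset %% 3 of the exon it stands in for)
phase_translation <- function(s, phase, gc) {
  head_nt <- (3L - phase) %% 3L
  body_len <- ((nchar(s) - head_nt) %/% 3L) * 3L
  if (body_len < 3L) return(NULL)
  fast_translate(substr(s, head_nt + 1L, head_nt + body_len), gc)
}

#' Similarity of a candidate window to a source exon
#'
#' Fraction of identical aligned positions after global alignment of the
#' two translated sequences (both read in the source exon's frame);
#' symmetric, in \[0, 1\]. A window whose required frame contains an
#' internal stop scores 0 and is flagged.
#'
#' @param cand_seq candidate nucleotide sequence (gene orientation).
#' @param exon_seq source exon nucleotide sequence (gene orientation).
#' @param phase source exon phase (`cds_offset %% 3`).
#' @param codon_table NCBI genetic-code table id.
#' @param protein_level score on translations (default) or on nucleotides.
#' @return numeric similarity, with attribute `flagged = TRUE` when the
#'   candidate was untranslatable.
#' @export
score_similarity <- function(cand_seq, exon_seq, phase = 0L,
                             codon_table = 1L, protein_level = TRUE) {
  if (protein_level) {
    gc <- codon_table(codon_table)
    a <- phase_translation(cand_seq, phase, gc)
    b <- phase_translation(exon_seq, phase, gc)
    if (is.null(a) || is.null(b))
      return(structure(0, flagged = TRUE))
    if (grepl("*", substr(a, 1, nchar(a) - 1L), fixed = TRUE))
      return(structure(0, flagged = TRUE))
    al <- align_pair(a, b, type = "protein", mode = "global")
  } else {
    al <- align_pair(cand_seq, exon_seq, type = "dna", mode = "global")
  }
  n_id <- sum((al$blocks$a_end - al$blocks$a_start) - al$blocks$n_mismatch)
  n_id / max(al$n_columns, 1L)
}

# search regions for one source exon, as gene-oriented sequences with a
# converter back to forward coordinates
mxe_search_regions <- function(g, contig, exon_index, params) {
  regions <- list()
  add_region <- function(name, fs, fe) {
    if (fe - fs < 2L * params$margin + 3L) return()
    s <- subseq0(contig, fs, fe)
    if (g$strand == "-") s <- reverse_complement(s)
    regions[[length(regions) + 1L]] <<- list(name = name, seq = s,
                                             f_start = fs, f_end = fe)
  }
  n_int <- nrow(g$introns)
  idx <- if (params$search_all_introns) seq_len(n_int)
         else intersect(c(exon_index - 1L, exon_index), seq_len(n_int))
  for (i in idx) add_region(paste0("intron_", i),
                            g$introns$start[i], g$introns$end[i])
  if (params$flank_search > 0L) {
    sp <- gene_span(g)
    add_region("flank_upstream", max(0L, sp[1] - params$flank_search), sp[1])
    add_region("flank_downstream", sp[2],
               min(nchar(contig), sp[2] + params$flank_search))
  }
  regions
}

# forward-coordinate interval of [a, b) inside a region (gene orientation)
region_to_fwd <- function(g, region, a, b) {
  if (g$strand == "+") c(region$f_start + a, region$f_start + b)
  else c(region$f_end - b, region$f_end - a)
}

#' Enumerate MXE candidates for one exon
#'
#' Scans the search space (the introns adjacent to the exon by default,
#' every intron with `search_all_introns`, plus up/downstream windows with
#' `flank_search`) for AG..GT/GC-flanked windows whose length is within
#' `max_length_difference` of the source exon and congruent to it modulo 3,
#' scores each by [score_similarity()], and returns those at or above
#' `min_similarity`, sorted by similarity.
#'
#' @param g a `gene_structure`.
#' @param contig contig sequence.
#' @param exon_index source exon.
#' @param params an [mxe_params()] list.
#' @param masked optional tibble of forward intervals (`start`, `end`)
#'   excluded from the search (already-accepted candidates).
#' @param source_seq,source_phase override the source sequence (used by the
#'   recursive search); defaults to the exon itself.
#' @return tibble: `source_exon`, `region`, `start`, `end` (forward),
#'   `length`, `similarity`, `donor`, `acceptor`, `flagged`.
#' @export
enumerate_candidates <- function(g, contig, exon_index,
                                 params = mxe_params(), masked = NULL,
                                 source_seq = NULL, source_phase = NULL) {
  ex <- g$exons[exon_index, ]
  src <- source_seq %||% gs_exon_seq(g, contig, exon_index)
  phase <- source_phase %||% ex$phase
  L <- nchar(src)
  lmin <- ceiling(L * (1 - params$max_length_difference))
  lmax <- floor(L * (1 + params$max_length_difference))
  regions <- mxe_search_regions(g, contig, exon_index, params)
  donors <- vapply(params$splice_pairs %||% c("GT-AG", "GC-AG"),
                   function(p) substr(p, 1, 2), "")
  if (!length(donors)) donors <- c("GT", "GC")
  out <- list()
  for (rg in regions) {
    rs <- rg$seq; rl <- nchar(rs)
    ag <- gregexpr("AG", rs, fixed = TRUE)[[1L]]
    gt <- sort(c(gregexpr("GT", rs, fixed = TRUE)[[1L]],
                 gregexpr("GC", rs, fixed = TRUE)[[1L]]))
    ag <- ag[ag > 0L]; gt <- gt[gt > 0L]
    for (a1 in ag) {
      a0 <- a1 + 1L          # 0-based candidate start; AG occupies [a0-2, a0)
      if (a0 < params$margin) next
      for (b1 in gt) {
        b0 <- b1 - 1L                      # 0-based donor position
        len <- b0 - a0
        if (len < lmin) next
        if (len > lmax) break
        if (len %% 3L != L %% 3L) next
        if (rl - b0 < params$margin) next
        cand <- substr(rs, a0 + 1L, b0)
        sim <- score_similarity(cand, src, phase, g$codon_table,
                                params$protein_level)
        if (sim < params$min_similarity) next
        f <- region_to_fwd(g, rg, a0, b0)
        if (!is.null(masked) && nrow(masked) &&
            any(pmin(masked$end, f[2]) - pmax(masked$start, f[1]) > 0L))
          next
        out[[length(out) + 1L]] <- tibble(
          source_exon = exon_index, region = rg$name,
          start = as.integer(f[1]), end = as.integer(f[2]),
          length = len, similarity = as.numeric(sim),
          donor = substr(rs, b0 + 1L, b0 + 2L),
          acceptor = substr(rs, a0 - 1L, a0),
          flagged = isTRUE(attr(sim, "flagged")))
      }
    }
  }
  if (!length(out))
    return(tibble(source_exon = integer(), region = character(),
                  start = integer(), end = integer(), length = integer(),
                  similarity = numeric(), donor = character(),
                  acceptor = character(), flagged = logical()))
  res <- bind_rows(out)
  res <- res[!duplicated(res[c("start", "end")]), ]
  res <- arrange(res, desc(similarity), start)
  # cluster members are mutually non-overlapping: greedy by similarity
  keep <- logical(nrow(res))
  for (k in seq_len(nrow(res))) {
    ov <- keep & pmin(res$end, res$end[k]) - pmax(res$start, res$start[k]) > 0L
    keep[k] <- !any(ov)
  }
  res[keep, ]
}

#' Predict MXE clusters for a reconstructed gene
#'
#' One cluster per source exon with at least one candidate. Terminal exons
#' are excluded by default (internal-exon geometry: acceptor upstream,
#' donor downstream). In recursive mode accepted candidates are re-used as
#' sources until no new candidate appears; accepted intervals are masked,
#' so the recursion terminates.
#'
#' @param g a `gene_structure`.
#' @param contig contig sequence.
#' @param params an [mxe_params()] list.
#' @param include_terminal also search for the first and last exon.
#' @return tibble of cluster members (`source_exon`, `generation`,
#'   `parent_similarity`, plus the [enumerate_candidates()] columns),
#'   ordered by source exon and similarity.
#' @export
build_clusters <- function(g, contig, params = mxe_params(),
                           include_terminal = FALSE) {
  n <- nrow(g$exons)
  src_idx <- if (include_terminal) seq_len(n)
             else setdiff(seq_len(n), c(1L, n))
  all <- list()
  masked <- tibble(start = g$exons$start, end = g$exons$end)
  for (i in src_idx) {
    cands <- enumerate_candidates(g, contig, i, params, masked = masked)
    if (!nrow(cands)) next
    cands$generation <- 1L
    cands$parent_similarity <- cands$similarity
    accepted <- cands
    masked <- bind_rows(masked, select(cands, start, end))
    if (params$recursive) {
      frontier <- cands
      gen <- 1L
      while (nrow(frontier) && gen < 10L) {
        gen <- gen + 1L
        nxt <- list()
        for (k in seq_len(nrow(frontier))) {
          fs <- frontier$start[k]; fe <- frontier$end[k]
          cseq <- subseq0(contig, fs, fe)
          if (g$strand == "-") cseq <- reverse_complement(cseq)
          more <- enumerate_candidates(g, contig, i, params, masked = masked,
                                       source_seq = cseq,
                                       source_phase = g$exons$phase[i])
          if (!nrow(more)) next
          more$parent_similarity <- more$similarity
          # similarity reported against the cluster's source exon
          more$similarity <- vapply(seq_len(nrow(more)), function(q) {
            s2 <- subseq0(contig, more$start[q], more$end[q])
            if (g$strand == "-") s2 <- reverse_complement(s2)
            as.numeric(score_similarity(s2, gs_exon_seq(g, contig, i),
                                        g$exons$phase[i], g$codon_table,
                                        params$protein_level))
          }, numeric(1))
          more$generation <- gen
          masked <- bind_rows(masked, select(more, start, end))
          nxt[[length(nxt) + 1L]] <- more
        }
        frontier <- if (length(nxt)) bind_rows(nxt) else frontier[0, ]
        if (nrow(frontier)) accepted <- bind_rows(accepted, frontier)
      }
    }
    all[[length(all) + 1L]] <- accepted
  }
  if (!length(all))
    return(tibble(source_exon = integer(), region = character(),
                  start = integer(), end = integer(), length = integer(),
                  similarity = numeric(), donor = character(),
                  acceptor = character(), flagged = logical(),
                  generation = integer(), parent_similarity = numeric()))
  arrange(bind_rows(all), source_exon, desc(similarity))
}
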