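# Protein-to-genome reconstruction: seeding and chaining (seed.R) are
# followed here by exhaustive splice-boundary refinement, micro-exon
# placement and discrepancy annotation. All refinement runs in "working"
# coordinates (the contig as-is for "+", its reverse complement for "-"),
# so gene order is always ascending; conversion back to forward contig
# coordinates happens when the gene_structure is materialised.

fwd_interval <- function(strand, L, s, e) {
  if (strand == "+") c(s, e) else c(L - e, L - s)
}

splice_pair_class <- function(donor, acceptor, pairs) {
  p <- paste0(donor, "-", acceptor)
  m <- match(p, pairs)
  if (is.na(m)) 0L else m
}

# positions p (working, ascending) where translate(w[p, p+3*len)) == pep
find_peptide_positions <- function(w, region_start, region_end, pep, gc) {
  lp <- nchar(pep)
  out <- integer(0)
  for (r in 0:2) {
    s0 <- region_start + r
    nc <- (region_end - s0) %/% 3L
    if (nc < lp) next
    fa <- fast_translate(substr(w, s0 + 1L, s0 + 3L * nc), gc)
    mm <- gregexpr(pep, fa, fixed = TRUE)[[1L]]
    if (mm[1L] == -1L) next
    out <- c(out, s0 + 3L * (as.integer(mm) - 1L))
  }
  sort(out)
}

# Recursive codon-aligned placement of residues q_lo..q_hi inside
# [region_start, region_end) of the working sequence. Pieces are separated
# by introns >= min_intron_len with an allowed donor and an AG acceptor.
# left_open / right_open relax the flanking-intron requirement at a gene
# terminus. Returns a list of pieces (q_from, q_to, w_from, w_to) or NULL.
place_pieces <- function(query, w, q_lo, q_hi, region_start, region_end,
                         left_open, right_open, params, gc, depth = 0L) {
  m <- q_hi - q_lo + 1L
  if (m <= 0L || depth > 12L) return(NULL)
  donors <- vapply(params$splice_pairs, function(p) substr(p, 1, 2), "")
  if (!left_open) {
    d <- substr(w, region_start + 1L, region_start + 2L)
    if (!d %in% donors) return(NULL)
  }
  for (l in seq.int(m, 1L)) {
    if (l < params$min_exon_len_aa) break
    pep <- substr(query, q_lo, q_lo + l - 1L)
    if (grepl("[X*]", pep)) next
    ps <- find_peptide_positions(w, region_start, region_end, pep, gc)
    for (p in ps) {
      if (!left_open) {
        if (p - region_start < params$min_intron_len) next
        if (substr(w, p - 1L, p) != "AG") next
      }
      pend <- p + 3L * l
      if (l == m) {
        if (right_open) {
          return(list(list(q_from = q_lo, q_to = q_hi, w_from = p, w_to = pend)))
        }
        if (region_end - pend < params$min_intron_len) next
        if (!substr(w, pend + 1L, pend + 2L) %in% donors) next
        if (substr(w, region_end - 1L, region_end) != "AG") next
        return(list(list(q_from = q_lo, q_to = q_hi, w_from = p, w_to = pend)))
      }
      rest <- place_pieces(query, w, q_lo + l, q_hi, pend, region_end,
                           left_open = FALSE, right_open = right_open,
                           params = params, gc = gc, depth = depth + 1L)
      if (!is.null(rest))
        return(c(list(list(q_from = q_lo, q_to = q_lo + l - 1L,
                           w_from = p, w_to = pend)), rest))
    }
  }
  NULL
}

# Exhaustive boundary scan for one junction. Returns the best placement:
# list(x, nmatch, total, pairclass). qe/we: last residue and codon end of
# the left exon; qs/ws: first residue and codon start of the right exon;
# m residues lie between. x = nt appended to the left exon end (may be
# negative); 3m - x nt are prepended to the right exon.
refine_boundary <- function(query, w, qe, we, qs, ws, m,
                            left_limits, right_limits, params, gc) {
  Wd <- params$boundary_window
  marg <- Wd %/% 3L + 2L
  r1 <- max(left_limits$q_min, qe - marg)
  r2 <- min(right_limits$q_max, qs + marg)
  c1 <- we - 3L * (qe - r1 + 1L)
  c2 <- ws + 3L * (r2 - qs + 1L)
  c1 <- max(c1, left_limits$w_min)
  r1 <- qe - (we - c1) %/% 3L + 1L
  c1 <- we - 3L * (qe - r1 + 1L)
  c2 <- min(c2, right_limits$w_max)
  r2 <- qs + (c2 - ws) %/% 3L - 1L
  c2 <- ws + 3L * (r2 - qs + 1L)
  if (r2 < r1) return(NULL)
  target <- chars(substr(query, r1, r2))
  gap_idx <- if (m > 0L) seq.int(qe + 1L - r1 + 1L, qs - 1L - r1 + 1L)
             else integer(0)
  x_lo <- max(-Wd, c1 - we + 3L)
  x_hi <- min(3L * m + Wd, c2 - ws + 3L * m - 3L)
  if (x_hi < x_lo) return(NULL)
  best <- NULL
  for (x in seq.int(x_lo, x_hi)) {
    is_ <- we + x; ie_ <- ws - (3L * m - x)
    if (is_ < c1 || ie_ > c2 || is_ < 0L || ie_ > nchar(w) || ie_ <= is_) next
    chunk <- paste0(substr(w, c1 + 1L, is_), substr(w, ie_ + 1L, c2))
    aa <- fast_translate_v(chunk, gc)
    nm <- sum(aa == target)
    pc <- splice_pair_class(substr(w, is_ + 1L, is_ + 2L),
                            substr(w, ie_ - 1L, ie_), params$splice_pairs)
    cand <- list(x = x, nmatch = nm, total = length(target), pairclass = pc,
                 r1 = r1, r2 = r2, match_vec = aa == target,
                 nmatch_gap = if (length(gap_idx))
                   sum(aa[gap_idx] == target[gap_idx]) else 0L)
    if (is.null(best)) { best <- cand; next }
    better <- (nm > best$nmatch) ||
      (nm == best$nmatch && (pc > 0L) > (best$pairclass > 0L)) ||
      (nm == best$nmatch && pc > 0L && best$pairclass > 0L && pc < best$pairclass)
    if (better) best <- cand
  }
  best
}

# ---- draft construction -----------------------------------------------------

new_draft <- function(chain, query, w, contig_id, strand, L, params) {
  h <- chain$hits; lk <- chain$links
  segs <- list(); juncs <- list()
  cur <- list(q_from = h$q_start[1], q_to = h$q_end[1],
              w_from = h$w_start[1], w_to = h$w_end[1], pends = list())
  if (nrow(h) > 1L) for (k in seq_len(nrow(h) - 1L)) {
    if (lk$type[k] == "intron") {
      segs[[length(segs) + 1L]] <- cur
      juncs[[length(segs)]] <- list(
        qe = cur$q_to, we = cur$w_to,
        qs = h$q_start[k + 1L], ws = h$w_start[k + 1L],
        m = lk$m[k], mode = "boundary", x = 0L, pairclass = 0L,
        nmatch = NA_integer_, total = NA_integer_, pieces = NULL)
      cur <- list(q_from = h$q_start[k + 1L], q_to = h$q_end[k + 1L],
                  w_from = h$w_start[k + 1L], w_to = h$w_end[k + 1L],
                  pends = list())
    } else {
      cur$pends[[length(cur$pends) + 1L]] <- list(
        qe = cur$q_to, we = cur$w_to,
        qs = h$q_start[k + 1L], ws = h$w_start[k + 1L], delta = lk$delta[k])
      cur$q_to <- h$q_end[k + 1L]; cur$w_to <- h$w_end[k + 1L]
    }
  }
  segs[[length(segs) + 1L]] <- cur
  structure(list(query = query, w = w, L = L, strand = strand,
                 contig_id = contig_id, segs = segs, juncs = juncs,
                 prefix = list(mode = "none"), suffix = list(mode = "none"),
                 params = params, gc = codon_table(params$codon_table)),
            class = "recon_draft")
}

seg_limits <- function(seg) {
  # region of a segment guaranteed free of pending frame disruptions
  w_min <- seg$w_from; q_min <- seg$q_from
  w_max <- seg$w_to; q_max <- seg$q_to
  if (length(seg$pends)) {
    last <- seg$pends[[length(seg$pends)]]
    w_min2 <- last$ws; q_min2 <- last$qs
    first <- seg$pends[[1L]]
    w_max2 <- first$we; q_max2 <- first$qe
    list(tail = list(w_min = w_min2, q_min = q_min2),
         head = list(w_max = w_max2, q_max = q_max2))
  } else {
    list(tail = list(w_min = w_min, q_min = q_min),
         head = list(w_max = w_max, q_max = q_max))
  }
}

# ---- junction refinement ----------------------------------------------------

refine_draft_junctions <- function(draft) {
  p <- draft$params; gc <- draft$gc
  for (k in seq_along(draft$juncs)) {
    j <- draft$juncs[[k]]
    left <- seg_limits(draft$segs[[k]])$tail
    right <- seg_limits(draft$segs[[k + 1L]])$head
    bnd <- NULL
    if (j$m <= 6L)
      bnd <- refine_boundary(draft$query, draft$w, j$qe, j$we, j$qs, j$ws,
                             j$m, left, right, p, gc)
    bnd_perfect <- !is.null(bnd) && bnd$nmatch == bnd$total
    # intron-internal placement of the intervening residues; the anchoring
    # hits may have overshot the true exon ends, so small retractions of
    # either anchor are tried as well. Skipped when the boundary solution
    # already explains every residue.
    rec <- NULL; rec_tl <- 0L; rec_tr <- 0L
    if (!bnd_perfect) {
      seg_l <- draft$segs[[k]]; seg_r <- draft$segs[[k + 1L]]
      for (tt in 0:6) {
        for (tl in 0:min(tt, 3L)) {
          tr <- tt - tl
          if (tr > 3L) next
          if (j$m + tl + tr < 1L) next
          if (3L * (tl + 1L) >= seg_l$w_to - seg_l$w_from) next
          if (3L * (tr + 1L) >= seg_r$w_to - seg_r$w_from) next
          rec <- place_pieces(draft$query, draft$w,
                              j$qe + 1L - tl, j$qs - 1L + tr,
                              j$we - 3L * tl, j$ws + 3L * tr,
                              left_open = FALSE, right_open = FALSE,
                              params = p, gc = gc)
          if (!is.null(rec)) { rec_tl <- tl; rec_tr <- tr; break }
        }
        if (!is.null(rec)) break
      }
    }
    use_rec <- FALSE
    if (!is.null(rec)) {
      if (is.null(bnd)) use_rec <- TRUE
      else {
        # an intron-internal placement must beat the boundary solution on
        # the residues it claims, at a cost of ~1.2 residues per extra
        # intron pair; this keeps micro-exon calls out of noisy junctions
        claimed <- seq.int(j$qe + 1L - rec_tl, j$qs - 1L + rec_tr)
        claimed <- claimed[claimed >= bnd$r1 & claimed <= bnd$r2]
        deficit <- sum(!bnd$match_vec[claimed - bnd$r1 + 1L])
        use_rec <- deficit > 1.2 * length(rec)
      }
    }
    if (use_rec) {
      j$mode <- "pieces"; j$pieces <- rec
      j$trim_l <- rec_tl; j$trim_r <- rec_tr
    } else if (!is.null(bnd)) {
      j$mode <- "boundary"; j$x <- bnd$x; j$pairclass <- bnd$pairclass
      j$nmatch <- bnd$nmatch; j$total <- bnd$total
    } else {
      j$mode <- "gap"
    }
    draft$juncs[[k]] <- j
  }
  draft
}

# ---- terminal placement -----------------------------------------------------

place_draft_terminals <- function(draft) {
  p <- draft$params; gc <- draft$gc; w <- draft$w; q <- draft$query
  first <- draft$segs[[1L]]
  m0 <- first$q_from - 1L
  if (m0 > 0L) {
    region_start <- max(0L, first$w_from - p$terminal_flank)
    # the anchoring hit may have overshot the true exon start by a few
    # residues; retry the placement with small retractions of the anchor
    rec <- NULL
    for (t in 0:3) {
      if (3L * (t + 1L) >= first$w_to - first$w_from) break
      rec <- place_pieces(q, w, 1L, m0 + t, region_start,
                          first$w_from + 3L * t,
                          left_open = TRUE, right_open = FALSE,
                          params = p, gc = gc)
      if (!is.null(rec)) { rec_trim <- t; break }
    }
    if (!is.null(rec)) {
      draft$prefix <- list(mode = "pieces", pieces = rec, trim = rec_trim)
    } else if (first$w_from - 3L * m0 >= 0L) {
      ext <- substr(w, first$w_from - 3L * m0 + 1L, first$w_from)
      aa <- fast_translate_v(ext, gc)
      nm <- sum(aa == chars(substr(q, 1L, m0)))
      if (!any(aa == "*") && nm >= m0 - max(1L, floor(0.3 * m0)))
        draft$prefix <- list(mode = "extend", n = m0)
      else draft$prefix <- list(mode = "unmatched", n = m0)
    } else draft$prefix <- list(mode = "unmatched", n = m0)
  }
  last <- draft$segs[[length(draft$segs)]]
  m1 <- nchar(q) - last$q_to
  if (m1 > 0L) {
    region_end <- min(draft$L, last$w_to + p$terminal_flank)
    rec <- NULL
    for (t in 0:3) {
      if (3L * (t + 1L) >= last$w_to - last$w_from) break
      rec <- place_pieces(q, w, last$q_to + 1L - t, nchar(q),
                          last$w_to - 3L * t, region_end,
                          left_open = FALSE, right_open = TRUE,
                          params = p, gc = gc)
      if (!is.null(rec)) { rec_trim <- t; break }
    }
    if (!is.null(rec)) {
      draft$suffix <- list(mode = "pieces", pieces = rec, trim = rec_trim)
    } else if (last$w_to + 3L * m1 <= draft$L) {
      ext <- substr(w, last$w_to + 1L, last$w_to + 3L * m1)
      aa <- fast_translate_v(ext, gc)
      nm <- sum(aa == chars(substr(q, last$q_to + 1L, nchar(q))))
      if (!any(aa == "*") && nm >= m1 - max(1L, floor(0.3 * m1)))
        draft$suffix <- list(mode = "extend", n = m1)
      else draft$suffix <- list(mode = "unmatched", n = m1)
    } else draft$suffix <- list(mode = "unmatched", n = m1)
  }
  draft
}

# ---- pending frame-shift polishing ------------------------------------------

polish_pends <- function(draft) {
  gc <- draft$gc; w <- draft$w; q <- draft$query
  for (si in seq_along(draft$segs)) {
    seg <- draft$segs[[si]]
    if (!length(seg$pends)) next
    seg$shifts <- list()
    np <- length(seg$pends)
    for (pi in seq_len(np)) {
      pd <- seg$pends[[pi]]
      if (pd$delta == 0L) next
      # stay clear of the neighbouring frame disruptions in this segment
      q_lo <- if (pi > 1L) seg$pends[[pi - 1L]]$qs + 1L else seg$q_from
      q_hi <- if (pi < np) seg$pends[[pi + 1L]]$qe - 1L else seg$q_to
      r1 <- max(q_lo, pd$qe - 32L)
      r2 <- min(q_hi, pd$qs + 32L)
      c1 <- pd$we - 3L * (pd$qe - r1 + 1L)
      c2 <- pd$ws + 3L * (r2 - pd$qs + 1L)
      if (c1 < seg$w_from) { r1 <- pd$qe - (pd$we - seg$w_from) %/% 3L + 1L
                             c1 <- pd$we - 3L * (pd$qe - r1 + 1L) }
      if (c2 > seg$w_to)   { r2 <- pd$qs + (seg$w_to - pd$ws) %/% 3L - 1L
                             c2 <- pd$ws + 3L * (r2 - pd$qs + 1L) }
      target <- chars(substr(q, r1, r2))
      lo <- max(c1, pd$we - 90L); hi <- min(c2 - max(pd$delta, 0L), pd$ws + 90L)
      best <- NULL
      for (cc in seq.int(lo, hi)) {
        if (pd$delta > 0L)
          chunk <- paste0(substr(w, c1 + 1L, cc),
                          substr(w, cc + pd$delta + 1L, c2))
        else
          chunk <- paste0(substr(w, c1 + 1L, cc), strrep("N", -pd$delta),
                          substr(w, cc + 1L, c2))
        aa <- fast_translate_v(chunk, gc)
        nm <- sum(aa == target)
        if (is.null(best) || nm > best$nm) best <- list(c = cc, nm = nm)
      }
      if (is.null(best)) next
      off <- best$c - c1
      pstart <- r1 + off %/% 3L
      pend_ <- if (pd$delta > 0L) pstart
               else r1 + (off - pd$delta - 1L) %/% 3L
      seg$shifts[[length(seg$shifts) + 1L]] <- list(
        w_pos = best$c, delta = pd$delta,
        protein_start = min(pstart, nchar(q)), protein_end = min(pend_, nchar(q)))
    }
    draft$segs[[si]] <- seg
  }
  draft
}

# ---- materialisation --------------------------------------------------------

materialise_draft <- function(draft, contig) {
  p <- draft$params; L <- draft$L; strand <- draft$strand
  exw <- list()    # working-coordinate exons: w_from, w_to, q_from, q_to, shifts
  add_exon <- function(w_from, w_to, q_from, q_to, shifts = list())
    exw[[length(exw) + 1L]] <<- list(w_from = w_from, w_to = w_to,
                                     q_from = q_from, q_to = q_to,
                                     shifts = shifts)
  unmatched <- list()
  add_unmatched <- function(p1, p2, w_pos, pad)
    unmatched[[length(unmatched) + 1L]] <<- list(protein_start = p1,
                                                 protein_end = p2,
                                                 w_pos = w_pos, pad = pad)
  # prefix
  if (draft$prefix$mode == "pieces")
    for (pc in draft$prefix$pieces)
      add_exon(pc$w_from, pc$w_to, pc$q_from, pc$q_to)
  # main segments with junction adjustments
  nseg <- length(draft$segs)
  for (k in seq_len(nseg)) {
    seg <- draft$segs[[k]]
    w_from <- seg$w_from; w_to <- seg$w_to
    q_from <- seg$q_from; q_to <- seg$q_to
    if (k > 1L) {
      j <- draft$juncs[[k - 1L]]
      if (j$mode == "boundary") w_from <- j$ws - (3L * j$m - j$x)
      if (j$mode == "pieces" && (j$trim_r %||% 0L) > 0L) {
        w_from <- w_from + 3L * j$trim_r
        q_from <- q_from + j$trim_r
      }
    }
    if (k < nseg) {
      j <- draft$juncs[[k]]
      if (j$mode == "boundary") w_to <- j$we + j$x
      if (j$mode == "pieces" && (j$trim_l %||% 0L) > 0L) {
        w_to <- w_to - 3L * j$trim_l
        q_to <- q_to - j$trim_l
      }
    }
    if (k == 1L && draft$prefix$mode == "extend") {
      w_from <- w_from - 3L * draft$prefix$n; q_from <- 1L
    }
    if (k == 1L && draft$prefix$mode == "pieces" &&
        (draft$prefix$trim %||% 0L) > 0L) {
      w_from <- w_from + 3L * draft$prefix$trim
      q_from <- q_from + draft$prefix$trim
    }
    if (k == nseg && draft$suffix$mode == "extend") {
      w_to <- w_to + 3L * draft$suffix$n; q_to <- nchar(draft$query)
    }
    if (k == nseg && draft$suffix$mode == "pieces" &&
        (draft$suffix$trim %||% 0L) > 0L) {
      w_to <- w_to - 3L * draft$suffix$trim
      q_to <- q_to - draft$suffix$trim
    }
    add_exon(w_from, w_to, q_from, q_to, seg$shifts %||% list())
    if (k < nseg) {
      j <- draft$juncs[[k]]
      if (j$mode == "pieces")
        for (pc in j$pieces) add_exon(pc$w_from, pc$w_to, pc$q_from, pc$q_to)
      if (j$mode == "gap" && j$m > 0L)
        add_unmatched(j$qe + 1L, j$qs - 1L, w_pos = w_to, pad = -3L * j$m)
    }
  }
  # suffix
  if (draft$suffix$mode == "pieces")
    for (pc in draft$suffix$pieces)
      add_exon(pc$w_from, pc$w_to, pc$q_from, pc$q_to)
  if (draft$prefix$mode == "unmatched")
    add_unmatched(1L, draft$prefix$n, w_pos = exw[[1L]]$w_from,
                  pad = -3L * draft$prefix$n)
  if (draft$suffix$mode == "unmatched")
    add_unmatched(nchar(draft$query) - draft$suffix$n + 1L, nchar(draft$query),
                  w_pos = exw[[length(exw)]]$w_to, pad = -3L * draft$suffix$n)

  exw <- exw[order(vapply(exw, `[[`, numeric(1), "w_from"))]
  # forward conversion
  ex <- bind_rows(lapply(exw, function(e) {
    iv <- fwd_interval(strand, L, e$w_from, e$w_to)
    tibble(start = as.integer(iv[1]), end = as.integer(iv[2]))
  }))  # exw is in gene order already (ascending working coordinates)

  drows <- list()
  for (e in exw) for (sh in e$shifts) {
    wiv <- c(sh$w_pos, sh$w_pos + max(sh$delta, 0L))
    iv <- fwd_interval(strand, L, wiv[1], wiv[2])
    drows[[length(drows) + 1L]] <- tibble(
      kind = "sequence_shift", protein_start = sh$protein_start,
      protein_end = sh$protein_end, genomic_start = as.integer(iv[1]),
      genomic_end = as.integer(iv[2]), shift = as.integer(sh$delta),
      detail = sprintf("%+d nt frame disruption", sh$delta))
  }
  for (u in unmatched) {
    iv <- fwd_interval(strand, L, u$w_pos, u$w_pos)
    drows[[length(drows) + 1L]] <- tibble(
      kind = "unmatched", protein_start = u$protein_start,
      protein_end = u$protein_end, genomic_start = as.integer(iv[1]),
      genomic_end = as.integer(iv[2]), shift = as.integer(u$pad),
      detail = "query residues not placed")
  }
  disc <- if (length(drows)) bind_rows(drows) else empty_discrepancies()

  gene_structure(query_id = attr(draft$query, "id") %||% "query",
                 query = draft$query, contig_id = draft$contig_id,
                 strand = strand, exons = ex, discrepancies = disc,
                 codon_table = p$codon_table, contig = contig)
}

# ---- exported pipeline stages -----------------------------------------------

#' Refine exon/intron boundaries of a chained draft
#'
#' Slides every candidate intron boundary within an exhaustive window to
#' place an allowed splice pair while keeping the translation of the
#' adjusted exon ends consistent with the query. Among equal-scoring
#' placements the canonical GT-AG pair wins, then the most 5' donor.
#' Junctions whose intervening residues are better explained by one or more
#' short intron-internal exons are seated as such; junctions that cannot be
#' resolved keep their intron with a non-canonical flag or become unmatched
#' gaps (never silently dropped).
#'
#' @param chain output of [chain_exons()].
#' @param query protein query string.
#' @param contig contig nucleotide string.
#' @param params a [reconstruction_params()] list.
#' @return a `gene_structure` (without mismatch/stop annotation; see
#'   [annotate_discrepancies()]).
#' @export
refine_splice_sites <- function(chain, query, contig,
                                params = reconstruction_params()) {
  strand <- chain$hits$strand[1]
  w <- if (strand == "+") contig else reverse_complement(contig)
  draft <- new_draft(chain, query, w, attr(contig, "id") %||% "contig",
                     strand, nchar(contig), params)
  draft <- refine_draft_junctions(draft)
  draft <- place_draft_terminals(draft)
  draft <- polish_pends(draft)
  materialise_draft(draft, contig)
}

#' Place short unmatched exons
#'
#' Re-examines the unmatched regions of a gene structure and exhaustively
#' searches the corresponding intronic or flanking windows for codon-aligned,
#' splice-site-flanked placements of the unmatched peptide stretches (down
#' to `min_exon_len_aa` residues). Residues that cannot be placed stay
#' annotated as `unmatched`.
#'
#' @param g a `gene_structure` with possible `unmatched` discrepancies.
#' @param contig contig sequence.
#' @param params a [reconstruction_params()] list.
#' @return an updated `gene_structure`.
#' @export
place_short_exons <- function(g, contig, params = reconstruction_params()) {
  d <- g$discrepancies
  un <- which(d$kind == "unmatched")
  if (!length(un)) return(g)
  gc <- codon_table(params$codon_table)
  L <- nchar(contig)
  w <- if (g$strand == "+") contig else reverse_complement(contig)
  to_w <- function(s, e) if (g$strand == "+") c(s, e) else c(L - e, L - s)
  qlen <- nchar(g$query)
  new_ex <- list(); resolved <- integer(0)
  span <- gene_span(g)
  wspan <- to_w(span[1], span[2])
  for (k in un) {
    p1 <- d$protein_start[k]; p2 <- d$protein_end[k]
    if (p1 == 1L && p2 < qlen) {             # prefix
      rs <- max(0L, wspan[1] - params$terminal_flank)
      rec <- place_pieces(g$query, w, p1, p2, rs, wspan[1],
                          left_open = TRUE, right_open = FALSE, params, gc)
    } else if (p2 == qlen && p1 > 1L) {      # suffix
      re_ <- min(L, wspan[2] + params$terminal_flank)
      rec <- place_pieces(g$query, w, p1, p2, wspan[2], re_,
                          left_open = FALSE, right_open = TRUE, params, gc)
    } else {                                 # internal gap: its intron
      wp <- to_w(d$genomic_start[k], d$genomic_start[k])[1]
      ii <- which(vapply(seq_len(nrow(g$introns)), function(i) {
        iv <- to_w(g$introns$start[i], g$introns$end[i])
        iv[1] == wp
      }, logical(1)))
      if (!length(ii)) next
      iv <- to_w(g$introns$start[ii[1]], g$introns$end[ii[1]])
      rec <- place_pieces(g$query, w, p1, p2, iv[1], iv[2],
                          left_open = FALSE, right_open = FALSE, params, gc)
    }
    if (!is.null(rec)) {
      new_ex <- c(new_ex, rec)
      resolved <- c(resolved, k)
    }
  }
  if (!length(resolved)) return(g)
  exw <- lapply(seq_len(nrow(g$exons)), function(i)
    to_w(g$exons$start[i], g$exons$end[i]))
  allw <- c(exw, lapply(new_ex, function(e) c(e$w_from, e$w_to)))
  allw <- allw[order(vapply(allw, `[`, numeric(1), 1))]
  ex <- bind_rows(lapply(allw, function(v) {
    iv <- fwd_interval(g$strand, L, v[1], v[2])
    tibble(start = as.integer(iv[1]), end = as.integer(iv[2]))
  }))
  gene_structure(g$query_id, g$query, g$contig_id, g$strand, ex,
                 discrepancies = g$discrepancies[-resolved, ],
                 codon_table = g$codon_table, contig = contig)
}

#' Annotate discrepancies between query and target translation
#'
#' Compares the translation of the assembled CDS with the query and records
#' every deviation as exactly one of the four categories: `mismatch`,
#' `sequence_shift` (already placed during reconstruction), `inframe_stop`,
#' or `unmatched`. Previous mismatch/stop rows are recomputed.
#'
#' @param g a `gene_structure`.
#' @param contig contig sequence.
#' @return `g` with a complete `discrepancies` table.
#' @export
annotate_discrepancies <- function(g, contig) {
  keep <- g$discrepancies[g$discrepancies$kind %in%
                            c("sequence_shift", "unmatched"), , drop = FALSE]
  g$discrepancies <- keep
  g <- rescue_frameshift_pairs(g, contig)
  keep <- g$discrepancies
  cds <- gs_cds(g, contig)
  tr <- fast_translate_v(cds, codon_table(g$codon_table))
  q <- chars(g$query)
  nn <- min(length(tr), length(q))
  covered <- rep(FALSE, length(q))
  if (nrow(keep)) for (k in seq_len(nrow(keep))) {
    r <- seq.int(max(1L, keep$protein_start[k]),
                 min(length(q), keep$protein_end[k]))
    covered[r] <- TRUE
  }
  rows <- list()
  for (i in seq_len(nn)) {
    if (covered[i] || tr[i] == "X" || tr[i] == q[i]) next
    iv <- tryCatch(cds_to_genomic(g, 3L * (i - 1L), 3L * i),
                   error = function(e) NULL)
    gs_ <- if (!is.null(iv) && nrow(iv)) min(iv$start) else NA_integer_
    ge_ <- if (!is.null(iv) && nrow(iv)) max(iv$end) else NA_integer_
    rows[[length(rows) + 1L]] <- tibble(
      kind = if (tr[i] == "*") "inframe_stop" else "mismatch",
      protein_start = i, protein_end = i,
      genomic_start = gs_, genomic_end = ge_, shift = 0L,
      detail = sprintf("query %s vs target %s", q[i], tr[i]))
  }
  if (length(rows)) g$discrepancies <- bind_rows(keep, bind_rows(rows))
  g
}

# A pair of compensating 1-2 nt frame disruptions inside one exon leaves
# the exon boundaries intact but garbles the translation in between, so the
# chain never sees a genomic gap. Detect runs of consecutive translation
# mismatches and test every placement of an excision + N-pad pair (both
# orders) on the assembled CDS; a placement that restores the translation
# exactly (outside the padded codons) is recorded as two sequence_shift
# discrepancies.
rescue_frameshift_pairs <- function(g, contig) {
  gc <- codon_table(g$codon_table)
  for (round in 1:3) {
    cds <- gs_cds(g, contig)
    tr <- fast_translate_v(cds, gc)
    q <- chars(g$query)
    nn <- min(length(tr), length(q))
    covered <- rep(FALSE, length(q))
    d <- g$discrepancies
    if (nrow(d)) for (k in seq_len(nrow(d)))
      covered[seq.int(max(1L, d$protein_start[k]),
                      min(length(q), d$protein_end[k]))] <- TRUE
    bad <- which(tr[seq_len(nn)] != q[seq_len(nn)] &
                   tr[seq_len(nn)] != "X" & !covered[seq_len(nn)])
    if (!length(bad)) return(g)
    runs <- split(bad, cumsum(c(1L, diff(bad) != 1L)))
    runs <- Filter(function(r) length(r) >= 4L, runs)
    if (!length(runs)) return(g)
    fixed <- FALSE
    for (r in runs) {
      c_lo <- 3L * (min(r) - 1L) - 6L
      c_hi <- 3L * max(r) + 6L
      ex <- g$exons
      lens <- vapply(seq_len(nrow(ex)), function(i) gs_exon_cds_len(g, i),
                     integer(1))
      ei <- which(ex$cds_offset <= c_lo & ex$cds_offset + lens >= c_hi)
      if (length(ei) != 1L) next
      c_lo <- max(c_lo, ex$cds_offset[ei])
      c_hi <- min(c_hi, ex$cds_offset[ei] + lens[ei])
      r1 <- c_lo %/% 3L + 1L; r2 <- (c_hi - 1L) %/% 3L + 1L
      r2 <- min(r2, length(q))
      a1 <- 3L * (r1 - 1L); a2 <- 3L * r2
      target <- q[r1:r2]
      best <- NULL
      for (k in 1:2) for (ord in 1:2) {
        for (A in seq.int(c_lo, c_hi - k - 3L)) {
          for (B in seq.int(A + 3L, c_hi - k)) {
            if (ord == 1L) {    # extra genomic at A, missing at B
              mod <- paste0(substr(cds, a1 + 1L, A),
                            substr(cds, A + k + 1L, B),
                            strrep("N", k),
                            substr(cds, B + 1L, a2))
            } else {            # missing at A, extra at B
              mod <- paste0(substr(cds, a1 + 1L, A), strrep("N", k),
                            substr(cds, A + 1L, B),
                            substr(cds, B + k + 1L, a2))
            }
            aa <- fast_translate_v(mod, gc)
            ok_idx <- aa != "X"
            nm <- sum(aa[ok_idx] == target[ok_idx])
            need <- sum(ok_idx)
            if (nm == need &&
                (is.null(best) || need > best$need)) {
              best <- list(k = k, ord = ord, A = A, B = B, need = need)
            }
          }
        }
      }
      if (is.null(best)) next
      mkrow <- function(cpos, shift) {
        if (shift > 0L) {
          iv <- cds_to_genomic(g, cpos, cpos + shift)
          gs_ <- min(iv$start); ge_ <- max(iv$end)
          p1 <- cpos %/% 3L + 1L; p2 <- p1
        } else {
          iv <- cds_to_genomic(g, cpos, cpos + 1L)
          gs_ <- if (g$strand == "+") iv$start[1] else iv$end[1]
          ge_ <- gs_
          p1 <- cpos %/% 3L + 1L
          p2 <- (cpos - shift - 1L) %/% 3L + 1L
        }
        tibble(kind = "sequence_shift", protein_start = p1,
               protein_end = min(p2, nchar(g$query)),
               genomic_start = as.integer(gs_), genomic_end = as.integer(ge_),
               shift = as.integer(shift),
               detail = sprintf("%+d nt frame disruption (compensated)",
                                shift))
      }
      sh_a <- if (best$ord == 1L) best$k else -best$k
      sh_b <- -sh_a
      g$discrepancies <- bind_rows(g$discrepancies,
                                   mkrow(best$A, sh_a), mkrow(best$B, sh_b))
      g$exons <- gs_assign_offsets(g)
      fixed <- TRUE
      break   # re-translate before attacking the next run
    }
    if (!fixed) return(g)
  }
  g
}

# ---- top-level driver -------------------------------------------------------

#' Reconstruct the gene structure of a protein on genomic sequence
#'
#' Runs the full pipeline: seeded translated matching, colinear exon
#' chaining, exhaustive splice-boundary refinement, short-exon placement and
#' discrepancy annotation, on every contig and both strands; the
#' best-scoring reconstruction is returned. Deterministic given inputs and
#' parameters.
#'
#' @param query protein query (string, or single-row tibble with `id`,
#'   `seq`).
#' @param contigs named character vector of contig sequences, or a tibble
#'   with columns `id` and `seq`.
#' @param params a [reconstruction_params()] list.
#' @return a [result_document()] whose `gene` slot holds the reconstruction
#'   (or `NULL` with a diagnostic when no reconstruction clears the
#'   identity/coverage floors).
#' @export
reconstruct <- function(query, contigs, params = reconstruction_params()) {
  if (is.data.frame(query)) {
    qid <- query$id[1]; qseq <- clean_protein(query$seq[1], qid)
  } else {
    qid <- names(query)[1] %||% "query"; qseq <- clean_protein(query[[1]], qid)
  }
  if (is.data.frame(contigs)) {
    cid <- contigs$id; cseq <- contigs$seq
  } else {
    cid <- names(contigs) %||% paste0("contig_", seq_along(contigs))
    cseq <- unname(contigs)
  }
  best <- NULL
  for (ci in seq_along(cseq)) {
    hits <- find_seed_hits(qseq, cseq[ci], params)
    for (strand in c("+", "-")) {
      hs <- hits[hits$strand == strand, , drop = FALSE]
      if (!nrow(hs)) next
      ch <- chain_exons(hs, params)
      if (is.null(ch)) next
      if (is.null(best) || ch$score > best$score)
        best <- list(score = ch$score, chain = ch, contig = ci)
    }
  }
  if (is.null(best))
    return(result_document(gene = NULL, provenance = recon_provenance(
      qid, qseq, cid, cseq, params),
      diagnostics = "no seed hits above threshold on any contig/strand"))
  contig <- cseq[best$contig]
  attr(contig, "id") <- cid[best$contig]
  attr(qseq, "id") <- qid
  g <- refine_splice_sites(best$chain, qseq, contig, params)
  g <- place_short_exons(g, contig, params)
  g <- annotate_discrepancies(g, contig)
  qlen <- nchar(qseq)
  d <- g$discrepancies
  n_un <- if (nrow(d)) sum(pmax(0L, d$protein_end[d$kind == "unmatched"] -
                                  d$protein_start[d$kind == "unmatched"] + 1L))
          else 0L
  n_bad <- if (nrow(d)) sum(d$kind %in% c("mismatch", "inframe_stop")) else 0L
  coverage <- (qlen - n_un) / qlen
  identity <- (qlen - n_un - n_bad) / qlen
  diag <- character(0)
  if (coverage < params$min_coverage)
    diag <- c(diag, sprintf(
      "reconstruction failed: query coverage %.2f below floor %.2f",
      coverage, params$min_coverage))
  if (identity < params$min_identity)
    diag <- c(diag, sprintf(
      "reconstruction failed: identity %.2f below floor %.2f",
      identity, params$min_identity))
  result_document(
    gene = if (length(diag)) NULL else g,
    partial = if (length(diag)) g else NULL,
    provenance = recon_provenance(qid, qseq, cid, cseq, params),
    stats = tibble(identity = identity, coverage = coverage,
                   chain_score = best$score),
    diagnostics = if (length(diag)) paste(diag, collapse = "; ") else NULL)
}

recon_provenance <- function(qid, qseq, cid, cseq, params) {
  list(query_id = qid, query_md5 = string_md5(qseq),
       contig_ids = as.character(cid),
       contig_md5 = vapply(cseq, string_md5, "", USE.NAMES = FALSE),
       params = unclass(params))
}
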