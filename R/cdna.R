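# Two-step cDNA/EST mapping. Step 1 filters the cDNA set by local
# alignment against the CDS (or the genomic span, or the translation for
# cross-species sets); step 2 maps every retained cDNA against the genomic
# sequence of the gene as a spliced alignment, which is what exposes
# alternative splice forms: hits may contain sequence not present in the
# CDS. Coordinates inside this module are "gene space": 0-based positions
# along the genomic span in gene orientation; conversion to forward contig
# coordinates happens when events are reported.

gene_space_features <- function(g) {
  sp <- gene_span(g)
  conv <- function(s, e) {
    if (g$strand == "+") c(s - sp[1], e - sp[1]) else c(sp[2] - e, sp[2] - s)
  }
  ex <- bind_rows(lapply(seq_len(nrow(g$exons)), function(i) {
    v <- conv(g$exons$start[i], g$exons$end[i])
    tibble(index = i, gs = v[1], ge = v[2],
           cds_offset = g$exons$cds_offset[i])
  }))
  it <- if (nrow(g$introns)) bind_rows(lapply(seq_len(nrow(g$introns)),
    function(i) {
      v <- conv(g$introns$start[i], g$introns$end[i])
      tibble(index = i, gs = v[1], ge = v[2])
    })) else tibble(index = integer(), gs = integer(), ge = integer())
  list(exons = ex, introns = it, span = sp)
}

gene_to_fwd <- function(g, gs, ge) {
  sp <- gene_span(g)
  if (g$strand == "+") c(sp[1] + gs, sp[1] + ge) else c(sp[2] - ge, sp[2] - gs)
}

# ---- step 1 -----------------------------------------------------------------

#' Map cDNAs against the CDS (step 1)
#'
#' Filters a cDNA set by best local alignment against the chosen target
#' space: the CDS (default), the genomic span (`"genomic"`, which also
#' retains sequences mapping only to introns), or the translation
#' (`"translated_cds"`, for cDNA sets from a different species, aligning
#' all six reading frames of each cDNA against the protein).
#'
#' @param cdnas tibble with columns `id`, `seq`.
#' @param g a `gene_structure`.
#' @param contig its contig sequence.
#' @param target_space `"cds"`, `"genomic"` or `"translated_cds"`.
#' @param params a [cdna_params()] list.
#' @return list of retained hits; each has `cdna_id`, `orientation`
#'   (`"+"` = as given, `"-"` = reverse complement), `score`, `identity`,
#'   `blocks` (gapless aligned blocks, 0-based half-open, `a_*` = cdna,
#'   `b_*` = target), and `unmatched` cdna intervals.
#' @export
map_step1 <- function(cdnas, g, contig,
                      target_space = c("cds", "genomic", "translated_cds"),
                      params = cdna_params()) {
  target_space <- match.arg(target_space)
  if (!nrow(cdnas)) return(list())
  target <- switch(target_space,
    cds = unname(gs_cds(g, contig)),
    genomic = unname(extract_seqs(g, contig, "genomic")),
    translated_cds = unname(extract_seqs(g, contig, "translation")))
  hits <- list()
  for (i in seq_len(nrow(cdnas))) {
    sq <- cdnas$seq[i]
    if (target_space == "translated_cds") {
      best <- NULL
      for (orient in c("+", "-")) {
        s2 <- if (orient == "+") sq else reverse_complement(sq)
        for (f in 0:2) {
          nc <- (nchar(s2) - f) %/% 3L
          if (nc < 10L) next
          aa <- translate_cds(substr(s2, f + 1L, f + 3L * nc), g$codon_table,
                              allow_partial = TRUE)
          al <- align_pair(aa, target, type = "protein", mode = "local")
          if (is.null(best) || al$score > best$al$score)
            best <- list(al = al, orient = orient, frame = f)
        }
      }
      if (!is.null(best) && best$al$identity >= 0.5 &&
          best$al$n_columns >= params$min_aligned_len %/% 3L)
        hits[[length(hits) + 1L]] <- list(
          cdna_id = cdnas$id[i], orientation = best$orient,
          frame = best$frame, score = best$al$score,
          identity = best$al$identity, blocks = best$al$blocks,
          unmatched = tibble(start = integer(), end = integer()),
          target_space = target_space)
      next
    }
    best <- NULL
    orients <- if (params$try_revcomp) c("+", "-") else "+"
    for (orient in orients) {
      s2 <- if (orient == "+") sq else reverse_complement(sq)
      al <- align_pair(s2, target, type = "dna", mode = "local")
      if (is.null(best) || al$score > best$al$score)
        best <- list(al = al, orient = orient)
    }
    al <- best$al
    # retention/skipping reads align to the CDS as clean exonic stretches
    # joined by noisy or gapped wandering; the filter therefore asks for a
    # window of min_aligned_len at min_identity somewhere inside a gapless
    # block rather than judging the whole local path
    bl <- al$blocks
    w <- params$min_aligned_len
    max_mm <- floor((1 - params$min_identity) * w)
    bl_ok <- FALSE
    for (bi in seq_len(nrow(bl))) {
      blen <- bl$a_end[bi] - bl$a_start[bi]
      if (blen < w) next
      mmp <- sort(al$mismatches$a_pos[al$mismatches$a_pos >= bl$a_start[bi] &
                                        al$mismatches$a_pos < bl$a_end[bi]])
      if (length(mmp) <= max_mm) { bl_ok <- TRUE; break }
      # fewest mismatches over any w-long window inside the block
      lo_ <- bl$a_start[bi]; hi_ <- bl$a_end[bi] - w
      best_mm <- Inf
      for (s0 in unique(pmin(pmax(c(lo_, mmp + 1L), lo_), hi_))) {
        cnt <- sum(mmp >= s0 & mmp < s0 + w)
        best_mm <- min(best_mm, cnt)
      }
      if (best_mm <= max_mm) { bl_ok <- TRUE; break }
    }
    if (bl_ok) {
      un <- tibble(start = c(0L, al$a_end), end = c(al$a_start, nchar(sq)))
      un <- un[un$end > un$start, ]
      hits[[length(hits) + 1L]] <- list(
        cdna_id = cdnas$id[i], orientation = best$orient, score = al$score,
        identity = al$identity, blocks = al$blocks, unmatched = un,
        target_space = target_space)
    }
  }
  hits
}

# ---- step 2: spliced alignment against the genomic span ---------------------

kmer_index <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(list())
  km <- substring(s, 1:(n - k + 1L), k:n)
  split(seq_len(n - k + 1L), km)
}

# anchor segments on shared diagonals, merged and chained colinearly
anchor_chain <- function(cdna, gseq, k) {
  idx <- kmer_index(gseq, k)
  n <- nchar(cdna)
  if (n < k) return(NULL)
  cm <- substring(cdna, 1:(n - k + 1L), k:n)
  hit <- idx[cm]
  cpos <- rep(seq_along(cm), lengths(hit))
  gpos <- unlist(hit, use.names = FALSE)
  if (!length(gpos)) return(NULL)
  d <- gpos - cpos
  o <- order(d, cpos)
  cpos <- cpos[o]; gpos <- gpos[o]; d <- d[o]
  # merge runs on the same diagonal with gaps <= 30 nt (substitution noise)
  segs <- list()
  cs <- cpos[1]; ce <- cpos[1] + k - 1L; cd <- d[1]
  for (i in seq_along(cpos)[-1]) {
    if (d[i] == cd && cpos[i] <= ce + 30L) {
      ce <- max(ce, cpos[i] + k - 1L)
    } else {
      segs[[length(segs) + 1L]] <- c(cs, ce, cd)
      cs <- cpos[i]; ce <- cpos[i] + k - 1L; cd <- d[i]
    }
  }
  segs[[length(segs) + 1L]] <- c(cs, ce, cd)
  sg <- do.call(rbind, segs)
  sg <- tibble(c_start = sg[, 1] - 1L, c_end = sg[, 2],   # 0-based half-open
               diag = sg[, 3], g_start = sg[, 1] - 1L + sg[, 3],
               g_end = sg[, 2] + sg[, 3])
  sg <- arrange(sg, c_start, g_start)
  # colinear chain DP maximising anchored length
  nseg <- nrow(sg)
  len <- sg$c_end - sg$c_start
  dp <- as.numeric(len); prev <- rep(NA_integer_, nseg)
  for (j in seq_len(nseg)) for (i in seq_len(nseg)) {
    if (i == j) next
    if (sg$c_start[i] >= sg$c_start[j] || sg$c_end[i] >= sg$c_end[j]) next
    if (sg$g_start[i] >= sg$g_start[j] || sg$g_end[i] >= sg$g_end[j]) next
    ov <- max(0L, sg$c_end[i] - sg$c_start[j])
    dg <- sg$g_start[j] - sg$g_end[i]
    if (dg < ov - 5L) next
    cand <- dp[i] + len[j] - ov - ifelse(dg > 30L, 3, 0)
    if (cand > dp[j]) { dp[j] <- cand; prev[j] <- i }
  }
  jb <- which.max(dp)
  path <- integer(0); j <- jb
  while (!is.na(j)) { path <- c(j, path); j <- prev[j] }
  sg[path, ]
}

#' Spliced mapping of retained cDNAs against the genomic span (step 2)
#'
#' Anchors exact `anchor_len`-mers, chains them colinearly, merges
#' same-diagonal runs into gapless blocks, extends block edges, and places
#' every inter-block junction by an exhaustive scan that maximises matched
#' bases and prefers an allowed splice pair (canonical first, then the most
#' 5' donor). Genomic gaps of at least `min_intron_len` become junctions;
#' smaller gaps merge into one block.
#'
#' @param step1 list from [map_step1()] (cds or genomic space).
#' @param cdnas tibble `id`/`seq` (sequences of the retained hits).
#' @param g a `gene_structure`.
#' @param contig contig sequence.
#' @param params a [cdna_params()] list.
#' @return list of `spliced_hit` objects: `cdna_id`, `orientation`,
#'   `blocks` (gene-space, with `c_start`/`c_end`/`g_start`/`g_end`/
#'   `n_mismatch`), `junctions` (`g_end` of the left block, `g_start` of
#'   the right, donor/acceptor dinucleotides), `unmatched` cdna intervals.
#' @export
map_step2 <- function(step1, cdnas, g, contig, params = cdna_params()) {
  gseq <- unname(extract_seqs(g, contig, "genomic"))
  gv <- chars(gseq)
  out <- list()
  for (h in step1) {
    sq0 <- cdnas$seq[match(h$cdna_id, cdnas$id)]
    if (is.na(sq0)) next
    sq <- if (h$orientation == "+") sq0 else reverse_complement(sq0)
    sg <- anchor_chain(sq, gseq, params$anchor_len)
    if (is.null(sg) || !nrow(sg)) next
    cv <- chars(sq)
    # trim query overlaps between consecutive chain segments
    if (nrow(sg) > 1L) for (i in 2:nrow(sg)) {
      ov <- max(0L, sg$c_end[i - 1L] - sg$c_start[i])
      if (ov > 0L) { sg$c_start[i] <- sg$c_start[i] + ov
                     sg$g_start[i] <- sg$g_start[i] + ov }
    }
    # merge segments whose genomic gap is too small to be an intron
    blocks <- list(); cur <- sg[1L, ]
    if (nrow(sg) > 1L) for (i in 2:nrow(sg)) {
      dg <- sg$g_start[i] - cur$g_end
      dc <- sg$c_start[i] - cur$c_end
      if (dg - dc < params$min_intron_len) {
        cur$c_end <- sg$c_end[i]; cur$g_end <- sg$g_end[i]
      } else {
        blocks[[length(blocks) + 1L]] <- cur
        cur <- sg[i, ]
      }
    }
    blocks[[length(blocks) + 1L]] <- cur
    bl <- bind_rows(blocks)
    # drop flimsy terminal blocks: a random adapter tail can anchor a
    # single k-mer somewhere in the span and fabricate a junction
    while (nrow(bl) > 1L &&
           bl$c_end[1L] - bl$c_start[1L] < params$min_terminal_block)
      bl <- bl[-1L, ]
    while (nrow(bl) > 1L &&
           bl$c_end[nrow(bl)] - bl$c_start[nrow(bl)] < params$min_terminal_block)
      bl <- bl[-nrow(bl), ]
    # greedy edge extension of the first/last block (noise-tolerant)
    ext <- function(cpos, gpos, dir) {
      moved <- 0L
      while (TRUE) {
        cn <- cpos + dir; gn <- gpos + dir
        if (cn < 1L || gn < 1L || cn > length(cv) || gn > length(gv)) break
        if (cv[cn] == gv[gn]) { cpos <- cn; gpos <- gn; moved <- moved + 1L
                                next }
        ok <- TRUE
        for (s in 1:3) {
          c2 <- cn + dir * s; g2 <- gn + dir * s
          if (c2 < 1L || g2 < 1L || c2 > length(cv) || g2 > length(gv) ||
              cv[c2] != gv[g2]) { ok <- FALSE; break }
        }
        if (!ok) break
        cpos <- cn + 3L * dir; gpos <- gn + 3L * dir; moved <- moved + 4L
      }
      c(cpos, gpos)
    }
    v <- ext(bl$c_start[1L] + 1L, bl$g_start[1L] + 1L, -1L)
    bl$c_start[1L] <- v[1] - 1L; bl$g_start[1L] <- v[2] - 1L
    nb <- nrow(bl)
    v <- ext(bl$c_end[nb], bl$g_end[nb], +1L)
    bl$c_end[nb] <- v[1]; bl$g_end[nb] <- v[2]
    # junction refinement
    juncs <- list()
    if (nb > 1L) for (i in seq_len(nb - 1L)) {
      dc <- bl$c_start[i + 1L] - bl$c_end[i]
      wnd <- params$junction_window
      best <- NULL
      for (x in seq.int(-wnd, dc + wnd)) {
        jl <- bl$g_end[i] + x            # donor position (intron start)
        jr <- bl$g_start[i + 1L] - (dc - x)
        if (jl < 0L || jr > nchar(gseq) || jr - jl < params$min_intron_len)
          next
        if (jl < bl$g_start[i] + 1L || jr > bl$g_end[i + 1L] - 1L) next
        cl <- bl$c_end[i] + x            # cdna boundary (= split point)
        if (cl < bl$c_start[i] + 1L || cl > bl$c_end[i + 1L] - 1L ||
            cl > length(cv)) next
        # score = matches gained by extending minus matches lost by
        # retracting, on each side of the junction
        nm <- 0L
        if (x > 0L) {
          idx <- seq_len(x)
          nm <- nm + sum(cv[bl$c_end[i] + idx] == gv[bl$g_end[i] + idx])
        } else if (x < 0L) {
          idx <- seq_len(-x)
          nm <- nm - sum(cv[bl$c_end[i] - idx + 1L] ==
                           gv[bl$g_end[i] - idx + 1L])
        }
        y <- dc - x
        if (y > 0L) {
          idx <- seq_len(y)
          nm <- nm + sum(cv[bl$c_start[i + 1L] - idx + 1L] ==
                           gv[bl$g_start[i + 1L] - idx + 1L])
        } else if (y < 0L) {
          idx <- seq_len(-y)
          nm <- nm - sum(cv[bl$c_start[i + 1L] + idx] ==
                           gv[bl$g_start[i + 1L] + idx])
        }
        pc <- splice_pair_class(substr(gseq, jl + 1L, jl + 2L),
                                substr(gseq, jr - 1L, jr),
                                params$splice_pairs)
        cand <- list(x = x, nm = nm, pc = pc, jl = jl, jr = jr)
        if (is.null(best)) { best <- cand; next }
        better <- (nm > best$nm) ||
          (nm == best$nm && (pc > 0L) > (best$pc > 0L)) ||
          (nm == best$nm && pc > 0L && best$pc > 0L && pc < best$pc)
        if (better) best <- cand
      }
      if (is.null(best)) next
      bl$c_end[i] <- bl$c_end[i] + best$x
      bl$g_end[i] <- best$jl
      bl$c_start[i + 1L] <- bl$c_end[i]
      bl$g_start[i + 1L] <- best$jr
      juncs[[length(juncs) + 1L]] <- tibble(
        left = i, g_end_left = best$jl, g_start_right = best$jr,
        donor = substr(gseq, best$jl + 1L, best$jl + 2L),
        acceptor = substr(gseq, best$jr - 1L, best$jr),
        canonical = best$pc > 0L)
    }
    mmrows <- list()
    bl$n_mismatch <- vapply(seq_len(nrow(bl)), function(i) {
      idx <- seq.int(bl$c_start[i] + 1L, bl$c_end[i])
      bad <- which(cv[idx] != gv[bl$g_start[i] + seq_along(idx)])
      if (length(bad))
        mmrows[[length(mmrows) + 1L]] <<- tibble(
          c_pos = bl$c_start[i] + bad - 1L,
          g_pos = bl$g_start[i] + bad - 1L)
      length(bad)
    }, 0L)
    mism <- if (length(mmrows)) bind_rows(mmrows) else
      tibble(c_pos = integer(), g_pos = integer())
    un <- tibble(start = c(0L, bl$c_end[nrow(bl)]),
                 end = c(bl$c_start[1L], nchar(sq)))
    un <- un[un$end > un$start, ]
    out[[length(out) + 1L]] <- structure(list(
      cdna_id = h$cdna_id, orientation = h$orientation,
      blocks = select(bl, c_start, c_end, g_start, g_end, n_mismatch),
      junctions = if (length(juncs)) bind_rows(juncs) else
        tibble(left = integer(), g_end_left = integer(),
               g_start_right = integer(), donor = character(),
               acceptor = character(), canonical = logical()),
      unmatched = un, mismatches = mism,
      cdna_length = nchar(sq)), class = "spliced_hit")
  }
  out
}

#' Annotate a spliced hit with gene-model coordinates
#'
#' Labels every block with the exon/intron indices it overlaps and the CDS
#' projection of its exonic parts. The conversion is lossless: gene-space
#' block coordinates are retained.
#'
#' @param sh a `spliced_hit`.
#' @param g a `gene_structure`.
#' @return `sh` with `labels` (per-block feature overlaps) and
#'   `cds_projection` (per-block exonic CDS intervals) tibbles added.
#' @export
convert_coordinates <- function(sh, g) {
  gf <- gene_space_features(g)
  labs <- list(); proj <- list()
  for (i in seq_len(nrow(sh$blocks))) {
    b <- sh$blocks[i, ]
    for (k in seq_len(nrow(gf$exons))) {
      e <- gf$exons[k, ]
      ov <- interval_overlap(b$g_start, b$g_end, e$gs, e$ge)
      if (ov > 0L) {
        labs[[length(labs) + 1L]] <- tibble(block = i, feature = "exon",
                                            index = e$index, overlap = ov)
        s <- max(b$g_start, e$gs); e2 <- min(b$g_end, e$ge)
        proj[[length(proj) + 1L]] <- tibble(
          block = i, exon = e$index,
          cds_start = e$cds_offset + (s - e$gs),
          cds_end = e$cds_offset + (e2 - e$gs),
          c_start = b$c_start + (s - b$g_start),
          c_end = b$c_start + (e2 - b$g_start))
      }
    }
    for (k in seq_len(nrow(gf$introns))) {
      it <- gf$introns[k, ]
      ov <- interval_overlap(b$g_start, b$g_end, it$gs, it$ge)
      if (ov > 0L)
        labs[[length(labs) + 1L]] <- tibble(block = i, feature = "intron",
                                            index = it$index, overlap = ov)
    }
  }
  sh$labels <- if (length(labs)) bind_rows(labs) else
    tibble(block = integer(), feature = character(), index = integer(),
           overlap = integer())
  sh$cds_projection <- if (length(proj)) bind_rows(proj) else
    tibble(block = integer(), exon = integer(), cds_start = integer(),
           cds_end = integer(), c_start = integer(), c_end = integer())
  sh
}

#' Classify the splice events supported by one spliced hit
#'
#' Every deviation of the hit from the annotated exon/intron structure is
#' assigned exactly one type: a block extending an exon across its donor
#' into the downstream intron is an alternative 5' splice site; across the
#' acceptor, an alternative 3' splice site; a junction spanning one or more
#' complete exons is exon skipping (one event per skipped exon); a block
#' covering an entire intron plus flanking exon sequence is intron
#' retention; a block wholly inside an intron bounded by junctions is a
#' novel exon. Hits matching the annotation exactly yield one `consistent`
#' event. Deviations that cannot be classified (extensions shorter than
#' `min_event_extension`, or truncated by the end of the hit) are reported
#' with `type = NA` and a diagnostic, never guessed.
#'
#' @param sh a converted `spliced_hit` (see [convert_coordinates()]).
#' @param g a `gene_structure`.
#' @param params a [cdna_params()] list.
#' @return tibble: `cdna_id`, `type`, `anchor_kind`, `anchor_index`,
#'   `genomic_start`, `genomic_end` (forward contig coordinates), `detail`.
#' @export
classify_events <- function(sh, g, params = cdna_params()) {
  gf <- gene_space_features(g)
  bl <- sh$blocks
  jn <- sh$junctions
  ev <- list()
  add <- function(type, kind, index, gs, ge, detail = NA_character_) {
    f <- gene_to_fwd(g, gs, ge)
    ev[[length(ev) + 1L]] <<- tibble(
      cdna_id = sh$cdna_id, type = type, anchor_kind = kind,
      anchor_index = as.integer(index), genomic_start = as.integer(f[1]),
      genomic_end = as.integer(f[2]), detail = detail)
  }
  nb <- nrow(bl)
  junction_at <- function(pos, side) {
    if (!nrow(jn)) return(FALSE)
    if (side == "left") any(jn$g_start_right == pos)
    else any(jn$g_end_left == pos)
  }
  explained <- rep(FALSE, nrow(jn))
  for (i in seq_len(nb)) {
    b <- bl[i, ]
    for (k in seq_len(nrow(gf$introns))) {
      it <- gf$introns[k, ]
      ov <- interval_overlap(b$g_start, b$g_end, it$gs, it$ge)
      if (ov == 0L) next
      inside <- b$g_start >= it$gs && b$g_end <= it$ge
      covers <- b$g_start <= it$gs && b$g_end >= it$ge
      if (covers && b$g_start < it$gs && b$g_end > it$ge) {
        add("intron_retention", "intron", k, it$gs, it$ge)
      } else if (inside) {
        bounded <- junction_at(b$g_start, "left") &&
          junction_at(b$g_end, "right")
        if (bounded) {
          add("novel_exon", "intron", k, b$g_start, b$g_end)
          explained[jn$g_start_right == b$g_start] <- TRUE
          explained[jn$g_end_left == b$g_end] <- TRUE
        } else {
          add(NA_character_, "intron", k, b$g_start, b$g_end,
              "intra-intron block truncated by the end of the hit")
        }
      } else if (b$g_start <= it$gs && b$g_end < it$ge) {
        # extension of exon k across its donor site
        extn <- b$g_end - it$gs
        ends_at_junction <- junction_at(b$g_end, "right")
        if (extn >= params$min_event_extension && ends_at_junction) {
          add("alt_5prime_splice_site", "exon", k, it$gs, b$g_end)
          explained[jn$g_end_left == b$g_end] <- TRUE
        } else {
          add(NA_character_, "exon", k, it$gs, b$g_end,
              if (extn < params$min_event_extension)
                "donor-side extension below the evidence floor"
              else "donor-side extension truncated by the end of the hit")
        }
      } else {
        # extension of exon k+1 across its acceptor site
        extn <- it$ge - b$g_start
        starts_at_junction <- junction_at(b$g_start, "left")
        if (extn >= params$min_event_extension && starts_at_junction) {
          add("alt_3prime_splice_site", "exon", k + 1L, b$g_start, it$ge)
          explained[jn$g_start_right == b$g_start] <- TRUE
        } else {
          add(NA_character_, "exon", k + 1L, b$g_start, it$ge,
              if (extn < params$min_event_extension)
                "acceptor-side extension below the evidence floor"
              else "acceptor-side extension truncated by the end of the hit")
        }
      }
    }
  }
  if (nrow(jn)) for (i in seq_len(nrow(jn))) {
    jl <- jn$g_end_left[i]; jr <- jn$g_start_right[i]
    if (any(gf$introns$gs == jl & gf$introns$ge == jr)) {
      explained[i] <- TRUE; next      # annotated intron
    }
    skipped <- gf$exons[gf$exons$gs >= jl & gf$exons$ge <= jr, ]
    if (nrow(skipped)) {
      for (k in seq_len(nrow(skipped)))
        add("exon_skipping", "exon", skipped$index[k],
            skipped$gs[k], skipped$ge[k])
      explained[i] <- TRUE
      next
    }
    if (explained[i]) next            # endpoint claimed by an extension /
                                      # novel-exon event above
    # endpoints at annotated boundaries do not need an event of their own
    end_ok <- any(gf$introns$gs == jl)
    start_ok <- any(gf$introns$ge == jr)
    if (!(end_ok && start_ok))
      add(NA_character_, "intron", NA_integer_, jl, jr,
          "junction matches no annotated intron")
  }
  evt <- if (length(ev)) bind_rows(ev) else NULL
  # deviations below the evidence floor are alignment slop: they are kept
  # as diagnostics but do not contradict consistency with the annotation
  substantive <- !is.null(evt) && nrow(evt) && {
    det <- ifelse(is.na(evt$detail), "", evt$detail)
    any(!is.na(evt$type) | !grepl("below the evidence floor", det))
  }
  if (!substantive) {
    sp <- c(0L, gf$span[2] - gf$span[1])
    f <- gene_to_fwd(g, sp[1], sp[2])
    evt <- bind_rows(evt,
      tibble(cdna_id = sh$cdna_id, type = "consistent",
             anchor_kind = "gene", anchor_index = NA_integer_,
             genomic_start = f[1], genomic_end = f[2],
             detail = NA_character_))
  } else {
    evt <- evt[!duplicated(evt[c("type", "anchor_kind", "anchor_index",
                                 "genomic_start", "genomic_end")]), ]
  }
  evt
}

#' Call synonymous / non-synonymous substitutions from a spliced hit
#'
#' Each cDNA/genome mismatch inside a fully covered codon of an exonic
#' block yields one substitution with its effect under the gene's codon
#' table; mismatches in codons split by block edges are reported without
#' an effect call.
#'
#' @param sh a converted `spliced_hit`.
#' @param g a `gene_structure`.
#' @param contig contig sequence.
#' @param cdna_seq the cDNA sequence (in the hit's orientation).
#' @return tibble: `cdna_id`, `cds_pos` (0-based), `codon_index` (1-based),
#'   `ref_codon`, `alt_codon`, `effect` (`synonymous`, `nonsynonymous`, or
#'   `NA` for split codons).
#' @export
call_substitutions <- function(sh, g, contig, cdna_seq) {
  cds <- unname(gs_cds(g, contig))
  gc <- codon_table(g$codon_table)
  cv <- chars(cdna_seq)
  cdsv <- chars(cds)
  pr <- sh$cds_projection
  if (is.null(pr) || !nrow(pr)) return(tibble(
    cdna_id = character(), cds_pos = integer(), codon_index = integer(),
    ref_codon = character(), alt_codon = character(), effect = character()))
  # per-base CDS coverage and cdna base at each covered CDS position
  cov <- rep(NA_integer_, nchar(cds))
  for (i in seq_len(nrow(pr))) {
    p <- pr[i, ]
    idx <- seq.int(p$cds_start + 1L, p$cds_end)
    cov[idx] <- p$c_start + seq_along(idx)
  }
  mm <- which(!is.na(cov) & cv[cov] != cdsv)
  rows <- list()
  for (pos in mm) {
    ci <- (pos - 1L) %/% 3L
    cidx <- seq.int(3L * ci + 1L, 3L * ci + 3L)
    ref <- str_from(cdsv[cidx])
    if (all(!is.na(cov[cidx]))) {
      altv <- cv[cov[cidx]]
      alt <- str_from(altv)
      effect <- if (identical(unname(gc[ref]), unname(gc[alt])))
        "synonymous" else "nonsynonymous"
    } else {
      alt <- NA_character_; effect <- NA_character_
    }
    rows[[length(rows) + 1L]] <- tibble(
      cdna_id = sh$cdna_id, cds_pos = pos - 1L, codon_index = ci + 1L,
      ref_codon = ref, alt_codon = alt, effect = effect)
  }
  if (length(rows)) bind_rows(rows) else tibble(
    cdna_id = character(), cds_pos = integer(), codon_index = integer(),
    ref_codon = character(), alt_codon = character(), effect = character())
}

#' Merged CDS coverage of a set of spliced hits
#'
#' Per-base union of all exonic block projections (the "merged scheme"
#' overview of which query regions carry cDNA evidence).
#'
#' @param hits list of converted `spliced_hit` objects.
#' @param g a `gene_structure`.
#' @param contig contig sequence.
#' @return list with `profile` (tibble of covered CDS intervals) and
#'   `fraction` (covered fraction of the CDS).
#' @export
merge_coverage <- function(hits, g, contig) {
  cds_len <- nchar(gs_cds(g, contig))
  cov <- rep(FALSE, cds_len)
  for (sh in hits) {
    pr <- sh$cds_projection
    if (is.null(pr)) next
    for (i in seq_len(nrow(pr)))
      cov[seq.int(pr$cds_start[i] + 1L, pr$cds_end[i])] <- TRUE
  }
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  profile <- tibble(cds_start = starts[r$values], cds_end = ends[r$values])
  list(profile = profile, fraction = mean(cov))
}

#' Full two-step cDNA analysis of a reconstructed gene
#'
#' Convenience driver: step-1 filtering, step-2 spliced mapping, coordinate
#' conversion, event classification, substitution calls and merged
#' coverage.
#'
#' @param cdnas tibble `id`/`seq`.
#' @param g a `gene_structure`.
#' @param contig contig sequence.
#' @param target_space step-1 target space.
#' @param params a [cdna_params()] list.
#' @return list with `hits` (converted spliced hits), `events`,
#'   `substitutions` (tibbles) and `coverage` (see [merge_coverage()]).
#' @export
map_cdnas <- function(cdnas, g, contig, target_space = "cds",
                      params = cdna_params()) {
  s1 <- map_step1(cdnas, g, contig, target_space, params)
  s2 <- map_step2(s1, cdnas, g, contig, params)
  s2 <- lapply(s2, convert_coordinates, g = g)
  events <- bind_rows(lapply(s2, classify_events, g = g, params = params))
  subs <- bind_rows(lapply(s2, function(sh) {
    sq <- cdnas$seq[match(sh$cdna_id, cdnas$id)]
    if (sh$orientation == "-") sq <- reverse_complement(sq)
    call_substitutions(sh, g, contig, sq)
  }))
  list(hits = s2, events = events, substitutions = subs,
       coverage = merge_coverage(s2, g, contig))
}
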