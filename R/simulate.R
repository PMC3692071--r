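# Deterministic synthetic-locus generator. Every fixture used by the tests
# and the acceptance analyses is produced here from a seed: a random gene
# (exons cut at arbitrary CDS positions, GT..AG introns, random flanks)
# with a ground-truth gene_structure, plus planted discrepancies, splice
# variants, MXE candidates and tandem duplicates. Sub-steps draw from
# forked seeds so adding a feature never perturbs earlier draws.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  code
}

# sample one element of a vector (avoids the scalar expansion of sample())
sample1 <- function(v) v[sample.int(length(v), 1L)]

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

rand_dna <- function(n, gc = 0.45) {
  if (n <= 0L) return("")
  paste0(sample(c("A","T","G","C"), n, replace = TRUE,
                prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
         collapse = "")
}

# codon -> aa and aa -> codons for one genetic code
rev_codon_table <- function(table_id) {
  gc <- codon_table(table_id)
  split(names(gc), unname(gc))
}

encode_protein <- function(aa_vec, rct) {
  vapply(aa_vec, function(a) {
    cs <- rct[[a]]
    sample1(cs)
  }, "")
}

#' Fixture specification
#'
#' Parameters of one synthetic locus. The same spec (seed included) always
#' produces byte-identical output.
#'
#' @param seed master seed; all randomness forks from it.
#' @param n_exons number of exons.
#' @param exon_len nt length range of exons (cut points may split codons).
#' @param exon_lens explicit exon lengths in nt (overrides `exon_len`).
#' @param intron_len nt length range of introns.
#' @param gc GC content of introns and flanks.
#' @param flank_len nt of random sequence on each side of the gene.
#' @param codon_table NCBI genetic-code table id.
#' @param codon_aligned force all exon boundaries onto codon boundaries
#'   (required when planting micro-exons).
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_exons = 5L, exon_len = c(60L, 300L),
                         intron_len = c(30L, 2000L), gc = 0.45,
                         flank_len = 400L, codon_table = 1L,
                         codon_aligned = FALSE, exon_lens = NULL) {
  stopifnot(n_exons >= 1L, all(exon_len >= 3L), all(intron_len >= 22L),
            gc > 0, gc < 1)
  if (!is.null(exon_lens)) {
    stopifnot(length(exon_lens) == n_exons, all(exon_lens >= 3L))
    exon_lens <- as.integer(exon_lens)
  }
  structure(list(seed = as.integer(seed), n_exons = as.integer(n_exons),
                 exon_len = as.integer(exon_len), exon_lens = exon_lens,
                 intron_len = as.integer(intron_len), gc = gc,
                 flank_len = as.integer(flank_len),
                 codon_table = as.integer(codon_table),
                 codon_aligned = isTRUE(codon_aligned)),
            class = "fixture_spec")
}

# alternative intron placements that would tie with the truth during
# boundary refinement: intron slid by x with a valid splice pair and an
# identical spliced translation (synonymous slides count). Direct string
# construction, independent of the refinement code.
boundary_ambiguous <- function(w, we, ws, gc, window = 96L) {
  ref <- fast_translate(paste0(substr(w, 1L, we),
                               substr(w, ws + 1L, nchar(w))), gc)
  for (x in seq.int(-window, window)) {
    if (x == 0L) next
    if (we + x < 2L || ws + x + 2L > nchar(w)) next
    d <- substr(w, we + x + 1L, we + x + 2L)
    a <- substr(w, ws + x - 1L, ws + x)
    if (!(d %in% c("GT", "GC") && a == "AG")) next
    alt <- fast_translate(paste0(substr(w, 1L, we + x),
                                 substr(w, ws + x + 1L, nchar(w))), gc)
    if (alt == ref) return(TRUE)
  }
  FALSE
}

#' Generate a synthetic locus with known ground truth
#'
#' A random protein is encoded as a CDS, cut into exons, interleaved with
#' GT..AG introns and embedded in random flanks. Intron boundaries are
#' re-drawn until no alternative sliding placement with a valid splice pair
#' exists, so the planted structure is the unique exact reconstruction.
#'
#' @param spec a [fixture_spec()].
#' @return list with `contig` (string), `truth` (a `gene_structure`),
#'   `protein` (query string) and `spec`.
#' @export
make_locus <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    n <- spec$n_exons
    if (!is.null(spec$exon_lens)) {
      lens <- spec$exon_lens
    } else if (length(spec$exon_len) == 2L) {
      lens <- sample(seq.int(spec$exon_len[1], spec$exon_len[2]), n,
                     replace = TRUE)
      if (spec$exon_len[1] == spec$exon_len[2]) lens <- rep(spec$exon_len[1], n)
    } else {
      lens <- rep(spec$exon_len[1], n)
    }
    if (spec$codon_aligned) lens <- pmax(3L, (lens %/% 3L) * 3L)
    r <- sum(lens) %% 3L
    if (r != 0L) lens[length(lens)] <- lens[length(lens)] + (3L - r)
    total_aa <- sum(lens) %/% 3L
    if (total_aa < 5L) stopf("infeasible spec: CDS shorter than 5 codons")
    rct <- rev_codon_table(spec$codon_table)
    prot <- c("M", sample(AA20, total_aa - 1L, replace = TRUE))
    cds <- paste0(encode_protein(prot, rct), collapse = "")
    cuts <- cumsum(lens)
    exon_seqs <- substring(cds, c(1L, head(cuts, -1L) + 1L), cuts)
    n_int <- n - 1L
    intron_seqs <- character(n_int)
    gc_tab <- codon_table(spec$codon_table)
    if (n_int > 0L) {
      irange <- seq.int(spec$intron_len[1], spec$intron_len[2])
      ilens <- irange[sample.int(length(irange), n_int, replace = TRUE)]
      for (i in seq_len(n_int)) {
        # probe includes enough coding context for split-codon translation
        left <- paste0(exon_seqs[seq_len(i)], collapse = "")
        right <- paste0(exon_seqs[seq.int(i + 1L, n)], collapse = "")
        for (try in 1:50) {
          body <- rand_dna(ilens[i] - 4L, spec$gc)
          intron_seqs[i] <- paste0("GT", body, "AG")
          probe <- paste0(left, intron_seqs[i], right)
          we <- nchar(left)
          ws <- we + ilens[i]
          if (!boundary_ambiguous(probe, we, ws, gc_tab)) break
          if (try == 50L) stopf("could not disambiguate intron %d", i)
        }
      }
    }
    f5 <- rand_dna(spec$flank_len, spec$gc)
    f3 <- rand_dna(spec$flank_len, spec$gc)
    pieces <- character(0)
    for (i in seq_len(n)) {
      pieces <- c(pieces, exon_seqs[i])
      if (i <= n_int) pieces <- c(pieces, intron_seqs[i])
    }
    contig <- paste0(f5, paste0(pieces, collapse = ""), f3)
    starts <- integer(n); ends <- integer(n)
    pos <- nchar(f5)
    for (i in seq_len(n)) {
      starts[i] <- pos; pos <- pos + nchar(exon_seqs[i]); ends[i] <- pos
      if (i <= n_int) pos <- pos + nchar(intron_seqs[i])
    }
    protein <- paste0(prot, collapse = "")
    truth <- gene_structure(query_id = sprintf("synthetic_%d", spec$seed),
                            query = protein, contig_id = "contig_1",
                            strand = "+",
                            exons = tibble(start = starts, end = ends),
                            codon_table = spec$codon_table, contig = contig)
    list(contig = contig, truth = truth, protein = protein, spec = spec)
  })
}

# ---- planted discrepancies --------------------------------------------------

# positions (1-based aa) whose codon sits entirely inside one exon, at least
# `margin` nt from both exon edges and from any previous pick
safe_codon_positions <- function(truth, margin = 9L) {
  ex <- truth$exons
  out <- integer(0)
  for (i in seq_len(nrow(ex))) {
    off <- ex$cds_offset[i]; len <- ex$end[i] - ex$start[i]
    lo <- off + margin; hi <- off + len - margin - 3L
    if (hi < lo) next
    p1 <- (lo + 2L) %/% 3L + 1L
    p2 <- hi %/% 3L
    if (p2 >= p1) out <- c(out, seq.int(p1, p2))
  }
  out[out > 1L]
}

#' Plant typed discrepancies into a locus
#'
#' Applies point mutations (non-synonymous), in-frame stops and 1-2 nt
#' indels to the contig at positions safely inside exons, returning the
#' edited contig and a truth table of the expected discrepancy calls.
#' Coordinates of the truth gene are adjusted for indels.
#'
#' @param locus output of [make_locus()].
#' @param n_mismatch,n_stop,n_ins,n_del counts of each edit type.
#' @param seed seed for the edit draws.
#' @param indel_margin smallest distance (nt) between an indel and an exon
#'   edge. A 1-2 nt indel closer to a splice site than the boundary-search
#'   window cannot be distinguished from an alternative boundary placement
#'   with the same translation, so indels are planted in the exon interior.
#' @return list with `contig`, `truth` (coordinates updated) and `events`
#'   (tibble `kind`, `protein_pos`).
#' @export
plant_discrepancies <- function(locus, n_mismatch = 0L, n_stop = 0L,
                                n_ins = 0L, n_del = 0L, seed = 1L,
                                indel_margin = 60L) {
  with_seed(fork_seed(seed, 7L), {
    truth <- locus$truth; contig <- locus$contig
    rct <- rev_codon_table(truth$codon_table)
    total <- n_mismatch + n_stop + n_ins + n_del
    n_indel <- n_ins + n_del
    pool <- safe_codon_positions(truth)
    pool_indel <- safe_codon_positions(truth, margin = indel_margin)
    if (!length(pool_indel) && n_indel > 0L)
      stopf("no exon interior wide enough for indels")
    # keep picks >= 5 codons apart so edits never interact; indels draw
    # from the interior pool
    kinds <- c(rep("ins", n_ins), rep("del", n_del),
               rep("mismatch", n_mismatch), rep("inframe_stop", n_stop))
    pool <- pool[sample.int(length(pool))]
    pool_indel <- pool_indel[sample.int(length(pool_indel))]
    picks <- integer(0)
    for (k in seq_along(kinds)) {
      src <- if (kinds[k] %in% c("ins", "del")) pool_indel else pool
      found <- FALSE
      for (p in src) {
        if (!length(picks) || min(abs(picks - p)) >= 5L) {
          picks <- c(picks, p); found <- TRUE; break
        }
      }
      if (!found) stopf("locus too small for requested edits")
    }
    # apply right-to-left so earlier coordinates stay valid
    ord <- order(picks, decreasing = TRUE)
    events <- list()
    for (k in ord) {
      p <- picks[k]; kind <- kinds[k]
      iv <- protein_to_genomic(truth, p)   # single interval by construction
      cs <- iv$start[1]
      cur <- substr(contig, cs + 1L, cs + 3L)
      if (kind == "mismatch") {
        cur_aa <- fast_translate(cur, codon_table(truth$codon_table))
        new_aa <- sample1(setdiff(AA20, cur_aa))
        newc <- sample1(rct[[new_aa]])
        contig <- paste0(substr(contig, 1L, cs), newc,
                         substr(contig, cs + 4L, nchar(contig)))
        events[[length(events) + 1L]] <- tibble(kind = "mismatch",
                                                protein_pos = p)
      } else if (kind == "inframe_stop") {
        contig <- paste0(substr(contig, 1L, cs), "TAA",
                         substr(contig, cs + 4L, nchar(contig)))
        events[[length(events) + 1L]] <- tibble(kind = "inframe_stop",
                                                protein_pos = p)
      } else if (kind == "ins") {
        klen <- sample1(1:2)
        ins <- rand_dna(klen, 0.5)
        contig <- paste0(substr(contig, 1L, cs + 1L), ins,
                         substr(contig, cs + 2L, nchar(contig)))
        truth <- shift_gene_coords(truth, cs + 1L, klen, contig)
        events[[length(events) + 1L]] <- tibble(kind = "sequence_shift",
                                                protein_pos = p)
      } else {
        klen <- sample1(1:2)
        contig <- paste0(substr(contig, 1L, cs + 1L),
                         substr(contig, cs + 2L + klen, nchar(contig)))
        truth <- shift_gene_coords(truth, cs + 1L, -klen, contig)
        events[[length(events) + 1L]] <- tibble(kind = "sequence_shift",
                                                protein_pos = p)
      }
    }
    list(contig = contig, truth = truth,
         events = arrange(bind_rows(events), protein_pos))
  })
}

# shift all truth coordinates at/after pos by delta and rebuild
shift_gene_coords <- function(truth, pos, delta, contig) {
  ex <- truth$exons
  ex$start <- ifelse(ex$start > pos, ex$start + delta, ex$start)
  ex$end <- ifelse(ex$end > pos, ex$end + delta, ex$end)
  gene_structure(truth$query_id, truth$query, truth$contig_id, truth$strand,
                 tibble(start = as.integer(ex$start), end = as.integer(ex$end)),
                 discrepancies = truth$discrepancies,
                 codon_table = truth$codon_table, contig = contig)
}

#' Mutate a protein to a target identity
#'
#' Each residue (except the initial M) is replaced with a different random
#' amino acid with probability `1 - identity`; emulates a cross-species
#' query.
#'
#' @param protein protein string.
#' @param identity target fraction of identical residues.
#' @param seed seed.
#' @param avoid residue positions exempt from mutation (e.g. the
#'   junction-adjacent codons from [junction_residues()], whose mutation
#'   can make the planted boundary genuinely non-identifiable).
#' @return mutated protein string.
#' @export
mutate_protein <- function(protein, identity, seed = 1L, avoid = integer(0)) {
  with_seed(fork_seed(seed, 11L), {
    v <- chars(protein)
    hit <- which(runif(length(v)) > identity)
    hit <- setdiff(hit[hit > 1L], avoid)
    for (i in hit) v[i] <- sample1(setdiff(AA20, v[i]))
    str_from(v)
  })
}

#' Residues whose codons lie near a splice junction
#'
#' @param g a `gene_structure`.
#' @param margin codons on each side of every exon boundary.
#' @return sorted integer vector of 1-based residue positions.
#' @export
junction_residues <- function(g, margin = 2L) {
  ex <- g$exons
  out <- integer(0)
  for (i in seq_len(nrow(ex))) {
    for (off in c(ex$cds_offset[i],
                  ex$cds_offset[i] + gs_exon_cds_len(g, i))) {
      p <- off %/% 3L + 1L
      out <- c(out, seq.int(p - margin, p + margin))
    }
  }
  sort(unique(out[out >= 1L & out <= nchar(g$query)]))
}

# ---- EST / cDNA simulation --------------------------------------------------

# transcript sequence + per-base forward genomic coordinates for a variant
variant_transcript <- function(truth, contig, variant = NULL) {
  ex <- truth$exons
  pieces <- list()
  add <- function(s, e) pieces[[length(pieces) + 1L]] <<- seq.int(s, e - 1L)
  n <- nrow(ex)
  for (i in seq_len(n)) {
    if (!is.null(variant) && variant$type == "exon_skipping" &&
        variant$anchor == i) next
    if (!is.null(variant) && variant$type == "alt_3prime_splice_site" &&
        variant$anchor == i)
      add(truth$introns$end[i - 1L] - variant$s, truth$introns$end[i - 1L])
    add(ex$start[i], ex$end[i])
    if (!is.null(variant) && variant$type == "alt_5prime_splice_site" &&
        variant$anchor == i)
      add(truth$introns$start[i], truth$introns$start[i] + variant$s)
    if (!is.null(variant) && variant$type == "intron_retention" &&
        variant$anchor == i && i <= nrow(truth$introns))
      add(truth$introns$start[i], truth$introns$end[i])
    if (!is.null(variant) && variant$type == "novel_exon" &&
        variant$anchor == i && i <= nrow(truth$introns))
      add(variant$a, variant$b)
  }
  gpos <- unlist(pieces)
  cv <- chars(contig)
  list(seq = str_from(cv[gpos + 1L]), gpos = gpos)
}

#' Simulate an EST/cDNA set with planted splice variants
#'
#' Builds variant transcripts for the requested events (planting the
#' necessary GT/AG dinucleotides in the contig), samples reads that fully
#' cover each event with margins, and optionally adds unmatched adapter
#' tails and uniform per-base noise. Returns the edited contig, the reads
#' and a per-read truth table.
#'
#' @param truth a plus-strand `gene_structure` from [make_locus()].
#' @param contig its contig.
#' @param events tibble with columns `type` (one of the five variant
#'   types), `anchor` (exon index for alt5/skip; exon index following the
#'   intron for alt3; intron index for retention/novel), and optional
#'   `shift` (nt, alt sites) and `novel_len`.
#' @param n_consistent reads drawn from the unmodified transcript.
#' @param n_per_event reads supporting each event.
#' @param est_len read length range.
#' @param noise per-base substitution probability.
#' @param adapter_prob probability of an unmatched 25-nt adapter tail on
#'   each end of a read.
#' @param focus_margin nt of flanking transcript guaranteed on each side of
#'   a planted event in its supporting reads.
#' @param seed seed.
#' @return list with `contig` (possibly edited), `ests` (tibble `id`,
#'   `seq`) and `truth_events` (tibble `est_id`, `type`, `anchor_kind`,
#'   `anchor_index`).
#' @export
make_ests <- function(truth, contig, events = NULL, n_consistent = 3L,
                      n_per_event = 2L, est_len = c(150L, 400L),
                      noise = 0, adapter_prob = 0, focus_margin = 60L,
                      seed = 1L) {
  stopifnot(truth$strand == "+")
  with_seed(fork_seed(seed, 23L), {
    n_ex <- nrow(truth$exons)
    variants <- list()
    if (!is.null(events) && nrow(events)) {
      for (k in seq_len(nrow(events))) {
        ev <- events[k, ]
        type <- ev$type
        if (type %in% c("exon_skipping") &&
            (n_ex < 3L || ev$anchor %in% c(1L, n_ex)))
          stopf("cannot skip a terminal exon")
        if (type == "alt_5prime_splice_site") {
          s <- ev$shift %||% 12L
          it <- truth$introns[ev$anchor, ]
          if (it$end - it$start < s + 30L) stopf("intron too short for shift")
          pos <- it$start + s
          contig <- paste0(substr(contig, 1L, pos), "GT",
                           substr(contig, pos + 3L, nchar(contig)))
          variants[[k]] <- list(type = type, anchor = ev$anchor, s = s,
                                region = c(it$start, it$start + s),
                                anchor_kind = "exon")
        } else if (type == "alt_3prime_splice_site") {
          s <- ev$shift %||% 12L
          it <- truth$introns[ev$anchor - 1L, ]
          if (it$end - it$start < s + 30L) stopf("intron too short for shift")
          pos <- it$end - s - 2L
          contig <- paste0(substr(contig, 1L, pos), "AG",
                           substr(contig, pos + 3L, nchar(contig)))
          variants[[k]] <- list(type = type, anchor = ev$anchor, s = s,
                                region = c(it$end - s, it$end),
                                anchor_kind = "exon")
        } else if (type == "exon_skipping") {
          # focus on the novel junction (the skipped exon is absent from the
          # variant transcript, so the read must span its flanking exons)
          variants[[k]] <- list(
            type = type, anchor = ev$anchor,
            region = c(truth$exons$end[ev$anchor - 1L] - 10L,
                       truth$exons$start[ev$anchor + 1L] + 10L),
            anchor_kind = "exon")
        } else if (type == "intron_retention") {
          it <- truth$introns[ev$anchor, ]
          variants[[k]] <- list(type = type, anchor = ev$anchor,
                                region = c(it$start, it$end),
                                anchor_kind = "intron")
        } else if (type == "novel_exon") {
          it <- truth$introns[ev$anchor, ]
          l <- ev$novel_len %||% 60L
          if (it$end - it$start < l + 120L) stopf("intron too short for novel exon")
          a <- it$start + (it$end - it$start - l) %/% 2L
          b <- a + l
          contig <- paste0(substr(contig, 1L, a - 2L), "AG",
                           substr(contig, a + 1L, b), "GT",
                           substr(contig, b + 3L, nchar(contig)))
          variants[[k]] <- list(type = type, anchor = ev$anchor, a = a, b = b,
                                region = c(a, b), anchor_kind = "intron")
        } else stopf("unknown event type: %s", type)
      }
    }
    reads <- list(); truth_rows <- list()
    rid <- 0L
    sample_read <- function(tx, focus = NULL) {
      len <- sample1(seq.int(est_len[1], est_len[2]))
      n <- nchar(tx$seq)
      len <- min(len, n)
      if (is.null(focus)) {
        s <- sample.int(max(1L, n - len + 1L), 1L)
      } else {
        # transcript positions of the focus genomic region, with margins
        inreg <- which(tx$gpos >= focus[1] & tx$gpos < focus[2])
        lo <- max(1L, min(inreg) - focus_margin)
        hi <- min(n, max(inreg) + focus_margin)
        need <- hi - lo + 1L
        len <- max(len, need)
        len <- min(len, n)
        smin <- max(1L, hi - len + 1L); smax <- min(lo, n - len + 1L)
        if (smax < smin) s <- max(1L, min(lo, n - len + 1L))
        else s <- sample1(seq.int(smin, smax))
      }
      substr(tx$seq, s, s + len - 1L)
    }
    add_read <- function(sq, rows) {
      rid <<- rid + 1L
      id <- sprintf("est_%03d", rid)
      if (adapter_prob > 0) {
        if (runif(1) < adapter_prob) sq <- paste0(rand_dna(25L, 0.5), sq)
        if (runif(1) < adapter_prob) sq <- paste0(sq, rand_dna(25L, 0.5))
      }
      if (noise > 0) {
        v <- chars(sq)
        hit <- which(runif(length(v)) < noise)
        for (i in hit) v[i] <- sample(setdiff(c("A","C","G","T"), v[i]), 1L)
        sq <- str_from(v)
      }
      reads[[rid]] <<- tibble(id = id, seq = sq)
      for (r in rows)
        truth_rows[[length(truth_rows) + 1L]] <<-
          mutate(r, est_id = id)
    }
    base_tx <- variant_transcript(truth, contig)
    for (i in seq_len(n_consistent))
      add_read(sample_read(base_tx),
               list(tibble(type = "consistent", anchor_kind = "gene",
                           anchor_index = NA_integer_)))
    for (v in variants) {
      tx <- variant_transcript(truth, contig, v)
      for (i in seq_len(n_per_event))
        add_read(sample_read(tx, focus = v$region),
                 list(tibble(type = v$type, anchor_kind = v$anchor_kind,
                             anchor_index = v$anchor)))
    }
    list(contig = contig, ests = bind_rows(reads),
         truth_events = bind_rows(truth_rows))
  })
}

# ---- planted MXE candidates and tandem duplicates ---------------------------

# mutate the in-frame codons of a coding fragment to a target protein
# identity, keeping partial codons at the edges verbatim
mutate_coding_fragment <- function(s, phase, identity, table_id, rct) {
  head_nt <- (3L - phase) %% 3L
  body_len <- ((nchar(s) - head_nt) %/% 3L) * 3L
  body <- substr(s, head_nt + 1L, head_nt + body_len)
  tail <- substr(s, head_nt + body_len + 1L, nchar(s))
  aa <- fast_translate_v(body, codon_table(table_id))
  codons <- substring(body, 3L * (seq_along(aa) - 1L) + 1L, 3L * seq_along(aa))
  hit <- which(runif(length(aa)) > identity & aa != "*")
  for (i in hit) {
    new_aa <- sample1(setdiff(AA20, aa[i]))
    codons[i] <- sample1(rct[[new_aa]])
  }
  paste0(substr(s, 1L, head_nt), paste0(codons, collapse = ""), tail)
}

#' Plant a mutually exclusive exon candidate into an intron
#'
#' Inserts a similarity-controlled copy of a chosen exon (with AG/GT
#' flanks) into the middle of a chosen intron, shifting all downstream
#' truth coordinates.
#'
#' @param truth plus-strand `gene_structure`.
#' @param contig its contig.
#' @param exon_index source exon to copy.
#' @param intron_index intron that receives the candidate.
#' @param identity protein-level identity dial of the copy.
#' @param codon_delta change of candidate length in codons (keeps frame).
#' @param seed seed.
#' @return list with `contig`, `truth` (shifted) and `mxe` (tibble
#'   `source_exon`, `start`, `end`, `identity` (the dial) and
#'   `realized_identity` (the copy's actual translated identity)).
#' @export
plant_mxe <- function(truth, contig, exon_index, intron_index,
                      identity = 1.0, codon_delta = 0L, seed = 1L) {
  with_seed(fork_seed(seed, 31L), {
    rct <- rev_codon_table(truth$codon_table)
    e <- truth$exons[exon_index, ]
    src <- subseq0(contig, e$start, e$end)
    cand <- mutate_coding_fragment(src, e$phase, identity,
                                   truth$codon_table, rct)
    # realised protein identity of the copy (the dial has sampling noise)
    gc_tab <- codon_table(truth$codon_table)
    head_nt0 <- (3L - e$phase) %% 3L
    body_len0 <- ((nchar(src) - head_nt0) %/% 3L) * 3L
    aa_src <- fast_translate_v(substr(src, head_nt0 + 1L,
                                      head_nt0 + body_len0), gc_tab)
    aa_cand <- fast_translate_v(substr(cand, head_nt0 + 1L,
                                       head_nt0 + body_len0), gc_tab)
    realized <- mean(aa_src == aa_cand)
    if (codon_delta != 0L) {
      head_nt <- (3L - e$phase) %% 3L
      if (codon_delta > 0L) {
        ins <- paste0(encode_protein(sample(AA20, codon_delta, TRUE), rct),
                      collapse = "")
        cand <- paste0(substr(cand, 1L, head_nt + 3L), ins,
                       substr(cand, head_nt + 4L, nchar(cand)))
      } else {
        k <- -3L * codon_delta
        cand <- paste0(substr(cand, 1L, head_nt),
                       substr(cand, head_nt + k + 1L, nchar(cand)))
      }
    }
    it <- truth$introns[intron_index, ]
    if (it$end - it$start < nchar(cand) + 120L)
      stopf("intron %d too short for an MXE candidate", intron_index)
    pos <- it$start + (it$end - it$start - nchar(cand)) %/% 2L
    block <- paste0("AG", cand, "GT")
    contig2 <- paste0(substr(contig, 1L, pos), block,
                      substr(contig, pos + 1L, nchar(contig)))
    truth2 <- shift_gene_coords(truth, pos, nchar(block), contig2)
    list(contig = contig2, truth = truth2,
         mxe = tibble(source_exon = exon_index,
                      start = pos + 2L, end = pos + 2L + nchar(cand),
                      identity = identity,
                      realized_identity = realized))
  })
}

#' Plant a tandemly arrayed gene duplicate
#'
#' Copies the full gene region (optionally at reduced protein identity,
#' with one intron deleted to create a fused exon or one extra intron
#' inserted to create split exons) into the flank at a given distance, on
#' either strand.
#'
#' @param truth plus-strand `gene_structure`.
#' @param contig its contig.
#' @param side `"down"` or `"up"`.
#' @param distance nt between the gene span and the inserted copy.
#' @param identity protein-level identity dial.
#' @param strand strand of the inserted copy.
#' @param fuse_intron intron index deleted in the copy (or `NULL`).
#' @param split_exon exon index receiving an extra intron (or `NULL`).
#' @param seed seed.
#' @return list with `contig`, `truth` (shifted if upstream) and
#'   `duplicate` (tibble `start`, `end`, `strand`, `identity`, `relation`).
#' @export
plant_duplicate <- function(truth, contig, side = "down", distance = 500L,
                            identity = 1.0, strand = "+", fuse_intron = NULL,
                            split_exon = NULL, seed = 1L) {
  with_seed(fork_seed(seed, 43L), {
    rct <- rev_codon_table(truth$codon_table)
    ex <- truth$exons
    n <- nrow(ex)
    cds <- gs_cds(truth, contig)
    cds2 <- mutate_coding_fragment(cds, 0L, identity, truth$codon_table, rct)
    lens <- ex$end - ex$start
    cuts <- cumsum(lens)
    exon_seqs <- substring(cds2, c(1L, head(cuts, -1L) + 1L), cuts)
    intron_seqs <- vapply(seq_len(max(n - 1L, 0L)), function(i)
      gs_intron_seq(truth, contig, i), "")
    if (!is.null(split_exon)) {
      es <- exon_seqs[split_exon]
      cut <- nchar(es) %/% 2L
      newint <- paste0("GT", rand_dna(76L, 0.45), "AG")
      exon_seqs <- append(exon_seqs[-split_exon],
                          c(substr(es, 1L, cut),
                            substr(es, cut + 1L, nchar(es))),
                          after = split_exon - 1L)
      intron_seqs <- append(intron_seqs, newint, after = split_exon - 1L)
    }
    if (!is.null(fuse_intron)) {
      fi <- fuse_intron + if (!is.null(split_exon) &&
                              split_exon <= fuse_intron) 1L else 0L
      exon_seqs <- append(exon_seqs[-c(fi, fi + 1L)],
                          paste0(exon_seqs[fi], exon_seqs[fi + 1L]),
                          after = fi - 1L)
      intron_seqs <- intron_seqs[-fi]
    }
    dup <- character(0)
    for (i in seq_along(exon_seqs)) {
      dup <- c(dup, exon_seqs[i])
      if (i <= length(intron_seqs)) dup <- c(dup, intron_seqs[i])
    }
    dup <- paste0(dup, collapse = "")
    if (strand == "-") dup <- reverse_complement(dup)
    sp <- gene_span(truth)
    if (side == "down") {
      pos <- sp[2] + distance
      if (pos + nchar(dup) > nchar(contig))
        stopf("downstream flank too short for duplicate")
      contig2 <- paste0(substr(contig, 1L, pos), dup,
                        substr(contig, pos + 1L, nchar(contig)))
      truth2 <- truth
    } else {
      # insertion shifts the gene right by nchar(dup), so inserting at
      # sp[1] - distance leaves exactly `distance` nt between the copy and
      # the (shifted) gene start
      pos <- sp[1] - distance
      if (pos - nchar(dup) < 0L) stopf("upstream flank too short for duplicate")
      contig2 <- paste0(substr(contig, 1L, pos), dup,
                        substr(contig, pos + 1L, nchar(contig)))
      truth2 <- shift_gene_coords(truth, pos, nchar(dup), contig2)
    }
    relation <- if (!is.null(fuse_intron)) "fused"
                else if (!is.null(split_exon)) "split" else "one_to_one"
    list(contig = contig2, truth = truth2,
         duplicate = tibble(start = as.integer(pos),
                            end = as.integer(pos + nchar(dup)),
                            strand = strand, identity = identity,
                            relation = relation,
                            anchor = fuse_intron %||% split_exon %||%
                              NA_integer_))
  })
}
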