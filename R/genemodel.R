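#' Gene-structure objects
#'
#' A `gene_structure` is the central container of the package: the ordered
#' exons and introns of one protein query reconstructed on one genomic
#' contig, together with typed discrepancies between the query and the
#' target translation. Coordinates are 0-based, half-open, on the forward
#' strand of the contig; exon/intron `index` runs in gene order (on the
#' minus strand, exon 1 has the highest forward coordinates).
#'
#' Discrepancy kinds are exactly `mismatch`, `sequence_shift`,
#' `inframe_stop` and `unmatched`. A `sequence_shift` carries a signed
#' `shift`: positive = extra genomic bases inside an exon that are excluded
#' from the CDS, negative = missing genomic bases, padded with `N` in the
#' assembled CDS so downstream codons stay in frame.
#'
#' @param query_id,query protein query identifier and sequence.
#' @param contig_id contig identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons tibble with columns `start`, `end` (0-based half-open,
#'   forward strand), ordered in gene order. `index`, `cds_offset` and
#'   `phase` are computed if absent.
#' @param introns optional tibble; derived from the exon gaps and `contig`
#'   when `NULL`.
#' @param discrepancies tibble with columns `kind`, `protein_start`,
#'   `protein_end`, `genomic_start`, `genomic_end`, `shift`, `detail`.
#' @param codon_table NCBI genetic-code table id.
#' @param contig contig sequence, required when introns are derived.
#' @return an object of class `gene_structure`.
#' @export
gene_structure <- function(query_id, query, contig_id, strand, exons,
                           introns = NULL, discrepancies = empty_discrepancies(),
                           codon_table = 1L, contig = NULL) {
  stopifnot(strand %in% c("+", "-"))
  query <- clean_protein(query, query_id)
  exons <- as_tibble(exons)
  stopifnot(all(c("start", "end") %in% names(exons)), nrow(exons) >= 1L)
  exons$start <- as.integer(exons$start); exons$end <- as.integer(exons$end)
  if (any(exons$end <= exons$start)) stopf("exon with non-positive length")
  exons$index <- seq_len(nrow(exons))
  g <- structure(list(
    query_id = query_id, query = query, contig_id = contig_id,
    strand = strand, exons = exons, introns = introns,
    discrepancies = as_tibble(discrepancies),
    codon_table = as.integer(codon_table)), class = "gene_structure")
  g$exons <- gs_assign_offsets(g)
  if (is.null(introns)) {
    if (nrow(exons) > 1L && is.null(contig))
      stopf("contig sequence required to derive introns")
    g$introns <- derive_introns(g, contig)
  } else {
    g$introns <- as_tibble(introns)
  }
  g
}

#' @rdname gene_structure
#' @export
empty_discrepancies <- function() {
  tibble(kind = character(), protein_start = integer(), protein_end = integer(),
         genomic_start = integer(), genomic_end = integer(), shift = integer(),
         detail = character())
}

discrepancy_kinds <- c("mismatch", "sequence_shift", "inframe_stop", "unmatched")

# effective CDS length contributed by exon i: genomic length minus inserted
# shift bases plus N-padding for deletions
gs_exon_cds_len <- function(g, i) {
  e <- g$exons[i, ]
  len <- e$end - e$start
  d <- g$discrepancies
  if (nrow(d)) {
    # any discrepancy with a nonzero shift adjusts the CDS: insertions are
    # excised, deletions and unmatched gaps are N-padded
    sh <- d[d$shift != 0L &
              d$genomic_start >= e$start & d$genomic_end <= e$end, , drop = FALSE]
    if (nrow(sh)) len <- len - sum(pmax(sh$shift, 0L)) + sum(pmax(-sh$shift, 0L))
  }
  as.integer(len)
}

gs_assign_offsets <- function(g) {
  ex <- g$exons
  lens <- vapply(seq_len(nrow(ex)), function(i) gs_exon_cds_len(g, i), integer(1))
  ex$cds_offset <- as.integer(cumsum(c(0L, lens))[seq_len(nrow(ex))])
  ex$phase <- ex$cds_offset %% 3L
  ex
}

# forward-coordinate span covered by the gene
#' @export
gene_span <- function(g) {
  c(min(g$exons$start), max(g$exons$end))
}

# exon i sequence in gene orientation
gs_exon_seq <- function(g, contig, i) {
  e <- g$exons[i, ]
  s <- subseq0(contig, e$start, e$end)
  if (g$strand == "-") reverse_complement(s) else s
}

gs_intron_seq <- function(g, contig, i) {
  it <- g$introns[i, ]
  s <- subseq0(contig, it$start, it$end)
  if (g$strand == "-") reverse_complement(s) else s
}

derive_introns <- function(g, contig) {
  n <- nrow(g$exons)
  if (n <= 1L)
    return(tibble(index = integer(), start = integer(), end = integer(),
                  donor = character(), acceptor = character(),
                  canonical = logical()))
  ex <- g$exons
  rows <- lapply(seq_len(n - 1L), function(i) {
    if (g$strand == "+") {
      s <- ex$end[i]; e <- ex$start[i + 1L]
    } else {
      s <- ex$end[i + 1L]; e <- ex$start[i]
    }
    if (e <= s) stopf("exons %d and %d leave no room for an intron", i, i + 1L)
    seq <- subseq0(contig, s, e)
    if (g$strand == "-") seq <- reverse_complement(seq)
    donor <- substr(seq, 1L, 2L)
    acceptor <- substr(seq, nchar(seq) - 1L, nchar(seq))
    tibble(index = i, start = as.integer(s), end = as.integer(e),
           donor = donor, acceptor = acceptor,
           canonical = paste0(donor, "-", acceptor) %in% c("GT-AG", "GC-AG"))
  })
  bind_rows(rows)
}

# ---- coordinate algebra -----------------------------------------------------

# per-exon map pieces: tibble(exon_index, l_start, l_end (gene-oriented local
# coords within the exon's genomic span), cds_start, cds_end). Insertion
# shifts produce local intervals with no CDS; deletions produce CDS intervals
# with no local extent (these are omitted: CDS positions falling in an N-pad
# map to a zero-length genomic interval at the pad point).
gs_map_segments <- function(g) {
  d <- g$discrepancies
  out <- list()
  for (i in seq_len(nrow(g$exons))) {
    e <- g$exons[i, ]
    len <- e$end - e$start
    sh <- if (nrow(d)) d[d$shift != 0L & d$genomic_start >= e$start &
                           d$genomic_end <= e$end, , drop = FALSE]
          else d[0, ]
    # local (gene-oriented) coordinates of shift intervals
    loc <- function(gs, ge) {
      if (g$strand == "+") c(gs - e$start, ge - e$start)
      else c(e$end - ge, e$end - gs)
    }
    cuts <- tibble(l_start = integer(), l_end = integer(), pad = integer())
    if (nrow(sh)) {
      for (k in seq_len(nrow(sh))) {
        lv <- loc(sh$genomic_start[k], sh$genomic_end[k])
        cuts <- bind_rows(cuts, tibble(l_start = as.integer(lv[1]),
                                       l_end = as.integer(lv[2]),
                                       pad = as.integer(pmax(-sh$shift[k], 0L))))
      }
      cuts <- cuts[order(cuts$l_start), ]
    }
    cds <- e$cds_offset
    pos <- 0L
    pieces <- list()
    addpiece <- function(l1, l2) {
      if (l2 > l1) {
        pieces[[length(pieces) + 1L]] <<-
          tibble(exon_index = i, l_start = l1, l_end = l2,
                 cds_start = cds, cds_end = cds + (l2 - l1))
        cds <<- cds + (l2 - l1)
      }
    }
    if (nrow(cuts)) {
      for (k in seq_len(nrow(cuts))) {
        addpiece(pos, cuts$l_start[k])
        cds <- cds + cuts$pad[k]       # N-pad consumes CDS, no genomic extent
        pos <- cuts$l_end[k]           # insertion consumes genomic, no CDS
      }
    }
    addpiece(pos, len)
    out <- c(out, pieces)
  }
  bind_rows(out)
}

# gene-oriented local coord within exon i -> forward contig coordinate
gs_local_to_fwd <- function(g, i, l) {
  e <- g$exons[i, ]
  if (g$strand == "+") e$start + l else e$end - 1L - l
}

#' Convert a CDS interval to genomic intervals
#'
#' @param g a `gene_structure`.
#' @param cds_start,cds_end 0-based half-open CDS interval.
#' @return tibble of forward-strand genomic intervals in gene order
#'   (`start`, `end`, `exon_index`).
#' @export
cds_to_genomic <- function(g, cds_start, cds_end) {
  segs <- gs_map_segments(g)
  hit <- segs[segs$cds_end > cds_start & segs$cds_start < cds_end, , drop = FALSE]
  if (!nrow(hit))
    return(tibble(start = integer(), end = integer(), exon_index = integer()))
  rows <- lapply(seq_len(nrow(hit)), function(k) {
    p <- hit[k, ]
    c1 <- max(cds_start, p$cds_start); c2 <- min(cds_end, p$cds_end)
    l1 <- p$l_start + (c1 - p$cds_start); l2 <- p$l_start + (c2 - p$cds_start)
    f1 <- gs_local_to_fwd(g, p$exon_index, l1)
    f2 <- gs_local_to_fwd(g, p$exon_index, l2 - 1L)
    tibble(start = as.integer(min(f1, f2)), end = as.integer(max(f1, f2) + 1L),
           exon_index = p$exon_index)
  })
  bind_rows(rows)
}

#' Convert a forward genomic position to a CDS position
#'
#' @param g a `gene_structure`.
#' @param pos 0-based forward contig coordinate.
#' @return 0-based CDS position, or `NA` for non-exonic / shift positions.
#' @export
genomic_to_cds <- function(g, pos) {
  segs <- gs_map_segments(g)
  for (k in seq_len(nrow(segs))) {
    p <- segs[k, ]
    e <- g$exons[p$exon_index, ]
    l <- if (g$strand == "+") pos - e$start else e$end - 1L - pos
    if (!is.na(l) && l >= p$l_start && l < p$l_end)
      return(as.integer(p$cds_start + (l - p$l_start)))
  }
  NA_integer_
}

#' Map a protein position to its genomic codon interval(s)
#'
#' Returns one interval, or two when the codon is split by an intron.
#' Positions inside an `unmatched` discrepancy raise a condition of class
#' `genestructr_unmapped_position`.
#'
#' @param g a `gene_structure`.
#' @param p 1-based query position.
#' @return tibble of forward-strand intervals in gene order, total width 3.
#' @export
protein_to_genomic <- function(g, p) {
  stopifnot(p >= 1L, p <= nchar(g$query))
  d <- g$discrepancies
  if (nrow(d)) {
    un <- d[d$kind == "unmatched", , drop = FALSE]
    if (nrow(un) && any(un$protein_start <= p & un$protein_end >= p))
      abort(sprintf("protein position %d lies in an unmatched region", p),
            class = "genestructr_unmapped_position")
  }
  iv <- cds_to_genomic(g, 3L * (p - 1L), 3L * p)
  if (sum(iv$end - iv$start) != 3L)
    abort(sprintf("protein position %d is not fully mapped", p),
          class = "genestructr_unmapped_position")
  iv
}

# ---- extraction -------------------------------------------------------------

#' Extract sequences from a gene structure
#'
#' @param g a `gene_structure`.
#' @param contig the contig sequence the gene lives on.
#' @param what one of `"exons"`, `"introns"`, `"genomic"`, `"cds"`,
#'   `"translation"`.
#' @return named character vector of sequences (single element for
#'   `genomic`, `cds`, `translation`).
#' @export
extract_seqs <- function(g, contig,
                         what = c("exons", "introns", "genomic", "cds",
                                  "translation")) {
  what <- match.arg(what)
  n <- nrow(g$exons)
  switch(what,
    exons = setNames(
      vapply(seq_len(n), function(i) gs_exon_seq(g, contig, i), character(1)),
      paste0("exon_", seq_len(n))),
    introns = {
      m <- nrow(g$introns)
      if (m == 0L) return(setNames(character(0), character(0)))
      setNames(vapply(seq_len(m), function(i) gs_intron_seq(g, contig, i),
                      character(1)), paste0("intron_", seq_len(m)))
    },
    genomic = {
      sp <- gene_span(g)
      s <- subseq0(contig, sp[1], sp[2])
      if (g$strand == "-") s <- reverse_complement(s)
      c(genomic = s)
    },
    cds = c(cds = gs_cds(g, contig)),
    translation = c(translation = translate_cds(gs_cds(g, contig),
                                                g$codon_table,
                                                allow_partial = TRUE)))
}

# assemble CDS in gene orientation, applying sequence shifts
gs_cds <- function(g, contig) {
  d <- g$discrepancies
  parts <- character(nrow(g$exons))
  for (i in seq_len(nrow(g$exons))) {
    e <- g$exons[i, ]
    s <- gs_exon_seq(g, contig, i)
    sh <- if (nrow(d)) d[d$shift != 0L & d$genomic_start >= e$start &
                           d$genomic_end <= e$end, , drop = FALSE]
          else d[0, ]
    if (nrow(sh)) {
      # local gene-oriented shift intervals, applied right-to-left
      loc <- lapply(seq_len(nrow(sh)), function(k) {
        if (g$strand == "+")
          c(sh$genomic_start[k] - e$start, sh$genomic_end[k] - e$start,
            sh$shift[k])
        else c(e$end - sh$genomic_end[k], e$end - sh$genomic_start[k],
               sh$shift[k])
      })
      loc <- loc[order(vapply(loc, `[`, numeric(1), 1), decreasing = TRUE)]
      for (lv in loc) {
        if (lv[3] > 0L) {            # insertion in genome: excise
          s <- paste0(substr(s, 1L, lv[1]), substr(s, lv[2] + 1L, nchar(s)))
        } else {                     # deletion in genome: pad with N
          s <- paste0(substr(s, 1L, lv[1]),
                      strrep("N", -lv[3]),
                      substr(s, lv[1] + 1L, nchar(s)))
        }
      }
    }
    parts[i] <- s
  }
  paste0(parts, collapse = "")
}

# ---- validation -------------------------------------------------------------

#' Validate a gene structure against its contig
#'
#' Checks the structural invariants (exon/intron alternation and tiling,
#' offset chaining, recorded splice dinucleotides, translation consistency
#' outside discrepancy positions). Violations are returned as data, one row
#' each, never raised.
#'
#' @param g a `gene_structure`.
#' @param contig the contig sequence.
#' @return tibble with columns `invariant`, `location`, `detail`; zero rows
#'   when all invariants hold.
#' @export
validate_gene <- function(g, contig) {
  v <- list()
  bad <- function(invariant, location, detail)
    v[[length(v) + 1L]] <<- tibble(invariant = invariant,
                                   location = as.character(location),
                                   detail = detail)
  ex <- g$exons; it <- g$introns
  if (nrow(it) != nrow(ex) - 1L)
    bad("intron_count", "gene", sprintf("%d exons but %d introns",
                                        nrow(ex), nrow(it)))
  feats <- bind_rows(
    tibble(type = "exon", index = ex$index, start = ex$start, end = ex$end),
    if (nrow(it)) tibble(type = "intron", index = it$index,
                         start = it$start, end = it$end))
  feats <- feats[order(feats$start), ]
  if (nrow(feats) > 1L) {
    for (k in seq_len(nrow(feats) - 1L)) {
      if (feats$end[k] > feats$start[k + 1L])
        bad("tiling", paste(feats$type[k], feats$index[k]), "features overlap")
      else if (feats$end[k] < feats$start[k + 1L])
        bad("tiling", paste(feats$type[k], feats$index[k]),
            "gap between adjacent features")
      if (feats$type[k] == feats$type[k + 1L])
        bad("alternation", paste(feats$type[k], feats$index[k]),
            "two adjacent features of the same type")
    }
  }
  # offset chaining
  expect_off <- gs_assign_offsets(g)
  if (!identical(ex$cds_offset, expect_off$cds_offset))
    bad("cds_offsets", "gene", "cds_offset chain inconsistent with exon lengths")
  # splice dinucleotides recorded verbatim
  if (nrow(it)) {
    for (i in seq_len(nrow(it))) {
      seq <- gs_intron_seq(g, contig, i)
      if (substr(seq, 1, 2) != it$donor[i] ||
          substr(seq, nchar(seq) - 1, nchar(seq)) != it$acceptor[i])
        bad("splice_dinucleotides", paste("intron", i),
            "recorded donor/acceptor differ from sequence")
    }
  }
  # translation consistency
  cds <- gs_cds(g, contig)
  tr <- translate_cds(cds, g$codon_table, allow_partial = TRUE)
  q <- g$query
  d <- g$discrepancies
  covered <- rep(FALSE, nchar(q))
  if (nrow(d)) for (k in seq_len(nrow(d))) {
    r <- seq.int(max(1L, d$protein_start[k]), min(nchar(q), d$protein_end[k]))
    covered[r] <- TRUE
  }
  nn <- min(nchar(tr), nchar(q))
  qv <- chars(q)[seq_len(nn)]; tv <- chars(tr)[seq_len(nn)]
  diffpos <- which(qv != tv & tv != "X")
  extra <- setdiff(diffpos, which(covered))
  if (length(extra))
    bad("translation", paste0("protein ", paste(head(extra, 5), collapse = ",")),
        sprintf("%d uncovered translation difference(s)", length(extra)))
  if (nchar(tr) < nchar(q) && !any(d$kind == "unmatched"))
    bad("translation", "gene", "CDS shorter than query with no unmatched record")
  if (!length(v)) tibble(invariant = character(), location = character(),
                         detail = character())
  else bind_rows(v)
}

# ---- tidy methods -----------------------------------------------------------

#' Tidy a gene structure into a feature table
#'
#' @param x a `gene_structure`.
#' @param ... unused.
#' @return tibble with one row per exon and intron, in gene order.
#' @export
tidy.gene_structure <- function(x, ...) {
  ex <- mutate(x$exons, feature = "exon")
  it <- if (nrow(x$introns)) mutate(x$introns, feature = "intron") else NULL
  out <- bind_rows(
    select(ex, feature, index, start, end),
    if (!is.null(it)) select(it, feature, index, start, end))
  out <- mutate(out, length = end - start, strand = x$strand,
                contig = x$contig_id)
  arrange(out, factor(feature, c("exon", "intron")), index)
}

#' One-row summary of a gene structure
#'
#' @param x a `gene_structure`.
#' @param ... unused.
#' @export
glance.gene_structure <- function(x, ...) {
  sp <- gene_span(x)
  tibble(query_id = x$query_id, contig_id = x$contig_id, strand = x$strand,
         n_exons = nrow(x$exons), n_introns = nrow(x$introns),
         cds_length = sum(vapply(seq_len(nrow(x$exons)),
                                 function(i) gs_exon_cds_len(x, i), integer(1))),
         span_start = sp[1], span_end = sp[2],
         n_discrepancies = nrow(x$discrepancies))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
print.gene_structure <- function(x, ...) {
  cat(sprintf("<gene_structure> %s on %s (%s), %d exon(s), %d intron(s), %d discrepancy(ies)\n",
              x$query_id, x$contig_id, x$strand, nrow(x$exons),
              nrow(x$introns), nrow(x$discrepancies)))
  invisible(x)
}
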