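# Readers/writers: FASTA (via Biostrings), GFF3 and the versioned YAML
# result dialect. All writers are deterministic: fixed key order, fixed
# wrapping, no floats with locale-dependent formatting.

RESULT_FORMAT_VERSION <- "1.0"

#' Read a FASTA file
#'
#' @param path file path.
#' @param alphabet `"dna"` or `"protein"`; sequences are validated and
#'   canonicalised accordingly.
#' @return tibble with columns `id` (first whitespace-delimited header
#'   token) and `seq`, in file order.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stopf("no such file: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stopf("cannot parse FASTA %s: %s",
                                            path, conditionMessage(e)))
  if (!length(set)) stopf("empty FASTA file: %s", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(ids))
    stopf("duplicate FASTA id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(set)
  clean <- if (alphabet == "dna") clean_dna else clean_protein
  tibble(id = ids,
         seq = vapply(seq_along(seqs), function(i) clean(seqs[i], ids[i]), ""))
}

#' Write sequences as FASTA
#'
#' @param x tibble with columns `id`, `seq`, or a named character vector.
#' @param path output path.
#' @param width wrap width (default 60 columns).
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (!is.data.frame(x)) x <- tibble(id = names(x), seq = unname(x))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    writeLines(paste0(">", x$id[i]), con)
    s <- x$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# ---- result document --------------------------------------------------------

#' Create a result document
#'
#' The container for everything one analysis produces: the reconstructed
#' gene, optional splice events, MXE clusters and tandem duplicates, plus
#' provenance (parameters and input checksums). Serialises losslessly to
#' the package's versioned YAML dialect.
#'
#' @param gene a `gene_structure` or `NULL`.
#' @param splice_events,mxe_clusters,duplicates optional result tibbles.
#' @param provenance named list of parameters and input checksums.
#' @param stats optional one-row tibble of summary statistics.
#' @param partial partially reconstructed gene retained with a failure
#'   diagnostic.
#' @param diagnostics character diagnostic message(s) or `NULL`.
#' @param extra unknown keys carried through from a deserialised document.
#' @return object of class `result_document`.
#' @export
result_document <- function(gene = NULL, splice_events = NULL,
                            mxe_clusters = NULL, duplicates = NULL,
                            provenance = list(), stats = NULL,
                            partial = NULL, diagnostics = NULL,
                            extra = NULL) {
  structure(list(version = RESULT_FORMAT_VERSION, gene = gene,
                 splice_events = splice_events, mxe_clusters = mxe_clusters,
                 duplicates = duplicates, provenance = provenance,
                 stats = stats, partial = partial, diagnostics = diagnostics,
                 extra = extra),
            class = "result_document")
}

#' @export
print.result_document <- function(x, ...) {
  cat(sprintf("<result_document v%s>\n", x$version))
  if (!is.null(x$gene)) print(x$gene) else cat("  gene: (none)\n")
  for (nm in c("splice_events", "mxe_clusters", "duplicates"))
    if (!is.null(x[[nm]]))
      cat(sprintf("  %s: %d row(s)\n", nm, nrow(x[[nm]])))
  if (!is.null(x$diagnostics)) cat("  diagnostics:", x$diagnostics, "\n")
  invisible(x)
}

#' @export
glance.result_document <- function(x, ...) {
  tibble(version = x$version,
         has_gene = !is.null(x$gene),
         n_splice_events = if (is.null(x$splice_events)) 0L
                           else nrow(x$splice_events),
         n_mxe_clusters = if (is.null(x$mxe_clusters)) 0L
                          else length(unique(x$mxe_clusters$source_exon)),
         n_duplicates = if (is.null(x$duplicates)) 0L
                        else length(unique(x$duplicates$duplicate_id)),
         diagnostics = x$diagnostics %||% NA_character_)
}

# ---- YAML dialect -----------------------------------------------------------

tibble_to_plain <- function(tb) {
  if (is.null(tb)) return(NULL)
  lapply(as.list(tb), function(col) as.vector(col))
}

plain_to_tibble <- function(pl) {
  if (is.null(pl)) return(NULL)
  cols <- lapply(pl, unlist)
  cols <- cols[!vapply(cols, is.null, logical(1))]
  if (!length(cols)) return(NULL)
  as_tibble(cols)
}

gene_to_plain <- function(g) {
  if (is.null(g)) return(NULL)
  list(query_id = g$query_id, query = g$query, contig_id = g$contig_id,
       strand = g$strand, codon_table = g$codon_table,
       exons = tibble_to_plain(g$exons),
       introns = tibble_to_plain(g$introns),
       discrepancies = tibble_to_plain(g$discrepancies))
}

plain_to_gene <- function(pl) {
  if (is.null(pl)) return(NULL)
  ex <- plain_to_tibble(pl$exons)
  disc <- plain_to_tibble(pl$discrepancies)
  if (is.null(disc) || !nrow(disc)) disc <- empty_discrepancies()
  g <- gene_structure(pl$query_id, pl$query, pl$contig_id, pl$strand,
                      exons = ex, introns = plain_to_tibble(pl$introns),
                      discrepancies = disc, codon_table = pl$codon_table)
  g
}

#' Serialise / deserialise a result document as YAML
#'
#' The dialect is versioned; unknown top-level keys survive a read-write
#' round trip. Writing is deterministic: the same document always produces
#' byte-identical text.
#'
#' @param doc a `result_document`.
#' @return `write_yaml_result`: the YAML text (invisibly when `path` is
#'   given); `read_yaml_result`: a `result_document`.
#' @param path optional file path to write to / read from.
#' @param text YAML text (alternative to `path`).
#' @export
write_yaml_result <- function(doc, path = NULL) {
  stopifnot(inherits(doc, "result_document"))
  pl <- list(version = doc$version, gene = gene_to_plain(doc$gene))
  for (nm in c("splice_events", "mxe_clusters", "duplicates", "stats"))
    if (!is.null(doc[[nm]]) && nrow(doc[[nm]]) > 0L)
      pl[[nm]] <- tibble_to_plain(doc[[nm]])
  if (length(doc$provenance)) pl$provenance <- doc$provenance
  if (!is.null(doc$partial)) pl$partial <- gene_to_plain(doc$partial)
  if (!is.null(doc$diagnostics)) pl$diagnostics <- doc$diagnostics
  if (!is.null(doc$extra)) pl <- c(pl, doc$extra)
  txt <- yaml::as.yaml(pl, indent = 2, precision = 12)
  if (!is.null(path)) { writeLines(txt, path, sep = ""); return(invisible(txt)) }
  txt
}

#' @rdname write_yaml_result
#' @export
read_yaml_result <- function(text = NULL, path = NULL) {
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE),
                                   collapse = "\n")
  pl <- yaml::yaml.load(text)
  if (is.null(pl$version))
    stopf("not a result document: missing version key")
  if (pl$version != RESULT_FORMAT_VERSION)
    stopf("result document version %s needs upgrading (this build reads %s)",
          pl$version, RESULT_FORMAT_VERSION)
  known <- c("version", "gene", "splice_events", "mxe_clusters", "duplicates",
             "stats", "provenance", "partial", "diagnostics")
  extra <- pl[setdiff(names(pl), known)]
  result_document(
    gene = plain_to_gene(pl$gene),
    splice_events = plain_to_tibble(pl$splice_events),
    mxe_clusters = plain_to_tibble(pl$mxe_clusters),
    duplicates = plain_to_tibble(pl$duplicates),
    stats = plain_to_tibble(pl$stats),
    provenance = pl$provenance %||% list(),
    partial = plain_to_gene(pl$partial),
    diagnostics = pl$diagnostics,
    extra = if (length(extra)) extra else NULL)
}

#' Verify provenance checksums against input sequences
#'
#' @param doc a `result_document`.
#' @param query protein query string.
#' @param contigs contig sequences (named vector or tibble `id`/`seq`).
#' @return `TRUE` if all checksums match, otherwise `FALSE`.
#' @export
check_provenance <- function(doc, query, contigs) {
  pv <- doc$provenance
  if (is.null(pv$query_md5)) return(NA)
  if (is.data.frame(contigs)) contigs <- setNames(contigs$seq, contigs$id)
  ok <- identical(pv$query_md5, string_md5(query))
  md5s <- vapply(unname(contigs), string_md5, "", USE.NAMES = FALSE)
  ok && identical(unname(unlist(pv$contig_md5)), md5s)
}

# ---- GFF3 -------------------------------------------------------------------

gff_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}

#' Write a result document as GFF3
#'
#' Emits gene, mRNA, exon and CDS rows (1-based inclusive coordinates,
#' ascending within the contig; the phase column gives the bases to skip to
#' reach the next codon start). Splice events, MXE candidates and tandem
#' duplicates are emitted as additional features with type-specific
#' attributes.
#'
#' @param doc a `result_document` with a gene.
#' @param path output path.
#' @export
write_gff <- function(doc, path) {
  g <- doc$gene %||% doc$partial
  if (is.null(g)) stopf("result document has no gene to export")
  gid <- paste0("gene:", g$query_id)
  mid <- paste0("mrna:", g$query_id)
  sp <- gene_span(g)
  src <- "genestructr"
  row <- function(type, s, e, strand, phase, attrs)
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            g$contig_id, src, type, s + 1L, e, strand, phase, attrs)
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s %d %d", g$contig_id, 1L,
                     max(sp[2], 1L)))
  lines <- c(lines,
             row("gene", sp[1], sp[2], g$strand, ".",
                 sprintf("ID=%s;Name=%s", gff_escape(gid),
                         gff_escape(g$query_id))),
             row("mRNA", sp[1], sp[2], g$strand, ".",
                 sprintf("ID=%s;Parent=%s", gff_escape(mid), gff_escape(gid))))
  ex <- g$exons[order(g$exons$start), ]
  for (i in seq_len(nrow(ex))) {
    e <- ex[i, ]
    gff_phase <- (3L - e$phase) %% 3L
    lines <- c(lines,
               row("exon", e$start, e$end, g$strand, ".",
                   sprintf("ID=exon:%s.%d;Parent=%s", gff_escape(g$query_id),
                           e$index, gff_escape(mid))),
               row("CDS", e$start, e$end, g$strand,
                   as.character(gff_phase),
                   sprintf("ID=cds:%s.%d;Parent=%s;exon_index=%d",
                           gff_escape(g$query_id), e$index, gff_escape(mid),
                           e$index)))
  }
  ev <- doc$splice_events
  if (!is.null(ev) && nrow(ev)) {
    ev <- ev[order(ev$genomic_start, ev$cdna_id, ev$type), ]
    for (i in seq_len(nrow(ev))) {
      r <- ev[i, ]
      if (is.na(r$type)) next
      lines <- c(lines, row(
        "splice_variant_evidence", r$genomic_start, r$genomic_end,
        g$strand, ".",
        sprintf("ID=event:%d;Parent=%s;event_type=%s;anchor=%s_%d;support=%s",
                i, gff_escape(mid), r$type, r$anchor_kind, r$anchor_index,
                gff_escape(r$cdna_id))))
    }
  }
  mx <- doc$mxe_clusters
  if (!is.null(mx) && nrow(mx)) {
    for (i in seq_len(nrow(mx))) {
      r <- mx[i, ]
      lines <- c(lines, row(
        "mutually_exclusive_exon_candidate", r$start, r$end, g$strand, ".",
        sprintf("ID=mxe:%d;Parent=%s;source_exon=%d;similarity=%.4f",
                i, gff_escape(mid), r$source_exon, r$similarity)))
    }
  }
  du <- doc$duplicates
  if (!is.null(du) && nrow(du)) {
    for (did in unique(du$duplicate_id)) {
      r <- du[du$duplicate_id == did, ][1L, ]
      lines <- c(lines, row(
        "gene", r$dup_start, r$dup_end, r$dup_strand, ".",
        sprintf("ID=dup:%d;duplicate_of=%s;mean_similarity=%.4f",
                did, gff_escape(gid), r$mean_similarity)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFF3 gene back into a gene structure
#'
#' Parses the exon/CDS rows written by [write_gff()] (query sequence is not
#' stored in GFF, so it must be supplied).
#'
#' @param path GFF3 path.
#' @param query protein query string.
#' @param contig contig sequence (used to re-derive introns).
#' @param codon_table NCBI genetic-code table id.
#' @return a `gene_structure` without discrepancy records.
#' @export
read_gff_gene <- function(path, query, contig, codon_table = 1L) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  f <- strsplit(ln, "\t", fixed = TRUE)
  f <- f[vapply(f, length, 0L) == 9L]
  typ <- vapply(f, `[`, "", 3L)
  ex <- f[typ == "exon"]
  if (!length(ex)) stopf("no exon rows in %s", path)
  starts <- vapply(ex, function(r) as.integer(r[4]) - 1L, 0L)
  ends <- vapply(ex, function(r) as.integer(r[5]), 0L)
  strand <- ex[[1L]][7L]
  contig_id <- ex[[1L]][1L]
  ord <- order(starts)
  if (strand == "-") ord <- rev(ord)
  idx <- vapply(ex, function(r) {
    m <- regmatches(r[9], regexec("exon:[^.]*\\.(\\d+)", r[9]))[[1L]]
    if (length(m) == 2L) as.integer(m[2]) else NA_integer_
  }, 0L)
  if (!anyNA(idx)) ord <- order(idx)
  gene_structure(query_id = sub("^gene:", "", "query"), query = query,
                 contig_id = contig_id, strand = strand,
                 exons = tibble(start = starts[ord], end = ends[ord]),
                 codon_table = codon_table, contig = contig)
}
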