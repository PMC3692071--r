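# SVG rendering of gene-structure schemes: one row for the gene (exons
# dark grey, introns light grey, discrepancies in type-specific colours,
# MXE candidates with opacity proportional to similarity), one row per
# spliced hit (unmatched cDNA as red bars, mismatches as red lines) and a
# merged-coverage row. Rendering is a pure function of its inputs:
# identical documents produce byte-identical SVG.

#' Rendering parameters
#'
#' @param nt_per_px horizontal scale (nucleotides per pixel).
#' @param row_height,row_gap,margin layout in pixels.
#' @param min_opacity lower clamp of the similarity-driven MXE opacity.
#' @param colors named list of fill colours (colour-blind-safe defaults).
#' @return list of class `render_spec`.
#' @export
render_spec <- function(nt_per_px = 10, row_height = 14, row_gap = 10,
                        margin = 20, min_opacity = 0.15,
                        colors = list(
                          exon = "#555555", intron = "#cccccc",
                          mxe = "#0072B2", coverage = "#009E73",
                          block = "#555555", unmatched = "#D55E00",
                          mismatch = "#D55E00", duplicate = "#CC79A7",
                          disc_mismatch = "#D55E00",
                          disc_sequence_shift = "#E69F00",
                          disc_inframe_stop = "#B22222",
                          disc_unmatched = "#999999")) {
  structure(list(nt_per_px = nt_per_px, row_height = row_height,
                 row_gap = row_gap, margin = margin,
                 min_opacity = min_opacity, colors = colors),
            class = "render_spec")
}

svg_num <- function(x) sprintf("%.2f", x)

#' Render a result document as SVG
#'
#' @param doc a `result_document` with a gene.
#' @param spec a [render_spec()].
#' @param hits optional list of converted `spliced_hit` objects (one row
#'   each).
#' @param coverage optional output of [merge_coverage()] for the merged
#'   row.
#' @return SVG text (a single string).
#' @export
render_svg <- function(doc, spec = render_spec(), hits = NULL,
                       coverage = NULL) {
  g <- doc$gene %||% doc$partial
  if (is.null(g)) stopf("result document has no gene to render")
  sp <- gene_span(g)
  if (sp[2] <= sp[1]) stopf("zero-length gene cannot be rendered")
  xmin <- sp[1]
  ex_dup <- doc$duplicates
  if (!is.null(ex_dup) && nrow(ex_dup)) xmin <- min(xmin, ex_dup$dup_start)
  xmax <- sp[2]
  if (!is.null(ex_dup) && nrow(ex_dup)) xmax <- max(xmax, ex_dup$dup_end)
  mx <- doc$mxe_clusters
  if (!is.null(mx) && nrow(mx)) { xmin <- min(xmin, mx$start)
                                  xmax <- max(xmax, mx$end) }
  px <- function(pos) spec$margin + (pos - xmin) / spec$nt_per_px
  n_rows <- 1L + length(hits) + (!is.null(coverage)) +
    (!is.null(ex_dup) && nrow(ex_dup) > 0L)
  width <- spec$margin * 2 + (xmax - xmin) / spec$nt_per_px
  height <- spec$margin * 2 + n_rows * (spec$row_height + spec$row_gap)
  out <- c(sprintf(
    paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" version=\"1.1\" ",
           "width=\"%s\" height=\"%s\">"), svg_num(width), svg_num(height)))
  rect <- function(id, cls, x1, x2, y, h, fill, opacity = 1, title = NULL) {
    t <- if (!is.null(title))
      sprintf("><title>%s</title></rect>", title) else "/>"
    sprintf(paste0("<rect id=\"%s\" class=\"%s\" x=\"%s\" y=\"%s\" ",
                   "width=\"%s\" height=\"%s\" fill=\"%s\" ",
                   "fill-opacity=\"%s\"%s"),
            id, cls, svg_num(px(x1)), svg_num(y),
            svg_num(max((x2 - x1) / spec$nt_per_px, 0.5)), svg_num(h),
            fill, svg_num(opacity), t)
  }
  vline <- function(id, cls, x, y, h, colour)
    sprintf(paste0("<line id=\"%s\" class=\"%s\" x1=\"%s\" y1=\"%s\" ",
                   "x2=\"%s\" y2=\"%s\" stroke=\"%s\"/>"),
            id, cls, svg_num(px(x)), svg_num(y), svg_num(px(x)),
            svg_num(y + h), colour)
  y <- spec$margin
  # gene row
  for (i in seq_len(nrow(g$introns)))
    out <- c(out, rect(sprintf("intron-%d", i), "intron",
                       g$introns$start[i], g$introns$end[i],
                       y + spec$row_height * 0.25, spec$row_height * 0.5,
                       spec$colors$intron))
  for (i in seq_len(nrow(g$exons)))
    out <- c(out, rect(sprintf("exon-%d", i), "exon",
                       g$exons$start[i], g$exons$end[i], y,
                       spec$row_height, spec$colors$exon))
  d <- g$discrepancies
  if (nrow(d)) for (i in seq_len(nrow(d))) {
    if (is.na(d$genomic_start[i])) next
    out <- c(out, vline(sprintf("disc-%d", i),
                        paste0("discrepancy ", d$kind[i]),
                        d$genomic_start[i], y, spec$row_height,
                        spec$colors[[paste0("disc_", d$kind[i])]] %||%
                          "#000000"))
  }
  if (!is.null(mx) && nrow(mx)) for (i in seq_len(nrow(mx))) {
    op <- min(max(mx$similarity[i], spec$min_opacity), 1)
    out <- c(out, rect(sprintf("mxe-%d", i), "mxe", mx$start[i], mx$end[i],
                       y, spec$row_height, spec$colors$mxe, op,
                       title = sprintf("MXE candidate for exon %d, similarity %.2f",
                                       mx$source_exon[i], mx$similarity[i])))
  }
  ev <- doc$splice_events
  # hit rows
  hi <- 0L
  for (sh in hits %||% list()) {
    hi <- hi + 1L
    y <- spec$margin + hi * (spec$row_height + spec$row_gap)
    bl <- sh$blocks
    if (nrow(bl) > 1L) for (b in seq_len(nrow(bl) - 1L))
      out <- c(out, rect(sprintf("hit%d-gap-%d", hi, b), "hit-gap",
                         gene_to_fwd(g, bl$g_end[b], bl$g_start[b + 1L])[1],
                         gene_to_fwd(g, bl$g_end[b], bl$g_start[b + 1L])[2],
                         y + spec$row_height * 0.4, spec$row_height * 0.2,
                         spec$colors$intron))
    hit_events <- if (!is.null(ev))
      ev[ev$cdna_id == sh$cdna_id & !is.na(ev$type), , drop = FALSE]
      else NULL
    for (b in seq_len(nrow(bl))) {
      f <- gene_to_fwd(g, bl$g_start[b], bl$g_end[b])
      ttl <- NULL
      if (!is.null(hit_events) && nrow(hit_events)) {
        ovl <- hit_events[pmin(hit_events$genomic_end, f[2]) -
                            pmax(hit_events$genomic_start, f[1]) > 0L, ]
        if (nrow(ovl)) ttl <- paste(unique(ovl$type), collapse = ", ")
      }
      out <- c(out, rect(sprintf("hit%d-block-%d", hi, b), "hit-block",
                         f[1], f[2], y, spec$row_height,
                         spec$colors$block, title = ttl))
    }
    if (!is.null(sh$mismatches) && nrow(sh$mismatches))
      for (m in seq_len(nrow(sh$mismatches))) {
        f <- gene_to_fwd(g, sh$mismatches$g_pos[m],
                         sh$mismatches$g_pos[m] + 1L)
        out <- c(out, vline(sprintf("hit%d-mm-%d", hi, m), "hit-mismatch",
                            f[1], y, spec$row_height, spec$colors$mismatch))
      }
    if (nrow(sh$unmatched)) for (u in seq_len(nrow(sh$unmatched))) {
      # unmatched cDNA has no genomic position: draw a red bar hanging off
      # the nearest mapped end of the hit
      bl1 <- bl[1, ]; bln <- bl[nrow(bl), ]
      at_start <- sh$unmatched$end[u] <= bl1$c_start
      anchor <- if (at_start) gene_to_fwd(g, bl1$g_start, bl1$g_start)[1]
                else gene_to_fwd(g, bln$g_end, bln$g_end)[1]
      w_nt <- (sh$unmatched$end[u] - sh$unmatched$start[u])
      x1 <- if (at_start) anchor - w_nt else anchor
      out <- c(out, rect(sprintf("hit%d-unmatched-%d", hi, u),
                         "hit-unmatched", x1, x1 + w_nt, y,
                         spec$row_height, spec$colors$unmatched))
    }
  }
  # merged coverage row
  if (!is.null(coverage)) {
    y <- spec$margin + (1L + length(hits %||% list())) *
      (spec$row_height + spec$row_gap)
    pr <- coverage$profile
    ci <- 0L
    for (i in seq_len(nrow(pr))) {
      iv <- cds_to_genomic(g, pr$cds_start[i], pr$cds_end[i])
      for (k in seq_len(nrow(iv))) {
        ci <- ci + 1L
        out <- c(out, rect(sprintf("cov-%d", ci), "coverage",
                           iv$start[k], iv$end[k], y, spec$row_height,
                           spec$colors$coverage,
                           title = sprintf("covered fraction %.3f",
                                           coverage$fraction)))
      }
    }
  }
  if (!is.null(ex_dup) && nrow(ex_dup)) {
    y <- spec$margin + (n_rows - 1L) * (spec$row_height + spec$row_gap)
    for (i in seq_len(nrow(ex_dup)))
      out <- c(out, rect(sprintf("dup-%d", i), "duplicate",
                         ex_dup$dup_start[i], ex_dup$dup_end[i], y,
                         spec$row_height, spec$colors$duplicate,
                         min(max(ex_dup$mean_similarity[i] %||% 1,
                                 spec$min_opacity), 1),
                         title = sprintf("tandem duplicate (%s strand)",
                                         ex_dup$dup_strand[i])))
  }
  out <- c(out, "</svg>")
  paste0(out, collapse = "\n")
}

#' Plot a gene structure with ggplot2
#'
#' @param object a `gene_structure`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.gene_structure <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = start, xmax = end,
      ymin = ifelse(feature == "exon", 0, 0.3),
      ymax = ifelse(feature == "exon", 1, 0.7),
      fill = feature)) +
    ggplot2::scale_fill_manual(values = c(exon = "#555555",
                                          intron = "#cccccc")) +
    ggplot2::labs(x = sprintf("%s (%s strand)", object$contig_id,
                              object$strand), y = NULL,
                  title = object$query_id) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank(),
                   panel.grid.minor.y = ggplot2::element_blank())
}
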