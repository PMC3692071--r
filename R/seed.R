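# Seeded translated matcher: exact amino-acid k-mer seeds on the six frames
# of the target, extended along each seeded diagonal by maximal-scoring
# segment search under BLOSUM62. This replaces an external similarity-search
# tool so the package is self-contained.

# translate the three forward frames of a working-strand sequence
frame_translations <- function(w, table_id) {
  n <- nchar(w)
  lapply(0:2, function(f) {
    len <- (n - f) %/% 3L
    if (len < 1L) return("")
    translate_cds(substr(w, f + 1L, f + 3L * len), table_id,
                  allow_partial = TRUE)
  })
}

# all seed diagonals (frame, diag) shared by query and a frame translation
seed_diagonals <- function(qv, fv, k) {
  nq <- length(qv); nf <- length(fv)
  if (nq < k || nf < k) return(integer(0))
  qk <- vapply(seq_len(nq - k + 1L), function(i)
    paste0(qv[i:(i + k - 1L)], collapse = ""), character(1))
  fk <- vapply(seq_len(nf - k + 1L), function(i)
    paste0(fv[i:(i + k - 1L)], collapse = ""), character(1))
  idx <- split(seq_along(fk), fk)
  hits <- idx[qk]
  qpos <- rep(seq_along(qk), lengths(hits))
  fpos <- unlist(hits, use.names = FALSE)
  if (!length(fpos)) return(integer(0))
  unique(fpos - qpos)   # diagonal = frame aa position - query aa position
}

#' Find seeded translated local matches of a protein on a contig
#'
#' Seeds exact `seed_word_len`-mer amino-acid matches between the query and
#' all six frame translations of the contig, then extends each seeded
#' diagonal to its maximal-scoring BLOSUM62 segments.
#'
#' @param query protein string.
#' @param contig nucleotide string.
#' @param params a [reconstruction_params()] list.
#' @return tibble of hits sorted by score: `strand`, `frame` (0-5; 3-5 are
#'   the reverse strand), `q_start`/`q_end` (1-based residues, inclusive),
#'   `g_start`/`g_end` (0-based half-open forward contig coordinates),
#'   `w_start`/`w_end` (working-strand coordinates used internally), `score`.
#' @export
find_seed_hits <- function(query, contig, params = reconstruction_params()) {
  if (nchar(contig) < 3L) stopf("contig shorter than one codon")
  if (nchar(query) < params$seed_word_len)
    stopf("query shorter than seed word length")
  qv <- chars(query)
  L <- nchar(contig)
  out <- list()
  for (strand in c("+", "-")) {
    w <- if (strand == "+") contig else reverse_complement(contig)
    frames <- frame_translations(w, params$codon_table)
    for (f in 0:2) {
      fa <- frames[[f + 1L]]
      if (nchar(fa) < params$seed_word_len) next
      fv <- chars(fa)
      diags <- seed_diagonals(qv, fv, params$seed_word_len)
      for (d in diags) {
        i1 <- max(1L, 1L - d); i2 <- min(length(qv), length(fv) - d)
        if (i2 - i1 + 1L < params$seed_word_len) next
        sc <- blosum_scores(qv[i1:i2], fv[(i1 + d):(i2 + d)])
        # segment on a sharpened score (-2 per residue) so that stretches of
        # frame-shifted or intronic junk split a diagonal into its clean
        # fragments; the chain stage re-merges fragments separated by small
        # gaps, so over-splitting is harmless while bridging hides indels
        segs <- cpp_best_segments(sc - 2L, params$seed_min_score %/% 2L, 6L)
        # a second, harsher pass: a diagonal crossing a frame disruption
        # still bridges the junk between its clean flanks, so re-segment
        # with a strong per-residue tax to expose the flanks as their own
        # hits; the chain stage picks whichever decomposition scores best
        sharp <- cpp_best_segments(sc - 4L, 12L, 8L)
        segs <- list(start = c(segs$start, sharp$start),
                     end = c(segs$end, sharp$end))
        if (!length(segs$start)) next
        dup <- duplicated(paste(segs$start, segs$end))
        segs <- list(start = segs$start[!dup], end = segs$end[!dup])
        keep <- vapply(seq_along(segs$start), function(s)
          sum(sc[(segs$start[s] + 1L):(segs$end[s] + 1L)]), integer(1))
        sel <- keep >= params$seed_min_score %/% 2L
        segs <- list(start = segs$start[sel], end = segs$end[sel],
                     score = keep[sel])
        if (!length(segs$start)) next
        for (s in seq_along(segs$start)) {
          qs <- i1 + segs$start[s]; qe <- i1 + segs$end[s]   # 1-based aa
          js <- qs + d; je <- qe + d                          # frame aa pos
          ws <- f + 3L * (js - 1L); we <- f + 3L * je
          out[[length(out) + 1L]] <- tibble(
            strand = strand, frame = f + if (strand == "-") 3L else 0L,
            q_start = qs, q_end = qe,
            w_start = ws, w_end = we,
            g_start = if (strand == "+") ws else L - we,
            g_end = if (strand == "+") we else L - ws,
            score = segs$score[s])
        }
      }
    }
  }
  if (!length(out))
    return(tibble(strand = character(), frame = integer(), q_start = integer(),
                  q_end = integer(), w_start = integer(), w_end = integer(),
                  g_start = integer(), g_end = integer(), score = integer()))
  h <- bind_rows(out)
  h <- h[!duplicated(h[c("strand", "q_start", "q_end", "w_start", "w_end")]), ]
  arrange(h, desc(score))
}

# link classification between two chained hits (working coordinates, after
# trimming query overlap): returns NULL if the pair cannot be linked
link_between <- function(qe_i, we_i, qs_j, ws_j, params) {
  m <- qs_j - qe_i - 1L
  if (m < 0L) return(NULL)
  G <- ws_j - we_i
  delta <- G - 3L * m
  if (delta >= params$min_intron_len && delta <= params$max_intron_len)
    return(list(type = "intron", m = m, delta = delta,
                penalty = params$intron_open + params$intron_scale * log(delta)))
  if (abs(delta) <= 2L && G >= -2L)
    return(list(type = "contig", m = m, delta = delta,
                penalty = 2 + 6 * abs(delta) + 0.5 * m))
  NULL
}

#' Chain seed hits into a colinear draft exon chain
#'
#' Dynamic programming over hits of one strand: selects a colinear,
#' non-overlapping subset maximising total hit score minus gap penalties
#' (affine in log intron length). Query overlaps up to
#' `max_chain_protein_overlap` residues are resolved by trimming the later
#' hit.
#'
#' @param hits tibble from [find_seed_hits()] (one strand).
#' @param params a [reconstruction_params()] list.
#' @return list with `hits` (chained rows, trimmed, in gene order), `links`
#'   (tibble of junction types between consecutive chain members) and
#'   `score`; `NULL` when no chain exists.
#' @export
chain_exons <- function(hits, params = reconstruction_params()) {
  if (!nrow(hits)) return(NULL)
  stopifnot(length(unique(hits$strand)) == 1L)
  h <- arrange(hits, q_start, w_start)
  n <- nrow(h)
  dp <- as.numeric(h$score)
  prev <- rep(NA_integer_, n)
  trim <- rep(0L, n)   # residues trimmed off the start when linked to prev
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      if (i == j) next
      if (h$q_start[i] >= h$q_start[j] || h$q_end[i] >= h$q_end[j]) next
      if (h$w_start[i] >= h$w_start[j] || h$w_end[i] >= h$w_end[j]) next
      o <- max(0L, h$q_end[i] - h$q_start[j] + 1L)
      if (o > params$max_chain_protein_overlap) next
      qs_j <- h$q_start[j] + o; ws_j <- h$w_start[j] + 3L * o
      if (qs_j > h$q_end[j]) next
      lk <- link_between(h$q_end[i], h$w_end[i], qs_j, ws_j, params)
      if (is.null(lk)) next
      cand <- dp[i] + h$score[j] - lk$penalty - 5 * o
      if (cand > dp[j]) { dp[j] <- cand; prev[j] <- i; trim[j] <- o }
    }
  }
  jbest <- which.max(dp)
  path <- integer(0); j <- jbest
  while (!is.na(j)) { path <- c(j, path); j <- prev[j] }
  ch <- h[path, ]
  tr <- trim[path]; tr[1L] <- 0L
  ch$q_start <- ch$q_start + tr
  ch$w_start <- ch$w_start + 3L * tr
  links <- NULL
  if (nrow(ch) > 1L) {
    links <- bind_rows(lapply(seq_len(nrow(ch) - 1L), function(k) {
      lk <- link_between(ch$q_end[k], ch$w_end[k],
                         ch$q_start[k + 1L], ch$w_start[k + 1L], params)
      tibble(type = lk$type, m = lk$m, delta = lk$delta)
    }))
  } else {
    links <- tibble(type = character(), m = integer(), delta = integer())
  }
  list(hits = ch, links = links, score = dp[jbest])
}

# brute-force chaining oracle support: enumerate all hit subsets (used in
# tests for instances with few hits) lives in the test helpers, not here.
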