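# Pairwise alignment wrappers around the C++ Gotoh kernel.
#
# Score matrices are 128x128 integer matrices indexed by raw char code so a
# single kernel serves nucleotide and protein alignments.

.matrix_cache <- new.env(parent = emptyenv())

score_matrix_dna <- function(match = 5L, mismatch = -4L, n_score = 0L) {
  key <- paste0("dna", match, mismatch, n_score)
  if (!is.null(.matrix_cache[[key]])) return(.matrix_cache[[key]])
  m <- matrix(mismatch, 128L, 128L)
  for (b in c("A", "C", "G", "T")) {
    i <- utf8ToInt(b) + 1L
    m[i, i] <- match
  }
  ni <- utf8ToInt("N") + 1L
  m[ni, ] <- n_score; m[, ni] <- n_score
  .matrix_cache[[key]] <- m
  m
}

score_matrix_protein <- function() {
  if (!is.null(.matrix_cache[["blosum62"]]))
    return(.matrix_cache[["blosum62"]])
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  b <- e$BLOSUM62
  m <- matrix(-4L, 128L, 128L)
  aas <- rownames(b)
  for (x in aas) for (y in aas)
    m[utf8ToInt(x) + 1L, utf8ToInt(y) + 1L] <- as.integer(b[x, y])
  .matrix_cache[["blosum62"]] <- m
  m
}

# BLOSUM62 score for two aligned residue strings of equal length (vectorised)
blosum_scores <- function(a_chars, b_chars) {
  m <- score_matrix_protein()
  m[cbind(utf8ToInt(paste0(a_chars, collapse = "")) + 1L,
          utf8ToInt(paste0(b_chars, collapse = "")) + 1L)]
}

#' Pairwise alignment of two sequences
#'
#' Affine-gap alignment (Gotoh) with either local (Smith-Waterman) or
#' global (Needleman-Wunsch) semantics. Used for cDNA-to-CDS mapping,
#' translated-mode mapping and exon similarity scoring.
#'
#' @param a,b sequences (character strings).
#' @param type `"dna"` (match +5 / mismatch -4 / `N` neutral) or
#'   `"protein"` (BLOSUM62).
#' @param mode `"local"` or `"global"`.
#' @param gap_open,gap_ext affine gap penalties (positive).
#' @return list with `score`, 0-based half-open aligned intervals
#'   `a_start`/`a_end`/`b_start`/`b_end`, a run-length op table
#'   (`op` in M/D/I, `len`), a `blocks` tibble of gapless aligned blocks
#'   with per-block mismatch counts, the overall `identity` over aligned
#'   columns, and `mismatches` (positions, 0-based in each sequence).
#' @export
align_pair <- function(a, b, type = c("dna", "protein"),
                       mode = c("local", "global"),
                       gap_open = 12L, gap_ext = 2L) {
  type <- match.arg(type); mode <- match.arg(mode)
  smat <- if (type == "dna") score_matrix_dna() else score_matrix_protein()
  r <- cpp_align(a, b, smat, as.integer(gap_open), as.integer(gap_ext), mode)
  decorate_alignment(r, a, b)
}

decorate_alignment <- function(r, a, b) {
  ops <- r$op; lens <- r$len
  ai <- r$a_start; bi <- r$b_start
  blocks <- list(); mm_a <- integer(); mm_b <- integer()
  ncols <- 0L; nid <- 0L
  av <- chars(a); bv <- chars(b)
  for (k in seq_along(ops)) {
    L <- lens[k]
    if (ops[k] == "M") {
      sa <- av[(ai + 1L):(ai + L)]; sb <- bv[(bi + 1L):(bi + L)]
      mm <- which(sa != sb)
      blocks[[length(blocks) + 1L]] <-
        tibble(a_start = ai, a_end = ai + L, b_start = bi, b_end = bi + L,
               n_mismatch = length(mm))
      mm_a <- c(mm_a, ai + mm - 1L); mm_b <- c(mm_b, bi + mm - 1L)
      ncols <- ncols + L; nid <- nid + (L - length(mm))
      ai <- ai + L; bi <- bi + L
    } else if (ops[k] == "D") {
      ai <- ai + L; ncols <- ncols + L
    } else {
      bi <- bi + L; ncols <- ncols + L
    }
  }
  r$blocks <- if (length(blocks)) bind_rows(blocks) else
    tibble(a_start = integer(), a_end = integer(), b_start = integer(),
           b_end = integer(), n_mismatch = integer())
  r$mismatches <- tibble(a_pos = mm_a, b_pos = mm_b)
  r$identity <- if (ncols > 0L) nid / ncols else 0
  r$n_columns <- ncols
  r
}
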