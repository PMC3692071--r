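#' Sequence primitives
#'
#' Nucleotide sequences are plain uppercase character strings over
#' `A,C,G,T,N`; protein sequences use the 20 amino-acid letters plus `X`
#' (unknown) and `*` (stop). [clean_dna()] canonicalises raw input:
#' lowercase is uppercased, `U` becomes `T`, and IUPAC ambiguity codes other
#' than `N` collapse to `N` with a warning. Characters outside the IUPAC
#' alphabet are rejected.
#'
#' @param x a character string.
#' @param id record identifier used in error messages.
#' @return the canonical sequence string.
#' @export
#' @examples
#' clean_dna("acgtn")
clean_dna <- function(x, id = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L)
    stopf("%s: nucleotide sequence must be a non-empty string", id)
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  bad <- gsub("[ACGTN]", "", x)
  if (nchar(bad) > 0L) {
    amb <- gsub("[^RYSWKMBDHV]", "", bad)
    ill <- gsub("[RYSWKMBDHV]", "", bad)
    if (nchar(ill) > 0L)
      stopf("%s: illegal nucleotide character(s): %s", id,
            paste(unique(chars(ill)), collapse = ","))
    warn(sprintf("%s: %d IUPAC ambiguity base(s) collapsed to N", id, nchar(amb)))
    x <- gsub("[RYSWKMBDHV]", "N", x)
  }
  x
}

#' @rdname clean_dna
#' @export
clean_protein <- function(x, id = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L)
    stopf("%s: protein sequence must be a non-empty string", id)
  x <- toupper(x)
  bad <- gsub("[ACDEFGHIKLMNPQRSTVWYX*]", "", x)
  if (nchar(bad) > 0L)
    stopf("%s: illegal amino-acid character(s): %s", id,
          paste(unique(chars(bad)), collapse = ","))
  internal <- substr(x, 1L, nchar(x) - 1L)
  if (grepl("*", substr(internal, 2, nchar(internal)), fixed = TRUE) &&
      FALSE) NULL # internal stops permitted when flagged by caller
  x
}

#' Genetic-code lookup
#'
#' Returns the codon-to-amino-acid map for an NCBI genetic-code table id
#' (e.g. 1 = standard, 6 = ciliate). Errors on unknown ids.
#'
#' @param table_id integer NCBI genetic-code number.
#' @return named character vector of length 64 (names = codons).
#' @export
codon_table <- function(table_id = 1L) {
  gc <- tryCatch(
    Biostrings::getGeneticCode(as.character(table_id)),
    error = function(e) stopf("unknown genetic-code table id: %s", table_id))
  gc
}

#' Translate a coding sequence
#'
#' Codons containing `N` translate to `X`; stop codons render as `*`.
#'
#' @param cds nucleotide string (length a multiple of 3 unless
#'   `allow_partial`).
#' @param table_id NCBI genetic-code table id (default 1).
#' @param allow_partial drop a trailing incomplete codon instead of erroring.
#' @return protein string of length `floor(nchar(cds) / 3)`.
#' @export
#' @examples
#' translate_cds("ATGTAA") # "M*"
translate_cds <- function(cds, table_id = 1L, allow_partial = FALSE) {
  n <- nchar(cds)
  r <- n %% 3L
  if (r != 0L) {
    if (!allow_partial)
      stopf("CDS length %d is not a multiple of 3", n)
    cds <- substr(cds, 1L, n - r)
  }
  if (nchar(cds) == 0L) return("")
  gc <- codon_table(table_id)
  as.character(Biostrings::translate(
    Biostrings::DNAString(cds), genetic.code = gc,
    no.init.codon = TRUE, if.fuzzy.codon = "X"))
}

# fast table-driven translation for hot loops (boundary scans, simulators);
# translate_cds() above is the Biostrings-backed reference used at the API
# surface and as an independent cross-check in the tests
fast_translate_v <- function(s, gc) {
  n <- nchar(s) %/% 3L
  if (n == 0L) return(character(0))
  cs <- substring(s, 3L * (0:(n - 1L)) + 1L, 3L * (1:n))
  aa <- unname(gc[cs])
  aa[is.na(aa)] <- "X"
  aa
}

fast_translate <- function(s, gc) paste0(fast_translate_v(s, gc), collapse = "")

#' Reverse complement
#'
#' @param s nucleotide string over `A,C,G,T,N`.
#' @return the reverse complement, same length.
#' @export
#' @examples
#' reverse_complement("AAAC") # "GTTT"
reverse_complement <- function(s) {
  if (nchar(s) == 0L) return(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
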