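# Internal helpers. All genomic coordinates in this package are 0-based,
# half-open, on the forward strand of the contig; conversion to 1-based
# inclusive happens only in the GFF writer.

# substring by 0-based half-open interval
subseq0 <- function(s, start, end) {
  if (end <= start) return("")
  substr(s, start + 1L, end)
}

# vectorised character access (1-based index into string)
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

str_from <- function(v) paste0(v, collapse = "")

# deterministic sub-seed derivation: fork stream `k` from a master seed
# (double arithmetic: the product exceeds integer range)
fork_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 16807) %% 2147483562)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# md5 of a string via a temp file (provenance checksums)
string_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeChar(x, f, eos = NULL)
  unname(tools::md5sum(f))
}

interval_overlap <- function(s1, e1, s2, e2) {
  max(0L, min(e1, e2) - max(s1, s2))
}
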