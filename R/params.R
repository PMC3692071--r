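#' Reconstruction parameters
#'
#' Tunables for the protein-to-genome reconstruction engine. All values are
#' surfaced here so difficult cases (very short exons, cross-species
#' searches, non-standard genetic codes) can be accommodated without
#' touching the algorithm.
#'
#' @param min_intron_len minimum intron length in nt (default 22, a standard
#'   eukaryotic floor leaving room for both splice dinucleotides).
#' @param max_intron_len maximum intron length considered when chaining.
#' @param min_identity minimum fraction of query residues that must match
#'   the target translation for a reconstruction to be accepted; relax for
#'   cross-species searches.
#' @param min_coverage minimum fraction of query residues that must be
#'   placed in exons.
#' @param min_exon_len_aa smallest exon the short-exon placer will seat
#'   (residues; 1 allows runs of very short exons).
#' @param splice_pairs allowed donor-acceptor pairs in preference order.
#' @param codon_table NCBI genetic-code table id.
#' @param seed_word_len exact-match seed length in residues for the
#'   translated matcher.
#' @param seed_min_score minimum BLOSUM62 score of an extended seed hit.
#' @param boundary_window half-width (nt) of the exhaustive window scanned
#'   when refining an exon/intron boundary.
#' @param intron_open,intron_scale chain penalty for an intron of length L:
#'   `intron_open + intron_scale * log(L)` (affine in log length).
#' @param max_chain_protein_overlap largest query overlap (residues)
#'   tolerated between chained seed hits before trimming.
#' @param terminal_flank nt of sequence beyond the outermost seeded exons
#'   searched when placing terminal short exons.
#' @return a named list of class `reconstruction_params`.
#' @export
reconstruction_params <- function(min_intron_len = 22L,
                                  max_intron_len = 50000L,
                                  min_identity = 0.9,
                                  min_coverage = 0.8,
                                  min_exon_len_aa = 1L,
                                  splice_pairs = c("GT-AG", "GC-AG"),
                                  codon_table = 1L,
                                  seed_word_len = 5L,
                                  seed_min_score = 20L,
                                  boundary_window = 90L,
                                  intron_open = 4,
                                  intron_scale = 1.5,
                                  max_chain_protein_overlap = 30L,
                                  terminal_flank = 600L) {
  stopifnot(min_identity > 0, min_identity <= 1, min_intron_len >= 4L)
  structure(list(
    min_intron_len = as.integer(min_intron_len),
    max_intron_len = as.integer(max_intron_len),
    min_identity = min_identity, min_coverage = min_coverage,
    min_exon_len_aa = as.integer(min_exon_len_aa),
    splice_pairs = splice_pairs, codon_table = as.integer(codon_table),
    seed_word_len = as.integer(seed_word_len),
    seed_min_score = as.integer(seed_min_score),
    boundary_window = as.integer(boundary_window),
    intron_open = intron_open, intron_scale = intron_scale,
    max_chain_protein_overlap = as.integer(max_chain_protein_overlap),
    terminal_flank = as.integer(terminal_flank)),
    class = "reconstruction_params")
}

#' cDNA mapping parameters
#'
#' @param min_identity minimum identity of a step-1 local alignment for a
#'   cDNA to be retained.
#' @param min_aligned_len minimum aligned length (nt) of a step-1 hit.
#' @param anchor_len exact-match anchor length (nt) for the step-2 spliced
#'   mapper.
#' @param min_intron_len smallest genomic gap treated as an intron in a
#'   spliced hit.
#' @param junction_window half-width (nt) of the exhaustive scan used to
#'   place each spliced-hit junction on a splice pair.
#' @param min_event_extension smallest exon extension (nt) accepted as
#'   splice-event evidence; shorter deviations are reported unclassifiable.
#' @param min_terminal_block smallest terminal block (nt) kept in a spliced
#'   hit; guards against junctions fabricated by adapter-tail anchors.
#' @param splice_pairs allowed donor-acceptor pairs in preference order.
#' @param try_revcomp also map the reverse complement of each cDNA and keep
#'   the better orientation.
#' @return a named list of class `cdna_params`.
#' @export
cdna_params <- function(min_identity = 0.9, min_aligned_len = 30L,
                        anchor_len = 10L, min_intron_len = 22L,
                        junction_window = 60L, min_event_extension = 3L,
                        min_terminal_block = 15L,
                        splice_pairs = c("GT-AG", "GC-AG"),
                        try_revcomp = TRUE) {
  structure(list(min_identity = min_identity,
                 min_aligned_len = as.integer(min_aligned_len),
                 anchor_len = as.integer(anchor_len),
                 min_intron_len = as.integer(min_intron_len),
                 junction_window = as.integer(junction_window),
                 min_event_extension = as.integer(min_event_extension),
                 min_terminal_block = as.integer(min_terminal_block),
                 splice_pairs = splice_pairs,
                 try_revcomp = isTRUE(try_revcomp)),
            class = "cdna_params")
}

#' Mutually-exclusive-exon search parameters
#'
#' @param max_length_difference largest candidate/source length difference
#'   as a fraction of the source exon length.
#' @param min_similarity similarity floor (fraction of identical aligned
#'   residues) for a candidate to enter a cluster.
#' @param recursive re-run the search treating accepted candidates as new
#'   sources until no new candidates appear.
#' @param search_all_introns search every intron instead of only the introns
#'   adjacent to the source exon.
#' @param flank_search nt of up/downstream sequence beyond the gene span to
#'   include in the search space (0 disables).
#' @param protein_level score similarity on translated exons (default);
#'   `FALSE` scores at the nucleotide level.
#' @param margin smallest intronic margin (nt) that must remain on either
#'   side of a candidate.
#' @return a named list of class `mxe_params`.
#' @export
mxe_params <- function(max_length_difference = 0.20, min_similarity = 0.15,
                       recursive = FALSE, search_all_introns = FALSE,
                       flank_search = 0L, protein_level = TRUE,
                       margin = 22L) {
  stopifnot(max_length_difference > 0, max_length_difference <= 1,
            min_similarity > 0, min_similarity <= 1, flank_search >= 0)
  structure(list(max_length_difference = max_length_difference,
                 min_similarity = min_similarity, recursive = isTRUE(recursive),
                 search_all_introns = isTRUE(search_all_introns),
                 flank_search = as.integer(flank_search),
                 protein_level = isTRUE(protein_level),
                 margin = as.integer(margin)),
            class = "mxe_params")
}

#' Tandem-duplicate search parameters
#'
#' @param min_identity identity floor for a reconstructed duplicate to be
#'   reported.
#' @param min_coverage query-coverage floor for a duplicate.
#' @param boundary_tolerance nt of slack ignored when matching exon
#'   boundaries between query and duplicate in homology mapping; covers
#'   the boundary jitter of reconstructing a diverged copy, while real
#'   fused/split overlaps are exon-sized and far exceed it.
#' @return a named list of class `tandem_params`.
#' @export
tandem_params <- function(min_identity = 0.6, min_coverage = 0.8,
                          boundary_tolerance = 12L) {
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 boundary_tolerance = as.integer(boundary_tolerance)),
            class = "tandem_params")
}
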