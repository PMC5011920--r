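# Global protein alignment used for family assignment and for transferring
# reference residue numbering onto queries. Needleman-Wunsch with affine
# gaps via Biostrings; a gap of length L costs gap_open + L * gap_extend.

default_submat <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Global pairwise protein alignment
#'
#' Optimal global (Needleman-Wunsch) alignment under a substitution matrix
#' with affine gap penalties. Identity is the fraction of aligned columns
#' that are exact matches (gaps count in the denominator), so a
#' self-alignment has identity 1.
#'
#' @param a,b Protein sequences (character scalars).
#' @param submat Substitution matrix; defaults to BLOSUM62.
#' @param gap_open,gap_extend Affine gap penalties (positive costs);
#'   defaults 10 and 1.
#' @return A list with `score`, `aligned_a`, `aligned_b` (gapped strings of
#'   equal length) and `identity` in \[0, 1\].
#' @examples
#' global_align("HAK", "HAK")$identity
#' @export
global_align <- function(a, b, submat = default_submat(),
                         gap_open = 10, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) {
    abort("cannot align an empty sequence")
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend,
    type = "global"
  )
  pa <- as.character(Biostrings::alignedPattern(aln))
  pb <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(pa, "")[[1]]
  cb <- strsplit(pb, "")[[1]]
  list(
    score = Biostrings::score(aln),
    aligned_a = pa,
    aligned_b = pb,
    identity = sum(ca == cb & ca != "-") / length(ca)
  )
}

# map 1-based positions of reference `b` onto residues of query `a` through
# a global alignment; returns the query residue at each reference position,
# or NA where the alignment places a gap
residues_at_reference_positions <- function(query, reference, positions,
                                            ...) {
  aln <- global_align(query, reference, ...)
  qa <- strsplit(aln$aligned_a, "")[[1]]
  rb <- strsplit(aln$aligned_b, "")[[1]]
  ref_pos <- cumsum(rb != "-")
  vapply(positions, function(p) {
    col <- which(ref_pos == p & rb != "-")[1]
    if (is.na(col) || qa[col] == "-") NA_character_ else qa[col]
  }, character(1))
}
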