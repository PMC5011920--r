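# Shared low-level sequence helpers. All sequences are plain upper-case
# character scalars/vectors internally; Biostrings objects are used at the
# file boundary and for alignment.

NUC_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X"
)

#' Reverse complement of DNA strings
#'
#' Vectorised over its input; `N` maps to `N`.
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

# validate residues of one sequence against the declared alphabet; errors name
# the offending record and 1-based position
check_alphabet <- function(seq, moltype, id) {
  alphabet <- if (moltype == "nucleotide") NUC_ALPHABET else AA_ALPHABET
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% alphabet)
  if (length(bad) > 0) {
    abort(sprintf(
      "record '%s': residue '%s' at position %d is not in the %s alphabet",
      id, chars[bad[1]], bad[1], moltype
    ))
  }
  invisible(TRUE)
}

# all k-mers of one sequence (forward strand), dropping any containing N
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) {
    return(character(0))
  }
  km <- substring(seq, seq_len(n - k + 1), k:n)
  km[!stringr::str_detect(km, "N")]
}

# strand-collapsed (canonical) k-mers: lexicographic min of k-mer and its
# reverse complement
canonical_kmers <- function(kmers) {
  rc <- revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE

# deterministic codon choice per amino acid (uses the current RNG state, so
# callers seed); stop residue not allowed
sample_codon <- function(aa) {
  codons <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE == aa]
  if (length(codons) == 0) {
    abort(sprintf("no codon encodes residue '%s'", aa))
  }
  codons[sample.int(length(codons), 1)]
}

# reverse-translate a protein (no stop appended) into a CDS
reverse_translate <- function(protein) {
  aas <- strsplit(protein, "", fixed = TRUE)[[1]]
  paste(vapply(aas, sample_codon, character(1)), collapse = "")
}

translate_cds <- function(cds) {
  as.character(Biostrings::translate(
    Biostrings::DNAString(cds),
    if.fuzzy.codon = "solve"
  ))
}

# random DNA of given length and GC content, using the current RNG state
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

`%||%` <- rlang::`%||%`
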