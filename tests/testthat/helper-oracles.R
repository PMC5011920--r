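# Independent oracles, deliberately naive: exhaustive enumeration over the
# global-alignment space with affine gap bookkeeping, and a brute-force
# non-overlapping motif scanner.

# Maximum global alignment score by enumerating every alignment path.
# A gap of length L costs open + L * ext; `last` tracks the previous move
# so gap openings are charged once per run.
oracle_align_score <- function(a, b, submat, open = 10, ext = 1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  rec <- function(i, j, last) {
    if (i > length(ca) && j > length(cb)) {
      return(0)
    }
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      best <- max(best, submat[ca[i], cb[j]] + rec(i + 1, j + 1, "d"))
    }
    if (i <= length(ca)) { # gap in b
      cost <- ext + if (last == "a") 0 else open
      best <- max(best, rec(i + 1, j, "a") - cost)
    }
    if (j <= length(cb)) { # gap in a
      cost <- ext + if (last == "b") 0 else open
      best <- max(best, rec(i, j + 1, "b") - cost)
    }
    best
  }
  rec(1, 1, "d")
}

# Non-overlapping leftmost SPKK/SPKR count by explicit position walking.
oracle_spkk_count <- function(protein, n_term_len = 60) {
  region <- substr(protein, 1, min(n_term_len, nchar(protein)))
  i <- 1
  count <- 0
  while (i <= nchar(region) - 3) {
    word <- substr(region, i, i + 3)
    if (word %in% c("SPKK", "SPKR")) {
      count <- count + 1
      i <- i + 4
    } else {
      i <- i + 1
    }
  }
  count
}

random_protein <- function(n, weights = NULL) {
  aas <- c(
    "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
  )
  paste(sample(aas, n, replace = TRUE, prob = weights), collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
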