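# Sperm-histone motif analysis: SPKK/SPKR repeat counting in N-terminal
# tails, R/K basicity profiling and the protamine screen.

#' Count SPKK/SPKR repeats in an N-terminal tail
#'
#' Non-overlapping, leftmost-first matches of S-P-K-\[K/R\] within the
#' scanned N-terminal segment, so tandem arrays like SPKKSPKK count once
#' per repeat and SPKKK counts once.
#'
#' @param protein Protein sequence.
#' @param n_term_len Length of the N-terminal segment to scan. Defaults to
#'   60 residues; when classification has located the histone-fold start,
#'   pass that position instead.
#' @return List with `protein_id` (`NA` unless supplied), `region`
#'   (`c(start, end)`, 1-based), `count` and `match_positions` (1-based
#'   starts).
#' @examples
#' count_spkk("MSPKKSPKRAGKA")$count
#' @export
count_spkk <- function(protein, n_term_len = 60) {
  n_term_len <- min(n_term_len, nchar(protein))
  region <- stringr::str_sub(protein, 1, n_term_len)
  m <- stringr::str_locate_all(region, "SPK[KR]")[[1]]
  list(
    protein_id = NA_character_,
    region = c(1L, as.integer(n_term_len)),
    count = nrow(m),
    match_positions = as.integer(m[, "start"])
  )
}

#' Profile the arginine/lysine basicity of a protein
#'
#' Computes global R, K and R+K fractions, the maximum R+K fraction over a
#' sliding window, and a protamine-likeness flag: sperm nuclear basic
#' proteins of the protamine (P) type are arginine-dominated, while
#' protamine-like (PL) proteins are strongly basic with more balanced R/K.
#'
#' @param protein Protein sequence.
#' @param window Sliding-window width in residues (default 30; clipped to
#'   the protein length).
#' @param rk_threshold Global R+K fraction at and above which the protein is
#'   protamine-like (default 0.45).
#' @param r_threshold Minimum global R fraction for protamine-likeness
#'   (default 0.25); R fraction >= 0.45 hints at the P type, otherwise PL.
#' @return One-row tibble: `fraction_R`, `fraction_K`, `fraction_RK`,
#'   `windowed_max_RK`, `protamine_like`, `protamine_type_hint`.
#' @export
basicity_profile <- function(protein, window = 30,
                             rk_threshold = 0.45, r_threshold = 0.25) {
  if (!nzchar(protein)) {
    abort("empty protein")
  }
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  n <- length(chars)
  is_r <- chars == "R"
  is_k <- chars == "K"
  fr <- sum(is_r) / n
  fk <- sum(is_k) / n
  frk <- fr + fk
  w <- min(window, n)
  rk <- as.integer(is_r | is_k)
  run <- cumsum(rk)
  wins <- run[w:n] - c(0, run)[seq_len(n - w + 1)]
  wmax <- max(wins) / w
  pl <- frk >= rk_threshold && fr >= r_threshold
  hint <- if (!pl) {
    "none"
  } else if (fr >= 0.45) {
    "P-type-like"
  } else {
    "PL-type-like"
  }
  tibble(
    fraction_R = fr, fraction_K = fk, fraction_RK = frk,
    windowed_max_RK = wmax, protamine_like = pl, protamine_type_hint = hint
  )
}

#' Screen a proteome for protamine or protamine-like proteins
#'
#' @param proteome Tibble with `id` and `residues`, or a named character
#'   vector.
#' @param ... Passed to [basicity_profile()].
#' @return Tibble with one row per protein (id plus the basicity profile),
#'   ordered as input. The flagged subset is `dplyr::filter(out, protamine_like)`;
#'   attribute `n_flagged` carries the summary count.
#' @export
protamine_screen <- function(proteome, ...) {
  if (is.character(proteome)) {
    proteome <- tibble(id = names(proteome), residues = unname(proteome))
  }
  if (nrow(proteome) == 0) {
    out <- tibble(
      protein_id = character(), fraction_R = numeric(),
      fraction_K = numeric(), fraction_RK = numeric(),
      windowed_max_RK = numeric(), protamine_like = logical(),
      protamine_type_hint = character()
    )
    attr(out, "n_flagged") <- 0L
    return(out)
  }
  out <- map(seq_len(nrow(proteome)), function(i) {
    prof <- basicity_profile(proteome$residues[i], ...)
    mutate(prof, protein_id = proteome$id[i], .before = 1)
  }) |> list_rbind()
  attr(out, "n_flagged") <- sum(out$protamine_like)
  out
}
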