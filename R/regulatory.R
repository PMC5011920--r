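# Regulatory hallmarks of replication-dependent histone genes: upstream
# TATA-box, 3'-UTR stem-loop (16 nt: 6-bp stem + 4-nt loop), purine-rich
# histone downstream element (HDE) and polyA signal, and the rule-based
# replication-dependency / pseudogene verdict built from them.

# stem pair score: GC = 3, AT = 2, GU(GT) = 1, anything else -2. A perfect
# all-AT stem scores 12, which is the default stability threshold: mismatched
# stems always fall below it (3 matches + 3 mismatches tops out at 3).
STEM_PAIR_SCORES <- c(
  "GC" = 3, "CG" = 3, "AT" = 2, "TA" = 2, "GT" = 1, "TG" = 1
)

#' Default stem-loop stability threshold
#'
#' The additive pair score of a perfect all-AT 6-bp stem (12). Hits scoring
#' below this are flagged thermodynamically unstable, standing in for an RNA
#' folding energy calculation.
#'
#' @return Numeric scalar.
#' @export
stability_threshold_default <- function() 12

#' Scan upstream sequence for TATA-boxes
#'
#' Matches the consensus TAWAAA (W = A or T) on the forward strand within
#' the window closest to the start codon.
#'
#' @param upstream Nucleotide sequence immediately upstream of the start
#'   codon (its last base abuts the ATG).
#' @param window Number of terminal bases to scan (default 120).
#' @return Integer vector of hit distances upstream of the start codon
#'   (1-based; the value is the number of bases between the first base of
#'   the motif and the ATG, inclusive of the motif).
#' @export
scan_tata <- function(upstream, window = 120) {
  n <- nchar(upstream)
  if (window > n) {
    window <- n
  }
  region <- stringr::str_sub(upstream, n - window + 1, n)
  # manual scan so overlapping occurrences (runs like TATAAAA) all report
  starts <- integer(0)
  for (s in seq_len(max(0, nchar(region) - 5))) {
    if (grepl("^TA[AT]AAA", stringr::str_sub(region, s, s + 5))) {
      starts <- c(starts, s)
    }
  }
  rev(window - starts + 1L)
}

#' Find the 3'-UTR stem-loop element
#'
#' Scans offsets 0..`search_span` after the stop codon for a 16-nt window
#' whose bases 1-6 pair antiparallel with bases 16-11 (Watson-Crick or GU),
#' with at most `max_mismatch` broken pairs. The best hit by additive
#' stability score (GC 3, AT 2, GU 1, mismatch -2) is returned; ties go to
#' the leftmost window.
#'
#' @param utr Nucleotide sequence beginning immediately after the stop
#'   codon.
#' @param search_span Maximum offset of the element start (default 40 nt,
#'   covering the 6-17-nt non-conserved spacer).
#' @param max_mismatch Maximum broken stem pairs (default 3).
#' @param consensus Optional 16-nt consensus for the reported edit
#'   distance (default: the metazoan histone stem-loop consensus).
#' @param stability_threshold Score below which the hit is flagged
#'   unstable.
#' @return One-row tibble (`offset_after_stop`, `element_sequence`,
#'   `stem_len`, `loop_len`, `stem_mismatches`, `stability_score`,
#'   `consensus_distance`, `stable`) or `NULL` when no window qualifies.
#' @export
find_stem_loop <- function(utr, search_span = 40, max_mismatch = 3,
                           consensus = "GGCTCTTTTCAGAGCC",
                           stability_threshold = stability_threshold_default()) {
  n <- nchar(utr)
  if (n < 16) {
    return(NULL)
  }
  best <- NULL
  for (off in 0:min(search_span, n - 16)) {
    win <- stringr::str_sub(utr, off + 1, off + 16)
    sc <- stem_score(win)
    if (sc$mismatches > max_mismatch) {
      next
    }
    if (is.null(best) || sc$score > best$stability_score) {
      best <- tibble(
        offset_after_stop = off,
        element_sequence = win,
        stem_len = 6L,
        loop_len = 4L,
        stem_mismatches = sc$mismatches,
        stability_score = sc$score,
        consensus_distance = as.integer(adist(win, consensus)),
        stable = sc$score >= stability_threshold
      )
    }
  }
  best
}

# additive pair score and mismatch count of a 16-nt window under the fixed
# 6 + 4 + 6 hairpin geometry
stem_score <- function(window) {
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  pairs <- paste0(chars[1:6], chars[16:11])
  scores <- STEM_PAIR_SCORES[pairs]
  mism <- sum(is.na(scores))
  scores[is.na(scores)] <- -2
  list(score = sum(scores), mismatches = mism)
}

#' Scan for a purine-rich histone downstream element (HDE)
#'
#' @param downstream Nucleotide sequence beginning immediately after the
#'   stem-loop element.
#' @param window HDE width in nt (default 10).
#' @param span Search range for the window start (default 25 nt).
#' @param min_purine_fraction Reporting threshold (default 0.7).
#' @return One-row tibble (`position` = 0-based window start after the
#'   stem-loop, `purine_fraction`) or `NULL`. Best window by purine
#'   fraction, ties to the leftmost.
#' @export
scan_hde <- function(downstream, window = 10, span = 25,
                     min_purine_fraction = 0.7) {
  n <- nchar(downstream)
  if (n < window) {
    return(NULL)
  }
  starts <- 0:min(span, n - window)
  frac <- vapply(starts, function(s) {
    win <- stringr::str_sub(downstream, s + 1, s + window)
    stringr::str_count(win, "[AG]") / window
  }, numeric(1))
  best <- which.max(frac)
  if (frac[best] < min_purine_fraction) {
    return(NULL)
  }
  tibble(position = starts[best], purine_fraction = frac[best])
}

#' Scan a 3'-UTR for a polyadenylation signal
#'
#' @param utr Nucleotide (DNA) sequence of the 3'-UTR.
#' @param motifs Accepted signal motifs (default AATAAA and ATTAAA).
#' @return 0-based position of the first occurrence, or `NULL`.
#' @export
scan_polyA <- function(utr, motifs = c("AATAAA", "ATTAAA")) {
  if (stringr::str_detect(utr, "U")) {
    abort("nucleotide alphabet is DNA; found 'U' in the 3'-UTR")
  }
  hits <- map_int(motifs, function(m) {
    p <- stringr::str_locate(utr, stringr::fixed(m))[1, "start"]
    if (is.na(p)) NA_integer_ else as.integer(p - 1L)
  })
  if (all(is.na(hits))) {
    return(NULL)
  }
  min(hits, na.rm = TRUE)
}

#' Compute the full 3'-UTR / promoter feature set for one gene
#'
#' Runs [scan_tata()], [find_stem_loop()], [scan_hde()] (only downstream of
#' a found stem-loop) and [scan_polyA()] and bundles the results.
#'
#' @param gene_id Gene identifier.
#' @param upstream Sequence upstream of the start codon.
#' @param utr Sequence immediately after the stop codon.
#' @param ... Passed to the individual scanners.
#' @return A list of class `utr_feature_set` with elements `gene_id`,
#'   `tata_hits`, `stem_loop`, `hde`, `polyA`.
#' @export
utr_features <- function(gene_id, upstream, utr, ...) {
  args <- list(...)
  sl <- do.call(find_stem_loop, c(list(utr), args[names(args) %in%
    c("search_span", "max_mismatch", "consensus", "stability_threshold")]))
  hde <- NULL
  if (!is.null(sl)) {
    after <- stringr::str_sub(utr, sl$offset_after_stop + 17, nchar(utr))
    if (nchar(after) >= 10) {
      hde <- scan_hde(after)
    }
  }
  structure(
    list(
      gene_id = gene_id,
      tata_hits = scan_tata(upstream),
      stem_loop = sl,
      hde = hde,
      polyA = scan_polyA(utr)
    ),
    class = "utr_feature_set"
  )
}

#' Call replication-dependency from 3'-UTR features
#'
#' Rules, applied in order:
#' 1. stable stem-loop + HDE + no polyA signal -> `replication_dependent`
#' 2. polyA signal + no stem-loop -> `replication_independent`
#' 3. unstable stem-loop + no polyA + no expression evidence in any stage
#'    -> `pseudogene_candidate`
#' 4. otherwise `ambiguous`
#'
#' @param features A `utr_feature_set` from [utr_features()].
#' @param expression Optional expression-evidence tibble ([read_expression_table()]);
#'   only rows for `features$gene_id` are consulted.
#' @param stability_threshold Stem-loop score at and above which the loop
#'   counts as stable.
#' @return One-row tibble: `gene_id`, `verdict`, `rationale` (list-column
#'   with at least one fired rule).
#' @export
call_dependency <- function(features, expression = NULL,
                            stability_threshold = stability_threshold_default()) {
  sl <- features$stem_loop
  has_sl <- !is.null(sl)
  stable <- has_sl && sl$stability_score >= stability_threshold
  has_hde <- !is.null(features$hde)
  has_polya <- !is.null(features$polyA)
  expressed <- NA
  if (!is.null(expression)) {
    rows <- expression[expression$gene_id == features$gene_id, ]
    expressed <- if (nrow(rows) == 0) NA else any(rows$detected)
  }
  rationale <- character(0)
  if (stable && has_hde && !has_polya) {
    verdict <- "replication_dependent"
    rationale <- c(
      sprintf("stable 3'-UTR stem-loop (score %d >= %d)",
              sl$stability_score, stability_threshold),
      sprintf("HDE with purine fraction %.2f", features$hde$purine_fraction),
      "no polyA signal"
    )
  } else if (has_polya && !has_sl) {
    verdict <- "replication_independent"
    rationale <- c(
      sprintf("polyA signal at UTR position %d", features$polyA),
      "no 3'-UTR stem-loop"
    )
  } else if (has_sl && !stable && !has_polya && identical(expressed, FALSE)) {
    verdict <- "pseudogene_candidate"
    rationale <- c(
      sprintf("stem-loop with %d mismatches, stability score %d < %d (unstable)",
              sl$stem_mismatches, sl$stability_score, stability_threshold),
      "no polyA signal",
      "no expression evidence in any stage"
    )
  } else {
    verdict <- "ambiguous"
    rationale <- sprintf(
      "no rule fired (stem-loop: %s, stable: %s, HDE: %s, polyA: %s, expressed: %s)",
      has_sl, stable, has_hde, has_polya, expressed
    )
  }
  tibble(
    gene_id = features$gene_id, verdict = verdict, rationale = list(rationale)
  )
}
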