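# Histone family/variant classification: global-alignment scoring against a
# bundled reference set, refined by diagnostic residues (H3.3 sites, the
# H2A.X C-terminal SQ motif, macro-domain length, sperm-H2B SPKK tails).

#' Load a histone reference set
#'
#' The bundled references cover the five histone families (H1, H2A, H2B,
#' H3, H4) plus the variants H3.3, H2A.X, H2A.Z, macroH2A and CENP-A.
#' Human canonical isoform sequences are used; the macroH2A and CENP-A
#' entries are synthetic H2A-/H3-derived constructs (marked `synthetic` in
#' their ids and descriptions).
#'
#' @param path FASTA of reference proteins whose headers carry `family=` and
#'   `variant=` tokens; defaults to the bundled set.
#' @return Tibble with `id`, `family`, `variant`, `residues`, sorted by
#'   family then variant (the classification tie-break order).
#' @export
reference_set <- function(path = system.file("extdata",
                                             "reference_histones.fasta",
                                             package = "histannot")) {
  recs <- read_fasta(path, "protein")
  refs <- recs |>
    mutate(
      family = stringr::str_match(.data$description, "family=(\\S+)")[, 2],
      variant = stringr::str_match(.data$description, "variant=(\\S+)")[, 2]
    ) |>
    select("id", "family", "variant", "residues") |>
    arrange(.data$family, .data$variant)
  missing <- setdiff(c("H1", "H2A", "H2B", "H3", "H4"), refs$family)
  if (length(missing) > 0) {
    abort(sprintf(
      "reference set lacks family/families: %s", paste(missing, collapse = ", ")
    ))
  }
  refs
}

ref_seq <- function(refs, family, variant) {
  hit <- refs$residues[refs$family == family & refs$variant == variant]
  if (length(hit) == 0) {
    abort(sprintf("reference set has no %s/%s entry", family, variant))
  }
  hit[1]
}

#' H3.3 diagnostic sites
#'
#' The five positions (canonical H3 numbering of the mature protein) that
#' separate H3.3 from canonical H3: 31 (A vs S), 87/89/90 (SAVM vs AAIG) and
#' 96 (C vs S). Site 96 is accepted in either the S or A state because the
#' two are reported interchangeably for this site; the observed residue is
#' always recorded.
#'
#' @return Tibble with `position`, `canonical`, `variant_states`.
#' @export
h3_diagnostic_sites <- function() {
  tibble(
    position = c(31L, 87L, 89L, 90L, 96L),
    canonical = c("A", "S", "V", "M", "C"),
    variant_states = list("S", "A", "I", "G", c("S", "A"))
  )
}

#' Score the H3.3 diagnostic residues of a query against canonical H3
#'
#' Positions are defined on the canonical reference and transferred onto the
#' query through a global alignment. A gap at a diagnostic site is reported
#' `indeterminate` and excluded from the match count.
#'
#' @param query Protein sequence (character scalar).
#' @param canonical_h3 Canonical H3 reference sequence; defaults to the
#'   bundled one.
#' @param min_identity Minimum query/reference identity for the transfer to
#'   be meaningful (default 0.8).
#' @return List with `report` (tibble: position, canonical, observed,
#'   status) and `matches` (number of sites in the H3.3 state).
#' @export
h3_variant_diagnostics <- function(query,
                                   canonical_h3 = ref_seq(reference_set(),
                                                          "H3", "canonical"),
                                   min_identity = 0.8) {
  aln <- global_align(query, canonical_h3)
  if (aln$identity < min_identity) {
    abort(sprintf(
      "query identity to canonical H3 (%.2f) below %.2f; diagnostic transfer unreliable",
      aln$identity, min_identity
    ))
  }
  sites <- h3_diagnostic_sites()
  observed <- residues_at_reference_positions(
    query, canonical_h3, sites$position
  )
  status <- pmap(
    list(observed, sites$canonical, sites$variant_states),
    function(obs, can, var) {
      if (is.na(obs)) {
        "indeterminate"
      } else if (obs %in% var && obs != can) {
        "variant"
      } else if (obs == can) {
        "canonical"
      } else {
        "other"
      }
    }
  )
  report <- tibble(
    position = sites$position,
    canonical = sites$canonical,
    observed = observed,
    status = unlist(status)
  )
  list(report = report, matches = sum(report$status == "variant"))
}

#' Test the H2A.X C-terminal SQ motif
#'
#' The replication-linked H2A.X variant carries an extreme C-terminal
#' S-Q-\[E/D/I\]-\[Y/F/L\] tetrad whose serine is phosphorylated on DNA
#' damage. A near match fits positions 1, 2 and 4 but not 3 (the SQAY-type
#' tail).
#'
#' @param query Protein sequence of length >= 4.
#' @return List with `match`, `tetrad` (the final four residues) and
#'   `near_match`.
#' @export
h2ax_cterm_check <- function(query) {
  if (nchar(query) < 4) {
    abort("query shorter than 4 residues")
  }
  tetrad <- stringr::str_sub(query, -4, -1)
  r <- strsplit(tetrad, "")[[1]]
  ok124 <- r[1] == "S" && r[2] == "Q" && r[4] %in% c("Y", "F", "L")
  ok3 <- r[3] %in% c("E", "D", "I")
  list(match = ok124 && ok3, tetrad = tetrad, near_match = ok124 && !ok3)
}

#' Test for a macro-domain-length C-terminal extension
#'
#' macroH2A is an H2A-family variant roughly 2.8 times the length of
#' canonical H2A; any H2A-family protein longer than `factor` times the
#' canonical reference is flagged as macro-domain carrying.
#'
#' @param query Protein sequence.
#' @param canonical_h2a Canonical H2A reference sequence.
#' @param factor Length ratio threshold (default 1.8).
#' @return Logical.
#' @export
macro_length_check <- function(query,
                               canonical_h2a = ref_seq(reference_set(),
                                                       "H2A", "canonical"),
                               factor = 1.8) {
  nchar(query) > factor * nchar(canonical_h2a)
}

# refine the variant label of one query given its family and the reference
# scores; returns list(variant, evidence)
refine_variant <- function(query, family, best, per_ref, refs, spkk_min = 2) {
  evidence <- sprintf(
    "best reference %s (%s/%s), score %.1f, identity %.3f",
    best$id, best$family, best$variant, best$score, best$identity
  )
  variant <- best$variant
  if (family == "H2A") {
    cterm <- h2ax_cterm_check(query)
    if (macro_length_check(query, ref_seq(refs, "H2A", "canonical"))) {
      variant <- "macroH2A"
      evidence <- c(evidence, sprintf(
        "length %d exceeds 1.8x canonical H2A: macro-domain extension",
        nchar(query)
      ))
    } else if (cterm$match || cterm$near_match) {
      variant <- "H2A.X"
      evidence <- c(evidence, sprintf(
        "C-terminal tetrad %s %s SQ[E/D/I][Y/F/L]", cterm$tetrad,
        if (cterm$match) "matches" else "near-matches"
      ))
    } else if (variant %in% c("H2A.X", "macroH2A")) {
      # best reference suggested a variant its diagnostics do not support
      variant <- "canonical"
    }
  } else if (family == "H3") {
    diag <- tryCatch(
      h3_variant_diagnostics(query, ref_seq(refs, "H3", "canonical")),
      error = function(e) NULL
    )
    if (variant == "CENP-A") {
      evidence <- c(evidence, "H3-derived centromeric reference is best hit")
    } else if (!is.null(diag) && diag$matches >= 3) {
      variant <- "H3.3"
      evidence <- c(evidence, sprintf(
        "%d/%d diagnostic sites in the H3.3 state (%s)",
        diag$matches, nrow(diag$report),
        paste(diag$report$position[diag$report$status == "variant"],
              collapse = ",")
      ))
    } else if (!is.null(diag)) {
      variant <- "canonical"
      evidence <- c(evidence, sprintf(
        "%d/%d diagnostic sites in the H3.3 state", diag$matches,
        nrow(diag$report)
      ))
    }
  } else if (family == "H2B") {
    spkk <- count_spkk(query)
    if (spkk$count >= spkk_min) {
      variant <- "sperm-H2B"
      evidence <- c(evidence, sprintf(
        "%d SPKK/SPKR repeats in the N-terminal tail", spkk$count
      ))
    }
  }
  list(variant = variant, evidence = evidence)
}

#' Assign histone family and variant to query proteins
#'
#' Each query is globally aligned to every reference; the best-scoring
#' reference sets the family when identity reaches `min_identity`
#' (otherwise `unclassified`). The variant is then refined by diagnostic
#' rules: H3.3 sites, the H2A.X C-terminal tetrad, macroH2A length, and
#' SPKK-repeat tails for sperm-type H2B. References are scored in a fixed
#' (family, variant) order so permuting the reference file never changes a
#' call.
#'
#' @param queries Tibble with `id` and `residues` (as from [read_fasta()]),
#'   or a named character vector of protein sequences.
#' @param refs Reference tibble from [reference_set()].
#' @param min_identity Family-level identity floor (default 0.35; shuffled
#'   controls score well below genuine histones).
#' @param spkk_min Minimum SPKK/SPKR repeat count for the sperm-H2B variant
#'   label (default 2).
#' @return Tibble with one row per query: `query_id`, `family`, `variant`,
#'   `score`, `identity` and an `evidence` list-column of fired rules.
#' @export
assign_family <- function(queries, refs = reference_set(),
                          min_identity = 0.35, spkk_min = 2) {
  if (is.character(queries)) {
    queries <- tibble(id = names(queries), residues = unname(queries))
  }
  stopifnot(all(c("id", "residues") %in% names(queries)))
  rows <- map(seq_len(nrow(queries)), function(i) {
    q <- queries$residues[i]
    per_ref <- map(seq_len(nrow(refs)), function(j) {
      aln <- global_align(q, refs$residues[j])
      tibble(
        id = refs$id[j], family = refs$family[j], variant = refs$variant[j],
        score = aln$score, identity = aln$identity
      )
    }) |> list_rbind()
    # ties resolved by the (family, variant) sort order of the reference set
    best <- per_ref[which.max(per_ref$score), ]
    if (best$identity < min_identity) {
      tibble(
        query_id = queries$id[i], family = "unclassified", variant = "",
        score = best$score, identity = best$identity,
        evidence = list(sprintf(
          "best identity %.3f below floor %.2f", best$identity, min_identity
        ))
      )
    } else {
      ref <- refine_variant(q, best$family, best, per_ref, refs, spkk_min)
      tibble(
        query_id = queries$id[i], family = best$family,
        variant = ref$variant, score = best$score, identity = best$identity,
        evidence = list(ref$evidence)
      )
    }
  })
  out <- list_rbind(rows)
  class(out) <- c("histone_calls", class(out))
  out
}

#' Tabulate a classification into per-family and per-variant counts
#'
#' @param calls Tibble from [assign_family()].
#' @return Tibble with `family`, `variant`, `n`; `sum(n)` equals the number
#'   of classified inputs.
#' @export
inventory <- function(calls) {
  if (nrow(calls) == 0) {
    return(tibble(
      family = c("H1", "H2A", "H2B", "H3", "H4"), variant = "canonical",
      n = 0L
    ))
  }
  calls |>
    count(.data$family, .data$variant, name = "n") |>
    arrange(.data$family, .data$variant)
}
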