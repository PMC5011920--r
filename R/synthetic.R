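# Synthetic genomes with planted ground truth. The generator emulates the
# genomic organisation the annotation pipeline targets: a tandem-repeated
# cluster unit of five intron-less canonical histone genes (TATA-box,
# 3'-UTR stem-loop, HDE, no polyA), dispersed variant loci with introns and
# polyA signals, one pseudogene analogue with a 3-mismatch stem-loop, and
# sperm-type H2B genes with SPKK-repeat N-termini. Coding sequences derive
# from the bundled references via seeded codon sampling plus residue
# substitutions, so classification against the same references is exercised
# across genuine divergence.

# Pyrimidine-only filler: C/T cannot form Watson-Crick or GU pairs with each
# other and contain no A/G, so inert spacers can never harbour spurious
# TATA-boxes, stem-loops, HDEs or polyA signals. Random composition (drawn
# from the caller's seeded RNG) keeps spacer k-mers locus-specific, so
# repeat-cluster k-mer depths reflect the planted copy number rather than
# shared low-complexity filler.
inert <- function(n) {
  if (n <= 0) {
    return("")
  }
  paste(sample(c("C", "T"), n, replace = TRUE), collapse = "")
}

#' Build a 16-nt histone stem-loop element with a given number of stem
#' mismatches
#'
#' Starts from a perfect 6-bp-stem / 4-nt-loop element and breaks `m` stem
#' pairs by substituting bases on the 3' side of the stem (substitutions
#' chosen so no GU wobble pair survives).
#'
#' @param mismatches Number of broken stem pairs, 0-6.
#' @param base Perfect element to start from.
#' @return 16-nt character scalar.
#' @export
make_stem_loop <- function(mismatches = 0, base = "GGCTCTTTTCAGAGCC") {
  stopifnot(mismatches >= 0, mismatches <= 6, nchar(base) == 16)
  chars <- strsplit(base, "", fixed = TRUE)[[1]]
  # Break pairs loop-proximal-first via the 3' stem side (positions 11..16
  # pair with 6..1). Pyrimidine substitutions are used where possible so a
  # mismatched element gains no spurious wobble pairs in shifted windows.
  subs <- c("11" = "C", "12" = "T", "13" = "C", "14" = "T", "15" = "A",
            "16" = "A")
  if (mismatches > 0) {
    for (p in names(subs)[seq_len(mismatches)]) {
      chars[as.integer(p)] <- subs[[p]]
    }
  }
  paste(chars, collapse = "")
}

#' Prepend SPKK/SPKR repeat blocks to an H2B sequence
#'
#' Builds a sperm-type H2B analogue: `n_repeats` S-P-K-\[K/R\] blocks
#' (fourth residue alternating K, R) are prepended to the N terminus.
#' Accepts a protein or a CDS (detected by alphabet); for a CDS the blocks
#' are inserted immediately after the start codon.
#'
#' @param base_h2b Protein or CDS sequence.
#' @param n_repeats Number of repeat blocks, 0-10.
#' @return Modified sequence; [count_spkk()] on (the translation of) the
#'   result returns exactly `n_repeats` more than on the base.
#' @export
make_sperm_h2b <- function(base_h2b, n_repeats) {
  stopifnot(n_repeats >= 0, n_repeats <= 10)
  blocks <- paste(rep_len(c("SPKK", "SPKR"), n_repeats), collapse = "")
  if (n_repeats == 0) {
    return(base_h2b)
  }
  if (!stringr::str_detect(base_h2b, "[^ACGTN]")) {
    cds_block <- paste(vapply(
      strsplit(blocks, "", fixed = TRUE)[[1]],
      function(aa) c(S = "AGC", P = "CCA", K = "AAA", R = "AGA")[[aa]],
      character(1)
    ), collapse = "")
    if (startsWith(base_h2b, "ATG")) {
      paste0("ATG", cds_block, stringr::str_sub(base_h2b, 4))
    } else {
      paste0(cds_block, base_h2b)
    }
  } else {
    paste0(blocks, base_h2b)
  }
}

# residue substitution at `rate` outside protected 1-based positions;
# replacements drawn from a broad pool, never the original residue
mutate_protein <- function(protein, rate, protected = integer(0)) {
  if (rate <= 0) {
    return(protein)
  }
  pool <- c("A", "R", "N", "D", "Q", "E", "G", "H", "I", "L", "K", "M", "F",
            "P", "S", "T", "V", "Y")
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  hit <- setdiff(hit, protected)
  for (i in hit) {
    chars[i] <- sample(setdiff(pool, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' The default 19-gene synthetic histone complement
#'
#' Mirrors the feature logic of a full hydrozoan-style histone complement:
#' five clustered canonical genes (H1.1, H2A.1, H2B.1, H3.1, H4.1), a
#' pseudogene analogue (H1.3: 3-mismatch stem-loop, no HDE, no polyA, never
#' expressed), replication-independent variants with polyA signals and
#' introns (H1.2, H2A.X.1, H2A.X.2, H2A.Z, macroH2A, CENP-A, H3.3.1), a
#' replication-dependent H3.3 (H3.3.2) and five sperm-type/variant H2B
#' genes with SPKK-repeat tails (H2B.2-6; repeats 0, 6, 7, 5, 6).
#'
#' @return Tibble of per-gene specifications consumed by
#'   [generate_genome()].
#' @export
default_gene_set <- function() {
  g <- function(id, family, variant, ref, clustered, sl, hde, polya,
                introns, spkk, strand, expressed, verdict) {
    tibble(
      gene_id = id, family = family, variant = variant, base_ref = ref,
      clustered = clustered, stem_loop_mismatches = sl, hde = hde,
      polyA = polya, introns = introns, spkk = spkk, strand = strand,
      expressed_stages = list(expressed), expected_verdict = verdict
    )
  }
  stages_all <- c("larva", "feeding", "male", "female")
  bind_rows(
    g("H1.1", "H1", "canonical", "H1_ref", TRUE, 0L, TRUE, FALSE, 0L, 0L,
      "+", stages_all, "replication_dependent"),
    g("H2A.1", "H2A", "canonical", "H2A_ref", TRUE, 0L, TRUE, FALSE, 0L, 0L,
      "+", stages_all, "replication_dependent"),
    g("H2B.1", "H2B", "canonical", "H2B_ref", TRUE, 0L, TRUE, FALSE, 0L, 0L,
      "+", stages_all, "replication_dependent"),
    g("H3.1", "H3", "canonical", "H3_ref", TRUE, 0L, TRUE, FALSE, 0L, 0L,
      "+", stages_all, "replication_dependent"),
    g("H4.1", "H4", "canonical", "H4_ref", TRUE, 0L, TRUE, FALSE, 0L, 0L,
      "+", stages_all, "replication_dependent"),
    g("H1.2", "H1", "canonical", "H1_ref", FALSE, NA_integer_, FALSE, TRUE,
      1L, 0L, "+", stages_all, "replication_independent"),
    g("H1.3", "H1", "canonical", "H1_ref", FALSE, 3L, FALSE, FALSE, 0L, 0L,
      "+", character(0), "pseudogene_candidate"),
    g("H2A.X.1", "H2A", "H2A.X", "H2AX_ref", FALSE, NA_integer_, FALSE,
      TRUE, 1L, 0L, "+", stages_all, "replication_independent"),
    g("H2A.X.2", "H2A", "H2A.X", "H2AX_ref", FALSE, NA_integer_, FALSE,
      TRUE, 4L, 0L, "+", "female", "replication_independent"),
    g("H2A.Z", "H2A", "H2A.Z", "H2AZ_ref", FALSE, NA_integer_, FALSE, TRUE,
      4L, 0L, "-", stages_all, "replication_independent"),
    g("macroH2A", "H2A", "macroH2A", "macroH2A_ref_synthetic", FALSE,
      NA_integer_, FALSE, TRUE, 7L, 0L, "+", stages_all,
      "replication_independent"),
    g("CENP-A", "H3", "CENP-A", "CENPA_ref_synthetic", FALSE, NA_integer_,
      FALSE, TRUE, 1L, 0L, "+", stages_all, "replication_independent"),
    g("H3.3.1", "H3", "H3.3", "H33_ref", FALSE, NA_integer_, FALSE, TRUE,
      1L, 0L, "-", stages_all, "replication_independent"),
    g("H3.3.2", "H3", "H3.3", "H33_ref", FALSE, 0L, TRUE, FALSE, 0L, 0L,
      "+", stages_all, "replication_dependent"),
    g("H2B.2", "H2B", "canonical", "H2B_ref", FALSE, 0L, TRUE, FALSE, 0L,
      0L, "+", "male", "replication_dependent"),
    g("H2B.3", "H2B", "sperm-H2B", "H2B_ref", FALSE, 0L, TRUE, FALSE, 0L,
      6L, "+", "male", "replication_dependent"),
    g("H2B.4", "H2B", "sperm-H2B", "H2B_ref", FALSE, 0L, TRUE, FALSE, 0L,
      7L, "+", c("larva", "feeding", "male", "female"),
      "replication_dependent"),
    g("H2B.5", "H2B", "sperm-H2B", "H2B_ref", FALSE, 0L, TRUE, FALSE, 0L,
      5L, "+", "male", "replication_dependent"),
    g("H2B.6", "H2B", "sperm-H2B", "H2B_ref", FALSE, 0L, TRUE, FALSE, 0L,
      6L, "+", "male", "replication_dependent")
  )
}

#' Simulation configuration
#'
#' @param seed Integer RNG seed; fixed seed implies byte-identical outputs.
#' @param background_length Background genome length in nt.
#' @param background_gc Background GC fraction (the emulated genome is
#'   AT-rich; default 0.35).
#' @param cluster_copies Tandem copies of the canonical cluster unit.
#' @param genes Per-gene specification tibble ([default_gene_set()] by
#'   default); `clustered` rows form the cluster unit in order, the rest
#'   are dispersed variant loci.
#' @param read_length Read length in nt.
#' @param coverage Sequencing depth over the whole genome (fold).
#' @param error_rate Per-base substitution error rate of simulated reads.
#' @param paired Emit mate pairs instead of single-end reads.
#' @param aa_substitution_rate Residue substitution rate applied to
#'   reference-derived proteins outside protected diagnostic regions
#'   (default 0.05; with random codon usage this yields roughly 15%
#'   nucleotide divergence, synonymous-biased).
#' @param intron_length Length of each inserted intron (GT...AG).
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, background_length = 20000,
                              background_gc = 0.35, cluster_copies = 5L,
                              genes = default_gene_set(),
                              read_length = 250L, coverage = 20,
                              error_rate = 0, paired = FALSE,
                              aa_substitution_rate = 0.05,
                              intron_length = 60L) {
  cfg <- list(
    seed = as.integer(seed), background_length = background_length,
    background_gc = background_gc, cluster_copies = as.integer(cluster_copies),
    genes = genes, read_length = as.integer(read_length),
    coverage = coverage, error_rate = error_rate, paired = paired,
    aa_substitution_rate = aa_substitution_rate,
    intron_length = as.integer(intron_length)
  )
  validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_config <- function(cfg) {
  checks <- list(
    seed = is.finite(cfg$seed),
    background_length = cfg$background_length >= 1000,
    background_gc = cfg$background_gc >= 0 && cfg$background_gc <= 1,
    cluster_copies = cfg$cluster_copies >= 0,
    read_length = cfg$read_length >= 20,
    coverage = cfg$coverage > 0,
    error_rate = cfg$error_rate >= 0 && cfg$error_rate < 1,
    aa_substitution_rate = cfg$aa_substitution_rate >= 0 &&
      cfg$aa_substitution_rate < 1,
    intron_length = cfg$intron_length >= 10
  )
  bad <- names(checks)[!vapply(checks, isTRUE, logical(1))]
  if (length(bad) > 0) {
    abort(sprintf("invalid config field: %s", bad[1]))
  }
  invisible(cfg)
}

# protected residue positions (1-based, on the mature reference-derived
# protein before the initiator M is added)
protected_positions <- function(gene, protein_len) {
  if (gene$family == "H3" && gene$variant != "CENP-A") {
    c(31L, 87L, 89L, 90L, 96L)
  } else if (gene$family == "H2A") {
    seq.int(protein_len - 3L, protein_len)
  } else if (gene$family == "H2B") {
    seq_len(min(60L, protein_len))
  } else {
    integer(0)
  }
}

# derive the mature protein for one gene spec from the reference set
base_protein <- function(gene, refs) {
  base <- refs$residues[refs$id == gene$base_ref]
  if (length(base) == 0) {
    abort(sprintf("gene %s references unknown %s", gene$gene_id,
                  gene$base_ref))
  }
  p <- base
  if (gene$gene_id %in% c("H3.3.1", "H3.3.2")) {
    # hydrozoan-style H3.3: sites 31/87/89/90 in the variant state, site 96
    # kept in the canonical (C) state
    stringr::str_sub(p, 96, 96) <- "C"
  }
  if (gene$gene_id == "H2A.X.2") {
    # SQAY-type tail
    stringr::str_sub(p, -2, -2) <- "A"
  }
  if (gene$gene_id == "H2B.2") {
    p <- stringr::str_sub(p, 21) # uncommonly short N terminus
  }
  if (gene$spkk > 0) {
    p <- make_sperm_h2b(p, gene$spkk)
  }
  p
}

# assemble one gene cassette; returns list(seq, features, cds, protein)
# with features in cassette-relative 0-based half-open coordinates
build_cassette <- function(gene, protein, cds_core, intron_length) {
  up <- paste0(inert(90), "TATAAA", inert(24))
  cds <- paste0("ATG", cds_core, "TAA")
  exon_bounds <- NULL
  if (gene$introns > 0) {
    n_codons <- nchar(cds) / 3
    cut_after <- floor(seq_len(gene$introns) * n_codons /
                         (gene$introns + 1)) * 3
    intron_seq <- paste0("GT", inert(intron_length - 4), "AG")
    pieces <- character(0)
    prev <- 0
    for (cut in cut_after) {
      pieces <- c(pieces, stringr::str_sub(cds, prev + 1, cut), intron_seq)
      prev <- cut
    }
    pieces <- c(pieces, stringr::str_sub(cds, prev + 1, nchar(cds)))
    gene_body <- paste(pieces, collapse = "")
    # exon coordinates relative to gene body start
    exon_bounds <- tibble(
      start = c(0, cumsum(diff(c(0, cut_after)) + intron_length)
                [seq_len(gene$introns)]),
      end = c(cut_after, nchar(cds)) +
        intron_length * (0:gene$introns)
    )
  } else {
    gene_body <- cds
    exon_bounds <- tibble(start = 0, end = nchar(cds))
  }
  utr <- if (!is.na(gene$stem_loop_mismatches)) {
    sl <- make_stem_loop(gene$stem_loop_mismatches)
    hde_seq <- if (gene$hde) paste0(inert(5), "GAAGAGGAAG", inert(10)) else
      inert(25)
    paste0(inert(10), sl, hde_seq, inert(15))
  } else if (gene$polyA) {
    # the signal sits past the stem-loop search span so the A-run cannot
    # seed a spurious low-score hairpin window
    paste0(inert(57), "AATAAA", inert(17))
  } else {
    inert(66)
  }
  seq <- paste0(up, gene_body, utr)
  up_len <- nchar(up)
  body_len <- nchar(gene_body)
  feats <- new_feature_tbl()
  add <- function(f, type, start, end, attrs) {
    bind_rows(f, new_feature_tbl(
      seq_id = "synthetic_genome", start = start, end = end,
      strand = gene$strand, type = type, attributes = list(attrs)
    ))
  }
  id_attr <- c(ID = gene$gene_id)
  feats <- add(feats, "gene", up_len, up_len + body_len, id_attr)
  feats <- add(feats, "TATA_box", 90L, 96L,
               c(Parent = gene$gene_id))
  for (i in seq_len(nrow(exon_bounds))) {
    feats <- add(feats, "exon", up_len + exon_bounds$start[i],
                 up_len + exon_bounds$end[i],
                 c(Parent = gene$gene_id, exon_number = as.character(i)))
  }
  utr0 <- up_len + body_len
  if (!is.na(gene$stem_loop_mismatches)) {
    feats <- add(feats, "stem_loop", utr0 + 10L, utr0 + 26L, c(
      Parent = gene$gene_id,
      mismatches = as.character(gene$stem_loop_mismatches)
    ))
    if (gene$hde) {
      feats <- add(feats, "HDE", utr0 + 31L, utr0 + 41L,
                   c(Parent = gene$gene_id))
    }
  } else if (gene$polyA) {
    feats <- add(feats, "polyA_signal", utr0 + 57L, utr0 + 63L,
                 c(Parent = gene$gene_id))
  }
  list(seq = seq, features = feats, cds = cds, protein = paste0("M", protein))
}

# shift cassette-relative features to an absolute position, flipping
# coordinates when the cassette is inserted in reverse complement
place_features <- function(feats, cassette_len, abs_start, strand) {
  if (strand == "-") {
    feats <- feats |>
      mutate(
        new_start = cassette_len - .data$end,
        end = cassette_len - .data$start,
        start = .data$new_start
      ) |>
      select(-"new_start")
  }
  feats |> mutate(
    start = .data$start + abs_start,
    end = .data$end + abs_start
  )
}

#' Generate a synthetic genome with planted ground truth
#'
#' @param config A [simulation_config()].
#' @return List of class `synthetic_genome`: `genome` (named character,
#'   one sequence), `features` (truth feature tibble, GFF3-serialisable),
#'   `truth` (per gene instance: id, family, variant, coordinates, strand,
#'   expected dependency verdict, expected SPKK count), `proteins` and
#'   `cds` (tibbles for the unique genes), `expression` (stage-resolved
#'   evidence with the pseudogene analogue undetected everywhere),
#'   `cluster_copies`, `unit_length` and the `config`.
#' @export
generate_genome <- function(config = simulation_config()) {
  validate_config(config)
  refs <- reference_set()
  genes <- config$genes
  withr::with_seed(config$seed, {
    cassettes <- map(seq_len(nrow(genes)), function(i) {
      gene <- genes[i, ]
      prot <- base_protein(gene, refs)
      prot <- mutate_protein(
        prot, config$aa_substitution_rate,
        protected_positions(gene, nchar(prot))
      )
      cds_core <- reverse_translate(prot)
      c(list(gene = gene),
        build_cassette(gene, prot, cds_core, config$intron_length))
    })
    names(cassettes) <- genes$gene_id
    # H1.3 shares the canonical H1 coding sequence exactly; only its UTR
    # (degenerate stem-loop) differs
    if (all(c("H1.1", "H1.3") %in% genes$gene_id)) {
      h11 <- cassettes[["H1.1"]]
      g13 <- cassettes[["H1.3"]]$gene
      rebuilt <- build_cassette(
        g13, stringr::str_sub(h11$protein, 2),
        stringr::str_sub(h11$cds, 4, -4), config$intron_length
      )
      cassettes[["H1.3"]] <- c(list(gene = g13), rebuilt)
    }

    clustered <- genes$gene_id[genes$clustered]
    dispersed <- genes$gene_id[!genes$clustered]

    # cluster unit: the clustered cassettes head-to-tail plus a placeholder
    # block standing in for the non-histone cluster residents (5S rRNA,
    # U1/U2 snRNA, Arg-tRNA)
    placeholder <- random_dna(120, config$background_gc)
    unit_parts <- map_chr(cassettes[clustered], "seq")
    unit_seq <- paste0(paste(unit_parts, collapse = ""), placeholder)
    unit_len <- nchar(unit_seq)

    n_disp <- length(dispersed)
    seg_len <- floor(config$background_length / (n_disp + 2))
    if (seg_len < 200) {
      abort("background too short for the dispersed loci (increase background_length)")
    }
    segs <- map_chr(seq_len(n_disp + 2), function(i) {
      random_dna(seg_len, config$background_gc)
    })

    pieces <- character(0)
    features <- new_feature_tbl()
    truth <- list()
    pos <- 0L
    push <- function(s) {
      pieces <<- c(pieces, s)
      pos <<- pos + nchar(s)
    }
    push(segs[1])
    # tandem cluster
    if (config$cluster_copies > 0) {
      rel_offsets <- c(0, cumsum(nchar(unit_parts)))[seq_along(clustered)]
      for (cc in seq_len(config$cluster_copies)) {
        unit_start <- pos
        features <- bind_rows(features, new_feature_tbl(
          seq_id = "synthetic_genome", start = unit_start,
          end = unit_start + unit_len, strand = "+", type = "cluster_unit",
          attributes = list(c(ID = sprintf("cluster_unit_%d", cc)))
        ))
        for (gi in seq_along(clustered)) {
          cas <- cassettes[[clustered[gi]]]
          cas_start <- unit_start + rel_offsets[gi]
          f <- place_features(cas$features, nchar(cas$seq), cas_start, "+")
          f$attributes <- map(f$attributes, function(a) {
            if ("ID" %in% names(a)) {
              a[["ID"]] <- sprintf("%s_copy%d", a[["ID"]], cc)
            }
            if ("Parent" %in% names(a)) {
              a[["Parent"]] <- sprintf("%s_copy%d", a[["Parent"]], cc)
            }
            a
          })
          features <- bind_rows(features, f)
          gene_row <- f[f$type == "gene", ]
          truth[[length(truth) + 1]] <- tibble(
            instance_id = sprintf("%s_copy%d", clustered[gi], cc),
            gene_id = clustered[gi],
            family = cas$gene$family, variant = cas$gene$variant,
            start = gene_row$start, end = gene_row$end, strand = "+",
            clustered = TRUE, copy = cc,
            expected_verdict = cas$gene$expected_verdict,
            expected_spkk = cas$gene$spkk
          )
        }
        push(unit_seq)
      }
    }
    # dispersed variant loci
    for (di in seq_along(dispersed)) {
      push(segs[di + 1])
      cas <- cassettes[[dispersed[di]]]
      strand <- cas$gene$strand
      ins <- if (strand == "-") revcomp(cas$seq) else cas$seq
      f <- place_features(cas$features, nchar(cas$seq), pos, strand)
      features <- bind_rows(features, f)
      gene_row <- f[f$type == "gene", ]
      truth[[length(truth) + 1]] <- tibble(
        instance_id = dispersed[di], gene_id = dispersed[di],
        family = cas$gene$family, variant = cas$gene$variant,
        start = gene_row$start, end = gene_row$end, strand = strand,
        clustered = FALSE, copy = 1L,
        expected_verdict = cas$gene$expected_verdict,
        expected_spkk = cas$gene$spkk
      )
      push(ins)
    }
    push(segs[n_disp + 2])
    genome <- paste(pieces, collapse = "")

    stages <- c("larva", "feeding", "male", "female")
    expression <- map(seq_len(nrow(genes)), function(i) {
      tibble(
        gene_id = genes$gene_id[i], stage = stages,
        detected = stages %in% genes$expressed_stages[[i]]
      )
    }) |> list_rbind()

    structure(
      list(
        genome = c(synthetic_genome = genome),
        features = features,
        truth = list_rbind(truth),
        proteins = tibble(
          id = genes$gene_id,
          description = paste0("synthetic ", genes$family),
          residues = map_chr(cassettes[genes$gene_id], "protein"),
          moltype = "protein"
        ),
        cds = tibble(
          id = genes$gene_id,
          description = "synthetic CDS",
          residues = map_chr(cassettes[genes$gene_id], "cds"),
          moltype = "nucleotide"
        ),
        expression = expression,
        cluster_copies = config$cluster_copies,
        unit_length = unit_len,
        config = config
      ),
      class = "synthetic_genome"
    )
  })
}

#' Simulate shotgun reads over a genome
#'
#' Uniform start positions, random strand (50/50), per-base substitution
#' errors at `error_rate`. The read count is
#' `ceiling(coverage * genome_length / read_length)` (mate pairs each
#' contribute one read of the pair's two).
#'
#' @param genome Character scalar (or a `synthetic_genome`).
#' @param config A [simulation_config()]; `read_length`, `coverage`,
#'   `error_rate`, `paired` and `seed` are used.
#' @return Tibble with `id`, `residues` (and `mate` when paired).
#' @export
simulate_reads <- function(genome, config = simulation_config()) {
  if (inherits(genome, "synthetic_genome")) {
    genome <- genome$genome
  }
  genome <- unname(genome[1])
  glen <- nchar(genome)
  rl <- config$read_length
  if (rl > glen) {
    abort("read_length exceeds genome length")
  }
  n_reads <- as.integer(ceiling(config$coverage * glen / rl))
  withr::with_seed(config$seed + 1L, {
    if (config$paired) {
      insert <- min(2L * rl + 100L, glen)
      n_pairs <- ceiling(n_reads / 2)
      fragments <- sample.int(glen - insert + 1L, n_pairs, replace = TRUE)
      fwd <- stringr::str_sub(genome, fragments, fragments + rl - 1L)
      rev <- revcomp(stringr::str_sub(
        genome, fragments + insert - rl, fragments + insert - 1L
      ))
      reads <- tibble(
        id = c(sprintf("read%d/1", seq_len(n_pairs)),
               sprintf("read%d/2", seq_len(n_pairs))),
        mate = rep(1:2, each = n_pairs),
        residues = c(fwd, rev)
      )
    } else {
      starts <- sample.int(glen - rl + 1L, n_reads, replace = TRUE)
      seqs <- stringr::str_sub(genome, starts, starts + rl - 1L)
      flip <- stats::runif(n_reads) < 0.5
      seqs[flip] <- revcomp(seqs[flip])
      reads <- tibble(id = sprintf("read%d", seq_len(n_reads)),
                      residues = seqs)
    }
    if (config$error_rate > 0) {
      reads$residues <- map_chr(reads$residues, function(s) {
        chars <- strsplit(s, "", fixed = TRUE)[[1]]
        hit <- which(stats::runif(length(chars)) < config$error_rate)
        for (i in hit) {
          chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
        }
        paste(chars, collapse = "")
      })
    }
    reads
  })
}
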