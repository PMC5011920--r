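# End-to-end orchestration: annotate (classify -> regulatory -> motifs),
# copynum, simulate and distances, each callable on in-memory objects or
# file paths, with a machine-readable run summary.

pkg_version <- function() {
  as.character(utils::packageVersion("histannot"))
}

# extract the promoter-proximal upstream window and the 3'-UTR of one gene,
# honouring strand
gene_context <- function(genome, start, end, strand, upstream_len = 120,
                         utr_len = 80) {
  glen <- nchar(genome)
  if (strand == "+") {
    up <- stringr::str_sub(genome, max(1, start - upstream_len + 1), start)
    utr <- stringr::str_sub(genome, end + 1, min(glen, end + utr_len))
  } else {
    up <- revcomp(stringr::str_sub(genome, end + 1,
                                   min(glen, end + upstream_len)))
    utr <- revcomp(stringr::str_sub(genome, max(1, start - utr_len + 1),
                                    start))
  }
  list(upstream = up, utr = utr)
}

#' Annotate histone genes: classification, regulatory features, motifs
#'
#' Runs the three analysis stages over a set of gene models and their
#' proteins and merges the results into one per-gene report mirroring a
#' histone-complement summary table (type, replication-dependency, locus
#' features, SPKK repeats, basicity).
#'
#' @param genome Genome FASTA path, named character vector, or a
#'   `synthetic_genome`.
#' @param features Gene feature tibble (or GFF3 path); rows with
#'   `type == "gene"` and an `ID` attribute define the gene models. When a
#'   `synthetic_genome` is given this defaults to its truth features
#'   restricted to first cluster copies plus dispersed loci.
#' @param proteins Protein tibble (or FASTA path); ids must match gene IDs.
#' @param expression Optional expression tibble (or TSV path).
#' @param out_dir Optional directory for report TSV/GFF3 output.
#' @param min_identity,stability_threshold Passed through to the stages.
#' @return List of class `histone_annotation`: `report` (per-gene tibble),
#'   `calls` (classification), `inventory`, `summary` (parameter snapshot
#'   and counts).
#' @export
run_annotate <- function(genome, features = NULL, proteins = NULL,
                         expression = NULL, out_dir = NULL,
                         min_identity = 0.35,
                         stability_threshold = stability_threshold_default()) {
  if (inherits(genome, "synthetic_genome")) {
    sim <- genome
    genome <- sim$genome
    if (is.null(features)) {
      keep <- sim$truth[sim$truth$copy == 1L, ]
      features <- sim$features |>
        filter(.data$type == "gene") |>
        mutate(id = map_chr(.data$attributes, ~ .x[["ID"]] %||% NA_character_)) |>
        filter(.data$id %in% keep$instance_id) |>
        mutate(id = sub("_copy1$", "", .data$id))
    }
    if (is.null(proteins)) proteins <- sim$proteins
    if (is.null(expression)) expression <- sim$expression
  }
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- with(read_fasta(genome, "nucleotide"), setNames(residues, id))
  }
  if (is.character(features) && length(features) == 1) {
    features <- read_gff3(features)
  }
  if (is.character(proteins) && length(proteins) == 1) {
    proteins <- read_fasta(proteins, "protein")
  }
  if (is.character(expression) && length(expression) == 1) {
    expression <- read_expression_table(expression)
  }
  genes <- features
  if (!"id" %in% names(genes)) {
    genes <- genes |>
      filter(.data$type == "gene") |>
      mutate(id = map_chr(.data$attributes, ~ .x[["ID"]] %||% NA_character_))
  }
  if (nrow(proteins) == 0) {
    abort("no records in the protein input")
  }

  calls <- assign_family(proteins, min_identity = min_identity)

  gseq <- unname(genome[1])
  reg <- map(seq_len(nrow(genes)), function(i) {
    ctx <- gene_context(gseq, genes$start[i], genes$end[i], genes$strand[i])
    fs <- utr_features(genes$id[i], ctx$upstream, ctx$utr,
                       stability_threshold = stability_threshold)
    dep <- call_dependency(fs, expression, stability_threshold)
    sl <- fs$stem_loop
    tibble(
      gene_id = genes$id[i],
      n_tata = length(fs$tata_hits),
      stem_loop_offset = if (is.null(sl)) NA_integer_ else sl$offset_after_stop,
      stem_loop_seq = if (is.null(sl)) NA_character_ else sl$element_sequence,
      stem_mismatches = if (is.null(sl)) NA_integer_ else sl$stem_mismatches,
      stability_score = if (is.null(sl)) NA_real_ else sl$stability_score,
      hde_fraction = if (is.null(fs$hde)) NA_real_ else fs$hde$purine_fraction,
      polyA_pos = if (is.null(fs$polyA)) NA_integer_ else fs$polyA,
      verdict = dep$verdict,
      rationale = dep$rationale
    )
  }) |> list_rbind()

  mot <- map(seq_len(nrow(proteins)), function(i) {
    spkk <- count_spkk(proteins$residues[i])
    prof <- basicity_profile(proteins$residues[i])
    tibble(
      gene_id = proteins$id[i], spkk_count = spkk$count,
      fraction_RK = prof$fraction_RK, protamine_like = prof$protamine_like
    )
  }) |> list_rbind()

  report <- calls |>
    rename(gene_id = "query_id") |>
    left_join(reg, by = "gene_id") |>
    left_join(mot, by = "gene_id")

  inv <- inventory(calls)
  summary <- list(
    tool = "histannot", version = pkg_version(),
    parameters = list(min_identity = min_identity,
                      stability_threshold = stability_threshold),
    n_genes = nrow(genes), n_proteins = nrow(proteins),
    inventory = inv,
    verdicts = as.list(table(report$verdict)),
    n_protamine_like = sum(report$protamine_like, na.rm = TRUE)
  )
  out <- structure(
    list(report = report, calls = calls, inventory = inv, summary = summary),
    class = "histone_annotation"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    flat <- report |>
      mutate(
        evidence = map_chr(.data$evidence, paste, collapse = "; "),
        rationale = map_chr(.data$rationale, paste, collapse = "; ")
      )
    readr::write_tsv(flat, file.path(out_dir, "annotation_report.tsv"))
    jsonlite::write_json(
      summary, file.path(out_dir, "run_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  out
}

#' Estimate tandem-cluster copy number from reads
#'
#' Builds the k-mer histogram, locates the diploid peak, measures the
#' median region depth and reports the copy estimate.
#'
#' @param reads Read tibble, character vector, or one or more FASTA/FASTQ
#'   paths.
#' @param region Region sequence (character scalar, tibble or FASTA path).
#' @param k Word length (default 17).
#' @param min_multiplicity Error-peak exclusion bound (default 4).
#' @param region_id Region label for the report.
#' @param out_dir Optional directory for histogram/estimate TSV output.
#' @return List of class `copy_number_run`: `histogram`
#'   (`kmer_histogram`), `diploid_peak`, `region_coverage`, `estimate`
#'   (`copy_estimate` tibble).
#' @export
run_copynum <- function(reads, region, k = 17, min_multiplicity = 4,
                        region_id = "region", out_dir = NULL) {
  if (is.character(reads) && all(file.exists(reads))) {
    reads <- map(reads, function(p) {
      fmt <- if (grepl("\\.(fq|fastq)$", p)) "fastq" else "fasta"
      read_fasta(p, "nucleotide", format = fmt)
    }) |> list_rbind()
  }
  if (is.character(region) && length(region) == 1 && file.exists(region)) {
    region <- read_fasta(region, "nucleotide")
  }
  hist <- build_histogram(reads, k)
  peak <- find_diploid_peak(hist, min_multiplicity)
  rcov <- region_coverage(region, hist, k)
  est <- estimate_copies(rcov, peak, region_id)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(hist$histogram, file.path(out_dir, "kmer_histogram.tsv"))
    readr::write_tsv(est, file.path(out_dir, "copy_estimate.tsv"))
  }
  structure(
    list(histogram = hist, diploid_peak = peak, region_coverage = rcov,
         estimate = est),
    class = "copy_number_run"
  )
}

#' Generate and write a synthetic dataset
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory; genome FASTA, reads FASTQ, truth GFF3,
#'   truth/expression TSV and protein/CDS FASTA are written there.
#' @return The `synthetic_genome` object, with `$paths` attached.
#' @export
run_simulate <- function(config = simulation_config(), out_dir) {
  sim <- generate_genome(config)
  reads <- simulate_reads(sim, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    genome = file.path(out_dir, "genome.fasta"),
    reads = file.path(out_dir, "reads.fastq"),
    truth_gff = file.path(out_dir, "truth.gff3"),
    truth_tsv = file.path(out_dir, "truth.tsv"),
    proteins = file.path(out_dir, "proteins.fasta"),
    cds = file.path(out_dir, "cds.fasta"),
    expression = file.path(out_dir, "expression.tsv")
  )
  write_fasta(
    tibble(id = names(sim$genome), residues = unname(sim$genome)),
    paths$genome
  )
  write_fastq(reads, paths$reads)
  write_gff3(sim$features, paths$truth_gff,
             seq_lengths = setNames(nchar(sim$genome), names(sim$genome)))
  readr::write_tsv(sim$truth, paths$truth_tsv)
  write_fasta(sim$proteins, paths$proteins)
  write_fasta(sim$cds, paths$cds)
  write_expression_table(sim$expression, paths$expression)
  sim$paths <- paths
  sim
}

#' Alignment-free comparison and clustering of stem-loop elements
#'
#' @param elements Named character vector of element sequences, a tibble
#'   with `id`/`residues`, or a `histone_annotation` (whose reported
#'   stem-loop sequences are used).
#' @param k Word length for the Jaccard distance (default 4).
#' @param linkage `"average"` or `"single"`.
#' @param out_dir Optional directory for matrix TSV and Newick output.
#' @return List of class `stemloop_distances`: `matrix`, `dendrogram`
#'   (`ak_dendrogram`).
#' @export
run_distances <- function(elements, k = 4, linkage = "average",
                          out_dir = NULL) {
  if (inherits(elements, "histone_annotation")) {
    rep <- elements$report
    keep <- !is.na(rep$stem_loop_seq)
    elements <- setNames(rep$stem_loop_seq[keep], rep$gene_id[keep])
  }
  d <- all_pairs(elements, k)
  dend <- ak_cluster(d, linkage)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(
      as_tibble(d, rownames = "element"),
      file.path(out_dir, "distance_matrix.tsv")
    )
    write_newick(dend, file.path(out_dir, "dendrogram.nwk"))
  }
  structure(list(matrix = d, dendrogram = dend),
            class = "stemloop_distances")
}
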