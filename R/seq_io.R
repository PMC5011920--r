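# File IO and the shared sequence/feature data model.
#
# Sequences travel as tibbles with one row per record (id, description,
# residues, moltype); genomic features as tibbles with 0-based half-open
# internal coordinates. GFF3 serialisation converts to the standard 1-based
# inclusive convention.

FEATURE_TYPES <- c(
  "gene", "exon", "CDS", "TATA_box", "stem_loop", "HDE",
  "polyA_signal", "SPKK_repeat", "cluster_unit", "region"
)

#' Read sequences from a FASTA (or FASTQ) file
#'
#' Residues are upper-cased and validated against the declared alphabet
#' (`A/C/G/T` plus `N` for nucleotide; the 20 amino acids plus `X` for
#' protein). Record order is preserved and ids must be unique.
#'
#' @param path Path to a FASTA file (or FASTQ when `format = "fastq"`;
#'   qualities are discarded).
#' @param moltype `"nucleotide"` or `"protein"`.
#' @param format `"fasta"` (default) or `"fastq"`.
#' @return A tibble with columns `id`, `description`, `residues`, `moltype`.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">h4 demo", "acgtACGT"), tf)
#' read_fasta(tf, "nucleotide")
#' @export
read_fasta <- function(path, moltype = c("nucleotide", "protein"),
                       format = c("fasta", "fastq")) {
  moltype <- match.arg(moltype)
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("file '%s' does not exist", path))
  }
  # parse as raw strings so alphabet violations surface as our own
  # record/position-naming errors rather than parser failures
  set <- Biostrings::readBStringSet(path, format = format)
  if (length(set) == 0) {
    abort(sprintf("no records in '%s'", path))
  }
  headers <- names(set)
  ids <- stringr::str_extract(headers, "^\\S+")
  desc <- stringr::str_trim(stringr::str_remove(headers, "^\\S+\\s*"))
  if (anyDuplicated(ids)) {
    abort(sprintf(
      "duplicate record id '%s' in '%s'", ids[duplicated(ids)][1], path
    ))
  }
  residues <- toupper(as.character(set))
  names(residues) <- NULL
  for (i in seq_along(residues)) {
    check_alphabet(residues[i], moltype, ids[i])
    if (nchar(residues[i]) == 0) {
      abort(sprintf("record '%s' is empty", ids[i]))
    }
  }
  tibble(id = ids, description = desc, residues = residues, moltype = moltype)
}

#' Write sequence records to FASTA
#'
#' @param records Tibble as returned by [read_fasta()] (columns `id`,
#'   `residues`, optionally `description`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "residues") %in% names(records)))
  desc <- if ("description" %in% names(records)) {
    records$description
  } else {
    rep("", nrow(records))
  }
  headers <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  lines <- character(0)
  for (i in seq_len(nrow(records))) {
    body <- gsub("(.{70})", "\\1\n", records$residues[i])
    body <- sub("\n$", "", body)
    lines <- c(lines, paste0(">", headers[i]), body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write reads to FASTQ
#'
#' Qualities are constant (`I`); the copy-number machinery uses counts
#' only.
#'
#' @param reads Tibble with `id` and `residues`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- as.vector(rbind(
    paste0("@", reads$id),
    reads$residues,
    "+",
    strrep("I", nchar(reads$residues))
  ))
  writeLines(lines, path)
  invisible(path)
}

new_feature_tbl <- function(seq_id = character(), start = integer(),
                            end = integer(), strand = character(),
                            type = character(), attributes = list()) {
  tibble(
    seq_id = seq_id, start = as.integer(start), end = as.integer(end),
    strand = strand, type = type, attributes = attributes
  )
}

validate_features <- function(features, seq_lengths = NULL) {
  stopifnot(all(
    c("seq_id", "start", "end", "strand", "type", "attributes") %in%
      names(features)
  ))
  if (any(features$end <= features$start)) {
    abort("feature end must be greater than start (0-based half-open)")
  }
  if (any(features$start < 0)) {
    abort("feature start must be >= 0")
  }
  if (!all(features$strand %in% c("+", "-"))) {
    abort("feature strand must be '+' or '-'")
  }
  if (!all(features$type %in% FEATURE_TYPES)) {
    bad <- setdiff(unique(features$type), FEATURE_TYPES)
    abort(sprintf("unknown feature type(s): %s", paste(bad, collapse = ", ")))
  }
  if (!is.null(seq_lengths)) {
    len <- seq_lengths[features$seq_id]
    if (anyNA(len)) {
      abort("feature references unknown seq_id")
    }
    if (any(features$end > len)) {
      abort("feature extends beyond the end of its sequence")
    }
  }
  invisible(features)
}

# GFF3 attribute encoding: percent-escape the reserved characters so that
# arbitrary key/value text round-trips
gff3_escape <- function(x) {
  for (ch in c("%", ";", "=", "&", ",", "\t", "\n")) {
    x <- gsub(ch, sprintf("%%%02X", utf8ToInt(ch)), x, fixed = TRUE)
  }
  x
}

gff3_unescape <- function(x) {
  vapply(x, utils::URLdecode, character(1), USE.NAMES = FALSE)
}

encode_attributes <- function(attrs) {
  vapply(attrs, function(a) {
    if (is.null(a) || length(a) == 0) {
      return(".")
    }
    paste0(gff3_escape(names(a)), "=", gff3_escape(unname(a)), collapse = ";")
  }, character(1))
}

decode_attributes <- function(col) {
  map(col, function(s) {
    if (is.na(s) || s == "." || s == "") {
      return(character(0))
    }
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    kv <- strsplit(parts, "=", fixed = TRUE)
    vals <- vapply(kv, `[`, character(1), 2)
    vals[is.na(vals)] <- "" # "key=" round-trips as an empty value
    setNames(
      gff3_unescape(vals),
      gff3_unescape(vapply(kv, `[`, character(1), 1))
    )
  })
}

#' Write genomic features to GFF3
#'
#' Internal 0-based half-open coordinates are emitted as standard GFF3
#' 1-based inclusive columns 4 and 5. [read_gff3()] restores identical
#' internal features.
#'
#' @param features Feature tibble (`seq_id`, `start`, `end`, `strand`,
#'   `type`, `attributes` list-column of named character vectors).
#' @param path Output path.
#' @param seq_lengths Optional named vector of sequence lengths; when given,
#'   features beyond the end of their sequence raise an error.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path, seq_lengths = NULL) {
  validate_features(features, seq_lengths)
  lines <- "##gff-version 3"
  if (nrow(features) > 0) {
    lines <- c(lines, paste(
      features$seq_id, "histannot", features$type,
      features$start + 1L, features$end,
      ".", features$strand, ".",
      encode_attributes(features$attributes),
      sep = "\t"
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFF3 file written by [write_gff3()]
#'
#' @param path Path to a GFF3 file.
#' @return Feature tibble with 0-based half-open coordinates.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(new_feature_tbl())
  }
  m <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  if (ncol(m) != 9) {
    abort("malformed GFF3: expected 9 tab-separated columns")
  }
  validate_features(new_feature_tbl(
    seq_id = m[, 1],
    start = as.integer(m[, 4]) - 1L,
    end = as.integer(m[, 5]),
    strand = m[, 7],
    type = m[, 3],
    attributes = decode_attributes(m[, 9])
  ))
}

#' Read per-gene expression evidence from TSV
#'
#' The table stands in for stage-resolved RNA-seq presence/absence evidence
#' and feeds the pseudogene rule of [call_dependency()].
#'
#' @param path TSV with header columns `gene_id`, `stage`, `detected`
#'   (`0/1/true/false`).
#' @return Tibble with `gene_id`, `stage`, `detected` (logical); duplicate
#'   `(gene_id, stage)` pairs raise an error.
#' @export
read_expression_table <- function(path) {
  tab <- readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_id = readr::col_character(),
      stage = readr::col_character(),
      detected = readr::col_character()
    )
  )
  if (!all(c("gene_id", "stage", "detected") %in% names(tab))) {
    abort("expression table must have columns gene_id, stage, detected")
  }
  det <- tolower(tab$detected)
  if (!all(det %in% c("0", "1", "true", "false"))) {
    abort("detected must be one of 0, 1, true, false")
  }
  tab$detected <- det %in% c("1", "true")
  if (anyDuplicated(tab[c("gene_id", "stage")])) {
    abort("duplicate (gene_id, stage) pair in expression table")
  }
  tab
}

#' Write an expression-evidence table to TSV
#'
#' @param evidence Tibble with `gene_id`, `stage`, `detected`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(evidence, path) {
  out <- evidence
  out$detected <- as.integer(out$detected)
  readr::write_tsv(out, path)
  invisible(path)
}
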