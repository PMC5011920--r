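# Tandem-cluster copy-number estimation from a k-mer depth histogram:
# count canonical (strand-collapsed) k-mers in reads, locate the diploid
# coverage peak, measure the median k-mer depth of a repeat region, and
# divide. With the diploid peak at p-fold coverage a region at r-fold
# coverage represents r / p copies per diploid nucleus (r / 2p per
# haplotype).

#' Build a k-mer multiplicity table and histogram from reads
#'
#' K-mers are canonicalised (lexicographic minimum of a k-mer and its
#' reverse complement) so both strands count together; k-mers containing N
#' are skipped, as are reads shorter than k.
#'
#' @param reads Character vector of read sequences, or a tibble with a
#'   `residues` column (as from [read_fasta()]).
#' @param k Word length (default 17).
#' @return List of class `kmer_histogram`: `k`, `counts` (named integer
#'   vector, k-mer -> multiplicity), `histogram` (tibble `multiplicity`,
#'   `distinct_kmers`), `total_kmers` (number of distinct k-mers).
#' @export
build_histogram <- function(reads, k = 17) {
  if (is.data.frame(reads)) {
    reads <- reads$residues
  }
  stopifnot(k >= 1)
  usable <- reads[nchar(reads) >= k]
  if (length(usable) == 0) {
    abort(sprintf("all reads are shorter than k = %d", k))
  }
  kmers <- unlist(map(usable, seq_kmers, k = k), use.names = FALSE)
  kmers <- canonical_kmers(kmers)
  counts <- table(kmers)
  counts <- setNames(as.integer(counts), names(counts))
  hist_tab <- table(counts)
  histogram <- tibble(
    multiplicity = as.integer(names(hist_tab)),
    distinct_kmers = as.integer(hist_tab)
  )
  structure(
    list(
      k = k, counts = counts, histogram = histogram,
      total_kmers = length(counts)
    ),
    class = "kmer_histogram"
  )
}

#' Locate the diploid coverage peak of a k-mer histogram
#'
#' The modal multiplicity after moving-average smoothing, restricted to
#' multiplicities strictly above `min_multiplicity` so the low-multiplicity
#' sequencing-error peak is excluded. Ties resolve to the lower
#' multiplicity.
#'
#' @param hist A `kmer_histogram` (or its `histogram` tibble).
#' @param min_multiplicity Multiplicities at or below this are ignored
#'   (default 4).
#' @param smooth Moving-average width (odd; default 3).
#' @return The peak multiplicity (fold-coverage) as a numeric scalar.
#' @export
find_diploid_peak <- function(hist, min_multiplicity = 4, smooth = 3) {
  htab <- if (inherits(hist, "kmer_histogram")) hist$histogram else hist
  htab <- htab[htab$multiplicity > min_multiplicity, ]
  if (nrow(htab) == 0) {
    abort("degenerate histogram: no k-mers above min_multiplicity")
  }
  # dense counts over the multiplicity range, then centred moving average
  mrange <- seq(min(htab$multiplicity), max(htab$multiplicity))
  dense <- setNames(numeric(length(mrange)), mrange)
  dense[as.character(htab$multiplicity)] <- htab$distinct_kmers
  half <- (smooth - 1) / 2
  sm <- vapply(seq_along(dense), function(i) {
    lo <- max(1, i - half)
    hi <- min(length(dense), i + half)
    mean(dense[lo:hi])
  }, numeric(1))
  if (max(sm) == min(sm) && length(sm) > 1) {
    abort("degenerate histogram: flat above min_multiplicity")
  }
  mrange[which.max(sm)]
}

#' Median k-mer depth of a region
#'
#' The median multiplicity of the region's canonical k-mers in the read
#' k-mer table; k-mers absent from the table contribute 0.
#'
#' @param region Nucleotide sequence of the region (character scalar or a
#'   one-row tibble with `residues`).
#' @param kmer_counts Named multiplicity vector from [build_histogram()]
#'   (`$counts`), or a `kmer_histogram`.
#' @param k Word length; must match the table.
#' @return Fold-coverage (numeric scalar).
#' @export
region_coverage <- function(region, kmer_counts, k = 17) {
  if (is.data.frame(region)) {
    region <- region$residues[1]
  }
  if (inherits(kmer_counts, "kmer_histogram")) {
    stopifnot(kmer_counts$k == k)
    kmer_counts <- kmer_counts$counts
  }
  if (nchar(region) < k) {
    abort(sprintf("region shorter than k = %d", k))
  }
  km <- canonical_kmers(seq_kmers(region, k))
  depth <- unname(kmer_counts[km])
  depth[is.na(depth)] <- 0L
  median(depth)
}

#' Copy number from region coverage and the diploid peak
#'
#' The estimate follows the printed arithmetic of the k-mer-depth method:
#' copies per diploid nucleus = region coverage / diploid peak coverage,
#' and half that per haplotype. Under the alternative reading in which the
#' diploid peak already represents two copies, both numbers would differ by
#' a factor of 2; the divisor convention is recorded in the output.
#'
#' @param region_cov Region fold-coverage.
#' @param diploid_peak Diploid-peak fold-coverage (> 0).
#' @param region_id Optional region label.
#' @return One-row tibble of class `copy_estimate`: `region_id`,
#'   `region_coverage`, `diploid_peak`, `copies_diploid`,
#'   `copies_per_haplotype`.
#' @examples
#' estimate_copies(28000, 20)
#' @export
estimate_copies <- function(region_cov, diploid_peak, region_id = "region") {
  if (diploid_peak <= 0) {
    abort("diploid_peak must be positive")
  }
  out <- tibble(
    region_id = region_id,
    region_coverage = region_cov,
    diploid_peak = diploid_peak,
    copies_diploid = region_cov / diploid_peak,
    copies_per_haplotype = region_cov / diploid_peak / 2
  )
  class(out) <- c("copy_estimate", class(out))
  out
}
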