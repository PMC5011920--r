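# broom-style tidiers for the pipeline's result objects.

#' @exportS3Method generics::tidy
tidy.copy_estimate <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @exportS3Method generics::glance
glance.copy_estimate <- function(x, ...) {
  tibble(
    n_regions = nrow(x),
    mean_copies_diploid = mean(x$copies_diploid),
    diploid_peak = x$diploid_peak[1]
  )
}

#' @exportS3Method generics::tidy
tidy.copy_number_run <- function(x, ...) {
  tidy(x$estimate)
}

#' @exportS3Method generics::glance
glance.copy_number_run <- function(x, ...) {
  tibble(
    k = x$histogram$k,
    total_distinct_kmers = x$histogram$total_kmers,
    diploid_peak = x$diploid_peak,
    region_coverage = x$region_coverage,
    copies_diploid = x$estimate$copies_diploid,
    copies_per_haplotype = x$estimate$copies_per_haplotype
  )
}

#' @exportS3Method generics::tidy
tidy.kmer_histogram <- function(x, ...) {
  x$histogram
}

#' @exportS3Method generics::tidy
tidy.histone_calls <- function(x, ...) {
  out <- x
  out$evidence <- map_chr(out$evidence, paste, collapse = "; ")
  as_tibble(out)
}

#' @exportS3Method generics::tidy
tidy.histone_annotation <- function(x, ...) {
  out <- x$report
  out$evidence <- map_chr(out$evidence, paste, collapse = "; ")
  out$rationale <- map_chr(out$rationale, paste, collapse = "; ")
  as_tibble(out)
}

#' @exportS3Method generics::glance
glance.histone_annotation <- function(x, ...) {
  tibble(
    n_genes = x$summary$n_genes,
    n_classified = sum(x$calls$family != "unclassified"),
    n_families = length(unique(
      x$calls$family[x$calls$family != "unclassified"]
    )),
    n_replication_dependent =
      sum(x$report$verdict == "replication_dependent", na.rm = TRUE),
    n_replication_independent =
      sum(x$report$verdict == "replication_independent", na.rm = TRUE),
    n_pseudogene_candidates =
      sum(x$report$verdict == "pseudogene_candidate", na.rm = TRUE),
    n_protamine_like = sum(x$report$protamine_like, na.rm = TRUE)
  )
}

#' @exportS3Method generics::tidy
tidy.ak_dendrogram <- function(x, ...) {
  x$merges
}

#' @export
print.histone_annotation <- function(x, ...) {
  cat(sprintf(
    "<histone_annotation> %d genes, %d classified; verdicts: %s\n",
    x$summary$n_genes, sum(x$calls$family != "unclassified"),
    paste(names(x$summary$verdicts), unlist(x$summary$verdicts),
          sep = "=", collapse = ", ")
  ))
  invisible(x)
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat(sprintf(
    "<kmer_histogram> k=%d, %d distinct k-mers, multiplicities %d..%d\n",
    x$k, x$total_kmers, min(x$histogram$multiplicity),
    max(x$histogram$multiplicity)
  ))
  invisible(x)
}
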