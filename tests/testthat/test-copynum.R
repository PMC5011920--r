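test_that("k-mer histograms count distinct canonical k-mers", {
  # 20 - 17 + 1 = 4 k-mer positions, none reverse-complement-equivalent
  h <- build_histogram("AAAAAAAACCCCCCCCAAAA", k = 17)
  expect_equal(h$total_kmers, 4)
  expect_equal(h$histogram,
               tibble::tibble(multiplicity = 1L, distinct_kmers = 4L))

  read <- "ATGGCTAGCTAGGATCCATGCA"
  h2 <- build_histogram(c(read, revcomp(read)), k = 17)
  expect_true(all(h2$counts == 2))

  expect_error(build_histogram(c("ACGT", "GGG"), k = 17), "shorter than k")

  # N-containing k-mers are skipped
  h3 <- build_histogram("ACGTACGTNACGTACGTA", k = 17)
  expect_equal(h3$total_kmers, 0)
})

test_that("histograms are invariant under read order and strand flips", {
  withr::local_seed(13)
  reads <- vapply(1:30, function(i) random_dna_str(60), character(1))
  base <- build_histogram(reads, k = 17)
  perm <- build_histogram(sample(reads), k = 17)
  expect_equal(perm$counts[order(names(perm$counts))],
               base$counts[order(names(base$counts))])
  flip <- reads
  idx <- sample(30, 12)
  flip[idx] <- revcomp(flip[idx])
  flipped <- build_histogram(flip, k = 17)
  expect_equal(flipped$counts[order(names(flipped$counts))],
               base$counts[order(names(base$counts))])
})

test_that("the diploid peak is the smoothed mode above the error cut", {
  unimodal <- tibble::tibble(
    multiplicity = 5:40,
    distinct_kmers = as.integer(round(1000 * exp(-((5:40) - 20)^2 / 30)))
  )
  expect_equal(find_diploid_peak(unimodal), 20)

  bimodal <- dplyr::bind_rows(
    tibble::tibble(multiplicity = 1L, distinct_kmers = 1000000L),
    tibble::tibble(
      multiplicity = 20:40,
      distinct_kmers = as.integer(round(500 * exp(-((20:40) - 30)^2 / 20)))
    )
  )
  expect_equal(find_diploid_peak(bimodal), 30)

  flat <- tibble::tibble(multiplicity = 5:30, distinct_kmers = 7L)
  expect_error(find_diploid_peak(flat), "degenerate")
  low <- tibble::tibble(multiplicity = 1:3, distinct_kmers = c(9L, 5L, 2L))
  expect_error(find_diploid_peak(low), "degenerate")
})

test_that("region coverage is the median k-mer depth, absent k-mers count 0", {
  withr::local_seed(14)
  region <- random_dna_str(100)
  km <- unique(histannot:::canonical_kmers(histannot:::seq_kmers(region, 17)))
  counts <- setNames(rep(28000L, length(km)), km)
  expect_equal(region_coverage(region, counts, k = 17), 28000)

  other <- random_dna_str(100)
  expect_equal(region_coverage(other, counts, k = 17), 0)
  expect_error(region_coverage("ACGT", counts, k = 17), "shorter")
})

test_that("copy arithmetic reproduces the worked example exactly", {
  est <- estimate_copies(28000, 20, "histone_cluster")
  expect_equal(est$copies_diploid, 1400)
  expect_equal(est$copies_per_haplotype, 700)
  expect_equal(estimate_copies(46000, 20)$copies_diploid, 2300)
  expect_equal(estimate_copies(20, 20)$copies_diploid, 1)
  expect_error(estimate_copies(100, 0), "positive")
})

test_that("copies_diploid times the peak recovers region coverage exactly", {
  withr::local_seed(15)
  for (i in 1:25) {
    r <- stats::runif(1, 1, 1e5)
    p <- stats::runif(1, 1, 100)
    est <- estimate_copies(r, p)
    expect_equal(est$copies_diploid * p, r, tolerance = 1e-12)
    expect_equal(est$copies_per_haplotype * 2, est$copies_diploid)
  }
})

test_that("simulated single-copy coverage lands near the nominal depth", {
  withr::local_seed(16)
  genome <- random_dna_str(20000)
  cfg <- simulation_config(seed = 16, coverage = 30, read_length = 250)
  reads <- simulate_reads(c(g = genome), cfg)
  h <- build_histogram(reads, k = 17)
  peak <- find_diploid_peak(h)
  # effective k-mer depth is coverage * (L - k + 1) / L
  eff <- 30 * (250 - 17 + 1) / 250
  expect_lt(abs(peak - eff) / eff, 0.10)
})

test_that("doubling depth doubles peak and region coverage but not the estimate", {
  withr::local_seed(17)
  genome <- random_dna_str(30000)
  region <- substr(genome, 5000, 7500)
  est <- function(cov) {
    cfg <- simulation_config(seed = 18, coverage = cov)
    reads <- simulate_reads(c(g = genome), cfg)
    run_copynum(reads, region)
  }
  a <- est(20)
  b <- est(40)
  expect_gt(b$diploid_peak / a$diploid_peak, 1.7)
  expect_gt(b$region_coverage / a$region_coverage, 1.7)
  expect_lt(
    abs(b$estimate$copies_diploid - a$estimate$copies_diploid) /
      a$estimate$copies_diploid,
    0.15
  )
})
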