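test_that("generation is byte-identical for a fixed seed", {
  cfg <- simulation_config(seed = 33, cluster_copies = 2)
  s1 <- generate_genome(cfg)
  s2 <- generate_genome(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$truth, s2$truth)
  expect_identical(simulate_reads(s1, cfg), simulate_reads(s2, cfg))
  s3 <- generate_genome(simulation_config(seed = 34, cluster_copies = 2))
  expect_false(identical(s1$genome, s3$genome))
})

test_that("truth bookkeeping scales with cluster copies", {
  cfg0 <- simulation_config(seed = 35, cluster_copies = 0)
  s0 <- generate_genome(cfg0)
  expect_equal(nrow(s0$truth), sum(!cfg0$genes$clustered))

  cfg50 <- simulation_config(seed = 35, cluster_copies = 50,
                             background_length = 5000,
                             genes = default_gene_set()[
                               default_gene_set()$clustered, ])
  s50 <- generate_genome(cfg50)
  expect_equal(sum(s50$truth$clustered), 250)
})

test_that("planted features re-extract from the emitted genome", {
  sim <- generate_genome(simulation_config(seed = 36, cluster_copies = 1))
  g <- unname(sim$genome)
  sl <- sim$features[sim$features$type == "stem_loop", ]
  for (i in seq_len(nrow(sl))) {
    el <- substr(g, sl$start[i] + 1, sl$end[i])
    if (sl$strand[i] == "-") el <- revcomp(el)
    expect_equal(nchar(el), 16)
    mm <- as.integer(sl$attributes[[i]][["mismatches"]])
    expect_equal(histannot:::stem_score(el)$mismatches, mm)
  }
  tata <- sim$features[sim$features$type == "TATA_box", ]
  for (i in seq_len(nrow(tata))) {
    el <- substr(g, tata$start[i] + 1, tata$end[i])
    if (tata$strand[i] == "-") el <- revcomp(el)
    expect_match(el, "^TA[AT]AAA$")
  }
  polya <- sim$features[sim$features$type == "polyA_signal", ]
  for (i in seq_len(nrow(polya))) {
    el <- substr(g, polya$start[i] + 1, polya$end[i])
    if (polya$strand[i] == "-") el <- revcomp(el)
    expect_equal(el, "AATAAA")
  }
})

test_that("error-free reads are exact genome substrings at the expected count", {
  withr::local_seed(37)
  genome <- c(g = random_dna_str(10000))
  cfg <- simulation_config(seed = 37, coverage = 20, read_length = 250)
  reads <- simulate_reads(genome, cfg)
  expect_equal(nrow(reads), ceiling(20 * 10000 / 250))
  for (i in sample(nrow(reads), 20)) {
    r <- reads$residues[i]
    expect_true(grepl(r, genome, fixed = TRUE) ||
                  grepl(revcomp(r), genome, fixed = TRUE))
  }
})

test_that("substitution errors appear at the configured rate", {
  genome <- c(g = strrep("ACGT", 3000))
  cfg <- simulation_config(seed = 38, coverage = 10, read_length = 250,
                           error_rate = 0.01)
  reads <- simulate_reads(genome, cfg)
  # align each read to its error-free twin by regenerating without errors
  cfg0 <- simulation_config(seed = 38, coverage = 10, read_length = 250)
  clean <- simulate_reads(genome, cfg0)
  mism <- mapply(function(x, y) {
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  }, reads$residues, clean$residues)
  n_bases <- sum(nchar(reads$residues))
  p_hat <- sum(mism) / n_bases
  expect_lt(abs(p_hat - 0.01), 3 * sqrt(0.01 * 0.99 / n_bases))
})

test_that("paired mode emits mate pairs from opposite strands", {
  genome <- c(g = strrep("ACGTTGCA", 2000))
  cfg <- simulation_config(seed = 39, coverage = 5, paired = TRUE)
  reads <- simulate_reads(genome, cfg)
  expect_true(all(c(1, 2) %in% reads$mate))
  expect_equal(sum(reads$mate == 1), sum(reads$mate == 2))
})

test_that("sperm-H2B construction plants exact SPKK counts", {
  refs <- reference_set()
  h2b <- refs$residues[refs$id == "H2B_ref"]
  for (n in 0:10) {
    expect_equal(count_spkk(make_sperm_h2b(h2b, n))$count, n)
  }
  # CDS input: blocks inserted after the start codon
  cds <- paste0("ATG", histannot:::reverse_translate(h2b), "TAA")
  mod <- make_sperm_h2b(cds, 4)
  expect_equal(count_spkk(histannot:::translate_cds(mod))$count, 4)
})

test_that("the expression truth leaves only the pseudogene analogue silent", {
  sim <- generate_genome(simulation_config(seed = 40, cluster_copies = 1))
  by_gene <- dplyr::summarise(
    dplyr::group_by(sim$expression, gene_id),
    any_detected = any(detected)
  )
  expect_false(by_gene$any_detected[by_gene$gene_id == "H1.3"])
  expect_true(all(by_gene$any_detected[by_gene$gene_id != "H1.3"]))
})

test_that("invalid configuration names the offending field", {
  expect_error(simulation_config(coverage = -1), "coverage")
  expect_error(simulation_config(background_gc = 1.5), "background_gc")
  expect_error(simulation_config(read_length = 5), "read_length")
})
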