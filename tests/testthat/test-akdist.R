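test_that("k-mer Jaccard distance handles the boundary cases", {
  expect_equal(kmer_distance("ACGTACGT", "ACGTACGT", 4), 0)
  expect_equal(kmer_distance("AAAAAA", "CCCCCC", 3), 1)
  # hand-enumerated: {ACG,CGT,GTA,TAC} vs {ACG,CGT,GTA,TAC,CGA};
  # intersection 4, union 5
  expect_equal(kmer_distance("ACGTACGT", "ACGTACGA", 3), 1 / 5)
  expect_error(kmer_distance("AC", "ACGT", 4), "at least k")
})

test_that("the Jaccard k-mer distance is a metric on random triples", {
  withr::local_seed(23)
  for (i in 1:1000) {
    a <- random_dna_str(sample(8:20, 1))
    b <- random_dna_str(sample(8:20, 1))
    c <- random_dna_str(sample(8:20, 1))
    dab <- kmer_distance(a, b)
    dba <- kmer_distance(b, a)
    dac <- kmer_distance(a, c)
    dbc <- kmer_distance(b, c)
    expect_equal(dab, dba)
    expect_gte(dab, 0)
    expect_lte(dab, 1)
    expect_lte(dac, dab + dbc + 1e-12)
  }
  expect_equal(kmer_distance("ACGTACG", "ACGTACG"), 0)
})

test_that("all-pairs matrices are symmetric and match pairwise calls", {
  withr::local_seed(24)
  els <- setNames(
    vapply(1:20, function(i) random_dna_str(16), character(1)),
    paste0("e", 1:20)
  )
  d <- all_pairs(els)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  for (i in 1:5) {
    a <- sample(20, 1)
    b <- sample(20, 1)
    expect_equal(d[a, b], kmer_distance(els[[a]], els[[b]]))
  }

  ident <- setNames(rep("ACGTACGTACGTACGT", 3), c("x", "y", "z"))
  expect_true(all(all_pairs(ident) == 0))

  dup <- setNames(els[1:3], c("a", "a", "b"))
  expect_error(all_pairs(dup), "unique")
  expect_error(all_pairs(els[1]), "at least two")
})

test_that("clustering heights are non-decreasing and ties break deterministically", {
  withr::local_seed(25)
  for (i in 1:50) {
    n <- sample(4:10, 1)
    m <- matrix(0, n, n, dimnames = list(paste0("l", 1:n), paste0("l", 1:n)))
    vals <- stats::runif(n * (n - 1) / 2)
    m[lower.tri(m)] <- vals
    m <- m + t(m)
    for (link in c("average", "single")) {
      dend <- ak_cluster(m, link)
      expect_equal(nrow(dend$merges), n - 1)
      expect_true(all(diff(dend$merges$height) >= -1e-12))
    }
  }
})

test_that("clustering is invariant under label order permutation", {
  withr::local_seed(26)
  els <- setNames(
    vapply(1:8, function(i) random_dna_str(16), character(1)),
    paste0("e", 1:8)
  )
  d <- all_pairs(els)
  base <- ak_cluster(d)
  perm <- sample(8)
  d2 <- d[perm, perm]
  expect_equal(ak_cluster(d2)$merges, base$merges)
})

test_that("average-linkage heights agree with hclust on tie-free matrices", {
  withr::local_seed(27)
  n <- 9
  m <- matrix(0, n, n, dimnames = list(paste0("l", 1:n), paste0("l", 1:n)))
  m[lower.tri(m)] <- stats::runif(n * (n - 1) / 2, 0.1, 1)
  m <- m + t(m)
  ours <- ak_cluster(m, "average")
  ref <- stats::hclust(stats::as.dist(m), method = "average")
  expect_equal(sort(ours$merges$height), sort(ref$height), tolerance = 1e-10)
  ours_s <- ak_cluster(m, "single")
  ref_s <- stats::hclust(stats::as.dist(m), method = "single")
  expect_equal(sort(ours_s$merges$height), sort(ref_s$height),
               tolerance = 1e-10)
})

test_that("a divergent stem-loop joins the dendrogram last", {
  els <- setNames(rep(make_stem_loop(0), 18), paste0("sl", sprintf("%02d", 1:18)))
  els <- c(els, sl_H13 = make_stem_loop(3))
  d <- all_pairs(els)
  dend <- ak_cluster(d)
  n <- length(els)
  early <- unlist(dend$members[seq_len(n - 2)])
  expect_false("sl_H13" %in% early)
  expect_true("sl_H13" %in% dend$members[[n - 1]])
})

test_that("two equidistant triplets form two clean clusters", {
  a <- "ACGTACGTACGTACGT"
  b <- "TTTTCCCCGGGGAAAA"
  els <- c(a1 = a, a2 = a, a3 = a, b1 = b, b2 = b, b3 = b)
  dend <- ak_cluster(all_pairs(els))
  # first four merges happen at height 0 within the triplets
  expect_equal(dend$merges$height[1:4], rep(0, 4))
  expect_setequal(dend$members[[2]], c("a1", "a2", "a3"))
  expect_setequal(dend$members[[4]], c("b1", "b2", "b3"))
})

test_that("dendrograms convert to hclust and serialise to Newick", {
  withr::local_seed(28)
  els <- setNames(
    vapply(1:6, function(i) random_dna_str(16), character(1)),
    paste0("e", 1:6)
  )
  dend <- ak_cluster(all_pairs(els))
  hc <- as_hclust(dend)
  expect_s3_class(hc, "hclust")
  expect_setequal(hc$order, 1:6)
  tf <- withr::local_tempfile(fileext = ".nwk")
  write_newick(dend, tf)
  tree <- ape::read.tree(tf)
  expect_setequal(tree$tip.label, names(els))
})
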