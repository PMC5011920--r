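test_that("TATA scanning matches the TAWAAA consensus", {
  up <- paste0(strrep("C", 50), "TATAAA", strrep("C", 30))
  expect_length(scan_tata(up), 1)
  up2 <- paste0(strrep("C", 50), "TACAAA", strrep("C", 30))
  expect_length(scan_tata(up2), 0)
  # both W states
  expect_length(scan_tata("CCTAAAAACC"), 1)
})

test_that("TATA hit counts on random sequence match a regex oracle and the binomial expectation", {
  withr::local_seed(5)
  seq <- random_dna_str(100000)
  hits <- scan_tata(seq, window = nchar(seq))
  oracle <- length(gregexpr("(?=TA[AT]AAA)", seq, perl = TRUE)[[1]])
  expect_equal(length(hits), oracle)
  n <- nchar(seq) - 5
  p <- 2 * (1 / 4)^6
  expect_lt(abs(length(hits) - n * p), 3 * sqrt(n * p * (1 - p)))
})

test_that("stem-loop detection finds planted hairpins and flags instability", {
  withr::local_seed(1)
  spacer <- paste(sample(c("C", "T"), 10, replace = TRUE), collapse = "")
  tail <- paste(sample(c("C", "T"), 30, replace = TRUE), collapse = "")

  hit <- find_stem_loop(paste0(spacer, make_stem_loop(0), tail))
  expect_equal(hit$offset_after_stop, 10)
  expect_equal(hit$stem_mismatches, 0)
  expect_true(hit$stable)
  expect_equal(nchar(hit$element_sequence), 16)

  bad <- find_stem_loop(paste0(spacer, make_stem_loop(3), tail),
                        max_mismatch = 3)
  expect_equal(bad$stem_mismatches, 3)
  expect_false(bad$stable)
  expect_lt(bad$stability_score, stability_threshold_default())

  expect_null(find_stem_loop(strrep("A", 100)))
  expect_null(find_stem_loop("ACGT"))
})

test_that("stem-loop stability decreases monotonically with mismatches", {
  scores <- vapply(0:6, function(m) {
    find_stem_loop(make_stem_loop(m), search_span = 0,
                   max_mismatch = 6)$stability_score
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("the reverse complement of a UTR does not report the same element", {
  utr <- paste0(strrep("T", 10), make_stem_loop(0), strrep("C", 14))
  fwd <- find_stem_loop(utr)
  rev <- find_stem_loop(revcomp(utr))
  expect_false(identical(fwd$offset_after_stop, rev$offset_after_stop) &&
                 identical(fwd$element_sequence, rev$element_sequence))
})

test_that("HDE scanning reports the best purine-rich window", {
  hit <- scan_hde("GAAAGAGAGA")
  expect_equal(hit$purine_fraction, 1)
  expect_equal(hit$position, 0)
  expect_null(scan_hde("CTCTCTCTCTCT"))

  withr::local_seed(9)
  fracs <- vapply(1:2000, function(i) {
    win <- random_dna_str(10)
    stringr::str_count(win, "[AG]") / 10
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.5), 3 * sqrt(0.25 / 10 / 2000))
})

test_that("polyA scanning finds the first signal and rejects RNA", {
  expect_equal(scan_polyA(paste0(strrep("C", 12), "AATAAA")), 12)
  expect_equal(scan_polyA("ATTAAACCAATAAA"), 0)
  expect_null(scan_polyA("CCCCCCCC"))
  expect_error(scan_polyA("AAUAAA"), "DNA")
})

test_that("dependency rules fire in their specified order", {
  withr::local_seed(2)
  sp <- function(n) paste(sample(c("C", "T"), n, replace = TRUE), collapse = "")
  up <- paste0(sp(50), "TATAAA", sp(24))

  dep_utr <- paste0(sp(10), make_stem_loop(0), sp(5), "GAAGAGGAAG", sp(20))
  f1 <- utr_features("g1", up, dep_utr)
  v1 <- call_dependency(f1)
  expect_equal(v1$verdict, "replication_dependent")
  expect_gt(length(v1$rationale[[1]]), 0)

  ind_utr <- paste0(sp(57), "AATAAA", sp(17))
  f2 <- utr_features("g2", up, ind_utr)
  v2 <- call_dependency(f2)
  expect_equal(v2$verdict, "replication_independent")

  pseudo_utr <- paste0(sp(10), make_stem_loop(3), sp(40))
  f3 <- utr_features("H1.3", up, pseudo_utr)
  expr <- tibble::tibble(
    gene_id = "H1.3", stage = c("larva", "male"), detected = FALSE
  )
  v3 <- call_dependency(f3, expr)
  expect_equal(v3$verdict, "pseudogene_candidate")

  # same unstable loop but with expression evidence -> ambiguous
  expr2 <- dplyr::mutate(expr, detected = c(TRUE, FALSE))
  expect_equal(call_dependency(f3, expr2)$verdict, "ambiguous")

  # purity: identical inputs, identical verdicts
  expect_identical(call_dependency(f3, expr), call_dependency(f3, expr))
})

test_that("HDE is only reported downstream of a stem-loop", {
  # C and A alone can pair with neither each other nor themselves, so this
  # UTR has a perfect purine block but no possible hairpin
  utr <- paste0(strrep("C", 20), strrep("A", 10), strrep("C", 30))
  f <- utr_features("g", strrep("C", 60), utr)
  expect_null(f$stem_loop)
  expect_null(f$hde)
  expect_equal(scan_hde(strrep("A", 10))$purine_fraction, 1)
})
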