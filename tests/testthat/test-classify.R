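refs <- reference_set()

test_that("the bundled reference set covers all families", {
  expect_setequal(unique(refs$family), c("H1", "H2A", "H2B", "H3", "H4"))
  expect_true(all(c("H3.3", "H2A.X", "H2A.Z", "macroH2A", "CENP-A") %in%
    refs$variant))
})

test_that("every bundled reference self-classifies with identity 1", {
  calls <- assign_family(
    tibble::tibble(id = refs$id, residues = refs$residues), refs
  )
  expect_equal(calls$family, refs$family)
  expect_equal(calls$identity, rep(1, nrow(refs)))
  expect_equal(calls$variant, refs$variant)
})

test_that("classification is invariant under reference order permutation", {
  withr::local_seed(3)
  q <- tibble::tibble(id = "q", residues = refs$residues[refs$id == "H33_ref"])
  base <- assign_family(q, refs)
  for (i in 1:3) {
    shuffled <- refs[sample(nrow(refs)), ]
    expect_equal(assign_family(q, shuffled), base)
  }
})

test_that("composition-preserving shuffles fall below a calibrated identity floor", {
  withr::local_seed(11)
  h4 <- refs$residues[refs$id == "H4_ref"]
  shuffle_identity <- vapply(1:100, function(i) {
    s <- paste(sample(strsplit(h4, "")[[1]]), collapse = "")
    global_align(s, h4)$identity
  }, numeric(1))
  floor_id <- max(shuffle_identity) + 0.01
  expect_lt(floor_id, 1)
  s <- paste(sample(strsplit(h4, "")[[1]]), collapse = "")
  call <- assign_family(c(shuf = s), refs, min_identity = floor_id)
  expect_equal(call$family, "unclassified")
  expect_equal(call$variant, "")
})

test_that("H3.3 diagnostics score the five canonical-vs-variant sites", {
  h31 <- refs$residues[refs$id == "H3_ref"]
  h33 <- refs$residues[refs$id == "H33_ref"]
  human <- h3_variant_diagnostics(h33, h31)
  expect_equal(human$matches, 5)
  expect_equal(human$report$status, rep("variant", 5))

  self <- h3_variant_diagnostics(h31, h31)
  expect_equal(self$matches, 0)

  # hydrozoan-style H3.3: site 96 remains in the canonical (C) state
  hyd <- h33
  substr(hyd, 96, 96) <- "C"
  d <- h3_variant_diagnostics(hyd, h31)
  expect_equal(d$matches, 4)
  expect_equal(d$report$status[d$report$position == 96], "canonical")
  expect_equal(d$report$observed[d$report$position == 96], "C")
})

test_that("a deletion spanning a diagnostic site reports indeterminate", {
  h31 <- refs$residues[refs$id == "H3_ref"]
  gapped <- paste0(substr(h31, 1, 27), substr(h31, 34, nchar(h31)))
  d <- h3_variant_diagnostics(gapped, h31)
  expect_equal(d$report$status[d$report$position == 31], "indeterminate")
  expect_equal(d$matches, 0)
})

test_that("the H2A.X C-terminal tetrad check distinguishes match classes", {
  expect_true(h2ax_cterm_check("AAASQEY")$match)
  sqay <- h2ax_cterm_check("AAASQAY")
  expect_false(sqay$match)
  expect_true(sqay$near_match)
  expect_equal(sqay$tetrad, "SQAY")
  aqey <- h2ax_cterm_check("AAAAQEY")
  expect_false(aqey$match)
  expect_false(aqey$near_match)
  expect_error(h2ax_cterm_check("SQ"), "shorter")
})

test_that("macro-domain length flag requires a 1.8-fold extension", {
  h2a <- refs$residues[refs$id == "H2A_ref"]
  macro <- refs$residues[refs$id == "macroH2A_ref_synthetic"]
  expect_true(macro_length_check(macro, h2a))
  expect_false(macro_length_check(h2a, h2a))
  expect_false(macro_length_check(paste0(h2a, "GGGGGGGGGG"), h2a))
})

test_that("H2A.X-tailed queries are called as the H2A.X variant", {
  h2a <- refs$residues[refs$id == "H2A_ref"]
  q <- paste0(substr(h2a, 1, nchar(h2a) - 4), "SQEY")
  call <- assign_family(c(x = q), refs)
  expect_equal(call$family, "H2A")
  expect_equal(call$variant, "H2A.X")
  expect_true(any(grepl("SQEY", unlist(call$evidence))))
})

test_that("inventory totals classified inputs and an empty input is all zero", {
  calls <- assign_family(
    tibble::tibble(id = refs$id, residues = refs$residues), refs
  )
  inv <- inventory(calls)
  expect_equal(sum(inv$n), nrow(refs))

  empty <- inventory(calls[0, ])
  expect_true(all(empty$n == 0))
})
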