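test_that("consensus calls follow the fixed/alternative/X column rules", {
  aln <- make_alignment(c(
    a = "FDACDEFGH",
    b = "FDCCDEFGH",
    c = "FEWCDEFGH"))
  cons <- build_consensus(aln, fixed_frac = 1, alt_max = 4)
  expect_equal(cons$entries[[1]], "F")                 # unanimous
  expect_equal(cons$entries[[2]], c("D", "E"))         # {D,D,E} -> frequency order
  expect_equal(cons$entries[[3]], c("A", "C", "W"))    # singles tie alphabetically
  # a column with too many distinct residues is X
  many <- make_alignment(c(a = "A", b = "C", c = "D", d = "E", e = "F",
                           f = "G", g = "H", h = "I"))
  expect_equal(build_consensus(many)$entries[[1]], "X")
  # under-covered columns are X
  gappy <- make_alignment(c(a = "A-", b = "A-", c = "A-", d = "AC", e = "AC"))
  expect_equal(build_consensus(gappy, min_coverage = 0.8)$entries[[2]], "X")
})

test_that("formatted consensus strings round-trip", {
  set.seed(101)
  for (i in 1:25) {
    cons <- random_consensus(sample(5:40, 1))
    expect_equal(parse_consensus(format_consensus(cons))$entries, cons$entries)
  }
})

test_that("longest phrase matches the documented worked example", {
  cons <- parse_consensus("ABXXCDEFXG")
  ph <- longest_phrase(cons)
  expect_equal(c(ph$start_col, ph$end_col), c(5L, 10L))  # XX blocks extension left
  expect_equal(ph$formatted, "CDEFXG")

  none <- parse_consensus("ABCDEF")
  expect_equal(c(longest_phrase(none)$start_col, longest_phrase(none)$end_col),
               c(1L, 6L))
  single <- parse_consensus("ABXDEF")
  expect_equal(longest_phrase(single)$formatted, "ABXDEF")  # one X is spanned

  expect_message(allx <- longest_phrase(parse_consensus("XXXX")), "degenerate")
  expect_equal(c(allx$start_col, allx$end_col), c(1L, 1L))
})

test_that("longest phrase equals the exhaustive window scan on random consensi", {
  set.seed(111)
  for (i in 1:80) {
    cons <- random_consensus(sample(4:60, 1))
    ph <- suppressMessages(longest_phrase(cons))
    orc <- oracle_phrase(cons$entries)
    expect_equal(c(ph$start_col, ph$end_col), c(orc[1], orc[2]))
    # no adjacent X pair inside the reported phrase
    expect_false(grepl("XX", ph$formatted, fixed = TRUE))
    # maximality: extending by one column breaks validity or bounds
    x <- famhist:::is_x(cons$entries)
    if (ph$start_col > 1 && !identical(c(ph$start_col, ph$end_col), c(1L, 1L))) {
      a <- ph$start_col - 1L
      expect_true(x[a] && (x[a + 1] || (a > 1 && x[a - 1])))
    }
    if (ph$end_col < cons$m && !identical(c(ph$start_col, ph$end_col), c(1L, 1L))) {
      b <- ph$end_col + 1L
      expect_true(x[b] && (x[b - 1] || (b < cons$m && x[b + 1])))
    }
  }
})

test_that("phrase reports map columns to reference coordinates", {
  # ungapped reference covering the whole alignment
  aln <- make_alignment(c(r = "ACDEF", s = "ACDEF", t = "ACDEF"))
  ph <- phrase_report(longest_phrase(build_consensus(aln)), aln, "r")
  expect_equal(c(ph$ref_start, ph$ref_end), c(1, 5))
  expect_equal(ph$fraction_of_alignment, 1)
  expect_equal(ph$fraction_of_reference, 1)

  # gapped reference: phrase starting on a reference gap maps to the next residue
  aln2 <- make_alignment(c(r = "--CDE-----", s = "ACCDEFGHIK", t = "ACCDEFGHIK",
                           u = "ACCDEFGHIK", v = "ACCDEFGHIK"))
  cons2 <- build_consensus(aln2, min_coverage = 0.8)
  ph2 <- phrase_report(longest_phrase(cons2), aln2, "r")
  expect_equal(ph2$ref_start, 1)          # first covered reference residue
  expect_equal(ph2$fraction_of_reference, 1)
  expect_equal(ph2$fraction_of_alignment, 1)

  expect_error(phrase_report(longest_phrase(build_consensus(aln)), aln, "zz"),
               "not in alignment")
})

test_that("the synthetic motif alignments reproduce the published spans", {
  for (fam in c("alpha", "beta")) {
    fx <- synthetic_consensus_alignment(fam)
    ph <- phrase_report(longest_phrase(build_consensus(fx$aln)), fx$aln,
                        fx$reference_id)
    expect_equal(ph$start_col, fx$block_start)
    expect_equal(ph$end_col, fx$block_end)
    if (fam == "alpha") {
      expect_equal(round(100 * ph$fraction_of_alignment), 4)
      expect_equal(round(100 * ph$fraction_of_reference), 7)
      expect_equal(ph$ref_start, 45)
    } else {
      expect_equal(round(100 * ph$fraction_of_alignment), 15)
      expect_equal(round(100 * ph$fraction_of_reference), 20)
      expect_equal(ph$ref_start, 140)
    }
    # formatted phrase parses back to the same entries (round-trip)
    expect_equal(parse_consensus(ph$formatted)$entries, ph$entries)
  }
})
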