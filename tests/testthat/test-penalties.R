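test_that("default penalty constants match the model", {
  s <- pg_penalties()
  expect_equal(s$mismatch, 1.0)
  expect_equal(s$insertion, 1.5)
  expect_equal(s$gap, 1.1)
  expect_equal(s$frameshift, 2.5)
  expect_equal(s$intron, 2.0)
  expect_equal(s$min_intron_len, 22L)
  expect_equal(s$accepted_intron_penalty, 0.25)
})

test_that("splice-site penalty tables", {
  expect_equal(donor_penalty("GT"), 0)
  expect_equal(donor_penalty("GC"), 0.25)
  expect_equal(donor_penalty("AT"), 0.75)
  expect_equal(donor_penalty("CA"), 1.0)
  expect_equal(acceptor_penalty("AG"), 0)
  expect_equal(acceptor_penalty("AC"), 0.75)
  expect_equal(acceptor_penalty("TT"), 1.0)
})

test_that("intron penalty is base plus splice terms", {
  s <- pg_penalties()
  expect_equal(intron_penalty(make_test_intron(30)), 2.0)
  expect_equal(intron_penalty(make_test_intron(30, donor = "GC")), 2.25)
  expect_equal(intron_penalty(make_test_intron(30, "AT", "AC")), 3.5)
  # below the minimum length there is no admissible intron
  expect_true(is.infinite(intron_penalty(make_test_intron(21))) ||
                is.na(intron_penalty(make_test_intron(21))))
})

test_that("match penalty distinguishes match and mismatch", {
  expect_equal(match_penalty("M", "ATG"), 0)
  expect_equal(match_penalty("K", "ATG"), 1.0)
  # unknown residues and stop codons never count as matches
  expect_equal(match_penalty("X", "ATG"), 1.0)
  expect_equal(match_penalty("M", "TAA"), 1.0)
})

test_that("codon translation follows the standard code", {
  expect_equal(translate_codon("ATG"), "M")
  expect_equal(translate_codon("TAA"), "*")
  expect_equal(translate_codon("TGA"), "*")
  # table 6: TAA/TAG read as Q
  expect_equal(translate_codon("TAA", 6), "Q")
})

test_that("intron classification by splice-site penalty threshold", {
  expect_equal(classify_intron("GT", "AG"), "intron")
  expect_equal(classify_intron("GC", "AG"), "intron")
  expect_equal(classify_intron("AT", "AC"), "intron?")
  expect_equal(classify_intron("CA", "AG"), "intron?")
  raised <- pg_penalties(accepted_intron_penalty = 1.5)
  expect_equal(classify_intron("AT", "AC", raised), "intron")
})

test_that("penalty scheme validation", {
  expect_error(pg_penalties(mismatch = -1), "non-negative")
  expect_error(pg_penalties(min_intron_len = 1), ">= 2")
})

test_that("parse_cost sums per-segment penalties and rejects bad shapes", {
  p <- rbind(parse_segment("codon_match", "M", "ATG"),
             parse_segment("intron", "", make_test_intron(25)),
             parse_segment("codon_match", "K", "AAA"))
  expect_equal(parse_cost(p), 2.0)
  bad <- parse_segment("codon_match", "MK", "ATGAAA")
  expect_true(is.na(parse_cost(bad)))
  short_intron <- parse_segment("intron", "", make_test_intron(10))
  expect_true(is.na(parse_cost(short_intron)))
})
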