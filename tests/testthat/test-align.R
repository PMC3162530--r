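test_that("perfect single-exon alignment costs zero", {
  prot <- "MKHW"
  p <- align_spliced(prot, encode_cds(prot))
  expect_equal(p$cost, 0)
  expect_true(all(p$segments$category == "codon_match"))
})

test_that("one perfect GT--AG intron costs exactly the intron penalty", {
  cds <- encode_cds("MKHWL")
  target <- paste0(substr(cds, 1, 9), make_test_intron(40),
                   substr(cds, 10, 15))
  p <- align_spliced("MKHWL", target)
  expect_equal(p$cost, 2.0)
  expect_equal(sum(p$segments$category == "intron"), 1L)
})

test_that("GC--AG and AT--AC introns add their splice penalties", {
  cds <- encode_cds("MKHWL")
  for (b in list(c("GC", "AG", 2.25), c("AT", "AC", 3.5))) {
    target <- paste0(substr(cds, 1, 9),
                     make_test_intron(40, b[1], b[2]),
                     substr(cds, 10, 15))
    expect_equal(align_spliced("MKHWL", target)$cost, as.numeric(b[3]))
  }
})

test_that("a lone unmatched residue costs the insertion penalty", {
  # query MKW against codons for M,W: K has no codon counterpart
  target <- paste0(FIXED_CODON[["M"]], FIXED_CODON[["W"]])
  p <- align_spliced("MKW", target)
  expect_equal(p$cost, 1.5)
  expect_equal(sum(p$segments$category == "insertion"), 1L)
})

test_that("a lone extra codon costs the gap penalty", {
  target <- paste0(FIXED_CODON[["M"]], "GGG", FIXED_CODON[["W"]])
  p <- align_spliced("MW", target)
  expect_equal(p$cost, 1.1)
  expect_equal(sum(p$segments$category == "gap"), 1L)
})

test_that("extra non-multiple-of-three bases are frameshifts", {
  target <- paste0(FIXED_CODON[["M"]], "G", FIXED_CODON[["W"]])
  p <- align_spliced("MW", target)
  expect_equal(p$cost, 2.5)
  expect_equal(sum(p$segments$category == "frameshift"), 1L)
})

test_that("introns below the minimum length are not used", {
  # a single extra codon is cheaper as a gap than as any admissible intron
  target <- paste0("AAA", "CCC", "AAA")
  p <- align_spliced("KK", target)
  expect_false(any(p$segments$category %in%
                     c("intron", "split_codon_intron")))
  expect_equal(p$cost, 1.1)
  # any intron the aligner does emit is at least min_intron_len long
  set.seed(31)
  for (rep in 1:40) {
    inst <- random_instance(max_q = 3L, max_t = 50L)
    segs <- align_spliced(inst$query, inst$target)$segments
    ir <- segs[segs$category == "intron", , drop = FALSE]
    if (nrow(ir)) expect_true(all(nchar(ir$target) >= 22L))
    sc <- segs[segs$category == "split_codon_intron", , drop = FALSE]
    if (nrow(sc)) expect_true(all(nchar(sc$intron) >= 22L))
  }
})

test_that("split codons across an intron are recognized in both phases", {
  cds <- encode_cds("MKHWL")
  for (phase in 1:2) {
    cut <- 6L + phase       # inside the codon of residue 3
    target <- paste0(substr(cds, 1, cut), make_test_intron(40),
                     substr(cds, cut + 1, 15))
    p <- align_spliced("MKHWL", target)
    expect_equal(p$cost, 2.0)
    sci <- p$segments[p$segments$category == "split_codon_intron", ]
    expect_equal(nrow(sci), 1L)
    expect_equal(sci$split, phase)
  }
})

test_that("parse segments reproduce the reported cost", {
  set.seed(99)
  for (rep in 1:50) {
    inst <- random_instance()
    p <- align_spliced(inst$query, inst$target)
    expect_equal(parse_cost(p$segments), p$cost,
                 info = sprintf("q=%s t=%s", inst$query, inst$target))
  }
})

test_that("production alignment agrees with the exhaustive oracle", {
  scheme <- pg_penalties(min_intron_len = 5L)
  set.seed(7)
  for (rep in 1:150) {
    inst <- random_instance()
    got <- align_spliced(inst$query, inst$target, scheme)$cost
    want <- enumerate_parses(inst$query, inst$target, scheme)
    expect_equal(got, want,
                 info = sprintf("q=%s t=%s", inst$query, inst$target))
  }
})

test_that("empty inputs have defined costs", {
  expect_equal(align_spliced("", "")$cost, 0)
  expect_equal(align_spliced("M", "")$cost, 1.5)
  expect_equal(align_spliced("", "ATG")$cost, 1.1)
})
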