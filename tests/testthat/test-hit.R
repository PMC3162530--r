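test_that("unmatched target regions classify as insertion or intron candidate", {
  # in frame, stop free, shorter than the minimum intron: merge
  expect_equal(classify_unmatched_target("GGTGGAGGCGGGGCAGCCGCG"),
               "merge_into_exon")
  # not a multiple of three
  expect_equal(classify_unmatched_target(strrep("G", 20)),
               "intron_candidate")
  # contains an in-frame stop codon
  expect_equal(classify_unmatched_target(paste0("GGT", "TAA", "GGTGGAGGC")),
               "intron_candidate")
  # at or above the minimum intron length
  expect_equal(classify_unmatched_target(strrep("GGT", 8)),
               "intron_candidate")
})

test_that("refine_hit reconstructs a multi-exon gene exactly", {
  fx <- generate_gene(protein_length = 100, n_introns = 3, seed = 61)
  tseq <- as.character(fx$genome[[1]])
  h <- seed_hits(fx$protein, fx$genome)[[1]]
  p <- refine_hit(h, fx$protein, tseq)
  expect_s3_class(p, "pg_part")
  expect_true(exact_exon_boundaries(p, fx$exons))
  expect_equal(nrow(p$introns), 3L)
  expect_equal(p$introns$phase, fx$introns$phase)
  expect_equal(p$introns$status, fx$introns$status)
  expect_equal(p$stats$identity, 1)
  expect_equal(p$stats$coverage, 1)
})

test_that("split codons are represented and phased correctly", {
  for (phase in 1:2) {
    fx <- generate_gene(protein_length = 60, exon_lengths = c(30, 30),
                        intron_lengths = 100, phases = phase, seed = 63)
    p <- single_part(map_protein(c(q = fx$protein), fx$genome))
    expect_true(exact_exon_boundaries(p, fx$exons))
    expect_equal(p$introns$phase, phase)
    segs <- p$segments
    expect_equal(sum(segs$type == "codon5"), 1L)
    expect_equal(sum(segs$type == "codon3"), 1L)
    # the split residue is counted exactly once
    expect_equal(p$stats$matches + p$stats$mismatches, 60)
  }
})

test_that("an exact internal micro-exon (1 aa) is recovered", {
  fx <- generate_gene(protein_length = 61, exon_lengths = c(30, 1, 30),
                      intron_lengths = c(80, 90), phases = c(0, 0),
                      seed = 65)
  p <- single_part(map_protein(c(q = fx$protein), fx$genome))
  expect_true(exact_exon_boundaries(p, fx$exons))
  expect_equal(nrow(p$exons), 3L)
})

test_that("a mismatched internal short exon is rejected as a gap", {
  fx <- generate_gene(protein_length = 70, exon_lengths = c(30, 3, 37),
                      intron_lengths = c(80, 90), phases = c(0, 0),
                      seed = 11)
  pr <- fx$protein
  substr(pr, 32, 32) <- if (substr(pr, 32, 32) == "A") "V" else "A"
  p <- single_part(map_protein(c(q = pr), fx$genome))
  expect_equal(nrow(p$exons), 2L)
  expect_equal(nrow(p$gaps), 1L)
  expect_equal(p$gaps$qstart, 30L)
  expect_equal(p$gaps$qend, 33L)
})

test_that("terminal exon search honors the gap_to_close limit", {
  flank <- paste0(strrep("T", 30), encode_cds("MKHWLA"),
                  make_test_intron(30))
  flank <- paste0(flank, "")     # N-side flank ends right before the gene
  # 6 residues: searched and found
  fe <- find_terminal_exon("MKHWLA", flank, side = "N")
  expect_false(is.null(fe))
  expect_equal(fe$exon_offset, 30L)
  expect_equal(fe$intron_end - fe$intron_start, 30L)
  # 7 residues: never searched at defaults
  flank7 <- paste0(strrep("T", 30), encode_cds("MKHWLAC"),
                   make_test_intron(30))
  expect_null(find_terminal_exon("MKHWLAC", flank7, side = "N"))
  # C side
  flankC <- paste0(make_test_intron(30), encode_cds("MKHWLA"),
                   strrep("T", 30))
  feC <- find_terminal_exon("MKHWLA", flankC, side = "C")
  expect_false(is.null(feC))
  expect_equal(feC$intron_end, 30L)
})

test_that("margin trimming frees residues at block junctions", {
  blocks <- data.frame(qstart = c(0L, 40L), qend = c(30L, 80L),
                       tstart = c(0L, 500L), tend = c(90L, 620L),
                       matches = c(30L, 40L), mismatches = c(0L, 0L))
  h <- list(query_id = "q", target_id = "t", strand = "+", blocks = blocks)
  tr <- trim_hit_margins(h, 6L)$blocks
  expect_equal(tr$qend[1], 24L)
  expect_equal(tr$qstart[2], 46L)
  expect_equal(tr$tend[1], 72L)
  expect_equal(tr$tstart[2], 518L)
  # untouched at the hit's outer ends
  expect_equal(tr$qstart[1], 0L)
  expect_equal(tr$qend[2], 80L)
})

test_that("clean insertion junctions are exempt from margin trimming", {
  # two abutting blocks separated by a 21-nt in-frame stop-free insertion
  blocks <- data.frame(qstart = c(0L, 30L), qend = c(30L, 60L),
                       tstart = c(0L, 111L), tend = c(90L, 201L),
                       matches = c(30L, 30L), mismatches = c(0L, 0L))
  h <- list(query_id = "q", target_id = "t", strand = "+", blocks = blocks)
  tseq <- paste0(encode_cds(strrep("M", 30)), "GGTGGAGGCGGGGCAGCCGCG",
                 encode_cds(strrep("K", 30)))
  tr <- trim_hit_margins(h, 6L, tseq, pg_params())$blocks
  expect_identical(tr, blocks)
})

test_that("in-frame stops and frameshifts are detected and located", {
  fx <- generate_gene(protein_length = 100, n_introns = 2, seed = 41)
  fe <- inject_errors(fx, n_frameshifts = 1, n_inframe_stops = 1, seed = 1)
  # interior positions (precondition of this scenario)
  expect_true(all(c(fe$expected_frameshifts, fe$expected_stops) %in% 15:85))
  p <- single_part(map_protein(c(q = fe$protein), fe$genome))
  expect_equal(p$frameshifts, fe$expected_frameshifts)
  expect_equal(p$stops, fe$expected_stops)
})
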