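test_that("generated genes are internally consistent", {
  fx <- generate_gene(protein_length = 120, n_introns = 4, seed = 81)
  gs <- as.character(fx$genome[[1]])
  # concatenated exon sequence translates back to the protein
  cds <- paste(vapply(seq_len(nrow(fx$exons)), function(k)
    substr(gs, fx$exons$tstart[k] + 1L, fx$exons$tend[k]), ""),
    collapse = "")
  expect_equal(nchar(cds), 3L * nchar(fx$protein))
  aa <- paste(vapply(seq(1, nchar(cds), 3), function(o)
    translate_codon(substr(cds, o, o + 2)), ""), collapse = "")
  expect_equal(aa, fx$protein)
  # intron borders spell their patterns
  for (k in seq_len(nrow(fx$introns))) {
    expect_equal(substr(gs, fx$introns$tstart[k] + 1L,
                        fx$introns$tstart[k] + 2L), fx$introns$donor[k])
    expect_equal(substr(gs, fx$introns$tend[k] - 1L, fx$introns$tend[k]),
                 fx$introns$acceptor[k])
  }
  # exons and introns tile the gene region contiguously
  bounds <- rbind(fx$exons[, c("tstart", "tend")],
                  fx$introns[, c("tstart", "tend")])
  bounds <- bounds[order(bounds$tstart), ]
  expect_true(all(bounds$tstart[-1] == bounds$tend[-nrow(bounds)]))
})

test_that("generation is deterministic per seed", {
  a <- generate_gene(protein_length = 50, n_introns = 2, seed = 83)
  b <- generate_gene(protein_length = 50, n_introns = 2, seed = 83)
  expect_identical(a$protein, b$protein)
  expect_identical(as.character(a$genome[[1]]), as.character(b$genome[[1]]))
  c <- generate_gene(protein_length = 50, n_introns = 2, seed = 84)
  expect_false(identical(as.character(a$genome[[1]]),
                         as.character(c$genome[[1]])))
})

test_that("intron-free genes are supported", {
  fx <- generate_gene(protein_length = 40, n_introns = 0, seed = 85)
  expect_equal(nrow(fx$introns), 0L)
  expect_equal(nrow(fx$exons), 1L)
})

test_that("divergence substitutes the requested fraction of codons", {
  fx <- generate_gene(protein_length = 200, n_introns = 2, seed = 87)
  dv <- apply_divergence(fx, aa_substitution_rate = 0.2, seed = 1)
  # substitutions are applied to genomic codons; the query protein and the
  # truth coordinates stay fixed, and affected residues are recorded
  expect_identical(dv$protein, fx$protein)
  expect_false(identical(as.character(dv$genome[[1]]),
                         as.character(fx$genome[[1]])))
  expect_identical(dv$exons, fx$exons)
  diffs <- length(dv$expected_mismatches)
  expect_gte(diffs, 20)
  expect_lte(diffs, 60)
  # each recorded residue now translates to a non-matching amino acid
  gs <- as.character(dv$genome[[1]])
  for (r in dv$expected_mismatches[1:5]) {
    codon <- paste(strsplit(gs, "")[[1]][dv$codon_pos[r, ] + 1L],
                   collapse = "")
    expect_false(translate_codon(codon) == substr(fx$protein, r, r))
  }
})

test_that("injected errors are recorded with their positions", {
  fx <- generate_gene(protein_length = 100, n_introns = 2, seed = 41)
  fe <- inject_errors(fx, n_frameshifts = 2, n_inframe_stops = 1, seed = 4)
  expect_length(fe$expected_frameshifts, 2L)
  expect_length(fe$expected_stops, 1L)
  expect_false(identical(as.character(fe$genome[[1]]),
                         as.character(fx$genome[[1]])))
})

test_that("fragmentation remaps truth to per-contig coordinates", {
  fx <- generate_gene(protein_length = 150, n_introns = 3, seed = 31,
                      intron_length_range = c(80, 150))
  mid <- as.integer((fx$introns$tstart[2] + fx$introns$tend[2]) / 2)
  f2 <- fragment_into_contigs(fx, breakpoints = mid, seed = 1)
  expect_length(f2$genome, 2L)
  # without padding the two contigs concatenate to the original genome
  expect_equal(paste0(as.character(f2$genome[[1]]),
                      as.character(f2$genome[[2]])),
               as.character(fx$genome[[1]]))
  # every exon survives on exactly one contig; the cut intron is dropped
  expect_equal(nrow(f2$exons), nrow(fx$exons))
  expect_equal(nrow(f2$introns), nrow(fx$introns) - 1L)
  expect_equal(f2$n_introns_total, nrow(fx$introns))
  # remapped exons still translate to their protein segments
  for (k in seq_len(nrow(f2$exons))) {
    ctg <- as.character(f2$genome[[f2$exons$contig[k]]])
    expect_true(f2$exons$tend[k] <= nchar(ctg))
  }
})

test_that("reverse-complement fixtures flip coordinates consistently", {
  fx <- generate_gene(protein_length = 60, n_introns = 1, seed = 89)
  rc <- reverse_complement_fixture(fx)
  L <- Biostrings::width(fx$genome)[1]
  expect_setequal(rc$exons$tstart, L - fx$exons$tend)
  expect_setequal(rc$exons$tend, L - fx$exons$tstart)
  expect_equal(as.character(rc$genome[[1]]),
               as.character(Biostrings::reverseComplement(fx$genome[[1]])))
})

test_that("the fixture panel is reproducible and spans the design space", {
  panel <- fixture_panel(seed = 1)
  expect_length(panel, 25L)
  nex <- vapply(panel, function(f) nrow(f$exons), integer(1))
  expect_equal(min(nex), 1L)
  expect_equal(max(nex), 12L)
  sizes <- unlist(lapply(panel, function(f)
    (f$exons$tend - f$exons$tstart) / 3))
  expect_lte(min(sizes), 4)            # micro-exons present
  expect_gte(max(sizes), 200)          # large exons present
  phases <- unlist(lapply(panel, function(f) f$introns$phase))
  expect_setequal(unique(phases), 0:2)
  donors <- unlist(lapply(panel, function(f) f$introns$donor))
  expect_setequal(unique(donors), c("GT", "GC"))
  ilen <- unlist(lapply(panel, function(f) f$introns$tend - f$introns$tstart))
  expect_gte(min(ilen), 22)
  expect_lte(max(ilen), 500)
  panel2 <- fixture_panel(seed = 1)
  expect_identical(panel[[7]]$protein, panel2[[7]]$protein)
})
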