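test_that("the seeder finds a single-exon gene exactly", {
  set.seed(3)
  prot <- random_aa(40)
  genome <- paste0(strrep("T", 150), encode_cds(prot), strrep("T", 150))
  hits <- seed_hits(prot, c(ctg = genome))
  expect_length(hits, 1L)
  h <- hits[[1]]
  expect_equal(h$target_id, "ctg")
  expect_equal(h$strand, "+")
  expect_equal(min(h$blocks$qstart), 0L)
  expect_equal(max(h$blocks$qend), 40L)
  expect_equal(min(h$blocks$tstart), 150L)
  # blocks keep the 3:1 nucleotide:residue ratio
  expect_true(all(h$blocks$tend - h$blocks$tstart ==
                    3L * (h$blocks$qend - h$blocks$qstart)))
})

test_that("the seeder chains blocks across introns", {
  fx <- generate_gene(protein_length = 90, n_introns = 2, seed = 21)
  hits <- seed_hits(fx$protein, fx$genome)
  expect_length(hits, 1L)
  bl <- hits[[1]]$blocks
  expect_gte(nrow(bl), 3L)
  # every residue except those with codons split by a phased intron
  expect_equal(sum(bl$matches), 90 - sum(fx$introns$phase > 0))
  # strictly collinear in query and target
  expect_true(all(diff(bl$qstart) > 0))
  expect_true(all(diff(bl$tstart) > 0))
})

test_that("minus-strand genes are seeded on the reverse complement", {
  fx <- reverse_complement_fixture(
    generate_gene(protein_length = 60, n_introns = 1, seed = 23))
  hits <- seed_hits(fx$protein, fx$genome)
  expect_length(hits, 1L)
  expect_equal(hits[[1]]$strand, "-")
})

test_that("hit statistics follow their definitions", {
  blocks <- data.frame(qstart = c(0L, 50L), qend = c(40L, 80L),
                       tstart = c(0L, 300L), tend = c(120L, 390L),
                       matches = c(38L, 28L), mismatches = c(2L, 2L))
  h <- list(query_id = "q", target_id = "t", strand = "+", blocks = blocks)
  s <- compute_stats(h, 100L)
  expect_equal(s$matches, 66)
  expect_equal(s$mismatches, 4)
  expect_equal(s$coverage, 0.70)           # mapped / query length
  expect_equal(s$identity, 66 / 70)
  expect_equal(s$score, (66 - 4) / 100)
})

test_that("filter_hits applies all four thresholds", {
  mk <- function(ma, mi, qlen_mapped) {
    list(query_id = "q", target_id = "t", strand = "+",
         blocks = data.frame(qstart = 0L, qend = qlen_mapped,
                             tstart = 0L, tend = 3L * qlen_mapped,
                             matches = ma, mismatches = mi))
  }
  good <- mk(70L, 2L, 72L)
  expect_length(filter_hits(list(good), 100L), 1L)
  # coverage 0.50 at defaults is rejected
  half <- mk(50L, 0L, 50L)
  expect_length(filter_hits(list(half), 100L), 0L)
  expect_length(filter_hits(list(half), 100L, min_coverage = 0.5), 1L)
  # identity below 0.9
  lowid <- mk(60L, 12L, 72L)
  expect_length(filter_hits(list(lowid), 100L), 0L)
  # score below 0.3
  lowsc <- mk(65L, 36L, 101L)
  expect_length(filter_hits(list(lowsc), 120L), 0L)
  # max_mismatch
  expect_length(filter_hits(list(good), 100L, max_mismatch = 1), 0L)
})

test_that("seeding is deterministic", {
  fx <- generate_gene(protein_length = 80, n_introns = 2, seed = 25)
  h1 <- seed_hits(fx$protein, fx$genome)
  h2 <- seed_hits(fx$protein, fx$genome)
  expect_identical(h1, h2)
})

test_that("no hits on an unrelated genome", {
  set.seed(11)
  prot <- random_aa(50)
  genome <- c(ctg = strrep("TACG", 500))
  hits <- seed_hits(prot, genome)
  expect_true(length(hits) == 0L ||
                all(vapply(hits, function(h) sum(h$blocks$matches),
                           numeric(1)) < 15))
})
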