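# study condition for fragmented assemblies: a partial per-contig hit can
# never reach the default score/coverage thresholds by construction
frag_params <- pg_params(min_score = 0, min_coverage = 0)

frag_fixture <- function() {
  generate_gene(protein_length = 150, n_introns = 3, seed = 31,
                intron_length_range = c(80, 150))
}

intron_midpoints <- function(fx)
  with(fx$introns, as.integer((tstart + tend) / 2))

test_that("a gene split across three contigs reassembles exactly", {
  fx <- frag_fixture()
  f3 <- fragment_into_contigs(fx, breakpoints = intron_midpoints(fx)[c(1, 3)],
                              seed = 5)
  res <- map_protein(c(q = f3$protein), f3$genome, frag_params)
  g <- res$queries$q$results[[1]]
  expect_length(g$parts, 3L)
  expect_equal(g$targets, c("ctg1_part1", "ctg1_part2", "ctg1_part3"))
  expect_equal(nrow(g$joins), 2L)
  expect_equal(g$stats$coverage, 1)
  for (p in g$parts) {
    tr <- f3$exons[f3$exons$contig == p$contig, , drop = FALSE]
    expect_true(exact_exon_boundaries(p, tr), info = p$contig)
  }
})

test_that("codons split across contig junctions are completed", {
  fx <- frag_fixture()
  # cuts at phase-1 and phase-2 introns split two codons across contigs
  expect_equal(fx$introns$phase[c(1, 3)], c(1L, 2L))
  f3 <- fragment_into_contigs(fx, breakpoints = intron_midpoints(fx)[c(1, 3)],
                              seed = 5)
  g <- map_protein(c(q = f3$protein), f3$genome,
                   frag_params)$queries$q$results[[1]]
  expect_equal(g$stats$matches, 150)
  # residue carried by the upstream contig; remaining bases downstream
  expect_equal(sum(vapply(g$parts, function(p)
    sum(p$segments$type == "codon5"), integer(1))), 2L)
  expect_equal(sum(vapply(g$parts, function(p)
    sum(p$segments$type == "codon3"), integer(1))), 2L)
})

test_that("single_target_hits never composes across contigs", {
  fx <- frag_fixture()
  f3 <- fragment_into_contigs(fx, breakpoints = intron_midpoints(fx)[c(1, 3)],
                              seed = 5)
  prm <- pg_params(min_score = 0, min_coverage = 0,
                   single_target_hits = TRUE)
  res <- map_protein(c(q = f3$protein), f3$genome, prm)
  for (g in res$queries$q$results) {
    expect_length(g$parts, 1L)
    expect_equal(nrow(g$joins), 0L)
  }
})

test_that("implied joins above max_assemble_size discard the lower-scoring part", {
  fx <- frag_fixture()
  mid <- intron_midpoints(fx)[2]
  ok <- fragment_into_contigs(fx, breakpoints = mid, pad = 37000, seed = 6)
  g_ok <- map_protein(c(q = ok$protein), ok$genome,
                      frag_params)$queries$q$results[[1]]
  expect_length(g_ok$parts, 2L)
  expect_lte(g_ok$joins$implied_len, 75000)
  over <- fragment_into_contigs(fx, breakpoints = mid, pad = 38000, seed = 6)
  g_over <- map_protein(c(q = over$protein), over$genome,
                        frag_params)$queries$q$results[[1]]
  expect_length(g_over$parts, 1L)
  expect_equal(nrow(g_over$joins), 0L)
})

test_that("combined statistics include DNA coverage of implied joins", {
  fx <- generate_gene(protein_length = 90, n_introns = 1, seed = 71)
  p <- single_part(map_protein(c(q = fx$protein), fx$genome))
  joins <- data.frame(from_contig = "a", to_contig = "b",
                      implied_len = 1000)
  s <- combined_stats(list(p), joins, 90L)
  expect_equal(s$matches, 90)
  span <- diff(range(c(p$exons$tstart, p$exons$tend)))
  expect_equal(s$dna_coverage, 100 * 3 * 90 / (span + 1000))
})

test_that("select_results ranks by score and applies thresholds", {
  fx <- generate_gene(protein_length = 90, n_introns = 1, seed = 71)
  p <- single_part(map_protein(c(q = fx$protein), fx$genome))
  gs <- assemble_structures(list(p), 90L)
  picked <- select_results(gs)
  expect_length(picked, 1L)
  strict <- select_results(gs, pg_params(min_score = 1.01))
  expect_length(strict, 0L)
  expect_match(attr(strict, "diagnostic"), "rejected")
  none <- select_results(list())
  expect_length(none, 0L)
  expect_match(attr(none, "diagnostic"), "no hits")
})

test_that("multiple_results reports every passing candidate", {
  fx <- generate_gene(protein_length = 90, n_introns = 1, seed = 45)
  g2 <- c(ctgA = as.character(fx$genome[[1]]),
          ctgB = as.character(fx$genome[[1]]))
  multi <- map_protein(c(q = fx$protein), g2,
                       pg_params(multiple_results = TRUE))
  expect_length(multi$queries$q$results, 2L)
  expect_setequal(vapply(multi$queries$q$results,
                         function(g) g$targets[1], ""),
                  c("ctgA", "ctgB"))
  single <- map_protein(c(q = fx$protein), g2)
  expect_length(single$queries$q$results, 1L)
})
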