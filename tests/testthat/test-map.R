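test_that("map_protein returns a classed result with plus-strand recovery", {
  fx <- generate_gene(protein_length = 90, n_introns = 2, seed = 91)
  res <- map_protein(c(myq = fx$protein), fx$genome)
  expect_s3_class(res, "pg_result")
  q <- res$queries$myq
  expect_equal(q$query_length, 90L)
  p <- q$results[[1]]$parts[[1]]
  expect_true(exact_exon_boundaries(p, fx$exons))
})

test_that("minus-strand genes map with correct forward coordinates", {
  fx <- reverse_complement_fixture(
    generate_gene(protein_length = 90, n_introns = 2, seed = 91))
  res <- map_protein(c(q = fx$protein), fx$genome)
  p <- res$queries$q$results[[1]]$parts[[1]]
  expect_equal(p$strand, "-")
  fwd <- t(vapply(seq_len(nrow(p$exons)), function(i)
    pgalign:::to_forward(p$exons$tstart[i], p$exons$tend[i], "-",
                         p$contig_length), numeric(2)))
  expect_setequal(fwd[, 1], fx$exons$tstart)
  expect_setequal(fwd[, 2], fx$exons$tend)
})

test_that("genome input is accepted as a FASTA path", {
  fx <- generate_gene(protein_length = 60, n_introns = 1, seed = 93)
  path <- tempfile(fileext = ".fa")
  pgalign:::write_fasta_file(fx$genome, path)
  res <- map_protein(c(q = fx$protein), path)
  expect_length(res$queries$q$results, 1L)
})

test_that("print, summary, and plot methods work", {
  fx <- generate_gene(protein_length = 60, n_introns = 1, seed = 93)
  res <- map_protein(c(q = fx$protein), fx$genome)
  expect_output(print(res), "mapping: 1 query")
  s <- summary(res)
  expect_s3_class(s, "summary.pg_result")
  expect_equal(nrow(s$table), 1L)
  expect_equal(s$table$exons, 2L)
  expect_output(print(s), "Mapping summary")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(res))
})

test_that("duplicate contig names are rejected", {
  expect_error(map_protein(c(q = "MKHW"),
                           c(a = "ACGT", a = "ACGT")),
               "duplicate")
})

test_that("the CLI maps a genome/query pair and honors flags", {
  fx <- generate_gene(protein_length = 70, n_introns = 2, seed = 95)
  dir <- tempfile(); dir.create(dir)
  gp <- file.path(dir, "g.fa"); qp <- file.path(dir, "q.fa")
  pgalign:::write_fasta_file(fx$genome, gp)
  pgalign:::write_fasta_file(c(q = fx$protein), qp)
  out <- file.path(dir, "res.yaml")
  status <- suppressMessages(
    run_cli(c(gp, qp, "--out-format", "yaml", "--outfile", out)))
  expect_equal(status, 0L)
  doc <- yaml::yaml.load_file(out)
  expect_equal(doc[[1]]$query, "q")
  gffout <- file.path(dir, "res.gff")
  status <- suppressMessages(
    run_cli(c(gp, qp, "--out-format", "gff", "--outfile", gffout)))
  expect_equal(status, 0L)
  expect_equal(readLines(gffout)[1], "##gff-version 3")
  # bad inputs exit nonzero
  expect_equal(suppressMessages(run_cli(c("missing.fa", qp))), 1L)
  expect_equal(suppressMessages(
    run_cli(c(gp, qp, "--out-format", "nope"))), 1L)
})
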