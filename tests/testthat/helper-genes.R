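# Shared helpers for building hand-crafted genes in tests.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# one fixed codon per residue (standard code), for deterministic CDS spelling
FIXED_CODON <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
                 G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
                 M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
                 S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE),
                               collapse = "")

encode_cds <- function(protein) {
  paste(FIXED_CODON[strsplit(protein, "")[[1]]], collapse = "")
}

# neutral intron: given borders, filled with pyrimidine-rich interior that
# spells no start/stop-free reading frames resembling the query
make_test_intron <- function(len, donor = "GT", acceptor = "AG") {
  stopifnot(len >= 4)
  paste0(donor, strrep("C", len - 4L), acceptor)
}

exact_exon_boundaries <- function(part, truth_exons) {
  identical(part$exons$tstart, as.integer(truth_exons$tstart)) &&
    identical(part$exons$tend, as.integer(truth_exons$tend))
}

single_part <- function(result, qid = "q") {
  res <- result$queries[[qid]]$results
  expect_length(res, 1L)
  expect_length(res[[1]]$parts, 1L)
  res[[1]]$parts[[1]]
}

# random alignment instance for oracle comparison: small query/target with
# planted structure so that nontrivial parses arise
random_instance <- function(max_q = 3L, max_t = 40L) {
  q <- paste(sample(c(AA20, "X"), sample(0:max_q, 1), replace = TRUE,
                    prob = c(rep(1, 20), 0.5)), collapse = "")
  t <- paste(sample(c("A", "C", "G", "T"), sample(0:max_t, 1),
                    replace = TRUE), collapse = "")
  list(query = q, target = t)
}
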