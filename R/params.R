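#' Search and processing parameters
#'
#' Collects every user-tunable parameter of the mapping pipeline in one
#' object, with the documented defaults.
#'
#' @param min_score minimum hit score, where score =
#'   (matches - mismatches) / query length, clipped at 0 (default 0.3).
#' @param min_identity minimum fraction of mapped residues that are matches
#'   (default 0.90).
#' @param max_mismatch maximum number of mismatches per hit
#'   (default `Inf`).
#' @param min_coverage minimum fraction of the query mapped as match or
#'   mismatch; hits strictly below it are rejected (default 0.60).
#' @param transtable NCBI translation table identifier (default 1), for
#'   species using non-standard codes.
#' @param min_intron_len minimum intron length in nucleotides (default 22);
#'   shorter in-frame, stop-free target stretches are treated as exonic
#'   insertions.
#' @param gap_to_close maximum number of unmatched terminal query residues
#'   that are resolved either by the exact terminal-exon search or by
#'   forcing them onto the adjacent exon border at the cost of mismatches
#'   (default 6).
#' @param exhaust_align_size maximum target span, in bp, submitted to the
#'   exhaustive spliced alignment when closing a gap (default 15000).
#' @param exhaust_gap_size maximum query gap, in residues, submitted to the
#'   exhaustive spliced alignment (default 21, three times the default seed
#'   tile size).
#' @param max_move_exon number of residues cut off from the margins of
#'   seeded exon blocks and realigned, to recover from misassigned
#'   intron-border sequence (default 6).
#' @param accepted_intron_penalty splice-site penalty threshold separating
#'   `"intron"` from `"intron?"` (default 0.25: GT--AG and GC--AG accepted).
#' @param single_target_hits forbid composing one gene from hits on several
#'   targets (chromosome mode; default `FALSE`).
#' @param multiple_results return all results passing the thresholds rather
#'   than only the best one (default `FALSE`).
#' @param max_assemble_size maximum implied intron length, in nucleotides,
#'   when joining partial hits across two contigs (default 75000).
#' @param min_dna_coverage minimum query/target length ratio of a composed
#'   hit, in percent; 0 disables the check (default 0).
#' @param tilesize seed k-mer length, in residues, of the built-in
#'   translated seeder (default 7).
#' @param penalties a [pg_penalties()] scheme; its `min_intron_len` and
#'   `accepted_intron_penalty` are overridden by the arguments above so
#'   there is a single source of truth.
#' @return An object of class `pg_params`.
#' @export
pg_params <- function(min_score = 0.3, min_identity = 0.90,
                      max_mismatch = Inf, min_coverage = 0.60,
                      transtable = 1, min_intron_len = 22L,
                      gap_to_close = 6L, exhaust_align_size = 15000L,
                      exhaust_gap_size = 21L, max_move_exon = 6L,
                      accepted_intron_penalty = 0.25,
                      single_target_hits = FALSE, multiple_results = FALSE,
                      max_assemble_size = 75000L, min_dna_coverage = 0,
                      tilesize = 7L, penalties = pg_penalties()) {
  stopifnot(min_coverage >= 0, min_coverage <= 1,
            min_identity >= 0, min_identity <= 1,
            gap_to_close >= 0, max_move_exon >= 0, tilesize >= 3,
            exhaust_gap_size >= 0, exhaust_align_size >= 0,
            max_assemble_size >= 0, min_dna_coverage >= 0)
  penalties$min_intron_len <- as.integer(min_intron_len)
  if (penalties$min_intron_len < 2L) stop("min_intron_len must be >= 2")
  penalties$accepted_intron_penalty <- accepted_intron_penalty
  structure(list(min_score = min_score, min_identity = min_identity,
                 max_mismatch = max_mismatch, min_coverage = min_coverage,
                 transtable = transtable,
                 gap_to_close = as.integer(gap_to_close),
                 exhaust_align_size = as.integer(exhaust_align_size),
                 exhaust_gap_size = as.integer(exhaust_gap_size),
                 max_move_exon = as.integer(max_move_exon),
                 single_target_hits = isTRUE(single_target_hits),
                 multiple_results = isTRUE(multiple_results),
                 max_assemble_size = as.integer(max_assemble_size),
                 min_dna_coverage = min_dna_coverage,
                 tilesize = as.integer(tilesize),
                 penalties = penalties),
            class = "pg_params")
}

#' @export
print.pg_params <- function(x, ...) {
  cat("Protein-to-genome mapping parameters\n")
  cat(sprintf("  filters: min_score %.2f, min_identity %.2f, max_mismatch %s, min_coverage %.0f%%\n",
              x$min_score, x$min_identity, format(x$max_mismatch),
              100 * x$min_coverage))
  cat(sprintf("  gaps: min_intron_len %d, gap_to_close %d, exhaust_gap_size %d aa, exhaust_align_size %d bp\n",
              x$penalties$min_intron_len, x$gap_to_close,
              x$exhaust_gap_size, x$exhaust_align_size))
  cat(sprintf("  borders: max_move_exon %d, accepted_intron_penalty %.2f\n",
              x$max_move_exon, x$penalties$accepted_intron_penalty))
  cat(sprintf("  assembly: single_target_hits %s, multiple_results %s, max_assemble_size %d, min_dna_coverage %g%%\n",
              x$single_target_hits, x$multiple_results, x$max_assemble_size,
              x$min_dna_coverage))
  cat(sprintf("  seeding: tilesize %d; translation table %s\n",
              x$tilesize, x$transtable))
  invisible(x)
}

# evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards; all fixture generation goes through this
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
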