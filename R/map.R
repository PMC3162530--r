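# Main entry point: map protein queries onto a genome.

as_aa_set <- function(x) {
  if (methods::is(x, "AAStringSet")) return(x)
  x <- stats::setNames(toupper(as.character(x)), names(x))
  if (is.null(names(x)))
    names(x) <- if (length(x) == 1L) "query" else
      sprintf("query%d", seq_along(x))
  Biostrings::AAStringSet(x)
}

as_dna_set <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  x <- stats::setNames(toupper(as.character(x)), names(x))
  if (is.null(names(x)))
    names(x) <- sprintf("target%d", seq_along(x))
  Biostrings::DNAStringSet(x)
}

# forward-strand nucleotide coordinates of an oriented [s, e) interval
to_forward <- function(s, e, strand, contig_length) {
  if (strand == "+") c(s, e) else c(contig_length - e, contig_length - s)
}

#' Map protein queries onto a genome
#'
#' The main fitting function of the package.  For each query it seeds
#' candidate hits (built-in translated k-mer seeder, or externally supplied
#' alignments via `hits`), filters them by the score/identity/coverage
#' thresholds, refines each hit into an exact gene structure
#' (intron borders, split codons, frameshifts, in-frame stops), assembles
#' partial hits from fragmented contigs, and selects the final result(s).
#'
#' @param queries protein sequences: named character vector or
#'   `AAStringSet`.
#' @param genome genome contigs: named character vector, `DNAStringSet`,
#'   or path to a FASTA file.
#' @param params a [pg_params()] object.
#' @param hits optional externally seeded hits (e.g. from [read_psl()]);
#'   a list of hits as produced by [seed_hits()].  When supplied the
#'   built-in seeder is skipped.
#' @return An object of class `pg_result`: per-query lists of
#'   `gene_structure` results with diagnostics, plus the parameters used.
#' @examples
#' fx <- generate_gene(protein_length = 40, n_introns = 1, seed = 7)
#' res <- map_protein(stats::setNames(fx$protein, "demo"), fx$genome)
#' res
#' @export
map_protein <- function(queries, genome, params = pg_params(),
                        hits = NULL) {
  stopifnot(inherits(params, "pg_params"))
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_fasta(genome, type = "DNA")
  queries <- as_aa_set(queries)
  genome <- as_dna_set(genome)
  if (anyDuplicated(names(genome)))
    stop("duplicate contig names in genome")
  oriented <- list(
    "+" = lapply(seq_along(genome), function(i) as.character(genome[[i]])),
    "-" = lapply(seq_along(genome), function(i)
      as.character(Biostrings::reverseComplement(genome[[i]]))))
  names(oriented[["+"]]) <- names(oriented[["-"]]) <- names(genome)
  out <- list()
  for (qi in seq_along(queries)) {
    qid <- names(queries)[qi]
    qseq <- as.character(queries[[qi]])
    qlen <- nchar(qseq)
    qhits <- if (is.null(hits))
      seed_hits(qseq, genome, tilesize = params$tilesize,
                table_id = params$transtable, query_id = qid)
    else Filter(function(h) identical(h$query_id, qid), hits)
    qhits <- Filter(function(h) h$target_id %in% names(genome), qhits)
    if (!is.null(hits))
      qhits <- lapply(qhits, function(h)
        recount_blocks(h, qseq, oriented[[h$strand]][[h$target_id]],
                       params$transtable))
    qhits <- filter_hits(qhits, qlen,
                         min_score = params$min_score,
                         min_identity = params$min_identity,
                         max_mismatch = params$max_mismatch,
                         min_coverage = params$min_coverage)
    parts <- lapply(qhits, function(h)
      refine_hit(h, qseq, oriented[[h$strand]][[h$target_id]], params,
                 contig_length = nchar(oriented[[h$strand]][[h$target_id]])))
    candidates <- assemble_structures(parts, qlen, params,
                                      query = qseq, oriented = oriented)
    results <- select_results(candidates, params)
    out[[qid]] <- list(query_id = qid, query_length = qlen,
                       results = results,
                       diagnostic = attr(results, "diagnostic"))
  }
  structure(list(queries = out, params = params,
                 contig_lengths = stats::setNames(Biostrings::width(genome),
                                                  names(genome))),
            class = "pg_result")
}

#' @export
print.pg_result <- function(x, ...) {
  cat(sprintf("Protein-to-genome mapping: %d quer%s\n", length(x$queries),
              if (length(x$queries) == 1L) "y" else "ies"))
  for (q in x$queries) {
    cat(sprintf("\n$%s (%d aa): %d result(s)\n", q$query_id,
                q$query_length, length(q$results)))
    if (length(q$results) == 0L && !is.null(q$diagnostic))
      cat(sprintf("  [%s]\n", q$diagnostic))
    for (g in q$results) print(g)
  }
  invisible(x)
}

#' @export
summary.pg_result <- function(object, ...) {
  rows <- NULL
  for (q in object$queries) {
    for (g in q$results) {
      rows <- rbind(rows, data.frame(
        query = q$query_id,
        targets = paste(g$targets, collapse = ","),
        strand = paste(unique(vapply(g$parts, function(p) p$strand, "")),
                       collapse = ","),
        exons = sum(vapply(g$parts, function(p) nrow(p$exons), 0L)),
        introns = sum(vapply(g$parts, function(p) nrow(p$introns), 0L)),
        matches = g$stats$matches, mismatches = g$stats$mismatches,
        score = g$stats$score, identity = g$stats$identity,
        coverage = g$stats$coverage, stringsAsFactors = FALSE))
    }
    if (length(q$results) == 0L)
      rows <- rbind(rows, data.frame(
        query = q$query_id, targets = NA_character_, strand = NA_character_,
        exons = 0L, introns = 0L, matches = 0, mismatches = 0,
        score = 0, identity = 0, coverage = 0, stringsAsFactors = FALSE))
  }
  structure(list(table = rows), class = "summary.pg_result")
}

#' @export
print.summary.pg_result <- function(x, ...) {
  cat("Mapping summary\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Sketch mapped gene structures
#'
#' Draws, for each result, the exons (boxes) and introns (kinked lines)
#' along the oriented target coordinate, one row per result.
#'
#' @param x a `pg_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pg_result <- function(x, ...) {
  rows <- list()
  for (q in x$queries) for (g in q$results) for (p in g$parts)
    rows[[length(rows) + 1L]] <-
      list(label = sprintf("%s @ %s(%s)", q$query_id, p$contig, p$strand),
           part = p)
  if (length(rows) == 0L) {
    graphics::plot.new()
    graphics::text(0.5, 0.5, "no results")
    return(invisible(x))
  }
  n <- length(rows)
  xmax <- max(vapply(rows, function(r)
    max(r$part$exons$tend, r$part$introns$tend, 1L), numeric(1)))
  xmin <- min(vapply(rows, function(r)
    min(r$part$exons$tstart, r$part$introns$tstart, xmax), numeric(1)))
  graphics::plot(NA, xlim = c(xmin, xmax), ylim = c(0.5, n + 0.5),
                 xlab = "target position (oriented, bp)", ylab = "",
                 yaxt = "n", ...)
  graphics::axis(2, at = seq_len(n),
                 labels = vapply(rows, function(r) r$label, ""),
                 las = 1, cex.axis = 0.7)
  for (k in seq_len(n)) {
    p <- rows[[k]]$part
    for (e in seq_len(nrow(p$exons)))
      graphics::rect(p$exons$tstart[e], k - 0.25, p$exons$tend[e], k + 0.25,
                     col = "steelblue", border = "black")
    for (i in seq_len(nrow(p$introns))) {
      mid <- (p$introns$tstart[i] + p$introns$tend[i]) / 2
      graphics::lines(c(p$introns$tstart[i], mid, p$introns$tend[i]),
                      c(k, k + 0.35, k),
                      col = if (p$introns$status[i] == "intron") "gray30"
                            else "firebrick")
    }
  }
  invisible(x)
}
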