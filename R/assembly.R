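# Cross-contig assembly: compose partial hits from different contigs into
# one gene structure when the query spans are collinear and the implied
# intron at each contig junction is plausibly short.

part_qspan <- function(p) {
  if (nrow(p$exons) == 0L) return(c(0L, 0L))
  c(min(p$exons$qstart, na.rm = TRUE), max(p$exons$qend, na.rm = TRUE))
}

part_tspan <- function(p) {
  if (nrow(p$exons) == 0L) return(c(0L, 0L))
  c(min(p$exons$tstart), max(p$exons$tend))
}

# nucleotides from the last mapped position to the contig end, and from the
# contig start to the first mapped position, in the strand-oriented frame
part_tail_len <- function(p) p$contig_length - part_tspan(p)[2L]
part_head_len <- function(p) part_tspan(p)[1L]

#' Combined statistics of a (possibly composed) gene structure
#'
#' Sums matches and mismatches over the parts; `dna_coverage` is
#' `100 * 3 * mapped residues / total genomic span` where the span includes
#' the implied introns at contig junctions — a composition stretched over
#' implausibly long implied introns scores a low DNA coverage.
#'
#' @param parts list of `pg_part` objects.
#' @param joins data frame of contig junctions with an `implied_len`
#'   column (may have zero rows).
#' @param query_length full query length in residues.
#' @return list of combined statistics.
#' @export
combined_stats <- function(parts, joins, query_length) {
  ma <- sum(vapply(parts, function(p) p$stats$matches, numeric(1)))
  mi <- sum(vapply(parts, function(p) p$stats$mismatches, numeric(1)))
  span <- sum(vapply(parts, function(p) diff(part_tspan(p)), numeric(1))) +
    if (nrow(joins)) sum(joins$implied_len) else 0
  list(matches = ma, mismatches = mi,
       score = max(0, (ma - mi) / query_length),
       identity = if (ma + mi > 0) ma / (ma + mi) else 0,
       coverage = (ma + mi) / query_length,
       dna_coverage = if (span > 0) 100 * 3 * (ma + mi) / span else 0)
}

new_gene_structure <- function(parts, query_length, params) {
  joins <- data.frame(from_contig = character(0), to_contig = character(0),
                      implied_len = numeric(0), stringsAsFactors = FALSE)
  if (length(parts) > 1L) {
    for (k in seq_len(length(parts) - 1L)) {
      a <- parts[[k]]; b <- parts[[k + 1L]]
      joins <- rbind(joins, data.frame(
        from_contig = a$contig, to_contig = b$contig,
        implied_len = part_tail_len(a) + part_head_len(b),
        stringsAsFactors = FALSE))
    }
  }
  structure(list(query_id = parts[[1L]]$query_id,
                 query_length = query_length,
                 parts = parts, joins = joins,
                 targets = vapply(parts, function(p) p$contig, ""),
                 stats = combined_stats(parts, joins, query_length)),
            class = "gene_structure")
}

#' @export
print.gene_structure <- function(x, ...) {
  s <- x$stats
  cat(sprintf("Gene structure for %s on %s\n", x$query_id,
              paste(sprintf("%s(%s)", x$targets,
                            vapply(x$parts, function(p) p$strand, "")),
                    collapse = " + ")))
  cat(sprintf("  %d exon(s), %d intron(s) across %d part(s)\n",
              sum(vapply(x$parts, function(p) nrow(p$exons), 0L)),
              sum(vapply(x$parts, function(p) nrow(p$introns), 0L)),
              length(x$parts)))
  cat(sprintf("  matches %d, mismatches %d, score %.3f, identity %.3f, coverage %.3f\n",
              s$matches, s$mismatches, s$score, s$identity, s$coverage))
  invisible(x)
}

# hits whose blocks extended past a contig break (chance matches in the
# intron remnant) overlap the next contig's part by a few query residues;
# the chain tolerates this and the overlap is trimmed at composition time
PART_CHAIN_MAX_OVERLAP <- 10L

# best collinear chain of parts maximizing matches - mismatches, under the
# junction constraints; returns indices into `parts` in query order
chain_parts <- function(parts, max_assemble_size) {
  n <- length(parts)
  qs <- t(vapply(parts, part_qspan, integer(2)))
  ord <- order(qs[, 1L], qs[, 2L])
  val <- vapply(parts, function(p) p$stats$matches - p$stats$mismatches,
                numeric(1))[ord]
  score <- val
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    a <- ord[i]
    for (j in seq_len(i - 1L)) {
      b <- ord[j]
      ov <- qs[b, 2L] - qs[a, 1L]
      if (ov > PART_CHAIN_MAX_OVERLAP) next     # query overlap too large
      if (ov > 0L && qs[a, 2L] - qs[a, 1L] <= ov) next
      if (parts[[b]]$contig == parts[[a]]$contig) next
      if (part_tail_len(parts[[b]]) + part_head_len(parts[[a]]) >
          max_assemble_size) next
      gain <- val[i] - max(0L, ov)
      if (score[j] + gain > score[i]) {
        score[i] <- score[j] + gain
        prev[i] <- j
      }
    }
  }
  i <- which.max(score)
  chain <- integer(0)
  while (!is.na(i)) { chain <- c(i, chain); i <- prev[i] }
  ord[chain]
}

# restrict a part to query residues in [lo, hi): residue-carrying rows
# outside the window are dropped (query gaps are clipped), then dangling
# zero-residue rows at either end are removed and the part re-derived
trim_part_query <- function(p, lo, hi) {
  rows <- p$segments
  keep <- rep(TRUE, nrow(rows))
  for (k in seq_len(nrow(rows))) {
    if (rows$qlen[k] == 0L) next
    if (rows$qstart[k] >= lo && rows$qend[k] <= hi) next
    if (rows$type[k] == "qgap") {
      rows$qstart[k] <- max(rows$qstart[k], lo)
      rows$qend[k] <- min(rows$qend[k], hi)
      rows$qlen[k] <- rows$qend[k] - rows$qstart[k]
      if (rows$qlen[k] <= 0L) keep[k] <- FALSE
    } else keep[k] <- FALSE
  }
  rows <- rows[keep, , drop = FALSE]
  while (nrow(rows) > 0L && rows$qlen[1L] == 0L)
    rows <- rows[-1L, , drop = FALSE]
  while (nrow(rows) > 0L &&
         (rows$qlen[nrow(rows)] == 0L ||
          rows$type[nrow(rows)] == "codon5"))
    rows <- rows[-nrow(rows), , drop = FALSE]
  derive_part(rows, p$query_id, p$query_length, p$contig, p$strand,
              p$contig_length)
}

part_matches_below <- function(p, r) {
  s <- p$segments
  sum(s$match[s$type %in% c("codon", "codon5") & s$qend <= r], na.rm = TRUE)
}

part_matches_from <- function(p, r) {
  s <- p$segments
  sum(s$match[s$type %in% c("codon", "codon5") & s$qstart >= r], na.rm = TRUE)
}

# clip every part's unmatched-query rows to the query range it is
# responsible for in the chain: residues before a part's first exon back to
# the previous part's last exon (the whole query start for the first part),
# residues after its last exon are left to the next part.  Without this a
# part-local terminal gap would re-report residues that another contig maps.
clip_part_ranges <- function(parts, query_length) {
  if (length(parts) < 2L) return(parts)
  ends <- vapply(parts, function(p) part_qspan(p)[2L], integer(1))
  for (k in seq_along(parts)) {
    lo <- if (k == 1L) 0L else ends[k - 1L]
    hi <- if (k == length(parts)) query_length else
      part_qspan(parts[[k + 1L]])[1L]
    parts[[k]] <- clip_qgap_rows(parts[[k]], lo, hi)
  }
  parts
}

# restrict only the unmatched-query rows of a part to [lo, hi)
clip_qgap_rows <- function(p, lo, hi) {
  rows <- p$segments
  changed <- FALSE
  for (i in which(rows$type == "qgap")) {
    ns <- max(rows$qstart[i], lo); ne <- min(rows$qend[i], hi)
    if (ns != rows$qstart[i] || ne != rows$qend[i]) {
      rows$qstart[i] <- ns; rows$qend[i] <- max(ns, ne)
      rows$qlen[i] <- rows$qend[i] - rows$qstart[i]
      changed <- TRUE
    }
  }
  if (!changed) return(p)
  rows <- rows[!(rows$type == "qgap" & rows$qlen == 0L), , drop = FALSE]
  derive_part(rows, p$query_id, p$query_length, p$contig, p$strand,
              p$contig_length)
}

# remove query residue q from any unmatched-query row covering it
drop_qgap_residue <- function(rows, q) {
  for (i in which(rows$type == "qgap")) {
    if (rows$qstart[i] <= q && rows$qend[i] > q) {
      if (rows$qstart[i] == q) rows$qstart[i] <- q + 1L else
        rows$qend[i] <- q
      rows$qlen[i] <- max(0L, rows$qend[i] - rows$qstart[i])
    }
  }
  rows[!(rows$type == "qgap" & rows$qlen == 0L), , drop = FALSE]
}

# complete codons split across a contig junction: when exactly one query
# residue is unassigned between two chained parts, try reading its codon as
# the first p nucleotides following the upstream part's last exon plus the
# last 3 - p nucleotides preceding the downstream part's first exon
bridge_split_codons <- function(parts, query, oriented, params) {
  if (length(parts) < 2L || is.null(query) || is.null(oriented))
    return(parts)
  tid <- params$transtable
  for (k in seq_len(length(parts) - 1L)) {
    a <- parts[[k]]; b <- parts[[k + 1L]]
    qa <- part_qspan(a)[2L]; qb <- part_qspan(b)[1L]
    if (qb != qa + 1L) next
    sa <- oriented[[a$strand]][[a$contig]]
    sb <- oriented[[b$strand]][[b$contig]]
    if (is.null(sa) || is.null(sb)) next
    ta <- part_tspan(a)[2L]; tb <- part_tspan(b)[1L]
    res <- substr(query, qa + 1L, qa + 1L)
    for (p in 1:2) {
      if (ta + p > nchar(sa) || tb - (3L - p) < 0L) next
      cod <- paste0(substr(sa, ta + 1L, ta + p),
                    substr(sb, tb - (3L - p) + 1L, tb))
      if (translate_codon(cod, tid) != res) next
      a5 <- seg_row("codon5", a$contig, ta, ta + p, qa, qa + 1L, 1L,
                    match = TRUE, stop = FALSE)
      b3 <- seg_row("codon3", b$contig, tb - (3L - p), tb, qa, qa + 1L, 0L)
      parts[[k]] <- derive_part(rbind(drop_qgap_residue(a$segments, qa), a5),
                                a$query_id, a$query_length, a$contig,
                                a$strand, a$contig_length)
      parts[[k + 1L]] <- derive_part(rbind(b3,
                                           drop_qgap_residue(b$segments, qa)),
                                     b$query_id, b$query_length, b$contig,
                                     b$strand, b$contig_length)
      break
    }
  }
  parts
}

# make consecutive chained parts disjoint in the query: split each overlap
# at the residue boundary that keeps the most matches overall
resolve_part_overlaps <- function(parts) {
  if (length(parts) < 2L) return(parts)
  for (k in seq_len(length(parts) - 1L)) {
    a <- parts[[k]]; b <- parts[[k + 1L]]
    ov_lo <- part_qspan(b)[1L]; ov_hi <- part_qspan(a)[2L]
    if (ov_hi <= ov_lo) next
    cand <- ov_lo:ov_hi
    kept <- vapply(cand, function(r)
      part_matches_below(a, r) + part_matches_from(b, r), numeric(1))
    r <- cand[which.max(kept)]
    if (ov_hi > r) parts[[k]] <- trim_part_query(a, 0L, r)
    if (ov_lo < r) parts[[k + 1L]] <- trim_part_query(b, r, b$query_length)
  }
  parts
}

#' Assemble refined hits into candidate gene structures
#'
#' Composes partial hits from *different* contigs whose query spans are
#' collinear, joining two parts only when the implied intron at the contig
#' junction — the unmapped tail of the first contig plus the unmapped head
#' of the second — is at most `max_assemble_size` nucleotides.  With
#' `single_target_hits` no composition is attempted and every part stands
#' alone.  Compositions whose DNA coverage falls below `min_dna_coverage`
#' percent are discarded in favour of their single best part.
#'
#' @param parts list of `pg_part` objects (refined hits for one query).
#' @param query_length full query length in residues.
#' @param params a [pg_params()] object.
#' @param query full query sequence (optional; enables completion of
#'   codons split across contig junctions).
#' @param oriented strand-oriented target sequences, a list with elements
#'   `"+"` and `"-"` each mapping contig name to sequence (optional, used
#'   with `query`).
#' @return list of candidate `gene_structure` objects.
#' @export
assemble_structures <- function(parts, query_length, params = pg_params(),
                                query = NULL, oriented = NULL) {
  if (length(parts) == 0L) return(list())
  if (params$single_target_hits)
    return(lapply(parts, function(p)
      new_gene_structure(list(p), query_length, params)))
  candidates <- list()
  remaining <- parts
  repeat {
    idx <- chain_parts(remaining, params$max_assemble_size)
    chained <- resolve_part_overlaps(remaining[idx])
    chained <- clip_part_ranges(chained, query_length)
    chained <- bridge_split_codons(chained, query, oriented, params)
    gs <- new_gene_structure(chained, query_length, params)
    if (length(idx) > 1L && params$min_dna_coverage > 0 &&
        gs$stats$dna_coverage < params$min_dna_coverage) {
      # composition too stretched: fall back to its single best part
      best <- idx[which.max(vapply(remaining[idx], function(p)
        p$stats$matches - p$stats$mismatches, numeric(1)))]
      gs <- new_gene_structure(remaining[best], query_length, params)
      idx <- best
    }
    candidates[[length(candidates) + 1L]] <- gs
    remaining <- remaining[-idx]
    if (!params$multiple_results || length(remaining) == 0L) break
  }
  candidates
}

#' Select the final results among assembled candidates
#'
#' Ranks candidates by score (ties broken by identity, then by target names
#' and leftmost coordinate for determinism).  With `multiple_results` all
#' candidates passing the score and identity thresholds are returned;
#' otherwise only the single best candidate is, provided it passes.  An
#' empty list carries a `diagnostic` attribute explaining the rejection.
#'
#' @param candidates list of `gene_structure` objects.
#' @param params a [pg_params()] object.
#' @return list of `gene_structure` objects, possibly empty with a
#'   `diagnostic` attribute.
#' @export
select_results <- function(candidates, params = pg_params()) {
  if (length(candidates) == 0L) {
    out <- list()
    attr(out, "diagnostic") <- "no hits found"
    return(out)
  }
  key <- vapply(candidates, function(g)
    sprintf("%012.6f|%012.6f|%s|%012d",
            g$stats$score, g$stats$identity,
            paste(g$targets, collapse = ","),
            part_tspan(g$parts[[1L]])[1L]),
    "")
  ord <- order(key, decreasing = TRUE)
  candidates <- candidates[ord]
  pass <- vapply(candidates, function(g)
    g$stats$score >= params$min_score &&
      g$stats$identity >= params$min_identity &&
      g$stats$mismatches <= params$max_mismatch, logical(1))
  out <- if (params$multiple_results) candidates[pass] else
    candidates[seq_len(1L)][pass[1L]]
  if (length(out) == 0L)
    attr(out, "diagnostic") <-
      sprintf("best candidate rejected: score %.3f (min %.3f), identity %.3f (min %.3f)",
              candidates[[1L]]$stats$score, params$min_score,
              candidates[[1L]]$stats$identity, params$min_identity)
  out
}
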