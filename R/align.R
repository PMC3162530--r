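# nucleotide integer coding shared with the C++ core: A=0 C=1 G=2 T=3, any
# other letter (N, ambiguity codes) = 4
nt_codes <- function(x) {
  if (nchar(x) == 0L) return(integer(0))
  v <- match(strsplit(toupper(x), "")[[1]], c("A", "C", "G", "T"))
  v[is.na(v)] <- 5L
  v - 1L
}

aa_codes <- function(x) {
  if (nchar(x) == 0L) return(integer(0))
  utf8ToInt(toupper(x))
}

# 125-entry codon translation table (base-5 index n1*25 + n2*5 + n3) holding
# the integer character code of the residue; '*' = stop, 'X' = unknown
codon_int_table <- function(table_id = 1) {
  key <- paste0("int_", table_id)
  if (!is.null(codon_table_cache[[key]])) return(codon_table_cache[[key]])
  gc <- codon_lookup(table_id)
  nts <- c("A", "C", "G", "T", "N")
  tab <- integer(125)
  for (a in 1:5) for (b in 1:5) for (c in 1:5) {
    idx <- (a - 1L) * 25L + (b - 1L) * 5L + (c - 1L) + 1L
    if (a == 5L || b == 5L || c == 5L) tab[idx] <- utf8ToInt("X")
    else tab[idx] <- utf8ToInt(unname(gc[paste0(nts[a], nts[b], nts[c])]))
  }
  codon_table_cache[[key]] <- tab
  tab
}

splice_matrix <- function(table) {
  nts <- c("A", "C", "G", "T", "N")
  m <- matrix(0, 5, 5)
  for (a in 1:5) for (b in 1:5)
    m[a, b] <- dinuc_penalty(table, paste0(nts[a], nts[b]))
  m
}

#' Optimal spliced alignment of a protein fragment to a DNA fragment
#'
#' Computes the minimum-penalty global parse of a protein query fragment
#' against a genomic target fragment under a [pg_penalties()] scheme.  The
#' parse may contain codon matches/mismatches, insertions (unmatched query
#' residues), gaps (extra target codons), frameshifts (1-2 stray
#' nucleotides) and introns, including introns that split a codon after its
#' first or second nucleotide.  Implemented as a dynamic programme whose
#' intron moves are closed through nine precomputed running-minimum
#' matrices (one for in-frame introns, four indexed by the codon nucleotide
#' before a phase-1 intron, four by the hypothesised nucleotide after a
#' phase-2 intron), making each cell O(1).
#'
#' Ties are broken deterministically: codon match over intron over gap over
#' insertion over frameshift, and the leftmost donor among equal-cost
#' intron placements.
#'
#' @param query protein fragment (character, possibly empty).
#' @param target DNA fragment (character, possibly empty; `N` allowed).
#' @param scheme a [pg_penalties()] scheme.
#' @param table_id NCBI translation table identifier.
#' @param keep_matrix keep the DP matrix in the result (for diagnostics).
#' @return An object of class `pg_parse`: list with `cost`, `segments` (a
#'   data frame of [parse_segment()] rows), `query`, `target`.
#' @examples
#' p <- align_spliced("MK", "ATGAAA")
#' p$cost            # 0: two exact codons
#' @export
align_spliced <- function(query, target, scheme = pg_penalties(),
                          table_id = 1, keep_matrix = FALSE) {
  query <- toupper(query); target <- toupper(target)
  res <- spliced_nw_cpp(nt_codes(target), aa_codes(query),
                        codon_int_table(table_id),
                        splice_matrix(scheme$donor),
                        splice_matrix(scheme$acceptor),
                        scheme$mismatch, scheme$insertion, scheme$gap,
                        scheme$frameshift, scheme$intron,
                        scheme$min_intron_len, keep_matrix)
  segs <- vector("list", length(res$move))
  for (k in seq_along(res$move)) {
    i0 <- res$ifrom[k]; i1 <- res$ito[k]
    j0 <- res$jfrom[k]; j1 <- res$jto[k]
    qf <- if (j1 > j0) substr(query, j1, j1) else ""
    tf <- if (i1 > i0) substr(target, i0 + 1L, i1) else ""
    segs[[k]] <- switch(as.character(res$move[k]),
      "1" = parse_segment("codon_match", qf, tf),
      "2" = parse_segment("intron", "", tf),
      "3" = parse_segment("split_codon_intron", qf, tf,
                          intron = substr(target, i0 + 2L, i1 - 2L),
                          split = 1L),
      "4" = parse_segment("split_codon_intron", qf, tf,
                          intron = substr(target, i0 + 3L, i1 - 1L),
                          split = 2L),
      "5" = parse_segment("gap", "", tf),
      "6" = parse_segment("insertion", qf, ""),
      parse_segment("frameshift", qf, tf))
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    parse_segment("gap")[0, ]
  out <- list(cost = res$cost, segments = segments,
              query = query, target = target)
  if (keep_matrix) out$matrix <- res$matrix
  class(out) <- "pg_parse"
  out
}

#' @export
print.pg_parse <- function(x, ...) {
  cat(sprintf("Spliced alignment parse: |query| = %d aa, |target| = %d nt, cost = %g\n",
              nchar(x$query), nchar(x$target), x$cost))
  if (nrow(x$segments)) {
    tab <- table(x$segments$category)
    cat("  segments:", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  }
  invisible(x)
}

#' Exhaustive minimal parse cost (test oracle)
#'
#' Computes the minimum parse cost by directly enumerating, per DP cell,
#' every admissible last segment straight from the penalty definitions —
#' including every intron length and both codon-split positions — without
#' the running-minimum intron variants used by [align_spliced()].  Feasible
#' only for tiny inputs; used to validate the production alignment.
#'
#' @param query protein fragment, at most 4 residues.
#' @param target DNA fragment, at most 60 nucleotides.
#' @param scheme a [pg_penalties()] scheme.
#' @param table_id NCBI translation table identifier.
#' @return the minimal parse cost (numeric scalar).
#' @export
enumerate_parses <- function(query, target, scheme = pg_penalties(),
                             table_id = 1) {
  query <- toupper(query); target <- toupper(target)
  m <- nchar(query); n <- nchar(target)
  if (m > 4L || n > 60L)
    stop("enumerate_parses is an exhaustive oracle; query <= 4 aa and target <= 60 nt only")
  q <- strsplit(query, "")[[1]]
  t <- strsplit(target, "")[[1]]
  lmin <- scheme$min_intron_len
  tsub <- function(a, b) paste(t[a:b], collapse = "")
  pm <- function(res, codon) match_penalty(res, codon, scheme, table_id)
  B <- matrix(Inf, n + 1L, m + 1L)
  B[1L, 1L] <- 0
  for (i in 0:n) for (j in 0:m) {
    if (i == 0L && j == 0L) next
    best <- Inf
    if (i >= 3L && j >= 1L)
      best <- min(best, B[i - 2L, j] + pm(q[j], tsub(i - 2L, i)))
    if (j >= 1L) best <- min(best, B[i + 1L, j] + scheme$insertion)
    if (i >= 3L) best <- min(best, B[i - 2L, j + 1L] + scheme$gap)
    for (w in 1:2) {             # frameshifts, with or without a residue
      if (i >= w) {
        best <- min(best, B[i - w + 1L, j + 1L] + scheme$frameshift)
        if (j >= 1L)
          best <- min(best, B[i - w + 1L, j] + scheme$frameshift)
      }
    }
    if (i >= lmin) {             # in-frame introns of every length
      for (L in lmin:i) {
        ip <- intron_penalty(tsub(i - L + 1L, i), scheme)
        best <- min(best, B[i - L + 1L, j + 1L] + ip)
      }
    }
    if (j >= 1L && i >= lmin + 3L) {   # codon-splitting introns
      for (L in lmin:(i - 3L)) {
        pred <- B[i - 3L - L + 1L, j]
        if (!is.finite(pred)) next
        # split after the first codon nucleotide
        ip1 <- intron_penalty(tsub(i - 1L - L, i - 2L), scheme)
        best <- min(best, pred + ip1 +
                      pm(q[j], paste0(t[i - 2L - L], t[i - 1L], t[i])))
        # split after the second codon nucleotide
        ip2 <- intron_penalty(tsub(i - L, i - 1L), scheme)
        best <- min(best, pred + ip2 +
                      pm(q[j], paste0(t[i - 2L - L], t[i - 1L - L], t[i])))
      }
    }
    B[i + 1L, j + 1L] <- best
  }
  B[n + 1L, m + 1L]
}
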