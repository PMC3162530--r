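# Hit refinement: turn a chained seed hit into a full gene structure.
#
# Internally a hit is represented as an ordered *segment stream*, one row
# per elementary piece of the alignment, with 0-based half-open coordinates
# on the strand-oriented target:
#   codon   residue vs codon (qlen 1, tlen 3)
#   codon5  first 1-2 nt of a codon split by an intron; carries the residue
#   codon3  remaining nt of a split codon after the intron (qlen 0)
#   gapnt   extra target codon with no residue (exonic insertion)
#   ins     query residue with no target counterpart
#   fs      1-2 stray target nucleotides (frameshift)
#   intron  intron with donor/acceptor dinucleotides and phase
#   qgap    unresolved unmatched query residues
# Exons are maximal runs not interrupted by intron/qgap rows.

seg_row <- function(type, contig, tstart, tend, qstart, qend, qlen,
                    match = NA, stop = NA, donor = NA_character_,
                    acceptor = NA_character_, phase = NA_integer_) {
  data.frame(type = type, contig = contig,
             tstart = as.integer(tstart), tend = as.integer(tend),
             qstart = as.integer(qstart), qend = as.integer(qend),
             qlen = as.integer(qlen), match = match, stop = stop,
             donor = donor, acceptor = acceptor,
             phase = as.integer(phase), status = NA_character_,
             stringsAsFactors = FALSE)
}

empty_stream <- function() seg_row("codon", "x", 0, 0, 0, 0, 0)[0, ]

# rows for `count` consecutive codons starting at tstart/qstart
codon_rows <- function(contig, tstart, qstart, count, query, tseq,
                       table_id = 1) {
  if (count <= 0L) return(empty_stream())
  off <- 3L * (seq_len(count) - 1L)
  codons <- substring(tseq, tstart + off + 1L, tstart + off + 3L)
  aa <- translate_codon(codons, table_id)
  res <- substring(query, qstart + seq_len(count), qstart + seq_len(count))
  seg_row("codon", contig, tstart + off, tstart + off + 3L,
          qstart + seq_len(count) - 1L, qstart + seq_len(count), 1L,
          match = aa == res & aa != "*" & aa != "X", stop = aa == "*")
}

#' Classify a target region left between mapped blocks
#'
#' For a target stretch with no unmatched query on either side: short
#' stretches whose length is a multiple of three and whose translation is
#' free of in-frame stop codons are insertions rather than true introns and
#' are merged into the surrounding exon; anything at least
#' `min_intron_len` long is an intron candidate; the remainder (out of
#' frame or stop-containing, but too short for an intron) is resolved into
#' the cheapest combination of gap/frameshift segments by the spliced
#' aligner.
#'
#' @param region nucleotide string between two mapped blocks.
#' @param scheme a [pg_penalties()] scheme.
#' @param table_id NCBI translation table identifier.
#' @return `"merge_into_exon"` or `"intron_candidate"`.
#' @export
classify_unmatched_target <- function(region, scheme = pg_penalties(),
                                      table_id = 1) {
  len <- nchar(region)
  if (len < scheme$min_intron_len && len %% 3L == 0L) {
    aa <- translate_frame(region, table_id)
    if (!grepl("*", aa, fixed = TRUE)) return("merge_into_exon")
  }
  "intron_candidate"
}

intron_row <- function(contig, tstart, tend, tseq, phase = 0L) {
  seg_row("intron", contig, tstart, tend, NA, NA, 0L,
          donor = substr(tseq, tstart + 1L, tstart + 2L),
          acceptor = substr(tseq, tend - 1L, tend), phase = phase)
}

# convert an align_spliced parse into stream rows, with flags recomputed
parse_to_stream <- function(parse, contig, toff, qoff, query, tseq,
                            params) {
  tid <- params$transtable
  rows <- list(); tc <- toff; qc <- qoff
  segs <- parse$segments
  for (k in seq_len(nrow(segs))) {
    s <- segs[k, ]
    tl <- nchar(s$target); ql <- nchar(s$query)
    rows[[k]] <- switch(s$category,
      codon_match = {
        aa <- translate_codon(s$target, tid)
        seg_row("codon", contig, tc, tc + 3L, qc, qc + 1L, 1L,
                match = aa == s$query & aa != "*" & aa != "X",
                stop = aa == "*")
      },
      insertion = seg_row("ins", contig, tc, tc, qc, qc + 1L, 1L),
      gap = {
        aa <- translate_codon(s$target, tid)
        seg_row("gapnt", contig, tc, tc + 3L, qc, qc, 0L, stop = aa == "*")
      },
      frameshift = seg_row("fs", contig, tc, tc + tl, qc, qc + ql, ql),
      intron = intron_row(contig, tc, tc + tl, tseq, phase = 0L),
      split_codon_intron = {
        p <- s$split; il <- nchar(s$intron)
        codon <- paste0(substr(s$target, 1L, p),
                        substr(s$target, p + il + 1L, tl))
        aa <- translate_codon(codon, tid)
        ok <- aa == s$query & aa != "*" & aa != "X"
        rbind(
          seg_row("codon5", contig, tc, tc + p, qc, qc + 1L, 1L,
                  match = ok, stop = aa == "*"),
          intron_row(contig, tc + p, tc + p + il, tseq, phase = p),
          seg_row("codon3", contig, tc + p + il, tc + tl, qc, qc + 1L, 0L))
      })
    tc <- tc + tl; qc <- qc + ql
  }
  if (length(rows)) do.call(rbind, rows) else empty_stream()
}

# is the intron row's border pair accepted (clean) under the scheme?
intron_accepted <- function(row, scheme)
  classify_intron(row$donor, row$acceptor, scheme) == "intron"

# enforce the short-exon identity rule on the rows of one gap closure:
# internal exons of 1-4 residues are kept only if mismatch-free, indel-free
# and flanked by accepted splice sites; otherwise the exon and its flanking
# introns are collapsed into one intron and the residues become a gap
enforce_short_exon_rule <- function(rows, tseq, params) {
  scheme <- params$penalties
  repeat {
    n <- nrow(rows)
    intr <- which(rows$type == "intron")
    if (length(intr) < 2L) return(rows)
    rejected <- FALSE
    for (z in seq_len(length(intr) - 1L)) {
      a <- intr[z]; b <- intr[z + 1L]
      if (b - a < 2L) next                    # no exon between
      run <- rows[(a + 1L):(b - 1L), , drop = FALSE]
      if (any(run$type %in% c("intron", "qgap"))) next
      n_res <- sum(run$qlen[run$type %in% c("codon", "codon5")]) +
        as.integer(run$type[1L] == "codon3")
      if (n_res < 1L || n_res > 4L) next
      clean <- !any(run$type %in% c("gapnt", "fs", "ins")) &&
        all(run$match[run$type %in% c("codon", "codon5")]) &&
        intron_accepted(rows[a, ], scheme) &&
        intron_accepted(rows[b, ], scheme)
      # a split codon shared with a neighbouring exon must match too
      if (clean && run$type[1L] == "codon3" && a >= 2L &&
          rows$type[a - 1L] == "codon5")
        clean <- isTRUE(rows$match[a - 1L])
      if (clean) next
      # reject: collapse [flanking codon5] intron exon intron [codon3]
      lo <- if (!is.na(rows$phase[a]) && rows$phase[a] > 0L && a >= 2L &&
                rows$type[a - 1L] == "codon5") a - 1L else a
      hi <- if (!is.na(rows$phase[b]) && rows$phase[b] > 0L && b < n &&
                rows$type[b + 1L] == "codon3") b + 1L else b
      dem <- rows[lo:hi, , drop = FALSE]
      qs <- suppressWarnings(min(dem$qstart[dem$qlen > 0L |
                                              dem$type == "codon5"], na.rm = TRUE))
      qe <- suppressWarnings(max(dem$qend[dem$qlen > 0L |
                                            dem$type == "codon5"], na.rm = TRUE))
      ts <- min(dem$tstart, na.rm = TRUE)
      te <- max(dem$tend, na.rm = TRUE)
      merged <- intron_row(dem$contig[1L], ts, te, tseq, phase = 0L)
      repl <- if (is.finite(qs) && qe > qs)
        rbind(seg_row("qgap", dem$contig[1L], ts, ts, qs, qe, qe - qs),
              merged) else merged
      rows <- rbind(if (lo > 1L) rows[1L:(lo - 1L), ] else NULL,
                    repl,
                    if (hi < n) rows[(hi + 1L):n, ] else NULL)
      rejected <- TRUE
      break
    }
    if (!rejected) return(rows)
  }
}

# The flip side of the short-exon identity rule: a 1-4 residue internal
# exon that matches exactly, bordered by accepted splice sites on both
# flanks, is accepted even where the penalty optimum would merge it into
# one long intron (two intron penalties usually exceed one intron penalty
# plus a mismatch).  Searches the closure region for a parse
#   [codons] intron1 [short exon] intron2 [codons]
# spelling the query fragment exactly; split codons at either intron are
# allowed.  Returns segment rows, or NULL if no such parse exists.
recover_short_exon <- function(contig, qstart, qend, tstart, tend, query,
                               tseq, params) {
  L <- qend - qstart
  n <- tend - tstart
  lmin <- params$penalties$min_intron_len
  if (L < 1L || n < 3L * L + 2L * lmin) return(NULL)
  region <- substr(tseq, tstart + 1L, tend)
  frag <- substr(query, qstart + 1L, qend)
  tid <- params$transtable
  scheme <- params$penalties
  # 0-based positions p in the region where "AG" ends at p (acceptor ends)
  agp <- gregexpr("AG", region, fixed = TRUE)[[1]]
  agp <- if (agp[1L] == -1L) integer(0) else as.integer(agp) + 1L
  for (a in 0:(3L * L - 1L)) {
    # intron1 = [a, a+i1): donor inside the region at a
    if (!substr(region, a + 1L, a + 2L) %in% c("GT", "GC")) next
    for (e in seq_len(min(14L, 3L * L - a))) {
      b <- 3L * L - a - e
      i2 <- 0L  # placeholder; b fixes acceptor2 at region end
      if (!identical(substr(region, n - b - 1L, n - b), "AG")) next
      for (p in agp) {
        i1 <- p - a
        if (i1 < lmin) next
        i2 <- n - 3L * L - i1
        if (i2 < lmin) break   # agp ascending: i1 only grows
        s <- a + i1            # exon start (0-based in region)
        if (!substr(region, s + e + 1L, s + e + 2L) %in% c("GT", "GC"))
          next
        if (!identical(substr(region, n - b - 1L, n - b), "AG")) next
        cds <- paste0(substr(region, 1L, a),
                      substr(region, s + 1L, s + e),
                      substr(region, n - b + 1L, n))
        if (translate_frame(cds, tid) != frag) next
        if (grepl("[*X]", frag)) next
        # 0-based genomic position of every coding nucleotide
        pos <- c(tstart + seq_len(a) - 1L,
                 tstart + s + seq_len(e) - 1L,
                 tstart + (n - b) + seq_len(b) - 1L)
        ex_lo <- tstart + s; ex_hi <- tstart + s + e
        nres_ex <- sum(vapply(seq_len(L) - 1L, function(j)
          any(pos[(3L * j + 1L):(3L * j + 3L)] >= ex_lo &
                pos[(3L * j + 1L):(3L * j + 3L)] < ex_hi), logical(1)))
        if (nres_ex < 1L || nres_ex > 4L) next
        rows <- list()
        if (a == 0L)
          rows[[1L]] <- intron_row(contig, tstart, tstart + i1, tseq, 0L)
        prev_end <- NULL
        ok <- TRUE
        for (j in seq_len(L) - 1L) {
          p3 <- pos[(3L * j + 1L):(3L * j + 3L)]
          if (!is.null(prev_end) && p3[1L] != prev_end)
            rows[[length(rows) + 1L]] <-
              intron_row(contig, prev_end, p3[1L], tseq, 0L)
          brk <- which(diff(p3) != 1L)
          if (length(brk) > 1L) { ok <- FALSE; break }
          if (length(brk) == 0L) {
            rows[[length(rows) + 1L]] <-
              seg_row("codon", contig, p3[1L], p3[3L] + 1L,
                      qstart + j, qstart + j + 1L, 1L,
                      match = TRUE, stop = FALSE)
          } else {
            k <- brk
            rows[[length(rows) + 1L]] <- rbind(
              seg_row("codon5", contig, p3[1L], p3[k] + 1L,
                      qstart + j, qstart + j + 1L, 1L,
                      match = TRUE, stop = FALSE),
              intron_row(contig, p3[k] + 1L, p3[k + 1L], tseq,
                         phase = k),
              seg_row("codon3", contig, p3[k + 1L], p3[3L] + 1L,
                      qstart + j, qstart + j + 1L, 0L))
          }
          prev_end <- p3[3L] + 1L
        }
        if (!ok) next
        if (b == 0L)
          rows[[length(rows) + 1L]] <-
            intron_row(contig, tend - i2, tend, tseq, 0L)
        out <- do.call(rbind, rows)
        ir <- out[out$type == "intron", , drop = FALSE]
        if (any(classify_intron(ir$donor, ir$acceptor, scheme) !=
                "intron")) next
        return(out)
      }
    }
  }
  NULL
}

# a closure result is flawless if every residue matches, no indel or
# frameshift rows remain and every intron has accepted splice sites
closure_flawless <- function(rows, scheme) {
  if (any(rows$type %in% c("ins", "fs", "gapnt", "qgap"))) return(FALSE)
  resrows <- rows$type %in% c("codon", "codon5")
  if (any(!rows$match[resrows])) return(FALSE)
  ir <- rows[rows$type == "intron", , drop = FALSE]
  nrow(ir) == 0L ||
    all(classify_intron(ir$donor, ir$acceptor, scheme) == "intron")
}

# close the region between two anchored blocks (or report it unresolved)
close_region <- function(contig, qstart, qend, tstart, tend, query, tseq,
                         params) {
  qgap <- qend - qstart; tspan <- tend - tstart
  scheme <- params$penalties
  if (qgap == 0L && tspan == 0L) return(empty_stream())
  region <- substr(tseq, tstart + 1L, tend)
  if (qgap == 0L) {
    if (classify_unmatched_target(region, scheme, params$transtable) ==
        "merge_into_exon") {
      k <- tspan %/% 3L
      off <- 3L * (seq_len(k) - 1L)
      aa <- translate_codon(substring(region, off + 1L, off + 3L),
                            params$transtable)
      return(seg_row("gapnt", contig, tstart + off, tstart + off + 3L,
                     qstart, qstart, 0L, stop = aa == "*"))
    }
    if (tspan >= scheme$min_intron_len)
      return(intron_row(contig, tstart, tend, tseq))
    # too short for an intron, not a clean insertion: cheapest combination
    p <- align_spliced("", region, scheme, params$transtable)
    return(parse_to_stream(p, contig, tstart, qstart, query, tseq, params))
  }
  if (qgap <= params$exhaust_gap_size && tspan <= params$exhaust_align_size) {
    qf <- substr(query, qstart + 1L, qend)
    p <- align_spliced(qf, region, scheme, params$transtable)
    rows <- parse_to_stream(p, contig, tstart, qstart, query, tseq, params)
    if (!closure_flawless(rows, scheme)) {
      rec <- recover_short_exon(contig, qstart, qend, tstart, tend, query,
                                tseq, params)
      if (!is.null(rec)) return(rec)
    }
    return(enforce_short_exon_rule(rows, tseq, params))
  }
  # unresolved: query gap stays; the target region is an intron candidate
  gap <- seg_row("qgap", contig, tstart, tstart, qstart, qend, qgap)
  if (tspan >= scheme$min_intron_len)
    return(rbind(gap, intron_row(contig, tstart, tend, tseq)))
  if (tspan > 0L) {
    p <- align_spliced("", region, scheme, params$transtable)
    return(rbind(gap, parse_to_stream(p, contig, tstart, qstart, query,
                                      tseq, params)))
  }
  gap
}

#' Trim seed-block margins for realignment
#'
#' Cuts up to `max_move_exon` residues from each side of every internal
#' block junction of a chained hit; the freed residues (plus the region
#' between the blocks) are subsequently re-placed by the exhaustive spliced
#' alignment, which recovers intron borders that the seeder misassigned
#' (intronic sequence with chance homology absorbed into an exon).  With
#' `max_move_exon = 0` the hit is returned unchanged.
#'
#' Junctions whose unmatched target region already classifies as a clean
#' in-frame insertion (no missing query residues, fewer than
#' `min_intron_len` extra bases, a multiple of three, stop-free) are
#' decided by the insertion rule itself and are left untrimmed: freeing
#' residues there would let the realignment replace the insertion with a
#' spurious intron, since one intron penalty undercuts several gap-codon
#' penalties.
#'
#' @param hit a seed hit.
#' @param max_move_exon residues to cut per junction side.
#' @param tseq strand-oriented target sequence (optional; enables the
#'   insertion-junction exemption).
#' @param params a [pg_params()] object (used with `tseq`).
#' @return the hit with trimmed blocks.
#' @export
trim_hit_margins <- function(hit, max_move_exon = 6L, tseq = NULL,
                             params = pg_params()) {
  bl <- hit$blocks
  nb <- nrow(bl)
  if (max_move_exon <= 0L || nb == 0L) return(hit)
  keep <- rep(FALSE, nb)          # keep[k]: junction after block k is fixed
  if (!is.null(tseq) && nb > 1L) {
    for (k in seq_len(nb - 1L)) {
      if (bl$qstart[k + 1L] > bl$qend[k]) next
      region <- substr(tseq, bl$tend[k] + 1L, bl$tstart[k + 1L])
      keep[k] <- nchar(region) > 0L &&
        classify_unmatched_target(region, params$penalties,
                                  params$transtable) == "merge_into_exon"
    }
  }
  for (k in seq_len(nb)) {
    len <- bl$qend[k] - bl$qstart[k]
    lt <- if (k > 1L && !keep[k - 1L]) min(max_move_exon, len - 1L) else 0L
    len <- len - lt
    rt <- if (k < nb && !keep[k]) min(max_move_exon, len - 1L) else 0L
    bl$qstart[k] <- bl$qstart[k] + lt
    bl$tstart[k] <- bl$tstart[k] + 3L * lt
    bl$qend[k] <- bl$qend[k] - rt
    bl$tend[k] <- bl$tend[k] - 3L * rt
  }
  hit$blocks <- bl
  hit
}

#' Exact pattern search for a terminal exon
#'
#' Searches a bounded target flank for an exact codon-level spelling of an
#' unmatched query terminus.  A candidate is accepted only if the implied
#' intron between the terminal exon and the anchored gene body is at least
#' `min_intron_len` long and bordered by one of the two most common splice
#' site patterns (GT--AG or GC--AG).  Among candidates the one with the
#' shortest implied intron is returned.  Termini longer than `gap_to_close`
#' are not searched.
#'
#' @param terminus unmatched terminal query residues.
#' @param flank_seq target flank: for the N side the sequence ending
#'   immediately before the anchored gene start, for the C side the
#'   sequence starting immediately after the anchored gene end.
#' @param side `"N"` or `"C"`.
#' @param params a [pg_params()] object.
#' @return `NULL`, or a list with `exon_offset` (0-based within the flank),
#'   `intron_start`, `intron_end` (0-based half-open within the flank).
#' @export
find_terminal_exon <- function(terminus, flank_seq, side = c("N", "C"),
                               params = pg_params()) {
  side <- match.arg(side)
  L <- nchar(terminus); Fl <- nchar(flank_seq)
  if (L == 0L || L > params$gap_to_close) return(NULL)
  lmin <- params$penalties$min_intron_len
  need <- 3L * L
  if (Fl < need + lmin) return(NULL)
  tid <- params$transtable
  if (side == "N") {
    if (substr(flank_seq, Fl - 1L, Fl) != "AG") return(NULL)
    # prefer the candidate closest to the gene body (largest offset)
    for (p in seq(Fl - need - lmin, 0L)) {
      if (translate_frame(substr(flank_seq, p + 1L, p + need), tid) != terminus)
        next
      if (substr(flank_seq, p + need + 1L, p + need + 2L) %in% c("GT", "GC"))
        return(list(exon_offset = p, intron_start = p + need,
                    intron_end = Fl))
    }
  } else {
    if (substr(flank_seq, 1L, 2L) %in% c("GT", "GC") == FALSE) return(NULL)
    for (p in seq(lmin, Fl - need)) {
      if (substr(flank_seq, p - 1L, p) != "AG") next
      if (translate_frame(substr(flank_seq, p + 1L, p + need), tid) == terminus)
        return(list(exon_offset = p, intron_start = 0L, intron_end = p))
    }
  }
  NULL
}

# resolve an unmatched query terminus: exact terminal-exon search, then
# forced absorption onto the adjacent exon border, else a remaining gap
terminal_rows <- function(contig, side, qstart, qend, anchor_t, query, tseq,
                          params) {
  qgap <- qend - qstart
  if (qgap <= 0L) return(empty_stream())
  tid <- params$transtable
  terminus <- substr(query, qstart + 1L, qend)
  tlen <- nchar(tseq)
  if (side == "N") {
    Fl <- min(anchor_t, params$exhaust_align_size)
    flank <- substr(tseq, anchor_t - Fl + 1L, anchor_t)
    fe <- if (qgap <= params$gap_to_close)
      find_terminal_exon(terminus, flank, "N", params) else NULL
    base <- anchor_t - Fl
    if (!is.null(fe)) {
      return(rbind(
        codon_rows(contig, base + fe$exon_offset, qstart, qgap, query,
                   tseq, tid),
        intron_row(contig, base + fe$intron_start, base + fe$intron_end,
                   tseq)))
    }
    if (qgap <= params$gap_to_close && anchor_t >= 3L * qgap)
      return(codon_rows(contig, anchor_t - 3L * qgap, qstart, qgap, query,
                        tseq, tid))
    return(seg_row("qgap", contig, anchor_t, anchor_t, qstart, qend, qgap))
  }
  Fl <- min(tlen - anchor_t, params$exhaust_align_size)
  flank <- substr(tseq, anchor_t + 1L, anchor_t + Fl)
  fe <- if (qgap <= params$gap_to_close)
    find_terminal_exon(terminus, flank, "C", params) else NULL
  if (!is.null(fe)) {
    return(rbind(
      intron_row(contig, anchor_t + fe$intron_start,
                 anchor_t + fe$intron_end, tseq),
      codon_rows(contig, anchor_t + fe$intron_end, qstart, qgap, query,
                 tseq, tid)))
  }
  if (qgap <= params$gap_to_close && tlen - anchor_t >= 3L * qgap)
    return(codon_rows(contig, anchor_t, qstart, qgap, query, tseq, tid))
  seg_row("qgap", contig, anchor_t, anchor_t, qstart, qend, qgap)
}

#' Refine a seed hit into a gene-structure part
#'
#' Runs the per-hit processing pipeline: trims and realigns block margins,
#' classifies unmatched target regions as exonic insertions or introns,
#' closes query gaps with the exhaustive spliced alignment (enforcing the
#' short-exon identity rule), searches for terminal exons, absorbs
#' remaining marginal residues, and classifies every intron's splice sites.
#'
#' @param hit a chained seed hit (blocks strictly increasing in query and
#'   target, block spans in 3:1 nucleotide:residue ratio).
#' @param query full protein query (character scalar).
#' @param tseq strand-oriented target sequence (already
#'   reverse-complemented for minus-strand hits).
#' @param params a [pg_params()] object.
#' @param contig_length length of the target contig.
#' @return an object of class `pg_part`: segment stream plus derived
#'   exons/introns/gaps/positions and statistics.
#' @export
refine_hit <- function(hit, query, tseq, params = pg_params(),
                       contig_length = nchar(tseq)) {
  query <- toupper(query); tseq <- toupper(tseq)
  tid <- params$transtable
  hit <- trim_hit_margins(hit, params$max_move_exon, tseq, params)
  bl <- hit$blocks
  nb <- nrow(bl)
  streams <- list()
  streams[[1]] <- terminal_rows(hit$target_id, "N", 0L, bl$qstart[1L],
                                bl$tstart[1L], query, tseq, params)
  for (k in seq_len(nb)) {
    streams[[length(streams) + 1L]] <-
      codon_rows(hit$target_id, bl$tstart[k], bl$qstart[k],
                 bl$qend[k] - bl$qstart[k], query, tseq, tid)
    if (k < nb)
      streams[[length(streams) + 1L]] <-
        close_region(hit$target_id, bl$qend[k], bl$qstart[k + 1L],
                     bl$tend[k], bl$tstart[k + 1L], query, tseq, params)
  }
  streams[[length(streams) + 1L]] <-
    terminal_rows(hit$target_id, "C", bl$qend[nb], nchar(query),
                  bl$tend[nb], query, tseq, params)
  rows <- do.call(rbind, streams)
  rownames(rows) <- NULL
  # the full stream may still contain short exons flanked by introns that
  # arose across closure boundaries; re-check once on the whole stream
  rows <- enforce_short_exon_rule(rows, tseq, params)
  rows$status[rows$type == "intron"] <-
    classify_intron(rows$donor[rows$type == "intron"],
                    rows$acceptor[rows$type == "intron"], params$penalties)
  derive_part(rows, hit$query_id, nchar(query), hit$target_id, hit$strand,
              contig_length)
}

# derive the exon/intron/gap views and statistics from a segment stream
derive_part <- function(rows, query_id, query_len, contig, strand,
                        contig_length) {
  exonic <- c("codon", "codon5", "codon3", "gapnt", "fs", "ins")
  breaker <- !(rows$type %in% exonic)
  grp <- cumsum(breaker)
  exons <- NULL
  for (g in unique(grp[!breaker])) {
    run <- rows[grp == g & !breaker, , drop = FALSE]
    if (sum(run$tend - run$tstart) == 0L) next
    qs <- suppressWarnings(min(run$qstart[run$type != "gapnt"], na.rm = TRUE))
    qe <- suppressWarnings(max(run$qend[run$type != "gapnt"], na.rm = TRUE))
    exons <- rbind(exons, data.frame(
      contig = run$contig[1L],
      tstart = min(run$tstart), tend = max(run$tend),
      qstart = if (is.finite(qs)) qs else NA_integer_,
      qend = if (is.finite(qe)) qe else NA_integer_,
      stringsAsFactors = FALSE))
  }
  if (is.null(exons))
    exons <- data.frame(contig = character(0), tstart = integer(0),
                        tend = integer(0), qstart = integer(0),
                        qend = integer(0), stringsAsFactors = FALSE)
  iro <- rows[rows$type == "intron", , drop = FALSE]
  introns <- data.frame(contig = iro$contig, tstart = iro$tstart,
                        tend = iro$tend, donor = iro$donor,
                        acceptor = iro$acceptor, phase = iro$phase,
                        status = iro$status, stringsAsFactors = FALSE)
  gr <- rows[rows$type %in% c("ins", "qgap"), , drop = FALSE]
  gaps <- if (nrow(gr)) {
    g <- gr[order(gr$qstart), c("qstart", "qend")]
    merged <- g[1, , drop = FALSE]
    for (r in seq_len(nrow(g))[-1]) {
      if (g$qstart[r] <= merged$qend[nrow(merged)])
        merged$qend[nrow(merged)] <- max(merged$qend[nrow(merged)], g$qend[r])
      else merged <- rbind(merged, g[r, ])
    }
    merged
  } else data.frame(qstart = integer(0), qend = integer(0))
  resrows <- rows$type %in% c("codon", "codon5")
  ma <- sum(rows$match[resrows], na.rm = TRUE)
  mi <- sum(!rows$match[resrows], na.rm = TRUE)
  mismatches <- rows$qend[resrows & !rows$match & !(rows$stop %in% TRUE)]
  stops <- rows$qend[resrows & rows$stop %in% TRUE]
  frameshifts <- rows$qend[rows$type == "fs"]
  structure(list(query_id = query_id, query_length = query_len,
                 contig = contig, strand = strand,
                 contig_length = contig_length,
                 exons = exons, introns = introns, gaps = gaps,
                 mismatches = sort(unique(mismatches)),
                 frameshifts = sort(unique(frameshifts)),
                 stops = sort(unique(stops)),
                 stats = list(matches = ma, mismatches = mi,
                              score = max(0, (ma - mi) / query_len),
                              identity = if (ma + mi > 0) ma / (ma + mi) else 0,
                              coverage = (ma + mi) / query_len),
                 segments = rows),
            class = "pg_part")
}

#' @export
print.pg_part <- function(x, ...) {
  cat(sprintf("Gene-structure part: %s on %s(%s), %d exon(s), %d intron(s), score %.3f\n",
              x$query_id, x$contig, x$strand, nrow(x$exons),
              nrow(x$introns), x$stats$score))
  invisible(x)
}
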