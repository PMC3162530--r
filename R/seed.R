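# Built-in translated seeder: exact amino-acid k-mer matches between the
# query and all six translated frames of each target, merged into ungapped
# diagonal blocks, extended with bounded mismatch tolerance and chained into
# collinear seed hits.  A stand-in for an external local aligner; PSL input
# (read_psl) is the drop-in alternative.

# translate an in-frame nucleotide string to residues; N -> X, stops -> *
translate_frame <- function(seq, table_id = 1) {
  n <- nchar(seq) - nchar(seq) %% 3L
  if (n < 3L) return("")
  codons <- substring(seq, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  paste(translate_codon(codons, table_id), collapse = "")
}

# maximum run of consecutive mismatches tolerated while extending a seed
SEED_EXTEND_MAX_MISS <- 5L

# score used when cutting an extension back: a chance match inside an
# intron must not pay for the mismatches leading up to it, or blocks creep
# past exon borders further than margin trimming can repair
SEED_EXTEND_MATCH <- 1
SEED_EXTEND_MISMATCH <- -1

extend_run <- function(qv, fv, qs, qe, fs) {
  # qs..qe: 1-based exact-match run in query, fs: frame position of qs;
  # extension stops after 5 consecutive mismatches and is cut back to the
  # maximal-scoring point
  m <- length(qv); n <- length(fv)
  # left
  miss <- 0L; i <- qs - 1L; j <- fs - 1L
  sc <- 0; best_sc <- 0; best <- qs
  while (i >= 1L && j >= 1L && miss < SEED_EXTEND_MAX_MISS) {
    if (qv[i] == fv[j] && fv[j] != "X" && fv[j] != "*") {
      sc <- sc + SEED_EXTEND_MATCH; miss <- 0L
      if (sc > best_sc) { best_sc <- sc; best <- i }
    } else { sc <- sc + SEED_EXTEND_MISMATCH; miss <- miss + 1L }
    i <- i - 1L; j <- j - 1L
  }
  qs2 <- best
  # right
  miss <- 0L; i <- qe + 1L; j <- fs + (qe - qs) + 1L
  sc <- 0; best_sc <- 0; best <- qe
  while (i <= m && j <= n && miss < SEED_EXTEND_MAX_MISS) {
    if (qv[i] == fv[j] && fv[j] != "X" && fv[j] != "*") {
      sc <- sc + SEED_EXTEND_MATCH; miss <- 0L
      if (sc > best_sc) { best_sc <- sc; best <- i }
    } else { sc <- sc + SEED_EXTEND_MISMATCH; miss <- miss + 1L }
    i <- i + 1L; j <- j + 1L
  }
  c(qs2, best)
}

# blocks on one translated frame of one target strand
frame_blocks <- function(qv, fv, tilesize) {
  m <- length(qv); n <- length(fv)
  if (m < tilesize || n < tilesize) return(NULL)
  qk <- vapply(seq_len(m - tilesize + 1L),
               function(i) paste(qv[i:(i + tilesize - 1L)], collapse = ""), "")
  fk <- vapply(seq_len(n - tilesize + 1L),
               function(i) paste(fv[i:(i + tilesize - 1L)], collapse = ""), "")
  pos_by_kmer <- split(seq_along(qk), qk)
  hitq <- integer(0); hitf <- integer(0)
  idx <- which(fk %in% names(pos_by_kmer))
  for (j in idx) {
    qs <- pos_by_kmer[[fk[j]]]
    hitq <- c(hitq, qs); hitf <- c(hitf, rep.int(j, length(qs)))
  }
  if (!length(hitq)) return(NULL)
  diag <- hitf - hitq
  out <- NULL
  for (d in unique(diag)) {
    qs <- sort(hitq[diag == d])
    brk <- c(0L, which(diff(qs) > tilesize), length(qs))
    for (r in seq_len(length(brk) - 1L)) {
      run <- qs[(brk[r] + 1L):brk[r + 1L]]
      a <- run[1L]; b <- run[length(run)] + tilesize - 1L
      ext <- extend_run(qv, fv, a, b, a + d)
      out <- rbind(out, c(ext[1L], ext[2L], d))
    }
  }
  # merge overlapping extents on the same diagonal
  res <- NULL
  for (d in unique(out[, 3L])) {
    seg <- out[out[, 3L] == d, , drop = FALSE]
    seg <- seg[order(seg[, 1L]), , drop = FALSE]
    cur <- seg[1L, ]
    for (r in seq_len(nrow(seg))[-1L]) {
      if (seg[r, 1L] <= cur[2L] + 1L) cur[2L] <- max(cur[2L], seg[r, 2L])
      else { res <- rbind(res, cur); cur <- seg[r, ] }
    }
    res <- rbind(res, cur)
  }
  res
}

# order a chain by query position, trim query overlaps between
# consecutive blocks off the later block and recount it against the target
finalize_chain <- function(chain, qv, tseq, table_id) {
  chain <- chain[order(chain$qstart, chain$tstart), , drop = FALSE]
  for (r in seq_len(nrow(chain))[-1L]) {
    ov <- chain$qend[r - 1L] - chain$qstart[r]
    if (ov <= 0L) next
    chain$qstart[r] <- chain$qstart[r] + ov
    chain$tstart[r] <- chain$tstart[r] + 3L * ov
    aa <- translate_frame(substr(tseq, chain$tstart[r] + 1L,
                                 chain$tend[r]), table_id)
    cmp <- qv[(chain$qstart[r] + 1L):chain$qend[r]] ==
      strsplit(aa, "")[[1]]
    chain$matches[r] <- sum(cmp)
    chain$mismatches[r] <- sum(!cmp)
  }
  rownames(chain) <- NULL
  chain
}

# exact k-mer blocks of a query fragment against a bounded target window,
# in global coordinates (used to reseed gaps with a smaller tile)
window_blocks <- function(qv, qlo, qhi, tseq, tlo, thi, tilesize,
                          table_id) {
  if (qhi - qlo < tilesize || thi - tlo < 3L * tilesize) return(NULL)
  qf <- qv[(qlo + 1L):qhi]
  twin <- substr(tseq, tlo + 1L, thi)
  out <- NULL
  for (f in 0:2) {
    fs <- translate_frame(substr(twin, f + 1L, nchar(twin)), table_id)
    if (nchar(fs) < tilesize) next
    fv <- strsplit(fs, "")[[1]]
    fb <- frame_blocks(qf, fv, tilesize)
    if (is.null(fb)) next
    for (r in seq_len(nrow(fb))) {
      qs <- fb[r, 1L]; qe <- fb[r, 2L]; d <- fb[r, 3L]
      fpos <- qs + d
      cmp <- qf[qs:qe] == fv[fpos:(fpos + qe - qs)]
      out <- rbind(out, data.frame(
        qstart = qlo + qs - 1L, qend = qlo + qe,
        tstart = tlo + f + 3L * (fpos - 1L),
        tend = tlo + f + 3L * (fpos + qe - qs),
        matches = sum(cmp), mismatches = sum(!cmp)))
    }
  }
  out
}

# query gaps at least this long trigger reseeding with a smaller tile (a
# divergent exon can lack any exact tilesize-mer; if the resulting query
# gap exceeds exhaust_gap_size the exhaustive closure cannot recover it)
SEED_RESCUE_MIN_GAP <- 8L

# reseed junction and terminal gaps of a chain with a reduced tile size,
# restricted to the target window between the anchoring blocks
rescue_chain <- function(chain, qv, tseq, tilesize, table_id) {
  rtile <- max(3L, tilesize - 3L)
  if (rtile >= tilesize) return(chain)
  m <- length(qv); n <- nchar(tseq)
  for (pass in 1:3) {
    added <- NULL
    nb <- nrow(chain)
    slack <- 60L
    # left terminus
    if (chain$qstart[1L] >= SEED_RESCUE_MIN_GAP) {
      w <- 3L * chain$qstart[1L] + slack
      added <- rbind(added, window_blocks(
        qv, 0L, chain$qstart[1L], tseq,
        max(0L, chain$tstart[1L] - w), chain$tstart[1L], rtile, table_id))
    }
    # internal junctions
    for (k in seq_len(nb - 1L)) {
      if (chain$qstart[k + 1L] - chain$qend[k] < SEED_RESCUE_MIN_GAP) next
      added <- rbind(added, window_blocks(
        qv, chain$qend[k], chain$qstart[k + 1L], tseq,
        chain$tend[k], chain$tstart[k + 1L], rtile, table_id))
    }
    # right terminus
    if (m - chain$qend[nb] >= SEED_RESCUE_MIN_GAP) {
      w <- 3L * (m - chain$qend[nb]) + slack
      added <- rbind(added, window_blocks(
        qv, chain$qend[nb], m, tseq,
        chain$tend[nb], min(n, chain$tend[nb] + w), rtile, table_id))
    }
    if (is.null(added)) return(chain)
    pool <- unique(rbind(chain, added))
    if (nrow(pool) == nrow(chain)) return(chain)
    idx <- best_chain(pool)
    new_chain <- finalize_chain(pool[idx, , drop = FALSE], qv, tseq,
                                table_id)
    if (nrow(new_chain) == nrow(chain) &&
        isTRUE(all.equal(new_chain, chain))) return(chain)
    chain <- new_chain
  }
  chain
}

# blocks extended past a true exon border (chance matches in the intron)
# can overlap the next exon's block in the query by a few residues; the
# chain tolerates such overlaps (the later block is trimmed afterwards)
SEED_CHAIN_MAX_OVERLAP <- 10L

# chain blocks (rows: qstart,qend,tstart,tend 0-based, matches, mismatches)
# into the best-scoring collinear hit; returns row indices
best_chain <- function(bl) {
  n <- nrow(bl)
  ord <- order(bl$qstart, bl$tstart)
  b <- bl[ord, , drop = FALSE]
  score <- b$matches
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      ov <- max(0L, b$qend[j] - b$qstart[i])
      if (ov > SEED_CHAIN_MAX_OVERLAP) next
      if (b$qend[i] - b$qstart[i] <= ov) next       # later block vanishes
      if (b$tend[j] > b$tstart[i] + 3L * ov) next   # target order
      gain <- b$matches[i] - ov                      # trimmed residues lost
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

#' Seed protein-to-genome hits by translated k-mer search
#'
#' Finds exact amino-acid k-mer matches between the query and all six
#' translated frames of each target contig, merges them into ungapped
#' diagonal blocks, extends the blocks while match density allows (at most
#' 5 consecutive mismatches, ends trimmed back to matches), and chains
#' collinear blocks into seed hits.  Deterministic.  Each hit carries
#' blocks with 0-based half-open query (residue) and target (nucleotide)
#' spans satisfying `3 * query span = target span`.
#'
#' @param query protein sequence (character scalar).
#' @param targets genome contigs, a named `DNAStringSet` or named character
#'   vector.
#' @param tilesize seed k-mer length in residues (>= 3, default 7).
#' @param table_id NCBI translation table identifier.
#' @param query_id identifier stored in the hits.
#' @return list of seed hits: `list(query_id, target_id, strand, blocks)`.
#' @export
seed_hits <- function(query, targets, tilesize = 7L, table_id = 1,
                      query_id = "query") {
  stopifnot(tilesize >= 3L)
  query <- toupper(as.character(query))
  if (!methods::is(targets, "DNAStringSet"))
    targets <- Biostrings::DNAStringSet(toupper(targets))
  m <- nchar(query)
  if (m == 0L || length(targets) == 0L) return(list())
  qv <- strsplit(query, "")[[1]]
  hits <- list()
  for (ti in seq_along(targets)) {
    tname <- names(targets)[ti]
    for (strand in c("+", "-")) {
      tseq <- if (strand == "+") as.character(targets[[ti]]) else
        as.character(Biostrings::reverseComplement(targets[[ti]]))
      n <- nchar(tseq)
      blocks <- NULL
      for (frame in 0:2) {
        fs <- translate_frame(substr(tseq, frame + 1L, n), table_id)
        if (nchar(fs) < tilesize) next
        fv <- strsplit(fs, "")[[1]]
        fb <- frame_blocks(qv, fv, tilesize)
        if (is.null(fb)) next
        for (r in seq_len(nrow(fb))) {
          qs <- fb[r, 1L]; qe <- fb[r, 2L]; d <- fb[r, 3L]
          fpos <- qs + d
          cmp <- qv[qs:qe] == fv[fpos:(fpos + qe - qs)]
          blocks <- rbind(blocks, data.frame(
            qstart = qs - 1L, qend = qe,
            tstart = frame + 3L * (fpos - 1L),
            tend = frame + 3L * (fpos + qe - qs),
            matches = sum(cmp), mismatches = sum(!cmp)))
        }
      }
      if (is.null(blocks)) next
      blocks <- unique(blocks)
      while (nrow(blocks) > 0L) {
        idx <- best_chain(blocks)
        chain <- finalize_chain(blocks[idx, , drop = FALSE], qv, tseq,
                                table_id)
        if (sum(chain$matches) < tilesize) break
        chain <- rescue_chain(chain, qv, tseq, tilesize, table_id)
        hits[[length(hits) + 1L]] <- list(query_id = query_id,
                                          target_id = tname,
                                          strand = strand,
                                          blocks = chain)
        blocks <- blocks[-idx, , drop = FALSE]
        # secondary chains must stand on their own; drop fragments that
        # overlap the extracted chain on the same diagonal
        if (nrow(blocks)) {
          keep <- rep(TRUE, nrow(blocks))
          for (r in seq_len(nrow(blocks))) {
            ov <- blocks$qstart[r] < chain$qend & blocks$qend[r] > chain$qstart &
              blocks$tstart[r] < chain$tend & blocks$tend[r] > chain$tstart
            if (any(ov)) keep[r] <- FALSE
          }
          blocks <- blocks[keep, , drop = FALSE]
        }
      }
    }
  }
  hits
}

#' Per-hit mapping statistics
#'
#' Coverage is the number of mapped residues (match or mismatch) divided by
#' the query length; identity is the fraction of mapped residues that
#' match; the score is `(matches - mismatches) / query length`, clipped at
#' zero.
#'
#' @param hit a seed hit (or any object with a `blocks` data frame carrying
#'   `matches` and `mismatches` columns).
#' @param query_length query length in residues.
#' @return list with `matches`, `mismatches`, `score`, `identity`,
#'   `coverage`.
#' @export
compute_stats <- function(hit, query_length) {
  stopifnot(query_length > 0)
  ma <- sum(hit$blocks$matches); mi <- sum(hit$blocks$mismatches)
  mapped <- ma + mi
  list(matches = ma, mismatches = mi,
       score = max(0, (ma - mi) / query_length),
       identity = if (mapped > 0) ma / mapped else 0,
       coverage = mapped / query_length)
}

#' Filter seed hits by the general search thresholds
#'
#' Retains hits meeting all of: score at least `min_score`, identity at
#' least `min_identity`, at most `max_mismatch` mismatches, and coverage
#' (mapped residues over full query length, see [compute_stats()]) at
#' least `min_coverage`; hits with coverage strictly below the threshold
#' are rejected.  Note that on heavily fragmented assemblies a genuine
#' partial hit can never reach the default 60% coverage on its own
#' contig; such searches require lowered `min_score`/`min_coverage`.
#'
#' @param hits list of seed hits.
#' @param query_length full query length in residues.
#' @param min_score,min_identity,max_mismatch,min_coverage thresholds, see
#'   [pg_params()].
#' @return the retained subset of `hits`.
#' @export
filter_hits <- function(hits, query_length, min_score = 0.3,
                        min_identity = 0.9, max_mismatch = Inf,
                        min_coverage = 0.6) {
  keep <- vapply(hits, function(h) {
    s <- compute_stats(h, query_length)
    s$score >= min_score && s$identity >= min_identity &&
      s$mismatches <= max_mismatch && s$coverage >= min_coverage
  }, logical(1))
  hits[keep]
}
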