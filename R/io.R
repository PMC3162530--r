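# Readers and writers: FASTA in, PSL seed hits in, YAML and GFF3 out.
# Internal coordinates are 0-based half-open on the oriented strand; both
# writers emit forward-strand 1-based inclusive coordinates.

#' Read a FASTA file
#'
#' Hand-rolled line parser so that CRLF input, case folding and error
#' reporting (line number of a malformed header) are under control; N runs
#' are preserved.
#'
#' @param path readable FASTA file.
#' @param type `"DNA"` or `"AA"`.
#' @return a named `DNAStringSet` or `AAStringSet`, in file order; record
#'   names are the first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(trimws(lines[nonblank[1L]]), ">"))
    stop(sprintf("malformed FASTA header at line %d of %s: expected '>'",
                 nonblank[1L], path))
  heads <- which(startsWith(lines, ">"))
  seqs <- character(length(heads))
  nms <- character(length(heads))
  bounds <- c(heads, length(lines) + 1L)
  for (k in seq_along(heads)) {
    nms[k] <- strsplit(trimws(sub("^>", "", lines[heads[k]])), "\\s+")[[1]][1]
    if (is.na(nms[k]) || !nzchar(nms[k]))
      stop(sprintf("malformed FASTA header at line %d of %s: empty name",
                   heads[k], path))
    body <- lines[seq(heads[k] + 1L, bounds[k + 1L] - 1L)]
    body <- body[!startsWith(body, ">")]
    seqs[k] <- toupper(gsub("\\s", "", paste(body, collapse = "")))
  }
  names(seqs) <- nms
  if (type == "DNA") Biostrings::DNAStringSet(seqs)
  else Biostrings::AAStringSet(seqs)
}

write_fasta_file <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  seqs <- stats::setNames(as.character(seqs), names(seqs))
  for (k in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[k]), con)
    s <- seqs[[k]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read seed hits from a PSL file
#'
#' Parses protein-vs-translated-DNA PSL (format v3, 21 tab-separated
#' columns, optional 5-line header auto-detected).  Query coordinates are
#' residues, target block spans three nucleotides per residue.  For
#' negative-strand records (strand column ending in `-`) the target block
#' coordinates are taken, as in the format, on the reverse-complemented
#' strand — the package's oriented-frame convention.  Per-block
#' match/mismatch counts are not stored in PSL; blocks are provisionally
#' counted as all-match and recounted against the genome by
#' [map_protein()].
#'
#' @param path PSL file.
#' @return list of seed hits as produced by [seed_hits()].
#' @export
read_psl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  if (length(lines) && startsWith(lines[1L], "psLayout"))
    lines <- lines[-seq_len(min(5L, length(lines)))]
  lines <- lines[nzchar(trimws(lines))]
  hits <- list()
  for (ln in seq_along(lines)) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != 21L)
      stop(sprintf("PSL parse error at data line %d: %d columns, expected 21",
                   ln, length(f)))
    strand <- substr(f[9L], nchar(f[9L]), nchar(f[9L]))
    if (!strand %in% c("+", "-"))
      stop(sprintf("PSL parse error at data line %d: bad strand '%s'",
                   ln, f[9L]))
    nb <- as.integer(f[18L])
    ints <- function(s) as.integer(strsplit(sub(",$", "", s), ",")[[1]])
    sizes <- ints(f[19L]); qs <- ints(f[20L]); ts <- ints(f[21L])
    if (length(sizes) != nb || length(qs) != nb || length(ts) != nb)
      stop(sprintf("PSL parse error at data line %d: block list lengths disagree",
                   ln))
    hits[[length(hits) + 1L]] <- list(
      query_id = f[10L], target_id = f[14L], strand = strand,
      blocks = data.frame(qstart = qs, qend = qs + sizes,
                          tstart = ts, tend = ts + 3L * sizes,
                          matches = sizes, mismatches = 0L))
  }
  hits
}

# recount block matches/mismatches of an externally seeded hit against the
# oriented target sequence
recount_blocks <- function(hit, query, tseq, table_id = 1) {
  bl <- hit$blocks
  for (k in seq_len(nrow(bl))) {
    n <- bl$qend[k] - bl$qstart[k]
    off <- 3L * (seq_len(n) - 1L)
    aa <- translate_codon(substring(tseq, bl$tstart[k] + off + 1L,
                                    bl$tstart[k] + off + 3L), table_id)
    res <- substring(query, bl$qstart[k] + seq_len(n),
                     bl$qstart[k] + seq_len(n))
    ok <- aa == res & aa != "*" & aa != "X"
    bl$matches[k] <- sum(ok); bl$mismatches[k] <- sum(!ok)
  }
  hit$blocks <- bl
  hit
}

one_based <- function(s, e) c(s + 1L, e)

# the ordered matchings list of one part, forward-strand 1-based inclusive
matchings_from_part <- function(p) {
  out <- list()
  add <- function(type, ts = NA, te = NA, qs = NA, qe = NA, extra = list()) {
    m <- list(type = type)
    if (!is.na(ts)) {
      fwd <- to_forward(ts, te, p$strand, p$contig_length)
      ob <- one_based(fwd[1L], fwd[2L])
      m$nucl_start <- ob[1L]; m$nucl_end <- ob[2L]
    }
    if (!is.na(qs) && qe > qs) { m$prot_start <- qs + 1L; m$prot_end <- qe }
    out[[length(out) + 1L]] <<- c(m, extra)
  }
  feats <- NULL
  ex <- p$exons
  for (k in seq_len(nrow(ex)))
    feats <- rbind(feats, data.frame(kind = "exon", idx = k,
                                     tstart = ex$tstart[k]))
  ir <- p$introns
  for (k in seq_len(nrow(ir)))
    feats <- rbind(feats, data.frame(kind = "intron", idx = k,
                                     tstart = ir$tstart[k]))
  if (!is.null(feats)) {
    feats <- feats[order(feats$tstart, feats$kind), , drop = FALSE]
    for (r in seq_len(nrow(feats))) {
      if (feats$kind[r] == "exon") {
        k <- feats$idx[r]
        add("exon", ex$tstart[k], ex$tend[k], ex$qstart[k], ex$qend[k])
      } else {
        k <- feats$idx[r]
        add(ir$status[k], ir$tstart[k], ir$tend[k],
            extra = list(donor = ir$donor[k], acceptor = ir$acceptor[k],
                         phase = ir$phase[k]))
      }
    }
  }
  gp <- p$gaps
  for (k in seq_len(nrow(gp)))
    add("gap", qs = gp$qstart[k], qe = gp$qend[k])
  out
}

part_doc <- function(p) {
  list(target = p$contig,
       strand = p$strand,
       matches = p$stats$matches,
       mismatches = p$stats$mismatches,
       matchings = matchings_from_part(p),
       mismatch_positions = as.integer(p$mismatches),
       frameshift_positions = as.integer(p$frameshifts),
       stop_positions = as.integer(p$stops))
}

result_doc <- function(x) {
  stopifnot(inherits(x, "pg_result"))
  docs <- lapply(x$queries, function(q) {
    res <- lapply(q$results, function(g) {
      list(targets = as.list(g$targets),
           score = round(g$stats$score, 6),
           identity = round(g$stats$identity, 6),
           coverage = round(g$stats$coverage, 6),
           parts = lapply(g$parts, part_doc))
    })
    d <- list(query = q$query_id, query_length = q$query_length,
              results = res)
    if (length(res) == 0L && !is.null(q$diagnostic))
      d$diagnostic <- q$diagnostic
    d
  })
  unname(docs)
}

#' Write mapping results as YAML
#'
#' One document entry per query, with the target(s), strand, statistics
#' and an ordered matchings list typed `exon` / `intron` / `intron?` /
#' `gap`, each with forward-strand 1-based inclusive nucleotide
#' coordinates and 1-based inclusive protein coordinates, plus mismatch /
#' frameshift / in-frame stop position lists.  Key order is fixed, so
#' identical results serialize byte-identically.
#'
#' @param x a `pg_result` from [map_protein()].
#' @param path output file; `NULL` returns the YAML text.
#' @return the YAML text, invisibly when written to a file.
#' @export
write_result_yaml <- function(x, path = NULL) {
  txt <- yaml::as.yaml(result_doc(x), indent = 2, precision = 12)
  if (is.null(path)) return(txt)
  writeLines(sub("\n$", "", txt), path)
  invisible(txt)
}

gff_escape <- function(s) gsub("[;=%&,\t\n]", "_", s)

# GFF3 CDS phase: nucleotides to skip to reach the first complete codon.
# After an intron of phase p the next exon starts with 3-p completing
# nucleotides, i.e. GFF phase (3-p) mod 3; the first exon has phase 0.
part_gff_lines <- function(p, gene_id) {
  ex <- p$exons
  if (nrow(ex) == 0L) return(character(0))
  ex <- ex[order(ex$tstart), , drop = FALSE]
  ir <- p$introns[order(p$introns$tstart), , drop = FALSE]
  phases <- integer(nrow(ex))
  cum <- 0L
  for (k in seq_len(nrow(ex))) {
    if (k == 1L) phases[k] <- 0L
    else {
      between <- which(ir$tstart >= ex$tend[k - 1L] & ir$tend <= ex$tstart[k])
      phases[k] <- if (length(between) == 1L)
        (3L - ir$phase[between]) %% 3L else (3L - cum %% 3L) %% 3L
    }
    cum <- cum + (ex$tend[k] - ex$tstart[k])
  }
  fwd <- t(vapply(seq_len(nrow(ex)), function(k)
    to_forward(ex$tstart[k], ex$tend[k], p$strand, p$contig_length),
    integer(2)))
  span <- c(min(fwd[, 1L]), max(fwd[, 2L]))
  src <- "pgalign"
  lines <- c(
    sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s", p$contig, src,
            span[1L] + 1L, span[2L], p$strand, gene_id),
    sprintf("%s\t%s\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s", p$contig,
            src, span[1L] + 1L, span[2L], p$strand, gene_id, gene_id))
  ord <- if (p$strand == "+") order(fwd[, 1L]) else order(-fwd[, 1L])
  for (k in ord)
    lines <- c(lines, sprintf(
      "%s\t%s\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds%d;Parent=%s.t1",
      p$contig, src, fwd[k, 1L] + 1L, fwd[k, 2L], p$strand, phases[k],
      gene_id, k, gene_id))
  lines
}

#' Write mapping results as GFF3
#'
#' Emits `gene` / `mRNA` / `CDS` features with 1-based inclusive
#' forward-strand coordinates and the CDS phase column derived from the
#' intron phases.  On the minus strand CDS lines are written in descending
#' coordinate order (translation order).  Cross-contig results yield one
#' gene feature per contig part, suffixed `.p1`, `.p2`, ...
#'
#' @param x a `pg_result` from [map_protein()].
#' @param path output file; `NULL` returns the GFF3 text.
#' @return the GFF3 text, invisibly when written to a file.
#' @export
write_gff <- function(x, path = NULL) {
  stopifnot(inherits(x, "pg_result"))
  lines <- "##gff-version 3"
  for (q in x$queries) {
    for (gi in seq_along(q$results)) {
      g <- q$results[[gi]]
      for (pi in seq_along(g$parts)) {
        gid <- gff_escape(sprintf("%s.g%d%s", q$query_id, gi,
                                  if (length(g$parts) > 1L)
                                    sprintf(".p%d", pi) else ""))
        lines <- c(lines, part_gff_lines(g$parts[[pi]], gid))
      }
    }
  }
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(lines, path)
  invisible(txt)
}

#' Write a fixture's truth in the result YAML schema
#'
#' Serializes the fixture's genome and protein as FASTA and its ground
#' truth gene structure using the same YAML schema [write_result_yaml()]
#' emits, so truth and pipeline output are directly comparable.
#'
#' @param fixture a [generate_gene()] fixture.
#' @param dir output directory (created if needed).
#' @param basename file stem; writes `<stem>.genome.fa`,
#'   `<stem>.protein.fa`, `<stem>.truth.yaml`.
#' @return the three paths, invisibly.
#' @export
write_fixture_files <- function(fixture, dir, basename = "fixture") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gp <- file.path(dir, paste0(basename, ".genome.fa"))
  pp <- file.path(dir, paste0(basename, ".protein.fa"))
  yp <- file.path(dir, paste0(basename, ".truth.yaml"))
  write_fasta_file(fixture$genome, gp)
  write_fasta_file(stats::setNames(fixture$protein, "query"), pp)
  res <- truth_as_result(fixture)
  write_result_yaml(res, yp)
  invisible(c(genome = gp, protein = pp, truth = yp))
}

# wrap a fixture's truth as a pg_result so the writers can serialize it
truth_as_result <- function(fixture) {
  clens <- stats::setNames(Biostrings::width(fixture$genome),
                           names(fixture$genome))
  parts <- list()
  for (ctg in unique(fixture$exons$contig)) {
    ex <- fixture$exons[fixture$exons$contig == ctg, , drop = FALSE]
    ir <- fixture$introns[fixture$introns$contig == ctg, , drop = FALSE]
    n_res <- sum(ex$qend - ex$qstart)
    parts[[length(parts) + 1L]] <- structure(list(
      query_id = "query", query_length = nchar(fixture$protein),
      contig = ctg, strand = fixture$strand %||% "+",
      contig_length = clens[[ctg]],
      exons = ex[, c("contig", "tstart", "tend", "qstart", "qend")],
      introns = ir[, c("contig", "tstart", "tend", "donor", "acceptor",
                       "phase", "status")],
      gaps = data.frame(qstart = integer(0), qend = integer(0)),
      mismatches = integer(0), frameshifts = integer(0),
      stops = integer(0),
      stats = list(matches = n_res, mismatches = 0,
                   score = n_res / nchar(fixture$protein), identity = 1,
                   coverage = n_res / nchar(fixture$protein)),
      segments = empty_stream()), class = "pg_part")
  }
  qlen <- nchar(fixture$protein)
  gs <- new_gene_structure(parts, qlen, pg_params())
  structure(list(queries = list(query = list(
    query_id = "query", query_length = qlen,
    results = list(gs), diagnostic = NULL)),
    params = pg_params(), contig_lengths = clens), class = "pg_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
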