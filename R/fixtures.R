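# Synthetic gene fixtures: genomes with known exon-intron structures, used to
# validate every pipeline stage without external downloads.  Generation is
# deterministic per seed; truth tables carry 0-based half-open coordinates.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

# reverse genetic code: residue -> codons
codons_for <- function(residue, table_id = 1) {
  gc <- codon_lookup(table_id)
  names(gc)[gc == residue]
}

random_protein <- function(len) paste(sample(AA20, len, replace = TRUE),
                                      collapse = "")

random_dna <- function(len, gc = 0.5) {
  if (len <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

# spell a protein as codons, one random synonymous codon per residue
spell_codons <- function(protein, table_id = 1) {
  vapply(strsplit(protein, "")[[1]],
         function(r) sample(codons_for(r, table_id), 1L), "",
         USE.NAMES = FALSE)
}

# build one intron of length len with the requested border dinucleotides.
# The interior is kept free of decoy splice dinucleotides near the true
# borders (no G in the 6 nt after the donor or the 6 nt before the
# acceptor), so fixtures have a unique optimal gene structure.
make_intron <- function(len, donor = "GT", acceptor = "AG", gc = 0.5) {
  stopifnot(len >= 8)
  interior <- strsplit(random_dna(len - 4L, gc), "")[[1]]
  ni <- length(interior)
  head_idx <- seq_len(min(6L, ni))
  tail_idx <- seq(max(1L, ni - 5L), ni)
  interior[head_idx][interior[head_idx] == "G"] <- "A"
  interior[tail_idx][interior[tail_idx] == "G"] <- "C"
  paste0(donor, paste(interior, collapse = ""), acceptor)
}

#' Generate a synthetic gene fixture
#'
#' Builds a genomic contig containing one gene with known structure: the
#' protein's codon spelling interleaved with introns of requested lengths,
#' border dinucleotides and phases, embedded in random flanking sequence.
#' The returned truth tables use 0-based half-open coordinates.  A phase-1
#' (phase-2) intron splits the last codon of the upstream exon after its
#' first (second) nucleotide.
#'
#' @param protein query protein as a string, or `NULL` to generate one of
#'   `protein_length` random residues.
#' @param protein_length length of the generated protein when `protein` is
#'   `NULL`.
#' @param exon_lengths integer vector of exon lengths in residues (must sum
#'   to the protein length); `NULL` for a random partition into
#'   `n_introns + 1` exons.
#' @param n_introns number of introns when `exon_lengths` is `NULL`.
#' @param intron_lengths integer vector of intron lengths in nucleotides
#'   (recycled), or `NULL` to sample from `intron_length_range`.
#' @param intron_length_range range introns are sampled from.
#' @param border_patterns 4-letter donor+acceptor patterns per intron,
#'   recycled (e.g. `c("GTAG", "GCAG", "ATAC")`).
#' @param phases intron phases (0, 1 or 2), recycled; `NULL` for random.
#' @param flank lengths of the 5' and 3' flanking sequence.
#' @param gc GC content of flanks and intron interiors.
#' @param table_id NCBI translation table identifier.
#' @param contig_name name of the generated contig.
#' @param seed RNG seed; generation is deterministic per seed.
#' @return An object of class `pg_fixture`: protein, genome
#'   (`DNAStringSet`), truth `exons` and `introns` tables, per-residue
#'   codon positions, and empty expected mismatch/frameshift/stop records.
#' @export
generate_gene <- function(protein = NULL, protein_length = 120L,
                          exon_lengths = NULL, n_introns = 2L,
                          intron_lengths = NULL,
                          intron_length_range = c(60L, 200L),
                          border_patterns = "GTAG", phases = NULL,
                          flank = c(300L, 300L), gc = 0.5, table_id = 1,
                          contig_name = "ctg1", seed = 1L) {
  with_seed(seed, {
    if (is.null(protein)) protein <- random_protein(protein_length)
    P <- nchar(protein)
    if (is.null(exon_lengths)) {
      k <- n_introns + 1L
      if (k == 1L) exon_lengths <- P
      else {
        if (P < 2L * k) stop("protein too short for that many exons")
        cuts <- sort(sample(seq_len(P - 1L), k - 1L))
        exon_lengths <- diff(c(0L, cuts, P))
      }
    }
    exon_lengths <- as.integer(exon_lengths)
    stopifnot(sum(exon_lengths) == P, all(exon_lengths >= 1L))
    ni <- length(exon_lengths) - 1L
    if (is.null(phases)) phases <- sample(0:2, max(ni, 1L), replace = TRUE)
    phases <- as.integer(rep_len(phases, max(ni, 1L)))[seq_len(ni)]
    borders <- rep_len(toupper(border_patterns), max(ni, 1L))[seq_len(ni)]
    if (is.null(intron_lengths) && ni > 0L)
      intron_lengths <- sample(seq(intron_length_range[1],
                                   intron_length_range[2]), ni,
                               replace = TRUE)
    intron_lengths <- if (ni > 0L)
      as.integer(rep_len(intron_lengths, ni)) else integer(0)

    codons <- spell_codons(protein, table_id)
    cds <- paste(codons, collapse = "")
    # nt offset within the CDS at which intron k is inserted
    R <- cumsum(exon_lengths)[seq_len(ni)]
    ins_at <- ifelse(phases == 0L, 3L * R, 3L * (R - 1L) + phases)

    left <- random_dna(flank[1], gc)
    pieces <- character(0); exon_t <- integer(0)
    introns <- data.frame(contig = character(0), tstart = integer(0),
                          tend = integer(0), donor = character(0),
                          acceptor = character(0), phase = integer(0),
                          status = character(0), stringsAsFactors = FALSE)
    exons <- data.frame(contig = character(0), tstart = integer(0),
                        tend = integer(0), qstart = integer(0),
                        qend = integer(0), stringsAsFactors = FALSE)
    pos <- nchar(left)           # 0-based genome cursor
    prev_cds <- 0L               # nt of CDS already emitted
    bounds <- c(ins_at, 3L * P)
    scheme <- pg_penalties()
    for (k in seq_len(ni + 1L)) {
      seg_cds <- substr(cds, prev_cds + 1L, bounds[k])
      exlen <- nchar(seg_cds)
      q0 <- prev_cds %/% 3L                      # first residue touched
      q1 <- (bounds[k] + 2L) %/% 3L              # last residue touched + 1
      exons <- rbind(exons, data.frame(
        contig = contig_name, tstart = pos, tend = pos + exlen,
        qstart = q0, qend = q1, stringsAsFactors = FALSE))
      pieces <- c(pieces, seg_cds)
      pos <- pos + exlen
      prev_cds <- bounds[k]
      if (k <= ni) {
        donor <- substr(borders[k], 1, 2); acc <- substr(borders[k], 3, 4)
        iseq <- make_intron(intron_lengths[k], donor, acc, gc)
        introns <- rbind(introns, data.frame(
          contig = contig_name, tstart = pos, tend = pos + nchar(iseq),
          donor = donor, acceptor = acc, phase = phases[k],
          status = classify_intron(donor, acc, scheme),
          stringsAsFactors = FALSE))
        pieces <- c(pieces, iseq)
        pos <- pos + nchar(iseq)
      }
    }
    right <- random_dna(flank[2], gc)
    genome_seq <- paste0(left, paste(pieces, collapse = ""), right)

    # per-residue genome positions of the three codon nucleotides
    codon_pos <- matrix(NA_integer_, P, 3L)
    cds_to_genome <- integer(3L * P)
    cur <- nchar(left); cdsi <- 0L
    for (k in seq_len(ni + 1L)) {
      seg_len <- bounds[k] - (if (k == 1L) 0L else bounds[k - 1L])
      if (seg_len > 0L)
        cds_to_genome[(cdsi + 1L):(cdsi + seg_len)] <- cur + seq_len(seg_len) - 1L
      cur <- cur + seg_len
      cdsi <- cdsi + seg_len
      if (k <= ni) cur <- cur + intron_lengths[k]
    }
    codon_pos <- matrix(cds_to_genome, ncol = 3L, byrow = TRUE)

    genome <- Biostrings::DNAStringSet(setNames(genome_seq, contig_name))
    structure(list(protein = protein, genome = genome,
                   exons = exons, introns = introns,
                   codon_pos = codon_pos,
                   expected_mismatches = integer(0),
                   expected_frameshifts = integer(0),
                   expected_stops = integer(0),
                   expected_gaps = integer(0),
                   table_id = table_id, seed = seed),
              class = "pg_fixture")
  })
}

#' @export
print.pg_fixture <- function(x, ...) {
  cat(sprintf("Synthetic gene fixture: %d aa protein, %d exon(s), %d intron(s), %d contig(s)\n",
              nchar(x$protein), nrow(x$exons), nrow(x$introns),
              length(x$genome)))
  invisible(x)
}

# shift all truth coordinates at or beyond `at` on contig `ctg` by delta
shift_fixture <- function(fx, ctg, at, delta) {
  bump <- function(v) ifelse(v >= at, v + delta, v)
  sel <- fx$exons$contig == ctg
  fx$exons$tstart[sel] <- bump(fx$exons$tstart[sel])
  fx$exons$tend[sel] <- ifelse(fx$exons$tend[sel] > at,
                               fx$exons$tend[sel] + delta,
                               fx$exons$tend[sel])
  sel <- fx$introns$contig == ctg
  fx$introns$tstart[sel] <- bump(fx$introns$tstart[sel])
  fx$introns$tend[sel] <- bump(fx$introns$tend[sel])
  fx$codon_pos[fx$codon_pos >= at] <- fx$codon_pos[fx$codon_pos >= at] + delta
  fx
}

#' Apply sequence divergence to a fixture genome
#'
#' Emulates cross-species divergence: amino-acid substitutions are written
#' into the genome's codons (the query protein is unchanged, so each
#' substituted codon becomes an expected mismatch), and optional in-frame
#' insertions of extra coding sequence are placed at codon boundaries
#' inside exons.  Insertions shorter than the minimum intron length and
#' free of in-frame stops are expected to be absorbed into the exon.
#'
#' @param fixture a [generate_gene()] fixture (single contig, undiverged).
#' @param aa_substitution_rate per-residue probability of substituting the
#'   genomic codon by a codon of a different amino acid.
#' @param insertions data frame with columns `after_residue` (1-based, the
#'   insertion goes after this residue's codon) and `len` (nucleotides,
#'   multiple of 3 for in-frame insertions).
#' @param seed RNG seed.
#' @return the modified fixture with updated truth records.
#' @export
apply_divergence <- function(fixture, aa_substitution_rate = 0,
                             insertions = NULL, seed = 1L) {
  with_seed(seed, {
    fx <- fixture
    ctg <- names(fx$genome)[1]
    g <- strsplit(as.character(fx$genome[[1]]), "")[[1]]
    P <- nchar(fx$protein)
    if (aa_substitution_rate > 0) {
      hit <- which(stats::runif(P) < aa_substitution_rate)
      for (r in hit) {
        old <- substr(fx$protein, r, r)
        new_aa <- sample(setdiff(AA20, old), 1L)
        codon <- sample(codons_for(new_aa, fx$table_id), 1L)
        g[fx$codon_pos[r, ] + 1L] <- strsplit(codon, "")[[1]]
      }
      fx$expected_mismatches <- sort(union(fx$expected_mismatches, hit))
    }
    fx$genome <- Biostrings::DNAStringSet(setNames(paste(g, collapse = ""), ctg))
    if (!is.null(insertions) && nrow(insertions)) {
      for (k in order(-insertions$after_residue)) {
        r <- insertions$after_residue[k]; len <- insertions$len[k]
        at <- fx$codon_pos[r, 3] + 1L          # 0-based insert position
        ins <- if (len %% 3L == 0L) {
          paste(sample(setdiff(names(codon_lookup(fx$table_id)),
                               names(which(codon_lookup(fx$table_id) == "*"))),
                       len %/% 3L, replace = TRUE), collapse = "")
        } else random_dna(len)
        gs <- as.character(fx$genome[[1]])
        fx$genome <- Biostrings::DNAStringSet(setNames(
          paste0(substr(gs, 1L, at), ins, substr(gs, at + 1L, nchar(gs))),
          ctg))
        fx <- shift_fixture(fx, ctg, at, len)
      }
    }
    fx
  })
}

#' Inject sequencing-error artefacts into a fixture
#'
#' Places single-nucleotide insertions (frameshifts) at codon boundaries
#' inside exons and substitutes codons by in-frame stop codons, recording
#' the affected residue positions in the truth.
#'
#' @param fixture a single-contig fixture.
#' @param n_frameshifts number of 1-nt insertions to place.
#' @param n_inframe_stops number of codons to turn into `TAA`.
#' @param seed RNG seed.
#' @return the modified fixture.
#' @export
inject_errors <- function(fixture, n_frameshifts = 0L, n_inframe_stops = 0L,
                          seed = 1L) {
  with_seed(seed, {
    fx <- fixture
    ctg <- names(fx$genome)[1]
    P <- nchar(fx$protein)
    # candidate residues safely interior to an exon (whole codon inside)
    interior <- which(vapply(seq_len(P), function(r) {
      p <- fx$codon_pos[r, ]
      any(fx$exons$tstart <= p[1] & p[3] < fx$exons$tend &
            fx$exons$contig == ctg) && all(diff(p) == 1L)
    }, logical(1)))
    if (n_inframe_stops > 0L) {
      picks <- sample(interior, n_inframe_stops)
      g <- strsplit(as.character(fx$genome[[1]]), "")[[1]]
      for (r in picks) g[fx$codon_pos[r, ] + 1L] <- c("T", "A", "A")
      fx$genome <- Biostrings::DNAStringSet(setNames(paste(g, collapse = ""), ctg))
      fx$expected_stops <- sort(union(fx$expected_stops, picks))
      interior <- setdiff(interior, picks)
    }
    if (n_frameshifts > 0L) {
      picks <- sort(sample(interior, n_frameshifts), decreasing = TRUE)
      for (r in picks) {
        at <- fx$codon_pos[r, 3] + 1L
        gs <- as.character(fx$genome[[1]])
        fx$genome <- Biostrings::DNAStringSet(setNames(
          paste0(substr(gs, 1L, at), sample(c("A","C","G","T"), 1L),
                 substr(gs, at + 1L, nchar(gs))), ctg))
        fx <- shift_fixture(fx, ctg, at, 1L)
      }
      fx$expected_frameshifts <- sort(union(fx$expected_frameshifts,
                                            rev(picks)))
    }
    fx
  })
}

#' Fragment a fixture genome into several contigs
#'
#' Cuts the genome at the given positions (typically inside introns),
#' optionally padding the new contig ends with random filler sequence to
#' inflate the intron length implied when the gene is later reassembled
#' across contigs.  Truth records are remapped to per-contig coordinates;
#' introns spanning a cut are removed from the intron table (their two
#' sides become contig ends) but counted in `n_introns_total`.
#'
#' @param fixture a single-contig fixture.
#' @param breakpoints 0-based genome positions to cut at.
#' @param pad filler length added on both sides of each cut (recycled).
#' @param seed RNG seed for the filler sequence.
#' @return the fixture with a multi-contig genome and remapped truth.
#' @export
fragment_into_contigs <- function(fixture, breakpoints, pad = 0L, seed = 1L) {
  if (length(breakpoints) == 0L) return(fixture)
  with_seed(seed, {
    fx <- fixture
    n_total <- nrow(fx$introns)
    gs <- as.character(fx$genome[[1]])
    L <- nchar(gs)
    bp <- sort(as.integer(breakpoints))
    pad <- rep_len(as.integer(pad), length(bp))
    starts <- c(0L, bp); ends <- c(bp, L)
    contigs <- character(length(starts))
    names_new <- sprintf("%s_part%d", names(fx$genome)[1], seq_along(starts))
    exons <- fx$exons[0, ]; introns <- fx$introns[0, ]
    for (k in seq_along(starts)) {
      seg <- substr(gs, starts[k] + 1L, ends[k])
      lpad <- if (k > 1L) pad[k - 1L] else 0L
      rpad <- if (k <= length(bp)) pad[k] else 0L
      contigs[k] <- paste0(random_dna(lpad), seg, random_dna(rpad))
      remap <- function(df) {
        sel <- df$tstart >= starts[k] & df$tend <= ends[k]
        out <- df[sel, , drop = FALSE]
        if (nrow(out)) {
          out$contig <- names_new[k]
          out$tstart <- out$tstart - starts[k] + lpad
          out$tend <- out$tend - starts[k] + lpad
        }
        out
      }
      exons <- rbind(exons, remap(fx$exons))
      introns <- rbind(introns, remap(fx$introns))
    }
    fx$genome <- Biostrings::DNAStringSet(setNames(contigs, names_new))
    fx$exons <- exons
    fx$introns <- introns
    fx$n_introns_total <- n_total
    fx$codon_pos <- NULL    # no longer meaningful across contigs
    fx
  })
}

#' Reverse-complement a single-contig fixture
#'
#' Returns the fixture with its contig reverse-complemented and the truth
#' coordinates flipped to the new forward strand; used to exercise
#' minus-strand mapping.
#'
#' @param fixture a single-contig fixture.
#' @return the flipped fixture (exons ordered by new coordinates).
#' @export
reverse_complement_fixture <- function(fixture) {
  fx <- fixture
  L <- Biostrings::width(fx$genome)[1]
  fx$genome <- Biostrings::reverseComplement(fx$genome)
  names(fx$genome) <- names(fixture$genome)
  flip <- function(df) {
    if (!nrow(df)) return(df)
    s <- L - df$tend; e <- L - df$tstart
    df$tstart <- s; df$tend <- e
    df[order(df$tstart), , drop = FALSE]
  }
  fx$exons <- flip(fx$exons)
  fx$introns <- flip(fx$introns)
  if (nrow(fx$introns)) {
    # borders read on the minus strand stay as annotated; record them
    fx$introns <- fx$introns[, ]
  }
  fx$codon_pos <- NULL
  fx$strand <- "-"
  fx
}

#' The reference fixture panel
#'
#' A deterministic panel of 25 synthetic genes spanning the conditions the
#' pipeline is designed for: 1-12 exons per gene, exon sizes from 1 to 300
#' residues including internal micro-exons of 1-4 and short exons of 5-7
#' residues, intron lengths 22-500 nt, GT--AG and GC--AG borders, and all
#' three intron phases.  Used by the validation suite both undiverged and
#' under amino-acid substitution.
#'
#' @param seed base RNG seed; each panel member derives its own seed.
#' @return list of 25 [generate_gene()] fixtures.
#' @export
fixture_panel <- function(seed = 1L) {
  lapply(seq_len(25L), function(i) {
    n_ex <- ((i - 1L) %% 12L) + 1L
    fs <- (seed - 1L) * 101L + i
    sizes <- with_seed(fs * 7L + 3L, {
      s <- sample(25:90, n_ex, replace = TRUE)
      s[1] <- sample(30:120, 1L)                       # terminal exons
      s[n_ex] <- sample(30:120, 1L)
      if (i %% 4L == 1L) s[sample(n_ex, 1L)] <- sample(150:300, 1L)
      if (n_ex >= 3L) {
        internal <- 2:(n_ex - 1L)
        if (i %% 5L == 0L)            # micro-exon, 1-4 aa
          s[sample(internal, 1L)] <- ((i %/% 5L - 1L) %% 4L) + 1L
        else if (i %% 5L == 2L)       # short exon, 5-7 aa
          s[sample(internal, 1L)] <- sample(5:7, 1L)
      }
      s
    })
    borders <- rep_len(c("GTAG", "GTAG", "GCAG"), max(n_ex - 1L, 1L))
    phases <- rep_len(0:2, max(n_ex - 1L, 1L))
    generate_gene(protein_length = sum(sizes), exon_lengths = sizes,
                  intron_length_range = c(22L, 500L),
                  border_patterns = borders, phases = phases,
                  flank = c(250L, 250L),
                  contig_name = sprintf("ctg%02d", i), seed = fs)
  })
}
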