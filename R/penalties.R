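#' Penalty scheme for spliced alignment
#'
#' Bundles the penalty constants of the spliced Needleman-Wunsch model: the
#' match/mismatch penalty for a residue against a codon, the insertion penalty
#' (query residue with no target), the gap penalty (target codon with no
#' residue), the frameshift penalty (1-2 stray nucleotides), the constant
#' intron penalty, and splice-site penalty tables for donor and acceptor
#' dinucleotides.  An intron scores `intron + donor[d] + acceptor[a]`; with
#' the default tables GT--AG introns add nothing and GC--AG adds 0.25, so at
#' the default `accepted_intron_penalty` of 0.25 exactly GT--AG and GC--AG
#' are classified as clean introns and everything else as doubtful
#' (`"intron?"`).
#'
#' @param mismatch penalty for a residue aligned to a codon that translates
#'   to a different amino acid (default 1.0).  Stop codons and codons
#'   containing `N` always count as mismatches.
#' @param insertion penalty for a query residue with no target counterpart
#'   (default 1.5).
#' @param gap penalty for an extra target codon with no query residue
#'   (default 1.1).
#' @param frameshift penalty for 1 or 2 stray target nucleotides outside any
#'   codon (default 2.5).
#' @param intron constant penalty per intron (default 2.0), to which the
#'   donor and acceptor splice-site penalties are added.
#' @param donor,acceptor named numeric vectors of splice-site penalties per
#'   border dinucleotide; the `"default"` entry applies to unlisted
#'   dinucleotides.  `donor["GT"]` and `acceptor["AG"]` must be exactly 0.
#' @param min_intron_len minimum length, in nucleotides, for a target run to
#'   be scored as an intron rather than as insertions/frameshifts
#'   (default 22).
#' @param accepted_intron_penalty threshold on `donor + acceptor` penalty
#'   below or at which an intron is reported as `"intron"`; above it the
#'   status is the doubtful `"intron?"` (default 0.25).
#' @return An object of class `pg_penalties`.
#' @examples
#' sch <- pg_penalties()
#' intron_penalty(paste0("GT", strrep("A", 18), "AG"), sch)  # 2.0
#' @export
pg_penalties <- function(mismatch = 1.0, insertion = 1.5, gap = 1.1,
                         frameshift = 2.5, intron = 2.0,
                         donor = c(GT = 0, GC = 0.25, AT = 0.75, default = 1.0),
                         acceptor = c(AG = 0, AC = 0.75, default = 1.0),
                         min_intron_len = 22L,
                         accepted_intron_penalty = 0.25) {
  vals <- c(mismatch = mismatch, insertion = insertion, gap = gap,
            frameshift = frameshift, intron = intron,
            accepted_intron_penalty = accepted_intron_penalty)
  if (any(vals < 0) || any(donor < 0) || any(acceptor < 0))
    stop("all penalties must be non-negative")
  if (is.null(donor["default"]) || is.na(donor["default"]))
    stop("donor table needs a 'default' entry")
  if (is.null(acceptor["default"]) || is.na(acceptor["default"]))
    stop("acceptor table needs a 'default' entry")
  if (!isTRUE(donor[["GT"]] == 0))
    stop("donor penalty for GT must be exactly 0")
  if (!isTRUE(acceptor[["AG"]] == 0))
    stop("acceptor penalty for AG must be exactly 0")
  min_intron_len <- as.integer(min_intron_len)
  # an intron must at least carry its donor and acceptor dinucleotides
  if (min_intron_len < 2L)
    stop("min_intron_len must be >= 2")
  structure(list(mismatch = mismatch, insertion = insertion, gap = gap,
                 frameshift = frameshift, intron = intron,
                 donor = donor, acceptor = acceptor,
                 min_intron_len = min_intron_len,
                 accepted_intron_penalty = accepted_intron_penalty),
            class = "pg_penalties")
}

#' @export
print.pg_penalties <- function(x, ...) {
  cat("Spliced-alignment penalty scheme\n")
  cat(sprintf("  mismatch %.2f  insertion %.2f  gap %.2f  frameshift %.2f  intron %.2f\n",
              x$mismatch, x$insertion, x$gap, x$frameshift, x$intron))
  cat(sprintf("  min intron length %d nt, accepted splice penalty <= %.2f\n",
              x$min_intron_len, x$accepted_intron_penalty))
  cat("  donor:   ", paste(names(x$donor), x$donor, sep = "=", collapse = "  "), "\n")
  cat("  acceptor:", paste(names(x$acceptor), x$acceptor, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

dinuc_penalty <- function(table, dinuc) {
  v <- table[dinuc]
  v[is.na(v)] <- table[["default"]]
  unname(v)
}

#' Splice-site penalty of a donor dinucleotide
#'
#' @param dinuc character vector of dinucleotides (first two intron
#'   nucleotides for donors, last two for acceptors).
#' @param scheme a [pg_penalties()] scheme.
#' @return numeric penalties.
#' @export
donor_penalty <- function(dinuc, scheme = pg_penalties())
  dinuc_penalty(scheme$donor, toupper(dinuc))

#' @rdname donor_penalty
#' @export
acceptor_penalty <- function(dinuc, scheme = pg_penalties())
  dinuc_penalty(scheme$acceptor, toupper(dinuc))

# codon lookup tables, one per translation table id, cached per session.
# Codons containing N (or any non-ACGT letter) translate to "X" (unknown).
codon_table_cache <- new.env(parent = emptyenv())

codon_lookup <- function(table_id = 1) {
  key <- as.character(table_id)
  if (!is.null(codon_table_cache[[key]])) return(codon_table_cache[[key]])
  gc <- tryCatch(Biostrings::getGeneticCode(key),
                 error = function(e) stop("unsupported translation table: ",
                                          table_id, call. = FALSE))
  codon_table_cache[[key]] <- gc
  gc
}

#' Translate a codon under an NCBI genetic code
#'
#' Returns the single-letter amino acid, `"*"` for stop codons, and `"X"`
#' for codons containing `N` or other ambiguity letters (assemblies contain
#' N runs; translation must not fail on them).
#'
#' @param codon character vector of 3-letter codons over `A,C,G,T,N`.
#' @param table_id NCBI translation table identifier (default 1, standard).
#' @return character vector of residues (`"*"` = stop, `"X"` = unknown).
#' @examples
#' translate_codon(c("ATG", "TAA", "ANG"))  # "M" "*" "X"
#' @export
translate_codon <- function(codon, table_id = 1) {
  gc <- codon_lookup(table_id)
  codon <- toupper(codon)
  if (any(nchar(codon) != 3L)) stop("codons must have length 3")
  out <- unname(gc[codon])
  out[is.na(out)] <- "X"
  out
}

#' Match/mismatch penalty of a residue against a codon
#'
#' Zero when the codon translates exactly to the residue; the scheme's
#' mismatch penalty otherwise.  Stop codons and codons containing `N` always
#' score as mismatches (stops are additionally flagged in pipeline results,
#' not forbidden by the alignment).
#'
#' @param residue single-letter amino acid(s).
#' @param codon 3-letter codon(s).
#' @param scheme a [pg_penalties()] scheme.
#' @param table_id NCBI translation table identifier.
#' @return numeric penalties (0 or `scheme$mismatch`).
#' @export
match_penalty <- function(residue, codon, scheme = pg_penalties(),
                          table_id = 1) {
  aa <- translate_codon(codon, table_id)
  ifelse(aa == toupper(residue) & aa != "*" & aa != "X", 0, scheme$mismatch)
}

#' Penalty of a candidate intron sequence
#'
#' `intron + donor(first two nt) + acceptor(last two nt)`, or `NA` when the
#' sequence is shorter than the scheme's minimum intron length (in which
#' case the region cannot be scored as an intron at all).
#'
#' @param intron_seq character vector of nucleotide strings.
#' @param scheme a [pg_penalties()] scheme.
#' @return numeric penalties, `NA` where the sequence is too short.
#' @export
intron_penalty <- function(intron_seq, scheme = pg_penalties()) {
  intron_seq <- toupper(intron_seq)
  len <- nchar(intron_seq)
  don <- donor_penalty(substr(intron_seq, 1L, 2L), scheme)
  acc <- acceptor_penalty(substr(intron_seq, len - 1L, len), scheme)
  ifelse(len < scheme$min_intron_len, NA_real_, scheme$intron + don + acc)
}

#' Classify an intron as clean or doubtful
#'
#' An intron whose combined donor+acceptor splice penalty is at most
#' `accepted_intron_penalty` is reported as `"intron"`; otherwise as the
#' doubtful `"intron?"`.  Raising the threshold admits further border
#' patterns (e.g. AT--AC).
#'
#' @param donor,acceptor border dinucleotides (character vectors).
#' @param scheme a [pg_penalties()] scheme.
#' @return character vector, `"intron"` or `"intron?"`.
#' @examples
#' classify_intron("GT", "AG")               # "intron"
#' classify_intron("AT", "AC")               # "intron?"
#' @export
classify_intron <- function(donor, acceptor, scheme = pg_penalties()) {
  pen <- donor_penalty(donor, scheme) + acceptor_penalty(acceptor, scheme)
  ifelse(pen <= scheme$accepted_intron_penalty, "intron", "intron?")
}

# ---- parses -----------------------------------------------------------------

#' Build a parse segment
#'
#' A parse decomposes an aligned query/target pair into ordered segment
#' pairs; each segment has one of six categories: `codon_match` (residue vs
#' codon), `insertion` (residue vs nothing), `gap` (nothing vs codon),
#' `frameshift` (0-1 residues vs 1-2 nucleotides), `intron` (nothing vs a
#' run of at least `min_intron_len` nucleotides), and `split_codon_intron`
#' (a residue whose codon is interrupted by an intron after the first or
#' second nucleotide).
#'
#' @param category segment category, see above.
#' @param query query fragment (residues).
#' @param target target fragment (nucleotides); for `split_codon_intron`
#'   this is the codon with the intron sequence inserted.
#' @param intron intron subsequence (only for `split_codon_intron`).
#' @param split 1 or 2: codon nucleotides preceding the intron (only for
#'   `split_codon_intron`).
#' @return a one-row data frame; rbind rows to form a parse.
#' @export
parse_segment <- function(category, query = "", target = "", intron = "",
                          split = NA_integer_) {
  stopifnot(category %in% c("codon_match", "insertion", "gap", "frameshift",
                            "intron", "split_codon_intron"))
  data.frame(category = category, query = query, target = target,
             intron = intron, split = as.integer(split),
             stringsAsFactors = FALSE)
}

segment_valid <- function(seg, scheme) {
  ql <- nchar(seg$query); tl <- nchar(seg$target); il <- nchar(seg$intron)
  switch(seg$category,
    codon_match = ql == 1L && tl == 3L,
    insertion   = ql == 1L && tl == 0L,
    gap         = ql == 0L && tl == 3L,
    frameshift  = tl %in% c(1L, 2L) && ql %in% c(0L, 1L),
    intron      = ql == 0L && tl >= scheme$min_intron_len,
    split_codon_intron = {
      sp <- seg$split
      ql == 1L && !is.na(sp) && sp %in% c(1L, 2L) &&
        il >= scheme$min_intron_len && tl == 3L + il &&
        identical(seg$target,
                  paste0(substr(seg$target, 1L, sp), seg$intron,
                         substr(seg$target, sp + il + 1L, tl)))
    },
    FALSE)
}

segment_penalty <- function(seg, scheme, table_id = 1) {
  switch(seg$category,
    codon_match = match_penalty(seg$query, seg$target, scheme, table_id),
    insertion   = scheme$insertion,
    gap         = scheme$gap,
    frameshift  = scheme$frameshift,
    intron      = intron_penalty(seg$target, scheme),
    split_codon_intron = {
      sp <- seg$split; il <- nchar(seg$intron)
      codon <- paste0(substr(seg$target, 1L, sp),
                      substr(seg$target, sp + il + 1L, nchar(seg$target)))
      intron_penalty(seg$intron, scheme) +
        match_penalty(seg$query, codon, scheme, table_id)
    })
}

#' Total cost of a parse
#'
#' Sums the per-segment penalties of a parse (a data frame of
#' [parse_segment()] rows); returns `NA` if any segment violates its
#' category's shape constraints (an invalid parse has no defined cost).
#'
#' @param parse data frame of parse segments.
#' @param scheme a [pg_penalties()] scheme.
#' @param table_id NCBI translation table identifier.
#' @return the summed penalty, or `NA` for an invalid parse.
#' @export
parse_cost <- function(parse, scheme = pg_penalties(), table_id = 1) {
  if (is.null(parse) || nrow(parse) == 0L) return(0)
  total <- 0
  for (k in seq_len(nrow(parse))) {
    seg <- parse[k, , drop = FALSE]
    if (!segment_valid(seg, scheme)) return(NA_real_)
    p <- segment_penalty(seg, scheme, table_id)
    if (is.na(p)) return(NA_real_)
    total <- total + p
  }
  total
}
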