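#' DNA sequence with optional TSS-relative register
#'
#' Light container for a promoter or probe sequence. Coordinates inside the
#' package are 1-based inclusive; when `tss_offset` is given it is the
#' TSS-relative coordinate of base 1 under the biology convention that there
#' is no position 0 (... -2, -1, +1, +2 ...).
#'
#' @param bases Character scalar over the alphabet A/C/G/T (case-insensitive).
#' @param name Sequence name.
#' @param tss_offset Optional integer (never 0): TSS-relative coordinate of
#'   the first base.
#' @return An object of class `dna_sequence`.
#' @export
dna_sequence <- function(bases, name = "seq", tss_offset = NULL) {
  stopifnot(is.character(bases), length(bases) == 1L)
  bases <- toupper(bases)
  if (nchar(bases) == 0L) stop("empty sequence")
  if (grepl("[^ACGT]", bases)) stop("invalid alphabet: bases must be A/C/G/T")
  if (!is.null(tss_offset)) {
    tss_offset <- as.integer(tss_offset)
    if (tss_offset == 0L) stop("TSS convention has no position 0")
  }
  structure(list(name = name, bases = bases, tss_offset = tss_offset),
            class = "dna_sequence")
}

as_bases <- function(seq) {
  if (inherits(seq, "dna_sequence")) seq$bases else dna_sequence(seq)$bases
}

#' Reverse complement of a sequence
#' @param seq `dna_sequence` or character scalar.
#' @return Character scalar.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(as_bases(seq))))
}

is_palindromic_motif <- function(motif) {
  nchar(motif) %% 2L == 0L && identical(revcomp(motif), toupper(motif))
}

#' Scan a sequence for all occurrences of a motif
#'
#' Finds every occurrence (overlaps allowed), 1-based inclusive, sorted by
#' start. The canonical TTAA operator core is self-reverse-complementary, so
#' a single-strand scan already covers both strands; for non-palindromic
#' motifs the reverse strand is scanned too and hits are reported in
#' top-strand coordinates with a `strand` column.
#'
#' @param seq `dna_sequence` or character scalar.
#' @param motif Motif string (default "TTAA").
#' @return data.frame with columns start, end, center, motif, strand.
#' @export
scan_motif <- function(seq, motif = "TTAA") {
  bases <- as_bases(seq)
  motif <- toupper(motif)
  if (nchar(motif) == 0L) stop("empty motif")
  if (grepl("[^ACGT]", motif)) stop("invalid alphabet in motif")
  n <- nchar(bases); m <- nchar(motif)
  hit_starts <- function(subject, pat) {
    if (nchar(subject) < nchar(pat)) return(integer(0))
    Biostrings::start(Biostrings::matchPattern(pat, Biostrings::DNAString(subject)))
  }
  fwd <- hit_starts(bases, motif)
  hits <- data.frame(start = fwd, strand = rep("+", length(fwd)))
  if (!is_palindromic_motif(motif)) {
    rev_hits <- hit_starts(bases, revcomp(motif))
    hits <- rbind(hits, data.frame(start = rev_hits,
                                   strand = rep("-", length(rev_hits))))
  }
  hits <- hits[order(hits$start), , drop = FALSE]
  data.frame(start = hits$start,
             end = hits$start + m - 1L,
             center = hits$start + (m - 1) / 2,
             motif = rep(motif, nrow(hits)),
             strand = hits$strand,
             row.names = NULL)
}

#' Find paired operator sites (motif-N<spacer>-motif)
#'
#' Enumerates all pairs of motif hits separated by exactly `spacer`
#' intervening nucleotides. For TTAA with spacer 7 this is the 15-nt
#' TTAA-N7-TTAA operator.
#'
#' @param seq `dna_sequence` or character scalar.
#' @param motif Motif string.
#' @param spacer Exact number of nucleotides between first.end and
#'   second.start (default 7).
#' @return data.frame: first_start, first_end, second_start, second_end,
#'   spacer, span, center_distance.
#' @export
find_paired_sites <- function(seq, motif = "TTAA", spacer = 7L) {
  hits <- scan_motif(seq, motif)
  out <- list()
  if (nrow(hits) >= 2L) {
    for (i in seq_len(nrow(hits) - 1L)) for (j in (i + 1L):nrow(hits)) {
      sp <- hits$start[j] - hits$end[i] - 1L
      if (sp == spacer) {
        out[[length(out) + 1L]] <- data.frame(
          first_start = hits$start[i], first_end = hits$end[i],
          second_start = hits$start[j], second_end = hits$end[j],
          spacer = sp,
          span = hits$end[j] - hits$start[i] + 1L,
          center_distance = hits$center[j] - hits$center[i])
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(first_start = integer(0), first_end = integer(0),
                      second_start = integer(0), second_end = integer(0),
                      spacer = integer(0), span = integer(0),
                      center_distance = numeric(0)))
  do.call(rbind, out)
}

#' Inclusive length of a TSS-relative span
#'
#' Promoter coordinates skip zero, so a span crossing the TSS is one shorter
#' than naive subtraction suggests: (-120, +17) covers 137 bp.
#'
#' @param start,end TSS-relative coordinates, start <= end, neither 0.
#' @return Integer length in bp.
#' @export
tss_span_length <- function(start, end) {
  if (start == 0 || end == 0) stop("TSS convention has no position 0")
  if (start > end) stop("start must precede end in promoter order")
  len <- end - start + 1L
  if (start < 0 && end > 0) len <- len - 1L
  as.integer(len)
}

#' Test whether a site is an (almost perfect) direct repeat
#'
#' Anchored on the two TTAA cores of a paired site, compares 8-nt windows
#' holding the motif at the same relative offset in both copies; the site is
#' called a direct repeat when some alignment has at most `max_mismatch`
#' mismatches. The <= 2 tolerance operationalizes "almost perfect" and is a
#' documented heuristic.
#'
#' @param site `dna_sequence` or character scalar, length >= 16.
#' @param motif Anchor motif (default "TTAA").
#' @param unit_length Repeat-unit window length (default 8).
#' @param max_mismatch Maximum mismatches tolerated (default 2).
#' @return list(is_repeat, unit1, unit2, mismatches, offset).
#' @export
direct_repeat_check <- function(site, motif = "TTAA", unit_length = 8L,
                                max_mismatch = 2L) {
  bases <- as_bases(site)
  if (nchar(bases) < 16L) stop("site too short for repeat analysis")
  hits <- scan_motif(bases, motif)
  best <- list(is_repeat = FALSE, unit1 = NA_character_, unit2 = NA_character_,
               mismatches = NA_integer_, offset = NA_integer_)
  if (nrow(hits) < 2L) return(best)
  m <- nchar(motif)
  for (i in seq_len(nrow(hits) - 1L)) for (j in (i + 1L):nrow(hits)) {
    for (off in 0:(unit_length - m)) {
      a <- hits$start[i] - off; b <- hits$start[j] - off
      if (a < 1L || b + unit_length - 1L > nchar(bases)) next
      u1 <- substr(bases, a, a + unit_length - 1L)
      u2 <- substr(bases, b, b + unit_length - 1L)
      mm <- sum(strsplit(u1, "")[[1]] != strsplit(u2, "")[[1]])
      if (is.na(best$mismatches) || mm < best$mismatches)
        best <- list(is_repeat = mm <= max_mismatch, unit1 = u1, unit2 = u2,
                     mismatches = mm, offset = off)
    }
  }
  best
}
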