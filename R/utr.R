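#' uORF detection rule
#'
#' Operational definition of an upstream open reading frame start: a
#' near-cognate start codon in the 5'-UTR (AUG/CUG/GUG/UUG/ACG by
#' default) in adequate Kozak context — a purine (A/G) at position -3 and
#' a guanine at position +4, numbering the first base of the codon as +1.
#' UTRs shorter than `min_utr_length` (default 13 nt) are excluded from
#' feature analysis, since start codons that close to the cap initiate
#' inefficiently.
#'
#' @param start_codons Character vector of accepted start trinucleotides
#'   (RNA alphabet).
#' @param minus3_allowed Accepted bases at -3.
#' @param plus4_required Required base at +4.
#' @param min_utr_length Minimum UTR length for inclusion, nucleotides.
#' @return An object of class `uorf_rule`.
#' @export
uorf_rule <- function(start_codons = c("AUG", "CUG", "GUG", "UUG", "ACG"),
                      minus3_allowed = c("A", "G"),
                      plus4_required = "G",
                      min_utr_length = 13L) {
  if (!length(start_codons) || any(nchar(start_codons) != 3L)) {
    stop("uorf_rule: start codons must be non-empty trinucleotides")
  }
  if (!length(minus3_allowed) || length(plus4_required) != 1L) {
    stop("uorf_rule: context sets must be non-empty")
  }
  structure(list(start_codons = toupper(chartr("T", "U", start_codons)),
                 minus3_allowed = toupper(chartr("T", "U", minus3_allowed)),
                 plus4_required = toupper(chartr("T", "U", plus4_required)),
                 min_utr_length = as.integer(min_utr_length)),
            class = "uorf_rule")
}

# uppercase RNA alphabet; accepts T or U, case-insensitive
normalize_rna <- function(seq) {
  s <- chartr("t", "u", toupper(seq))
  s <- chartr("T", "U", s)
  bad <- gsub("[ACGUN]", "", s)
  if (any(nzchar(bad))) {
    stop("invalid nucleotide character(s): ",
         paste(unique(strsplit(paste(bad, collapse = ""), "")[[1]]),
               collapse = ""))
  }
  s
}

#' Extract the 5'-UTR from a transcript record
#'
#' Returns the bases upstream of the main start codon (positions 1 to
#' `cds_start - 1`), normalised to the uppercase RNA alphabet (T -> U).
#' `cds_start = 1` yields an empty UTR (such records are excluded from
#' feature analysis downstream).
#'
#' @param sequence Transcript sequence (DNA or RNA alphabet).
#' @param cds_start 1-based position of the first base of the main start
#'   codon.
#' @return The UTR sequence (possibly empty string).
#' @export
extract_utr <- function(sequence, cds_start) {
  s <- normalize_rna(sequence)
  n <- nchar(s)
  if (cds_start < 1L || cds_start > n - 2L) {
    stop("extract_utr: cds_start ", cds_start,
         " outside valid range 1..", n - 2L)
  }
  substr(s, 1L, cds_start - 1L)
}

#' GC percentage of a sequence
#'
#' 100 * (#G + #C) / length. `N` bases count in the denominator only.
#'
#' @param seq Normalised (or normalisable) nucleotide sequence.
#' @return Percentage in `[0, 100]`.
#' @export
gc_percent <- function(seq) {
  s <- normalize_rna(seq)
  if (!nchar(s)) stop("gc_percent: empty sequence")
  chars <- strsplit(s, "")[[1]]
  100 * sum(chars %in% c("G", "C")) / length(chars)
}

#' Scan a transcript for uORF starts
#'
#' Scans every position i (1-based, on the full transcript) whose codon
#' lies entirely within the 5'-UTR (i + 2 < cds_start), in all three
#' frames, counting every overlapping hit. A hit requires the codon to be
#' in the rule's start set, the base at i - 3 to be an allowed purine
#' (so i >= 4; candidates whose -3 position precedes the transcript
#' start are not counted), and the base at i + 3 to be the required G.
#' The +4 base may fall at or beyond the CDS start: context is read from
#' the full transcript, only the codon itself must be upstream. `N`
#' never matches any codon or context requirement.
#'
#' @param sequence Full transcript sequence.
#' @param cds_start 1-based main start codon position.
#' @param rule A [uorf_rule()].
#' @return A list with `positions` (1-based start positions, sorted) and
#'   `count`.
#' @export
scan_uorfs <- function(sequence, cds_start, rule = uorf_rule()) {
  s <- normalize_rna(sequence)
  utr_len <- cds_start - 1L
  # candidate starts: -3 exists and codon fully upstream of the CDS
  if (utr_len < 6L) return(list(positions = integer(0), count = 0L))
  cand <- 4:(utr_len - 2L)
  if (!length(cand)) return(list(positions = integer(0), count = 0L))
  codons <- substring(s, cand, cand + 2L)
  minus3 <- substring(s, cand - 3L, cand - 3L)
  plus4 <- substring(s, cand + 3L, cand + 3L)
  hit <- codons %in% rule$start_codons &
    minus3 %in% rule$minus3_allowed &
    plus4 == rule$plus4_required
  pos <- cand[hit]
  list(positions = as.integer(pos), count = length(pos))
}

#' Compute 5'-UTR translational features for transcript records
#'
#' For each record: extracts the UTR, applies the minimum-length
#' exclusion (UTRs shorter than `rule$min_utr_length` are omitted with
#' reason `"min_length"`), then computes length, GC percentage, uORF
#' count under the rule, and — when a fold model is supplied — the
#' minimum-free-energy proxy from [mfe_fold()]. Excluded records carry
#' `NA` feature values.
#'
#' @param transcripts Data.frame with `transcript_id`, `protein_id`,
#'   `sequence`, `cds_start`.
#' @param rule A [uorf_rule()].
#' @param fold_model An [energy_model()], or `NULL` to skip folding
#'   (`delta_g` is then `NA`).
#' @return A data.frame: `transcript_id`, `protein_id`, `length`,
#'   `gc_percent`, `delta_g`, `uorf_count`, `excluded`, `reason`.
#' @export
compute_features <- function(transcripts, rule = uorf_rule(),
                             fold_model = energy_model()) {
  n <- nrow(transcripts)
  length_out <- integer(n)
  gc <- rep(NA_real_, n)
  dg <- rep(NA_real_, n)
  uorf <- rep(NA_integer_, n)
  excluded <- logical(n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    utr <- extract_utr(transcripts$sequence[i], transcripts$cds_start[i])
    len <- nchar(utr)
    length_out[i] <- len
    if (len < rule$min_utr_length) {
      excluded[i] <- TRUE
      reason[i] <- "min_length"
      next
    }
    gc[i] <- gc_percent(utr)
    uorf[i] <- scan_uorfs(transcripts$sequence[i], transcripts$cds_start[i],
                          rule)$count
    if (!is.null(fold_model)) {
      dg[i] <- mfe_fold(utr, fold_model)$delta_g
    }
  }
  data.frame(transcript_id = transcripts$transcript_id,
             protein_id = transcripts$protein_id,
             length = length_out, gc_percent = gc, delta_g = dg,
             uorf_count = uorf, excluded = excluded, reason = reason,
             stringsAsFactors = FALSE)
}
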