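# ORF calling on the forward strand (directional library); a 6-frame
# mode exists for non-directional input.

GENETIC_CODE_STOPS <- c("TAA", "TAG", "TGA")

#' Find the best open reading frame of a transcript
#'
#' Scans reading frames for ATG-initiated, stop-terminated ORFs and
#' returns the longest with at least `min_aa` encoded amino acids
#' (ties: leftmost start).  Only the three forward frames are scanned by
#' default.
#'
#' @param seq Sequence over `{A,C,G,T,N}`.
#' @param min_aa Minimum peptide length (aa, stop excluded).
#' @param both_strands Also scan the reverse complement.
#' @return `NULL` if no qualifying ORF; otherwise a list of class
#'   `orf_call` with `frame` (0-2), `strand`, `start`, `end` (0-based
#'   half-open, ATG through stop), `aa_length` and `peptide`.
#' @export
find_orf <- function(seq, min_aa = 40L, both_strands = FALSE) {
  seq <- toupper(as.character(seq))
  best <- scan_orf_frames(seq, min_aa, strand = "+")
  if (both_strands) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    cand <- scan_orf_frames(rc, min_aa, strand = "-")
    if (!is.null(cand) &&
        (is.null(best) || cand$aa_length > best$aa_length))
      best <- cand
  }
  best
}

scan_orf_frames <- function(seq, min_aa, strand) {
  n <- nchar(seq)
  best <- NULL
  for (frame in 0:2) {
    n_cod <- (n - frame) %/% 3L
    if (n_cod < 2L) next
    starts <- frame + 3L * (seq_len(n_cod) - 1L)        # 0-based codon starts
    codons <- substring(seq, starts + 1L, starts + 3L)
    is_atg <- codons == "ATG"
    is_stop <- codons %in% GENETIC_CODE_STOPS
    if (!any(is_atg) || !any(is_stop)) next
    # for each stop, the ORF ending there starts at the first ATG after
    # the previous stop
    prev_stop <- 0L
    for (si in which(is_stop)) {
      rng <- if (prev_stop + 1L <= si - 1L)
        (prev_stop + 1L):(si - 1L) else integer(0)
      atg <- rng[is_atg[rng]]
      if (length(atg)) {
        ai <- atg[1]
        aa <- si - ai  # codons between ATG and stop, ATG included
        aa_len <- aa - 0L  # peptide length counts ATG, not the stop
        if (aa_len >= min_aa &&
            (is.null(best) || aa_len > best$aa_length ||
             (aa_len == best$aa_length && starts[ai] < best$start))) {
          s0 <- starts[ai]
          e0 <- starts[si] + 3L
          pep <- as.character(Biostrings::translate(
            Biostrings::DNAString(substr0(seq, s0, e0 - 3L)),
            no.init.codon = TRUE))
          best <- structure(list(frame = frame, strand = strand,
                                 start = s0, end = e0,
                                 aa_length = aa_len, peptide = pep),
                            class = "orf_call")
        }
      }
      prev_stop <- si
    }
  }
  best
}
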