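# INDEL detection on transcript-vs-reference alignments, region
# classification of events, per-region transcript counting, and the
# transposable-element exonization screen.

#' Detect INDEL events in a reference alignment
#'
#' Every gap event shorter than `min_intron` becomes one INDEL; target
#' -side gaps at or above the threshold are introns and are excluded
#' (each gap counts exactly once, as indel XOR intron).  Gaps are
#' left-normalized before anchoring: a gap is shifted left while the
#' base preceding it equals the last base it spans, so anchors are
#' deterministic under alignment ambiguity.
#'
#' @param alignment A `pairwise_alignment` against a reference
#'   transcript.
#' @param min_intron Intron threshold (nt).
#' @return Data frame of class-sorted events: `side`
#'   (`insertion-in-query` / `deletion-from-query`), `t_pos` (leftmost
#'   reference coordinate after normalization), `length`.
#' @export
detect_indels <- function(alignment, min_intron = 30L) {
  g <- alignment$gaps
  empty <- data.frame(side = character(0), t_pos = integer(0),
                      length = integer(0), stringsAsFactors = FALSE)
  if (!nrow(g)) return(empty)
  keep <- !(g$side == "target" & g$length >= min_intron)
  g <- g[keep & g$length < min_intron, , drop = FALSE]
  if (!nrow(g)) return(empty)
  out <- data.frame(
    side = ifelse(g$side == "target", "deletion-from-query",
                  "insertion-in-query"),
    t_pos = vapply(seq_len(nrow(g)), function(i)
      normalize_gap_left(alignment, g[i, ]), integer(1)),
    length = g$length, stringsAsFactors = FALSE)
  out <- out[order(out$t_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# shift a gap left while the base preceding it equals the base the gap
# would expose at its right edge; returns the normalized leftmost
# reference coordinate.  Deletions shift over the reference flank, and
# insertions over the read flank (standard left-alignment of indels).
normalize_gap_left <- function(alignment, gap) {
  pos <- as.integer(gap$t_pos)
  if (is.na(gap$content) || !nzchar(gap$content)) return(pos)
  bl <- alignment$blocks
  if (gap$side == "target") {
    prev <- bl[bl$t_end <= pos, , drop = FALSE]
    if (!nrow(prev)) return(pos)
    flank <- prev$tseq[which.max(prev$t_end)]
  } else {
    prev <- bl[bl$q_end <= gap$q_pos, , drop = FALSE]
    if (!nrow(prev)) return(pos)
    flank <- prev$qseq[which.max(prev$q_end)]
  }
  local <- strsplit(paste0(flank, gap$content), "", fixed = TRUE)[[1]]
  L <- nchar(gap$content)
  off <- nchar(flank)
  while (off > 0L && local[off] == local[off + L]) off <- off - 1L
  pos - (nchar(flank) - off)
}

#' Region category of one INDEL event
#'
#' The category of the anchor position (5UTR / CDS / 3UTR); a deletion
#' whose reference span crosses a region boundary gets the compound
#' label (5UTR_CDS or CDS_3UTR).
#'
#' @param event One row of [detect_indels()] output.
#' @param model Gene-model row of the reference transcript.
#' @return Category label.
#' @export
classify_indel_region <- function(event, model) {
  p <- event$t_pos
  if (p < 0L || p >= model$length)
    stop("classify_indel_region: anchor outside transcript")
  if (!model$coding) return("NR_XR")
  span_end <- if (event$side == "deletion-from-query")
    p + event$length else p + 1L
  classify_span(p, min(span_end, model$length),
                model$cds_start, model$cds_end, model$length)
}

#' Summarize INDELs per region
#'
#' Counts transcripts (not events) per region: a transcript with indels
#' in k regions contributes once to each of those k regions.  Raw event
#' counts are reported alongside.  The functional-region total sums the
#' five coding-gene categories.
#'
#' @param events Data frame with one row per event: `transcript_id`,
#'   `region`.
#' @return List with `by_region` (data frame `region`, `transcripts`,
#'   `events`), `functional_total` (transcript count over 5UTR,
#'   5UTR_CDS, CDS, CDS_3UTR, 3UTR), and `n_transcripts`.
#' @export
summarize_indels <- function(events) {
  regions <- c("5UTR", "5UTR_CDS", "CDS", "CDS_3UTR", "3UTR", "NR_XR")
  if (!nrow(events)) {
    by_region <- data.frame(region = regions, transcripts = 0L,
                            events = 0L, stringsAsFactors = FALSE)
    return(list(by_region = by_region, functional_total = 0L,
                n_transcripts = 0L))
  }
  by_region <- do.call(rbind, lapply(regions, function(r) {
    d <- events[events$region == r, , drop = FALSE]
    data.frame(region = r,
               transcripts = length(unique(d$transcript_id)),
               events = nrow(d), stringsAsFactors = FALSE)
  }))
  functional <- by_region$region %in%
    c("5UTR", "5UTR_CDS", "CDS", "CDS_3UTR", "3UTR")
  list(by_region = by_region,
       functional_total = functional_region_total(
         by_region$transcripts[functional]),
       n_transcripts = length(unique(events$transcript_id)))
}

#' Functional-region total of per-region transcript counts
#'
#' @param counts Integer vector of per-region transcript counts over the
#'   five functional regions.
#' @return Their sum.
#' @export
functional_region_total <- function(counts) {
  sum(as.integer(counts))
}

#' Screen genome blocks for transposable-element exonization
#'
#' For each intron-delimited genome block of a transcript that has no
#' corresponding aligned span in the transcript's best reference-mRNA
#' alignment, computes the fraction of the block covered by annotated
#' repeats and emits a call when coverage reaches `min_overlap`.  The
#' species-specific flag is set when the covering repeat family is
#' lineage-flagged.
#'
#' @param genome_aln Genome `pairwise_alignment` of the transcript.
#' @param mrna_aln Best reference-mRNA `pairwise_alignment`, or `NULL`
#'   (NO_HIT).
#' @param repeats Repeat table (`family`, `g_start`, `g_end`,
#'   `lineage_specific`), e.g. [read_repeats_bed()].
#' @param min_overlap Minimum repeat coverage fraction of the block.
#' @param min_intron Intron threshold for block merging.
#' @param max_mrna_overlap A block whose query interval is covered by
#'   the mRNA alignment above this fraction counts as present in the
#'   reference mRNA and is skipped.
#' @return Data frame with one row per call: `transcript_id`,
#'   `g_start`, `g_end`, `q_start`, `q_end`, `family`,
#'   `overlap_fraction`, `species_specific`, `absent_from_mrna`.
#' @export
screen_te_exons <- function(genome_aln, mrna_aln, repeats,
                            min_overlap = 0.5, min_intron = 30L,
                            max_mrna_overlap = 0.2) {
  empty <- data.frame(transcript_id = character(0), g_start = integer(0),
                      g_end = integer(0), q_start = integer(0),
                      q_end = integer(0), family = character(0),
                      overlap_fraction = numeric(0),
                      species_specific = logical(0),
                      absent_from_mrna = logical(0),
                      stringsAsFactors = FALSE)
  if (is.null(genome_aln)) return(empty)
  blocks <- exon_blocks(genome_aln, min_intron)
  if (!nrow(blocks) || !nrow(repeats)) return(empty)
  mrna_q <- if (!is.null(mrna_aln)) mrna_aln$blocks else NULL
  rows <- list()
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    blen <- b$q_end - b$q_start
    cov_mrna <- 0L
    if (!is.null(mrna_q) && nrow(mrna_q)) {
      cov_mrna <- sum(interval_overlap(mrna_q$q_start, mrna_q$q_end,
                                       b$q_start, b$q_end))
    }
    if (cov_mrna / blen > max_mrna_overlap) next
    ov <- interval_overlap(repeats$g_start, repeats$g_end,
                           b$t_start, b$t_end)
    if (all(ov == 0L)) next
    j <- which.max(ov)
    frac <- ov[j] / (b$t_end - b$t_start)
    if (frac < min_overlap) next
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = genome_aln$query_id,
      g_start = b$t_start, g_end = b$t_end,
      q_start = b$q_start, q_end = b$q_end,
      family = repeats$family[j],
      overlap_fraction = frac,
      species_specific = isTRUE(repeats$lineage_specific[j]),
      absent_from_mrna = TRUE,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}
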