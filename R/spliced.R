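# Transcript-to-genome mapping.  Seeds locate the candidate locus, then
# local alignments are chained recursively (each recursion aligns the
# unaligned query flank against the corresponding genomic flank), giving
# a co-linear chain of high-scoring pairs.  Target-side gaps at or above
# `min_intron` are introns and delimit the reported exon blocks.

#' Map a transcript to a genome with intron-aware blocks
#'
#' @param query Transcript sequence (character or `DNAString`).
#' @param genome Genome (`DNAStringSet`, named by chromosome, or a single
#'   sequence).
#' @param min_intron Target-side gap length (nt) at or above which a gap
#'   is an intron rather than a deletion.
#' @param scoring Scoring scheme for the local alignments.
#' @param min_identity,min_aligned Hit-acceptance thresholds applied to
#'   the combined chain.
#' @param k Seed length used to locate the candidate window.
#' @param window_pad Genomic padding around the seed cluster.
#' @param min_hsp_score Minimum score for an individual chained segment.
#' @param qid Query id stored on the result.
#' @return A `pairwise_alignment` whose target coordinates are genomic
#'   (element `target_id` is the chromosome), or `NULL` (NO_HIT).
#' @export
map_to_genome <- function(query, genome, min_intron = 30L,
                          scoring = default_scoring(),
                          min_identity = 0.90, min_aligned = 50L,
                          k = 16L, window_pad = 500L,
                          min_hsp_score = 20L, qid = "query") {
  query <- as.character(query)
  gseqs <- as_seq_vector(genome)
  if (nchar(query) < k) return(NULL)

  hit <- seed_window(query, gseqs, k = k, pad = window_pad)
  if (is.null(hit)) return(NULL)
  gseq <- gseqs[[hit$chrom]]
  wseq <- substr0(gseq, hit$start, hit$end)

  hsps <- hsp_chain(query, wseq, 0L, 0L, scoring, min_hsp_score)
  if (!length(hsps)) return(NULL)
  aln <- combine_hsps(hsps, qid = qid, tid = hit$chrom,
                      t_shift = hit$start)
  cols <- aligned_columns(aln)
  if (cols < min_aligned || aln$matches / cols < min_identity)
    return(NULL)
  aln
}

# locate the densest seed cluster of the query on the genome
seed_window <- function(query, gseqs, k = 16L, pad = 500L,
                        max_gap = 20000L) {
  n <- nchar(query)
  starts <- unique(c(seq.int(1L, max(1L, n - k + 1L), by = 8L),
                     n - k + 1L))
  kmers <- unique(substring(query, starts, starts + k - 1L))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))
  best <- NULL
  for (chrom in names(gseqs)) {
    mt <- Biostrings::matchPDict(pd, Biostrings::DNAString(gseqs[[chrom]]))
    pos <- sort(unlist(lapply(mt, IRanges::start), use.names = FALSE))
    if (!length(pos)) next
    # split seed positions into clusters, keep the densest
    grp <- cumsum(c(1L, diff(pos) > max_gap))
    counts <- tabulate(grp)
    g <- which.max(counts)
    cl <- pos[grp == g]
    cand <- list(chrom = chrom, n = length(cl),
                 start = max(0L, min(cl) - 1L - pad),
                 end = min(nchar(gseqs[[chrom]]), max(cl) + k + pad))
    if (is.null(best) || cand$n > best$n) best <- cand
  }
  best
}

# recursive chaining: best local HSP, then recurse on the flanks
hsp_chain <- function(qseq, tseq, q_off, t_off, scoring, min_hsp_score) {
  if (nchar(qseq) < 12L || nchar(tseq) < 12L) return(list())
  a <- align_local(qseq, tseq, scoring)
  if (a$score < min_hsp_score || !nrow(a$blocks)) return(list())
  a$q_span <- a$q_span + q_off
  a$t_span <- a$t_span + t_off
  a$blocks$q_start <- a$blocks$q_start + q_off
  a$blocks$q_end <- a$blocks$q_end + q_off
  a$blocks$t_start <- a$blocks$t_start + t_off
  a$blocks$t_end <- a$blocks$t_end + t_off
  if (nrow(a$gaps)) {
    a$gaps$q_pos <- a$gaps$q_pos + q_off
    a$gaps$t_pos <- a$gaps$t_pos + t_off
  }
  qs <- a$q_span[1] - q_off
  qe <- a$q_span[2] - q_off
  ts <- a$t_span[1] - t_off
  te <- a$t_span[2] - t_off
  left <- hsp_chain(substr0(qseq, 0L, qs), substr0(tseq, 0L, ts),
                    q_off, t_off, scoring, min_hsp_score)
  right <- hsp_chain(substr0(qseq, qe, nchar(qseq)),
                     substr0(tseq, te, nchar(tseq)),
                     q_off + qe, t_off + te, scoring, min_hsp_score)
  c(left, list(a), right)
}

# merge a sorted co-linear HSP chain into one pairwise_alignment;
# between-HSP skips become gap events on the appropriate side(s)
combine_hsps <- function(hsps, qid, tid, t_shift = 0L) {
  ord <- order(vapply(hsps, function(h) h$q_span[1], numeric(1)))
  hsps <- hsps[ord]
  blocks <- do.call(rbind, lapply(hsps, `[[`, "blocks"))
  gaps <- do.call(rbind, lapply(hsps, `[[`, "gaps"))
  for (i in seq_len(length(hsps) - 1L)) {
    a <- hsps[[i]]
    b <- hsps[[i + 1L]]
    tgap <- b$t_span[1] - a$t_span[2]
    qgap <- b$q_span[1] - a$q_span[2]
    if (tgap > 0L)   # skipped target stretch (intron-sized usually)
      gaps <- rbind(gaps, data.frame(
        side = "target", q_pos = a$q_span[2], t_pos = a$t_span[2],
        length = tgap, content = "", stringsAsFactors = FALSE))
    if (qgap > 0L)   # unaligned query stretch between chained segments
      gaps <- rbind(gaps, data.frame(
        side = "query", q_pos = a$q_span[2], t_pos = b$t_span[1],
        length = qgap, content = "", stringsAsFactors = FALSE))
  }
  blocks$t_start <- blocks$t_start + t_shift
  blocks$t_end <- blocks$t_end + t_shift
  if (nrow(gaps)) gaps$t_pos <- gaps$t_pos + t_shift
  gaps <- gaps[order(gaps$q_pos, gaps$t_pos), , drop = FALSE]
  rownames(gaps) <- NULL
  rownames(blocks) <- NULL
  eq <- mapply(function(q, t) {
    qs <- strsplit(q, "", fixed = TRUE)[[1]]
    ts <- strsplit(t, "", fixed = TRUE)[[1]]
    sum(qs == ts & qs != "N")
  }, blocks$qseq, blocks$tseq)
  matches <- sum(eq)
  cols <- sum(nchar(blocks$qseq))
  structure(list(
    query_id = qid, target_id = tid,
    score = sum(vapply(hsps, `[[`, numeric(1), "score")),
    blocks = blocks, gaps = gaps,
    matches = as.integer(matches),
    mismatches = as.integer(cols - matches),
    q_span = c(min(blocks$q_start), max(blocks$q_end)),
    t_span = c(min(blocks$t_start), max(blocks$t_end))),
    class = "pairwise_alignment")
}

#' Intron-delimited exon blocks of a genome alignment
#'
#' Merges gapless blocks separated by small (non-intron) gaps, so that
#' only target-side gaps of at least `min_intron` nt delimit blocks.
#' The number of rows is the reported "# of blocks" of a mapped
#' transcript.
#'
#' @param alignment A genome `pairwise_alignment`.
#' @param min_intron Intron threshold (nt).
#' @return Data frame with `q_start`, `q_end`, `t_start`, `t_end`, one
#'   row per exon segment.
#' @export
exon_blocks <- function(alignment, min_intron = 30L) {
  bl <- alignment$blocks
  if (!nrow(bl)) {
    return(data.frame(q_start = integer(0), q_end = integer(0),
                      t_start = integer(0), t_end = integer(0)))
  }
  bl <- bl[order(bl$q_start), , drop = FALSE]
  grp <- integer(nrow(bl))
  g <- 1L
  grp[1] <- g
  for (i in seq_len(nrow(bl) - 1L)) {
    tgap <- bl$t_start[i + 1L] - bl$t_end[i]
    if (tgap >= min_intron) g <- g + 1L
    grp[i + 1L] <- g
  }
  out <- lapply(split(bl, grp), function(d) data.frame(
    q_start = min(d$q_start), q_end = max(d$q_end),
    t_start = min(d$t_start), t_end = max(d$t_end)))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Export genome mappings in the tabular survey layout
#'
#' One row per mapped transcript: accession, read length, matched
#' length, query start/end, chromosome, number of intron-delimited
#' blocks, and the genomic context label.  The exported coordinates obey
#' `matched_length == query_end - query_start` (start 0-based, end
#' half-open).
#'
#' @param alignments Named list of genome `pairwise_alignment` objects
#'   (`NULL` entries skipped).
#' @param read_lengths Named integer vector of full read lengths.
#' @param context Optional named character vector of genomic-context
#'   labels (see [label_genome_context()]).
#' @param min_intron Intron threshold used for block counting.
#' @return Data frame with columns `acc`, `length`, `matched_length`,
#'   `query_start`, `query_end`, `chr`, `n_blocks`, `aligned_region`.
#' @export
export_genome_hits <- function(alignments, read_lengths,
                               context = NULL, min_intron = 30L) {
  alignments <- Filter(Negate(is.null), alignments)
  rows <- lapply(names(alignments), function(id) {
    a <- alignments[[id]]
    data.frame(
      acc = id,
      length = unname(read_lengths[id]),
      matched_length = a$q_span[2] - a$q_span[1],
      query_start = a$q_span[1],
      query_end = a$q_span[2],
      chr = a$target_id,
      n_blocks = nrow(exon_blocks(a, min_intron)),
      aligned_region = if (!is.null(context) && id %in% names(context))
        unname(context[id]) else "",
      stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(acc = character(0), length = integer(0),
                      matched_length = integer(0),
                      query_start = integer(0), query_end = integer(0),
                      chr = character(0), n_blocks = integer(0),
                      aligned_region = character(0)))
  }
  do.call(rbind, rows)
}
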