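# Pairwise local alignment with affine gaps, decomposed into gapless
# blocks with per-column bookkeeping.  The dynamic program itself is the
# standard Smith-Waterman with affine gaps (delegated to Biostrings); the
# package-level contract is the block/gap decomposition, identity
# arithmetic and deterministic best-hit selection built on top of it.
# All coordinates 0-based half-open.

#' Default local-alignment scoring scheme
#'
#' Match +1, mismatch -2, gap-open -5, gap-extend -1; a gap of length L
#' costs `5 + L`.  `N` never scores as a match.
#'
#' @return Named list with `match`, `mismatch`, `gap_open`, `gap_extend`.
#' @export
default_scoring <- function() {
  list(match = 1, mismatch = -2, gap_open = -5, gap_extend = -1)
}

scoring_matrix <- function(scoring) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(b, b))
  diag(m)[1:4] <- scoring$match   # N-N is a mismatch
  m
}

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman local alignment with affine gap penalties, returned as
#' a `pairwise_alignment`: gapless blocks carrying the aligned substrings,
#' gap events, match/mismatch counts and the query/target spans.
#'
#' @param query,target Sequences (character or `DNAString`) over
#'   `{A,C,G,T,N}`.
#' @param scoring Scoring scheme, see [default_scoring()].
#' @param qid,tid Identifiers stored on the result.
#' @return Object of class `pairwise_alignment` with elements
#'   `query_id`, `target_id`, `score`, `blocks` (data frame `q_start`,
#'   `q_end`, `t_start`, `t_end`, `qseq`, `tseq`), `gaps` (data frame
#'   `side` in `{query, target}`, `q_pos`, `t_pos`, `length`), `matches`,
#'   `mismatches`, `q_span`, `t_span`.  Empty input yields an empty
#'   alignment with score 0.
#' @export
align_local <- function(query, target, scoring = default_scoring(),
                        qid = "query", tid = "target") {
  query <- as.character(query)
  target <- as.character(target)
  if (nchar(query) == 0L || nchar(target) == 0L)
    return(empty_alignment(qid, tid))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(target),
    type = "local",
    substitutionMatrix = scoring_matrix(scoring),
    gapOpening = abs(scoring$gap_open),
    gapExtension = abs(scoring$gap_extend))
  if (Biostrings::score(pa) <= 0) return(empty_alignment(qid, tid))
  qal <- as.character(Biostrings::alignedPattern(pa))
  tal <- as.character(Biostrings::alignedSubject(pa))
  parse_gapped(qal, tal,
               q_off = Biostrings::start(Biostrings::pattern(pa)) - 1L,
               t_off = Biostrings::start(Biostrings::subject(pa)) - 1L,
               score = Biostrings::score(pa), qid = qid, tid = tid)
}

empty_alignment <- function(qid = "query", tid = "target") {
  structure(list(
    query_id = qid, target_id = tid, score = 0,
    blocks = data.frame(q_start = integer(0), q_end = integer(0),
                        t_start = integer(0), t_end = integer(0),
                        qseq = character(0), tseq = character(0),
                        stringsAsFactors = FALSE),
    gaps = data.frame(side = character(0), q_pos = integer(0),
                      t_pos = integer(0), length = integer(0),
                      content = character(0), stringsAsFactors = FALSE),
    matches = 0L, mismatches = 0L,
    q_span = c(0L, 0L), t_span = c(0L, 0L)), class = "pairwise_alignment")
}

# turn a pair of gapped aligned strings into blocks/gaps bookkeeping
parse_gapped <- function(qal, tal, q_off, t_off, score, qid, tid) {
  qc <- strsplit(qal, "", fixed = TRUE)[[1]]
  tc <- strsplit(tal, "", fixed = TRUE)[[1]]
  qgap <- qc == "-"
  tgap <- tc == "-"
  state <- ifelse(qgap, 1L, ifelse(tgap, 2L, 0L))  # 0 block, 1 qgap, 2 tgap
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L

  qpos <- q_off + cumsum(!qgap)   # 1-based query coord consumed up to col
  tpos <- t_off + cumsum(!tgap)

  blocks <- list()
  gaps <- list()
  matches <- 0L
  mismatches <- 0L
  for (i in seq_along(r$values)) {
    a <- starts[i]
    b <- ends[i]
    if (r$values[i] == 0L) {
      qs <- qpos[a] - 1L
      ts <- tpos[a] - 1L
      bq <- qc[a:b]
      bt <- tc[a:b]
      eq <- bq == bt & bq != "N"
      matches <- matches + sum(eq)
      mismatches <- mismatches + sum(!eq)
      blocks[[length(blocks) + 1L]] <- data.frame(
        q_start = qs, q_end = qpos[b], t_start = ts, t_end = tpos[b],
        qseq = paste(bq, collapse = ""), tseq = paste(bt, collapse = ""),
        stringsAsFactors = FALSE)
    } else {
      # side names the sequence whose bases fill the gap: a "target"
      # -side gap skips target bases (deletion from the query; long ones
      # are introns), a "query"-side gap inserts query bases
      side <- if (r$values[i] == 1L) "target" else "query"
      gaps[[length(gaps) + 1L]] <- data.frame(
        side = side,
        q_pos = if (side == "target") qpos[a] else qpos[a] - 1L,
        t_pos = if (side == "query") tpos[a] else tpos[a] - 1L,
        length = b - a + 1L,
        content = paste(if (side == "target") tc[a:b] else qc[a:b],
                        collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  blocks <- do.call(rbind, blocks)
  gaps <- if (length(gaps)) do.call(rbind, gaps) else
    data.frame(side = character(0), q_pos = integer(0),
               t_pos = integer(0), length = integer(0),
               content = character(0), stringsAsFactors = FALSE)
  structure(list(
    query_id = qid, target_id = tid, score = score,
    blocks = blocks, gaps = gaps,
    matches = matches, mismatches = mismatches,
    q_span = c(min(blocks$q_start), max(blocks$q_end)),
    t_span = c(min(blocks$t_start), max(blocks$t_end))),
    class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf(
    "pairwise_alignment %s vs %s: score %.0f, %d block(s), %d match / %d mismatch, query [%d,%d) target [%d,%d)\n",
    x$query_id, x$target_id, x$score, nrow(x$blocks), x$matches,
    x$mismatches, x$q_span[1], x$q_span[2], x$t_span[1], x$t_span[2]))
  invisible(x)
}

#' Alignment identity over (part of) the target
#'
#' Fraction of matching columns among block columns, optionally
#' restricted to those whose target coordinate falls in `restrict_to`.
#' Gap columns never enter the denominator.
#'
#' @param alignment A `pairwise_alignment`.
#' @param restrict_to Optional target interval `c(start, end)`, 0-based
#'   half-open.
#' @return Fraction in `[0, 1]`, or `NA` when no aligned column falls in
#'   the interval (undefined, distinct from 0).
#' @export
alignment_identity <- function(alignment, restrict_to = NULL) {
  bl <- alignment$blocks
  if (!nrow(bl)) return(NA_real_)
  m <- 0L
  tot <- 0L
  for (i in seq_len(nrow(bl))) {
    qs <- strsplit(bl$qseq[i], "", fixed = TRUE)[[1]]
    ts <- strsplit(bl$tseq[i], "", fixed = TRUE)[[1]]
    tcoord <- bl$t_start[i] + seq_along(ts) - 1L
    keep <- if (is.null(restrict_to)) rep(TRUE, length(ts)) else
      tcoord >= restrict_to[1] & tcoord < restrict_to[2]
    if (!any(keep)) next
    eq <- qs[keep] == ts[keep] & qs[keep] != "N"
    m <- m + sum(eq)
    tot <- tot + sum(keep)
  }
  if (tot == 0L) return(NA_real_)
  m / tot
}

#' Number of aligned (block) columns of an alignment
#'
#' @param alignment A `pairwise_alignment`.
#' @return Integer count of match + mismatch columns.
#' @export
aligned_columns <- function(alignment) {
  alignment$matches + alignment$mismatches
}

#' Best reference hit for a query
#'
#' Aligns the query against candidate targets and returns the single
#' best alignment passing the acceptance thresholds.  Ties are broken by
#' score, then longer query span, then lexicographically smaller target
#' id.  With an `index`, targets sharing no seeds with the query are
#' skipped (acceleration only; scores are unchanged).
#'
#' @param query Query sequence (character or `DNAString`).
#' @param targets Named targets (`DNAStringSet` or character vector).
#' @param scoring Scoring scheme.
#' @param min_identity Minimum identity over aligned columns.
#' @param min_aligned Minimum aligned columns.
#' @param index Optional [kmer_index()] over `targets`.
#' @param qid Query id stored on the result.
#' @return The best `pairwise_alignment`, or `NULL` (NO_HIT).
#' @export
best_hit <- function(query, targets, scoring = default_scoring(),
                     min_identity = 0.90, min_aligned = 100L,
                     index = NULL, qid = "query") {
  targets <- as_seq_vector(targets)
  query <- as.character(query)
  cand <- names(targets)
  if (!is.null(index)) {
    cand <- kmer_candidates(index, query, step = 4L, min_seeds = 2L,
                            max_candidates = 10L)
    if (!length(cand)) return(NULL)
  }
  best <- NULL
  for (id in sort(cand)) {
    a <- align_local(query, targets[[id]], scoring, qid = qid, tid = id)
    cols <- aligned_columns(a)
    if (cols < min_aligned) next
    if (a$matches / cols < min_identity) next
    if (is.null(best)) {
      best <- a
      next
    }
    span <- a$q_span[2] - a$q_span[1]
    bspan <- best$q_span[2] - best$q_span[1]
    if (a$score > best$score ||
        (a$score == best$score && span > bspan) ||
        (a$score == best$score && span == bspan &&
         a$target_id < best$target_id)) {
      best <- a
    }
  }
  best
}
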