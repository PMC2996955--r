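# Reference-anchored consensus building for gene clusters with >= 2
# members, and per-region identity statistics against the reference
# transcript.

#' Build a reference-anchored consensus for one gene cluster
#'
#' Members are anchored to the reference transcript through their
#' alignments; at every reference column covered by at least one member
#' the consensus base is the majority among covering members, ties
#' broken toward the base agreeing with the reference, then
#' alphabetically.  Columns covered by no member are absent.
#'
#' @param member_alignments List of `pairwise_alignment` objects (>= 2),
#'   all against the same reference transcript.
#' @param reference Reference transcript sequence (character or
#'   `DNAString`).
#' @return Object of class `consensus_record`: `tx_id`, `member_ids`,
#'   `n_members`, `columns` (data frame `t_pos`, `base`, `support`,
#'   `ref_base`), and `sequence` (consensus bases concatenated in
#'   reference order).
#' @export
build_consensus <- function(member_alignments, reference) {
  if (length(member_alignments) < 2L)
    stop("build_consensus: need at least 2 members")
  tx_id <- unique(vapply(member_alignments, `[[`, character(1),
                         "target_id"))
  if (length(tx_id) != 1L)
    stop("build_consensus: members anchored to different references")
  reference <- as.character(reference)
  refc <- strsplit(reference, "", fixed = TRUE)[[1]]

  votes <- new.env(hash = TRUE, parent = emptyenv())
  for (a in member_alignments) {
    bl <- a$blocks
    for (i in seq_len(nrow(bl))) {
      qs <- strsplit(bl$qseq[i], "", fixed = TRUE)[[1]]
      tpos <- bl$t_start[i] + seq_along(qs) - 1L
      for (j in seq_along(qs)) {
        key <- as.character(tpos[j])
        votes[[key]] <- c(votes[[key]], qs[j])
      }
    }
  }
  pos <- sort(as.integer(ls(votes)))
  base <- character(length(pos))
  support <- integer(length(pos))
  for (i in seq_along(pos)) {
    v <- votes[[as.character(pos[i])]]
    tab <- table(v)
    top <- names(tab)[tab == max(tab)]
    rb <- refc[pos[i] + 1L]
    base[i] <- if (rb %in% top) rb else sort(top)[1]
    support[i] <- length(v)
  }
  structure(list(
    tx_id = tx_id,
    member_ids = vapply(member_alignments, `[[`, character(1),
                        "query_id"),
    n_members = length(member_alignments),
    columns = data.frame(t_pos = pos, base = base, support = support,
                         ref_base = refc[pos + 1L],
                         stringsAsFactors = FALSE),
    sequence = paste(base, collapse = "")),
    class = "consensus_record")
}

#' Identity of a consensus against its reference, by region
#'
#' Computes the mapping category of the consensus's covered span and the
#' percent identity between consensus and reference bases over the
#' covered columns, optionally restricted to one region interval.
#'
#' @param consensus A [build_consensus()] record.
#' @param model Gene-model row for the reference transcript.
#' @param restrict_to Optional reference interval `c(start, end)`.
#' @return List with `category`, `identity_pct` (`NA` if no columns fall
#'   in the interval), and `n_columns`.
#' @export
per_region_identity <- function(consensus, model, restrict_to = NULL) {
  cols <- consensus$columns
  span <- c(min(cols$t_pos), max(cols$t_pos) + 1L)
  category <- classify_region(span, model)
  if (!is.null(restrict_to)) {
    cols <- cols[cols$t_pos >= restrict_to[1] &
                 cols$t_pos < restrict_to[2], , drop = FALSE]
  }
  if (!nrow(cols)) {
    return(list(category = category, identity_pct = NA_real_,
                n_columns = 0L))
  }
  id <- mean(cols$base == cols$ref_base & cols$base != "N")
  list(category = category, identity_pct = 100 * id,
       n_columns = nrow(cols))
}

#' Per-category identity report over consensus records
#'
#' @param records List of lists as returned by [per_region_identity()],
#'   each optionally carrying `gene_id` and `tx_id`.
#' @return List of class `identity_report`: `summary` (data frame
#'   `category`, `n`, `mean_pct` in the fixed report order, empty
#'   categories omitted), `identities` (one row per consensus), and the
#'   counts `n_consensus` / `n_genes`.
#' @export
identity_report <- function(records) {
  records <- Filter(function(r) !is.na(r$identity_pct), records)
  rows <- lapply(records, function(r) data.frame(
    gene_id = if (!is.null(r$gene_id)) r$gene_id else NA_character_,
    tx_id = if (!is.null(r$tx_id)) r$tx_id else NA_character_,
    category = r$category, identity_pct = r$identity_pct,
    n_columns = r$n_columns, stringsAsFactors = FALSE))
  ids <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), tx_id = character(0),
               category = character(0), identity_pct = numeric(0),
               n_columns = integer(0))
  order_cats <- c("5UTR_CDS", "5UTR_CDS_3UTR", "CDS", "CDS_3UTR", "3UTR")
  summ <- lapply(order_cats, function(cat) {
    d <- ids[ids$category == cat, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    data.frame(category = cat, n = nrow(d),
               mean_pct = round_half_up(mean(d$identity_pct), 1),
               stringsAsFactors = FALSE)
  })
  summ <- do.call(rbind, summ)
  if (is.null(summ))
    summ <- data.frame(category = character(0), n = integer(0),
                       mean_pct = numeric(0))
  structure(list(summary = summ, identities = ids,
                 n_consensus = nrow(ids),
                 n_genes = length(unique(stats::na.omit(ids$gene_id)))),
            class = "identity_report")
}

#' Consensus + identity statistics for a whole annotated read set
#'
#' Convenience wrapper: groups best hits by reference transcript, builds
#' a consensus for every transcript with >= 2 members, computes each
#' consensus's category and identity, and returns the identity report.
#'
#' @param hits Named list of `pairwise_alignment` objects vs reference
#'   transcripts.
#' @param transcripts Reference transcript sequences.
#' @param models Gene-model table.
#' @return An [identity_report()] (with a `records` attribute holding
#'   the consensus records).
#' @export
consensus_identity <- function(hits, transcripts, models) {
  hits <- Filter(Negate(is.null), hits)
  seqs <- as_seq_vector(transcripts)
  by_tx <- split(hits, vapply(hits, `[[`, character(1), "target_id"))
  recs <- list()
  results <- list()
  for (tx in names(by_tx)) {
    members <- by_tx[[tx]]
    if (length(members) < 2L) next
    cons <- build_consensus(members, seqs[[tx]])
    m <- models[match(tx, models$tx_id), ]
    if (!isTRUE(m$coding)) next  # identity reported for coding spans
    r <- per_region_identity(cons, m)
    r$gene_id <- m$gene_id
    r$tx_id <- tx
    recs[[tx]] <- cons
    results[[tx]] <- r
  }
  rep <- identity_report(results)
  attr(rep, "records") <- recs
  rep
}
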