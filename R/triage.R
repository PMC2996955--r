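# Triage of transcripts without a reference-transcriptome homolog:
# other-database evidence, spliced genome support, and ORF content.
# Cascade: reference set -> other databases -> genome + ORF -> ORF only
# -> unclassified.

#' Triage one transcript through the evidence cascade
#'
#' (1) A best hit against the reference transcript set yields
#' `REFSEQ_MATCH`; (2) otherwise a best hit against the other-database
#' pool yields `OTHER_DB_MATCH`; (3) otherwise the transcript is mapped
#' to the genome: a spliced hit together with a qualifying ORF yields
#' `GENOME_ORF`, an ORF without a genome hit yields `ORF_ONLY`, and
#' anything else is `UNCLASSIFIED` (never silently forced into a
#' class).
#'
#' @param seq Transcript sequence.
#' @param id Transcript id.
#' @param refseq_db Reference transcripts (`DNAStringSet`/character).
#' @param other_db Other-database transcripts, or `NULL`.
#' @param genome Genome sequences, or `NULL` to skip genome mapping.
#' @param annotation Optional [genome_annotation()] list for context
#'   labels.
#' @param params List of thresholds: `min_identity`, `min_aligned`,
#'   `min_aa`, `min_intron`, plus optional precomputed `refseq_index` /
#'   `other_index` ([kmer_index()]).
#' @return List of class `triage_result`: `id`, `class`, `hit` (best
#'   alignment or `NULL`), `genome_hit`, `orf`, `context` (label string
#'   or `NA`).
#' @export
triage <- function(seq, id, refseq_db, other_db = NULL, genome = NULL,
                   annotation = NULL, params = triage_params()) {
  seq <- as.character(seq)
  hit <- best_hit(seq, refseq_db, min_identity = params$min_identity,
                  min_aligned = params$min_aligned,
                  index = params$refseq_index, qid = id)
  if (!is.null(hit))
    return(triage_result(id, "REFSEQ_MATCH", hit = hit))
  if (!is.null(other_db)) {
    oh <- best_hit(seq, other_db, min_identity = params$min_identity,
                   min_aligned = params$min_aligned,
                   index = params$other_index, qid = id)
    if (!is.null(oh))
      return(triage_result(id, "OTHER_DB_MATCH", hit = oh))
  }
  orf <- find_orf(seq, min_aa = params$min_aa)
  ghit <- NULL
  context <- NA_character_
  if (!is.null(genome)) {
    ghit <- map_to_genome(seq, genome, min_intron = params$min_intron,
                          min_identity = params$min_identity,
                          min_aligned = params$min_genome_aligned,
                          qid = id)
    if (!is.null(ghit) && !is.null(annotation)) {
      context <- label_genome_context(
        exon_blocks(ghit, params$min_intron), annotation)
    }
  }
  cls <- if (!is.null(ghit) && !is.null(orf)) "GENOME_ORF"
  else if (is.null(ghit) && !is.null(orf)) "ORF_ONLY"
  else "UNCLASSIFIED"
  triage_result(id, cls, genome_hit = ghit, orf = orf, context = context)
}

triage_result <- function(id, class, hit = NULL, genome_hit = NULL,
                          orf = NULL, context = NA_character_) {
  structure(list(id = id, class = class, hit = hit,
                 genome_hit = genome_hit, orf = orf, context = context),
            class = "triage_result")
}

#' Default triage thresholds
#'
#' @param min_identity,min_aligned Database-hit acceptance thresholds.
#' @param min_genome_aligned Minimum aligned columns for a genome hit.
#' @param min_aa Minimum ORF length (aa).
#' @param min_intron Intron threshold for genome mapping (nt).
#' @param refseq_index,other_index Optional [kmer_index()] objects.
#' @return Parameter list.
#' @export
triage_params <- function(min_identity = 0.90, min_aligned = 100L,
                          min_genome_aligned = 50L, min_aa = 40L,
                          min_intron = 30L, refseq_index = NULL,
                          other_index = NULL) {
  list(min_identity = min_identity, min_aligned = min_aligned,
       min_genome_aligned = min_genome_aligned, min_aa = min_aa,
       min_intron = min_intron, refseq_index = refseq_index,
       other_index = other_index)
}

#' Triage a whole transcript set
#'
#' Runs [triage()] over a set, building seed indexes once.
#'
#' @param seqs Named sequences (`DNAStringSet`/character).
#' @param refseq_db,other_db,genome,annotation As in [triage()].
#' @param params [triage_params()].
#' @return List with `results` (list of `triage_result`) and `table`
#'   (data frame `id`, `class`, `db_hit`, `chr`, `n_blocks`,
#'   `matched_length`, `orf_aa`, `aligned_region`).
#' @export
triage_set <- function(seqs, refseq_db, other_db = NULL, genome = NULL,
                       annotation = NULL, params = triage_params()) {
  seqs <- as_seq_vector(seqs)
  if (is.null(params$refseq_index))
    params$refseq_index <- kmer_index(refseq_db, k = 12L, step = 1L)
  if (!is.null(other_db) && is.null(params$other_index))
    params$other_index <- kmer_index(other_db, k = 12L, step = 1L)
  results <- lapply(names(seqs), function(id)
    triage(seqs[[id]], id, refseq_db, other_db, genome, annotation,
           params))
  names(results) <- names(seqs)
  rows <- lapply(results, function(r) data.frame(
    id = r$id, class = r$class,
    db_hit = if (!is.null(r$hit)) r$hit$target_id else NA_character_,
    chr = if (!is.null(r$genome_hit)) r$genome_hit$target_id
      else NA_character_,
    n_blocks = if (!is.null(r$genome_hit))
      nrow(exon_blocks(r$genome_hit, params$min_intron)) else NA_integer_,
    matched_length = if (!is.null(r$genome_hit))
      r$genome_hit$q_span[2] - r$genome_hit$q_span[1] else NA_integer_,
    orf_aa = if (!is.null(r$orf)) r$orf$aa_length else NA_integer_,
    aligned_region = r$context,
    stringsAsFactors = FALSE))
  list(results = results, table = do.call(rbind, rows))
}

#' Label the genomic context of exon blocks
#'
#' Each block is `Exon` if it overlaps an annotated exon by >= 1 nt,
#' else `Intron` if it lies inside a gene span, else `Intergenic`.  The
#' transcript label concatenates, per overlapped gene, the gene name and
#' the set of its block labels, e.g. `"G0007 (Intron,Exon)"`;
#' `"Intergenic"` when all blocks are intergenic.
#'
#' @param blocks Data frame of genomic blocks (`t_start`, `t_end`), e.g.
#'   [exon_blocks()].
#' @param annotation A [genome_annotation()] list (`genes`, `exons`).
#' @return Single label string.
#' @export
label_genome_context <- function(blocks, annotation) {
  if (!nrow(blocks)) return("Intergenic")
  genes <- annotation$genes
  exons <- annotation$exons
  per_gene <- list()
  any_genic <- FALSE
  for (i in seq_len(nrow(blocks))) {
    s <- blocks$t_start[i]
    e <- blocks$t_end[i]
    gi <- which(interval_overlap(genes$g_start, genes$g_end, s, e) > 0L)
    if (!length(gi)) next
    any_genic <- TRUE
    for (g in gi) {
      gid <- genes$gene_id[g]
      ex <- exons[exons$gene_id == gid, , drop = FALSE]
      lab <- if (any(interval_overlap(ex$g_start, ex$g_end, s, e) > 0L))
        "Exon" else "Intron"
      per_gene[[gid]] <- union(per_gene[[gid]], lab)
    }
  }
  if (!any_genic) return("Intergenic")
  n_intergenic <- sum(vapply(seq_len(nrow(blocks)), function(i) {
    all(interval_overlap(genes$g_start, genes$g_end,
                         blocks$t_start[i], blocks$t_end[i]) == 0L)
  }, logical(1)))
  parts <- vapply(names(per_gene), function(gid) {
    labs <- intersect(c("Intron", "Exon"), per_gene[[gid]])
    sprintf("%s (%s)", gid, paste(labs, collapse = ","))
  }, character(1))
  lab <- paste(parts, collapse = ", ")
  if (n_intergenic > 0L) lab <- paste0(lab, ", Intergenic")
  lab
}
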