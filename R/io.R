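# File-format boundaries.  FASTA/FASTQ via Biostrings; GFF3 and BED via
# rtracklayer (GFF3 1-based inclusive, BED 0-based half-open); tables as
# TSV.

#' Write a synthetic bundle to disk
#'
#' Materializes a simulated library and its reference bundle as the
#' standard file set: `reads.fasta`, `reads.fastq`,
#' `reference_mrna.fasta`, `gene_models.gff3`, `genome.fasta`,
#' `repeats.bed`, `vector.fasta`, `host.fasta`, `other_db.fasta`,
#' `truth.tsv` (per read) and `truth_genes.tsv` (per-gene divergence
#' events).
#'
#' @param sim A [simulate_cdna_reads()] result.
#' @param refs The matching [make_reference_set()] bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_bundle <- function(sim, refs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)

  Biostrings::writeXStringSet(sim$reads, p("reads.fasta"))
  qreads <- Biostrings::QualityScaledDNAStringSet(sim$reads, sim$quals)
  Biostrings::writeQualityScaledXStringSet(qreads, p("reads.fastq"))
  Biostrings::writeXStringSet(refs$transcripts, p("reference_mrna.fasta"))
  Biostrings::writeXStringSet(refs$genome, p("genome.fasta"))
  Biostrings::writeXStringSet(refs$vector, p("vector.fasta"))
  Biostrings::writeXStringSet(refs$host, p("host.fasta"))
  Biostrings::writeXStringSet(refs$other_db, p("other_db.fasta"))

  write_gene_models_gff3(refs, p("gene_models.gff3"))
  write_repeats_bed(refs$repeats, p("repeats.bed"))

  tr <- sim$truth$reads
  write_tsv(tr, p("truth.tsv"))
  ev <- rbind(
    if (!is.null(sim$truth$subs) && nrow(sim$truth$subs))
      data.frame(tx_id = sim$truth$subs$tx_id, type = "sub",
                 h_pos = sim$truth$subs$h_pos, length = 1L,
                 region = sim$truth$subs$region,
                 detail = paste0(sim$truth$subs$h_base, ">",
                                 sim$truth$subs$r_base),
                 stringsAsFactors = FALSE),
    if (!is.null(sim$truth$indels) && nrow(sim$truth$indels))
      data.frame(tx_id = sim$truth$indels$tx_id,
                 type = sim$truth$indels$type,
                 h_pos = sim$truth$indels$h_pos,
                 length = sim$truth$indels$length,
                 region = sim$truth$indels$region,
                 detail = sim$truth$indels$ins_seq,
                 stringsAsFactors = FALSE))
  if (is.null(ev))
    ev <- data.frame(tx_id = character(0), type = character(0),
                     h_pos = integer(0), length = integer(0),
                     region = character(0), detail = character(0))
  write_tsv(ev, p("truth_genes.tsv"))
  invisible(dir)
}

# gene models: transcript-space CDS features, 1-based inclusive
write_gene_models_gff3 <- function(refs, path) {
  m <- refs$models
  cod <- m[m$coding, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = m$tx_id,
    ranges = IRanges::IRanges(start = 1L, end = m$length),
    strand = "+",
    type = "mRNA", source = "flcdna",
    ID = m$tx_id, gene_id = m$gene_id,
    coding = ifelse(m$coding, "coding", "NR_XR"))
  grc <- GenomicRanges::GRanges(
    seqnames = cod$tx_id,
    ranges = IRanges::IRanges(start = cod$cds_start + 1L,
                              end = cod$cds_end),
    strand = "+",
    type = "CDS", source = "flcdna", phase = 0L,
    ID = paste0(cod$tx_id, ".cds"), gene_id = cod$gene_id,
    coding = "coding")
  rtracklayer::export(c(gr, grc), path, format = "gff3")
  invisible(path)
}

write_repeats_bed <- function(repeats, path) {
  if (!nrow(repeats)) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = "chr1",
    ranges = IRanges::IRanges(start = repeats$g_start + 1L,
                              end = repeats$g_end),
    strand = repeats$strand,
    name = paste0(repeats$family, ifelse(repeats$lineage_specific,
                                         ":lineage", "")),
    score = 0L)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a repeat annotation from BED
#'
#' Accepts the `repeats.bed` written by [write_sim_bundle()] (or any BED
#' whose name column is `family[:lineage]`) and returns the repeat table
#' used by [screen_te_exons()].
#'
#' @param path BED file path.
#' @return Data frame with `family`, `g_start`, `g_end`, `strand`,
#'   `lineage_specific`.
#' @export
read_repeats_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  nm <- gr$name
  data.frame(
    family = sub(":lineage$", "", nm),
    g_start = GenomicRanges::start(gr) - 1L,
    g_end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    lineage_specific = grepl(":lineage$", nm),
    stringsAsFactors = FALSE)
}

#' Read gene models from a transcript-space GFF3
#'
#' Counterpart of the GFF3 written by [write_sim_bundle()]: mRNA
#' features define transcript ids, lengths and coding status; CDS
#' features carry the coding interval (converted back to 0-based
#' half-open).
#'
#' @param path GFF3 file path.
#' @return Gene-model data frame (`tx_id`, `gene_id`, `length`,
#'   `cds_start`, `cds_end`, `coding`).
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mr <- gr[gr$type == "mRNA"]
  cd <- gr[gr$type == "CDS"]
  cds_start <- setNames(GenomicRanges::start(cd) - 1L,
                        as.character(GenomicRanges::seqnames(cd)))
  cds_end <- setNames(GenomicRanges::end(cd),
                      as.character(GenomicRanges::seqnames(cd)))
  tx <- as.character(GenomicRanges::seqnames(mr))
  data.frame(
    tx_id = tx,
    gene_id = mr$gene_id,
    length = GenomicRanges::end(mr),
    cds_start = unname(cds_start[tx]),
    cds_end = unname(cds_end[tx]),
    coding = mr$coding == "coding",
    stringsAsFactors = FALSE)
}

#' Export genome alignments as BED12
#'
#' One BED12 record per transcript-to-genome alignment, with one block
#' per intron-delimited exon segment.
#'
#' @param alignments List of genome `pairwise_alignment` objects.
#' @param path Output BED file.
#' @param min_intron Target-side gap length at or above which a gap is an
#'   intron.
#' @return `path`, invisibly.
#' @export
export_bed12 <- function(alignments, path, min_intron = 30L) {
  alignments <- Filter(Negate(is.null), alignments)
  if (!length(alignments)) {
    file.create(path)
    return(invisible(path))
  }
  grl <- lapply(alignments, function(a) {
    ex <- exon_blocks(a, min_intron = min_intron)
    gr <- GenomicRanges::GRanges(
      seqnames = if (!is.null(a$target_id)) a$target_id else "chr1",
      ranges = IRanges::IRanges(start = min(ex$t_start) + 1L,
                                end = max(ex$t_end)),
      strand = "+",
      name = a$query_id, score = 0L)
    gr$blocks <- IRanges::IRangesList(
      IRanges::IRanges(start = ex$t_start - min(ex$t_start) + 1L,
                       width = ex$t_end - ex$t_start))
    gr
  })
  rtracklayer::export(do.call(c, unname(grl)), path, format = "bed")
  invisible(path)
}

#' Read a FASTQ file with qualities
#'
#' @param path FASTQ file.
#' @return A `QualityScaledDNAStringSet`.
#' @export
read_fastq <- function(path) {
  Biostrings::readQualityScaledDNAStringSet(path)
}
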