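#' Configuration for the synthetic cDNA library generator
#'
#' Describes the simulated world: a toy annotated reference transcriptome
#' embedded in a toy genome, and a directional 5'-sequenced cDNA library
#' read from the diverged ("rhesus") orthologs of those reference
#' ("human") transcripts.  Defaults encode the library this package's
#' analyses were designed around: ~0.8-1 kb single-pass reads, low
#' 5'-completeness, region-specific substitution divergence, occasional
#' indels, vector/host contamination, a ~10% fraction of reads with no
#' reference homolog, and a small fraction of genes carrying a
#' transposable-element-derived cassette exon.
#'
#' @param seed Integer RNG seed; the whole bundle is a deterministic
#'   function of the configuration including this seed.
#' @param n_genes Number of reference genes.
#' @param n_reads Number of raw reads to simulate.
#' @param utr5_len,cds_len,utr3_len Length specs, each a named numeric
#'   vector `c(mean=, sd=, min=)` (optionally `max=`) in nt.  CDS lengths
#'   are rounded to a multiple of 3 and include start and stop codons.
#' @param sub_rate_by_region Named per-site substitution probabilities for
#'   regions `5UTR`, `CDS`, `3UTR`, applied once per gene when deriving
#'   the diverged ortholog (so reads from one gene share the divergence).
#' @param indel_rate Expected indel events per kb of transcript.
#' @param indel_len_p Geometric parameter for indel lengths
#'   (length = 1 + Geom(p)).
#' @param max_indel_len Hard cap on planted indel length (must stay below
#'   the intron threshold used downstream).
#' @param p_5prime_complete Probability a read starts at transcript
#'   position 0 (the library's 5'-completeness).
#' @param read_len Read length spec `c(mean=, sd=, min=, max=)` in nt.
#' @param p_vector_contam Probability a read carries a terminal vector
#'   segment (trimmable carry-over from the cloning site).
#' @param p_vector_read Probability a raw read is pure vector (removed
#'   whole by cleaning).
#' @param p_host_read Probability a raw read is host (E. coli / phage)
#'   contamination.
#' @param p_unknown Fraction of (non-vector, non-host) reads drawn from
#'   loci with no reference-transcriptome homolog.
#' @param unknown_split Length-3 numeric: how the unknown fraction divides
#'   among other-database transcripts, novel genome-encoded loci, and free
#'   ORF-bearing transcripts.  Normalized internally.
#' @param p_te_exon Fraction of coding genes given a transposable-element
#'   derived alternative (cassette) exon in the diverged ortholog.
#' @param p_noncoding Fraction of reference models flagged non-coding /
#'   predicted ("NR_XR").
#' @param p_isoform Fraction of genes with a second (3'-shortened)
#'   isoform.
#' @param te_families Data frame describing repeat families:
#'   `family`, `class`, `length`, `lineage_specific`.
#' @param n_exons Integer range (length 2) for exons per gene on the toy
#'   genome.
#' @param intron_len,intergenic_len Integer ranges (length 2) for intron
#'   and intergenic segment lengths (introns at least 50 nt).
#' @param n_other_db,n_novel_genome,n_novel_free Pool sizes for
#'   non-reference transcripts.
#' @param quality Quality model `c(start=, end=, sd=)`: per-base Phred
#'   means decay linearly from `start` at the 5' end to `end` at the 3'
#'   end.
#' @param reverse_reads If `TRUE` a random half of reads are
#'   reverse-complemented; off by default (directional library).
#'
#' @return A validated list of class `sim_config`.
#' @seealso [make_reference_set()], [simulate_cdna_reads()],
#'   [paper_profile_rates()]
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 60L,
                       n_reads = 400L,
                       utr5_len = c(mean = 150, sd = 60, min = 30),
                       cds_len = c(mean = 900, sd = 300, min = 120),
                       utr3_len = c(mean = 500, sd = 200, min = 60),
                       sub_rate_by_region = c("5UTR" = 0.049,
                                              "CDS" = 0.032,
                                              "3UTR" = 0.067),
                       indel_rate = 0.2,
                       indel_len_p = 0.5,
                       max_indel_len = 20L,
                       p_5prime_complete = 0.2,
                       read_len = c(mean = 858, sd = 150,
                                    min = 170, max = 1174),
                       p_vector_contam = 0.25,
                       p_vector_read = 0.0825,
                       p_host_read = 0.005,
                       p_unknown = 0.102,
                       unknown_split = c(other_db = 66,
                                         novel_genome = 60,
                                         novel_free = 61),
                       p_te_exon = 0.05,
                       p_noncoding = 0.034,
                       p_isoform = 0.1,
                       te_families = default_te_families(),
                       n_exons = c(2L, 12L),
                       intron_len = c(60L, 400L),
                       intergenic_len = c(200L, 1000L),
                       n_other_db = 12L,
                       n_novel_genome = 12L,
                       n_novel_free = 12L,
                       quality = c(start = 40, end = 10, sd = 4),
                       reverse_reads = FALSE) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_reads = as.integer(n_reads),
              utr5_len = utr5_len, cds_len = cds_len, utr3_len = utr3_len,
              sub_rate_by_region = sub_rate_by_region,
              indel_rate = indel_rate, indel_len_p = indel_len_p,
              max_indel_len = as.integer(max_indel_len),
              p_5prime_complete = p_5prime_complete, read_len = read_len,
              p_vector_contam = p_vector_contam,
              p_vector_read = p_vector_read, p_host_read = p_host_read,
              p_unknown = p_unknown,
              unknown_split = unknown_split / sum(unknown_split),
              p_te_exon = p_te_exon, p_noncoding = p_noncoding,
              p_isoform = p_isoform, te_families = te_families,
              n_exons = as.integer(n_exons),
              intron_len = as.integer(intron_len),
              intergenic_len = as.integer(intergenic_len),
              n_other_db = as.integer(n_other_db),
              n_novel_genome = as.integer(n_novel_genome),
              n_novel_free = as.integer(n_novel_free),
              quality = quality, reverse_reads = isTRUE(reverse_reads))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$p_5prime_complete, cfg$p_vector_contam, cfg$p_vector_read,
             cfg$p_host_read, cfg$p_unknown, cfg$p_te_exon, cfg$p_noncoding,
             cfg$p_isoform, cfg$indel_len_p, cfg$sub_rate_by_region)
  if (any(probs < 0 | probs > 1))
    stop("sim_config: all probabilities must lie in [0, 1]")
  if (!all(c("5UTR", "CDS", "3UTR") %in% names(cfg$sub_rate_by_region)))
    stop("sim_config: sub_rate_by_region needs entries 5UTR, CDS, 3UTR")
  for (nm in c("utr5_len", "cds_len", "utr3_len", "read_len")) {
    spec <- cfg[[nm]]
    if (any(spec[c("mean", "min")] < 1))
      stop("sim_config: length parameters must be >= 1 (", nm, ")")
  }
  if (cfg$cds_len[["min"]] < 9)
    stop("sim_config: degenerate CDS length distribution (min < 9 nt)")
  if (cfg$n_genes < 1 || cfg$n_reads < 0)
    stop("sim_config: n_genes must be >= 1 and n_reads >= 0")
  if (cfg$intron_len[1] < 50)
    stop("sim_config: introns must be at least 50 nt")
  invisible(cfg)
}

#' Default repeat family table for the simulator
#'
#' A small panel of transposable-element families: two lineage-specific
#' Alu subfamilies and one lineage-specific LTR family (the kinds found
#' exonized in rhesus transcripts), plus two ancient families shared
#' across primates as negative controls for the species-specific flag.
#'
#' @return Data frame with columns `family`, `class`, `length`,
#'   `lineage_specific`.
#' @export
default_te_families <- function() {
  data.frame(
    family = c("AluYRa2", "AluYRa1", "MER11B", "AluSx", "L1MB5"),
    class = c("SINE", "SINE", "LTR", "SINE", "LINE"),
    length = c(300L, 300L, 500L, 300L, 600L),
    lineage_specific = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Per-category divergence rates of the library profile
#'
#' Substitution rates per mapping category chosen so that
#' `100 * (1 - rate)` equals the published per-category human-rhesus
#' consensus identities for a placenta full-length cDNA collection
#' (e.g. 96.8% in CDS-only spans, 93.3% in 3'UTR-only spans).  Used by
#' [simulate_region_panel()] and by the identity-recovery tests.
#'
#' @return Named numeric vector of per-site substitution probabilities,
#'   one per span category.
#' @export
paper_profile_rates <- function() {
  c("5UTR_CDS" = 0.049,
    "5UTR_CDS_3UTR" = 0.041,
    "CDS" = 0.032,
    "CDS_3UTR" = 0.043,
    "3UTR" = 0.067)
}
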