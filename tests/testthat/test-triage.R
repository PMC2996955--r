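# ORF calling and the evidence-cascade triage.

test_that("find_orf works on hand-checked cases", {
  orf <- find_orf("ATGAAATAA", min_aa = 2)
  expect_equal(orf$aa_length, 2L)
  expect_equal(orf$peptide, "MK")
  expect_equal(c(orf$start, orf$end), c(0L, 9L))
  expect_equal((orf$end - orf$start) %% 3, 0)

  expect_null(find_orf(strrep("C", 300)))          # no ATG at all
  expect_null(find_orf("ATGAAATAA", min_aa = 3))   # below the gate
  # ORF in frame 1
  orf2 <- find_orf(paste0("G", "ATGAAAAAATGA"), min_aa = 3)
  expect_equal(orf2$frame, 1L)
  expect_equal(orf2$aa_length, 3L)
})

test_that("find_orf equals exhaustive ATG..stop enumeration", {
  set.seed(51)
  for (i in 1:60) {
    seq <- if (i %% 3 == 0) orf_sequence(sample(40:120, 1)) else
      random_seq(900)
    got <- find_orf(seq, min_aa = 20)
    want <- oracle_best_orf(seq, min_aa = 20)
    if (is.null(want)) {
      expect_null(got, label = sprintf("case %d", i))
    } else {
      expect_false(is.null(got), label = sprintf("case %d", i))
      expect_equal(got$aa_length, want$aa, label = sprintf("case %d", i))
      expect_equal(got$start, want$start, label = sprintf("case %d", i))
      expect_equal(got$end, want$end, label = sprintf("case %d", i))
      # invariant: no internal stop in the peptide
      expect_false(grepl("*", got$peptide, fixed = TRUE))
      expect_equal(got$aa_length, (got$end - got$start) / 3 - 1)
    }
  }
})

test_that("triage cascade assigns the planted classes", {
  w <- clean_world()
  refs <- w$refs
  tr <- w$sim$truth$reads
  annot <- genome_annotation(refs)
  params <- triage_params()
  params$refseq_index <- kmer_index(refs$transcripts, k = 12L, step = 1L)

  # a reference-derived read is a REFSEQ_MATCH and never genome-mapped
  rid <- tr$read_id[tr$class == "REFSEQ"][1]
  res <- triage(as.character(w$sim$reads[[rid]]), rid,
                refs$transcripts, refs$other_db, refs$genome, annot,
                params)
  expect_equal(res$class, "REFSEQ_MATCH")
  expect_null(res$genome_hit)

  # a novel genome-encoded transcript with its ORF: GENOME_ORF with the
  # planted exon count
  gmap <- refs$genome_map
  nvg <- names(refs$novel_genome)[1]
  res2 <- triage(as.character(refs$novel_genome[[nvg]]), nvg,
                 refs$transcripts, refs$other_db, refs$genome, annot,
                 params)
  expect_equal(res2$class, "GENOME_ORF")
  planted <- sum(gmap$kind == "exon" & gmap$owner == nvg)
  expect_equal(nrow(exon_blocks(res2$genome_hit)), planted)

  # a free ORF-bearing transcript: ORF_ONLY
  nvf <- names(refs$novel_free)[1]
  res3 <- triage(as.character(refs$novel_free[[nvf]]), nvf,
                 refs$transcripts, refs$other_db, refs$genome, annot,
                 params)
  expect_equal(res3$class, "ORF_ONLY")

  # an other-database transcript: OTHER_DB_MATCH before genome mapping
  odb <- names(refs$other_db)[1]
  res4 <- triage(as.character(refs$other_db[[odb]]), odb,
                 refs$transcripts, refs$other_db, refs$genome, annot,
                 params)
  expect_equal(res4$class, "OTHER_DB_MATCH")
  expect_null(res4$genome_hit)

  # random sequence without ORF: UNCLASSIFIED, never forced
  set.seed(52)
  junk <- paste(sample(c("C", "G"), 400, replace = TRUE), collapse = "")
  res5 <- triage(junk, "junk", refs$transcripts, refs$other_db,
                 refs$genome, annot, params)
  expect_equal(res5$class, "UNCLASSIFIED")
})

test_that("triage_set partitions its input", {
  w <- clean_world()
  seqs <- c(
    as.character(w$sim$reads[1:5]),
    ODB = as.character(w$refs$other_db[[2]]),
    NVF = as.character(w$refs$novel_free[[2]]))
  tr <- triage_set(seqs, w$refs$transcripts, w$refs$other_db,
                   w$refs$genome, genome_annotation(w$refs))
  expect_equal(nrow(tr$table), length(seqs))
  expect_equal(sum(table(tr$table$class)), length(seqs))
  expect_equal(anyDuplicated(tr$table$id), 0L)
})

test_that("genome context labels follow the block/annotation overlap rules", {
  annot <- list(
    genes = data.frame(gene_id = "G1", g_start = 1000L, g_end = 5000L),
    exons = data.frame(gene_id = c("G1", "G1"),
                       g_start = c(1000L, 3000L),
                       g_end = c(1500L, 3500L)))
  blk <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(q_start = 0L, q_end = 0L, t_start = m[, 1], t_end = m[, 2])
  }
  expect_equal(label_genome_context(blk(8000, 8300), annot), "Intergenic")
  expect_equal(label_genome_context(blk(2000, 2200), annot),
               "G1 (Intron)")
  expect_equal(label_genome_context(blk(1200, 1300, 2000, 2200), annot),
               "G1 (Intron,Exon)")
  # block abutting an exon end under half-open arithmetic is intronic
  expect_equal(label_genome_context(blk(1500, 1600), annot),
               "G1 (Intron)")
  expect_equal(label_genome_context(blk(2000, 2100, 9000, 9100), annot),
               "G1 (Intron), Intergenic")
})
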