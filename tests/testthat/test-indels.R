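# INDEL detection, region classification and the exonization screen.

mk_model <- function(len = 1000L, cds_start = 200L, cds_end = 800L) {
  data.frame(tx_id = "T1", gene_id = "G1", length = len,
             cds_start = cds_start, cds_end = cds_end, coding = TRUE,
             stringsAsFactors = FALSE)
}

test_that("gapless alignments yield no indel events", {
  set.seed(61)
  t <- random_seq(300)
  a <- align_local(mutated_copy(t, 0.03), t)
  expect_equal(nrow(detect_indels(a)), 0L)
})

test_that("a planted deletion is recovered at its position", {
  set.seed(62)
  t <- random_seq(600)
  q <- paste0(substr(t, 1, 300), substr(t, 305, 600))  # del [300,304)
  ev <- detect_indels(align_local(q, t))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$side, "deletion-from-query")
  expect_equal(ev$length, 4L)
  expect_lte(abs(ev$t_pos - 300L), 2L)
})

test_that("a planted insertion is recovered with the right side", {
  set.seed(63)
  t <- random_seq(600)
  q <- paste0(substr(t, 1, 300), "TACGA", substr(t, 301, 600))
  ev <- detect_indels(align_local(q, t))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$side, "insertion-in-query")
  expect_equal(ev$length, 5L)
  expect_lte(abs(ev$t_pos - 300L), 2L)
})

test_that("target gaps at or above min_intron are introns, not indels", {
  set.seed(64)
  t <- random_seq(800)
  q <- paste0(substr(t, 1, 300), substr(t, 341, 800))  # 40-nt gap
  a <- align_local(q, t)
  expect_equal(nrow(detect_indels(a, min_intron = 30)), 0L)
  expect_equal(nrow(detect_indels(a, min_intron = 50)), 1L)
})

test_that("indel region classification honors boundaries and compounds", {
  m <- mk_model()
  del <- function(pos, len) data.frame(
    side = "deletion-from-query", t_pos = pos, length = len)
  ins <- function(pos) data.frame(
    side = "insertion-in-query", t_pos = pos, length = 3L)
  expect_equal(classify_indel_region(del(400, 4), m), "CDS")
  expect_equal(classify_indel_region(ins(400), m), "CDS")
  expect_equal(classify_indel_region(del(100, 4), m), "5UTR")
  expect_equal(classify_indel_region(del(900, 4), m), "3UTR")
  # deletion spanning cds_end gets the compound label
  expect_equal(classify_indel_region(del(798, 6), m), "CDS_3UTR")
  expect_equal(classify_indel_region(del(196, 6), m), "5UTR_CDS")
  expect_error(classify_indel_region(del(1200, 4), m), "outside")
})

test_that("summarize_indels counts transcripts per region", {
  ev <- data.frame(
    transcript_id = c("r1", "r1", "r1", "r2", "r3", "r3"),
    region = c("CDS", "CDS", "3UTR", "CDS", "5UTR", "5UTR"),
    stringsAsFactors = FALSE)
  s <- summarize_indels(ev)
  br <- s$by_region
  expect_equal(br$transcripts[br$region == "CDS"], 2L)   # r1, r2
  expect_equal(br$transcripts[br$region == "3UTR"], 1L)
  expect_equal(br$transcripts[br$region == "5UTR"], 1L)
  expect_equal(br$events[br$region == "CDS"], 3L)
  expect_equal(s$functional_total, 4L)  # r1 twice (CDS+3UTR), r2, r3
  expect_equal(s$n_transcripts, 3L)
  z <- summarize_indels(ev[0, ])
  expect_true(all(z$by_region$transcripts == 0L))
  expect_equal(z$functional_total, 0L)
})

test_that("every target gap is counted exactly once as indel xor intron", {
  w <- shared_world()
  hits <- local({
    idx <- kmer_index(w$refs$transcripts, k = 12L, step = 1L)
    seqs <- as.character(w$sim$reads)
    tr <- w$sim$truth$reads
    ids <- tr$read_id[tr$class == "REFSEQ"][1:25]
    hh <- lapply(ids, function(id)
      best_hit(seqs[[id]], w$refs$transcripts, index = idx, qid = id))
    names(hh) <- ids
    hh
  })
  for (a in Filter(Negate(is.null), hits)) {
    g <- a$gaps[a$gaps$side == "target", , drop = FALSE]
    ev <- detect_indels(a, min_intron = 30)
    n_indel_del <- sum(ev$side == "deletion-from-query")
    n_intron <- sum(g$length >= 30)
    expect_equal(n_indel_del + n_intron, nrow(g), label = a$query_id)
  }
})

test_that("TE exonization screen calls planted cassettes and respects thresholds", {
  w <- shared_world()
  te <- w$refs$te_ledger
  expect_gt(nrow(te), 0)
  tx <- te$tx_id[1]
  seq <- w$refs$ortholog[[tx]]$seq
  ga <- map_to_genome(seq, w$refs$genome, qid = tx)
  expect_false(is.null(ga))
  ma <- align_local(seq, as.character(w$refs$transcripts[[tx]]),
                    qid = tx, tid = tx)
  calls <- screen_te_exons(ga, ma, w$refs$repeats)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$family, te$family[1])
  expect_true(calls$species_specific)
  expect_gte(calls$overlap_fraction, 0.99)
  # the called block is the planted segment
  expect_lte(abs(calls$g_start - te$seg_g_start[1]), 4)
  expect_lte(abs(calls$g_end - te$seg_g_end[1]), 4)

  # a transcript without a cassette yields no calls
  plain_tx <- setdiff(w$refs$models$tx_id, te$tx_id)[1]
  pseq <- w$refs$ortholog[[plain_tx]]$seq
  pga <- map_to_genome(pseq, w$refs$genome, qid = plain_tx)
  pma <- align_local(pseq,
                     as.character(w$refs$transcripts[[plain_tx]]),
                     qid = plain_tx, tid = plain_tx)
  expect_equal(nrow(screen_te_exons(pga, pma, w$refs$repeats)), 0L)

  # coverage below min_overlap suppresses the call
  calls2 <- screen_te_exons(ga, ma, w$refs$repeats, min_overlap = 1.01)
  expect_equal(nrow(calls2), 0L)
})
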