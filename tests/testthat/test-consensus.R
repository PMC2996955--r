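# Consensus building and per-region identity recovery.

align_members <- function(members, ref) {
  lapply(names(members), function(id)
    align_local(members[[id]], ref, qid = id, tid = "T1"))
}

test_that("consensus of two identical members is the member", {
  set.seed(41)
  ref <- random_seq(300)
  mem <- mutated_copy(substr(ref, 51, 250), 0.03)
  alns <- align_members(c(m1 = mem, m2 = mem), ref)
  cons <- build_consensus(alns, ref)
  expect_equal(cons$sequence, mem)
  expect_equal(cons$n_members, 2L)
})

test_that("majority vote and reference tie-break behave as stated", {
  # members AAT, AAT, ACT at the same offset: column 2 majority A
  ref <- "GGAATGG"
  alns <- align_members(c(a = "GGAATGG", b = "GGAATGG", c = "GGACTGG"),
                        ref)
  cons <- build_consensus(alns, ref)
  expect_equal(cons$sequence, "GGAATGG")

  # two members tie A/C at one column; reference C wins
  refC <- "GGGGCTTTT"
  alns2 <- align_members(c(a = "GGGGATTTT", b = "GGGGCTTTT"), refC)
  cons2 <- build_consensus(alns2, refC)
  expect_equal(substr(cons2$sequence, 5, 5), "C")

  # tie between two non-reference bases falls back to alphabetical
  refT <- "GGGGTTTTT"
  alns3 <- align_members(c(a = "GGGGATTTT", b = "GGGGCTTTT"), refT)
  cons3 <- build_consensus(alns3, refT)
  expect_equal(substr(cons3$sequence, 5, 5), "A")

  expect_error(build_consensus(alns2[1], refC), "at least 2")
})

test_that("consensus bases always come from a covering member", {
  set.seed(42)
  ref <- random_seq(400)
  members <- setNames(lapply(1:3, function(i)
    mutated_copy(substr(ref, 20 + 10 * i, 380 - 5 * i), 0.05)),
    paste0("m", 1:3))
  alns <- align_members(members, ref)
  cons <- build_consensus(alns, ref)
  cols <- cons$columns
  # reconstruct per-column member bases independently
  for (i in sample(nrow(cols), 50)) {
    p <- cols$t_pos[i]
    bases <- character(0)
    for (a in alns) {
      for (b in seq_len(nrow(a$blocks))) {
        if (p >= a$blocks$t_start[b] && p < a$blocks$t_end[b]) {
          off <- p - a$blocks$t_start[b] + 1
          bases <- c(bases, substr(a$blocks$qseq[b], off, off))
        }
      }
    }
    expect_true(cols$base[i] %in% bases)
    expect_equal(cols$support[i], length(bases))
  }
})

test_that("per-region identity recovers planted category rates (small panel)", {
  panel <- simulate_region_panel(
    n_per_category = 25, members = 2,
    rates = c(CDS = 0.032, `3UTR` = 0.067), seed = 5)
  seqs <- as.character(panel$refs$transcripts)
  for (cat in c("CDS", "3UTR")) {
    truth <- panel$truth[panel$truth$category == cat, ]
    ids <- numeric(0)
    for (tx in truth$tx_id) {
      member_ids <- panel$assign$read_id[panel$assign$tx_id == tx]
      alns <- lapply(member_ids, function(rid)
        align_local(panel$reads[[rid]], seqs[[tx]], qid = rid, tid = tx))
      cons <- build_consensus(alns, seqs[[tx]])
      m <- panel$refs$models[match(tx, panel$refs$models$tx_id), ]
      r <- per_region_identity(cons, m)
      expect_equal(r$category, cat, label = tx)
      ids <- c(ids, r$identity_pct)
    }
    rate <- truth$rate[1]
    se <- stats::sd(ids) / sqrt(length(ids))
    expect_lt(abs(mean(ids) - 100 * (1 - rate)), 3 * se + 0.2)
  }
})

test_that("mean recovered identity decreases as the planted rate increases", {
  rates <- c(0.01, 0.05, 0.10)
  means <- vapply(seq_along(rates), function(k) {
    panel <- simulate_region_panel(
      n_per_category = 20, members = 2,
      rates = setNames(rates[k], "CDS"), seed = 100 + k)
    seqs <- as.character(panel$refs$transcripts)
    ids <- vapply(panel$truth$tx_id, function(tx) {
      member_ids <- panel$assign$read_id[panel$assign$tx_id == tx]
      alns <- lapply(member_ids, function(rid)
        align_local(panel$reads[[rid]], seqs[[tx]], qid = rid, tid = tx))
      m <- panel$refs$models[match(tx, panel$refs$models$tx_id), ]
      per_region_identity(build_consensus(alns, seqs[[tx]]),
                          m)$identity_pct
    }, numeric(1))
    mean(ids)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("identity_report aggregates in fixed category order", {
  recs <- list(
    list(category = "3UTR", identity_pct = 90, n_columns = 100,
         gene_id = "G1", tx_id = "G1.1"),
    list(category = "3UTR", identity_pct = 100, n_columns = 100,
         gene_id = "G2", tx_id = "G2.1"),
    list(category = "CDS", identity_pct = 97, n_columns = 200,
         gene_id = "G3", tx_id = "G3.1"),
    list(category = "CDS", identity_pct = NA_real_, n_columns = 0,
         gene_id = "G4", tx_id = "G4.1"))
  rep <- identity_report(recs)
  expect_equal(rep$summary$category, c("CDS", "3UTR"))
  expect_equal(rep$summary$mean_pct[rep$summary$category == "3UTR"], 95.0)
  expect_equal(rep$summary$n[rep$summary$category == "3UTR"], 2L)
  expect_equal(rep$n_consensus, 3L)  # the undefined record is excluded
  expect_equal(rep$n_genes, 3L)
  empty <- identity_report(list())
  expect_equal(nrow(empty$summary), 0L)
})
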