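# Local alignment: block bookkeeping, identity arithmetic, DP-oracle
# equivalence, best-hit selection.

test_that("identical sequences give one full-identity block", {
  s <- random_seq(50)
  a <- align_local(s, s)
  expect_equal(nrow(a$blocks), 1L)
  expect_equal(a$matches, 50L)
  expect_equal(a$mismatches, 0L)
  expect_equal(alignment_identity(a), 1.0)
  expect_equal(a$q_span, c(0L, 50L))
})

test_that("an internal deletion yields two blocks and one target-side gap", {
  set.seed(4)
  t <- random_seq(120)
  q <- paste0(substr(t, 1, 60), substr(t, 66, 120))  # 5-nt deletion
  a <- align_local(q, t)
  expect_equal(nrow(a$blocks), 2L)
  expect_equal(nrow(a$gaps), 1L)
  expect_equal(a$gaps$side, "target")
  expect_equal(a$gaps$length, 5L)
  expect_equal(a$gaps$t_pos, 60L)
})

test_that("empty input yields an empty alignment with score 0", {
  a <- align_local("", "ACGT")
  expect_equal(a$score, 0)
  expect_equal(nrow(a$blocks), 0L)
  expect_true(is.na(alignment_identity(a)))
})

test_that("alignment score equals the brute-force affine DP oracle", {
  set.seed(5)
  for (i in 1:60) {
    n1 <- sample(40:160, 1)
    related <- i %% 2 == 0
    q <- random_seq(n1)
    t <- if (related) {
      core <- mutated_copy(substr(q, 10, n1 - 5), 0.08)
      paste0(random_seq(sample(5:30, 1)), core, random_seq(sample(5:30, 1)))
    } else random_seq(sample(40:200, 1))
    a <- align_local(q, t)
    expect_equal(a$score, oracle_local_score(q, t),
                 label = sprintf("pair %d", i))
  }
})

test_that("score is symmetric under query/target swap", {
  set.seed(6)
  for (i in 1:10) {
    q <- mutated_copy(random_seq(100), 0)
    t <- mutated_copy(q, 0.1)
    expect_equal(align_local(q, t)$score, align_local(t, q)$score)
  }
})

test_that("block substrings are faithful and Hamming distance equals mismatches", {
  set.seed(7)
  for (i in 1:10) {
    t <- random_seq(300)
    q <- mutated_copy(substr(t, 20, 280), 0.05)
    a <- align_local(q, t, qid = "q", tid = "t")
    qcat <- paste(a$blocks$qseq, collapse = "")
    tcat <- paste(a$blocks$tseq, collapse = "")
    expect_equal(nchar(qcat), nchar(tcat))
    qc <- strsplit(qcat, "")[[1]]
    tc <- strsplit(tcat, "")[[1]]
    expect_equal(sum(qc != tc), a$mismatches)
    expect_equal(sum(qc == tc), a$matches)
    # block coordinates index the original sequences
    for (b in seq_len(nrow(a$blocks))) {
      expect_identical(a$blocks$qseq[b],
                       substr(q, a$blocks$q_start[b] + 1,
                              a$blocks$q_end[b]))
      expect_identical(a$blocks$tseq[b],
                       substr(t, a$blocks$t_start[b] + 1,
                              a$blocks$t_end[b]))
    }
  }
})

test_that("N never counts as a match", {
  s <- paste0(strrep("ACGT", 5), "NN", strrep("ACGT", 5))
  a <- align_local(s, s)  # flanks long enough to bridge the N island
  expect_equal(a$matches + a$mismatches, 42L)
  expect_equal(a$matches, 40L)   # the two N-N columns are mismatches
  expect_equal(a$mismatches, 2L)
})

test_that("identity restriction uses target coordinates and signals undefined", {
  set.seed(8)
  t <- random_seq(200)
  q <- mutated_copy(t, 0.05)
  a <- align_local(q, t)
  id_all <- alignment_identity(a)
  expect_equal(id_all, a$matches / (a$matches + a$mismatches))
  expect_true(is.na(alignment_identity(a, restrict_to = c(500, 600))))
  # 100 columns with 5 mismatches -> 0.95
  tt <- random_seq(100)
  qq <- strsplit(tt, "")[[1]]
  flip <- c(10, 30, 50, 70, 90)
  for (p in flip) qq[p] <- setdiff(c("A", "C", "G", "T"), qq[p])[1]
  a2 <- align_local(paste(qq, collapse = ""), tt)
  if (a2$matches + a2$mismatches == 100) {
    expect_equal(alignment_identity(a2), 0.95)
  }
})

test_that("best_hit picks the true target and honors thresholds and ties", {
  set.seed(9)
  targets <- setNames(vapply(1:5, function(i) random_seq(400),
                             character(1)), paste0("T", 1:5))
  q <- substr(targets[["T3"]], 50, 350)
  hit <- best_hit(q, targets)
  expect_equal(hit$target_id, "T3")

  expect_null(best_hit(random_seq(300), targets))

  # two identical targets: lexicographically smaller id wins
  targets2 <- c(B = targets[["T1"]], A = targets[["T1"]])
  q2 <- substr(targets[["T1"]], 30, 330)
  expect_equal(best_hit(q2, targets2)$target_id, "A")

  # below aligned-length threshold
  expect_null(best_hit(substr(targets[["T2"]], 1, 80), targets,
                       min_aligned = 100L))
})

test_that("seed-indexed best_hit agrees with exhaustive best_hit", {
  w <- clean_world()
  idx <- kmer_index(w$refs$transcripts, k = 12L, step = 1L)
  seqs <- as.character(w$sim$reads)[1:15]
  for (id in names(seqs)) {
    h1 <- best_hit(seqs[[id]], w$refs$transcripts, qid = id)
    h2 <- best_hit(seqs[[id]], w$refs$transcripts, index = idx, qid = id)
    expect_false(is.null(h1))
    expect_equal(h2$target_id, h1$target_id)
    expect_equal(h2$score, h1$score)
  }
})
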