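# Cleaning: quality trimming, vector screening, length filter.

test_that("quality_trim handles uniform-quality reads", {
  expect_equal(quality_trim(rep(40L, 80)), c(0L, 80L))
  expect_equal(quality_trim(rep(10L, 80)), c(0L, 0L))
  # read shorter than the window is a single whole-read window
  expect_equal(quality_trim(rep(30L, 5), window = 10), c(0L, 5L))
  expect_equal(quality_trim(rep(5L, 5), window = 10), c(0L, 0L))
})

test_that("quality_trim cuts a collapsing tail near the drop point", {
  q <- c(rep(30L, 50), rep(5L, 50))
  iv <- quality_trim(q, window = 10, min_mean_q = 20)
  expect_equal(iv[1], 0L)
  expect_true(iv[2] >= 50L && iv[2] <= 60L)
})

test_that("quality_trim agrees with the exhaustive interval oracle", {
  set.seed(1)
  for (i in 1:25) {
    n <- sample(20:90, 1)
    q <- sample(2:41, n, replace = TRUE)
    w <- sample(c(5L, 10L), 1)
    got <- quality_trim(q, window = w, min_mean_q = 20)
    want <- oracle_quality_trim(q, window = w, min_q = 20)
    expect_equal(got[2] - got[1], want[2] - want[1],
                 label = sprintf("case %d length", i))
    # the returned interval must itself be window-clean
    if (got[2] > got[1]) {
      sub <- q[(got[1] + 1):got[2]]
      if (length(sub) > w) {
        means <- vapply(0:(length(sub) - w), function(s)
          mean(sub[(s + 1):(s + w)]), numeric(1))
        expect_true(all(means >= 20))
      }
    }
  }
})

test_that("vector screening trims planted terminal vector and removes pure vector", {
  set.seed(2)
  vec <- random_seq(800)
  insert <- random_seq(400)
  read <- paste0(substr(vec, 741, 800), insert)  # 60-nt vector prefix
  vs <- vector_screen(read, c(v1 = vec))
  expect_equal(vs$status, "KEPT")
  expect_equal(substr(read, vs$start + 1, vs$end), insert)

  clean <- vector_screen(insert, c(v1 = vec))
  expect_equal(clean$status, "KEPT")
  expect_equal(c(clean$start, clean$end), c(0L, 400L))

  pure <- vector_screen(substr(vec, 101, 500), c(v1 = vec))
  expect_equal(pure$status, "REMOVED_VECTOR")

  # internal vector with long clean flanks marks a chimeric clone
  chim <- paste0(random_seq(150), substr(vec, 301, 400), random_seq(150))
  expect_equal(vector_screen(chim, c(v1 = vec))$status, "REMOVED_VECTOR")
})

test_that("length filter is strict at the threshold", {
  expect_equal(length_filter(c(100L, 101L, 5L), min_length = 100),
               c("REMOVED_SHORT", "KEPT", "REMOVED_SHORT"))
})

test_that("cleaning partitions reads and matches the simulation ledger", {
  w <- shared_world()
  cl <- clean_reads(w$sim$reads, w$sim$quals,
                    vector_lib = w$refs$vector, host = w$refs$host)
  rep <- cl$report
  expect_equal(nrow(rep), length(w$sim$reads))
  expect_equal(sum(rep$status == "KEPT") +
                 sum(startsWith(rep$status, "REMOVED")), nrow(rep))
  expect_equal(length(cl$kept), sum(rep$status == "KEPT"))

  tr <- w$sim$truth$reads
  vec_ids <- tr$read_id[tr$class == "VECTOR"]
  host_ids <- tr$read_id[tr$class == "HOST"]
  # every pure-vector read is removed as vector, every host read as host
  expect_true(all(rep$status[rep$read_id %in% vec_ids] ==
                    "REMOVED_VECTOR"))
  if (length(host_ids))
    expect_true(all(rep$status[rep$read_id %in% host_ids] ==
                      "REMOVED_HOST"))
  # kept-set size equals raw minus removals, and no source read is lost
  expect_equal(length(cl$kept),
               nrow(rep) - sum(startsWith(rep$status, "REMOVED")))
})

test_that("kept intervals are literal substrings and cleaning is idempotent", {
  w <- shared_world()
  cl <- clean_reads(w$sim$reads, w$sim$quals,
                    vector_lib = w$refs$vector, host = w$refs$host)
  raw <- as.character(w$sim$reads)
  rep <- cl$report[cl$report$status == "KEPT", ]
  for (i in seq_len(nrow(rep))) {
    id <- rep$read_id[i]
    expect_identical(as.character(cl$kept[[id]]),
                     substr(raw[[id]], rep$start[i] + 1, rep$end[i]))
  }
  cl2 <- clean_reads(cl$kept, quals = NULL,
                     vector_lib = w$refs$vector, host = w$refs$host)
  expect_true(all(cl2$report$status == "KEPT"))
  expect_identical(as.character(cl2$kept), as.character(cl$kept))
})

test_that("vector-contaminated reference reads recover their source substring", {
  w <- shared_world()
  tr <- w$sim$truth$reads
  contam <- tr[tr$class == "REFSEQ" & tr$vec5 > 0 & tr$vec3 == 0, ]
  expect_gt(nrow(contam), 0)
  for (i in seq_len(min(5, nrow(contam)))) {
    id <- contam$read_id[i]
    vs <- vector_screen(as.character(w$sim$reads[[id]]), w$refs$vector)
    expect_equal(vs$status, "KEPT", label = id)
    trimmed <- substr(as.character(w$sim$reads[[id]]),
                      vs$start + 1, vs$end)
    src <- w$refs$ortholog[[contam$tx_id[i]]]$seq
    expect_true(grepl(trimmed, src, fixed = TRUE), label = id)
  }
})
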