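# Synthetic-data generator: determinism, ledger closure, rate recovery.

test_that("identical config yields byte-identical output bundles", {
  cfg <- sim_config(seed = 11, n_genes = 8, n_reads = 20)
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  for (d in c(d1, d2)) {
    refs <- make_reference_set(cfg)
    sim <- simulate_cdna_reads(refs, cfg)
    write_sim_bundle(sim, refs, d)
  }
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("p_te_exon = 0 plants no lineage-specific repeat in any exon", {
  cfg <- sim_config(seed = 3, n_genes = 15, n_reads = 0, p_te_exon = 0)
  refs <- make_reference_set(cfg)
  expect_equal(nrow(refs$te_ledger), 0L)
  ex <- refs$genome_map[refs$genome_map$kind == "exon", ]
  rp <- refs$repeats[refs$repeats$lineage_specific, , drop = FALSE]
  if (nrow(rp) && nrow(ex)) {
    for (i in seq_len(nrow(rp))) {
      ov <- pmax(0, pmin(ex$g_end, rp$g_end[i]) -
                    pmax(ex$g_start, rp$g_start[i]))
      expect_true(all(ov == 0))
    }
  }
  succeed()
})

test_that("genome length equals the sum of the segment ledger", {
  cfg <- sim_config(seed = 5, n_genes = 50, n_reads = 0)
  refs <- make_reference_set(cfg)
  gmap <- refs$genome_map
  # ledger tiles the genome: contiguous, non-overlapping
  expect_equal(gmap$g_start, c(0L, gmap$g_end[-nrow(gmap)]))
  expect_equal(sum(gmap$g_end - gmap$g_start),
               nchar(as.character(refs$genome[[1]])))
})

test_that("gene models are well-formed", {
  refs <- shared_world()$refs
  m <- refs$models
  cod <- m[m$coding, ]
  expect_true(all((cod$cds_end - cod$cds_start) %% 3 == 0))
  expect_true(all(cod$cds_start >= 0 & cod$cds_end <= cod$length))
  for (i in seq_len(nrow(cod))) {
    tx <- as.character(refs$transcripts[[cod$tx_id[i]]])
    expect_identical(substr(tx, cod$cds_start[i] + 1,
                            cod$cds_start[i] + 3), "ATG")
    expect_true(substr(tx, cod$cds_end[i] - 2, cod$cds_end[i]) %in%
                  c("TAA", "TAG", "TGA"))
  }
  expect_true(all(is.na(m$cds_start[!m$coding])))
})

test_that("degenerate length distributions are rejected", {
  expect_error(sim_config(cds_len = c(mean = 0, sd = 0, min = 0)),
               "degenerate|>= 1")
  expect_error(sim_config(p_unknown = 1.4), "probabilities")
  expect_error(sim_config(sub_rate_by_region = c(CDS = 0.01)),
               "sub_rate_by_region")
})

test_that("noise-free reads are exact substrings of their source", {
  w <- clean_world()
  tr <- w$sim$truth$reads
  for (i in seq_len(nrow(tr))) {
    src <- as.character(w$refs$transcripts[[tr$tx_id[i]]])
    expect_true(grepl(as.character(w$sim$reads[[i]]), src, fixed = TRUE))
  }
})

test_that("p_unknown = 1 yields no reference-derived reads", {
  cfg <- sim_config(seed = 9, n_genes = 6, n_reads = 30, p_unknown = 1,
                    p_vector_read = 0, p_host_read = 0)
  refs <- make_reference_set(cfg)
  sim <- simulate_cdna_reads(refs, cfg)
  expect_true(all(sim$truth$reads$class != "REFSEQ"))
  expect_true(all(is.na(sim$truth$reads$gene_id)))
})

test_that("ledger closure: diffing ortholog vs reference recovers every planted substitution", {
  cfg <- sim_config(seed = 13, n_genes = 10, n_reads = 0,
                    indel_rate = 0, p_te_exon = 0)
  refs <- make_reference_set(cfg)
  for (tx in names(refs$ortholog)) {
    o <- refs$ortholog[[tx]]
    h <- strsplit(as.character(refs$transcripts[[tx]]), "")[[1]]
    r <- strsplit(o$seq, "")[[1]]
    expect_equal(length(h), length(r))
    observed <- which(h != r) - 1L
    expect_setequal(observed, o$subs$h_pos)
  }
})

test_that("empirical substitution rate recovers the configured rate within 3 SE", {
  cfg <- sim_config(seed = 17, n_genes = 50, n_reads = 0,
                    sub_rate_by_region = c("5UTR" = 0.02, "CDS" = 0.05,
                                           "3UTR" = 0.08),
                    utr5_len = c(mean = 300, sd = 60, min = 150),
                    utr3_len = c(mean = 600, sd = 100, min = 300),
                    indel_rate = 0, p_te_exon = 0, p_noncoding = 0)
  refs <- make_reference_set(cfg)
  for (reg in c("5UTR", "CDS", "3UTR")) {
    n_sites <- 0L
    n_subs <- 0L
    for (tx in names(refs$ortholog)) {
      m <- refs$models[match(tx, refs$models$tx_id), ]
      o <- refs$ortholog[[tx]]
      h <- strsplit(as.character(refs$transcripts[[tx]]), "")[[1]]
      r <- strsplit(o$seq, "")[[1]]
      pos <- 0:(length(h) - 1L)
      in_reg <- switch(reg,
        "5UTR" = pos < m$cds_start,
        "CDS" = pos >= m$cds_start & pos < m$cds_end,
        "3UTR" = pos >= m$cds_end)
      n_sites <- n_sites + sum(in_reg)
      n_subs <- n_subs + sum(h[in_reg] != r[in_reg])
    }
    expect_gt(n_sites, 10000)  # >= 10 kb simulated per region
    p <- cfg$sub_rate_by_region[[reg]]
    se <- sqrt(p * (1 - p) / n_sites)
    expect_lt(abs(n_subs / n_sites - p), 3 * se)
  }
})

test_that("simulated read lengths and truncation follow the configured library profile", {
  w <- shared_world()
  tr <- w$sim$truth$reads
  ref <- tr[tr$class == "REFSEQ", ]
  expect_true(all(ref$r_end > ref$r_start))
  # 5'-complete fraction within binomial noise of p_5prime_complete
  p <- mean(ref$r_start == 0)
  expect_lt(abs(p - w$cfg$p_5prime_complete),
            3 * sqrt(0.2 * 0.8 / nrow(ref)) + 0.05)
})
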