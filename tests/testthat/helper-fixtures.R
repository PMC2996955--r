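# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small default-world simulation shared by several module tests
shared_world <- function() {
  fixture("world", function() {
    cfg <- sim_config(seed = 42, n_genes = 25, n_reads = 80)
    refs <- make_reference_set(cfg)
    sim <- simulate_cdna_reads(refs, cfg)
    list(cfg = cfg, refs = refs, sim = sim)
  })
}

# noise-free world: reads are exact substrings of reference transcripts
clean_world <- function() {
  fixture("clean_world", function() {
    cfg <- sim_config(
      seed = 7, n_genes = 15, n_reads = 50,
      sub_rate_by_region = c("5UTR" = 0, "CDS" = 0, "3UTR" = 0),
      indel_rate = 0, p_vector_contam = 0, p_vector_read = 0,
      p_host_read = 0, p_unknown = 0, p_te_exon = 0, p_noncoding = 0)
    refs <- make_reference_set(cfg)
    sim <- simulate_cdna_reads(refs, cfg)
    list(cfg = cfg, refs = refs, sim = sim)
  })
}

# best hits of the clean world's reads against its transcriptome
clean_hits <- function() {
  fixture("clean_hits", function() {
    w <- clean_world()
    idx <- kmer_index(w$refs$transcripts, k = 12L, step = 1L)
    seqs <- as.character(w$sim$reads)
    hits <- lapply(names(seqs), function(id)
      best_hit(seqs[[id]], w$refs$transcripts, index = idx, qid = id))
    names(hits) <- names(seqs)
    hits
  })
}
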