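# Simulated directional 5'-sequenced cDNA reads with a ground-truth
# ledger.  Reads are contiguous substrings of the diverged ortholog of a
# reference transcript (or of a non-reference pool sequence), optionally
# carrying terminal vector segments; qualities decay toward the 3' end.

#' Simulate a cDNA read library from a synthetic reference bundle
#'
#' Draws `config$n_reads` single-pass reads.  Each read is either pure
#' vector, host contamination, a substring of a diverged reference
#' transcript, or a substring of one of the non-reference pools
#' (other-database transcripts, novel genome-encoded loci, free
#' ORF-bearing transcripts).  Reference-derived reads start at the
#' transcript 5' end with probability `p_5prime_complete` and at a
#' uniform internal position otherwise, emulating 5'-truncated clones.
#'
#' @param refs A [make_reference_set()] bundle.
#' @param config The same [sim_config()] used to build `refs`.
#' @return A list of class `flc_sim` with components `reads`
#'   (`DNAStringSet`), `quals` (`PhredQuality`), and `truth` (list with
#'   the per-read data frame `reads`, plus the per-gene divergence
#'   ledgers `subs`, `indels` and `te` copied from the bundle).
#' @export
simulate_cdna_reads <- function(refs, config = refs$config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)

  n <- config$n_reads
  seqs <- character(n)
  quals <- character(n)
  rows <- vector("list", n)
  vec_seq <- as.character(refs$vector[[1]])
  host_seqs <- as_seq_vector(refs$host)
  split_p <- config$unknown_split

  draw_class <- function() {
    u <- runif(1)
    if (u < config$p_vector_read) return("VECTOR")
    u <- u - config$p_vector_read
    if (u < config$p_host_read) return("HOST")
    if (runif(1) < config$p_unknown) {
      return(sample(c("OTHER_DB", "NOVEL_GENOME", "NOVEL_FREE"),
                    1L, prob = split_p))
    }
    "REFSEQ"
  }

  ref_tx_ids <- refs$models$tx_id

  for (i in seq_len(n)) {
    id <- sprintf("SIM%06d", i)
    cls <- draw_class()
    L <- draw_len(config$read_len)
    vec5 <- 0L
    vec3 <- 0L
    tx_id <- NA_character_
    gene_id <- NA_character_
    r_start <- NA_integer_
    r_end <- NA_integer_
    h_start <- NA_integer_
    h_end <- NA_integer_
    category <- NA_character_
    n_subs <- NA_integer_
    n_indels <- NA_integer_
    te_exon <- FALSE

    if (cls == "VECTOR") {
      s <- sample(0:(nchar(vec_seq) - L), 1L)
      seq <- substr0(vec_seq, s, s + L)
    } else if (cls == "HOST") {
      hseq <- host_seqs[[sample(length(host_seqs), 1L)]]
      s <- sample(0:(nchar(hseq) - L), 1L)
      seq <- substr0(hseq, s, s + L)
    } else if (cls == "REFSEQ") {
      tx_id <- sample(ref_tx_ids, 1L)
      gene_id <- refs$models$gene_id[match(tx_id, refs$models$tx_id)]
      o <- refs$ortholog[[tx_id]]
      rlen <- nchar(o$seq)
      r_start <- if (runif(1) < config$p_5prime_complete || rlen <= L + 1L)
        0L else sample.int(min(rlen - 100L, rlen - 1L), 1L)
      r_end <- min(r_start + L, rlen)
      seq <- substr0(o$seq, r_start, r_end)
      hiv <- map_r2h_interval(o$map, r_start, r_end)
      h_start <- hiv[1]
      h_end <- hiv[2]
      m <- refs$models[match(tx_id, refs$models$tx_id), ]
      category <- if (!is.na(h_start))
        true_category(m, h_start, h_end) else NA_character_
      n_subs <- sum(o$subs$h_pos >= h_start & o$subs$h_pos < h_end)
      n_indels <- sum(o$indels$h_pos >= h_start & o$indels$h_pos < h_end)
      if (!is.null(o$te))
        te_exon <- any(o$te$h_pos >= h_start & o$te$h_pos <= h_end)
      if (runif(1) < config$p_vector_contam) {
        vec5 <- sample(20:80, 1L)
        seq <- paste0(substr0(vec_seq, nchar(vec_seq) - vec5,
                              nchar(vec_seq)), seq)
        if (runif(1) < 0.3) {
          vec3 <- sample(20:80, 1L)
          seq <- paste0(seq, substr0(vec_seq, 0L, vec3))
        }
      }
    } else {
      pool <- switch(cls, OTHER_DB = refs$other_db,
                     NOVEL_GENOME = refs$novel_genome,
                     NOVEL_FREE = refs$novel_free)
      pv <- as_seq_vector(pool)
      tx_id <- sample(names(pv), 1L)
      src <- pv[[tx_id]]
      # novel reads cover (nearly) the whole pool transcript so the ORF
      # is retained
      r_start <- 0L
      r_end <- min(nchar(src), L)
      if (r_end < nchar(src) && r_end < 200L) r_end <- nchar(src)
      seq <- substr0(src, r_start, r_end)
    }

    if (config$reverse_reads && runif(1) < 0.5) {
      seq <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    }
    seqs[i] <- seq
    quals[i] <- simulate_quality(nchar(seq), config$quality)
    rows[[i]] <- data.frame(
      read_id = id, class = cls, tx_id = tx_id, gene_id = gene_id,
      r_start = r_start, r_end = r_end, h_start = h_start, h_end = h_end,
      category = category, n_subs = n_subs, n_indels = n_indels,
      te_exon = te_exon, vec5 = vec5, vec3 = vec3,
      read_len = nchar(seq), stringsAsFactors = FALSE)
  }

  truth_reads <- do.call(rbind, rows)
  names(seqs) <- truth_reads$read_id

  subs <- do.call(rbind, lapply(names(refs$ortholog), function(tx) {
    s <- refs$ortholog[[tx]]$subs
    if (!nrow(s)) return(NULL)
    cbind(tx_id = tx, s)
  }))
  indels <- do.call(rbind, lapply(names(refs$ortholog), function(tx) {
    s <- refs$ortholog[[tx]]$indels
    if (!nrow(s)) return(NULL)
    cbind(tx_id = tx, s)
  }))

  structure(list(
    reads = Biostrings::DNAStringSet(seqs),
    quals = Biostrings::PhredQuality(setNames(quals, names(seqs))),
    truth = list(reads = truth_reads, subs = subs, indels = indels,
                 te = refs$te_ledger)
  ), class = "flc_sim")
}

# per-base Phred means decay linearly start -> end along the read
simulate_quality <- function(len, qspec) {
  if (len == 0L) return("")
  mu <- seq(qspec[["start"]], qspec[["end"]], length.out = len)
  q <- round(rnorm(len, mu, qspec[["sd"]]))
  q <- pmin(pmax(q, 2L), 41L)
  rawToChar(as.raw(q + 33L))
}

# true mapping category of a reference-coordinate span
true_category <- function(model, h_start, h_end) {
  if (!model$coding) return("NR_XR")
  classify_span(h_start, h_end, model$cds_start, model$cds_end,
                model$length)
}

#' Simulate a per-category identity panel
#'
#' Generates, for each requested span category, `n_per_category` genes
#' whose diverged ortholog differs from the reference by substitutions
#' planted uniformly over the spanned region at the category's rate
#' (default: the library-profile rates of [paper_profile_rates()]), and
#' `members` overlapping reads per gene.  Used to check that the
#' consensus/identity machinery recovers the planted divergence.
#'
#' @param n_per_category Genes per category.
#' @param members Reads per gene (>= 2 so a consensus can be built).
#' @param rates Named per-category substitution rates.
#' @param seed RNG seed.
#' @return List with `refs` (transcripts + models), `reads` (named
#'   character vector), `assign` (read -> tx/gene table) and `truth`
#'   (per-gene planted rate and span).
#' @export
simulate_region_panel <- function(n_per_category = 30L, members = 2L,
                                  rates = paper_profile_rates(),
                                  seed = 1L) {
  set.seed(seed)
  cats <- names(rates)
  tx_seqs <- character(0)
  models <- list()
  reads <- character(0)
  assign <- list()
  truth <- list()
  u5 <- 120L; cds <- 600L; u3 <- 400L
  for (cat in cats) {
    for (i in seq_len(n_per_category)) {
      gene_id <- sprintf("P%s_%03d", gsub("[^A-Z0-9]", "", cat), i)
      tx_id <- paste0(gene_id, ".1")
      seq <- paste0(random_dna(u5), "ATG", random_codons(cds %/% 3L - 2L),
                    sample(STOP_CODONS, 1L), random_dna(u3))
      len <- nchar(seq)
      span <- switch(cat,
        "5UTR" = c(0L, u5 - 10L),
        "5UTR_CDS" = c(0L, u5 + cds - 50L),
        "CDS" = c(u5 + 10L, u5 + cds - 10L),
        "CDS_3UTR" = c(u5 + 10L, len),
        "3UTR" = c(u5 + cds + 10L, len),
        "5UTR_CDS_3UTR" = c(0L, len))
      n_span <- span[2] - span[1]
      ch <- strsplit(seq, "", fixed = TRUE)[[1]]
      hit <- span[1] + which(runif(n_span) < rates[[cat]])
      for (p in hit) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
      rseq <- paste(ch, collapse = "")
      tx_seqs[tx_id] <- seq
      models[[tx_id]] <- data.frame(
        tx_id = tx_id, gene_id = gene_id, length = len,
        cds_start = u5, cds_end = u5 + cds, coding = TRUE,
        stringsAsFactors = FALSE)
      for (k in seq_len(members)) {
        # members jitter slightly at the ends but all cover the span core
        js <- span[1] + if (k == 1L) 0L else sample(0:5, 1L)
        je <- span[2] - if (k == 1L) 0L else sample(0:5, 1L)
        rid <- sprintf("%s_m%d", gene_id, k)
        reads[rid] <- substr0(rseq, js, je)
        assign[[rid]] <- data.frame(read_id = rid, tx_id = tx_id,
                                    gene_id = gene_id,
                                    stringsAsFactors = FALSE)
      }
      truth[[tx_id]] <- data.frame(
        tx_id = tx_id, gene_id = gene_id, category = cat,
        rate = rates[[cat]], span_start = span[1], span_end = span[2],
        n_subs = length(hit), stringsAsFactors = FALSE)
    }
  }
  list(refs = list(transcripts = Biostrings::DNAStringSet(tx_seqs),
                   models = do.call(rbind, models)),
       reads = reads,
       assign = do.call(rbind, assign),
       truth = do.call(rbind, truth))
}
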