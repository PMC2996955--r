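# Synthetic reference bundle: a toy annotated "human" transcriptome
# embedded in a toy genome with repeat annotation, plus the diverged
# "rhesus" ortholog of every transcript (the library's source material).
# Everything is a deterministic function of the sim_config (seed included).

#' Generate the synthetic reference bundle
#'
#' Builds gene models (5'UTR + CDS + 3'UTR, start/stop codons, a
#' non-coding fraction), a single-chromosome genome embedding each
#' transcript as 2-12 exons separated by >= 50 nt introns, a repeat
#' annotation covering every planted transposable-element copy, a cloning
#' vector, host contaminant sequences, pools of non-reference transcripts
#' (other-database, novel genome-encoded, free ORF-bearing), and the
#' diverged ortholog of each reference transcript with its divergence
#' ledger (substitutions, indels, TE-derived cassette exons).
#'
#' @param config A [sim_config()].
#' @return A list of class `flc_reference`; see Details.
#' @details Components: `transcripts` (reference mRNA, `DNAStringSet`),
#'   `models` (gene-model table), `genome` (`DNAStringSet`, one
#'   chromosome), `genome_map` (segment ledger: every intergenic, exon
#'   and intron segment with genomic and transcript coordinates),
#'   `repeats` (repeat-copy table), `te_ledger` (planted exonizations),
#'   `vector`, `host`, `other_db`, `novel_genome`, `novel_free`
#'   (`DNAStringSet`s), `ortholog` (per-transcript diverged sequence,
#'   human/rhesus coordinate map and event ledgers), and the `config`.
#' @export
make_reference_set <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)

  te_cons <- make_te_consensus(config$te_families)
  gm <- make_gene_models(config)
  te_genes <- pick_te_genes(gm$models, config)
  asm <- assemble_genome(gm, te_genes, te_cons, config)
  orth <- derive_orthologs(gm, asm$te_ledger, config)

  refs <- list(
    transcripts = Biostrings::DNAStringSet(gm$tx_seqs),
    models = gm$models,
    genome = Biostrings::DNAStringSet(c(chr1 = asm$genome)),
    genome_map = asm$genome_map,
    repeats = asm$repeats,
    te_ledger = asm$te_ledger,
    vector = Biostrings::DNAStringSet(c(pFLC1 = make_vector_seq())),
    host = Biostrings::DNAStringSet(c(ecoli_frag = random_dna(20000L),
                                      lambda_frag = random_dna(8000L))),
    other_db = Biostrings::DNAStringSet(
      make_orf_pool("ODB", config$n_other_db)),
    novel_genome = Biostrings::DNAStringSet(asm$novel_tx),
    novel_free = Biostrings::DNAStringSet(
      make_orf_pool("NVF", config$n_novel_free)),
    ortholog = orth,
    config = config
  )
  class(refs) <- "flc_reference"
  refs
}

# ---- gene models --------------------------------------------------------

make_gene_models <- function(config) {
  n <- config$n_genes
  tx_seqs <- character(0)
  rows <- list()
  for (i in seq_len(n)) {
    gene_id <- sprintf("G%04d", i)
    tx_id <- paste0(gene_id, ".1")
    coding <- runif(1) >= config$p_noncoding
    u5 <- draw_len(config$utr5_len)
    u3 <- draw_len(config$utr3_len)
    cds <- draw_len(config$cds_len)
    cds <- max(9L, 3L * (cds %/% 3L))
    if (coding) {
      seq <- paste0(random_dna(u5),
                    "ATG", random_codons(cds %/% 3L - 2L),
                    sample(STOP_CODONS, 1L),
                    random_dna(u3))
      cds_start <- u5
      cds_end <- u5 + cds
    } else {
      seq <- random_dna(u5 + cds + u3)
      cds_start <- NA_integer_
      cds_end <- NA_integer_
    }
    tx_seqs[tx_id] <- seq
    rows[[length(rows) + 1L]] <- data.frame(
      tx_id = tx_id, gene_id = gene_id, length = nchar(seq),
      cds_start = cds_start, cds_end = cds_end, coding = coding,
      stringsAsFactors = FALSE)
    if (coding && runif(1) < config$p_isoform) {
      # 3'-shortened isoform sharing the locus
      iso_id <- paste0(gene_id, ".2")
      keep3 <- max(20L, round(0.6 * u3))
      iso_seq <- substr0(seq, 0L, cds_end + keep3)
      tx_seqs[iso_id] <- iso_seq
      rows[[length(rows) + 1L]] <- data.frame(
        tx_id = iso_id, gene_id = gene_id, length = nchar(iso_seq),
        cds_start = cds_start, cds_end = cds_end, coding = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  list(tx_seqs = tx_seqs, models = do.call(rbind, rows))
}

pick_te_genes <- function(models, config) {
  coding_genes <- unique(models$gene_id[models$coding])
  n_te <- rbinom(1L, length(coding_genes), config$p_te_exon)
  if (n_te == 0L) return(character(0))
  sample(coding_genes, n_te)
}

make_te_consensus <- function(families) {
  setNames(vapply(families$length, random_dna, character(1)),
           families$family)
}

mutate_copy <- function(seq, rate = 0.02) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
  paste(ch, collapse = "")
}

# ---- genome assembly ----------------------------------------------------

assemble_genome <- function(gm, te_genes, te_cons, config) {
  segs <- character(0)
  map_rows <- list()
  rep_rows <- list()
  te_rows <- list()
  offset <- 0L

  add_seg <- function(seq, kind, owner = NA_character_,
                      rank = NA_integer_, t_start = NA_integer_,
                      t_end = NA_integer_) {
    segs[[length(segs) + 1L]] <<- seq
    map_rows[[length(map_rows) + 1L]] <<- data.frame(
      kind = kind, owner = owner, rank = rank,
      t_start = t_start, t_end = t_end,
      g_start = offset, g_end = offset + nchar(seq),
      stringsAsFactors = FALSE)
    offset <<- offset + nchar(seq)
    invisible(NULL)
  }
  add_repeat <- function(family, seq_len_start, copy_len) {
    fam <- config$te_families[config$te_families$family == family, ]
    rep_rows[[length(rep_rows) + 1L]] <<- data.frame(
      family = family, class = fam$class,
      g_start = seq_len_start, g_end = seq_len_start + copy_len,
      strand = sample(c("+", "-"), 1L),
      lineage_specific = fam$lineage_specific, stringsAsFactors = FALSE)
    invisible(NULL)
  }
  rand_between <- function(rng) sample(rng[1]:rng[2], 1L)

  add_intergenic <- function() {
    len <- rand_between(config$intergenic_len)
    seq <- random_dna(len)
    # background repeat copies (never exonic): negative controls
    if (runif(1) < 0.35 && len > 700L) {
      fam <- sample(config$te_families$family, 1L)
      copy <- mutate_copy(te_cons[[fam]])
      at <- sample(50:(len - nchar(copy) - 50L), 1L)
      seq <- paste0(substr0(seq, 0L, at), copy,
                    substr0(seq, at, len - nchar(copy)))
      add_repeat(fam, offset + at, nchar(copy))
    }
    add_seg(seq, "intergenic")
  }

  split_exons <- function(len, n_ex) {
    # split [0,len) into n_ex chunks, each >= 30 nt
    n_ex <- max(1L, min(n_ex, len %/% 30L))
    if (n_ex == 1L) return(c(0L, len))
    repeat {
      cuts <- sort(sample(seq(30L, len - 30L), n_ex - 1L))
      b <- c(0L, cuts, len)
      if (all(diff(b) >= 30L)) return(b)
    }
  }

  embed_transcript <- function(tx_id, seq, te_plan = NULL) {
    n_ex <- rand_between(config$n_exons)
    b <- split_exons(nchar(seq), n_ex)
    n_ex <- length(b) - 1L
    te_intron <- if (!is.null(te_plan)) sample(seq_len(max(1L, n_ex - 1L)), 1L)
    for (e in seq_len(n_ex)) {
      add_seg(substr0(seq, b[e], b[e + 1L]), "exon", tx_id, e,
              b[e], b[e + 1L])
      if (e < n_ex) {
        ilen <- rand_between(config$intron_len)
        if (!is.null(te_plan) && e == te_intron) {
          copy <- mutate_copy(te_cons[[te_plan$family]], rate = 0.01)
          lpad <- sample(30:80, 1L)
          rpad <- sample(30:80, 1L)
          iseq <- paste0(random_dna(lpad), copy, random_dna(rpad))
          copy_gs <- offset + lpad
          add_repeat(te_plan$family, copy_gs, nchar(copy))
          # exonized sub-interval of the copy
          seg_len <- sample(80:min(200L, nchar(copy) - 20L), 1L)
          seg_off <- sample(0:(nchar(copy) - seg_len), 1L)
          te_rows[[length(te_rows) + 1L]] <<- data.frame(
            tx_id = tx_id, family = te_plan$family,
            copy_g_start = copy_gs, copy_g_end = copy_gs + nchar(copy),
            seg_g_start = copy_gs + seg_off,
            seg_g_end = copy_gs + seg_off + seg_len,
            seg_seq = substr0(copy, seg_off, seg_off + seg_len),
            h_pos = b[e + 1L],  # insertion point on the reference tx
            stringsAsFactors = FALSE)
          add_seg(iseq, "intron", tx_id, e)
        } else {
          add_seg(random_dna(ilen), "intron", tx_id, e)
        }
      }
    }
  }

  # reference genes (the .1 transcript defines the locus)
  primary <- gm$models[!duplicated(gm$models$gene_id), ]
  for (i in seq_len(nrow(primary))) {
    add_intergenic()
    tx_id <- primary$tx_id[i]
    te_plan <- NULL
    if (primary$gene_id[i] %in% te_genes) {
      fams <- config$te_families$family[config$te_families$lineage_specific]
      te_plan <- list(family = sample(fams, 1L))
    }
    embed_transcript(tx_id, gm$tx_seqs[[tx_id]], te_plan)
  }

  # novel genome-encoded loci (not in the reference transcriptome)
  novel_tx <- character(0)
  for (i in seq_len(config$n_novel_genome)) {
    add_intergenic()
    id <- sprintf("NVG%04d", i)
    seq <- make_orf_transcript()
    novel_tx[id] <- seq
    n_ex <- sample(1:4, 1L)
    b <- split_exons(nchar(seq), n_ex)
    for (e in seq_len(length(b) - 1L)) {
      add_seg(substr0(seq, b[e], b[e + 1L]), "exon", id, e, b[e], b[e + 1L])
      if (e < length(b) - 1L)
        add_seg(random_dna(rand_between(config$intron_len)), "intron", id, e)
    }
  }
  add_intergenic()

  repeats <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(family = character(0), class = character(0),
               g_start = integer(0), g_end = integer(0),
               strand = character(0), lineage_specific = logical(0))
  te_ledger <- if (length(te_rows)) do.call(rbind, te_rows) else
    data.frame(tx_id = character(0), family = character(0),
               copy_g_start = integer(0), copy_g_end = integer(0),
               seg_g_start = integer(0), seg_g_end = integer(0),
               seg_seq = character(0), h_pos = integer(0))

  list(genome = paste(segs, collapse = ""),
       genome_map = do.call(rbind, map_rows),
       repeats = repeats, te_ledger = te_ledger, novel_tx = novel_tx)
}

# ---- ORF-bearing pool transcripts --------------------------------------

make_orf_transcript <- function(aa_range = c(60L, 200L)) {
  n_aa <- sample(aa_range[1]:aa_range[2], 1L)
  paste0(random_dna(sample(40:120, 1L)),
         "ATG", random_codons(n_aa), sample(STOP_CODONS, 1L),
         random_dna(sample(60:150, 1L)))
}

make_orf_pool <- function(prefix, n) {
  setNames(vapply(seq_len(n), function(i) make_orf_transcript(),
                  character(1)),
           sprintf("%s%04d", prefix, seq_len(n)))
}

make_vector_seq <- function() {
  # toy cloning vector with a recognizable multiple-cloning-site core
  mcs <- "GAATTCGGATCCGTCGACCTGCAGAAGCTTCTCGAGGCGGCCGCTCTAGA"
  paste0(random_dna(1200L), mcs, random_dna(1200L))
}

# ---- ortholog derivation ------------------------------------------------

region_of_position <- function(model, pos) {
  if (!model$coding) return("3UTR")  # UTR-like divergence for NR_XR
  ifelse(pos < model$cds_start, "5UTR",
         ifelse(pos < model$cds_end, "CDS", "3UTR"))
}

# candidate indel positions: no homopolymer within the surrounding 6-mer,
# keeping planted coordinates alignment-unambiguous
indel_candidate_positions <- function(seq) {
  n <- nchar(seq)
  if (n < 12L) return(integer(0))
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ok <- logical(n)
  for (p in 4:(n - 4L)) {           # 0-based position p -> chars p-2..p+3
    w <- ch[(p - 2L):(p + 4L)]
    ok[p + 1L] <- all(w[-1] != w[-length(w)])
  }
  which(ok) - 1L
}

plan_divergence <- function(model, seq, config) {
  n <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  region <- region_of_position(model, 0:(n - 1L))
  rate <- config$sub_rate_by_region[region]
  sub_pos <- which(runif(n) < rate) - 1L
  subs <- data.frame(h_pos = sub_pos,
                     h_base = ch[sub_pos + 1L],
                     region = region[sub_pos + 1L],
                     stringsAsFactors = FALSE)
  subs$r_base <- vapply(subs$h_base,
                        function(b) sample(setdiff(DNA_BASES, b), 1L),
                        character(1))

  n_indel <- rpois(1L, config$indel_rate * n / 1000)
  cand <- indel_candidate_positions(seq)
  indels <- data.frame(h_pos = integer(0), type = character(0),
                       length = integer(0), region = character(0),
                       ins_seq = character(0), stringsAsFactors = FALSE)
  if (n_indel > 0L && length(cand) > 0L) {
    pos <- sort(sample(cand, min(n_indel, length(cand))))
    pos <- pos[c(TRUE, diff(pos) >= 40L)]  # keep events well separated
    for (p in pos) {
      len <- min(1L + stats::rgeom(1L, config$indel_len_p),
                 config$max_indel_len)
      type <- sample(c("ins", "del"), 1L)
      if (type == "del" && p + len > n) next
      indels <- rbind(indels, data.frame(
        h_pos = p, type = type, length = len,
        region = region_of_position(model, p),
        ins_seq = if (type == "ins") random_dna(len) else "",
        stringsAsFactors = FALSE))
    }
  }
  list(subs = subs, indels = indels)
}

# apply substitutions + indels (+ optional TE-exon insertion) to a
# reference sequence; returns the diverged sequence and the segment map
# (matched h/r intervals, equal lengths)
apply_divergence <- function(seq, subs, indels, te = NULL) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (nrow(subs)) ch[subs$h_pos + 1L] <- subs$r_base
  events <- indels[, c("h_pos", "type", "length", "ins_seq")]
  if (!is.null(te) && nrow(te)) {
    events <- rbind(events, data.frame(
      h_pos = te$h_pos, type = "ins",
      length = nchar(te$seg_seq), ins_seq = te$seg_seq,
      stringsAsFactors = FALSE))
  }
  events <- events[order(events$h_pos), , drop = FALSE]

  out <- character(0)
  map <- list()
  cur_h <- 0L
  cur_r <- 0L
  emit <- function(h_to) {
    if (h_to > cur_h) {
      out[[length(out) + 1L]] <<- paste(ch[(cur_h + 1L):h_to], collapse = "")
      map[[length(map) + 1L]] <<- data.frame(
        h_start = cur_h, h_end = h_to,
        r_start = cur_r, r_end = cur_r + (h_to - cur_h))
      cur_r <<- cur_r + (h_to - cur_h)
      cur_h <<- h_to
    }
  }
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (ev$h_pos < cur_h) next  # overlapping event dropped
    emit(ev$h_pos)
    if (ev$type == "del") {
      cur_h <- cur_h + ev$length
    } else {
      out[[length(out) + 1L]] <- ev$ins_seq
      cur_r <- cur_r + ev$length
    }
  }
  emit(length(ch))
  list(seq = paste(unlist(out), collapse = ""),
       map = do.call(rbind, map))
}

map_h2r <- function(map, pos) {
  # nearest diverged-transcript coordinate for a reference coordinate
  for (i in seq_len(nrow(map))) {
    if (pos >= map$h_start[i] && pos < map$h_end[i])
      return(map$r_start[i] + (pos - map$h_start[i]))
  }
  if (pos >= map$h_end[nrow(map)]) return(map$r_end[nrow(map)])
  map$r_start[which(map$h_start > pos)[1]]
}

map_r2h_interval <- function(map, r_start, r_end) {
  # reference-coordinate interval covered by a diverged interval
  hs <- he <- integer(0)
  for (i in seq_len(nrow(map))) {
    ov <- interval_overlap(map$r_start[i], map$r_end[i], r_start, r_end)
    if (ov > 0L) {
      s <- map$h_start[i] + max(0L, r_start - map$r_start[i])
      hs <- c(hs, s)
      he <- c(he, s + ov)
    }
  }
  if (!length(hs)) return(c(NA_integer_, NA_integer_))
  c(min(hs), max(he))
}

derive_orthologs <- function(gm, te_ledger, config) {
  orth <- list()
  for (i in seq_len(nrow(gm$models))) {
    m <- gm$models[i, ]
    seq <- gm$tx_seqs[[m$tx_id]]
    plan <- plan_divergence(m, seq, config)
    te <- te_ledger[te_ledger$tx_id == m$tx_id, , drop = FALSE]
    if (nrow(te)) te <- te[te$h_pos < nchar(seq), , drop = FALSE]
    div <- apply_divergence(seq, plan$subs, plan$indels, te)
    orth[[m$tx_id]] <- list(seq = div$seq, map = div$map,
                            subs = plan$subs, indels = plan$indels,
                            te = if (nrow(te)) te else NULL)
  }
  orth
}

#' Genome annotation derived from the synthetic reference
#'
#' Gene spans and exon intervals of the reference gene models on the toy
#' genome, as consumed by [label_genome_context()].
#'
#' @param refs A [make_reference_set()] bundle.
#' @return List with data frames `genes` (`gene_id`, `g_start`, `g_end`)
#'   and `exons` (`gene_id`, `g_start`, `g_end`).
#' @export
genome_annotation <- function(refs) {
  gmap <- refs$genome_map
  ref_tx <- refs$models$tx_id[!duplicated(refs$models$gene_id)]
  ex <- gmap[gmap$kind == "exon" & gmap$owner %in% ref_tx, , drop = FALSE]
  gene_of <- setNames(refs$models$gene_id, refs$models$tx_id)
  ex$gene_id <- unname(gene_of[ex$owner])
  genes <- do.call(rbind, lapply(split(ex, ex$gene_id), function(d) {
    data.frame(gene_id = d$gene_id[1], g_start = min(d$g_start),
               g_end = max(d$g_end), stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  list(genes = genes,
       exons = ex[, c("gene_id", "g_start", "g_end")])
}
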