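# End-to-end orchestration: simulate -> clean -> map -> annotate ->
# consensus -> triage -> indels -> TE screen, with TSV reports, a
# markdown summary and a reproducibility manifest.

#' Pipeline configuration
#'
#' @param out_dir Output directory for all reports.
#' @param sim A [sim_config()] describing the synthetic library (the
#'   pipeline can also consume files via [run_pipeline()]'s `inputs`).
#' @param stages Named logical vector enabling stages: `simulate`,
#'   `clean`, `map`, `annotate`, `consensus`, `triage`, `indels`,
#'   `te_screen`, `report`.
#' @param min_mean_q,window Quality-trim parameters.
#' @param min_length Length-filter threshold (strict).
#' @param min_identity,min_aligned Reference-hit thresholds.
#' @param min_intron Intron threshold (nt).
#' @param min_aa Minimum ORF length for triage (aa).
#' @param min_te_overlap Minimum repeat coverage of a novel block.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            sim = sim_config(),
                            stages = c(simulate = TRUE, clean = TRUE,
                                       map = TRUE, annotate = TRUE,
                                       consensus = TRUE, triage = TRUE,
                                       indels = TRUE, te_screen = TRUE,
                                       report = TRUE),
                            min_mean_q = 20, window = 10L,
                            min_length = 100L,
                            min_identity = 0.90, min_aligned = 100L,
                            min_intron = 30L, min_aa = 40L,
                            min_te_overlap = 0.5) {
  defaults <- c(simulate = TRUE, clean = TRUE, map = TRUE,
                annotate = TRUE, consensus = TRUE, triage = TRUE,
                indels = TRUE, te_screen = TRUE, report = TRUE)
  defaults[names(stages)] <- stages
  structure(list(out_dir = out_dir, sim = sim, stages = defaults,
                 min_mean_q = min_mean_q, window = window,
                 min_length = min_length, min_identity = min_identity,
                 min_aligned = min_aligned, min_intron = min_intron,
                 min_aa = min_aa, min_te_overlap = min_te_overlap),
            class = "pipeline_config")
}

#' Run the characterization pipeline
#'
#' Executes the enabled stages in order and writes, per stage:
#' `cleaning_report.tsv`, `table1.tsv`, `identity_report.tsv` +
#' `identities.tsv`, `triage.tsv`, `table2.tsv` (+ `blocks.bed`),
#' `indel_summary.tsv`, `te_calls.tsv`, `report.md` and
#' `manifest.json`.  A disabled stage leaves its report absent, and a
#' downstream stage that needs it stops with a stage-tagged error.
#' Re-running an identical configuration reproduces identical reports.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result` with the in-memory stage
#'   outputs (`refs`, `sim`, `clean`, `hits`, `annotations`, `summary`,
#'   `identity`, `triage`, `indels`, `te_calls`, `paths`).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  st <- config$stages
  need <- function(x, stage, from) {
    if (is.null(x))
      stop("[", stage, "] requires output of disabled stage '", from,
           "'", call. = FALSE)
    x
  }
  res <- list(paths = character(0))

  if (st[["simulate"]]) {
    message("[simulate] generating reference bundle and reads")
    res$refs <- make_reference_set(config$sim)
    res$sim <- simulate_cdna_reads(res$refs, config$sim)
    write_sim_bundle(res$sim, res$refs, config$out_dir)
  }

  if (st[["clean"]]) {
    sim <- need(res$sim, "clean", "simulate")
    message("[clean] quality/vector/host screening of ",
            length(sim$reads), " reads")
    res$clean <- clean_reads(
      sim$reads, sim$quals,
      vector_lib = res$refs$vector, host = res$refs$host,
      window = config$window, min_mean_q = config$min_mean_q,
      min_length = config$min_length)
    write_tsv(res$clean$report, p("cleaning_report.tsv"))
    res$paths["cleaning_report"] <- p("cleaning_report.tsv")
  }

  if (st[["map"]]) {
    cl <- need(res$clean, "map", "clean")
    message("[map] best-hit alignment of ", length(cl$kept),
            " clean reads to the reference transcriptome")
    idx <- kmer_index(res$refs$transcripts, k = 12L, step = 1L)
    seqs <- as_seq_vector(cl$kept)
    res$hits <- lapply(names(seqs), function(id)
      best_hit(seqs[[id]], res$refs$transcripts,
               min_identity = config$min_identity,
               min_aligned = config$min_aligned, index = idx, qid = id))
    names(res$hits) <- names(seqs)
  }

  if (st[["annotate"]]) {
    hits <- need(res$hits, "annotate", "map")
    message("[annotate] classifying mapped reads into categories")
    res$annotations <- annotate_regions(hits, res$refs$models)
    res$clusters <- cluster_by_gene(res$annotations)
    res$summary <- summarize_categories(res$annotations)
    write_table1(res$summary, p("table1.tsv"))
    res$paths["table1"] <- p("table1.tsv")
  }

  if (st[["consensus"]]) {
    hits <- need(res$hits, "consensus", "map")
    message("[consensus] building per-gene consensus sequences")
    res$identity <- consensus_identity(hits, res$refs$transcripts,
                                       res$refs$models)
    write_tsv(res$identity$summary, p("identity_report.tsv"))
    write_tsv(res$identity$identities, p("identities.tsv"))
    res$paths["identity_report"] <- p("identity_report.tsv")
  }

  if (st[["triage"]]) {
    cl <- need(res$clean, "triage", "clean")
    hits <- need(res$hits, "triage", "map")
    nohit <- names(hits)[vapply(hits, is.null, logical(1))]
    message("[triage] triaging ", length(nohit),
            " reads without a reference hit")
    annot <- genome_annotation(res$refs)
    seqs <- as_seq_vector(cl$kept)
    params <- triage_params(min_identity = config$min_identity,
                            min_aligned = config$min_aligned,
                            min_aa = config$min_aa,
                            min_intron = config$min_intron)
    tr <- triage_set(seqs[nohit], res$refs$transcripts,
                     other_db = res$refs$other_db,
                     genome = res$refs$genome, annotation = annot,
                     params = params)
    # reads with a reference hit enter the table as REFSEQ_MATCH
    matched <- data.frame(
      id = setdiff(names(hits), nohit), class = "REFSEQ_MATCH",
      db_hit = vapply(hits[setdiff(names(hits), nohit)], `[[`,
                      character(1), "target_id"),
      chr = NA_character_, n_blocks = NA_integer_,
      matched_length = NA_integer_, orf_aa = NA_integer_,
      aligned_region = NA_character_, stringsAsFactors = FALSE)
    res$triage <- list(results = tr$results,
                       table = rbind(matched, tr$table))
    write_tsv(res$triage$table, p("triage.tsv"))
    res$paths["triage"] <- p("triage.tsv")

    gmapped <- Filter(function(r) !is.null(r$genome_hit), tr$results)
    galn <- lapply(gmapped, `[[`, "genome_hit")
    ctx <- vapply(gmapped, function(r)
      if (is.na(r$context)) "" else r$context, character(1))
    t2 <- export_genome_hits(galn, setNames(nchar(seqs), names(seqs)),
                             context = ctx,
                             min_intron = config$min_intron)
    write_tsv(t2, p("table2.tsv"))
    export_bed12(galn, p("blocks.bed"), min_intron = config$min_intron)
    res$table2 <- t2
    res$paths["table2"] <- p("table2.tsv")
  }

  if (st[["indels"]]) {
    hits <- need(res$hits, "indels", "map")
    message("[indels] detecting indels in reference alignments")
    ev <- list()
    for (id in names(hits)) {
      a <- hits[[id]]
      if (is.null(a)) next
      events <- detect_indels(a, config$min_intron)
      if (!nrow(events)) next
      m <- res$refs$models[match(a$target_id, res$refs$models$tx_id), ]
      events$region <- vapply(seq_len(nrow(events)), function(i)
        classify_indel_region(events[i, ], m), character(1))
      events$transcript_id <- id
      ev[[id]] <- events
    }
    res$indel_events <- if (length(ev)) do.call(rbind, ev) else
      data.frame(side = character(0), t_pos = integer(0),
                 length = integer(0), region = character(0),
                 transcript_id = character(0))
    res$indels <- summarize_indels(res$indel_events)
    write_tsv(res$indels$by_region, p("indel_summary.tsv"))
    res$paths["indel_summary"] <- p("indel_summary.tsv")
  }

  if (st[["te_screen"]]) {
    hits <- need(res$hits, "te_screen", "map")
    cl <- need(res$clean, "te_screen", "clean")
    # candidate reads: reference-matched with an intron-sized gap in the
    # mRNA alignment (an unaligned cassette) -- only these are mapped to
    # the genome
    cand <- names(Filter(function(a) {
      !is.null(a) && nrow(a$gaps) &&
        any(a$gaps$side == "query" & a$gaps$length >= config$min_intron)
    }, hits))
    message("[te_screen] screening ", length(cand),
            " candidate reads for exonized repeats")
    seqs <- as_seq_vector(cl$kept)
    calls <- list()
    for (id in cand) {
      ga <- map_to_genome(seqs[[id]], res$refs$genome,
                          min_intron = config$min_intron,
                          min_identity = config$min_identity, qid = id)
      calls[[id]] <- screen_te_exons(ga, hits[[id]], res$refs$repeats,
                                     min_overlap = config$min_te_overlap,
                                     min_intron = config$min_intron)
    }
    res$te_calls <- if (length(calls)) do.call(rbind, calls) else
      screen_te_exons(NULL, NULL, res$refs$repeats)
    rownames(res$te_calls) <- NULL
    write_tsv(res$te_calls, p("te_calls.tsv"))
    res$paths["te_calls"] <- p("te_calls.tsv")
  }

  manifest <- list(
    package = "flcdna",
    version = as.character(utils::packageVersion("flcdna")),
    seed = config$sim$seed,
    parameters = config[setdiff(names(config), c("sim", "stages"))],
    stages = as.list(config$stages),
    n_reads = config$sim$n_reads, n_genes = config$sim$n_genes)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  res$paths["manifest"] <- p("manifest.json")

  if (st[["report"]]) {
    res$report <- make_report(res)
    writeLines(res$report, p("report.md"))
    res$paths["report"] <- p("report.md")
  }
  class(res) <- "pipeline_result"
  res
}

#' Human-readable run summary
#'
#' One markdown document collecting the cleaning outcome, the category
#' table, consensus identity means, triage class counts and indel region
#' counts from a pipeline run.  Totals are taken from the same in-memory
#' tables the TSV reports are written from.
#'
#' @param res A `pipeline_result` (possibly partial).
#' @return Character vector of markdown lines.
#' @export
make_report <- function(res) {
  out <- c("# Full-length cDNA characterization report", "")
  if (!is.null(res$clean)) {
    tab <- table(res$clean$report$status)
    out <- c(out, "## Cleaning", "",
             sprintf("- raw reads: %d", nrow(res$clean$report)),
             sprintf("- %s: %d", names(tab), as.integer(tab)), "")
  }
  if (!is.null(res$summary) && nrow(res$summary)) {
    out <- c(out, "## Mapping categories", "",
             "| Mapping Region | cDNA | RefSeq | Percent |",
             "|---|---|---|---|",
             sprintf("| %s | %d | %d | %.1f |", res$summary$category,
                     res$summary$cdna, res$summary$genes,
                     res$summary$percent), "")
  } else if (!is.null(res$summary)) {
    out <- c(out, "## Mapping categories", "", "0 annotated cDNAs", "")
  }
  if (!is.null(res$identity) && nrow(res$identity$summary)) {
    out <- c(out, "## Consensus identity", "",
             sprintf("- %d consensus sequences over %d genes",
                     res$identity$n_consensus, res$identity$n_genes),
             sprintf("- %s: mean %.1f%% (n=%d)",
                     res$identity$summary$category,
                     res$identity$summary$mean_pct,
                     res$identity$summary$n), "")
  }
  if (!is.null(res$triage)) {
    tab <- table(res$triage$table$class)
    out <- c(out, "## Triage", "",
             sprintf("- %d transcripts triaged", nrow(res$triage$table)),
             sprintf("- %s: %d", names(tab), as.integer(tab)), "")
  } else {
    out <- c(out, "## Triage", "", "0 transcripts", "")
  }
  if (!is.null(res$indels)) {
    out <- c(out, "## INDEL regions", "",
             sprintf("- %s: %d transcripts (%d events)",
                     res$indels$by_region$region,
                     res$indels$by_region$transcripts,
                     res$indels$by_region$events),
             sprintf("- functional-region total: %d",
                     res$indels$functional_total), "")
  }
  if (!is.null(res$te_calls)) {
    out <- c(out, "## Exonized repeats", "",
             sprintf("- %d call(s)", nrow(res$te_calls)),
             if (nrow(res$te_calls))
               sprintf("- %s in %s (%.0f%% repeat coverage%s)",
                       res$te_calls$family, res$te_calls$transcript_id,
                       100 * res$te_calls$overlap_fraction,
                       ifelse(res$te_calls$species_specific,
                              ", species-specific", "")), "")
  }
  out
}
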