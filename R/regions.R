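# Classification of aligned spans into the seven mapping categories
# (which reference regions a cDNA's aligned span touches), gene-level
# clustering, and the category summary table with percentages.

# category of a contiguous half-open span on a coding transcript
classify_span <- function(s, e, cds_start, cds_end, len,
                          min_overlap = 1L) {
  o5 <- interval_overlap(s, e, 0L, cds_start)
  oc <- interval_overlap(s, e, cds_start, cds_end)
  o3 <- interval_overlap(s, e, cds_end, len)
  present <- c(`5` = o5 >= min_overlap, c = oc >= min_overlap,
               `3` = o3 >= min_overlap)
  key <- paste(names(present)[present], collapse = "")
  switch(key,
         "5" = "5UTR", "5c" = "5UTR_CDS", "c" = "CDS",
         "c3" = "CDS_3UTR", "3" = "3UTR", "5c3" = "5UTR_CDS_3UTR",
         stop("span [", s, ",", e, ") touches no region or skips the CDS"))
}

#' Classify an aligned span into a mapping category
#'
#' Determines which reference-transcript regions (5'UTR, CDS, 3'UTR) the
#' aligned target span overlaps by at least `min_overlap` nt, and returns
#' the corresponding category label.  Spans on non-coding / predicted
#' reference models are `NR_XR`.
#'
#' @param t_span Target span `c(start, end)`, 0-based half-open, on the
#'   reference transcript.
#' @param model One row of a gene-model table (`tx_id`, `length`,
#'   `cds_start`, `cds_end`, `coding`).
#' @param min_overlap Minimum overlap (nt) for a region to count as
#'   touched.
#' @return One of [region_categories()].
#' @export
classify_region <- function(t_span, model, min_overlap = 1L) {
  s <- t_span[1]
  e <- t_span[2]
  if (e <= s) stop("classify_region: empty span")
  if (s < 0L || e > model$length)
    stop("classify_region: span outside transcript (alignment bug)")
  if (!model$coding) return("NR_XR")
  classify_span(s, e, model$cds_start, model$cds_end, model$length,
                min_overlap)
}

#' Annotate best hits with mapping categories
#'
#' @param hits Named list of `pairwise_alignment` objects (query vs
#'   reference transcript), e.g. from [best_hit()]; `NULL` entries
#'   (NO_HIT) are skipped.
#' @param models Gene-model table.
#' @param min_overlap Region-presence threshold (nt).
#' @return Data frame with `cdna_id`, `tx_id`, `gene_id`, `category`,
#'   `t_start`, `t_end`, and per-region overlap lengths `o5`, `oc`,
#'   `o3`.
#' @export
annotate_regions <- function(hits, models, min_overlap = 1L) {
  hits <- Filter(Negate(is.null), hits)
  rows <- lapply(names(hits), function(id) {
    a <- hits[[id]]
    m <- models[match(a$target_id, models$tx_id), ]
    s <- a$t_span[1]
    e <- a$t_span[2]
    coding <- isTRUE(m$coding)
    data.frame(
      cdna_id = id, tx_id = m$tx_id, gene_id = m$gene_id,
      category = classify_region(c(s, e), m, min_overlap),
      t_start = s, t_end = e,
      o5 = if (coding) interval_overlap(s, e, 0L, m$cds_start) else 0L,
      oc = if (coding)
        interval_overlap(s, e, m$cds_start, m$cds_end) else 0L,
      o3 = if (coding)
        interval_overlap(s, e, m$cds_end, m$length) else 0L,
      stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(cdna_id = character(0), tx_id = character(0),
                      gene_id = character(0), category = character(0),
                      t_start = integer(0), t_end = integer(0),
                      o5 = integer(0), oc = integer(0), o3 = integer(0)))
  }
  do.call(rbind, rows)
}

#' Cluster annotated cDNAs by gene
#'
#' One cluster per distinct gene id; isoform redundancy collapses at the
#' gene level.
#'
#' @param annotations Data frame from [annotate_regions()] (needs
#'   `cdna_id`, `gene_id`).
#' @return Named list (gene id -> character vector of member cDNA ids).
#' @export
cluster_by_gene <- function(annotations) {
  if (!nrow(annotations)) return(list())
  lapply(split(annotations$cdna_id, annotations$gene_id), as.character)
}

#' Category summary with cDNA counts, gene counts and percentages
#'
#' Per category: number of cDNAs, number of genes, and the gene count as
#' a percentage of all distinct genes (rounded half away from zero to
#' one decimal).  A totals row is appended.  Each gene is counted in
#' exactly one category -- that of its longest-spanning cDNA (ties:
#' canonical category order) -- so the gene column sums to the distinct
#' -gene total, matching the published table's conservation.
#'
#' @param annotations Data frame from [annotate_regions()], or any data
#'   frame with `cdna_id`, `gene_id`, `category` (and optionally
#'   `t_start`/`t_end` for the representative-cDNA rule).
#' @return Data frame with `category`, `cdna`, `genes`, `percent`.
#'   Empty input yields an empty summary (no division error).
#' @export
summarize_categories <- function(annotations) {
  if (!nrow(annotations)) {
    return(data.frame(category = character(0), cdna = integer(0),
                      genes = integer(0), percent = numeric(0)))
  }
  ann <- annotations
  if (is.null(ann$t_start)) {
    ann$t_start <- 0L
    ann$t_end <- 0L
  }
  gene_cat <- vapply(split(ann, ann$gene_id), function(d) {
    span <- d$t_end - d$t_start
    top <- d[span == max(span), , drop = FALSE]
    ord <- match(top$category, region_categories())
    top$category[which.min(ord)]
  }, character(1))
  cats <- union(unique(ann$category), unique(gene_cat))
  counts <- do.call(rbind, lapply(cats, function(cat) data.frame(
    category = cat,
    cdna = sum(ann$category == cat),
    genes = sum(gene_cat == cat),
    stringsAsFactors = FALSE)))
  category_summary(counts)
}

#' Build the summary table from per-category counts
#'
#' The arithmetic core of [summarize_categories()], usable directly on a
#' published count table: percent = 100 x genes / total genes, rounded
#' half away from zero to one decimal, with a totals row.
#'
#' @param counts Data frame with `category`, `cdna`, `genes`.
#' @return Data frame with `category`, `cdna`, `genes`, `percent`
#'   (categories in canonical order, then `Total`).
#' @export
category_summary <- function(counts) {
  if (!nrow(counts) || sum(counts$genes) == 0) {
    return(data.frame(category = character(0), cdna = integer(0),
                      genes = integer(0), percent = numeric(0)))
  }
  ord <- match(counts$category, region_categories())
  counts <- counts[order(ord), , drop = FALSE]
  total_genes <- sum(counts$genes)
  counts$percent <- round_half_up(100 * counts$genes / total_genes, 1)
  out <- rbind(counts, data.frame(
    category = "Total", cdna = sum(counts$cdna), genes = total_genes,
    percent = 100.0))
  rownames(out) <- NULL
  out
}

#' Write the category summary in the survey table layout
#'
#' @param summary Data frame from [summarize_categories()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_table1 <- function(summary, path) {
  out <- summary
  names(out) <- c("Mapping Region", "cDNA", "RefSeq", "Percent")
  write_tsv(out, path)
}
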