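# Internal helpers shared across modules.  All coordinates inside the
# package are 0-based half-open; exporters convert where a format demands
# otherwise (GFF3 is 1-based inclusive, BED stays 0-based half-open).

#' @import methods
#' @importFrom stats rbinom rnorm rpois runif setNames
#' @importFrom utils read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Region category labels in canonical report order
#'
#' The seven mapping categories used throughout: which of the reference
#' transcript regions (5'UTR, CDS, 3'UTR) an aligned span touches, plus
#' the non-coding/predicted reference class.
#'
#' @return Character vector of category labels.
#' @export
region_categories <- function() {
  c("5UTR", "5UTR_CDS", "CDS", "CDS_3UTR", "3UTR", "5UTR_CDS_3UTR", "NR_XR")
}

# round half away from zero to `digits` decimals (report convention;
# base::round() is round-half-even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# overlap length of two half-open intervals
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# n codons, none of them a stop
random_codons <- function(n) {
  if (n == 0L) return("")
  cod <- character(n)
  for (i in seq_len(n)) {
    repeat {
      c3 <- paste(sample(DNA_BASES, 3, replace = TRUE), collapse = "")
      if (!(c3 %in% STOP_CODONS)) break
    }
    cod[i] <- c3
  }
  paste(cod, collapse = "")
}

# draw one length from a (mean, sd, min[, max]) spec, rounded to integer
draw_len <- function(spec, n = 1L) {
  x <- round(rnorm(n, spec[["mean"]], spec[["sd"]]))
  x <- pmax(x, spec[["min"]])
  if (!is.na(spec["max"])) x <- pmin(x, spec[["max"]])
  as.integer(x)
}

substr0 <- function(x, start, end) {
  # 0-based half-open substring
  substr(x, start + 1L, end)
}

# ---- k-mer seeding ------------------------------------------------------

# unique k-mers of a sequence taken every `step` nt
seq_kmers <- function(seq, k = 12L, step = 4L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq.int(1L, n - k + 1L, by = step)
  unique(substring(seq, starts, starts + k - 1L))
}

#' Build a k-mer index over a set of target sequences
#'
#' Used to pre-select candidate targets before running the (exact) local
#' alignment, so that a query is only aligned against references it shares
#' seeds with.  Purely an acceleration device: the alignment itself is
#' unchanged.
#'
#' @param targets Named character vector or `DNAStringSet` of target
#'   sequences.
#' @param k Seed length (nt).
#' @param step Sampling stride along each target.
#' @return An opaque index object for [best_hit()].
#' @export
kmer_index <- function(targets, k = 12L, step = 1L) {
  seqs <- as_seq_vector(targets)
  env <- new.env(hash = TRUE, parent = emptyenv(), size = 4L * sum(nchar(seqs)))
  for (id in names(seqs)) {
    for (km in seq_kmers(seqs[[id]], k = k, step = step)) {
      env[[km]] <- c(env[[km]], id)
    }
  }
  structure(list(env = env, k = k), class = "kmer_index")
}

# candidate target ids sharing >= min_seeds k-mers with the query,
# ranked by shared-seed count
kmer_candidates <- function(index, query, step = 4L, min_seeds = 2L,
                            max_candidates = 10L) {
  kms <- seq_kmers(query, k = index$k, step = step)
  hits <- unlist(lapply(kms, function(km) index$env[[km]]), use.names = FALSE)
  if (length(hits) == 0L) return(character(0))
  tab <- sort(table(hits), decreasing = TRUE)
  ids <- names(tab)[tab >= min_seeds]
  utils::head(ids, max_candidates)
}

# coerce DNAStringSet / character to a named character vector
as_seq_vector <- function(x) {
  if (methods::is(x, "XStringSet")) {
    setNames(as.character(x), names(x))
  } else if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    x
  } else {
    stop("expected a character vector or DNAStringSet")
  }
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
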