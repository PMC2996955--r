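# Read cleaning: sliding-window quality trimming, vector/host screening,
# and a strict length filter.  Stage order is quality -> vector -> host
# -> length; each raw read ends with exactly one status.

#' Quality-trim a read to its longest window-clean interval
#'
#' Returns the longest interval of the read in which every sliding
#' window of `window` bases has mean quality at or above `min_mean_q`.
#' Reads shorter than `window` are judged as a single whole-read window.
#'
#' @param quals Integer vector of per-base Phred scores.
#' @param window Sliding-window length (nt).
#' @param min_mean_q Minimum mean quality per window.
#' @return Integer vector `c(start, end)`, 0-based half-open; `c(0, 0)`
#'   when no window passes.
#' @export
quality_trim <- function(quals, window = 10L, min_mean_q = 20) {
  n <- length(quals)
  if (n == 0L) return(c(0L, 0L))
  if (n <= window) {
    return(if (mean(quals) >= min_mean_q) c(0L, n) else c(0L, 0L))
  }
  cs <- c(0, cumsum(quals))
  nw <- n - window + 1L
  ok <- (cs[(window + 1L):(n + 1L)] - cs[1:nw]) / window >= min_mean_q
  if (!any(ok)) return(c(0L, 0L))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  good <- which(r$values)
  # run of consecutive good windows [i..j] covers bases [i-1, j+window-1)
  lens <- r$lengths[good] + window - 1L
  b <- good[which.max(lens)]
  c(starts[b] - 1L, ends[b] + window - 1L)
}

#' Screen a read for cloning-vector sequence
#'
#' Terminal vector alignments (>= `min_len` aligned nt at >= `min_ident`
#' identity, reaching within `margin` nt of a read end) are trimmed off.
#' An internal vector alignment flanked by >= 50 nt of non-vector on both
#' sides marks a chimeric clone and removes the read, as does a read that
#' is vector over (almost) its whole length.
#'
#' @param seq Read sequence (character).
#' @param vector_lib Vector sequences (`DNAStringSet` or character).
#' @param min_len Minimum vector alignment length (nt).
#' @param min_ident Minimum vector alignment identity.
#' @param margin Distance from a read end within which a vector hit
#'   counts as terminal.
#' @param index Optional [kmer_index()] over `vector_lib` for fast
#'   pre-screening.
#' @return List with `status` (`"KEPT"` or `"REMOVED_VECTOR"`), `start`,
#'   `end` (kept interval, 0-based half-open) and `evidence` (matched
#'   vector interval on the read, or `NULL`).
#' @export
vector_screen <- function(seq, vector_lib, min_len = 20L,
                          min_ident = 0.95, margin = 5L, index = NULL) {
  screen_contaminant(seq, vector_lib, min_len, min_ident, margin, index,
                     removed_status = "REMOVED_VECTOR")
}

screen_contaminant <- function(seq, lib, min_len, min_ident, margin,
                               index, removed_status) {
  n <- nchar(seq)
  lib <- as_seq_vector(lib)
  if (n == 0L)
    return(list(status = "KEPT", start = 0L, end = 0L, evidence = NULL))
  cand <- names(lib)
  if (!is.null(index)) {
    cand <- kmer_candidates(index, seq, step = 4L, min_seeds = 2L,
                            max_candidates = length(lib))
    if (!length(cand))
      return(list(status = "KEPT", start = 0L, end = n, evidence = NULL))
  }
  hits <- list()
  for (id in cand) {
    a <- align_local(seq, lib[[id]], qid = "read", tid = id)
    cols <- a$matches + a$mismatches
    if (cols >= min_len && a$matches / cols >= min_ident)
      hits[[length(hits) + 1L]] <- a$q_span
  }
  if (!length(hits))
    return(list(status = "KEPT", start = 0L, end = n, evidence = NULL))

  keep_s <- 0L
  keep_e <- n
  ev <- NULL
  for (h in hits) {
    ev <- if (is.null(ev)) h else c(min(ev[1], h[1]), max(ev[2], h[2]))
    terminal5 <- h[1] <= margin
    terminal3 <- h[2] >= n - margin
    if (terminal5 && terminal3) {
      return(list(status = removed_status, start = 0L, end = 0L,
                  evidence = h))
    } else if (terminal5) {
      keep_s <- max(keep_s, h[2])
    } else if (terminal3) {
      keep_e <- min(keep_e, h[1])
    } else if (h[1] >= 50L && n - h[2] >= 50L) {
      # internal hit with long clean flanks: chimeric clone
      return(list(status = removed_status, start = 0L, end = 0L,
                  evidence = h))
    } else if (h[1] < 50L) {
      keep_s <- max(keep_s, h[2])
    } else {
      keep_e <- min(keep_e, h[1])
    }
  }
  if (keep_e <= keep_s)
    return(list(status = removed_status, start = 0L, end = 0L,
                evidence = ev))
  list(status = "KEPT", start = keep_s, end = keep_e, evidence = ev)
}

#' Partition trimmed reads by a strict minimum length
#'
#' Keeps reads strictly longer than `min_length` nt; the rest are
#' `REMOVED_SHORT`.
#'
#' @param lengths Integer vector of trimmed read lengths.
#' @param min_length Threshold (kept means length > `min_length`).
#' @return Character vector of statuses (`"KEPT"` / `"REMOVED_SHORT"`).
#' @export
length_filter <- function(lengths, min_length = 100L) {
  ifelse(lengths > min_length, "KEPT", "REMOVED_SHORT")
}

#' Clean a raw read set
#'
#' Applies, in order: sliding-window quality trimming, vector screening
#' (terminal trim or removal), optional host screening (any strong host
#' hit removes the read), and the strict length filter.  The kept
#' interval is always a literal substring of the raw read.
#'
#' @param reads `DNAStringSet` (or named character) of raw reads.
#' @param quals Optional `PhredQuality` (or character) matching `reads`;
#'   without qualities the quality stage is skipped.
#' @param vector_lib Vector sequences; `NULL` skips vector screening.
#' @param host Host contaminant sequences; `NULL` skips host screening.
#' @param window,min_mean_q Quality-trim parameters.
#' @param min_vec_len,min_vec_ident Vector/host alignment thresholds.
#' @param min_length Length-filter threshold (strict).
#' @return List of class `clean_result`: `kept` (`DNAStringSet` of
#'   cleaned reads) and `report` (one row per raw read: `read_id`,
#'   `status`, `start`, `end`, `raw_len`, `clean_len`).
#' @export
clean_reads <- function(reads, quals = NULL, vector_lib = NULL,
                        host = NULL, window = 10L, min_mean_q = 20,
                        min_vec_len = 20L, min_vec_ident = 0.95,
                        min_length = 100L) {
  seqs <- as_seq_vector(reads)
  qmat <- NULL
  if (!is.null(quals)) {
    qs <- if (methods::is(quals, "XStringQuality"))
      as.character(quals) else as.character(quals)
    qmat <- lapply(qs, function(q) as.integer(charToRaw(q)) - 33L)
    names(qmat) <- names(seqs)
  }
  vec_index <- if (!is.null(vector_lib))
    kmer_index(vector_lib, k = 16L, step = 1L)
  host_index <- if (!is.null(host)) kmer_index(host, k = 16L, step = 1L)

  n <- length(seqs)
  status <- character(n)
  start <- integer(n)
  end <- integer(n)
  out <- character(n)

  for (i in seq_len(n)) {
    seq <- seqs[[i]]
    s <- 0L
    e <- nchar(seq)
    if (!is.null(qmat)) {
      iv <- quality_trim(qmat[[i]], window, min_mean_q)
      s <- iv[1]
      e <- iv[2]
      if (e <= s) {
        status[i] <- "REMOVED_QUALITY"
        out[i] <- ""
        next
      }
      seq <- substr0(seqs[[i]], s, e)
    }
    if (!is.null(vector_lib)) {
      vs <- vector_screen(seq, vector_lib, min_vec_len, min_vec_ident,
                          index = vec_index)
      if (vs$status != "KEPT") {
        status[i] <- vs$status
        start[i] <- s
        end[i] <- s
        out[i] <- ""
        next
      }
      s2 <- vs$start
      e2 <- vs$end
      seq <- substr0(seq, s2, e2)
      s <- s + s2
      e <- s + (e2 - s2)
    }
    if (!is.null(host)) {
      hs <- screen_contaminant(seq, host, min_len = 100L,
                               min_ident = min_vec_ident, margin = 5L,
                               index = host_index,
                               removed_status = "REMOVED_HOST")
      if (hs$status == "REMOVED_HOST" ||
          (!is.null(hs$evidence) &&
           (hs$evidence[2] - hs$evidence[1]) >= 100L)) {
        status[i] <- "REMOVED_HOST"
        out[i] <- ""
        next
      }
    }
    if (nchar(seq) <= min_length) {
      status[i] <- "REMOVED_SHORT"
      out[i] <- ""
      next
    }
    status[i] <- "KEPT"
    start[i] <- s
    end[i] <- e
    out[i] <- seq
  }

  report <- data.frame(
    read_id = names(seqs), status = status, start = start, end = end,
    raw_len = nchar(seqs), clean_len = nchar(out),
    stringsAsFactors = FALSE)
  kept <- Biostrings::DNAStringSet(out[status == "KEPT"])
  names(kept) <- names(seqs)[status == "KEPT"]
  structure(list(kept = kept, report = report), class = "clean_result")
}
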