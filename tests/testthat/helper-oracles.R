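# Independent oracles, deliberately written as slow brute force so they
# share no code path with the package implementation.

# Smith-Waterman with affine gaps (Gotoh), score only: a gap of length L
# costs open + L * extend.  Plain O(nm) loops.
oracle_local_score <- function(q, t, match = 1, mismatch = -2,
                               open = 5, extend = 1) {
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  tc <- strsplit(t, "", fixed = TRUE)[[1]]
  n <- length(qc)
  m <- length(tc)
  if (n == 0L || m == 0L) return(0)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)   # gap consuming target (row-wise)
  F <- matrix(-Inf, n + 1, m + 1)   # gap consuming query
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (qc[i - 1] == tc[j - 1] && qc[i - 1] != "N")
        match else mismatch
      E[i, j] <- max(H[i, j - 1] - open - extend, E[i, j - 1] - extend)
      F[i, j] <- max(H[i - 1, j] - open - extend, F[i - 1, j] - extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# exhaustive ORF enumeration: every ATG, scanned to its first in-frame
# stop; returns aa length + 0-based interval of the best (longest,
# leftmost) forward-frame ORF, or NULL
oracle_best_orf <- function(seq, min_aa) {
  n <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (s0 in 0:(n - 3)) {
    if (paste(ch[(s0 + 1):(s0 + 3)], collapse = "") != "ATG") next
    p <- s0 + 3
    while (p + 3 <= n) {
      cod <- paste(ch[(p + 1):(p + 3)], collapse = "")
      if (cod %in% stops) {
        aa <- (p - s0) / 3
        if (aa >= min_aa && (is.null(best) || aa > best$aa ||
                             (aa == best$aa && s0 < best$start))) {
          best <- list(start = s0, end = p + 3, aa = aa)
        }
        break
      }
      p <- p + 3
    }
  }
  best
}

# per-base region labeling: label every aligned target base, then read
# the category off the set of labels present
oracle_category <- function(t_span, cds_start, cds_end, len) {
  pos <- seq(t_span[1], t_span[2] - 1L)
  lab <- ifelse(pos < cds_start, "5", ifelse(pos < cds_end, "c", "3"))
  key <- paste(intersect(c("5", "c", "3"), unique(lab)), collapse = "")
  c("5" = "5UTR", "5c" = "5UTR_CDS", "c" = "CDS", "c3" = "CDS_3UTR",
    "3" = "3UTR", "5c3" = "5UTR_CDS_3UTR")[[key]]
}

# exhaustive quality-trim oracle: longest interval in which every
# sliding window passes, by scanning all candidate intervals
oracle_quality_trim <- function(quals, window, min_q) {
  n <- length(quals)
  win_ok <- function(s, e) {   # 0-based half-open interval check
    len <- e - s
    if (len <= window) return(mean(quals[(s + 1):e]) >= min_q)
    for (w in s:(e - window)) {
      if (mean(quals[(w + 1):(w + window)]) < min_q) return(FALSE)
    }
    TRUE
  }
  best <- c(0L, 0L)
  for (s in 0:(n - 1)) {
    for (e in (s + 1):n) {
      if (e - s > best[2] - best[1] && win_ok(s, e)) best <- c(s, e)
    }
  }
  best
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutated copy of a sequence (substitutions only)
mutated_copy <- function(seq, rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

orf_sequence <- function(n_aa, lead = 60, tail = 60) {
  codons <- character(n_aa)
  for (i in seq_len(n_aa)) {
    repeat {
      c3 <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                  collapse = "")
      if (!(c3 %in% c("TAA", "TAG", "TGA"))) break
    }
    codons[i] <- c3
  }
  paste0(random_seq(lead), "ATG", paste(codons, collapse = ""), "TAA",
         random_seq(tail))
}
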