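# Shared test scaffolding: independent oracles and small builders.

or_rc <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

rand_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# near-delta PFM from a consensus string (count `n` on the consensus base)
delta_pfm <- function(consensus, name = "delta", family = "other", n = 100) {
  bases <- strsplit(consensus, "")[[1]]
  cnt <- matrix(0, 4, length(bases))
  cnt[cbind(match(bases, c("A", "C", "G", "T")), seq_along(bases))] <- n
  pfm(cnt, name, family)
}

# Brute-force scanner oracle: enumerates every window on each strand and
# scores it by direct evaluation of the log-odds formula, independently of
# the package's vectorized path.
oracle_scan <- function(counts, seq, pseudocount, background, threshold,
                        strands = c("+", "-")) {
  W <- matrix(NA_real_, 4, ncol(counts),
              dimnames = list(c("A", "C", "G", "T")))
  for (j in seq_len(ncol(counts))) {
    nj <- sum(counts[, j])
    for (b in 1:4) {
      W[b, j] <- log2(((counts[b, j] + pseudocount * background[b]) /
                         (nj + pseudocount)) / background[b])
    }
  }
  smin <- sum(apply(W, 2, min))
  smax <- sum(apply(W, 2, max))
  w <- ncol(W)
  L <- nchar(seq)
  rows <- list()
  for (s in strands) {
    if (L < w) next
    for (i in seq_len(L - w + 1)) {
      win <- substr(seq, i, i + w - 1)
      sub <- if (s == "+") win else or_rc(win)
      if (grepl("N", sub, fixed = TRUE)) next
      raw <- 0
      for (j in seq_len(w)) raw <- raw + W[substr(sub, j, j), j]
      rel <- if (smax - smin == 0) 1 else {
        min(1, max(0, (raw - smin) / (smax - smin)))
      }
      if (rel >= threshold) {
        rows[[length(rows) + 1]] <- data.frame(
          start = i - 1L, end = i - 1L + w, strand = s,
          raw_score = raw, rel_score = rel, matched_seq = sub
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), raw_score = double(),
                      rel_score = double(), matched_seq = character()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), , drop = FALSE]
}

hit_key <- function(h) paste(h$seq_id, h$start, h$end, h$strand)

# column-set Jaccard of two interval tables over n columns
interval_jaccard <- function(a, b, n) {
  cov <- function(x) {
    v <- rep(FALSE, n)
    for (i in seq_len(nrow(x))) v[(x$start[i] + 1):x$end[i]] <- TRUE
    v
  }
  va <- cov(a)
  vb <- cov(b)
  sum(va & vb) / sum(va | vb)
}
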