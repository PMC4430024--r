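#' Generate random background sequences
#'
#' I.i.d. per-base sampling from a fixed composition; the Monte-Carlo
#' background against which dataset motif counts are compared. Fully
#' reproducible for a fixed seed (the global RNG state is left untouched).
#'
#' @param n Number of sequences.
#' @param length Sequence length in bp (default 1000, the promoter size).
#' @param composition Probabilities `(A, C, G, T)` summing to 1 (default
#'   uniform).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A sequence tibble with ids `rand_0001`, `rand_0002`, ...
#' @examples
#' random_sequences(2, length = 10, seed = 1)
#' @export
random_sequences <- function(n, length = 1000, composition = rep(0.25, 4),
                             seed = NULL) {
  if (n < 0) abort("n must be >= 0.")
  if (length(composition) != 4 || any(composition < 0) ||
      abs(sum(composition) - 1) > 1e-9) {
    abort("composition must be 4 non-negative probabilities summing to 1.")
  }
  if (n == 0) {
    return(seq_tbl(character(), character()))
  }
  draw <- function() {
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(DNA_BASES, length, replace = TRUE, prob = composition),
            collapse = "")
    }, character(1))
    seq_tbl(sprintf("rand_%04d", seq_len(n)), seqs, role = "other")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Mean motif hit count per sequence
#'
#' Arithmetic mean over the supplied sequences of the number of hits
#' (both strands) of a PWM or an IUPAC consensus pattern.
#'
#' @param seqs A non-empty sequence tibble.
#' @param motif A `crossreg_pwm` or an IUPAC pattern string.
#' @param rel_threshold Relative-score cutoff for PWM scanning
#'   (default 0.8); ignored for consensus patterns.
#' @param strands Strands to scan (default both).
#' @return Mean hit count (numeric scalar).
#' @export
mean_hit_count <- function(seqs, motif, rel_threshold = 0.8,
                           strands = c("+", "-")) {
  stopifnot(is.data.frame(seqs))
  if (nrow(seqs) == 0) abort("mean_hit_count() needs >= 1 sequence.")
  hits <- if (inherits(motif, "crossreg_pwm")) {
    scan_pwm(seqs, motif, rel_threshold = rel_threshold, strands = strands)
  } else if (is.character(motif) && length(motif) == 1) {
    match_consensus(seqs, motif, strands = strands)
  } else {
    abort("motif must be a crossreg_pwm or an IUPAC pattern string.")
  }
  per_seq <- table(factor(hits$seq_id, levels = seqs$id))
  mean(as.numeric(per_seq))
}

#' Dataset-vs-random background specificity comparison
#'
#' The pipeline's specificity control: the mean motif count over the real
#' dataset is compared with the mean over `n_rand` freshly generated random
#' sequences of the same length. The specificity ratio is
#' `mean_data / mean_rand`, and the empirical p-value is the add-one
#' permutation-style estimate
#' `(1 + #\{random sequences with count >= mean_data\}) / (n_rand + 1)`,
#' which can never be exactly zero. A motif is flagged `dataset_specific`
#' when `mean_data > mean_rand` and `empirical_p <= 0.05` (reported, not
#' enforced).
#'
#' @param data_seqs The dataset sequence tibble.
#' @param motif A `crossreg_pwm` or IUPAC pattern string.
#' @param n_rand Number of random sequences (default 100).
#' @param length Random sequence length (default 1000).
#' @param composition Background base probabilities (default uniform); use
#'   the dataset's own composition for a GC-matched control.
#' @param rel_threshold PWM relative-score cutoff (default 0.8).
#' @param seed Integer seed for the random set.
#' @return A one-row tibble: `tf`, `mean_data`, `mean_rand`,
#'   `specificity_ratio` (`NA` when `mean_rand` is 0), `empirical_p`,
#'   `dataset_specific`, `n_rand`, `seed`.
#' @export
specificity_comparison <- function(data_seqs, motif, n_rand = 100,
                                   length = 1000,
                                   composition = rep(0.25, 4),
                                   rel_threshold = 0.8, seed = 1) {
  if (n_rand < 1) abort("n_rand must be >= 1.")
  rand <- random_sequences(n_rand, length = length,
                           composition = composition, seed = seed)
  mean_data <- mean_hit_count(data_seqs, motif,
                              rel_threshold = rel_threshold)
  hits_rand <- if (inherits(motif, "crossreg_pwm")) {
    scan_pwm(rand, motif, rel_threshold = rel_threshold)
  } else {
    match_consensus(rand, motif)
  }
  counts_rand <- as.numeric(table(factor(hits_rand$seq_id,
                                         levels = rand$id)))
  mean_rand <- mean(counts_rand)
  tf <- if (inherits(motif, "crossreg_pwm")) motif$tf_name else motif
  emp_p <- (1 + sum(counts_rand >= mean_data)) / (n_rand + 1)
  tibble(
    tf = tf,
    mean_data = mean_data,
    mean_rand = mean_rand,
    specificity_ratio = if (mean_rand > 0) mean_data / mean_rand else NA_real_,
    empirical_p = emp_p,
    dataset_specific = mean_data > mean_rand & emp_p <= 0.05,
    n_rand = n_rand,
    seed = seed
  )
}
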