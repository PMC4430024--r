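#' Position frequency matrices
#'
#' A PFM holds per-position base counts from known binding sites of one
#' transcription factor. `pfm()` validates the 4 x width count matrix
#' (rows `A,C,G,T`, every column with positive sum) and attaches the factor
#' name and its family label (`"IRF"`, `"NFKB"`, `"cofactor"`, or other).
#'
#' @param counts Numeric 4 x width matrix of non-negative counts; rows in
#'   `A,C,G,T` order (rownames, if present, are checked).
#' @param tf_name Transcription-factor name.
#' @param family Family label.
#' @return An object of class `crossreg_pfm`.
#' @examples
#' pfm(matrix(c(10, 0, 0, 0), 4, 1, dimnames = list(c("A", "C", "G", "T"))),
#'     "toy", "other")
#' @export
pfm <- function(counts, tf_name, family = "other") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) abort("PFM must have 4 rows (A, C, G, T).")
  if (!is.null(rownames(counts)) &&
      !identical(toupper(rownames(counts)), DNA_BASES)) {
    abort("PFM rownames must be A, C, G, T in order.")
  }
  if (!is.numeric(counts) || anyNA(counts) || any(counts < 0)) {
    abort(paste0("PFM '", tf_name, "' has negative or non-numeric counts."))
  }
  if (any(colSums(counts) <= 0)) {
    abort(paste0("PFM '", tf_name, "' has a zero-sum column."))
  }
  rownames(counts) <- DNA_BASES
  structure(
    list(tf_name = as.character(tf_name), family = as.character(family),
         counts = counts),
    class = "crossreg_pfm"
  )
}

#' @export
print.crossreg_pfm <- function(x, ...) {
  cat("<PFM> ", x$tf_name, " (", x$family, "), width ", ncol(x$counts),
      "\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' @export
print.crossreg_pwm <- function(x, ...) {
  cat("<PWM> ", x$tf_name, " (", x$family, "), width ", ncol(x$weights),
      ", score range [", round(x$score_min, 3), ", ",
      round(x$score_max, 3), "]\n", sep = "")
  print(round(x$weights, 3))
  invisible(x)
}

#' Motif width
#' @param x A `crossreg_pfm` or `crossreg_pwm`.
#' @return Integer width in bp.
#' @export
motif_width <- function(x) {
  ncol(if (inherits(x, "crossreg_pfm")) x$counts else x$weights)
}

#' Convert a PFM to a log-odds PWM
#'
#' Per-position weights are log2 odds of the (pseudocount-regularized)
#' observed base frequency against a background distribution:
#' `weight[b, i] = log2(((counts[b, i] + pc * bg[b]) / (N_i + pc)) / bg[b])`
#' with `N_i` the column count sum. The pseudocount is distributed across
#' bases proportionally to the background, which avoids minus-infinity
#' weights for unobserved bases. `score_min` / `score_max` are the sums of
#' per-column minima / maxima and define the denominator of the relative
#' score used for thresholding.
#'
#' @param x A `crossreg_pfm`.
#' @param pseudocount Non-negative regularizer (default 0.8).
#' @param background Base probabilities `(A, C, G, T)`, all positive,
#'   summing to 1 (default uniform).
#' @return An object of class `crossreg_pwm`.
#' @examples
#' p <- pfm(matrix(c(10, 0, 0, 0), 4, 1), "toy")
#' pfm_to_pwm(p, pseudocount = 0)
#' @export
pfm_to_pwm <- function(x, pseudocount = 0.8,
                       background = rep(0.25, 4)) {
  stopifnot(inherits(x, "crossreg_pfm"))
  if (pseudocount < 0) abort("pseudocount must be >= 0.")
  if (length(background) != 4 || any(background <= 0)) {
    abort("background must be 4 positive probabilities.")
  }
  if (abs(sum(background) - 1) > 1e-9) abort("background must sum to 1.")
  n <- colSums(x$counts)
  freq <- sweep(x$counts + pseudocount * background, 2, n + pseudocount, "/")
  weights <- log2(freq / background)
  rownames(weights) <- DNA_BASES
  structure(
    list(
      tf_name = x$tf_name, family = x$family, weights = weights,
      score_min = sum(apply(weights, 2, min)),
      score_max = sum(apply(weights, 2, max)),
      # with pseudocount 0, unobserved bases weigh -Inf; the relative
      # score then uses the finite score range (see rel_score)
      score_min_finite = sum(apply(weights, 2, function(cl) {
        min(cl[is.finite(cl)])
      })),
      background = background, pseudocount = pseudocount
    ),
    class = "crossreg_pwm"
  )
}

#' Extreme attainable PWM scores
#'
#' @param pwm A `crossreg_pwm`.
#' @return Named numeric vector `c(score_min, score_max)`.
#' @export
pwm_extrema <- function(pwm) {
  stopifnot(inherits(pwm, "crossreg_pwm"))
  c(score_min = pwm$score_min, score_max = pwm$score_max)
}

# raw score -> relative score in [0,1]; a degenerate all-constant matrix
# (score_min == score_max) scores 1 by convention. When score_min is -Inf
# (pseudocount 0) the finite score range is used instead, and windows
# scoring -Inf map to -Inf so no threshold in [0,1] reports them.
rel_score <- function(raw, pwm) {
  lo <- if (is.finite(pwm$score_min)) pwm$score_min else pwm$score_min_finite
  rng <- pwm$score_max - lo
  if (rng == 0) {
    return(ifelse(raw == -Inf, -Inf, rep(1, length(raw))))
  }
  # raw lies in [score_min, score_max] by construction; clamping removes
  # one-ulp rounding from the per-column accumulation
  ifelse(raw == -Inf, -Inf, pmin(1, pmax(0, (raw - lo) / rng)))
}

empty_hits <- function() {
  tibble(
    seq_id = character(), start = integer(), end = integer(),
    strand = character(), tf = character(), family = character(),
    raw_score = double(), rel_score = double(), matched_seq = character()
  )
}

# Window scores of `weights` along an integer-encoded sequence (A=1..T=4,
# N=NA). Windows containing N propagate NA and are dropped by callers.
window_scores <- function(ints, weights) {
  w <- ncol(weights)
  L <- length(ints)
  if (L < w) return(numeric(0))
  scores <- numeric(L - w + 1)
  for (j in seq_len(w)) {
    scores <- scores + weights[cbind(ints[j:(L - w + j)], j)]
  }
  scores
}

scan_one_strand <- function(seq, pwm, rel_threshold) {
  ints <- match(stringi::stri_sub(seq, seq_len(nchar(seq)), length = 1),
                DNA_BASES)
  raw <- window_scores(ints, pwm$weights)
  rel <- rel_score(raw, pwm)
  keep <- which(!is.na(rel) & rel >= rel_threshold)
  list(start0 = keep - 1L, raw = raw[keep], rel = rel[keep])
}

#' Scan sequences with a PWM
#'
#' Slides the motif over every window of each sequence on the requested
#' strands and reports windows whose relative score (position within the
#' matrix's min-max score range) reaches `rel_threshold`. Minus-strand hits
#' are reported in plus-strand coordinates of the scanned sequence, with
#' `matched_seq` giving the motif-sense (reverse-complemented) window.
#' Windows containing `N` are skipped. Coordinates are 0-based half-open
#' (BED convention). Sequences shorter than the motif yield no hits.
#'
#' @param seqs A sequence tibble (see [seq_tbl()]).
#' @param pwm A `crossreg_pwm`.
#' @param rel_threshold Relative-score cutoff in `[0, 1]`; default 0.80,
#'   the conventional cutoff of ConSite-style scanners.
#' @param strands Subset of `c("+", "-")` to scan.
#' @return A tibble with one row per hit: `seq_id`, `start`, `end`,
#'   `strand`, `tf`, `family`, `raw_score`, `rel_score`, `matched_seq`,
#'   sorted by (`seq_id` input order, `start`, `strand`).
#' @examples
#' p <- pfm(matrix(c(9, 0, 0, 0,  0, 9, 0, 0), 4, 2), "toy")
#' scan_pwm(seq_tbl("s", "ACACAC"), pfm_to_pwm(p), rel_threshold = 1)
#' @export
scan_pwm <- function(seqs, pwm, rel_threshold = 0.8, strands = c("+", "-")) {
  stopifnot(is.data.frame(seqs), inherits(pwm, "crossreg_pwm"))
  if (rel_threshold < 0 || rel_threshold > 1) {
    abort("rel_threshold must be in [0, 1].")
  }
  if (!all(strands %in% c("+", "-"))) abort("strands must be within {+, -}.")
  w <- motif_width(pwm)
  res <- purrr::map2(seqs$id, seqs$seq, function(id, s) {
    L <- nchar(s)
    out <- list()
    if ("+" %in% strands) {
      h <- scan_one_strand(s, pwm, rel_threshold)
      if (length(h$start0)) {
        out$plus <- tibble(
          seq_id = id, start = h$start0, end = h$start0 + w, strand = "+",
          tf = pwm$tf_name, family = pwm$family,
          raw_score = h$raw, rel_score = h$rel,
          matched_seq = stringi::stri_sub(s, h$start0 + 1, length = w)
        )
      }
    }
    if ("-" %in% strands) {
      rc <- reverse_complement(s)
      h <- scan_one_strand(rc, pwm, rel_threshold)
      if (length(h$start0)) {
        start_plus <- L - h$start0 - w
        out$minus <- tibble(
          seq_id = id, start = start_plus, end = start_plus + w,
          strand = "-", tf = pwm$tf_name, family = pwm$family,
          raw_score = h$raw, rel_score = h$rel,
          matched_seq = stringi::stri_sub(rc, h$start0 + 1, length = w)
        )
      }
    }
    bind_rows(out)
  })
  out <- bind_rows(res)
  if (nrow(out) == 0) return(empty_hits())
  out[order(match(out$seq_id, seqs$id), out$start, out$strand), ]
}

#' Match an IUPAC consensus pattern
#'
#' Reports every window (on the requested strands) whose bases all fall in
#' the IUPAC set of the corresponding pattern symbol. Consensus hits carry
#' `rel_score = 1` and `raw_score = NA`; strand handling and coordinates
#' are as in [scan_pwm()]. Overlapping occurrences are all reported.
#'
#' @param seqs A sequence tibble.
#' @param pattern IUPAC string over `A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N`.
#' @param tf,family Labels attached to the hits (default: the pattern).
#' @param strands Subset of `c("+", "-")`.
#' @return A hit tibble as in [scan_pwm()].
#' @examples
#' match_consensus(seq_tbl("s", "AGGAAATTCCG"), "RGGRNNHHYYB", tf = "NFKB")
#' @export
match_consensus <- function(seqs, pattern, tf = pattern, family = NA_character_,
                            strands = c("+", "-")) {
  stopifnot(is.data.frame(seqs))
  pattern <- toupper(pattern)
  syms <- strsplit(pattern, "")[[1]]
  if (!all(syms %in% names(IUPAC_SETS))) {
    abort(paste0("Invalid IUPAC symbol in pattern: ",
                 paste(setdiff(syms, names(IUPAC_SETS)), collapse = ", ")))
  }
  if (!all(strands %in% c("+", "-"))) abort("strands must be within {+, -}.")
  w <- length(syms)
  sets <- IUPAC_SETS[syms]

  match_starts0 <- function(s) {
    L <- nchar(s)
    if (L < w) return(integer(0))
    chars <- stringi::stri_sub(s, seq_len(L), length = 1)
    ok <- rep(TRUE, L - w + 1)
    for (j in seq_len(w)) {
      ok <- ok & chars[j:(L - w + j)] %in% sets[[j]]
    }
    which(ok) - 1L
  }

  res <- purrr::map2(seqs$id, seqs$seq, function(id, s) {
    L <- nchar(s)
    out <- list()
    if ("+" %in% strands) {
      st <- match_starts0(s)
      if (length(st)) {
        out$plus <- tibble(
          seq_id = id, start = st, end = st + w, strand = "+",
          tf = tf, family = family, raw_score = NA_real_, rel_score = 1,
          matched_seq = stringi::stri_sub(s, st + 1, length = w)
        )
      }
    }
    if ("-" %in% strands) {
      rc <- reverse_complement(s)
      st <- match_starts0(rc)
      if (length(st)) {
        sp <- L - st - w
        out$minus <- tibble(
          seq_id = id, start = sp, end = sp + w, strand = "-",
          tf = tf, family = family, raw_score = NA_real_, rel_score = 1,
          matched_seq = stringi::stri_sub(rc, st + 1, length = w)
        )
      }
    }
    bind_rows(out)
  })
  out <- bind_rows(res)
  if (nrow(out) == 0) return(empty_hits())
  out[order(match(out$seq_id, seqs$id), out$start, out$strand), ]
}

#' Default transcription-factor family map
#'
#' Maps each factor scanned by the pipeline to its family rollup: the IRF
#' family, the NF-kB (Rel) family, and the AP-1/SP1 cofactors.
#'
#' @return Named character vector, `tf -> family`.
#' @export
default_family_map <- function() {
  c(
    IRF1 = "IRF", IRF2 = "IRF", IRF3 = "IRF", IRF7 = "IRF",
    NFKB1 = "NFKB", NFKB2 = "NFKB", RELA = "NFKB", RELB = "NFKB",
    REL = "NFKB",
    JUN = "cofactor", AP1 = "cofactor", `AP-1` = "cofactor", SP1 = "cofactor"
  )
}

#' Read a JASPAR-style plain-text PFM file
#'
#' Parses one or more matrices in JASPAR format: a `>id name` header
#' followed by four labeled count rows (`A [ 1 2 ... ]`, bracketed or
#' plain). Factor families are filled from `family_map`; unknown factors
#' get family `"other"`.
#'
#' @param path Path to the matrix file.
#' @param family_map Named character vector `tf -> family`
#'   (default [default_family_map()]).
#' @return A named list of `crossreg_pfm` objects, in file order.
#' @export
read_jaspar <- function(path, family_map = default_family_map()) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  lines <- stringr::str_trim(readLines(path))
  lines <- lines[nzchar(lines)]
  hdr <- which(stringr::str_starts(lines, ">"))
  if (length(hdr) == 0) abort("No '>' headers found in PFM file.")
  bounds <- c(hdr, length(lines) + 1L)
  out <- purrr::map(seq_along(hdr), function(i) {
    head_line <- stringr::str_remove(lines[hdr[i]], "^>\\s*")
    parts <- strsplit(head_line, "\\s+")[[1]]
    id <- parts[1]
    name <- if (length(parts) >= 2) parts[2] else parts[1]
    body <- lines[(bounds[i] + 1):(bounds[i + 1] - 1)]
    if (length(body) != 4) {
      abort(paste0("Matrix ", id, ": expected 4 count rows, got ",
                   length(body), "."))
    }
    rows <- purrr::map(body, function(ln) {
      ln <- stringr::str_remove(ln, "^[ACGTacgt]\\s*")
      ln <- stringr::str_remove_all(ln, "[\\[\\]]")
      vals <- strsplit(stringr::str_trim(ln), "\\s+")[[1]]
      num <- suppressWarnings(as.numeric(vals))
      if (anyNA(num)) abort(paste0("Matrix ", id, ": non-numeric counts."))
      num
    })
    if (length(unique(lengths(rows))) != 1) {
      abort(paste0("Matrix ", id, ": rows of unequal length."))
    }
    fam <- unname(family_map[name])
    pfm(do.call(rbind, rows), tf_name = name,
        family = if (is.na(fam) || is.null(fam)) "other" else fam)
  })
  names(out) <- purrr::map_chr(out, "tf_name")
  out
}

#' Bundled transcription-factor matrices
#'
#' Loads the PFM set shipped with the package (IRF1, IRF2, IRF3, NFKB1,
#' RELA, REL, JUN/AP-1, SP1). These matrices are synthetic stand-ins
#' constructed from each factor's published consensus with typical
#' per-column degeneracy — they are not the original database matrices —
#' and exist so the pipeline and its tests run fully offline.
#'
#' @inheritParams read_jaspar
#' @return Named list of `crossreg_pfm`.
#' @export
crossreg_pfms <- function(family_map = default_family_map()) {
  read_jaspar(
    system.file("extdata", "pfms", "synthetic_jaspar_pfms.txt",
                package = "crossreg", mustWork = TRUE),
    family_map = family_map
  )
}
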