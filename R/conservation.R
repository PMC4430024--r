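#' Alignment tables
#'
#' A pairwise or multiple alignment is a tibble with one row per species:
#' columns `species` and `aligned_seq` (uppercase, gapped with `-`). All
#' rows must have identical length; ungapping a row recovers the original
#' sequence.
#'
#' @param species Character vector of species labels.
#' @param aligned_seq Character vector of gapped sequences over
#'   `A,C,G,T,N,-`.
#' @return A tibble with columns `species`, `aligned_seq`.
#' @export
aln_tbl <- function(species, aligned_seq) {
  if (length(species) != length(aligned_seq) || length(species) == 0) {
    abort("Alignment needs >= 1 row and matching species labels.")
  }
  aligned_seq <- toupper(as.character(aligned_seq))
  bad <- stringi::stri_detect_regex(aligned_seq, "[^ACGTN-]")
  if (any(bad)) {
    abort(paste0("Alignment row(s) with invalid characters: ",
                 paste(species[bad], collapse = ", ")))
  }
  if (length(unique(nchar(aligned_seq))) != 1) {
    abort("Alignment rows have unequal lengths.")
  }
  if (nchar(aligned_seq[1]) == 0) abort("Empty alignment.")
  tibble(species = as.character(species), aligned_seq = aligned_seq)
}

#' Number of alignment columns
#' @param alignment An alignment tibble (see [aln_tbl()]).
#' @return Integer column count.
#' @export
aln_ncol <- function(alignment) nchar(alignment$aligned_seq[1])

#' Read a CLUSTAL or aligned-FASTA alignment
#'
#' CLUSTAL files (header line, then interleaved `name  sequence` blocks,
#' optional conservation lines and column numbers) and gapped multi-FASTA
#' are both supported.
#'
#' @param path Path to the alignment file.
#' @param format `"auto"` (default; sniffs a leading `>`), `"clustal"`, or
#'   `"fasta"`.
#' @return An alignment tibble (see [aln_tbl()]), rows in file order.
#' @export
read_alignment <- function(path, format = c("auto", "clustal", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (length(first) && stringr::str_starts(first, ">")) {
      "fasta"
    } else {
      "clustal"
    }
  }
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    if (length(ss) == 0) abort("Empty alignment.")
    ids <- stringr::str_extract(names(ss), "^\\S+")
    return(aln_tbl(ids, as.character(ss)))
  }
  lines <- readLines(path)
  if (length(lines) && stringr::str_starts(lines[1], "CLUSTAL")) {
    lines <- lines[-1]
  }
  # sequence rows: name, whitespace, gapped block, optional column count
  m <- stringr::str_match(
    lines, "^(\\S+)\\s+([A-Za-z\\-\\.]+)\\s*\\d*\\s*$"
  )
  seq_rows <- !is.na(m[, 1]) & !stringr::str_detect(lines, "^[\\s*:.]+$")
  if (!any(seq_rows)) abort("Empty alignment.")
  parts <- split(m[seq_rows, 3], factor(m[seq_rows, 2],
                                        levels = unique(m[seq_rows, 2])))
  aln_tbl(names(parts),
          chartr(".", "-", vapply(parts, paste, character(1),
                                  collapse = "")))
}

# split a gapped row into a character vector
aln_chars <- function(row) {
  stringi::stri_sub(row, seq_len(nchar(row)), length = 1)
}

#' Map ungapped sequence positions to alignment columns
#'
#' @param row One gapped alignment row (character scalar).
#' @return Integer vector `m` with `m[i + 1]` the 0-based alignment column
#'   of 0-based sequence position `i`; length equals the ungapped sequence
#'   length. The mapping is strictly increasing; gap columns have no
#'   preimage.
#' @examples
#' seq_to_aln_map("AC-GT")
#' @export
seq_to_aln_map <- function(row) {
  which(aln_chars(row) != "-") - 1L
}

#' Smoothed per-column identity profile of an alignment pair
#'
#' A column scores 1 when both rows carry the same unambiguous base and
#' neither is a gap, else 0; the profile is a centered moving average with
#' windows truncated at the alignment edges.
#'
#' @param alignment An alignment tibble.
#' @param pair Integer or character vector of length 2 selecting the rows.
#' @param window Odd window width in columns (default 21).
#' @return Numeric vector of length `aln_ncol(alignment)` in `[0, 1]`.
#' @export
identity_profile <- function(alignment, pair = c(1, 2), window = 21) {
  if (window < 1 || window %% 2 != 1) abort("window must be odd and >= 1.")
  rows <- select_pair(alignment, pair)
  a <- aln_chars(rows[1])
  b <- aln_chars(rows[2])
  id <- as.numeric(a == b & a != "-" & b != "-")
  n <- length(id)
  h <- (window - 1) / 2
  cs <- c(0, cumsum(id))
  i <- seq_len(n)
  lo <- pmax(1, i - h)
  hi <- pmin(n, i + h)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

select_pair <- function(alignment, pair) {
  stopifnot(is.data.frame(alignment))
  if (length(pair) != 2) abort("pair must select exactly two rows.")
  if (is.character(pair)) {
    idx <- match(pair, alignment$species)
    if (anyNA(idx)) abort("pair species not found in alignment.")
  } else {
    idx <- as.integer(pair)
    if (any(idx < 1 | idx > nrow(alignment))) {
      abort("pair rows out of range.")
    }
  }
  alignment$aligned_seq[idx]
}

#' Call conserved regions from an identity profile
#'
#' Maximal runs of columns with smoothed identity at or above
#' `min_identity`, kept when at least `min_len` columns long. Defaults
#' (window 21, identity 0.70, length 21) follow common phylogenetic-
#' footprinting practice.
#'
#' @param profile Numeric identity profile (see [identity_profile()]).
#' @param min_identity Identity cutoff in `[0, 1]` (default 0.70).
#' @param min_len Minimum region length in columns (default 21).
#' @return A tibble of 0-based half-open column intervals: `start`, `end`.
#' @export
call_conserved_regions <- function(profile, min_identity = 0.70,
                                   min_len = 21) {
  if (min_identity < 0 || min_identity > 1) {
    abort("min_identity must be in [0, 1].")
  }
  if (min_len < 1) abort("min_len must be >= 1.")
  if (length(profile) == 0) {
    return(tibble(start = integer(), end = integer()))
  }
  r <- rle(profile >= min_identity)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_len
  tibble(start = starts[keep], end = ends[keep])
}

#' Whole-alignment pairwise identity
#'
#' Percent identical columns between two rows. Columns where both rows are
#' gaps are excluded from the denominator; columns with exactly one gap
#' count as mismatches.
#'
#' @inheritParams identity_profile
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(alignment, pair = c(1, 2)) {
  rows <- select_pair(alignment, pair)
  a <- aln_chars(rows[1])
  b <- aln_chars(rows[2])
  usable <- !(a == "-" & b == "-")
  if (!any(usable)) abort("No usable (non-double-gap) columns.")
  100 * sum(a == b & a != "-" & usable) / sum(usable)
}

#' Cross-species conserved motif hits
#'
#' A reference-species hit is called conserved when (a) its alignment-column
#' span intersects a conserved region and (b) a hit for the same factor in
#' the other species overlaps it by at least `min_col_overlap` of the
#' reference span, in alignment columns. This is the phylogenetic-
#' footprinting filter: predicted sites are kept only with cross-species
#' support inside conserved domains.
#'
#' @param hits A hit tibble carrying a `species` column (add one after
#'   [scan_pwm()] / [match_consensus()], or via [attach_species()]).
#' @param alignment An alignment tibble whose rows are the aligned
#'   promoter copies of the species in `hits`.
#' @param regions Conserved-region tibble from [call_conserved_regions()].
#' @param min_col_overlap Minimum overlap fraction of the reference span
#'   (default 0.5).
#' @param reference Reference species label (default: first alignment row).
#' @param other Comparison species label (default: second alignment row).
#' @return A tibble with one row per conserved reference hit and columns
#'   `tf`, reference/other hit coordinates (`start_ref`, `end_ref`,
#'   `strand_ref`, `start_other`, `end_other`, `strand_other`), the mapped
#'   column spans, `col_overlap_fraction`, and the containing conserved
#'   region (`region_start`, `region_end`).
#' @export
conserved_hits <- function(hits, alignment, regions, min_col_overlap = 0.5,
                           reference = alignment$species[1],
                           other = alignment$species[2]) {
  stopifnot(is.data.frame(hits), is.data.frame(regions))
  if (!"species" %in% names(hits)) {
    abort("`hits` must carry a `species` column; see attach_species().")
  }
  if (min_col_overlap < 0 || min_col_overlap > 1) {
    abort("min_col_overlap must be in [0, 1].")
  }
  empty <- tibble(
    tf = character(), seq_id_ref = character(),
    start_ref = integer(), end_ref = integer(), strand_ref = character(),
    start_other = integer(), end_other = integer(),
    strand_other = character(),
    col_start_ref = integer(), col_end_ref = integer(),
    col_start_other = integer(), col_end_other = integer(),
    col_overlap_fraction = double(),
    region_start = integer(), region_end = integer()
  )
  map_ref <- seq_to_aln_map(select_pair(alignment, c(reference, other))[1])
  map_oth <- seq_to_aln_map(select_pair(alignment, c(reference, other))[2])
  h_ref <- hits[hits$species == reference, , drop = FALSE]
  h_oth <- hits[hits$species == other, , drop = FALSE]
  if (nrow(h_ref) == 0) return(empty)
  check_in_row <- function(h, m, label) {
    if (nrow(h) && (any(h$start < 0) || any(h$end > length(m)))) {
      abort(paste0("Hit coordinates outside the ", label, " row length."))
    }
  }
  check_in_row(h_ref, map_ref, "reference")
  check_in_row(h_oth, map_oth, "other-species")

  # 0-based half-open column span of a hit [s, e) through a gapped map
  span <- function(m, s, e) c(m[s + 1], m[e] + 1L)

  out <- purrr::pmap(
    list(seq_len(nrow(h_ref))),
    function(i) {
      hr <- h_ref[i, ]
      sa <- span(map_ref, hr$start, hr$end)
      # (a) must intersect a conserved region
      ov_reg <- pmin(regions$end, sa[2]) - pmax(regions$start, sa[1])
      if (nrow(regions) == 0 || all(ov_reg <= 0)) return(NULL)
      reg <- regions[which.max(ov_reg), ]
      # (b) same-TF support in the other species
      cand <- h_oth[h_oth$tf == hr$tf, , drop = FALSE]
      if (nrow(cand) == 0) return(NULL)
      best <- NULL
      best_frac <- -1
      for (k in seq_len(nrow(cand))) {
        sb <- span(map_oth, cand$start[k], cand$end[k])
        ov <- min(sa[2], sb[2]) - max(sa[1], sb[1])
        frac <- max(0, ov) / (sa[2] - sa[1])
        if (frac > best_frac) {
          best_frac <- frac
          best <- list(hit = cand[k, ], sb = sb)
        }
      }
      if (best_frac < min_col_overlap) return(NULL)
      tibble(
        tf = hr$tf, seq_id_ref = hr$seq_id,
        start_ref = hr$start, end_ref = hr$end, strand_ref = hr$strand,
        start_other = best$hit$start, end_other = best$hit$end,
        strand_other = best$hit$strand,
        col_start_ref = sa[1], col_end_ref = sa[2],
        col_start_other = best$sb[1], col_end_other = best$sb[2],
        col_overlap_fraction = best_frac,
        region_start = reg$start, region_end = reg$end
      )
    }
  )
  res <- bind_rows(out)
  if (nrow(res) == 0) empty else res
}

#' Attach a species label to a hit table
#'
#' Convenience for the conservation stage: joins `species` onto hits from
#' the sequence table they were scanned from.
#'
#' @param hits A hit tibble.
#' @param seqs The sequence tibble the hits came from (carries `species`).
#' @return `hits` with a `species` column.
#' @export
attach_species <- function(hits, seqs) {
  left_join(hits, select(seqs, "id", "species"),
            by = c(seq_id = "id"))
}

#' Global pairwise alignment (Needleman-Wunsch)
#'
#' Optimal global alignment under a linear gap scheme, provided as plumbing
#' so the conservation stage can run end-to-end when no pre-computed
#' alignment is supplied. Tie-breaking during traceback is deterministic:
#' diagonal, then up (gap in `seq_b`), then left.
#'
#' @param seq_a,seq_b Non-empty DNA sequences (character scalars).
#' @param match,mismatch,gap Scores (defaults 1, -1, -2).
#' @param species Labels for the two alignment rows.
#' @return An alignment tibble with attribute `"score"` (the optimal
#'   alignment score).
#' @examples
#' a <- align_pair("ACGT", "ACT")
#' attr(a, "score")
#' @export
align_pair <- function(seq_a, seq_b, match = 1, mismatch = -1, gap = -2,
                       species = c("seq_a", "seq_b")) {
  seq_a <- normalize_dna(seq_a)
  seq_b <- normalize_dna(seq_b)
  a <- aln_chars(seq_a)
  b <- aln_chars(seq_b)
  n <- length(a)
  m <- length(b)
  S <- matrix(0, n + 1, m + 1)
  S[1, ] <- gap * 0:m
  S[, 1] <- gap * 0:n
  jg <- gap * seq_len(m)
  for (i in seq_len(n)) {
    sub <- ifelse(b == a[i], match, mismatch)
    base <- pmax(S[i, 1:m] + sub, S[i, 2:(m + 1)] + gap)
    # running max over left-moves: S[i+1, j] = j*gap + max(i*gap,
    # cummax(base[k] - k*gap))
    S[i + 1, 2:(m + 1)] <- jg + pmax(i * gap, cummax(base - jg))
  }
  # traceback with diagonal > up > left preference
  ra <- character(0)
  rb <- character(0)
  i <- n
  j <- m
  while (i > 0 && j > 0) {
    sub <- if (a[i] == b[j]) match else mismatch
    if (S[i + 1, j + 1] == S[i, j] + sub) {
      ra <- c(a[i], ra); rb <- c(b[j], rb); i <- i - 1; j <- j - 1
    } else if (S[i + 1, j + 1] == S[i, j + 1] + gap) {
      ra <- c(a[i], ra); rb <- c("-", rb); i <- i - 1
    } else {
      ra <- c("-", ra); rb <- c(b[j], rb); j <- j - 1
    }
  }
  if (i > 0) { ra <- c(a[seq_len(i)], ra); rb <- c(rep("-", i), rb) }
  if (j > 0) { ra <- c(rep("-", j), ra); rb <- c(b[seq_len(j)], rb) }
  out <- aln_tbl(species, c(paste(ra, collapse = ""),
                            paste(rb, collapse = "")))
  attr(out, "score") <- S[n + 1, m + 1]
  out
}

#' Write an alignment as aligned FASTA
#' @param alignment An alignment tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  writeLines(
    as.vector(rbind(paste0(">", alignment$species), alignment$aligned_seq)),
    path
  )
  invisible(path)
}
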