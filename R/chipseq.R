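#' Read ChIP-seq peaks (BED3/BED6/narrowPeak)
#'
#' Plain-text peak files with bit-exact column semantics: 0-based
#' half-open intervals; narrowPeak column 7 is the signal value and column
#' 10 the summit offset from `start` (`-1` meaning absent). Malformed
#' lines (wrong column count, non-integer coordinates, `end <= start`)
#' raise an error with the line number.
#'
#' @param path Path to the peak file.
#' @param format `"auto"` (default; by column count), `"bed3"`, `"bed6"`,
#'   or `"narrowpeak"`.
#' @param cell_line,tf_name Labels attached to every peak.
#' @return A tibble of peaks: `seq_id`, `start`, `end`, `name`, `score`,
#'   `strand`, `signal`, `summit_offset`, `cell_line`, `tf`.
#' @export
read_peaks <- function(path, format = c("auto", "bed3", "bed6", "narrowpeak"),
                       cell_line = NA_character_, tf_name = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  lines <- readLines(path)
  keep <- nzchar(stringr::str_trim(lines)) &
    !stringr::str_starts(lines, "#") &
    !stringr::str_starts(lines, "track")
  idx <- which(keep)
  if (length(idx) == 0) {
    return(tibble(
      seq_id = character(), start = integer(), end = integer(),
      name = character(), score = double(), strand = character(),
      signal = double(), summit_offset = integer(),
      cell_line = character(), tf = character()
    ))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  want <- switch(format, bed3 = 3L, bed6 = 6L, narrowpeak = 10L,
                 auto = NA_integer_)
  if (is.na(want)) {
    want <- ncols[1]
    if (!want %in% c(3L, 6L, 10L)) {
      abort(paste0("Line ", idx[1], ": unsupported column count ", want,
                   " (expected BED3, BED6 or narrowPeak)."))
    }
  }
  bad <- which(ncols != want)
  if (length(bad)) {
    abort(paste0("Line ", idx[bad[1]], ": expected ", want,
                 " columns, found ", ncols[bad[1]], "."))
  }
  col <- function(k) vapply(fields, `[[`, character(1), k)
  start <- suppressWarnings(as.integer(col(2)))
  end <- suppressWarnings(as.integer(col(3)))
  if (anyNA(start) || anyNA(end)) {
    ln <- idx[which(is.na(start) | is.na(end))[1]]
    abort(paste0("Line ", ln, ": non-integer coordinates."))
  }
  if (any(end <= start)) {
    abort(paste0("Line ", idx[which(end <= start)[1]],
                 ": end <= start."))
  }
  out <- tibble(
    seq_id = col(1), start = start, end = end,
    name = if (want >= 6) col(4) else NA_character_,
    score = if (want >= 6) suppressWarnings(as.numeric(col(5))) else NA_real_,
    strand = if (want >= 6) col(6) else ".",
    signal = if (want >= 10) {
      suppressWarnings(as.numeric(col(7)))
    } else {
      NA_real_
    },
    summit_offset = if (want >= 10) {
      so <- suppressWarnings(as.integer(col(10)))
      ifelse(so < 0, NA_integer_, so)
    } else {
      NA_integer_
    },
    cell_line = cell_line, tf = tf_name
  )
  bad_summit <- !is.na(out$summit_offset) &
    (out$summit_offset >= out$end - out$start)
  if (any(bad_summit)) {
    abort(paste0("Line ", idx[which(bad_summit)[1]],
                 ": summit offset outside the peak."))
  }
  out
}

#' Annotate hits with ChIP-seq peak support
#'
#' A hit is supported by a peak set when it shares at least `min_bp` bases
#' with any peak on the same sequence. Hits and peaks must share a
#' coordinate system: either both promoter-local (the default mode) or
#' both genomic.
#'
#' @param hits A hit tibble.
#' @param peaks A peak tibble (see [read_peaks()]).
#' @param min_bp Minimum overlap in bp (default 1: any overlap).
#' @return `hits` with columns `supported` (logical), `best_overlap_bp`,
#'   and `n_peaks` (peaks meeting `min_bp`). If the sequence ids of hits
#'   and peaks are disjoint a coordinate-system mismatch warning is
#'   raised.
#' @export
intersect_hits_peaks <- function(hits, peaks, min_bp = 1) {
  stopifnot(is.data.frame(hits), is.data.frame(peaks))
  if (min_bp < 1) abort("min_bp must be >= 1.")
  if (nrow(hits) && nrow(peaks) &&
      length(intersect(unique(hits$seq_id), unique(peaks$seq_id))) == 0) {
    warn("No shared sequence ids between hits and peaks; coordinate systems may differ.")
  }
  if (nrow(hits) == 0) {
    return(mutate(hits, supported = logical(0),
                  best_overlap_bp = integer(0), n_peaks = integer(0)))
  }
  res <- purrr::pmap(list(hits$seq_id, hits$start, hits$end),
                     function(sid, s, e) {
    p <- peaks[peaks$seq_id == sid, , drop = FALSE]
    if (nrow(p) == 0) return(c(0L, 0L))
    ov <- pmin(p$end, e) - pmax(p$start, s)
    ov <- ov[ov >= min_bp]
    if (length(ov) == 0) c(0L, 0L) else c(max(ov), length(ov))
  })
  m <- do.call(rbind, res)
  mutate(hits, supported = m[, 1] >= min_bp, best_overlap_bp = m[, 1],
         n_peaks = m[, 2])
}

#' Cross-cell-line support summary
#'
#' Computes, for every hit, the fraction of ChIP-seq cell lines whose peak
#' set overlaps it, and per promoter the fraction of cell lines with at
#' least one peak on the promoter. This mirrors the validation logic of
#' checking computational predictions against peak presence across cell
#' lines (e.g. "supported in 9 of 10 lines").
#'
#' @param hits A hit tibble.
#' @param peak_sets A named list of peak tibbles, one per cell line, or a
#'   single peak tibble with a filled `cell_line` column.
#' @param min_bp Minimum hit/peak overlap in bp (default 1).
#' @return A list with tibbles `per_hit` (hit columns plus
#'   `n_lines_supported`, `n_lines`, `support_fraction`) and
#'   `per_promoter` (`seq_id`, `n_lines_with_peak`, `n_lines`,
#'   `promoter_support_fraction`).
#' @export
support_summary <- function(hits, peak_sets, min_bp = 1) {
  if (is.data.frame(peak_sets)) {
    if (all(is.na(peak_sets$cell_line))) {
      abort("peak_sets tibble must carry cell_line labels.")
    }
    peak_sets <- split(peak_sets, peak_sets$cell_line)
  }
  if (length(peak_sets) == 0) abort("Need >= 1 peak set.")
  k <- length(peak_sets)
  supp <- purrr::map(peak_sets, function(p) {
    intersect_hits_peaks(hits, p, min_bp = min_bp)$supported
  })
  supp_mat <- do.call(cbind, supp)
  per_hit <- mutate(
    hits,
    n_lines_supported = if (nrow(hits)) rowSums(supp_mat) else integer(0),
    n_lines = k,
    support_fraction = .data$n_lines_supported / k
  )
  proms <- unique(hits$seq_id)
  per_promoter <- purrr::map_dfr(proms, function(sid) {
    with_peak <- vapply(peak_sets, function(p) {
      pp <- p[p$seq_id == sid, , drop = FALSE]
      nrow(pp) > 0
    }, logical(1))
    tibble(
      seq_id = sid,
      n_lines_with_peak = sum(with_peak),
      n_lines = k,
      promoter_support_fraction = sum(with_peak) / k
    )
  })
  list(per_hit = per_hit, per_promoter = per_promoter)
}

#' Write peaks as narrowPeak
#' @param peaks A peak tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  out <- tibble(
    chrom = peaks$seq_id, start = peaks$start, end = peaks$end,
    name = tidyr::replace_na(peaks$name, "."),
    score = tidyr::replace_na(peaks$score, 0),
    strand = tidyr::replace_na(peaks$strand, "."),
    signal = tidyr::replace_na(peaks$signal, 0),
    p = -1, q = -1,
    summit = tidyr::replace_na(peaks$summit_offset, -1L)
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
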