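#' Sequence tables
#'
#' `crossreg` represents a set of DNA sequences (promoters, 3'UTRs, random
#' backgrounds) as an ordinary tibble with one row per sequence and columns
#' `id`, `description`, `seq`, `species`, `role`. `seq_tbl()` builds and
#' validates such a table from vectors; every other function in the package
#' that consumes sequences takes this table as its first argument, so calls
#' chain with the pipe.
#'
#' Sequences are normalized to an uppercase DNA alphabet over `A,C,G,T,N`;
#' RNA input is accepted and `U` is silently mapped to `T`, so 3'UTR analysis
#' of `AUUUA`-type elements operates on the DNA-sense `ATTTA`.
#'
#' @param id Character vector of unique sequence identifiers.
#' @param seq Character vector of sequences (DNA or RNA, any case).
#' @param description Optional character vector of free-text descriptions.
#' @param species Optional species label(s), recycled.
#' @param role Optional role tag(s), one of `"promoter"`, `"utr3"`,
#'   `"other"`, recycled.
#' @param allow_empty Permit empty sequences (default `FALSE`).
#'
#' @return A tibble with columns `id`, `description`, `seq`, `species`,
#'   `role`.
#' @examples
#' seq_tbl(c("p1", "p2"), c("acgt", "AUUUA"))
#' @export
seq_tbl <- function(id, seq, description = "", species = NA_character_,
                    role = NA_character_, allow_empty = FALSE) {
  if (length(id) != length(seq)) {
    abort("`id` and `seq` must have equal length.")
  }
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    abort(paste0("Duplicate sequence id(s): ", paste(dup, collapse = ", ")))
  }
  seq <- normalize_dna(seq, id, allow_empty = allow_empty)
  role <- as.character(role)
  bad_role <- !is.na(role) & !role %in% c("promoter", "utr3", "other")
  if (any(bad_role)) {
    abort(paste0("Invalid role: ", paste(unique(role[bad_role]), collapse = ", ")))
  }
  tibble(
    id = as.character(id),
    description = rep_len(as.character(description), length(id)),
    seq = seq,
    species = rep_len(as.character(species), length(id)),
    role = rep_len(role, length(id))
  )
}

# Uppercase, U->T, alphabet check; errors name the offending record.
normalize_dna <- function(seq, id = seq_along(seq), allow_empty = FALSE) {
  seq <- chartr("u", "T", toupper(as.character(seq)))
  seq <- chartr("U", "T", seq)
  bad <- stringi::stri_detect_regex(seq, "[^ACGTN]")
  if (any(bad)) {
    abort(paste0(
      "Sequence(s) with characters outside {A,C,G,T,N,U}: ",
      paste(head(id[bad], 5), collapse = ", ")
    ))
  }
  if (!allow_empty && any(!nzchar(seq))) {
    abort(paste0(
      "Empty sequence(s): ", paste(head(id[!nzchar(seq)], 5), collapse = ", ")
    ))
  }
  seq
}

#' Read a FASTA file into a sequence table
#'
#' Multi-record FASTA, wrapped or unwrapped. Lowercase and RNA input are
#' normalized (uppercase, `U -> T`); characters outside `A,C,G,T,N,U` raise
#' a format error naming the offending record. An empty file yields an empty
#' table so pipelines compose.
#'
#' @param path Path to a FASTA file.
#' @param species,role Optional labels attached to every record.
#' @return A sequence tibble (see [seq_tbl()]). The FASTA header up to the
#'   first whitespace becomes `id`; the remainder becomes `description`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">p1 demo", "AC", "GT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, species = NA_character_, role = NA_character_) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) {
    return(seq_tbl(character(), character(), species = species, role = role))
  }
  headers <- names(ss)
  ids <- stringr::str_extract(headers, "^\\S+")
  desc <- stringr::str_trim(stringr::str_remove(headers, "^\\S+\\s*"))
  seq_tbl(ids, as.character(ss),
    description = desc, species = species, role = role,
    allow_empty = TRUE
  )
}

#' Write a sequence table as FASTA
#'
#' @param seqs A sequence tibble (see [seq_tbl()]).
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  stopifnot(is.data.frame(seqs), all(c("id", "seq") %in% names(seqs)))
  desc <- if ("description" %in% names(seqs)) seqs$description else ""
  desc <- rep_len(as.character(desc), nrow(seqs))
  header <- ifelse(is.na(desc) | !nzchar(desc),
    paste0(">", seqs$id),
    paste0(">", seqs$id, " ", desc)
  )
  lines <- purrr::map2(header, seqs$seq, function(h, s) {
    if (!nzchar(s)) return(h)
    starts <- seq(1, nchar(s), by = width)
    c(h, stringi::stri_sub(s, starts, pmin(starts + width - 1, nchar(s))))
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Reverse complement
#'
#' Vectorized over a character vector of DNA sequences; `N` maps to `N`.
#'
#' @param seq Character vector over `A,C,G,T,N` (any case; `U` accepted).
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement(c("ACGT", "GAAA"))
#' @export
reverse_complement <- function(seq) {
  seq <- normalize_dna(seq, allow_empty = TRUE)
  stringi::stri_reverse(chartr("ACGT", "TGCA", seq))
}

#' Base composition
#'
#' `gc_content()` returns (#G + #C) / (#A + #C + #G + #T); `at_content()`
#' its complement over unambiguous bases. `N` is excluded from both
#' numerator and denominator, so `gc_content(s) + at_content(s) == 1` for
#' any sequence with at least one unambiguous base.
#'
#' @param seq Character vector of DNA sequences.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' gc_content("ACGTN")
#' at_content("ATAT")
#' @export
gc_content <- function(seq) {
  seq <- normalize_dna(seq, allow_empty = TRUE)
  gc <- stringi::stri_count_regex(seq, "[GC]")
  acgt <- stringi::stri_count_regex(seq, "[ACGT]")
  if (any(acgt == 0)) {
    abort("gc_content() undefined for empty or all-N sequence.")
  }
  gc / acgt
}

#' @rdname gc_content
#' @export
at_content <- function(seq) 1 - gc_content(seq)

#' Export motif hits as BED6
#'
#' Hit tables already use BED coordinates (0-based, half-open), so columns
#' map directly: `chrom = seq_id`, `name = tf`, `score = round(1000 *
#' rel_score)`, `strand`.
#'
#' @param hits A hit tibble (see [scan_pwm()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(hits, path) {
  stopifnot(all(c("seq_id", "start", "end", "strand", "tf") %in% names(hits)))
  rel <- if ("rel_score" %in% names(hits)) hits$rel_score else 1
  bed <- tibble(
    chrom = hits$seq_id, start = hits$start, end = hits$end,
    name = hits$tf, score = as.integer(round(1000 * rel)),
    strand = hits$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
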