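#' Per-promoter family count row
#'
#' Aggregates the hits of one promoter (one gene / species / variant) into
#' the per-family counting scheme of the headline table: the family count
#' is the number of distinct hit intervals (deduplicated across strands)
#' contributed by any member of the family, with "of which X" columns for
#' designated members. A parallel raw-occurrence count (all hits, both
#' strands) is reported alongside, since either convention may be wanted.
#'
#' @param hits Hit tibble for a single promoter.
#' @param family_map Named character vector `tf -> family`
#'   (default [default_family_map()]).
#' @param members_of_interest Factors that get their own "of which" column
#'   (default `c("IRF3", "REL")`).
#' @param gene,species,variant Row key labels.
#' @return A one-row tibble: key columns, `n_<family>` distinct-interval
#'   counts, `n_<family>_raw` raw counts, `of_which_<member>` counts,
#'   per-TF `tf_<name>` distinct counts, and `n_overlapping` (hits lying in
#'   a multi-hit overlap group).
#' @export
count_by_family <- function(hits, family_map = default_family_map(),
                            members_of_interest = c("IRF3", "REL"),
                            gene = NA_character_, species = NA_character_,
                            variant = NA_character_) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) > 0) {
    unknown <- setdiff(unique(hits$tf), names(family_map))
    if (length(unknown)) {
      abort(paste0("TF(s) missing from family_map: ",
                   paste(unknown, collapse = ", ")))
    }
    hits <- mutate(hits, family = unname(family_map[.data$tf]))
  }
  families <- sort(unique(unname(family_map)))
  row <- tibble(gene = gene, species = species, variant = variant)
  dedup <- distinct(hits, .data$tf, .data$family, .data$start, .data$end)
  for (fam in families) {
    fh <- dedup[dedup$family == fam, , drop = FALSE]
    row[[paste0("n_", fam)]] <-
      nrow(distinct(fh, .data$start, .data$end))
    row[[paste0("n_", fam, "_raw")]] <- sum(hits$family == fam)
  }
  for (mb in members_of_interest) {
    mh <- dedup[dedup$tf == mb, , drop = FALSE]
    row[[paste0("of_which_", mb)]] <-
      nrow(distinct(mh, .data$start, .data$end))
  }
  for (tf in sort(unique(dedup$tf))) {
    row[[paste0("tf_", tf)]] <-
      nrow(distinct(dedup[dedup$tf == tf, ], .data$start, .data$end))
  }
  groups <- find_overlaps(hits)
  row$n_overlapping <- if (nrow(groups)) {
    n_distinct(groups$hit_index)
  } else {
    0L
  }
  row
}

#' Overlap groups among hits on one sequence
#'
#' Clusters hits that share at least one bp (half-open intervals,
#' strand-agnostic) by transitive chaining; singleton groups are omitted.
#' Groups containing members of more than one family are flagged
#' `cross_family`.
#'
#' @param hits Hit tibble for one sequence.
#' @return A tibble with one row per hit in a multi-hit group: `group`,
#'   `hit_index` (row in the sorted input), hit columns, and
#'   `cross_family`.
#' @export
find_overlaps <- function(hits) {
  stopifnot(is.data.frame(hits))
  empty <- tibble(
    group = integer(), hit_index = integer(), seq_id = character(),
    start = integer(), end = integer(), strand = character(),
    tf = character(), family = character(), cross_family = logical()
  )
  if (nrow(hits) < 2) return(empty)
  h <- hits[order(hits$start, hits$end, hits$strand, hits$tf), , drop = FALSE]
  h$hit_index <- seq_len(nrow(h))
  grp <- integer(nrow(h))
  cur <- 1L
  max_end <- h$end[1]
  grp[1] <- cur
  for (i in 2:nrow(h)) {
    if (h$start[i] < max_end) {       # >= 1 shared bp with the open group
      grp[i] <- cur
    } else {
      cur <- cur + 1L
      grp[i] <- cur
    }
    max_end <- max(max_end, h$end[i])
  }
  h$group <- grp
  h <- group_by(h, .data$group)
  h <- filter(h, n() >= 2)
  h <- mutate(h, cross_family = n_distinct(.data$family) > 1)
  h <- ungroup(h)
  if (nrow(h) == 0) return(empty)
  cols <- intersect(
    c("group", "hit_index", "seq_id", "start", "end", "strand", "tf",
      "family", "cross_family"),
    names(h)
  )
  h[, cols]
}

#' Assemble per-promoter rows into the dataset count table
#'
#' @param rows A list of one-row tibbles from [count_by_family()], or a
#'   tibble of such rows.
#' @return A tibble ordered by (`gene`, `species`, `variant`); duplicate
#'   row keys raise an error. Missing per-TF columns are filled with 0.
#' @export
build_dataset_table <- function(rows) {
  tab <- if (is.data.frame(rows)) as_tibble(rows) else bind_rows(rows)
  if (nrow(tab) == 0) {
    return(tibble(gene = character(), species = character(),
                  variant = character()))
  }
  key <- paste(tab$gene, tab$species, tab$variant, sep = "\r")
  if (anyDuplicated(key)) {
    abort("Duplicate (gene, species, variant) row key in count table.")
  }
  num_cols <- setdiff(names(tab), c("gene", "species", "variant"))
  tab <- mutate(tab, dplyr::across(dplyr::all_of(num_cols),
                                   ~ tidyr::replace_na(.x, 0)))
  arrange(tab, .data$gene, .data$species, .data$variant)
}
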