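#' Sample a motif instance from a PFM
#'
#' Draws one sequence of the motif's width, each position sampled
#' proportionally to the PFM's column counts.
#'
#' @param x A `crossreg_pfm`.
#' @param n Number of instances (default 1).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return Character vector of `n` motif instances.
#' @export
sample_motif_instance <- function(x, n = 1, seed = NULL) {
  stopifnot(inherits(x, "crossreg_pfm"))
  draw <- function() {
    vapply(seq_len(n), function(i) {
      paste(apply(x$counts, 2, function(cl) {
        sample(DNA_BASES, 1, prob = cl / sum(cl))
      }), collapse = "")
    }, character(1))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# place n_sites non-overlapping width-w intervals uniformly in [0, length);
# bounded retries, then error
place_nonoverlapping <- function(length, w, n_sites, max_tries = 1000) {
  if (n_sites == 0) return(integer(0))
  if (n_sites * w > length) abort("Sites do not fit in the sequence.")
  for (try in seq_len(max_tries)) {
    starts <- sort(sample.int(length - w + 1, n_sites, replace = TRUE) - 1L)
    if (n_sites == 1 || all(diff(starts) >= w)) return(starts)
  }
  abort("Could not place non-overlapping sites; reduce n_sites or widen the sequence.")
}

random_dna <- function(length, composition = rep(0.25, 4)) {
  paste(sample(DNA_BASES, length, replace = TRUE, prob = composition),
        collapse = "")
}

splice_in <- function(seq, start0, insert) {
  paste0(
    stringi::stri_sub(seq, 1, start0),
    insert,
    stringi::stri_sub(seq, start0 + nchar(insert) + 1, nchar(seq))
  )
}

#' Plant motif instances in a random background sequence
#'
#' Background bases are sampled i.i.d. from `composition`; `n_sites`
#' non-overlapping motif instances (sampled from the PFM, strand chosen at
#' random) are placed uniformly at random. The returned truth table
#' records every placement, so scanner recall/precision can be evaluated
#' exactly.
#'
#' @param length Sequence length in bp.
#' @param x A `crossreg_pfm` to plant.
#' @param n_sites Number of instances to plant.
#' @param composition Background probabilities `(A, C, G, T)`.
#' @param seed Integer seed.
#' @param id Sequence id (default `"synth_1"`).
#' @param strands Strands instances may be planted on (default both).
#' @return A list with `seqs` (one-row sequence tibble) and `truth`
#'   (tibble: `seq_id`, `start`, `end`, `strand`, `tf`, `planted_seq` —
#'   the motif-sense instance).
#' @export
plant_motifs <- function(length, x, n_sites, composition = rep(0.25, 4),
                         seed = NULL, id = "synth_1",
                         strands = c("+", "-")) {
  stopifnot(inherits(x, "crossreg_pfm"))
  w <- motif_width(x)
  gen <- function() {
    seq <- random_dna(length, composition)
    starts <- place_nonoverlapping(length, w, n_sites)
    strand <- if (n_sites) sample(strands, n_sites, replace = TRUE) else character(0)
    inst <- sample_motif_instance(x, n = n_sites)
    for (i in seq_len(n_sites)) {
      placed <- if (strand[i] == "+") inst[i] else reverse_complement(inst[i])
      seq <- splice_in(seq, starts[i], placed)
    }
    list(
      seqs = seq_tbl(id, seq, role = "promoter"),
      truth = tibble(
        seq_id = id, start = starts, end = starts + w, strand = strand,
        tf = x$tf_name, planted_seq = inst
      )
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate a synthetic orthologous promoter family
#'
#' Emulates the cross-species design: an ancestral promoter is sampled,
#' then each species copy is mutated per site (substitutions only, no
#' indels, so the identity alignment is the true alignment) with
#' probability `divergence` outside conserved blocks and `divergence / 10`
#' inside them. Motif instances listed in `plants` are copied identically
#' into every species (their positions are exempt from substitution), so
#' planted sites are conserved by construction and conservation calls can
#' be scored against exact truth.
#'
#' @param length Promoter length in bp.
#' @param species_divergences Named numeric vector, species label ->
#'   per-site substitution probability in `[0, 1]`. Give the reference
#'   species (conventionally first) divergence 0 so it equals the
#'   ancestor.
#' @param conserved_blocks Tibble/data frame with 0-based half-open
#'   `start`, `end` columns of conserved blocks.
#' @param plants Optional tibble with columns `pfm` (list of
#'   `crossreg_pfm`) and `block` (index into `conserved_blocks` rows);
#'   each row plants one instance centered in that block. `NULL` for none.
#' @param composition Ancestor base probabilities.
#' @param seed Integer seed.
#' @return A list with `seqs` (sequence tibble, one row per species),
#'   `alignment` (the true, ungapped alignment tibble), and `truth` (list
#'   with `conserved_blocks` and `planted_sites` tibbles).
#' @export
generate_ortholog_family <- function(length, species_divergences,
                                     conserved_blocks = tibble(
                                       start = integer(), end = integer()
                                     ),
                                     plants = NULL,
                                     composition = rep(0.25, 4),
                                     seed = NULL) {
  if (any(species_divergences < 0 | species_divergences > 1)) {
    abort("divergences must be in [0, 1].")
  }
  if (is.null(names(species_divergences))) {
    abort("species_divergences must be named by species.")
  }
  blocks <- as_tibble(conserved_blocks)
  if (nrow(blocks) &&
      (any(blocks$start < 0) || any(blocks$end > length) ||
       any(blocks$start >= blocks$end))) {
    abort("conserved_blocks must be valid intervals within [0, length).")
  }
  gen <- function() {
    ancestor <- aln_chars(random_dna(length, composition))
    in_block <- rep(FALSE, length)
    for (i in seq_len(nrow(blocks))) {
      in_block[(blocks$start[i] + 1):blocks$end[i]] <- TRUE
    }
    planted <- tibble(
      species = character(), seq_id = character(), start = integer(),
      end = integer(), strand = character(), tf = character(),
      planted_seq = character()
    )
    plant_pos <- rep(FALSE, length)
    plant_list <- list()
    if (!is.null(plants) && nrow(plants)) {
      for (i in seq_len(nrow(plants))) {
        p <- plants$pfm[[i]]
        w <- motif_width(p)
        blk <- blocks[plants$block[i], ]
        if (blk$end - blk$start < w) abort("Plant wider than its block.")
        s0 <- blk$start + (blk$end - blk$start - w) %/% 2
        inst <- sample_motif_instance(p)
        ancestor[(s0 + 1):(s0 + w)] <- aln_chars(inst)
        plant_pos[(s0 + 1):(s0 + w)] <- TRUE
        plant_list[[i]] <- tibble(start = s0, end = s0 + w, strand = "+",
                                  tf = p$tf_name, planted_seq = inst)
      }
    }
    species <- names(species_divergences)
    seqs <- purrr::imap(species_divergences, function(d, sp) {
      rate <- ifelse(in_block, d / 10, d)
      rate[plant_pos] <- 0
      mut <- runif(length) < rate
      out <- ancestor
      if (any(mut)) {
        out[mut] <- vapply(out[mut], function(b) {
          sample(setdiff(DNA_BASES, b), 1)
        }, character(1))
      }
      paste(out, collapse = "")
    })
    ids <- paste0("prom_", species)
    st <- seq_tbl(ids, unlist(seqs), species = species, role = "promoter")
    if (length(plant_list)) {
      planted <- purrr::map_dfr(seq_along(species), function(k) {
        mutate(bind_rows(plant_list),
               species = species[k], seq_id = ids[k], .before = 1)
      })
    }
    list(
      seqs = st,
      alignment = aln_tbl(species, st$seq),
      truth = list(conserved_blocks = blocks, planted_sites = planted)
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# GC-leaning spacer with a prescribed AT count, pentamer-free by
# construction: AT bases are laid down as isolated A/T separated by G/C, so
# no TTT (hence no ATTTA) and no long AT run can arise. The two outermost
# positions on each side stay G/C so pentamers cannot form across feature
# junctions either.
make_spacer <- function(len, at_frac) {
  if (len == 0) return("")
  n_at <- round(at_frac * len)
  n_at <- max(0, min(n_at, ceiling(len / 2)))
  bases <- character(len)
  at_slots <- if (n_at > 0 && len >= 5) {
    unique(round(seq(3, len - 2, length.out = min(n_at, (len - 4) %/% 2 + 1))))
  } else {
    integer(0)
  }
  gc_pool <- c("G", "C")
  at_pool <- c("A", "T")
  bases[seq_len(len)] <- gc_pool[(seq_len(len) %% 2) + 1]
  bases[at_slots] <- at_pool[(seq_along(at_slots) %% 2) + 1]
  paste(bases, collapse = "")
}

# AT-rich run (>= 80% AT) of length len with every ATTTA destroyed
make_at_run <- function(len, at_frac = 0.85) {
  repeat {
    s <- random_dna(len, c(at_frac / 2, (1 - at_frac) / 2,
                           (1 - at_frac) / 2, at_frac / 2))
    # break pentamers by flipping the middle T to A (keeps AT content)
    guard <- 0
    while (length(p <- find_pentamers(s)) > 0 && guard < 50) {
      s <- paste0(stringi::stri_sub(s, 1, p[1] + 2), "A",
                  stringi::stri_sub(s, p[1] + 4, len))
      guard <- guard + 1
    }
    if (length(find_pentamers(s)) == 0) return(s)
  }
}

#' Generate a synthetic 3'UTR with known ARE content
#'
#' Assembles a UTR-like sequence from planted features with GC-leaning,
#' pentamer-free spacers whose AT content is adjusted so the whole
#' sequence lands near `at_target`:
#' * class II: an `ATTTATTTA` double-pentamer block;
#' * class I: a single `ATTTA` centered in a 25-nt context of >= 80% AT;
#' * class III: a 35-nt >= 80% AT run with every `ATTTA` destroyed.
#'
#' @param n_classI,n_classII,n_classIII Feature counts to plant.
#' @param at_target Target overall AT fraction.
#' @param length Total sequence length in bp.
#' @param seed Integer seed.
#' @param id Sequence id (default `"utr_1"`).
#' @return A list with `seqs` (one-row sequence tibble, role `utr3`) and
#'   `truth` (tibble: `utr_id`, `start`, `end`, `are_class`).
#' @export
generate_synthetic_utr <- function(n_classI, n_classII, n_classIII,
                                   at_target = 0.5, length = 1000,
                                   seed = NULL, id = "utr_1") {
  gen <- function() {
    feats <- c(
      purrr::map(seq_len(n_classII), function(i) {
        list(cls = "II", seq = "ATTTATTTA")
      }),
      purrr::map(seq_len(n_classI), function(i) {
        repeat {  # exactly one pentamer, the planted one
          s <- paste0(make_at_run(10, 0.95), "ATTTA", make_at_run(10, 0.95))
          if (identical(find_pentamers(s), 10L)) return(list(cls = "I", seq = s))
        }
      }),
      purrr::map(seq_len(n_classIII), function(i) {
        repeat {  # every 30-mer window must stay AT-rich enough to qualify
          s <- make_at_run(35, 0.9)
          ok <- vapply(0:5, function(k) {
            stringi::stri_count_regex(
              stringi::stri_sub(s, k + 1, length = 30), "[AT]"
            ) >= 24
          }, logical(1))
          if (all(ok)) return(list(cls = "III", seq = s))
        }
      })
    )
    if (length(feats) > 1) feats <- sample(feats)
    feat_len <- sum(vapply(feats, function(f) nchar(f$seq), numeric(1)))
    n_spacer <- length(feats) + 1
    spacer_total <- length - feat_len
    if (spacer_total < 15 * n_spacer) {
      abort("Features do not fit: increase length or reduce counts.")
    }
    # spacer AT fraction chosen so the whole sequence hits at_target
    feat_at <- sum(vapply(feats, function(f) {
      stringi::stri_count_regex(f$seq, "[AT]")
    }, numeric(1)))
    sp_at <- (at_target * length - feat_at) / spacer_total
    sp_at <- max(0, min(0.5, sp_at))
    sizes <- rep(spacer_total %/% n_spacer, n_spacer)
    sizes[n_spacer] <- sizes[n_spacer] + spacer_total %% n_spacer
    pieces <- character(0)
    truth <- list()
    pos <- 0L
    for (i in seq_along(feats)) {
      sp <- make_spacer(sizes[i], sp_at)
      pieces <- c(pieces, sp)
      pos <- pos + nchar(sp)
      pieces <- c(pieces, feats[[i]]$seq)
      truth[[i]] <- tibble(
        utr_id = id, start = pos, end = pos + nchar(feats[[i]]$seq),
        are_class = feats[[i]]$cls
      )
      pos <- pos + nchar(feats[[i]]$seq)
    }
    pieces <- c(pieces, make_spacer(sizes[n_spacer], sp_at))
    seq <- paste(pieces, collapse = "")
    list(
      seqs = seq_tbl(id, seq, role = "utr3"),
      truth = if (length(truth)) {
        bind_rows(truth)
      } else {
        tibble(utr_id = character(), start = integer(), end = integer(),
               are_class = character())
      }
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate a synthetic ChIP-seq peak file from truth sites
#'
#' Each true site is independently covered, with probability
#' `coverage_fraction`, by one peak of width 150-300 bp centered on the
#' site (plus uniform jitter of up to `jitter_bp`); `n_decoys` additional
#' peaks are placed away from every true site.
#'
#' @param truth Truth tibble with `seq_id`, `start`, `end` (e.g. from
#'   [plant_motifs()]).
#' @param seq_lengths Named integer vector, sequence id -> length.
#' @param coverage_fraction Probability a true site is covered.
#' @param jitter_bp Max center jitter in bp (default 0).
#' @param n_decoys Decoy peaks per sequence (default 0).
#' @param seed Integer seed.
#' @param cell_line,tf_name Labels for the peak set.
#' @return A peak tibble (as [read_peaks()]), with an extra logical
#'   column `is_decoy`.
#' @export
generate_peak_file <- function(truth, seq_lengths, coverage_fraction,
                               jitter_bp = 0, n_decoys = 0, seed = NULL,
                               cell_line = "synthetic", tf_name = NA_character_) {
  if (coverage_fraction < 0 || coverage_fraction > 1) {
    abort("coverage_fraction must be in [0, 1].")
  }
  gen <- function() {
    peaks <- list()
    covered <- runif(nrow(truth)) < coverage_fraction
    for (i in which(covered)) {
      L <- seq_lengths[[truth$seq_id[i]]]
      wpk <- sample(150:300, 1)
      center <- (truth$start[i] + truth$end[i]) %/% 2 +
        if (jitter_bp > 0) sample(-jitter_bp:jitter_bp, 1) else 0L
      s <- max(0L, as.integer(center - wpk %/% 2))
      e <- min(L, s + wpk)
      s <- max(0L, e - wpk)
      peaks[[length(peaks) + 1]] <- tibble(
        seq_id = truth$seq_id[i], start = s, end = e,
        name = sprintf("peak_%03d", length(peaks) + 1),
        score = 1000, strand = ".",
        signal = stats::rexp(1, 1 / 10) + 5,
        summit_offset = as.integer((truth$start[i] + truth$end[i]) %/% 2 - s),
        cell_line = cell_line, tf = tf_name, is_decoy = FALSE
      )
    }
    if (n_decoys > 0) {
      for (sid in unique(names(seq_lengths))) {
        L <- seq_lengths[[sid]]
        tr <- truth[truth$seq_id == sid, , drop = FALSE]
        placed <- 0
        guard <- 0
        while (placed < n_decoys && guard < 1000) {
          guard <- guard + 1
          wpk <- sample(150:300, 1)
          s <- sample.int(max(1, L - wpk), 1) - 1L
          e <- s + wpk
          if (nrow(tr) == 0 ||
              all(pmin(tr$end, e) - pmax(tr$start, s) <= 0)) {
            placed <- placed + 1
            peaks[[length(peaks) + 1]] <- tibble(
              seq_id = sid, start = s, end = e,
              name = sprintf("decoy_%03d", placed),
              score = 200, strand = ".", signal = stats::rexp(1, 1 / 5),
              summit_offset = as.integer(wpk %/% 2),
              cell_line = cell_line, tf = tf_name, is_decoy = TRUE
            )
          }
        }
      }
    }
    if (length(peaks) == 0) {
      tibble(
        seq_id = character(), start = integer(), end = integer(),
        name = character(), score = double(), strand = character(),
        signal = double(), summit_offset = integer(),
        cell_line = character(), tf = character(), is_decoy = logical()
      )
    } else {
      bind_rows(peaks)
    }
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Write a truth object as JSON
#'
#' Truth tables use the same 0-based half-open coordinates as BED and the
#' hit tables, so downstream comparisons need no conversion.
#'
#' @param truth A truth tibble or list of tibbles.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
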