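#' Pipeline configuration defaults
#'
#' Every parameter the promoter analysis leaves open has an explicit,
#' documented default collected here, so "what is configurable" is visible
#' in one place. `pipeline_config()` merges user settings (a YAML file
#' path or a nested list) over these defaults.
#'
#' @param config A YAML file path, a nested list, or `NULL` for pure
#'   defaults.
#' @return A nested list with elements `paths` (promoter FASTAs by
#'   species, UTR FASTA, PFM file, peak files by cell line), `params`
#'   (scanning, conservation, ARE, background), `reference_species`, and
#'   `out_dir`.
#' @export
pipeline_config <- function(config = NULL) {
  defaults <- list(
    paths = list(
      promoter_fasta = list(),   # species -> FASTA path
      utr_fasta = NULL,
      pfm_file = NULL,           # NULL -> bundled synthetic stand-ins
      peaks = list()             # cell line -> BED/narrowPeak path
    ),
    params = list(
      rel_threshold = 0.8,
      pseudocount = 0.8,
      conservation = list(window = 21, min_identity = 0.70, min_len = 21,
                          min_col_overlap = 0.5),
      are = unclass(are_params()),
      background = list(n_rand = 100, length = 1000,
                        composition = c(0.25, 0.25, 0.25, 0.25),
                        tfs = c("JUN", "SP1"), seed = 1),
      align = list(match = 1, mismatch = -1, gap = -2),
      chipseq = list(min_bp = 1)
    ),
    reference_species = "human",
    out_dir = "crossreg_run"
  )
  user <- if (is.null(config)) {
    list()
  } else if (is.character(config)) {
    yaml::read_yaml(config)
  } else if (is.list(config)) {
    config
  } else {
    abort("config must be a YAML path, a list, or NULL.")
  }
  merge_lists(defaults, user)
}

merge_lists <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]) &&
        !is.data.frame(user[[nm]])) {
      base[[nm]] <- merge_lists(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

run_stage <- function(name, log, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Pipeline stage '", name, "' failed: ",
                 conditionMessage(e)))
  })
}

#' Run the full promoter cross-regulation pipeline
#'
#' Orchestrates all stages deterministically: PWM scanning of every
#' promoter in every species, pairwise cross-species conservation
#' filtering against the reference species, per-gene family count tables,
#' promoter composition plus cofactor counts, 3'UTR ARE classification,
#' random-background specificity testing, and ChIP-seq peak support.
#' Promoter records are paired across species by record id (each record is
#' treated as one promoter variant). All outputs are TSV files under
#' `out_dir`, plus a run log recording every parameter and seed; rerunning
#' with the same config and inputs reproduces the bundle byte for byte.
#'
#' @param config A YAML path or nested list (see [pipeline_config()]).
#' @return Invisibly, a named list of the result tibbles (`hits`,
#'   `conserved`, `counts`, `composition`, `utr`, `background`,
#'   `chipseq_per_hit`, `chipseq_per_promoter`) plus `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  p <- cfg$params
  if (length(cfg$paths$promoter_fasta) == 0) {
    abort("config error: paths$promoter_fasta must map species to FASTA files.")
  }
  missing <- purrr::keep(unlist(cfg$paths, use.names = FALSE),
                         ~ is.character(.x) && !file.exists(.x))
  if (length(missing)) {
    abort(paste0("config error: missing input file(s): ",
                 paste(missing, collapse = ", ")))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    paste0("crossreg ", as.character(utils::packageVersion("crossreg"))),
    paste0("parameters: ", jsonlite::toJSON(p, auto_unbox = TRUE, digits = NA))
  )
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }

  pfms <- run_stage("load_pfms", note, {
    if (is.null(cfg$paths$pfm_file)) crossreg_pfms()
    else read_jaspar(cfg$paths$pfm_file)
  })
  pwms <- purrr::map(pfms, pfm_to_pwm, pseudocount = p$pseudocount)
  note("loaded ", length(pfms), " PFMs: ",
       paste(names(pfms), collapse = ", "))

  promoters <- run_stage("read_promoters", note, {
    bind_rows(purrr::imap(cfg$paths$promoter_fasta, function(path, sp) {
      fa <- read_fasta(path, species = sp, role = "promoter")
      mutate(fa, id = paste0(.data$id, "@", sp))
    }))
  })
  promoters <- mutate(promoters,
                      gene = stringr::str_remove(.data$id, "@[^@]*$"))
  note("read ", nrow(promoters), " promoters across ",
       n_distinct(promoters$species), " species")

  hits <- run_stage("scan", note, {
    bind_rows(purrr::map(pwms, function(pw) {
      scan_pwm(promoters, pw, rel_threshold = p$rel_threshold)
    }))
  })
  hits <- attach_species(hits, promoters)
  readr::write_tsv(hits, file.path(cfg$out_dir, "hits.tsv"))
  write_bed(hits, file.path(cfg$out_dir, "hits.bed"))
  note("scanned: ", nrow(hits), " hits at rel_threshold ", p$rel_threshold)

  # conservation: reference vs each other species, promoters paired by gene
  ref <- cfg$reference_species
  cons <- run_stage("conserve", note, {
    others <- setdiff(unique(promoters$species), ref)
    pc <- p$conservation
    purrr::map_dfr(others, function(sp) {
      genes <- intersect(promoters$gene[promoters$species == ref],
                         promoters$gene[promoters$species == sp])
      purrr::map_dfr(genes, function(g) {
        a <- promoters[promoters$gene == g & promoters$species == ref, ]
        b <- promoters[promoters$gene == g & promoters$species == sp, ]
        aln <- align_pair(a$seq[1], b$seq[1],
                          match = p$align$match,
                          mismatch = p$align$mismatch, gap = p$align$gap,
                          species = c(ref, sp))
        prof <- identity_profile(aln, window = pc$window)
        regions <- call_conserved_regions(prof,
                                          min_identity = pc$min_identity,
                                          min_len = pc$min_len)
        gh <- hits[hits$seq_id %in% c(a$id[1], b$id[1]), , drop = FALSE]
        ch <- conserved_hits(gh, aln, regions,
                             min_col_overlap = pc$min_col_overlap,
                             reference = ref, other = sp)
        if (nrow(ch)) {
          mutate(ch, gene = g, species_other = sp,
                 pairwise_identity = pairwise_identity(aln), .before = 1)
        } else {
          ch
        }
      })
    })
  })
  if (ncol(cons) == 0) {
    cons <- tibble(gene = character(), species_other = character(),
                   tf = character())
  }
  readr::write_tsv(cons, file.path(cfg$out_dir, "conserved_hits.tsv"))
  note("conservation: ", nrow(cons), " conserved hits vs reference '",
       ref, "'")

  counts <- run_stage("count", note, {
    fam_map <- setNames(
      purrr::map_chr(pfms, "family"),
      purrr::map_chr(pfms, "tf_name")
    )
    rows <- purrr::map(seq_len(nrow(promoters)), function(i) {
      pr <- promoters[i, ]
      count_by_family(hits[hits$seq_id == pr$id, , drop = FALSE],
                      family_map = fam_map,
                      gene = pr$gene, species = pr$species,
                      variant = pr$id)
    })
    build_dataset_table(rows)
  })
  readr::write_tsv(counts, file.path(cfg$out_dir, "count_table.tsv"))

  composition <- run_stage("composition", note, {
    refp <- promoters[promoters$species == ref, , drop = FALSE]
    purrr::map_dfr(seq_len(nrow(refp)), function(i) {
      h <- hits[hits$seq_id == refp$id[i], , drop = FALSE]
      cnt <- function(tf) {
        hh <- h[h$tf == tf, , drop = FALSE]
        c(nrow(distinct(hh, .data$start, .data$end)), nrow(hh))
      }
      jun <- cnt("JUN"); sp1 <- cnt("SP1")
      tibble(
        gene = refp$gene[i], gc_percent = 100 * gc_content(refp$seq[i]),
        n_AP1 = jun[1], n_AP1_raw = jun[2],
        n_SP1 = sp1[1], n_SP1_raw = sp1[2]
      )
    })
  })
  readr::write_tsv(composition, file.path(cfg$out_dir, "composition.tsv"))

  utr <- NULL
  if (!is.null(cfg$paths$utr_fasta)) {
    utr <- run_stage("are", note, {
      utr_summary(read_fasta(cfg$paths$utr_fasta, role = "utr3"),
                  params = p$are)
    })
    readr::write_tsv(utr, file.path(cfg$out_dir, "utr_summary.tsv"))
    note("ARE: summarized ", nrow(utr), " UTRs")
  }

  background <- NULL
  if (p$background$n_rand > 0) {
    background <- run_stage("background", note, {
      refp <- promoters[promoters$species == ref, , drop = FALSE]
      purrr::map_dfr(p$background$tfs, function(tf) {
        specificity_comparison(
          refp, pwms[[tf]],
          n_rand = p$background$n_rand, length = p$background$length,
          composition = p$background$composition,
          rel_threshold = p$rel_threshold, seed = p$background$seed
        )
      })
    })
    readr::write_tsv(background, file.path(cfg$out_dir, "background.tsv"))
  } else {
    note("background stage skipped (n_rand = 0)")
  }

  chip_hit <- NULL
  chip_prom <- NULL
  if (length(cfg$paths$peaks) > 0) {
    supp <- run_stage("chipseq", note, {
      sets <- purrr::imap(cfg$paths$peaks,
                          function(path, cl) read_peaks(path, cell_line = cl))
      support_summary(hits, sets, min_bp = p$chipseq$min_bp)
    })
    chip_hit <- supp$per_hit
    chip_prom <- supp$per_promoter
    readr::write_tsv(chip_hit, file.path(cfg$out_dir, "chipseq_support.tsv"))
    readr::write_tsv(chip_prom,
                     file.path(cfg$out_dir, "chipseq_promoters.tsv"))
  }

  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  invisible(list(
    hits = hits, conserved = cons, counts = counts,
    composition = composition, utr = utr, background = background,
    chipseq_per_hit = chip_hit, chipseq_per_promoter = chip_prom,
    out_dir = cfg$out_dir
  ))
}

#' Materialize the synthetic demo dataset
#'
#' Writes a complete, self-consistent input bundle with known ground
#' truth: four-species orthologous promoter FASTAs with conserved blocks
#' and planted IRF3/RELA sites, two 3'UTRs built to contrasting ARE
#' profiles, ChIP-seq peak files covering the planted reference-species
#' sites, JSON truth files, and a ready-to-run pipeline config YAML.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; the whole bundle is a pure function of it.
#' @param n_genes Number of synthetic genes (default 2).
#' @return The config YAML path, invisibly; truth files sit next to it.
#' @export
make_fixtures <- function(out_dir, seed = 1, n_genes = 2) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pfms <- crossreg_pfms()
  species <- c(human = 0, chimpanzee = 0.02, mouse = 0.5, cattle = 0.3)
  blocks <- tibble(start = c(150L, 650L), end = c(300L, 800L))
  plants <- tibble(pfm = list(pfms$IRF3, pfms$RELA), block = c(1L, 2L))
  fams <- purrr::map(seq_len(n_genes), function(g) {
    generate_ortholog_family(1000, species, blocks, plants,
                             seed = seed + g)
  })
  genes <- sprintf("gene%02d", seq_len(n_genes))
  for (sp in names(species)) {
    seqs <- purrr::map2_dfr(fams, genes, function(f, g) {
      mutate(f$seqs[f$seqs$species == sp, ], id = g)
    })
    write_fasta(seqs, file.path(out_dir, paste0("promoters_", sp, ".fa")))
  }
  truth_sites <- purrr::map2_dfr(fams, genes, function(f, g) {
    mutate(f$truth$planted_sites, gene = g)
  })
  write_truth_json(
    list(conserved_blocks = blocks, planted_sites = truth_sites),
    file.path(out_dir, "truth_promoters.json")
  )

  utr1 <- generate_synthetic_utr(4, 1, 8, at_target = 0.5, length = 2100,
                                 seed = seed + 101, id = "utr_long")
  utr2 <- generate_synthetic_utr(0, 0, 0, at_target = 0.425, length = 89,
                                 seed = seed + 102, id = "utr_short")
  write_fasta(bind_rows(utr1$seqs, utr2$seqs),
              file.path(out_dir, "utrs.fa"))
  write_truth_json(bind_rows(utr1$truth, utr2$truth),
                   file.path(out_dir, "truth_utrs.json"))

  human_truth <- truth_sites[truth_sites$species == "human", ]
  human_truth$seq_id <- paste0(human_truth$gene, "@human")
  seq_lengths <- setNames(rep(1000L, n_genes), paste0(genes, "@human"))
  cells <- c("cellA", "cellB", "cellC")
  for (i in seq_along(cells)) {
    pk <- generate_peak_file(human_truth, seq_lengths,
                             coverage_fraction = 0.9, jitter_bp = 20,
                             n_decoys = 1, seed = seed + 200 + i,
                             cell_line = cells[i])
    write_narrowpeak(pk, file.path(out_dir,
                                   paste0("peaks_", cells[i], ".narrowPeak")))
  }

  cfg <- list(
    paths = list(
      promoter_fasta = as.list(setNames(
        file.path(out_dir, paste0("promoters_", names(species), ".fa")),
        names(species)
      )),
      utr_fasta = file.path(out_dir, "utrs.fa"),
      peaks = as.list(setNames(
        file.path(out_dir, paste0("peaks_", cells, ".narrowPeak")), cells
      ))
    ),
    params = list(background = list(seed = seed)),
    reference_species = "human",
    out_dir = file.path(out_dir, "results")
  )
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}
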