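test_that("alignment tables validate shape and read both formats", {
  al <- aln_tbl(c("a", "b"), c("ACGTACGTAC", "ACGTACGTAC"))
  expect_equal(aln_ncol(al), 10)
  expect_equal(aln_ncol(aln_tbl(c("a", "b"), c("AC-GT", "ACAGT"))), 5)
  expect_error(aln_tbl(c("a", "b"), c("ACGTA", "ACGTAC")), "unequal")
  expect_error(aln_tbl(character(), character()), ">= 1 row")

  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">human", "AC-GT", ">mouse", "ACAGT"), fa)
  got <- read_alignment(fa)
  expect_equal(got$species, c("human", "mouse"))
  expect_equal(got$aligned_seq, c("AC-GT", "ACAGT"))

  cl <- withr::local_tempfile(fileext = ".aln")
  writeLines(c(
    "CLUSTAL W (2.1) multiple sequence alignment", "",
    "human           AC-GT", "mouse           ACAGT", ""
  ), cl)
  got2 <- read_alignment(cl, format = "clustal")
  expect_equal(got2$aligned_seq, got$aligned_seq)
})

test_that("seq_to_aln_map shifts around gaps", {
  expect_equal(seq_to_aln_map("ACGT"), 0:3)
  expect_equal(seq_to_aln_map("AC-GT"), c(0L, 1L, 3L, 4L))
  expect_equal(seq_to_aln_map("--AC"), c(2L, 3L))
  # strictly increasing on random gapped rows
  set.seed(21)
  for (k in 1:10) {
    row <- paste(sample(c("A", "C", "G", "T", "-"), 40, TRUE),
                 collapse = "")
    m <- seq_to_aln_map(row)
    expect_true(all(diff(m) > 0))
    expect_equal(length(m), nchar(gsub("-", "", row)))
  }
})

test_that("identity_profile averages per-column matches", {
  al <- aln_tbl(c("a", "b"), c("ACGTACGTAC", "ACGTACGTAC"))
  expect_equal(identity_profile(al, window = 5), rep(1, 10))
  expect_equal(identity_profile(aln_tbl(c("a", "b"), c("AAAA", "TTTT")),
                                window = 1), rep(0, 4))
  expect_equal(identity_profile(aln_tbl(c("a", "b"), c("AATT", "AAAA")),
                                window = 1), c(1, 1, 0, 0))
  # truncated centered window at edges
  expect_equal(identity_profile(aln_tbl(c("a", "b"), c("AATT", "AAAA")),
                                window = 3), c(1, 2 / 3, 1 / 3, 0))
  expect_error(identity_profile(al, window = 4), "odd")
})

test_that("call_conserved_regions finds qualifying runs", {
  expect_equal(
    call_conserved_regions(rep(1, 50), 0.7, 21),
    tibble::tibble(start = 0L, end = 50L)
  )
  expect_equal(nrow(call_conserved_regions(rep(0, 50), 0.7, 21)), 0)
  got <- call_conserved_regions(c(1, 1, 1, 0, 1, 1, 1), 0.5, 3)
  expect_equal(got$start, c(0L, 4L))
  expect_equal(got$end, c(3L, 7L))

  # tightening either knob never lengthens the total called region
  set.seed(22)
  prof <- pmin(1, pmax(0, stats::filter(runif(300), rep(1 / 21, 21),
                                        sides = 2)))
  prof[is.na(prof)] <- 0
  total <- function(mi, ml) {
    r <- call_conserved_regions(as.numeric(prof), mi, ml)
    sum(r$end - r$start)
  }
  for (mi in c(0.3, 0.5, 0.7)) {
    expect_gte(total(mi, 5), total(mi + 0.1, 5))
    expect_gte(total(mi, 5), total(mi, 15))
  }
})

test_that("pairwise_identity applies the gap conventions", {
  expect_equal(pairwise_identity(aln_tbl(c("a", "b"), c("ACGT", "ACGT"))),
               100)
  expect_equal(pairwise_identity(aln_tbl(c("a", "b"), c("AAAA", "AATT"))),
               50)
  expect_equal(pairwise_identity(aln_tbl(c("a", "b"), c("AA--", "AAAA"))),
               50)
  # both-gap columns leave the denominator
  expect_equal(
    pairwise_identity(aln_tbl(c("a", "b"), c("AA--", "AA-A"))),
    100 * 2 / 3
  )
  expect_equal(
    pairwise_identity(aln_tbl(c("a", "b"), c("ACAA", "AAAC")), c(1, 2)),
    pairwise_identity(aln_tbl(c("a", "b"), c("ACAA", "AAAC")), c(2, 1))
  )
})

test_that("conserved_hits keeps only cross-species-supported hits", {
  al <- aln_tbl(c("human", "mouse"), c("ACGTACGTACGT", "ACGTACGTACGT"))
  regions <- tibble::tibble(start = 0L, end = 12L)
  mk <- function(species, start, end, tf = "IRF3") {
    tibble::tibble(seq_id = paste0("p_", species), start = start,
                   end = end, strand = "+", tf = tf, species = species)
  }
  both <- dplyr::bind_rows(mk("human", 3L, 7L), mk("mouse", 3L, 7L))
  got <- conserved_hits(both, al, regions)
  expect_equal(nrow(got), 1)
  expect_equal(got$col_overlap_fraction, 1)
  expect_equal(got$start_ref, 3L)

  expect_equal(nrow(conserved_hits(mk("human", 3L, 7L), al, regions)), 0)

  # offset 2 columns, width 4: overlap fraction exactly 0.5
  off <- dplyr::bind_rows(mk("human", 3L, 7L), mk("mouse", 5L, 9L))
  expect_equal(conserved_hits(off, al, regions)$col_overlap_fraction, 0.5)
  expect_equal(nrow(conserved_hits(off, al, regions,
                                   min_col_overlap = 0.6)), 0)

  # a hit outside every conserved region is dropped
  expect_equal(nrow(conserved_hits(both, al,
                                   tibble::tibble(start = 9L, end = 12L))),
               0)
  # different TF in the other species gives no support
  mix <- dplyr::bind_rows(mk("human", 3L, 7L), mk("mouse", 3L, 7L, "RELA"))
  expect_equal(nrow(conserved_hits(mix, al, regions)), 0)
  expect_error(conserved_hits(mk("human", 3L, 99L), al, regions),
               "outside")

  # gapped mapping: hits are compared in alignment columns
  alg <- aln_tbl(c("human", "mouse"), c("AC--GTAC", "ACTTGTAC"))
  gap_hits <- dplyr::bind_rows(mk("human", 0L, 4L), mk("mouse", 2L, 6L))
  got_g <- conserved_hits(gap_hits, alg,
                          tibble::tibble(start = 0L, end = 8L))
  expect_equal(got_g$col_start_ref, 0L)
  expect_equal(got_g$col_end_ref, 6L)
})

test_that("conserved hits are a subset of reference hits", {
  set.seed(23)
  pw <- pfm_to_pwm(delta_pfm("GAAAGTGAAAGT"))
  fam <- generate_ortholog_family(
    600, c(human = 0, mouse = 0.4),
    tibble::tibble(start = 100L, end = 260L),
    tibble::tibble(pfm = list(delta_pfm("GAAAGTGAAAGT")), block = 1L),
    seed = 77
  )
  hits <- attach_species(scan_pwm(fam$seqs, pw, 0.75), fam$seqs)
  prof <- identity_profile(fam$alignment)
  regions <- call_conserved_regions(prof)
  got <- conserved_hits(hits, fam$alignment, regions)
  ref_keys <- paste(hits$start[hits$species == "human"],
                    hits$end[hits$species == "human"])
  expect_true(all(paste(got$start_ref, got$end_ref) %in% ref_keys))
})

test_that("align_pair computes optimal global alignments", {
  a <- align_pair("ACGT", "ACGT")
  expect_equal(attr(a, "score"), 4)
  expect_equal(a$aligned_seq, c("ACGT", "ACGT"))

  b <- align_pair("ACGT", "ACT")
  expect_equal(attr(b, "score"), 1)  # 3 matches + 1 gap
  expect_equal(b$aligned_seq, c("ACGT", "AC-T"))

  c1 <- align_pair("A", "T")
  expect_equal(attr(c1, "score"), -1)
  expect_equal(c1$aligned_seq, c("A", "T"))
  expect_error(align_pair("", "ACGT"), "Empty")
})

test_that("align_pair scores match an independent aligner", {
  set.seed(24)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (k in 1:8) {
    s1 <- rand_dna_str(sample(20:60, 1))
    s2 <- rand_dna_str(sample(20:60, 1))
    mine <- attr(align_pair(s1, s2), "score")
    ref <- Biostrings::pairwiseAlignment(
      s1, s2, type = "global", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 2, scoreOnly = TRUE
    )
    expect_equal(mine, ref)
    # ungapping the rows recovers the inputs
    al <- align_pair(s1, s2)
    expect_equal(gsub("-", "", al$aligned_seq), c(s1, s2))
  }
})
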