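test_that("sample_motif_instance draws per column in proportion to counts", {
  dp <- delta_pfm("ACGT")
  expect_equal(unique(sample_motif_instance(dp, n = 20)),
               "ACGT")
  expect_identical(sample_motif_instance(crossreg_pfms()$IRF3, 5, seed = 1),
                   sample_motif_instance(crossreg_pfms()$IRF3, 5, seed = 1))

  unif <- pfm(matrix(1, 4, 4), "u")
  draws <- sample_motif_instance(unif, n = 10000, seed = 2)
  first <- substr(draws, 1, 1)
  for (b in c("A", "C", "G", "T")) {
    # binomial 3 SD around 0.25
    expect_lte(abs(mean(first == b) - 0.25),
               3 * sqrt(0.25 * 0.75 / 10000))
  }
})

test_that("plant_motifs records exact, disjoint truth", {
  none <- plant_motifs(200, delta_pfm("ACGTAC"), 0, seed = 5)
  expect_equal(nrow(none$truth), 0)
  expect_equal(nchar(none$seqs$seq), 200)

  pl <- plant_motifs(1000, delta_pfm("GTACCGGTTAAC"), 3, seed = 6)
  tr <- pl$truth[order(pl$truth$start), ]
  expect_true(all(diff(tr$start) >= 12))
  expect_true(all(tr$end <= 1000))
  # scanning at threshold 1.0 recovers exactly the planted intervals
  hits <- scan_pwm(pl$seqs, pfm_to_pwm(delta_pfm("GTACCGGTTAAC")), 1)
  expect_setequal(paste(hits$start, hits$end), paste(tr$start, tr$end))
  # the planted strand is among the reported strands at each interval
  expect_true(all(paste(tr$start, tr$strand) %in%
                    paste(hits$start, hits$strand)))

  expect_error(plant_motifs(30, delta_pfm("ACGTACGTACGT"), 5, seed = 7),
               "fit")
  expect_identical(plant_motifs(500, delta_pfm("ACGTAC"), 2, seed = 8),
                   plant_motifs(500, delta_pfm("ACGTAC"), 2, seed = 8))
})

test_that("ortholog families follow the substitution model", {
  blocks <- tibble::tibble(start = 150L, end = 300L)
  same <- generate_ortholog_family(400, c(human = 0, mouse = 0), blocks,
                                   seed = 9)
  expect_equal(same$seqs$seq[1], same$seqs$seq[2])
  expect_equal(pairwise_identity(same$alignment), 100)

  # substitution-only: ungapped alignment, per-site match rate 1 - d
  div <- generate_ortholog_family(
    4000, c(human = 0, mouse = 0.4),
    tibble::tibble(start = integer(), end = integer()), seed = 10
  )
  expect_false(any(grepl("-", div$alignment$aligned_seq)))
  ident <- pairwise_identity(div$alignment) / 100
  expect_lte(abs(ident - 0.6), 3 * sqrt(0.4 * 0.6 / 4000))

  # block positions mutate at a tenth of the outside rate
  blk <- generate_ortholog_family(2000,
                                  c(human = 0, mouse = 0.5),
                                  tibble::tibble(start = 500L, end = 1500L),
                                  seed = 11)
  a <- strsplit(blk$seqs$seq[1], "")[[1]]
  b <- strsplit(blk$seqs$seq[2], "")[[1]]
  inside <- mean(a[501:1500] == b[501:1500])
  outside <- mean(a[c(1:500, 1501:2000)] == b[c(1:500, 1501:2000)])
  expect_gt(inside, 0.90)
  expect_lt(outside, 0.60)

  expect_error(
    generate_ortholog_family(100, c(h = 2), blocks),
    "divergences"
  )
})

test_that("planted cross-species sites survive into every species copy", {
  pf <- delta_pfm("GAAAGTGAAAGT", name = "IRF3", family = "IRF")
  fam <- generate_ortholog_family(
    1000, c(human = 0, chimpanzee = 0.5, mouse = 0.5),
    tibble::tibble(start = c(150L, 650L), end = c(300L, 800L)),
    tibble::tibble(pfm = list(pf, pf), block = c(1L, 2L)), seed = 12
  )
  tr <- fam$truth$planted_sites
  expect_equal(nrow(tr), 6)  # 2 plants x 3 species
  for (i in seq_len(nrow(tr))) {
    sp_seq <- fam$seqs$seq[fam$seqs$species == tr$species[i]]
    expect_equal(substr(sp_seq, tr$start[i] + 1, tr$end[i]),
                 tr$planted_seq[i])
  }
})

test_that("synthetic UTRs hit their ARE profile and AT target", {
  u0 <- generate_synthetic_utr(0, 0, 0, at_target = 0.425, length = 89,
                               seed = 13)
  expect_equal(nchar(u0$seqs$seq), 89)
  expect_lte(abs(at_content(u0$seqs$seq) - 0.425), 0.05)
  expect_equal(nrow(classify_are(u0$seqs$seq)), 0)

  u1 <- generate_synthetic_utr(1, 0, 0, at_target = 0.45, length = 300,
                               seed = 14)
  s1 <- classify_are(u1$seqs$seq)
  expect_equal(s1$are_class, "I")

  u <- generate_synthetic_utr(2, 1, 3, at_target = 0.5, length = 1200,
                              seed = 15)
  got <- utr_summary(u$seqs)
  expect_equal(got$n_class_I, 2)
  expect_equal(got$n_class_II, 1)
  expect_equal(got$n_class_III, 3)
  expect_lte(abs(got$at_content - 0.5), 0.05)
  expect_identical(
    u$seqs,
    generate_synthetic_utr(2, 1, 3, at_target = 0.5, length = 1200,
                           seed = 15)$seqs
  )
  expect_error(generate_synthetic_utr(10, 10, 10, length = 200, seed = 16),
               "fit")
})

test_that("synthetic peak coverage tracks the requested fraction", {
  pl <- plant_motifs(5000, delta_pfm("GAAAGTGAAAGT"), 40, seed = 17)
  w <- 12L
  full <- generate_peak_file(pl$truth, c(synth_1 = 5000L), 1, jitter_bp = 0,
                             seed = 18)
  hits_truth <- dplyr::mutate(pl$truth, family = "IRF", raw_score = 1,
                              rel_score = 1, matched_seq = "")
  expect_true(all(intersect_hits_peaks(hits_truth, full,
                                       min_bp = w)$supported))

  none <- generate_peak_file(pl$truth, c(synth_1 = 5000L), 0,
                             n_decoys = 3, seed = 19)
  expect_true(all(none$is_decoy))
  expect_false(any(intersect_hits_peaks(hits_truth, none)$supported))

  # coverage 0.5 over many sites: supported fraction within 3 binomial
  # SD; sites spaced beyond the maximum peak half-width so a peak can
  # only cover its own site
  sites <- tibble::tibble(
    seq_id = rep(paste0("s", 1:17), each = 12),
    start = rep(seq(200, 4800, by = 400), 17),
    end = rep(seq(200, 4800, by = 400), 17) + w
  )
  sites$start <- as.integer(sites$start)
  sites$end <- as.integer(sites$end)
  lens <- stats::setNames(rep(5000L, 17), paste0("s", 1:17))
  half <- generate_peak_file(sites, lens, 0.5, seed = 20)
  supp <- intersect_hits_peaks(
    dplyr::mutate(sites, strand = "+", tf = "x", family = "x",
                  raw_score = 1, rel_score = 1, matched_seq = ""),
    half
  )
  expect_lte(abs(mean(supp$supported) - 0.5), 3 * sqrt(0.25 / 204))
})
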