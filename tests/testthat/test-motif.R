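test_that("pfm_to_pwm evaluates the log-odds formula", {
  unif <- pfm(matrix(1, 4, 1), "unif")
  expect_equal(unname(pfm_to_pwm(unif, pseudocount = 0)$weights[, 1]),
               rep(0, 4))

  delta <- pfm(matrix(c(10, 0, 0, 0), 4, 1), "d")
  expect_equal(unname(pfm_to_pwm(delta, pseudocount = 0)$weights["A", 1]),
               2)

  # hand evaluation of the formula for column (A:3, C:1, G:0, T:0),
  # pseudocount 0.8, uniform background:
  # weight_G = log2(((0 + 0.8*0.25) / (4 + 0.8)) / 0.25)
  mixed <- pfm(matrix(c(3, 1, 0, 0), 4, 1), "m")
  pw <- pfm_to_pwm(mixed, pseudocount = 0.8)
  expect_equal(unname(pw$weights["G", 1]), log2((0.2 / 4.8) / 0.25))
  expect_equal(unname(pw$weights["A", 1]), log2(((3 + 0.2) / 4.8) / 0.25))

  expect_error(pfm(matrix(c(0, 0, 0, 0, 1, 1, 1, 1), 4, 2), "z"),
               "zero-sum")
  expect_error(pfm_to_pwm(mixed, background = c(0.5, 0.5, 0, 0)),
               "positive")
})

test_that("pwm_extrema brackets the attainable score range", {
  dp <- pfm_to_pwm(delta_pfm("ACGT"), pseudocount = 0)
  ex <- pwm_extrema(dp)
  expect_equal(unname(ex["score_max"]), 8)
  expect_true(ex["score_min"] <= ex["score_max"])

  # single mixed column: max over the four hand-computed weights
  pw <- pfm_to_pwm(pfm(matrix(c(3, 1, 0, 0), 4, 1), "m"), pseudocount = 0.8)
  manual <- log2((c(3.2, 1.2, 0.2, 0.2) / 4.8) / 0.25)
  expect_equal(unname(pwm_extrema(pw)), range(manual))

  # degenerate all-zero-weight matrix scores rel 1 everywhere
  unif <- pfm_to_pwm(pfm(matrix(1, 4, 2), "u"), pseudocount = 0)
  h <- scan_pwm(seq_tbl("s", "ACGTA"), unif, rel_threshold = 1,
                strands = "+")
  expect_equal(nrow(h), 4)
  expect_equal(h$rel_score, rep(1, 4))
})

test_that("scan_pwm finds planted windows on both strands", {
  dp <- pfm_to_pwm(delta_pfm("ACGT"), pseudocount = 0)
  h <- scan_pwm(seq_tbl("s", "ACGTACGT"), dp, rel_threshold = 1)
  expect_equal(nrow(h), 4)  # ACGT is its own reverse complement
  expect_equal(h$start, c(0L, 0L, 4L, 4L))
  expect_setequal(h$strand[h$start == 0], c("+", "-"))

  # threshold floor: every window reported on one strand
  any_pwm <- pfm_to_pwm(delta_pfm("GGA"))
  s <- seq_tbl("s", "ACGTACGTAC")
  expect_equal(nrow(scan_pwm(s, any_pwm, 0, strands = "+")), 10 - 3 + 1)

  expect_equal(nrow(scan_pwm(seq_tbl("s", "AAA"), dp, 0)), 0)
  # windows containing N are skipped
  hn <- scan_pwm(seq_tbl("s", "ACGTNACGT"),
                 pfm_to_pwm(delta_pfm("ACGT")), 0, strands = "+")
  expect_equal(hn$start, c(0L, 5L))
  expect_error(scan_pwm(s, dp, 1.2), "rel_threshold")
})

test_that("scan_pwm agrees with brute-force enumeration and is strand-symmetric", {
  set.seed(101)
  for (k in 1:40) {
    w <- sample(2:6, 1)
    cnt <- matrix(sample(0:9, 4 * w, replace = TRUE), 4, w)
    cnt[1, colSums(cnt) == 0] <- 1
    p <- pfm(cnt, "rnd")
    s <- rand_dna_str(sample(8:30, 1))
    thr <- runif(1, 0.4, 1)
    got <- scan_pwm(seq_tbl("s", s), pfm_to_pwm(p), thr)
    want <- oracle_scan(cnt, s, 0.8, rep(0.25, 4), thr)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$raw_score, want$raw_score, tolerance = 1e-12)
    expect_equal(got$matched_seq, want$matched_seq)
    expect_true(all(got$rel_score >= thr))

    # minus-strand hits mirror plus-strand hits on the reverse complement
    plus_rc <- scan_pwm(seq_tbl("s", or_rc(s)), pfm_to_pwm(p), thr,
                        strands = "+")
    minus <- scan_pwm(seq_tbl("s", s), pfm_to_pwm(p), thr, strands = "-")
    expect_equal(sort(nchar(s) - plus_rc$end), sort(minus$start))
    expect_equal(sort(plus_rc$raw_score), sort(minus$raw_score),
                 tolerance = 1e-12)
  }
})

test_that("match_consensus implements IUPAC semantics", {
  s <- seq_tbl("s", "AGGAAATTCCG")
  expect_equal(match_consensus(s, "AGGAAATTCCG", strands = "+")$start, 0L)
  # canonical RELA site satisfies the generalized NF-kB consensus
  expect_equal(match_consensus(s, "RGGRNNHHYYB", strands = "+")$start, 0L)
  expect_equal(
    match_consensus(seq_tbl("s", "GAAACCAAATC"), "GAAASSAAANY",
                    strands = "+")$start, 0L)
  # the reverse complement of the site fails the consensus (C at the R),
  # so both-strand search still yields the single plus-strand hit
  both <- match_consensus(s, "RGGRNNHHYYB")
  expect_equal(both$strand, "+")
  expect_equal(both$rel_score, 1)
  expect_error(match_consensus(s, "AGGJ"), "IUPAC")

  # a pattern without degenerate symbols is exact substring search
  set.seed(11)
  for (k in 1:10) {
    seqs <- seq_tbl("r", rand_dna_str(300))
    pat <- rand_dna_str(4)
    got <- match_consensus(seqs, pat, strands = "+")
    want <- as.integer(gregexpr(paste0("(?=", pat, ")"), seqs$seq,
                                perl = TRUE)[[1]]) - 1L
    want <- want[want >= 0]
    expect_equal(got$start, want)
  }
})

test_that("consensus matching agrees with Biostrings on degenerate patterns", {
  set.seed(12)
  s <- rand_dna_str(2000)
  pat <- "GAAASSAAANY"
  got <- match_consensus(seq_tbl("s", s), pat, strands = "+")
  want <- Biostrings::matchPattern(Biostrings::DNAString(pat),
                                   Biostrings::DNAString(s), fixed = FALSE)
  expect_equal(got$start, BiocGenerics::start(want) - 1L)
})

test_that("read_jaspar parses matrices and flags malformed input", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    ">M1 TFA",
    "A [ 1 2 3 4 5 6 7 8 9 10 11 ]",
    "C [ 0 0 0 0 0 0 0 0 0 0 0 ]",
    "G [ 1 1 1 1 1 1 1 1 1 1 1 ]",
    "T [ 2 2 2 2 2 2 2 2 2 2 2 ]",
    ">M2 TFB",
    "A [ 1 1 ]", "C [ 1 1 ]", "G [ 1 1 ]", "T [ 1 1 ]"
  ), f)
  got <- read_jaspar(f)
  expect_equal(names(got), c("TFA", "TFB"))
  expect_equal(motif_width(got$TFA), 11)
  expect_equal(motif_width(got$TFB), 2)

  writeLines(c(">M3 TFC", "A [ 1 1 1 ]", "C [ 1 1 1 ]", "G [ 1 1 1 ]",
               "T [ 1 1 ]"), f)
  expect_error(read_jaspar(f), "M3")
  writeLines(c(">M4 TFD", "A [ 1 x ]", "C [ 1 1 ]", "G [ 1 1 ]",
               "T [ 1 1 ]"), f)
  expect_error(read_jaspar(f), "non-numeric")
})

test_that("bundled PFM set loads with family labels", {
  pf <- crossreg_pfms()
  expect_setequal(
    names(pf),
    c("IRF1", "IRF2", "IRF3", "NFKB1", "RELA", "REL", "JUN", "SP1")
  )
  expect_equal(pf$IRF3$family, "IRF")
  expect_equal(pf$RELA$family, "NFKB")
  expect_equal(pf$SP1$family, "cofactor")
  expect_equal(motif_width(pf$IRF3), 11)
})

test_that("tidy and glance summarize motif objects", {
  p <- delta_pfm("ACGT")
  td <- tidy(p)
  expect_equal(nrow(td), 16)
  expect_equal(sum(td$freq), 4)
  gl <- glance(p)
  expect_equal(gl$width, 4)
  expect_gt(gl$information_bits, 7)  # near-delta: close to 2 bits/column
  pw <- pfm_to_pwm(p)
  expect_equal(glance(pw)$score_max, pw$score_max)
  expect_equal(nrow(tidy(pw)), 16)
})
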