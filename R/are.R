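#' Find ATTTA pentamers
#'
#' All (possibly overlapping) occurrences of the AU-rich element core
#' pentamer `AUUUA` (DNA-sense `ATTTA`) on the sense strand. AREs are mRNA
#' elements, so the antisense strand is never searched.
#'
#' @param seq A single DNA/RNA sequence (character scalar).
#' @return Sorted integer vector of 0-based start positions.
#' @examples
#' find_pentamers("ATTTATTTA")
#' @export
find_pentamers <- function(seq) {
  seq <- normalize_dna(seq, allow_empty = TRUE)
  if (nchar(seq) < 5) return(integer(0))
  m <- stringi::stri_locate_all_regex(seq, "(?=ATTTA)")[[1]]
  if (anyNA(m[, 1])) return(integer(0))
  as.integer(m[, 1]) - 1L
}

#' ARE classification parameters
#'
#' Defaults follow the standard three-class AU-rich element scheme:
#' class II sites are clusters of overlapping/adjacent `AUUUA` pentamers,
#' class I a single pentamer embedded in an AU-rich context, class III a
#' U-rich stretch without the pentamer. All knobs are exposed because the
#' class boundaries in the literature are operational, not canonical.
#'
#' @param cluster_gap Max distance (bp) between consecutive pentamer starts
#'   within one class II cluster (default 5: adjacent or overlapping).
#' @param ctx_window Flank width (bp) on each side of a singleton pentamer
#'   over which the AT context is measured (default 10).
#' @param ctx_at_min Minimum flanking AT fraction for class I (default
#'   0.65).
#' @param classIII_min_len Minimum AT-rich window length for class III
#'   (default 30).
#' @param classIII_at_min Minimum AT fraction of a class III window
#'   (default 0.75).
#' @return A named list of parameters.
#' @export
are_params <- function(cluster_gap = 5, ctx_window = 10, ctx_at_min = 0.65,
                       classIII_min_len = 30, classIII_at_min = 0.75) {
  if (cluster_gap < 0 || ctx_window < 0 || classIII_min_len < 1) {
    abort("ARE lengths/gaps must be non-negative (window length >= 1).")
  }
  if (ctx_at_min < 0 || ctx_at_min > 1 ||
      classIII_at_min < 0 || classIII_at_min > 1) {
    abort("ARE AT-fraction cutoffs must be in [0, 1].")
  }
  list(
    cluster_gap = cluster_gap, ctx_window = ctx_window,
    ctx_at_min = ctx_at_min, classIII_min_len = classIII_min_len,
    classIII_at_min = classIII_at_min
  )
}

#' Classify AU-rich elements on a 3'UTR
#'
#' Three-step procedure on the sense strand:
#' 1. `ATTTA` pentamers are grouped into clusters where consecutive starts
#'    differ by at most `cluster_gap`; clusters of two or more pentamers
#'    become one class II site spanning the cluster.
#' 2. Singleton pentamers whose flanking `ctx_window` bases on each side
#'    have AT fraction at least `ctx_at_min` become class I sites; other
#'    singletons stay unclassified.
#' 3. Maximal unions of `classIII_min_len`-wide windows with AT fraction at
#'    least `classIII_at_min` and containing no pentamer become class III
#'    sites (overlapping qualifying windows are merged).
#'
#' Class assignments are mutually exclusive: a pentamer belongs to exactly
#' one class I or II site, and class III sites contain no pentamer by
#' construction.
#'
#' @param seq A single DNA/RNA sequence (character scalar).
#' @param params Parameter list from [are_params()].
#' @return A tibble of sites: `start`, `end` (0-based half-open),
#'   `are_class` (`"I"`, `"II"`, `"III"`), `n_pentamers`,
#'   `context_at_fraction` (the AT fraction the classifying rule measured).
#' @examples
#' classify_are(paste0(strrep("T", 20), "ATTTATTTA", strrep("T", 20)))
#' @export
classify_are <- function(seq, params = are_params()) {
  params <- do.call(are_params, params)  # re-validate
  seq <- normalize_dna(seq, allow_empty = TRUE)
  L <- nchar(seq)
  empty <- tibble(
    start = integer(), end = integer(), are_class = character(),
    n_pentamers = integer(), context_at_fraction = double()
  )
  if (L == 0) return(empty)
  chars <- stringi::stri_sub(seq, seq_len(L), length = 1)
  is_at <- as.numeric(chars %in% c("A", "T"))
  cs_at <- c(0, cumsum(is_at))
  at_frac <- function(s0, e0) {        # 0-based half-open, clipped
    s0 <- max(0, s0); e0 <- min(L, e0)
    if (e0 <= s0) return(NA_real_)
    (cs_at[e0 + 1] - cs_at[s0 + 1]) / (e0 - s0)
  }

  pent <- find_pentamers(seq)
  sites <- list()

  if (length(pent)) {
    cl <- cumsum(c(1, diff(pent) > params$cluster_gap))
    for (g in unique(cl)) {
      p <- pent[cl == g]
      if (length(p) >= 2) {
        s0 <- p[1]; e0 <- p[length(p)] + 5L
        sites[[length(sites) + 1]] <- tibble(
          start = s0, end = e0, are_class = "II",
          n_pentamers = length(p),
          context_at_fraction = at_frac(s0, e0)
        )
      } else {
        flank_at <- c(cs_at[p + 1] - cs_at[max(0, p - params$ctx_window) + 1],
                      cs_at[min(L, p + 5 + params$ctx_window) + 1] -
                        cs_at[min(L, p + 5) + 1])
        flank_n <- (p - max(0, p - params$ctx_window)) +
          (min(L, p + 5 + params$ctx_window) - min(L, p + 5))
        frac <- if (flank_n > 0) sum(flank_at) / flank_n else 0
        if (frac >= params$ctx_at_min) {
          sites[[length(sites) + 1]] <- tibble(
            start = p, end = p + 5L, are_class = "I", n_pentamers = 1L,
            context_at_fraction = frac
          )
        }
      }
    }
  }

  # class III: merged qualifying windows free of pentamers
  wlen <- params$classIII_min_len
  if (L >= wlen) {
    pent_cover <- numeric(L)
    for (p in pent) pent_cover[(p + 1):min(L, p + 5)] <- 1
    cs_p <- c(0, cumsum(pent_cover))
    starts0 <- 0:(L - wlen)
    win_at <- (cs_at[starts0 + wlen + 1] - cs_at[starts0 + 1]) / wlen
    win_pent <- (cs_p[starts0 + wlen + 1] - cs_p[starts0 + 1]) > 0
    ok <- win_at >= params$classIII_at_min & !win_pent
    if (any(ok)) {
      qs <- starts0[ok]
      brk <- cumsum(c(1, diff(qs) >= wlen))  # overlapping windows chain
      for (g in unique(brk)) {
        q <- qs[brk == g]
        s0 <- q[1]; e0 <- q[length(q)] + wlen
        sites[[length(sites) + 1]] <- tibble(
          start = s0, end = e0, are_class = "III", n_pentamers = 0L,
          context_at_fraction = at_frac(s0, e0)
        )
      }
    }
  }

  if (length(sites) == 0) return(empty)
  arrange(bind_rows(sites), .data$start, .data$are_class)
}

#' Summarize 3'UTRs
#'
#' Per-UTR length, AT content, and ARE class counts from [classify_are()].
#'
#' @param seqs A sequence tibble of 3'UTRs.
#' @param params Parameter list from [are_params()].
#' @return A tibble with one row per UTR: `utr_id`, `length`,
#'   `at_content`, `n_class_I`, `n_class_II`, `n_class_III`.
#' @export
utr_summary <- function(seqs, params = are_params()) {
  stopifnot(is.data.frame(seqs))
  if (nrow(seqs) && any(!nzchar(seqs$seq))) {
    abort("utr_summary() requires non-empty sequences.")
  }
  purrr::map2_dfr(seqs$id, seqs$seq, function(id, s) {
    sites <- classify_are(s, params)
    tibble(
      utr_id = id,
      length = nchar(s),
      at_content = at_content(s),
      n_class_I = sum(sites$are_class == "I"),
      n_class_II = sum(sites$are_class == "II"),
      n_class_III = sum(sites$are_class == "III")
    )
  })
}
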