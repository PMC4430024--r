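#' Tidy a PFM into long format
#'
#' @param x A `crossreg_pfm`.
#' @param ... Unused.
#' @return A tibble with columns `tf`, `position` (1-based motif column),
#'   `base`, `count`, `freq`.
#' @export
tidy.crossreg_pfm <- function(x, ...) {
  w <- ncol(x$counts)
  tibble(
    tf = x$tf_name,
    position = rep(seq_len(w), each = 4),
    base = rep(DNA_BASES, w),
    count = as.vector(x$counts),
    freq = as.vector(sweep(x$counts, 2, colSums(x$counts), "/"))
  )
}

#' @rdname tidy.crossreg_pfm
#' @export
tidy.crossreg_pwm <- function(x, ...) {
  w <- ncol(x$weights)
  tibble(
    tf = x$tf_name,
    position = rep(seq_len(w), each = 4),
    base = rep(DNA_BASES, w),
    weight = as.vector(x$weights)
  )
}

#' One-row motif summaries
#'
#' `glance()` on a PFM reports its width and total information content in
#' bits (sum over positions of `2 + sum(f log2 f)`); on a PWM it reports
#' the attainable score range used by the relative-score threshold.
#'
#' @param x A `crossreg_pfm` or `crossreg_pwm`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.crossreg_pfm <- function(x, ...) {
  f <- sweep(x$counts, 2, colSums(x$counts), "/")
  ic <- sum(apply(f, 2, function(p) {
    2 + sum(ifelse(p > 0, p * log2(p), 0))
  }))
  tibble(tf = x$tf_name, family = x$family, width = ncol(x$counts),
         information_bits = ic)
}

#' @rdname glance.crossreg_pfm
#' @export
glance.crossreg_pwm <- function(x, ...) {
  tibble(tf = x$tf_name, family = x$family, width = ncol(x$weights),
         score_min = x$score_min, score_max = x$score_max,
         pseudocount = x$pseudocount)
}
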