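#' Anderson-Darling normality screen
#'
#' Reports the Anderson-Darling test of normality for a sample, as a
#' screening step alongside distribution comparisons. The result is
#' informational: nothing downstream is gated on it, it simply tells the
#' reader whether parametric summaries of the sample are reasonable.
#'
#' @param x Numeric sample (>= 8 values).
#' @return A list: \code{statistic} (A-squared), \code{p_value},
#'   \code{normal} (p >= 0.05).
#' @export
screen_normality <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 8) stopf("normality screen needs >= 8 finite values")
  ad <- nortest::ad.test(x)
  list(statistic = unname(ad$statistic), p_value = ad$p.value,
       normal = ad$p.value >= 0.05)
}
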