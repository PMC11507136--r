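#' Required sample size for a proportion with finite-population correction
#'
#' Standard conservative sample-size formula for estimating a proportion:
#' `n0 = z^2 * 0.25 / margin^2` with `z` the two-sided normal quantile at the
#' requested confidence level (0.25 is the worst-case `p(1-p)`), shrunk by the
#' finite-population correction `n = n0 / (1 + (n0 - 1) / population)` and
#' rounded up.
#'
#' @param confidence Confidence level in (0, 1), e.g. `0.85`.
#' @param margin Margin of error as a proportion in (0, 1), e.g. `0.10`.
#' @param population Size of the sampling frame (a positive integer).
#' @return Required sample size (integer).
#' @examples
#' sample_size(0.95, 0.05, 1e9)  # 385, the textbook value
#' sample_size(0.85, 0.10, 473)
#' @export
sample_size <- function(confidence, margin, population) {
  if (!is.numeric(confidence) || length(confidence) != 1L ||
      confidence <= 0 || confidence >= 1) {
    abort_param("`confidence` must lie strictly in (0, 1)")
  }
  if (!is.numeric(margin) || length(margin) != 1L || margin <= 0 || margin >= 1) {
    abort_param("`margin` must lie strictly in (0, 1)")
  }
  if (!is.numeric(population) || length(population) != 1L || population < 1) {
    abort_param("`population` must be at least 1")
  }
  z <- stats::qnorm((1 + confidence) / 2)
  n0 <- z^2 * 0.25 / margin^2
  as.integer(ceiling(n0 / (1 + (n0 - 1) / population)))
}
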