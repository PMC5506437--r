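#' Adaptive combined p-value for the two-part test
#'
#' For miRNAs analysed with both parts (the `"combined"` branch), each
#' model's p-value is inverted through the upper tail of a 1-df chi-squared
#' distribution to recover its Wald statistic; the two statistics are summed
#' and referred to a chi-squared distribution with two degrees of freedom.
#' Single-model branches pass the corresponding p-value through unchanged.
#'
#' @param p_binary P-value from the detected/undetected model (model 1), or
#'   `NA` when that branch does not use it.
#' @param p_continuous P-value from the continuous-Cq model (model 2), or
#'   `NA` likewise.
#' @param branch `"binary_only"`, `"continuous_only"`, or `"combined"`
#'   (vectorised; recycled against the p-value vectors).
#' @return Numeric vector of adaptive p-values in (0, 1].
#' @examples
#' adaptive_p(0.05, 0.05, "combined")        # ~0.0215
#' adaptive_p(NA, 0.003, "continuous_only")  # 0.003
#' @export
adaptive_p <- function(p_binary, p_continuous, branch) {
  n <- max(length(p_binary), length(p_continuous), length(branch))
  p_binary <- rep_len(p_binary, n)
  p_continuous <- rep_len(p_continuous, n)
  branch <- rep_len(branch, n)
  check_p <- function(p, who) {
    bad <- !is.na(p) & (p <= 0 | p > 1)
    if (any(bad)) abort(sprintf("%s outside (0, 1]", who))
  }
  check_p(p_binary, "p_binary")
  check_p(p_continuous, "p_continuous")

  out <- rep(NA_real_, n)
  bo <- branch == "binary_only"
  co <- branch == "continuous_only"
  cb <- branch == "combined"
  if (any(bo & is.na(p_binary)) || any(co & is.na(p_continuous)) ||
      any(cb & (is.na(p_binary) | is.na(p_continuous))))
    abort("p-value missing for its branch")
  out[bo] <- p_binary[bo]
  out[co] <- p_continuous[co]
  if (any(cb)) {
    s <- qchisq(p_binary[cb], df = 1, lower.tail = FALSE) +
      qchisq(p_continuous[cb], df = 1, lower.tail = FALSE)
    out[cb] <- pchisq(s, df = 2, lower.tail = FALSE)
  }
  out
}
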