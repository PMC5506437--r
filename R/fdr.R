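#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: with the p-values sorted
#' ascending, `q_(i) = min_{j >= i} p_(j) * m / j`, mapped back to the input
#' order. Delegates to [stats::p.adjust()] with `method = "BH"` after
#' validating the input domain.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, elementwise `>= p` and `<= 1`;
#'   empty input gives an empty result.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0 | p > 1)) abort("p-values must be in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Discovery counts at standard FDR thresholds
#'
#' Counts q-values strictly below each threshold and expresses them as a
#' percentage of the number of tests interrogated, the form used to
#' summarise an FDR screen ("93 (31%) had FDR q value < 0.05").
#'
#' @param q Numeric vector of q-values.
#' @param thresholds Thresholds, descending.
#' @return A tibble: `threshold`, `count`, `percent` (of `length(q)`;
#'   `NaN`-free zero row counts for empty input).
#' @export
threshold_summary <- function(q, thresholds = c(0.10, 0.05, 0.01, 0.001)) {
  if (is.unsorted(rev(thresholds))) abort("thresholds must be descending")
  n <- length(q)
  tibble(
    threshold = thresholds,
    count = vapply(thresholds, function(t) sum(q < t), integer(1)),
    percent = if (n == 0) rep(0, length(thresholds)) else
      vapply(thresholds, function(t) 100 * sum(q < t) / n, numeric(1))
  )
}
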