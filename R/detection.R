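#' Binary non-detection indicator for one miRNA
#'
#' Applies the censoring rule X = 1 if Cq > threshold, 0 otherwise: detected
#' entries at or below the threshold get 0, entries beyond it (including
#' explicit undetected codes, stored as `Inf`) get 1, and not-assayed
#' entries (`NA`) stay `NA` and are excluded from all models. The rule is
#' strict, so a Cq exactly equal to the threshold counts as detected.
#'
#' @param cq Numeric vector of Cq values (`Inf` = undetected, `NA` = not
#'   assayed).
#' @param threshold Detection limit in cycles (> 0).
#' @return Integer vector of 0/1 with `NA` for not-assayed entries.
#' @export
binary_indicator <- function(cq, threshold = 27) {
  if (threshold <= 0) abort("threshold must be > 0")
  if (all(is.na(cq))) abort("all entries are not-assayed; nothing to code")
  as.integer(cq > threshold)
}

#' Detection profile and analysis branch for one miRNA
#'
#' Routes a miRNA through the detection-fraction branching rule. A miRNA is
#' eligible only if it is detected in at least `eligibility_prop` of the
#' *full cohort* (floor computed as `ceiling(eligibility_prop * n_cohort)`).
#' Among eligible miRNAs, detection fraction (detected / assayed) below
#' `lower` routes to the binary model only, at or above `upper` to the
#' continuous model only, and in between to the combined two-part test.
#'
#' @param n_assayed Number of participants assayed (>= 1).
#' @param n_detected Number with detectable expression.
#' @param n_cohort Full cohort size (defaults to `n_assayed`).
#' @param eligibility_prop Minimum detected fraction of the full cohort.
#' @param lower,upper Detection-fraction cutpoints for the branch rule.
#' @return A one-row tibble: `n_assayed`, `n_detected`, `detected_fraction`,
#'   `branch` (one of `"ineligible"`, `"binary_only"`, `"combined"`,
#'   `"continuous_only"`).
#' @export
classify_branch <- function(n_assayed, n_detected, n_cohort = n_assayed,
                            eligibility_prop = 0.05,
                            lower = 0.10, upper = 0.90) {
  if (n_assayed < 1) abort("n_assayed must be >= 1")
  if (n_detected < 0 || n_detected > n_assayed)
    abort("n_detected must be in [0, n_assayed]")
  frac <- n_detected / n_assayed
  floor_count <- ceiling(eligibility_prop * n_cohort)
  branch <- if (n_detected < floor_count) {
    "ineligible"
  } else if (frac < lower) {
    "binary_only"
  } else if (frac >= upper) {
    "continuous_only"
  } else {
    "combined"
  }
  tibble(n_assayed = as.integer(n_assayed),
         n_detected = as.integer(n_detected),
         detected_fraction = frac,
         branch = branch)
}

#' Detection profiles for every miRNA in a Cq matrix
#'
#' @param cq Cq matrix tibble (`participant_id` plus miRNA columns).
#' @param threshold Detection limit in cycles.
#' @inheritParams classify_branch
#' @return A tibble with one row per miRNA (column `mirna` plus the
#'   [classify_branch()] columns), ordered by miRNA name.
#' @export
detection_profiles <- function(cq, threshold = 27, eligibility_prop = 0.05,
                               lower = 0.10, upper = 0.90) {
  mirnas <- sort(setdiff(names(cq), "participant_id"))
  n_cohort <- nrow(cq)
  map_dfr(mirnas, function(m) {
    x <- cq[[m]]
    assayed <- !is.na(x)
    detected <- assayed & x <= threshold
    bind_cols(tibble(mirna = m),
              classify_branch(sum(assayed), sum(detected), n_cohort,
                              eligibility_prop, lower, upper))
  })
}
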