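#' Two-part mixed-model association of every miRNA with grip strength
#'
#' For each miRNA in the Cq matrix (processed in name order), fits model 1
#' (grip on the undetected indicator X, in everyone assayed) and model 2
#' (grip on continuous Cq, in the detected subset), both adjusted for the
#' given covariates with a family random intercept; routes the miRNA
#' through the detection-fraction branching rule ([classify_branch()]); and
#' computes the adaptive p-value ([adaptive_p()]). Benjamini-Hochberg
#' q-values are computed across all eligible miRNAs with a valid adaptive
#' p. The continuous Cq predictor is centred within the detected subset, a
#' pure numerical-stability reparameterisation that leaves its coefficient
#' and p-value unchanged.
#'
#' Model 1 is fitted whenever the indicator varies; model 2 whenever at
#' least `min_fit_n` participants are detected with non-constant Cq. Fits
#' outside a miRNA's branch are reported for inspection but only the
#' branch's fits enter the adaptive p-value. Non-converged governing fits
#' give an `NA` adaptive p and are excluded from the FDR step with a
#' warning.
#'
#' @param cohort Phenotype tibble (one row per participant) containing the
#'   response, covariates, and grouping column.
#' @param cq Cq matrix tibble row-aligned with `cohort` (`Inf` =
#'   undetected, `NA` = not assayed).
#' @param covariates Character vector of covariate column names; `"sex"`
#'   and other character columns are handled as factors by the model
#'   formula.
#' @param threshold Detection limit in cycles.
#' @param eligibility_prop,lower,upper Branch-rule parameters, see
#'   [classify_branch()].
#' @param response Grip-strength column name.
#' @param group Family-identifier column name for the random intercept.
#' @param min_fit_n Minimum detected subset size for attempting model 2.
#' @return A tibble of class `grip_assoc`, one row per miRNA: detection
#'   profile columns, `n_cont`/`beta_cont`/`se_cont`/`p_cont` (model 2),
#'   `n_bin`/`beta_bin`/`se_bin`/`p_bin` (model 1), `adaptive_p`, `q`.
#' @export
associate_all <- function(cohort, cq, covariates,
                          threshold = 27, eligibility_prop = 0.05,
                          lower = 0.10, upper = 0.90,
                          response = "grip_kg", group = "family_id",
                          min_fit_n = 10) {
  if (!identical(cohort$participant_id, cq$participant_id))
    abort("cohort and cq are not row-aligned (participant_id mismatch)")
  missing_cov <- setdiff(c(covariates, response, group), names(cohort))
  if (length(missing_cov))
    abort(paste("columns not in cohort:", paste(missing_cov, collapse = ", ")))

  profiles <- detection_profiles(cq, threshold, eligibility_prop, lower, upper)
  eligible <- profiles$branch != "ineligible"
  if (!any(eligible)) warn("no eligible miRNAs")

  rows <- map_dfr(seq_len(nrow(profiles)), function(i) {
    pr <- profiles[i, ]
    empty_fit <- tibble(beta = NA_real_, se = NA_real_, p = NA_real_,
                        n = NA_integer_, converged = NA)
    if (pr$branch == "ineligible") {
      return(bind_cols(pr, tibble(
        n_cont = NA_integer_, beta_cont = NA_real_, se_cont = NA_real_,
        p_cont = NA_real_, n_bin = NA_integer_, beta_bin = NA_real_,
        se_bin = NA_real_, p_bin = NA_real_,
        conv_cont = NA, conv_bin = NA, adaptive_p = NA_real_)))
    }
    x <- cq[[pr$mirna]]
    assayed <- !is.na(x)

    # model 1: everyone assayed, undetected indicator
    fit_bin <- empty_fit
    d1 <- cohort[assayed, , drop = FALSE]
    d1$mirna_undetected <- binary_indicator(x[assayed], threshold)
    if (length(unique(d1$mirna_undetected)) > 1) {
      f1 <- fit_lmm(d1, response, "mirna_undetected", covariates, group)
      fit_bin <- tibble(beta = f1$beta, se = f1$se, p = f1$p,
                        n = f1$n_used, converged = f1$converged)
    }

    # model 2: detected subset, centred continuous Cq
    fit_cont <- empty_fit
    detected <- assayed & x <= threshold
    if (sum(detected) >= min_fit_n && sd(x[detected]) > 0) {
      d2 <- cohort[detected, , drop = FALSE]
      d2$mirna_cq <- x[detected] - mean(x[detected])
      f2 <- fit_lmm(d2, response, "mirna_cq", covariates, group)
      fit_cont <- tibble(beta = f2$beta, se = f2$se, p = f2$p,
                         n = f2$n_used, converged = f2$converged)
    }

    p_bin_use <- if (isTRUE(fit_bin$converged)) fit_bin$p else NA_real_
    p_cont_use <- if (isTRUE(fit_cont$converged)) fit_cont$p else NA_real_
    ap <- switch(pr$branch,
      binary_only = p_bin_use,
      continuous_only = p_cont_use,
      combined = if (is.na(p_bin_use) || is.na(p_cont_use)) NA_real_ else
        adaptive_p(p_bin_use, p_cont_use, "combined"))

    bind_cols(pr, tibble(
      n_cont = fit_cont$n, beta_cont = fit_cont$beta, se_cont = fit_cont$se,
      p_cont = fit_cont$p, n_bin = fit_bin$n, beta_bin = fit_bin$beta,
      se_bin = fit_bin$se, p_bin = fit_bin$p,
      conv_cont = fit_cont$converged, conv_bin = fit_bin$converged,
      adaptive_p = ap))
  })

  rows$q <- NA_real_
  usable <- !is.na(rows$adaptive_p)
  dropped <- sum(rows$branch != "ineligible" & !usable)
  if (dropped > 0)
    warn(sprintf("%d eligible miRNA(s) had no valid adaptive p (non-converged fits) and were excluded from FDR", dropped))
  if (any(usable)) rows$q[usable] <- bh_fdr(rows$adaptive_p[usable])

  structure(rows,
            class = c("grip_assoc", class(rows)),
            covariates = covariates, threshold = threshold,
            response = response)
}

#' Sex-stratified continuous-model associations
#'
#' For miRNAs detected in at least `upper` (default 90%) of assayed
#' participants in the full cohort, reruns the association separately in
#' women and men with `sex` removed from the covariate list (it is constant
#' within a stratum and would make the design rank-deficient).
#'
#' @inheritParams associate_all
#' @param min_stratum Minimum stratum size; smaller strata are skipped with
#'   a warning.
#' @return A `grip_assoc`-style tibble with a leading `sex` column
#'   (`"F"`/`"M"`), one row per miRNA and sex; empty when no stratum is
#'   large enough.
#' @export
sex_stratified <- function(cohort, cq, covariates, threshold = 27,
                           upper = 0.90, response = "grip_kg",
                           group = "family_id", min_stratum = 50, ...) {
  profiles <- detection_profiles(cq, threshold, upper = upper)
  keep <- profiles$mirna[profiles$detected_fraction >= upper]
  if (length(keep) == 0) {
    warn("no miRNAs detected in at least the required fraction of samples")
    return(tibble())
  }
  covs <- setdiff(covariates, "sex")
  out <- list()
  for (s in c("F", "M")) {
    idx <- cohort$sex == s
    if (sum(idx) < min_stratum) {
      warn(sprintf("sex stratum '%s' has %d participants (< %d); skipped",
                   s, sum(idx), min_stratum))
      next
    }
    res <- associate_all(cohort[idx, , drop = FALSE],
                         cq[idx, c("participant_id", keep), drop = FALSE],
                         covs, threshold = threshold, upper = upper,
                         response = response, group = group, ...)
    out[[s]] <- bind_cols(tibble(sex = s), as_tibble(res))
  }
  bind_rows(out)
}
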