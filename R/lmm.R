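#' Random-intercept linear mixed model with a Wald test for one predictor
#'
#' Fits `response ~ predictor + covariates + (1 | group)` by restricted
#' maximum likelihood via [lme4::lmer()] and returns the focal predictor's
#' estimate with its Wald chi-squared test: `wald_chi2 = (beta / se)^2`, p
#' from the upper tail of a 1-df chi-squared distribution. Rows with
#' missing values in any used column are dropped. A singular random-effect
#' fit (between-group variance estimated at zero) is legitimate — the fixed
#' effects then coincide with ordinary least squares — and is not flagged.
#' A rank-deficient fixed-effect design is an error; a constant response or
#' a non-converging optimisation returns `converged = FALSE` with `NA`
#' estimates.
#'
#' @param data A data frame.
#' @param response Name of the outcome column (kg in the grip analysis).
#' @param predictor Name of the focal predictor column.
#' @param covariates Character vector of adjustment covariate names.
#' @param group Name of the grouping column for the random intercept
#'   (default `"family_id"`); at least 2 distinct groups are required.
#' @return A one-row tibble: `predictor`, `beta`, `se`, `wald_chi2`, `p`,
#'   `n_used`, `n_groups`, `converged`.
#' @export
fit_lmm <- function(data, response, predictor, covariates = character(),
                    group = "family_id") {
  cols <- c(response, predictor, covariates, group)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    abort(paste("columns not in data:", paste(missing_cols, collapse = ", ")))
  df <- data[complete.cases(data[cols]), cols, drop = FALSE]
  if (nrow(df) == 0) abort("no complete rows to fit")
  if (length(unique(df[[group]])) < 2)
    abort("need >= 2 groups for a random intercept")
  if (sd(df[[response]]) == 0) {
    # constant response: no estimable effect; flag instead of fitting
    return(tibble(predictor = predictor, beta = NA_real_, se = NA_real_,
                  wald_chi2 = NA_real_, p = NA_real_,
                  n_used = as.integer(nrow(df)),
                  n_groups = length(unique(df[[group]])), converged = FALSE))
  }
  fixed_fml <- as.formula(paste(
    "~", paste(sprintf("`%s`", c(predictor, covariates)), collapse = " + ")))
  mm <- stats::model.matrix(fixed_fml, df)
  if (qr(mm)$rank < ncol(mm))
    abort("rank-deficient fixed-effect design after masking")

  fml <- as.formula(paste(
    sprintf("`%s` ~", response),
    paste(sprintf("`%s`", c(predictor, covariates)), collapse = " + "),
    sprintf("+ (1 | `%s`)", group)))
  eng <- lmm_engine(df, fml)
  extract_focal(eng, predictor, n_groups = length(unique(df[[group]])))
}

# Fit lmer defensively; returns list(fit=, ok=). calc.derivs = FALSE skips
# the post-hoc Hessian check, which at these problem sizes dominates runtime
# without changing the estimates.
lmm_engine <- function(df, fml) {
  ctrl <- lme4::lmerControl(
    calc.derivs = FALSE,
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))
  fit <- tryCatch(
    withCallingHandlers(
      lme4::lmer(fml, data = df, REML = TRUE, control = ctrl),
      warning = function(w) invokeRestart("muffleWarning"),
      message = function(m) invokeRestart("muffleMessage")),
    error = function(e) e)
  if (inherits(fit, "error")) return(list(fit = NULL, ok = FALSE))
  list(fit = fit, ok = TRUE)
}

extract_focal <- function(eng, predictor, n_groups) {
  bad <- tibble(predictor = predictor, beta = NA_real_, se = NA_real_,
                wald_chi2 = NA_real_, p = NA_real_, n_used = NA_integer_,
                n_groups = as.integer(n_groups), converged = FALSE)
  if (!eng$ok) return(bad)
  fit <- eng$fit
  fe <- lme4::fixef(fit)
  # coefficient name is the backtick-quoted column
  cn <- names(fe)
  idx <- which(cn == predictor | cn == sprintf("`%s`", predictor))
  if (length(idx) != 1) return(bad)
  vc <- as.matrix(vcov(fit))
  beta <- unname(fe[idx])
  se <- sqrt(vc[idx, idx])
  if (!is.finite(se) || se <= 0) return(bad)
  chi2 <- (beta / se)^2
  # keep p strictly positive: a Wald statistic large enough to underflow
  # the chi-squared tail is reported at the smallest representable double
  p <- max(pchisq(chi2, df = 1, lower.tail = FALSE), .Machine$double.xmin)
  tibble(predictor = predictor, beta = beta, se = se, wald_chi2 = chi2,
         p = p,
         n_used = as.integer(stats::nobs(fit)),
         n_groups = as.integer(n_groups), converged = TRUE)
}

# Refit the same mixed-model design with a new response (used for the
# gene-by-gene coexpression scan, where only the outcome changes).
refit_focal <- function(base_fit, new_response, predictor, n_groups) {
  fit <- tryCatch(
    withCallingHandlers(
      lme4::refit(base_fit, newresp = new_response),
      warning = function(w) invokeRestart("muffleWarning"),
      message = function(m) invokeRestart("muffleMessage")),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(extract_focal(list(ok = FALSE), predictor, n_groups))
  extract_focal(list(fit = fit, ok = TRUE), predictor, n_groups)
}
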