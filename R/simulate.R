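#' Simulate participants of a family-clustered cohort
#'
#' Draws covariates for `n_participants` people: sex, age, sex-specific
#' height and BMI, technical assay covariates (RNA concentration, 260/280
#' ratio, RNA quality score), a family assignment, and the family random
#' intercept (drawn once per family and shared by its members). Grip
#' strength is added later by [simulate_grip()], once the Cq matrix exists,
#' so that planted miRNA effects can enter the generating equation.
#'
#' Covariates are drawn independently of one another; the joint
#' distribution (e.g. any height-BMI correlation) is not modelled.
#'
#' @param params A [sim_params()] object.
#' @return A tibble with one row per participant: `participant_id`,
#'   `family_id`, `sex` (`"F"`/`"M"`), `age`, `height_in`, `bmi`,
#'   `rna_conc`, `ratio_260_280`, `rna_quality`, `family_effect`.
#' @export
simulate_participants <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n_participants
  nf <- params$n_families

  sex <- ifelse(runif(n) < params$prop_women, "F", "M")
  age <- rnorm(n, params$age_mean, params$age_sd)
  # sex-specific anthropometrics (means/SDs of a US community sample)
  height_in <- ifelse(sex == "M", rnorm(n, 69.3, 2.67), rnorm(n, 63.9, 2.5))
  bmi <- ifelse(sex == "M", rnorm(n, 29.0, 4.9), rnorm(n, 27.3, 6.1))
  bmi <- pmax(bmi, 14)

  family_id <- sprintf("F%04d", sample.int(nf, n, replace = TRUE))
  fam_levels <- sort(unique(family_id))
  fam_eff <- setNames(rnorm(length(fam_levels), 0, params$family_sd), fam_levels)

  tibble(
    participant_id = sprintf("P%05d", seq_len(n)),
    family_id = family_id,
    sex = sex,
    age = age,
    height_in = height_in,
    bmi = bmi,
    rna_conc = rnorm(n, 100, 20),
    ratio_260_280 = rnorm(n, 1.9, 0.1),
    rna_quality = rnorm(n, 7, 1),
    family_effect = unname(fam_eff[family_id])
  )
}

#' Simulate a censored Cq matrix
#'
#' For each [mirna_spec()] in `params$mirna_specs`, latent Cq values are
#' drawn from a Gaussian whose mean is shifted so that the probability of
#' detection (latent Cq at or below the detection threshold) equals the
#' spec's `target_detection_fraction`. Latent values beyond the threshold
#' are censored and recorded as undetected (`Inf`); a random
#' `1 - assay_fraction` subset of participants is recorded as not assayed
#' (`NA`), a distinct state excluded from all models. When
#' `target_detection_fraction` is exactly 1 the latent values are drawn at
#' `latent_cq_mean` and clamped to the threshold, so no entry is censored.
#'
#' @param cohort Tibble from [simulate_participants()].
#' @param params A [sim_params()] object.
#' @return A tibble `participant_id` plus one numeric column per miRNA
#'   (detected Cq, `Inf` = undetected, `NA` = not assayed), carrying the
#'   uncensored latent matrix in attribute `"latent"` for downstream mRNA
#'   simulation.
#' @export
simulate_cq_matrix <- function(cohort, params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed + 1L)
  n <- nrow(cohort)
  thr <- params$detection_threshold
  specs <- params$mirna_specs
  if (length(specs) == 0) abort("params$mirna_specs is empty")

  latent <- matrix(NA_real_, n, length(specs),
                   dimnames = list(cohort$participant_id,
                                   vapply(specs, `[[`, "", "name")))
  observed <- latent
  for (j in seq_along(specs)) {
    m <- specs[[j]]
    tf <- m$target_detection_fraction
    if (tf > 0 && tf < 1 && m$latent_cq_sd == 0)
      abort(sprintf(
        "miRNA %s: target_detection_fraction %.2f unreachable with latent_cq_sd = 0",
        m$name, tf))
    if (tf >= 1) {
      lat <- rnorm(n, m$latent_cq_mean, m$latent_cq_sd)
      lat <- pmin(lat, thr)            # clamp at the limit: nothing censored
    } else if (tf <= 0) {
      lat <- rep(thr + 6 * max(m$latent_cq_sd, 1), n)  # everything censored
    } else {
      mu <- thr - m$latent_cq_sd * qnorm(tf)
      lat <- rnorm(n, mu, m$latent_cq_sd)
    }
    obs <- ifelse(lat > thr, CQ_UNDETECTED, lat)
    if (m$assay_fraction < 1) {
      not_assayed <- runif(n) >= m$assay_fraction
      obs[not_assayed] <- NA_real_
    }
    latent[, j] <- lat
    observed[, j] <- obs
  }
  out <- bind_cols(tibble(participant_id = cohort$participant_id),
                   as_tibble(observed))
  attr(out, "latent") <- latent
  attr(out, "detection_threshold") <- thr
  out
}

#' Simulate grip strength with planted miRNA effects
#'
#' Grip strength (kg) is the sex-specific intercept plus centred age trends
#' (linear and quadratic, each centred so its expectation is zero), centred
#' height and BMI terms, the planted miRNA effects declared in the
#' [mirna_spec()]s, the family random intercept, and sex-specific residual
#' noise; the result is floored at 0 kg. For each miRNA, the continuous
#' effect multiplies the centred Cq of detected participants and the binary
#' effect is added for undetected participants; not-assayed participants
#' contribute nothing.
#'
#' @param cohort Tibble from [simulate_participants()].
#' @param cq Tibble from [simulate_cq_matrix()], row-aligned with `cohort`.
#' @param params A [sim_params()] object.
#' @return `cohort` with a `grip_kg` column added.
#' @export
simulate_grip <- function(cohort, cq, params) {
  stopifnot(inherits(params, "sim_params"))
  if (!identical(cohort$participant_id, cq$participant_id))
    abort("cohort and cq are not row-aligned (participant_id mismatch)")
  set.seed(params$seed + 2L)
  n <- nrow(cohort)
  men <- cohort$sex == "M"

  a <- cohort$age - params$age_mean
  mu <- ifelse(men, params$grip_intercept_by_sex[1],
                    params$grip_intercept_by_sex[2]) +
    params$grip_age_slope * a +
    params$grip_age_quad * (a^2 - params$age_sd^2) +
    params$height_effect *
      (cohort$height_in - ifelse(men, 69.3, 63.9)) +
    params$bmi_effect * (cohort$bmi - ifelse(men, 29.0, 27.3))

  for (m in params$mirna_specs) {
    if (m$beta_continuous == 0 && m$beta_binary == 0) next
    x <- cq[[m$name]]
    detected <- is.finite(x)
    undetected <- is.infinite(x)
    if (m$beta_continuous != 0 && any(detected)) {
      cc <- x[detected] - mean(x[detected])
      mu[detected] <- mu[detected] + m$beta_continuous * cc
    }
    if (m$beta_binary != 0 && any(undetected))
      mu[undetected] <- mu[undetected] + m$beta_binary
  }

  res_sd <- ifelse(men, params$residual_sd[1], params$residual_sd[2])
  grip <- mu + cohort$family_effect + rnorm(n, 0, res_sd)
  cohort$grip_kg <- pmax(grip, 0)
  cohort
}

#' Simulate an mRNA expression matrix with coexpressed blocks
#'
#' For each block miRNA, `genes_per_mirna` genes are generated as
#' `cor * z + sqrt(1 - cor^2) * noise`, where `z` is the standardized latent
#' Cq of that miRNA, so the population correlation between each block gene
#' and the latent Cq equals `cor`. `n_null_genes` further genes are
#' independent standard Gaussians. Expression is on a unit-variance
#' standardized scale.
#'
#' @param cq Tibble from [simulate_cq_matrix()] (its `"latent"` attribute
#'   supplies the uncensored miRNA values).
#' @param params A [sim_params()] object with non-`NULL` `mrna_specs`.
#' @return A tibble `participant_id` plus one column per gene; block genes
#'   are named `<miRNA>_tg01`, ..., null genes `GENE0001`, ... The full gene
#'   universe is attached as attribute `"universe"` and the per-miRNA block
#'   membership as attribute `"blocks"` (named list).
#' @export
simulate_mrna <- function(cq, params) {
  stopifnot(inherits(params, "sim_params"))
  spec <- params$mrna_specs
  if (is.null(spec)) abort("params$mrna_specs is NULL")
  set.seed(params$seed + 3L)
  latent <- attr(cq, "latent")
  if (is.null(latent)) abort("cq carries no latent matrix; use simulate_cq_matrix()")
  n <- nrow(latent)
  block_mirnas <- spec$block_mirnas %||% colnames(latent)

  blocks <- list()
  mats <- list()
  for (m in block_mirnas) {
    if (!m %in% colnames(latent)) abort(sprintf("unknown block miRNA '%s'", m))
    if (spec$genes_per_mirna == 0) next
    z <- as.numeric(scale(latent[, m]))
    g <- spec$cor * z +
      sqrt(1 - spec$cor^2) * matrix(rnorm(n * spec$genes_per_mirna), n)
    colnames(g) <- sprintf("%s_tg%02d", gsub("[^A-Za-z0-9]", ".", m),
                           seq_len(spec$genes_per_mirna))
    blocks[[m]] <- colnames(g)
    mats[[m]] <- g
  }
  if (spec$n_null_genes > 0) {
    nullg <- matrix(rnorm(n * spec$n_null_genes), n)
    colnames(nullg) <- sprintf("GENE%04d", seq_len(spec$n_null_genes))
    mats[["..null"]] <- nullg
  }
  expr <- do.call(cbind, unname(mats))
  out <- bind_cols(tibble(participant_id = cq$participant_id), as_tibble(expr))
  attr(out, "universe") <- colnames(expr)
  attr(out, "blocks") <- blocks
  out
}

#' Simulate a complete cohort in one call
#'
#' Convenience wrapper running [simulate_participants()],
#' [simulate_cq_matrix()], [simulate_grip()] and (when `mrna_specs` is set)
#' [simulate_mrna()].
#'
#' @param params A [sim_params()] object.
#' @return A list with elements `cohort`, `cq`, and `mrna` (or `NULL`).
#' @export
simulate_cohort <- function(params) {
  cohort <- simulate_participants(params)
  cq <- simulate_cq_matrix(cohort, params)
  cohort <- simulate_grip(cohort, cq, params)
  mrna <- if (!is.null(params$mrna_specs)) simulate_mrna(cq, params) else NULL
  list(cohort = cohort, cq = cq, mrna = mrna)
}
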