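#' Simulation parameters for a synthetic grip-strength cohort
#'
#' Bundles every knob of the synthetic-data generator. Defaults reproduce the
#' marginal structure of a large community-based family cohort: 5668
#' participants, 54% women, mean age 55.7 (SD 13.2) years, sex-specific grip
#' strength of 44.7 kg (men) and 26.5 kg (women) declining with age with a
#' quadratic trend, and whole-blood miRNA Cq values censored at a detection
#' limit of 27 cycles.
#'
#' Grip strength is generated as a sex-specific intercept plus mean-centred
#' age (linear and quadratic), height and BMI terms, any planted miRNA
#' effects, a family random intercept shared by all members of a family, and
#' residual noise. Because every covariate term is centred at its generating
#' mean, `grip_intercept_by_sex` is the expected sex-specific mean grip.
#'
#' @param n_participants Number of participants.
#' @param n_families Number of families; participants are assigned to
#'   families uniformly at random, so family sizes are roughly equal.
#' @param family_sd SD (kg) of the shared family random intercept.
#' @param residual_sd Residual SD (kg); either a single value or a length-2
#'   vector `c(men, women)`. The default is sex-specific so that total grip
#'   SD matches the observed 10.0 kg (men) and 6.3 kg (women) once the
#'   shared age/height/BMI variance components are added.
#' @param prop_women Fraction of women in the cohort.
#' @param age_mean,age_sd Age distribution (years).
#' @param grip_intercept_by_sex Named or ordered pair `c(men, women)` of
#'   expected grip means (kg).
#' @param grip_age_slope Linear age trend, kg per year (negative: decline).
#' @param grip_age_quad Quadratic age trend, kg per year squared.
#' @param height_effect kg per inch of height (centred within sex).
#' @param bmi_effect kg per kg/m^2 of BMI (centred within sex).
#' @param mirna_specs List of [mirna_spec()] objects describing the miRNA
#'   panel to simulate.
#' @param mrna_specs An [mrna_spec()] describing coexpressed mRNA blocks, or
#'   `NULL` for no mRNA matrix.
#' @param detection_threshold Cq detection limit (cycles); latent Cq beyond
#'   it is recorded as undetected.
#' @param seed Integer seed; every generator call derives its randomness
#'   from it, so identical parameters give identical cohorts.
#'
#' @return An object of class `sim_params` (a validated list).
#' @seealso [mirna_spec()], [mrna_spec()], [simulate_cohort()]
#' @export
sim_params <- function(n_participants = 5668,
                       n_families = 1500,
                       family_sd = 2,
                       residual_sd = c(men = 9.0, women = 4.6),
                       prop_women = 0.54,
                       age_mean = 55.7,
                       age_sd = 13.2,
                       grip_intercept_by_sex = c(men = 44.7, women = 26.5),
                       grip_age_slope = -0.25,
                       grip_age_quad = -0.004,
                       height_effect = 0.5,
                       bmi_effect = 0.15,
                       mirna_specs = list(),
                       mrna_specs = NULL,
                       detection_threshold = 27,
                       seed = 1L) {
  if (length(residual_sd) == 1) residual_sd <- c(residual_sd, residual_sd)
  p <- list(
    n_participants = as.integer(n_participants),
    n_families = as.integer(n_families),
    family_sd = family_sd,
    residual_sd = unname(residual_sd),
    prop_women = prop_women,
    age_mean = age_mean, age_sd = age_sd,
    grip_intercept_by_sex = unname(grip_intercept_by_sex),
    grip_age_slope = grip_age_slope,
    grip_age_quad = grip_age_quad,
    height_effect = height_effect,
    bmi_effect = bmi_effect,
    mirna_specs = mirna_specs,
    mrna_specs = mrna_specs,
    detection_threshold = detection_threshold,
    seed = as.integer(seed)
  )
  class(p) <- "sim_params"
  validate_sim_params(p)
}

validate_sim_params <- function(p) {
  if (p$n_participants < 1) abort("n_participants must be >= 1")
  if (p$n_families < 1 || p$n_families > p$n_participants)
    abort("n_families must be in [1, n_participants]")
  if (p$prop_women < 0 || p$prop_women > 1)
    abort("prop_women must be in [0, 1]")
  sds <- c(p$family_sd, p$residual_sd, p$age_sd)
  if (any(sds < 0)) abort("all SDs must be >= 0")
  if (p$detection_threshold <= 0) abort("detection_threshold must be > 0")
  for (m in p$mirna_specs) validate_mirna_spec(m)
  if (!is.null(p$mrna_specs)) validate_mrna_spec(p$mrna_specs)
  p
}

#' Specification of one simulated miRNA
#'
#' Describes the latent Cq distribution, the target detection fraction, the
#' fraction of the cohort in which the assay was run at all, and any planted
#' effect on grip strength.
#'
#' The latent Cq is Gaussian; its mean is location-shifted so that the
#' probability of falling at or below the detection threshold equals
#' `target_detection_fraction` (with `latent_cq_sd` fixed). Planted effects
#' act on the kg scale: `beta_continuous` multiplies the centred Cq of
#' detected participants (so a negative value means higher expression, i.e.
#' lower Cq, goes with stronger grip), and `beta_binary` is added for
#' participants in whom the miRNA is undetected.
#'
#' @param name miRNA identifier.
#' @param target_detection_fraction Expected fraction of assayed
#'   participants with detectable expression, in \[0, 1\].
#' @param latent_cq_mean,latent_cq_sd Latent Gaussian Cq location (cycles;
#'   the mean is only used directly when no censoring shift is needed) and SD.
#' @param beta_continuous Planted kg-per-Cq effect among detected
#'   participants; 0 for a null miRNA.
#' @param beta_binary Planted kg effect of undetected vs detected status;
#'   0 for a null miRNA.
#' @param assay_fraction Fraction of the cohort in which the miRNA was
#'   assayed at all; the remainder is recorded as not assayed.
#'
#' @return An object of class `mirna_spec`.
#' @export
mirna_spec <- function(name,
                       target_detection_fraction = 1,
                       latent_cq_mean = 22,
                       latent_cq_sd = 1.5,
                       beta_continuous = 0,
                       beta_binary = 0,
                       assay_fraction = 1) {
  m <- list(
    name = as.character(name),
    target_detection_fraction = target_detection_fraction,
    latent_cq_mean = latent_cq_mean,
    latent_cq_sd = latent_cq_sd,
    beta_continuous = beta_continuous,
    beta_binary = beta_binary,
    assay_fraction = assay_fraction
  )
  class(m) <- "mirna_spec"
  validate_mirna_spec(m)
}

validate_mirna_spec <- function(m) {
  if (m$target_detection_fraction < 0 || m$target_detection_fraction > 1)
    abort("target_detection_fraction must be in [0, 1]")
  if (m$assay_fraction < 0 || m$assay_fraction > 1)
    abort("assay_fraction must be in [0, 1]")
  if (m$latent_cq_sd < 0) abort("latent_cq_sd must be >= 0")
  m
}

#' A panel of null miRNAs spanning a range of detection fractions
#'
#' Convenience constructor for calibration studies: `n` miRNAs with no
#' planted effect whose target detection fractions are spread evenly over
#' `detection_range`, mimicking a panel in which some miRNAs are near-ubiquitous
#' and others rarely detected.
#'
#' @param n Number of miRNAs.
#' @param detection_range Length-2 range of target detection fractions.
#' @param latent_cq_sd Latent Cq SD shared by the panel.
#' @return A list of [mirna_spec()] objects named `miR-sim-001`, ...
#' @export
null_mirna_panel <- function(n, detection_range = c(0.15, 1), latent_cq_sd = 1.5) {
  fracs <- seq(detection_range[1], detection_range[2], length.out = n)
  lapply(seq_len(n), function(i) {
    mirna_spec(sprintf("miR-sim-%03d", i),
               target_detection_fraction = fracs[i],
               latent_cq_sd = latent_cq_sd)
  })
}

#' Specification of coexpressed mRNA blocks
#'
#' For each miRNA named in `block_mirnas` (default: every simulated miRNA),
#' `genes_per_mirna` genes are generated whose expression correlates with the
#' miRNA's latent Cq at strength `cor`; `n_null_genes` additional genes are
#' independent noise. Gene expression is on an arbitrary standardized scale.
#'
#' @param genes_per_mirna Genes per coexpressed block.
#' @param cor Target correlation between block genes and the latent Cq,
#'   strictly inside (-1, 1).
#' @param n_null_genes Number of independent background genes.
#' @param block_mirnas Character vector of miRNA names receiving a block, or
#'   `NULL` for all.
#' @return An object of class `mrna_spec`.
#' @export
mrna_spec <- function(genes_per_mirna = 10, cor = 0.5, n_null_genes = 100,
                      block_mirnas = NULL) {
  s <- list(genes_per_mirna = as.integer(genes_per_mirna),
            cor = cor,
            n_null_genes = as.integer(n_null_genes),
            block_mirnas = block_mirnas)
  class(s) <- "mrna_spec"
  validate_mrna_spec(s)
}

validate_mrna_spec <- function(s) {
  if (s$cor <= -1 || s$cor >= 1) abort("block correlation must be in (-1, 1)")
  if (s$genes_per_mirna < 0 || s$n_null_genes < 0)
    abort("gene counts must be >= 0")
  s
}
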