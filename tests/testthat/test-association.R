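test_that("fully detected miRNAs use only the continuous model", {
  dat <- small_cohort(mirna_specs = list(mirna_spec("full", 1.0)))
  res <- associate_all(dat$cohort, dat$cq, default_covariates)
  expect_s3_class(res, "grip_assoc")
  expect_equal(res$branch, "continuous_only")
  expect_true(is.na(res$beta_bin))      # indicator constant: no binary fit
  expect_equal(res$adaptive_p, res$p_cont)
  expect_equal(res$q, res$adaptive_p)   # single test: BH leaves p unchanged
})

test_that("eligible miRNAs route and combine; ineligible are carried as NA", {
  dat <- small_cohort(n = 800, n_families = 200, mirna_specs = list(
    mirna_spec("rare", 0.02),       # under the 5% floor
    mirna_spec("low", 0.08),
    mirna_spec("mid", 0.5)))
  res <- suppressWarnings(
    associate_all(dat$cohort, dat$cq, default_covariates))
  expect_equal(res$mirna, c("low", "mid", "rare"))  # name-ordered
  expect_equal(res$branch[res$mirna == "rare"], "ineligible")
  expect_true(is.na(res$adaptive_p[res$mirna == "rare"]))
  expect_equal(res$branch[res$mirna == "low"], "binary_only")
  expect_equal(res$adaptive_p[res$mirna == "low"],
               res$p_bin[res$mirna == "low"])
  mid <- res[res$mirna == "mid", ]
  expect_equal(mid$branch, "combined")
  expect_equal(mid$adaptive_p,
               oracle_adaptive_p(mid$p_bin, mid$p_cont), tolerance = 1e-10)
})

test_that("a planted effect is detected and estimated on the Cq scale", {
  p <- sim_params(n_participants = 3000, n_families = 750,
                  mirna_specs = list(
                    mirna_spec("hit", 0.95, beta_continuous = -0.30,
                               latent_cq_sd = 2),
                    mirna_spec("null", 0.95)),
                  seed = 33)
  dat <- simulate_cohort(p)
  res <- associate_all(dat$cohort, dat$cq, default_covariates)
  hit <- res[res$mirna == "hit", ]
  expect_lt(abs(hit$beta_cont - (-0.30)), 3 * hit$se_cont)
  expect_lt(hit$adaptive_p, 0.05)
})

test_that("results are invariant to participant row order", {
  dat <- small_cohort(n = 500, n_families = 120,
                      mirna_specs = list(mirna_spec("m", 0.6)))
  res1 <- associate_all(dat$cohort, dat$cq, default_covariates)
  set.seed(8)
  ord <- sample(nrow(dat$cohort))
  res2 <- associate_all(dat$cohort[ord, ], dat$cq[ord, ], default_covariates)
  expect_equal(res1$beta_cont, res2$beta_cont, tolerance = 1e-6)
  expect_equal(res1$adaptive_p, res2$adaptive_p, tolerance = 1e-6)
})

test_that("misalignment and missing covariates raise errors", {
  dat <- small_cohort(n = 100, n_families = 30,
                      mirna_specs = list(mirna_spec("m", 0.8)))
  expect_error(associate_all(dat$cohort[-1, ], dat$cq, default_covariates),
               "aligned")
  expect_error(associate_all(dat$cohort, dat$cq, c("sex", "nope")), "nope")
})

test_that("sex-stratified runs drop the sex covariate and recover shared effects", {
  p <- sim_params(n_participants = 2400, n_families = 600,
                  mirna_specs = list(
                    mirna_spec("ubiq", 0.97, beta_continuous = -0.5,
                               latent_cq_sd = 2),
                    mirna_spec("mid", 0.5)),
                  seed = 44)
  dat <- simulate_cohort(p)
  res <- sex_stratified(dat$cohort, dat$cq, default_covariates)
  # only the >= 90% detected miRNA is carried, once per sex
  expect_equal(sort(unique(res$mirna)), "ubiq")
  expect_setequal(res$sex, c("F", "M"))
  # effect planted identically in both sexes: estimates agree within joint CI
  bf <- res$beta_cont[res$sex == "F"]; bm <- res$beta_cont[res$sex == "M"]
  sf <- res$se_cont[res$sex == "F"];  sm <- res$se_cont[res$sex == "M"]
  expect_lt(abs(bf - bm), 1.96 * sqrt(sf^2 + sm^2))
  # one-sex cohort: the other stratum is skipped with a warning
  men <- dat$cohort$sex == "M"
  expect_warning(
    res_m <- sex_stratified(dat$cohort[men, ], dat$cq[men, ],
                            default_covariates),
    "skipped")
  expect_setequal(res_m$sex, "M")
})

test_that("cell-count imputation recovers linear signals and passes measured through", {
  set.seed(55)
  n <- 120; g <- 30
  expr <- matrix(rnorm(n * g), n, dimnames = list(NULL, sprintf("g%02d", 1:g)))
  comp <- expr[, 1:3]
  counts_true <- drop(comp %*% c(2, -1, 0.5)) + 10
  expression <- dplyr::bind_cols(
    tibble::tibble(participant_id = sprintf("P%03d", 1:n)),
    tibble::as_tibble(expr))
  measured <- tibble::tibble(participant_id = sprintf("P%03d", 1:80),
                             wbc = counts_true[1:80])
  out <- impute_cell_counts(expression, measured, max_comp = 6)
  expect_equal(out$wbc[1:80], counts_true[1:80])  # pass-through exact
  held <- counts_true[81:n]
  r2 <- 1 - sum((out$wbc[81:n] - held)^2) / sum((held - mean(held))^2)
  expect_gt(r2, 0.99)                              # noiseless recovery
  # pure-noise counts: predictions no better than the training mean
  measured_noise <- tibble::tibble(participant_id = sprintf("P%03d", 1:80),
                                   wbc = rnorm(80))
  out_n <- impute_cell_counts(expression, measured_noise, max_comp = 6)
  # predictions hug the training mean: less spread than the data, centred on it
  pred <- out_n$wbc[81:n]
  expect_lt(sd(pred), sd(measured_noise$wbc))
  expect_lt(abs(mean(pred) - mean(measured_noise$wbc)), 0.5)
  expect_lte(attr(out_n, "ncomp")[["wbc"]], 3)     # CV picks a small model
  expect_warning(
    impute_cell_counts(expression[1:8, ], measured[1:8, ], folds = 10),
    "folds")
})

test_that("cell-count-adjusted runs reuse the same code path", {
  dat <- small_cohort(n = 500, n_families = 120,
                      mirna_specs = list(mirna_spec("m", 0.6)))
  co <- dat$cohort
  set.seed(6)
  co$wbc <- rnorm(nrow(co), 6, 1)
  res <- associate_all(co, dat$cq, c(default_covariates, "wbc"))
  expect_s3_class(res, "grip_assoc")
  expect_equal(attr(res, "covariates"), c(default_covariates, "wbc"))
  expect_false(is.na(res$adaptive_p))
})
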