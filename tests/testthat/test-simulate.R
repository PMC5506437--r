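test_that("participant covariates match the target marginals", {
  p <- sim_params(mirna_specs = null_mirna_panel(1), seed = 7)
  co <- simulate_participants(p)
  n <- nrow(co)
  expect_equal(n, 5668)
  # 3-SE bands around the generating means
  expect_lt(abs(mean(co$age) - 55.7), 3 * 13.2 / sqrt(n))
  expect_lt(abs(mean(co$sex == "F") - 0.54),
            3 * sqrt(0.54 * 0.46 / n))
  expect_true(all(table(co$family_id) >= 1))
  # family effect is constant within family
  per_fam <- tapply(co$family_effect, co$family_id, function(x) length(unique(x)))
  expect_true(all(per_fam == 1))
})

test_that("degenerate age variance gives constant ages and invalid params error", {
  p <- small_params(age_sd = 0)
  co <- simulate_participants(p)
  expect_true(all(co$age == p$age_mean))
  expect_error(sim_params(prop_women = 1.2), "prop_women")
  expect_error(sim_params(family_sd = -1), "SD")
  expect_error(sim_params(n_participants = 10, n_families = 20), "n_families")
})

test_that("simulation is deterministic under a fixed seed", {
  p <- small_params(mrna_specs = mrna_spec(genes_per_mirna = 3,
                                           n_null_genes = 5))
  d1 <- simulate_cohort(p)
  d2 <- simulate_cohort(p)
  expect_identical(d1$cohort, d2$cohort)
  expect_identical(d1$cq, d2$cq)
  expect_identical(d1$mrna, d2$mrna)
})

test_that("empirical detection fraction converges to its target", {
  p <- sim_params(n_participants = 10000, n_families = 2500,
                  mirna_specs = list(mirna_spec("m50", 0.5),
                                     mirna_spec("m90", 0.9),
                                     mirna_spec("m10", 0.1)),
                  seed = 3)
  co <- simulate_participants(p)
  cq <- simulate_cq_matrix(co, p)
  targets <- c(m50 = 0.5, m90 = 0.9, m10 = 0.1)
  for (nm in names(targets)) {
    tf <- targets[[nm]]
    frac <- mean(is.finite(cq[[nm]]))
    expect_lt(abs(frac - tf), 3 * sqrt(tf * (1 - tf) / 10000))
  }
})

test_that("full detection yields no censored entries; partial assay marks NA", {
  p <- small_params(n = 5668, n_families = 1400, mirna_specs = list(
    mirna_spec("full", 1.0),
    mirna_spec("partial", 0.9, assay_fraction = 0.26)))
  co <- simulate_participants(p)
  cq <- simulate_cq_matrix(co, p)
  expect_false(any(is.infinite(cq$full)))
  expect_false(anyNA(cq$full))
  n_missing <- sum(is.na(cq$partial))
  expected <- 5668 * (1 - 0.26)
  expect_lt(abs(n_missing - expected), 3 * sqrt(5668 * 0.26 * 0.74))
  # unreachable detection fraction with zero latent SD
  bad <- small_params(mirna_specs = list(mirna_spec("b", 0.5, latent_cq_sd = 0)))
  cob <- simulate_participants(bad)
  expect_error(simulate_cq_matrix(cob, bad), "unreachable")
})

test_that("null-effect grip matches sex-specific means and SDs", {
  p <- sim_params(mirna_specs = null_mirna_panel(2), seed = 5)
  dat <- simulate_cohort(p)
  co <- dat$cohort
  m <- co[co$sex == "M", ]; w <- co[co$sex == "F", ]
  expect_lt(abs(mean(m$grip_kg) - 44.7), 3 * sd(m$grip_kg) / sqrt(nrow(m)))
  expect_lt(abs(mean(w$grip_kg) - 26.5), 3 * sd(w$grip_kg) / sqrt(nrow(w)))
  # SD within 15% of 10.0 (men) and 6.3 (women)
  expect_lt(abs(sd(m$grip_kg) - 10.0) / 10.0, 0.15)
  expect_lt(abs(sd(w$grip_kg) - 6.3) / 6.3, 0.15)
})

test_that("noise-free grip equals the deterministic covariate function", {
  p <- small_params(residual_sd = 0, family_sd = 0)
  dat <- simulate_cohort(p)
  co <- dat$cohort
  a <- co$age - p$age_mean
  men <- co$sex == "M"
  mu <- ifelse(men, 44.7, 26.5) +
    p$grip_age_slope * a + p$grip_age_quad * (a^2 - p$age_sd^2) +
    p$height_effect * (co$height_in - ifelse(men, 69.3, 63.9)) +
    p$bmi_effect * (co$bmi - ifelse(men, 29.0, 27.3))
  expect_equal(co$grip_kg, pmax(mu, 0), tolerance = 1e-12)
})

test_that("a planted continuous effect leaves a negative Cq-grip relation", {
  p <- small_params(n = 2000, n_families = 500, mirna_specs = list(
    mirna_spec("hit", 0.95, beta_continuous = -0.5)))
  dat <- simulate_cohort(p)
  det <- is.finite(dat$cq$hit)
  # brute-force check: regression of grip on Cq among detected is negative
  b <- coef(lm(dat$cohort$grip_kg[det] ~ dat$cq$hit[det]))[2]
  expect_lt(b, 0)
})

test_that("mRNA blocks achieve the declared correlation", {
  p <- sim_params(n_participants = 2000, n_families = 500,
                  mirna_specs = list(mirna_spec("m1", 1.0)),
                  mrna_specs = mrna_spec(genes_per_mirna = 10, cor = 0.5,
                                         n_null_genes = 50),
                  seed = 9)
  dat <- simulate_cohort(p)
  latent <- attr(dat$cq, "latent")
  block <- attr(dat$mrna, "blocks")[["m1"]]
  cors <- vapply(block, function(g) cor(dat$mrna[[g]], latent[, "m1"]),
                 numeric(1))
  expect_true(all(cors > 0.44 & cors < 0.56))  # Fisher-z band at n = 2000
  null_cors <- vapply(sprintf("GENE%04d", 1:50),
                      function(g) cor(dat$mrna[[g]], latent[, "m1"]),
                      numeric(1))
  expect_lt(mean(abs(null_cors)), 3 / sqrt(2000) * 2)
  expect_error(mrna_spec(cor = 1), "correlation")
})

test_that("cq matrix TSV round-trips the ND / not-assayed encoding", {
  p <- small_params(n = 80, n_families = 20, mirna_specs = list(
    mirna_spec("a", 0.6), mirna_spec("b", 0.9, assay_fraction = 0.5)))
  co <- simulate_participants(p)
  cq <- simulate_cq_matrix(co, p)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_cq_matrix(cq, tf)
  txt <- readLines(tf)
  expect_true(any(grepl("\tND", txt)))          # undetected written as ND
  back <- read_cq_matrix(tf)
  expect_equal(is.infinite(back$a), is.infinite(cq$a))
  expect_equal(is.na(back$b), is.na(cq$b))
  det <- is.finite(cq$a)
  expect_equal(back$a[det], cq$a[det], tolerance = 1e-8)
})

test_that("geneset fixture plants an enriched set and writes valid GMT", {
  universe <- sprintf("G%04d", 1:1000)
  block <- universe[1:10]
  sets <- make_geneset_fixture(block, n_sets = 5, set_size = 10,
                               universe = universe, seed = 2)
  expect_length(sets, 5)
  expect_gte(length(intersect(sets$planted_block_set, block)), 8)
  tf <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, tf)
  back <- read_gmt(tf)
  expect_equal(back, sets)
  # n_sets = 0 -> empty GMT
  tf0 <- withr::local_tempfile(fileext = ".gmt")
  make_geneset_fixture(block, 0, 10, universe, file = tf0)
  expect_length(read_gmt(tf0), 0)
  expect_error(make_geneset_fixture(block, 1, 2000, universe), "set_size")
  # random sets: expected overlap of a 100-gene list with a 50-gene set = 5
  set.seed(4)
  overlaps <- replicate(200, {
    s <- sample(universe, 50)
    length(intersect(s, universe[1:100]))
  })
  expect_lt(abs(mean(overlaps) - 5), 0.5)
})
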