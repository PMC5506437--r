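coexpr_fixture <- function(n = 1200, cor = 0.5, genes = 8, null_genes = 30,
                           seed = 61) {
  p <- sim_params(n_participants = n, n_families = n %/% 4,
                  mirna_specs = list(mirna_spec("mir1", 1.0),
                                     mirna_spec("mir2", 1.0)),
                  mrna_specs = mrna_spec(genes_per_mirna = genes, cor = cor,
                                         n_null_genes = null_genes,
                                         block_mirnas = "mir1"),
                  seed = seed)
  simulate_cohort(p)
}

test_that("top-k selection orders by q with deterministic tie-breaks", {
  res <- tibble::tibble(
    mirna = c("c", "a", "b", "d"),
    adaptive_p = c(0.001, 0.01, 0.01, 0.5),
    q = c(0.004, 0.02, 0.02, 0.5))
  expect_equal(select_top_mirnas(res, 1), "c")
  expect_equal(select_top_mirnas(res, 3), c("c", "a", "b"))  # name tie-break
  expect_equal(select_top_mirnas(res, 0), character(0))
  expect_warning(out <- select_top_mirnas(res, 10), "available")
  expect_length(out, 4)
})

test_that("negative-direction selection keys on the governing beta sign", {
  res <- tibble::tibble(
    mirna = c("pos_cont", "neg_cont", "pos_bin", "zero", "pos_but_ns"),
    branch = c("combined", "continuous_only", "binary_only",
               "combined", "combined"),
    beta_cont = c(0.3, -0.2, -0.1, 0, 0.4),
    beta_bin = c(0.1, NA, 0.8, 0, 0.2),
    q = c(0.01, 0.01, 0.01, 0.01, 0.4))
  # binary-only miRNAs are governed by the binary beta
  expect_equal(select_negative_direction(res), c("pos_bin", "pos_cont"))
  # beta exactly 0 excluded (strict sign); non-significant excluded
  none <- res[res$mirna == "zero", ]
  expect_length(select_negative_direction(none), 0)
})

test_that("a planted coexpression block is recovered and nulls are controlled", {
  dat <- coexpr_fixture()
  pairs <- coexpress_pairs(dat$cohort, dat$cq, dat$mrna, c("mir1", "mir2"),
                           default_covariates)
  expect_s3_class(pairs, "coexpr_pairs")
  expect_equal(nrow(pairs), 2 * (8 + 30))
  expect_true(all(pairs$q >= pairs$p))
  planted <- pairs[pairs$mirna == "mir1" & grepl("_tg", pairs$gene), ]
  expect_gte(sum(planted$significant), 7)
  # mir2 has no block: its hits among null genes stay near the FDR level
  null_pairs <- pairs[pairs$mirna == "mir2", ]
  expect_lte(mean(null_pairs$significant), 0.05 + 3 * sqrt(0.05 * 0.95 / 38))
  # block genes correlate with Cq positively (gene tracks latent Cq)
  expect_true(all(planted$beta > 0))
})

test_that("perfect coexpression gives beta 1 and a vanishing p", {
  dat <- coexpr_fixture(n = 300, null_genes = 2)
  mrna <- dat$mrna
  clone_tbl <- tibble::tibble(participant_id = mrna$participant_id,
                              clone = dat$cq$mir1 - mean(dat$cq$mir1))
  pairs <- coexpress_pairs(dat$cohort, dat$cq, clone_tbl,
                           "mir1", default_covariates)
  expect_equal(pairs$beta, 1, tolerance = 1e-6)
  expect_lt(pairs$p, 1e-12)
})

test_that("refit-based scan equals gene-by-gene full fits", {
  dat <- coexpr_fixture(n = 400, genes = 3, null_genes = 3)
  pairs <- coexpress_pairs(dat$cohort, dat$cq, dat$mrna, "mir1",
                           default_covariates)
  # brute force: independent full fit per gene
  x <- dat$cq$mir1
  d <- dat$cohort
  d$mirna_cq <- x - mean(x)
  for (i in seq_len(nrow(pairs))) {
    d$yy <- dat$mrna[[pairs$gene[i]]]
    f <- fit_lmm(d, "yy", "mirna_cq", default_covariates)
    expect_equal(pairs$beta[i], f$beta, tolerance = 1e-6)
    expect_equal(pairs$p[i], f$p, tolerance = 1e-4)
  }
})

test_that("prediction and signature overlaps count what they should", {
  pairs <- tibble::tibble(
    mirna = c("m1", "m1", "m2", "m2"),
    gene = c("g1", "g2", "g1", "g3"),
    significant = c(TRUE, TRUE, TRUE, FALSE))
  # empty prediction table
  none <- targetscan_overlap(pairs, tibble::tibble(mirna = character(),
                                                   gene = character()))
  expect_equal(attr(none, "n_predicted_significant"), 0L)
  # prediction table equal to the significant pairs
  preds <- pairs[pairs$significant, c("mirna", "gene")]
  all_hit <- targetscan_overlap(pairs, preds)
  expect_equal(attr(all_hit, "n_predicted_significant"), 3L)
  expect_equal(all_hit$predicted_target, c(TRUE, TRUE, TRUE, FALSE))
  # signature overlap: pairs and unique genes
  ov <- signature_overlap(pairs, c("g1", "g9"))
  expect_equal(ov$n_pairs, 2)   # m1-g1 and m2-g1 (significant only)
  expect_equal(ov$n_genes, 1)
  expect_lte(ov$n_genes, ov$n_pairs)
  disjoint <- signature_overlap(pairs, "g999")
  expect_equal(c(disjoint$n_pairs, disjoint$n_genes), c(0, 0))
  expect_error(signature_overlap(pairs, character(0)), "empty")
})
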