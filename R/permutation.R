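#' Permute the clinical block of a cohort
#'
#' Separates the clinical data (grip strength, covariates, and the family
#' identifier, which travels with the phenotype so the random-effect
#' grouping stays attached to it) from the miRNA data by re-ordering the
#' whole clinical block with one shared random permutation while the
#' participant row order — and hence the link to the Cq matrix — stays
#' fixed. Within-block relationships (e.g. grip vs age) are preserved
#' exactly; every clinical-miRNA link is broken.
#'
#' @param cohort Phenotype tibble.
#' @param seed Optional integer seed for the permutation.
#' @param clinical_cols Columns to permute as one block; default all except
#'   `participant_id`.
#' @return `cohort` with the clinical block re-ordered.
#' @export
permute_clinical <- function(cohort, seed = NULL, clinical_cols = NULL) {
  if (nrow(cohort) == 0) abort("cohort is empty")
  if (!is.null(seed)) set.seed(seed)
  cols <- clinical_cols %||% setdiff(names(cohort), "participant_id")
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols))
    abort(paste("permuted columns not in cohort:",
                paste(missing_cols, collapse = ", ")))
  perm <- sample.int(nrow(cohort))
  cohort[cols] <- cohort[perm, cols]
  cohort
}

#' Permutation calibration of the adaptive test's type-I error
#'
#' Re-runs the full two-part association on `n_replicates` copies of the
#' cohort whose clinical block has been randomly re-ordered (see
#' [permute_clinical()]), pooling the adaptive p-values across replicates.
#' Because the permutation severs every miRNA-phenotype link, the pooled
#' p-values should be Uniform(0, 1) if the adaptive test holds its nominal
#' size, regardless of any planted effects in the original cohort. The
#' report gives the pooled rejection fraction at each `alpha` and a
#' Kolmogorov-Smirnov test against uniformity. Replicates whose association
#' run fails are skipped with a warning; more than 10% failures is an
#' error.
#'
#' @inheritParams associate_all
#' @param n_replicates Number of permutation replicates (default 100).
#' @param seed Integer seed; replicate r permutes with `seed + r`.
#' @param alpha Nominal levels for the pooled rejection fractions.
#' @param ... Passed to [associate_all()].
#' @return An object of class `perm_calibration`: a list with `replicates`
#'   (per-replicate tibble), `pooled_p` (all adaptive p-values),
#'   `type1` (tibble of alpha / empirical fraction), `ks` (statistic and
#'   p-value), `n_replicates`, `seed`. `tidy()` returns the per-replicate
#'   tibble, `glance()` the pooled one-row summary, and `autoplot()` a
#'   histogram of pooled p-values against the uniform reference.
#' @export
permutation_calibration <- function(cohort, cq, covariates,
                                    n_replicates = 100, seed = 1L,
                                    alpha = c(0.05, 0.01), ...) {
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  reps <- list()
  pooled <- list()
  failures <- 0L
  for (r in seq_len(n_replicates)) {
    res <- tryCatch(
      suppressWarnings({
        perm <- permute_clinical(cohort, seed = seed + r)
        associate_all(perm, cq, covariates, ...)
      }),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1L
      warn(sprintf("replicate %d failed: %s", r, conditionMessage(res)))
      next
    }
    p <- res$adaptive_p[!is.na(res$adaptive_p)]
    pooled[[r]] <- p
    reps[[r]] <- tibble(
      replicate = r, n_tests = length(p),
      frac_lt_05 = mean(p < 0.05), frac_lt_01 = mean(p < 0.01),
      min_p = suppressWarnings(min(p)))
  }
  if (failures > 0.10 * n_replicates)
    abort(sprintf("%d of %d permutation replicates failed", failures,
                  n_replicates))
  pooled_p <- unlist(pooled, use.names = FALSE)
  ks <- suppressWarnings(ks.test(pooled_p, "punif"))
  out <- list(
    replicates = bind_rows(reps),
    pooled_p = pooled_p,
    type1 = tibble(alpha = alpha,
                   empirical = vapply(alpha, function(a) mean(pooled_p < a),
                                      numeric(1))),
    ks = list(statistic = unname(ks$statistic), p.value = ks$p.value),
    n_replicates = n_replicates, n_failed = failures, seed = seed)
  class(out) <- "perm_calibration"
  out
}

#' @export
print.perm_calibration <- function(x, ...) {
  cat("Permutation calibration:", x$n_replicates, "replicates,",
      length(x$pooled_p), "pooled adaptive p-values\n")
  for (i in seq_len(nrow(x$type1)))
    cat(sprintf("  fraction p < %.2f: %.4f\n",
                x$type1$alpha[i], x$type1$empirical[i]))
  cat(sprintf("  KS vs Uniform(0,1): D = %.4f, p = %.3g\n",
              x$ks$statistic, x$ks$p.value))
  invisible(x)
}

#' @rdname permutation_calibration
#' @param x A `perm_calibration` object.
#' @method tidy perm_calibration
#' @export
tidy.perm_calibration <- function(x, ...) x$replicates

#' @rdname permutation_calibration
#' @method glance perm_calibration
#' @export
glance.perm_calibration <- function(x, ...) {
  tibble(n_replicates = x$n_replicates, n_failed = x$n_failed,
         n_pooled = length(x$pooled_p),
         type1_05 = x$type1$empirical[match(0.05, x$type1$alpha)],
         type1_01 = x$type1$empirical[match(0.01, x$type1$alpha)],
         ks_statistic = x$ks$statistic, ks_p = x$ks$p.value)
}

#' @rdname permutation_calibration
#' @param object A `perm_calibration` object.
#' @method autoplot perm_calibration
#' @export
autoplot.perm_calibration <- function(object, ...) {
  df <- tibble(p = object$pooled_p)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            breaks = seq(0, 1, 0.05), fill = "grey70",
                            colour = "white") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "adaptive p-value (permuted replicates)",
                  y = "density",
                  title = "Permutation null of the adaptive test") +
    ggplot2::theme_minimal()
}
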