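#' Select the top-k miRNAs from an association result
#'
#' Orders by FDR q (ascending), breaking ties by adaptive p and then by
#' miRNA name, and returns the first `k` names. miRNAs without a q-value
#' (ineligible or non-converged) are excluded.
#'
#' @param results A `grip_assoc` tibble from [associate_all()].
#' @param k Number of miRNAs to select (default 15).
#' @return Character vector of miRNA names (length `min(k, available)`;
#'   shorter with a warning when fewer are available).
#' @export
select_top_mirnas <- function(results, k = 15) {
  avail <- results |>
    filter(!is.na(.data$q)) |>
    arrange(.data$q, .data$adaptive_p, .data$mirna)
  if (k > nrow(avail))
    warn(sprintf("requested %d miRNAs but only %d available", k, nrow(avail)))
  head(avail$mirna, k)
}

#' miRNAs whose expression is negatively associated with grip strength
#'
#' Among significant results (q strictly below `q_cutoff`), returns miRNAs
#' whose governing beta is strictly positive. Because higher Cq means lower
#' expression, a positive Cq coefficient means expression is negatively
#' associated with grip. The governing beta is the continuous-model
#' coefficient except on the binary-only branch, where it is the binary
#' coefficient.
#'
#' @param results A `grip_assoc` tibble.
#' @param q_cutoff FDR threshold (default 0.05).
#' @return Character vector of miRNA names (possibly empty), name-sorted.
#' @export
select_negative_direction <- function(results, q_cutoff = 0.05) {
  governing <- ifelse(results$branch == "binary_only",
                      results$beta_bin, results$beta_cont)
  hit <- !is.na(results$q) & results$q < q_cutoff &
    !is.na(governing) & governing > 0
  sort(results$mirna[hit])
}

#' Pairwise miRNA-mRNA coexpression with family random intercepts
#'
#' For each selected miRNA and every gene on the expression matrix, fits a
#' linear mixed model of gene expression on the miRNA's centred Cq
#' (detected subset only, where Cq is quantitative) with the given
#' covariates and a family random intercept; p-values come from the 1-df
#' Wald test and q-values from Benjamini-Hochberg across all pairs of the
#' run. The fixed design is identical for every gene within a miRNA, so
#' after the first gene the model is refitted to each new response rather
#' than rebuilt, which is substantially faster and numerically identical.
#'
#' @param cohort Phenotype tibble (covariates and family id), row-aligned
#'   with `cq` and `mrna`.
#' @param cq Cq matrix tibble.
#' @param mrna Expression tibble (`participant_id` plus gene columns).
#' @param mirnas Character vector of miRNA names to scan.
#' @param covariates Covariate column names in `cohort`.
#' @param threshold Detection limit in cycles.
#' @param group Family-identifier column.
#' @param q_cutoff FDR cutoff for the `significant` flag.
#' @param min_fit_n Minimum detected subset size per miRNA.
#' @return A tibble of class `coexpr_pairs`: `mirna`, `gene`, `n`, `beta`,
#'   `se`, `p`, `q`, `significant`. Zero-variance genes are skipped with a
#'   message.
#' @export
coexpress_pairs <- function(cohort, cq, mrna, mirnas, covariates,
                            threshold = 27, group = "family_id",
                            q_cutoff = 0.05, min_fit_n = 10) {
  if (!identical(cohort$participant_id, cq$participant_id) ||
      !identical(cohort$participant_id, mrna$participant_id))
    abort("cohort, cq and mrna are not row-aligned")
  genes <- setdiff(names(mrna), "participant_id")
  rows <- list()
  skipped <- 0L
  for (m in mirnas) {
    if (!m %in% names(cq)) abort(sprintf("miRNA '%s' not in cq matrix", m))
    x <- cq[[m]]
    detected <- !is.na(x) & x <= threshold
    if (sum(detected) < min_fit_n) {
      warn(sprintf("miRNA %s: only %d detected samples; skipped", m,
                   sum(detected)))
      next
    }
    d <- cohort[detected, c(covariates, group), drop = FALSE]
    d$mirna_cq <- x[detected] - mean(x[detected])
    keep <- complete.cases(d)
    d <- d[keep, , drop = FALSE]
    expr <- mrna[detected, genes, drop = FALSE][keep, , drop = FALSE]
    n_groups <- length(unique(d[[group]]))

    base_fit <- NULL
    for (g in genes) {
      y <- expr[[g]]
      if (anyNA(y) || sd(y) == 0) {
        skipped <- skipped + 1L
        next
      }
      if (is.null(base_fit)) {
        d$expr_y <- y
        f <- fit_lmm(d, "expr_y", "mirna_cq", covariates, group)
        if (isTRUE(f$converged)) {
          fml <- as.formula(paste(
            "expr_y ~",
            paste(sprintf("`%s`", c("mirna_cq", covariates)),
                  collapse = " + "),
            sprintf("+ (1 | `%s`)", group)))
          eng <- lmm_engine(d, fml)
          if (eng$ok) base_fit <- eng$fit
        }
      } else {
        f <- refit_focal(base_fit, y, "mirna_cq", n_groups)
      }
      rows[[length(rows) + 1L]] <- tibble(
        mirna = m, gene = g, n = f$n_used,
        beta = f$beta, se = f$se, p = f$p, converged = f$converged)
    }
  }
  if (skipped > 0) message(skipped, " zero-variance or incomplete gene(s) skipped")
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    warn("no coexpression pairs could be fitted")
    return(out)
  }
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bh_fdr(out$p[ok])
  out$significant <- !is.na(out$q) & out$q < q_cutoff
  out <- select(out, -"converged")
  structure(out, class = c("coexpr_pairs", class(out)))
}

#' Flag coexpression pairs predicted as miRNA targets
#'
#' Marks each pair whose (miRNA, gene) combination appears in a target
#' prediction table and reports the number of *significant* pairs that are
#' predicted targets (attached as attribute `"n_predicted_significant"`).
#'
#' @param pairs A `coexpr_pairs` tibble.
#' @param predictions Tibble with columns `mirna` and `gene` (e.g. from
#'   [read_predictions()]).
#' @return `pairs` with a logical `predicted_target` column.
#' @export
targetscan_overlap <- function(pairs, predictions) {
  key <- paste(predictions$mirna, predictions$gene, sep = "\r")
  pairs$predicted_target <- paste(pairs$mirna, pairs$gene, sep = "\r") %in% key
  attr(pairs, "n_predicted_significant") <-
    sum(pairs$predicted_target & pairs$significant)
  pairs
}

#' Overlap of coexpression pairs with a gene signature
#'
#' Restricts (by default) to significant pairs and returns those whose gene
#' belongs to the signature, together with the pair count and the number of
#' unique signature genes involved.
#'
#' @param pairs A `coexpr_pairs` tibble.
#' @param signature Character vector of signature genes (non-empty).
#' @param significant_only Restrict to pairs flagged significant (default
#'   `TRUE`; ignored when `pairs` has no `significant` column).
#' @return A list: `pairs` (the overlapping rows), `n_pairs`, `n_genes`.
#' @export
signature_overlap <- function(pairs, signature, significant_only = TRUE) {
  if (length(signature) == 0) abort("signature is empty")
  df <- pairs
  if (significant_only && "significant" %in% names(df))
    df <- df[df$significant, , drop = FALSE]
  hit <- df[df$gene %in% signature, , drop = FALSE]
  list(pairs = hit, n_pairs = nrow(hit),
       n_genes = length(unique(hit$gene)))
}
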