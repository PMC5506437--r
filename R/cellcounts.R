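#' Impute blood cell counts from gene expression by partial least squares
#'
#' Cell counts measured in only part of a cohort are completed for the rest
#' by partial-least-squares regression of each count variable on the
#' expression matrix (via [mixOmics::pls()], regression mode). The number
#' of latent components is chosen per variable to minimise k-fold
#' cross-validated RMSE on the measured subset; participants with measured
#' values keep them unchanged, the rest receive predictions from the model
#' refitted on the full measured subset at the selected component count.
#'
#' @param expression Tibble `participant_id` plus gene columns, covering
#'   every participant to be completed.
#' @param measured Tibble `participant_id` plus cell-count columns for the
#'   measured subset (all ids must appear in `expression`).
#' @param max_comp Maximum number of PLS components to consider.
#' @param folds Cross-validation folds (default 10); reduced with a warning
#'   when the measured subset is smaller than the fold count.
#' @param seed Integer seed for the fold assignment.
#' @return A tibble `participant_id` plus the cell-count columns for every
#'   participant in `expression`, with a logical `imputed` column; the
#'   selected component count per variable is attached as attribute
#'   `"ncomp"`.
#' @export
impute_cell_counts <- function(expression, measured, max_comp = 10,
                               folds = 10, seed = 1L) {
  if (nrow(measured) == 0) abort("measured subset is empty")
  if (!all(measured$participant_id %in% expression$participant_id))
    abort("expression must cover all measured participants")
  count_cols <- setdiff(names(measured), "participant_id")
  if (length(count_cols) == 0) abort("measured has no cell-count columns")

  X <- as.matrix(expression[setdiff(names(expression), "participant_id")])
  rownames(X) <- expression$participant_id
  Xtr <- X[measured$participant_id, , drop = FALSE]
  n_meas <- nrow(Xtr)
  if (n_meas < folds) {
    warn(sprintf("only %d measured samples; reducing folds from %d to %d",
                 n_meas, folds, max(2, n_meas)))
    folds <- max(2, min(folds, n_meas))
  }
  max_comp <- min(max_comp, ncol(X), n_meas - ceiling(n_meas / folds) - 1)
  if (max_comp < 1) abort("too few measured samples for PLS")

  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n_meas))
  unmeasured_ids <- setdiff(expression$participant_id,
                            measured$participant_id)
  out <- tibble(participant_id = expression$participant_id)
  ncomp_sel <- integer(0)

  for (v in count_cols) {
    y <- measured[[v]]
    sse <- numeric(max_comp)
    for (f in seq_len(folds)) {
      hold <- fold_id == f
      fit <- mixOmics::pls(Xtr[!hold, , drop = FALSE], y[!hold],
                           ncomp = max_comp, mode = "regression")
      pr <- predict(fit, Xtr[hold, , drop = FALSE])$predict[, 1, ]
      pr <- matrix(pr, nrow = sum(hold))
      sse <- sse + colSums((pr - y[hold])^2)
    }
    best <- which.min(sse)
    ncomp_sel[v] <- best
    fit_full <- mixOmics::pls(Xtr, y, ncomp = best, mode = "regression")
    filled <- setNames(rep(NA_real_, nrow(expression)),
                       expression$participant_id)
    filled[measured$participant_id] <- y
    if (length(unmeasured_ids)) {
      pr <- predict(fit_full,
                    X[unmeasured_ids, , drop = FALSE])$predict[, 1, best]
      filled[unmeasured_ids] <- pr
    }
    out[[v]] <- unname(filled)
  }
  out$imputed <- !(out$participant_id %in% measured$participant_id)
  attr(out, "ncomp") <- ncomp_sel
  out
}
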