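#' Plot an association result
#'
#' Volcano-style display of the per-miRNA two-part results: the governing
#' effect estimate (continuous-model beta except on the binary-only branch)
#' against -log10 adaptive p, coloured by branch. Because higher Cq means
#' lower expression, points to the left (negative beta) are miRNAs whose
#' expression is positively associated with grip strength.
#'
#' @param object A `grip_assoc` tibble from [associate_all()].
#' @param q_line Draw a dashed line at the largest adaptive p with
#'   q below this FDR level (default 0.05; `NULL` to omit).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot grip_assoc
#' @export
autoplot.grip_assoc <- function(object, q_line = 0.05, ...) {
  df <- as_tibble(object) |>
    filter(!is.na(.data$adaptive_p)) |>
    mutate(beta = ifelse(.data$branch == "binary_only",
                         .data$beta_bin, .data$beta_cont))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$beta,
                                         y = -log10(.data$adaptive_p),
                                         colour = .data$branch)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::labs(x = "effect on grip strength (kg per unit predictor)",
                  y = "-log10 adaptive p", colour = "branch",
                  title = "Two-part miRNA associations with grip strength") +
    ggplot2::theme_minimal()
  if (!is.null(q_line) && any(df$q < q_line, na.rm = TRUE)) {
    cut_p <- max(df$adaptive_p[!is.na(df$q) & df$q < q_line])
    gg <- gg + ggplot2::geom_hline(yintercept = -log10(cut_p), linetype = 2)
  }
  gg
}
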