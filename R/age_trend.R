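#' Sex-specific quadratic age trend of grip strength
#'
#' Per sex, fits ordinary least squares of grip strength on age and age
#' squared, and computes mean grip with standard errors in fixed-width age
#' bins for descriptive plotting. A sex stratum with fewer than 3 distinct
#' ages cannot identify the quadratic and is skipped with a warning.
#'
#' @param cohort Phenotype tibble with `sex`, `age`, and `grip_kg`.
#' @param bin_width Age bin width in years (default 5).
#' @return An object of class `age_trend`: list with `coefs` (tibble `sex`,
#'   `term`, `estimate`, `se`) and `bins` (tibble `sex`, `age_mid`,
#'   `mean_grip`, `se`, `n`). `tidy()` returns `coefs`; `autoplot()` draws
#'   binned means with the fitted quadratic curves.
#' @export
fit_age_trend <- function(cohort, bin_width = 5) {
  stopifnot(all(c("sex", "age", "grip_kg") %in% names(cohort)))
  edges <- seq(floor(min(cohort$age) / bin_width) * bin_width,
               ceiling(max(cohort$age) / bin_width) * bin_width,
               by = bin_width)
  coefs <- list()
  bins <- list()
  for (s in sort(unique(cohort$sex))) {
    d <- cohort[cohort$sex == s, ]
    if (length(unique(d$age)) < 3) {
      warn(sprintf("sex '%s': fewer than 3 distinct ages; quadratic skipped", s))
    } else {
      fit <- lm(grip_kg ~ age + I(age^2), data = d)
      sm <- summary(fit)$coefficients
      coefs[[s]] <- tibble(sex = s,
                           term = c("(Intercept)", "age", "age^2"),
                           estimate = unname(sm[, 1]),
                           se = unname(sm[, 2]))
    }
    cut_idx <- findInterval(d$age, edges, rightmost.closed = TRUE)
    bins[[s]] <- d |>
      mutate(age_mid = edges[cut_idx] + bin_width / 2) |>
      group_by(.data$age_mid) |>
      summarise(mean_grip = mean(.data$grip_kg),
                se = sd(.data$grip_kg) / sqrt(dplyr::n()),
                n = dplyr::n(), .groups = "drop") |>
      mutate(sex = s, .before = 1)
  }
  out <- list(coefs = bind_rows(coefs), bins = bind_rows(bins))
  class(out) <- "age_trend"
  out
}

#' @export
print.age_trend <- function(x, ...) {
  cat("Quadratic age trend of grip strength by sex\n")
  print(x$coefs)
  invisible(x)
}

#' @rdname fit_age_trend
#' @param x,object An `age_trend` object.
#' @param ... Unused.
#' @method tidy age_trend
#' @export
tidy.age_trend <- function(x, ...) x$coefs

#' @rdname fit_age_trend
#' @method glance age_trend
#' @export
glance.age_trend <- function(x, ...) {
  x$coefs |>
    filter(.data$term == "age") |>
    select(sex = "sex", age_slope = "estimate", age_slope_se = "se")
}

#' @rdname fit_age_trend
#' @method autoplot age_trend
#' @export
autoplot.age_trend <- function(object, ...) {
  curves <- object$coefs |>
    tidyr::pivot_wider(names_from = "term", values_from = c("estimate", "se"))
  grid <- bind_rows(lapply(split(object$bins, object$bins$sex), function(b) {
    tibble(sex = b$sex[1],
           age = seq(min(b$age_mid), max(b$age_mid), length.out = 100))
  }))
  grid <- left_join(grid, curves, by = "sex") |>
    mutate(grip = .data$`estimate_(Intercept)` +
             .data$estimate_age * .data$age +
             .data$`estimate_age^2` * .data$age^2)
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = .data$age_mid, y = .data$mean_grip,
                               colour = .data$sex)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_grip - .data$se,
                                          ymax = .data$mean_grip + .data$se)) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$age, y = .data$grip),
                       linetype = 2) +
    ggplot2::labs(x = "age (years)", y = "grip strength (kg)",
                  colour = "sex",
                  title = "Grip strength by age and sex") +
    ggplot2::theme_minimal()
}
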