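## broom-style tidiers and ggplot2 autoplot methods.

#' Tidy a single-variable targeted fit
#'
#' @param x A `tmle_fit` from [tmle_single()].
#' @param ... Unused.
#' @return One-row tibble: `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
tidy.tmle_fit <- function(x, ...) {
  tibble::tibble(term = x$id, estimate = x$beta_star, std.error = x$sigma,
                 statistic = x$t_stat, p.value = x$p_value)
}

#' Fit-level summary of a targeted fit
#'
#' @param x A `tmle_fit`.
#' @param ... Unused.
#' @return One-row tibble: initial estimate, fluctuation coefficient,
#'   confounder count, cutoff, sample size.
#' @export
glance.tmle_fit <- function(x, ...) {
  tibble::tibble(beta0 = x$beta0, epsilon = x$epsilon,
                 n_confounders = x$n_confounders, delta_used = x$delta_used,
                 n = x$n)
}

#' Tidy a benchmark report
#'
#' @param x A `vim_benchmark`.
#' @param ... Unused.
#' @return The replicate-averaged summary tibble (one row per design and
#'   downstream method).
#' @export
tidy.vim_benchmark <- function(x, ...) x$summary

#' One-line summary of a benchmark report
#'
#' @param x A `vim_benchmark`.
#' @param ... Unused.
#' @return One-row tibble with grand means of the risk-reduction and recovery
#'   ratios across designs.
#' @export
glance.vim_benchmark <- function(x, ...) {
  tibble::tibble(
    n_designs = length(unique(x$replicates$design)),
    n_rows = nrow(x$replicates),
    rr_a = mean(x$replicates$rr_a, na.rm = TRUE),
    rr_b = mean(x$replicates$rr_b, na.rm = TRUE),
    r_a = mean(x$replicates$r_a, na.rm = TRUE),
    r_w = mean(x$replicates$r_w, na.rm = TRUE))
}

#' Rank plot of a variable-importance table
#'
#' Variables by rank against `-log10(p)`, causal truth-agnostic; selected
#' variables are highlighted.
#'
#' @param object A `vim_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vim_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank,
                                   y = -log10(pmax(.data$p, 1e-300)),
                                   colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "rank", y = expression(-log[10](p)),
                  colour = "selected") +
    ggplot2::theme_minimal()
}

#' Risk-reduction plot of a benchmark report
#'
#' Mean proportional risk reduction of the targeted ranking over the
#' univariate baseline, by within-cluster correlation, faceted by the number
#' of non-causal variables; matched ("a") and cross-examination ("b") test
#' sets side by side.
#'
#' @param object A `vim_benchmark`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vim_benchmark <- function(object, ...) {
  df <- object$summary |>
    tidyr_longer_rr()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rho, y = .data$rr,
                                   colour = .data$test_set,
                                   linetype = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~.data$m_w, labeller = ggplot2::label_both) +
    ggplot2::labs(x = expression(rho), y = "proportional risk reduction",
                  colour = "test set") +
    ggplot2::theme_minimal()
}

## minimal pivot (avoids a tidyr dependency for one reshape)
tidyr_longer_rr <- function(summary) {
  a <- dplyr::transmute(summary, .data$rho, .data$m_w, .data$method,
                        test_set = "a", rr = .data$rr_a_mean)
  b <- dplyr::transmute(summary, .data$rho, .data$m_w, .data$method,
                        test_set = "b", rr = .data$rr_b_mean)
  dplyr::bind_rows(a, b)
}

#' Risk-versus-threshold curve plot
#'
#' @param curves Named list of tibbles from [risk_curve()] (names label the
#'   ranking methods), or a single tibble.
#' @return A ggplot object.
#' @export
plot_risk_curve <- function(curves) {
  if (is.data.frame(curves)) curves <- list(curve = curves)
  df <- dplyr::bind_rows(curves, .id = "ranking")
  long <- dplyr::bind_rows(lapply(grep("^risk_", names(df), value = TRUE), function(cl) {
    dplyr::transmute(df, .data$ranking, .data$threshold,
                     test_set = sub("^risk_", "", cl), risk = .data[[cl]])
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$risk,
                                     colour = .data$ranking,
                                     linetype = .data$test_set)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "p-value threshold", y = "L2 risk") +
    ggplot2::theme_minimal()
}
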