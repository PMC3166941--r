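## Second-stage targeting arithmetic. Everything here is closed-form: the
## fluctuation is a one-dimensional no-intercept least-squares step along the
## clever covariate, and inference comes from the efficient influence curve of
## the adjusted-effect parameter in the semiparametric model Y = beta*A + f(W).

#' Clever covariate of the targeting step
#'
#' The residual of the target variable on its fitted confounding mechanism,
#' `A - g_n(W)`. Regressing outcome residuals on this direction yields the
#' fluctuation coefficient that removes confounding bias from the initial
#' effect estimate.
#'
#' @param a_values Numeric vector, the target variable A.
#' @param g_fit A [confounding_fit] (or a bare numeric vector of fitted
#'   `E(A|W)` values of the same length).
#' @return Numeric vector `a_values - g`.
#' @export
clever_covariate <- function(a_values, g_fit) {
  g <- if (inherits(g_fit, "confounding_fit")) g_fit$g else as.numeric(g_fit)
  if (length(g) != length(a_values)) {
    abort("`a_values` and the confounding fit have different lengths",
          class = "tmlevim_shape_error")
  }
  a_values - g
}

#' Fluctuation coefficient
#'
#' No-intercept least-squares slope of the outcome residuals on the clever
#' covariate. The intercept is deliberately absent: `f(W)` is already absorbed
#' into the initial fitted values, so the residual regression on the clever
#' covariate alone is the targeting step.
#'
#' @param residuals Numeric vector `Y - Q0`.
#' @param clever Numeric vector, the clever covariate.
#' @return The scalar fluctuation coefficient epsilon.
#' @export
fit_epsilon <- function(residuals, clever) {
  if (length(residuals) != length(clever)) {
    abort("`residuals` and `clever` have different lengths",
          class = "tmlevim_shape_error")
  }
  css <- sum(clever^2)
  if (css <= 0 || !is.finite(css)) {
    abort("degenerate clever covariate: A is fully explained by W",
          class = "tmlevim_degenerate_error")
  }
  sum(residuals * clever) / css
}

#' Targeted update of the effect estimate
#'
#' @param initial An [initial_fit] (or a bare numeric `beta0`).
#' @param epsilon Fluctuation coefficient from [fit_epsilon()].
#' @return `beta0 + epsilon`.
#' @export
update_beta <- function(initial, epsilon) {
  beta0 <- if (inherits(initial, "initial_fit")) initial$beta0 else as.numeric(initial)
  beta0 + epsilon
}

#' Targeted update of the fitted values
#'
#' @inheritParams update_beta
#' @param clever Clever covariate vector.
#' @return `Q0 + epsilon * clever`.
#' @export
update_fitted <- function(initial, epsilon, clever) {
  q0 <- if (inherits(initial, "initial_fit")) initial$q0 else as.numeric(initial)
  if (length(q0) != length(clever)) {
    abort("`initial` fitted values and `clever` have different lengths",
          class = "tmlevim_shape_error")
  }
  q0 + epsilon * clever
}

#' Influence-curve variance of the targeted estimate
#'
#' Empirical variance of the efficient influence curve of the adjusted effect:
#' `IC_i = c_i (Y_i - Qstar_i) / mean(c^2)`, with the estimator's variance
#' `sigma^2 = sum(IC^2) / n^2`.
#'
#' @param y Outcome vector.
#' @param q_star Updated fitted values.
#' @param clever Clever covariate vector.
#' @return Scalar variance estimate (of the estimator, not of one observation).
#' @export
influence_curve_variance <- function(y, q_star, clever) {
  n <- length(y)
  if (length(q_star) != n || length(clever) != n) {
    abort("length mismatch in influence-curve inputs", class = "tmlevim_shape_error")
  }
  if (n < 2L) abort("need at least two observations", class = "tmlevim_input_error")
  mc2 <- mean(clever^2)
  if (mc2 <= 0 || !is.finite(mc2)) {
    abort("degenerate clever covariate: A is fully explained by W",
          class = "tmlevim_degenerate_error")
  }
  ic <- clever * (y - q_star) / mc2
  sum(ic^2) / n^2
}

#' Wald-type test of the targeted effect
#'
#' `T = beta_star / sqrt(sigma2)`; under the null `beta = 0`, T is
#' asymptotically standard normal, so the two-sided p-value is
#' `2 * pnorm(-|T|)`. When `sigma2 = 0`, a zero estimate yields `p = 1` by
#' convention and a nonzero estimate an infinite statistic with `p = 0`.
#'
#' @param beta_star Targeted effect estimate.
#' @param sigma2 Influence-curve variance from [influence_curve_variance()].
#' @return A list with elements `t_stat` and `p_value`.
#' @export
test_statistic <- function(beta_star, sigma2) {
  if (sigma2 < 0) abort("negative variance", class = "tmlevim_input_error")
  if (sigma2 == 0) {
    if (beta_star == 0) return(list(t_stat = 0, p_value = 1))
    return(list(t_stat = sign(beta_star) * Inf, p_value = 0))
  }
  t_stat <- beta_star / sqrt(sigma2)
  list(t_stat = t_stat, p_value = 2 * pnorm(-abs(t_stat)))
}

#' Targeted maximum likelihood estimate for one variable
#'
#' Chains the full second stage for a single target variable A: clever
#' covariate, fluctuation fit on the residuals `Y - Q0`, update of the effect
#' and fitted values, influence-curve variance, and the Wald test.
#'
#' @param data A `vim_dataset` or data frame (see [as_vim_dataset()]).
#' @param a_index Column index (or identifier) of the target variable.
#' @param initial An [initial_fit] for this variable.
#' @param g_fit A [confounding_fit] for this variable.
#' @param outcome Outcome column name when `data` is a data frame.
#' @return An object of class `tmle_fit`: epsilon, beta_star, sigma, t_stat,
#'   p_value, n_confounders, delta_used, plus the ingredients (clever, q_star).
#'   Has [tidy()] and [glance()] methods.
#' @examples
#' d <- sim_null(n = 200, p = 3, seed = 1)
#' init <- fit_univariate_initial(d$y, d$v[, 1])
#' g <- fit_confounding(d, 1, w_indices = 2:3, learner = learner_lm())
#' fit <- tmle_single(d, 1, init, g)
#' tidy(fit)
#' @export
tmle_single <- function(data, a_index, initial, g_fit, outcome = "y") {
  data <- as_vim_dataset(data, outcome = outcome)
  a_index <- resolve_index(data, a_index)
  a <- data$v[, a_index]
  clever <- clever_covariate(a, g_fit)
  eps <- fit_epsilon(data$y - initial$q0, clever)
  beta_star <- update_beta(initial, eps)
  q_star <- update_fitted(initial, eps, clever)
  sigma2 <- influence_curve_variance(data$y, q_star, clever)
  ts <- test_statistic(beta_star, sigma2)
  structure(
    list(id = data$ids[a_index], epsilon = eps, beta0 = initial$beta0,
         beta_star = beta_star, sigma = sqrt(sigma2), t_stat = ts$t_stat,
         p_value = ts$p_value,
         n_confounders = g_fit$n_confounders %||% NA_integer_,
         delta_used = g_fit$delta %||% NA_real_,
         n = length(a), clever = clever, q_star = q_star),
    class = "tmle_fit"
  )
}

#' @export
print.tmle_fit <- function(x, ...) {
  cat(sprintf("<tmle_fit> %s: beta* = %.4g (se %.3g), T = %.3f, p = %.3g\n",
              x$id, x$beta_star, x$sigma, x$t_stat, x$p_value))
  invisible(x)
}

resolve_index <- function(data, a_index) {
  if (is.character(a_index)) {
    j <- match(a_index, data$ids)
    if (is.na(j)) abort(sprintf("unknown variable '%s'", a_index),
                        class = "tmlevim_input_error")
    return(j)
  }
  j <- as.integer(a_index)
  if (j < 1L || j > ncol(data$v)) abort("variable index out of range",
                                        class = "tmlevim_input_error")
  j
}
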