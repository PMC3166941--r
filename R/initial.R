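## First-stage estimators: the initial outcome fit Q0 (univariate, or a grand
## penalized fit shared across target variables via an offset regression) and
## the confounding mechanism g_n(W) = E(A|W).

#' Bundle an initial outcome fit
#'
#' @param beta0 Initial effect estimate (outcome units per A unit).
#' @param q0 Fitted values of `E(Y|A, W)` on the training sample.
#' @return An `initial_fit` object.
#' @export
initial_fit <- function(beta0, q0) {
  stopifnot(is.finite(beta0), is.numeric(q0))
  structure(list(beta0 = as.numeric(beta0), q0 = as.numeric(q0)),
            class = "initial_fit")
}

#' Bundle a confounding-mechanism fit
#'
#' @param g Fitted values of `E(A|W)` on the training sample (A units).
#' @param n_confounders Number of variables that entered W.
#' @param delta Correlation cutoff used to pick W, if any.
#' @return A `confounding_fit` object.
#' @export
confounding_fit <- function(g, n_confounders = NA_integer_, delta = NA_real_) {
  stopifnot(is.numeric(g), all(is.finite(g)))
  structure(list(g = as.numeric(g), n_confounders = as.integer(n_confounders),
                 delta = as.numeric(delta)),
            class = "confounding_fit")
}

#' Univariate initial estimator
#'
#' Ordinary least squares of Y on (intercept, A); the slope is the initial
#' effect estimate and the fitted values play the role of `Q0`.
#'
#' @param y Outcome vector.
#' @param a_values Target variable, same length, not constant.
#' @return An [initial_fit()].
#' @export
fit_univariate_initial <- function(y, a_values) {
  n <- length(y)
  if (n < 3L || length(a_values) != n) {
    abort("need n >= 3 with matching lengths", class = "tmlevim_input_error")
  }
  sxx <- sum((a_values - mean(a_values))^2)
  if (sxx <= 0) {
    abort("constant target variable: univariate slope undefined",
          class = "tmlevim_degenerate_error")
  }
  slope <- sum((a_values - mean(a_values)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(a_values)
  initial_fit(slope, intercept + slope * a_values)
}

#' Grand outcome fit shared across target variables
#'
#' One fit of Y on all p candidate variables. Instead of refitting `E(Y|A, W)`
#' for every target variable, each variable reuses this grand estimate through
#' an offset regression ([offset_initial_for()]).
#'
#' @param data A `vim_dataset` or data frame.
#' @param learner A learner (default [learner_lasso()]).
#' @param outcome Outcome column name for data-frame input.
#' @param seed Seed forwarded to the learner.
#' @return A `grand_fit`: the predictor, fitted values, and coefficients.
#' @export
grand_initial <- function(data, learner = learner_lasso(), outcome = "y", seed = 1L) {
  data <- as_vim_dataset(data, outcome = outcome)
  pred <- learner$fit(data$v, data$y, seed = seed)
  structure(list(predictor = pred, fitted = pred$fitted, coef = pred$coef,
                 ids = data$ids, n = nrow(data$v)),
            class = "grand_fit")
}

#' Predict the grand fit with one variable set to zero
#'
#' For the linear predictors used here this is the fitted values minus the
#' variable's contribution `coef_a * A`, which avoids a second model
#' evaluation.
#'
#' @param grand A `grand_fit`.
#' @param data The dataset it was fitted on.
#' @param a_index Column index or identifier of the variable to zero out.
#' @return Numeric vector `G_n(A = 0)`.
#' @export
predict_zero <- function(grand, data, a_index) {
  data <- as_vim_dataset(data)
  j <- resolve_index(data, a_index)
  if (!is.null(grand$coef)) {
    grand$fitted - grand$coef[[j + 1L]] * data$v[, j]
  } else {
    v0 <- data$v
    v0[, j] <- 0
    grand$predictor$predict(v0)
  }
}

#' Per-variable initial fit from the grand estimate
#'
#' Regresses Y on A alone with the offset `G_n(A = 0)` and no intercept (the
#' intercept and `f(W)` already live inside the offset): the slope is the
#' initial effect estimate, and `q0 = offset + beta0 * A`.
#'
#' @param grand A `grand_fit` fitted on `data`.
#' @param data The dataset.
#' @param a_index Column index or identifier of the target variable.
#' @return An [initial_fit()].
#' @export
offset_initial_for <- function(grand, data, a_index) {
  data <- as_vim_dataset(data)
  j <- resolve_index(data, a_index)
  a <- data$v[, j]
  saa <- sum(a^2)
  if (saa <= 0) {
    abort("all-zero target variable: offset slope undefined",
          class = "tmlevim_degenerate_error")
  }
  offset <- predict_zero(grand, data, j)
  beta0 <- sum((data$y - offset) * a) / saa
  initial_fit(beta0, offset + beta0 * a)
}

#' Fit the confounding mechanism E(A|W)
#'
#' Learner fit of the target variable on its selected confounders; the fitted
#' values estimate `E(A|W)`. An empty confounder set carries no information,
#' so `g` falls back to the sample mean of A.
#'
#' @param data A `vim_dataset` or data frame.
#' @param a_index Target variable (index or identifier).
#' @param w_indices Integer indices of the confounders; must exclude
#'   `a_index`.
#' @param learner A learner (default [learner_lasso()]).
#' @param outcome Outcome column name for data-frame input.
#' @param seed Seed forwarded to the learner.
#' @param delta Correlation cutoff recorded in the result (bookkeeping only).
#' @return A [confounding_fit()].
#' @export
fit_confounding <- function(data, a_index, w_indices, learner = learner_lasso(),
                            outcome = "y", seed = 1L, delta = NA_real_) {
  data <- as_vim_dataset(data, outcome = outcome)
  j <- resolve_index(data, a_index)
  w_indices <- as.integer(w_indices)
  if (j %in% w_indices) {
    abort("the target variable cannot be its own confounder",
          class = "tmlevim_input_error")
  }
  a <- data$v[, j]
  if (length(w_indices) == 0L) {
    return(confounding_fit(rep(mean(a), length(a)), n_confounders = 0L,
                           delta = delta))
  }
  pred <- learner$fit(data$v[, w_indices, drop = FALSE], a, seed = seed)
  confounding_fit(pred$fitted, n_confounders = length(w_indices), delta = delta)
}
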