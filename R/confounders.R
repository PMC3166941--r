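## Which variables make up W for a given target A. Too little adjustment
## leaves confounding in; adjusting for near-copies of A destroys
## identifiability. The universal rule keeps every variable whose absolute
## Pearson correlation with A is strictly below a cutoff delta (0.7 is the
## conservative default); the adaptive rule scans a cutoff grid per variable.

#' Select confounders by a correlation cutoff
#'
#' @param v Numeric matrix of candidate variables (samples x variables), or a
#'   `vim_dataset`.
#' @param a_index Target variable column index (or identifier for a
#'   `vim_dataset`).
#' @param delta Correlation cutoff in (0, 1]. Variables with
#'   `|cor(V_j, A)| < delta` (strictly) are selected.
#' @param cor_with_a Optional precomputed vector of correlations of every
#'   column with A (used by the pipeline to avoid recomputation).
#' @return Integer vector of selected column indices. Zero-variance columns
#'   are excluded with a warning.
#' @export
select_confounders <- function(v, a_index, delta = 0.7, cor_with_a = NULL) {
  if (inherits(v, "vim_dataset")) {
    a_index <- resolve_index(v, a_index)
    v <- v$v
  }
  if (!(delta > 0 && delta <= 1)) {
    abort("`delta` must lie in (0, 1]", class = "tmlevim_input_error")
  }
  if (is.null(cor_with_a)) {
    sds <- apply(v, 2, sd)
    ok <- sds > 0
    if (!ok[a_index]) {
      abort("target variable has zero variance", class = "tmlevim_degenerate_error")
    }
    if (any(!ok)) warn(sprintf("excluding %d zero-variance column(s)", sum(!ok)))
    cor_with_a <- rep(NA_real_, ncol(v))
    cor_with_a[ok] <- as.numeric(cor(v[, ok, drop = FALSE], v[, a_index]))
  }
  sel <- which(!is.na(cor_with_a) & abs(cor_with_a) < delta)
  setdiff(sel, a_index)
}

#' Configuration for the adaptive cutoff scan
#'
#' @param delta_grid Strictly increasing cutoffs in (0, 1].
#' @param lambda P-value threshold in (0, 1) deciding whether a cutoff
#'   "qualifies"; smaller values adjust more conservatively.
#' @return An `adaptive_config`.
#' @export
adaptive_config <- function(delta_grid = seq(0.1, 0.9, by = 0.1), lambda = 0.05) {
  stopifnot(all(delta_grid > 0), all(delta_grid <= 1),
            all(diff(delta_grid) > 0), length(delta_grid) >= 1L,
            lambda > 0, lambda < 1)
  structure(list(delta_grid = as.numeric(delta_grid), lambda = as.numeric(lambda)),
            class = "adaptive_config")
}

#' Adaptive correlation-cutoff TMLE for one variable
#'
#' Computes a targeted fit per cutoff in the grid (confounders selected at
#' that cutoff) and returns the largest cutoff whose p-value falls below
#' `lambda`, together with its fit. Larger qualifying cutoffs adjust for more
#' confounders; the scan protects the estimate from adjusting for variables so
#' correlated with A that the effect becomes unidentifiable. If no cutoff
#' qualifies, the smallest-cutoff fit is returned flagged as non-qualifying so
#' that every variable still gets a p-value.
#'
#' @param data A `vim_dataset` or data frame.
#' @param a_index Target variable (index or identifier).
#' @param config An [adaptive_config()].
#' @param initial An [initial_fit()] for this variable (shared across cutoffs).
#' @param learner Learner for the confounding mechanism.
#' @param outcome,seed See [fit_confounding()].
#' @return A list: `delta_star`, `qualified` (logical), and `fit` (the
#'   `tmle_fit` at `delta_star`).
#' @export
adaptive_delta <- function(data, a_index, config, initial,
                           learner = learner_lasso(), outcome = "y", seed = 1L) {
  stopifnot(inherits(config, "adaptive_config"))
  data <- as_vim_dataset(data, outcome = outcome)
  j <- resolve_index(data, a_index)
  sds <- apply(data$v, 2, sd)
  cor_with_a <- rep(NA_real_, ncol(data$v))
  cor_with_a[sds > 0] <- as.numeric(cor(data$v[, sds > 0, drop = FALSE], data$v[, j]))
  fits <- vector("list", length(config$delta_grid))
  for (k in seq_along(config$delta_grid)) {
    delta <- config$delta_grid[k]
    w <- select_confounders(data$v, j, delta, cor_with_a = cor_with_a)
    fit <- tryCatch({
      g <- fit_confounding(data, j, w, learner = learner,
                           seed = derive_seed(seed, k), delta = delta)
      tmle_single(data, j, initial, g)
    }, tmlevim_degenerate_error = function(e) {
      warn(sprintf("cutoff %.3g skipped for %s: degenerate clever covariate",
                   delta, data$ids[j]))
      NULL
    })
    fits[[k]] <- fit
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    abort(sprintf("every cutoff degenerate for variable %s", data$ids[j]),
          class = "tmlevim_degenerate_error")
  }
  pvals <- vapply(fits[ok], function(f) f$p_value, numeric(1))
  deltas <- config$delta_grid[ok]
  qual <- pvals < config$lambda
  if (any(qual)) {
    k <- max(which(qual))
    list(delta_star = deltas[k], qualified = TRUE, fit = fits[ok][[k]])
  } else {
    list(delta_star = deltas[1], qualified = FALSE, fit = fits[ok][[1]])
  }
}
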