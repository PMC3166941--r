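#' Targeted variable-importance ranking of all variables
#'
#' For every candidate variable A, estimates its adjusted marginal effect on
#' the outcome in the semiparametric model `Y = beta*A + f(W)` by a two-stage
#' targeted procedure: an initial machine-learning fit of the outcome is
#' updated along the clever covariate `A - E(A|W)`, and the resulting effect
#' estimate is tested against zero with an influence-curve standard error. The
#' p-values index variable importance; the table they populate drives
#' dimension reduction via [vim_reduce()].
#'
#' The initial fit is either one grand cross-validated lasso of Y on all
#' variables, reused across targets through an offset regression
#' (`initial = "grand_lasso"`), or a per-variable univariate regression
#' (`initial = "univariate"`). The confounding mechanism `E(A|W)` is fitted by
#' cross-validated lasso on the variables whose absolute correlation with A is
#' strictly below `delta`, or on a per-variable adaptive cutoff when
#' `adaptive` is supplied.
#'
#' @param data A data frame containing the outcome column, or a `vim_dataset`.
#' @param outcome Outcome column name (data-frame input).
#' @param initial `"grand_lasso"` or `"univariate"`.
#' @param delta Universal correlation cutoff for confounder selection.
#' @param adaptive Optional [adaptive_config()]; overrides `delta` with the
#'   per-variable cutoff scan.
#' @param folds,nlambda,lambda_min_ratio Cross-validation controls for the
#'   lasso fits (see [learner_lasso()]).
#' @param seed Integer seed; the whole table is deterministic given it, and
#'   per-variable sub-seeds make the result independent of evaluation order.
#' @param p_threshold,top_k,fdr_threshold Truncation rule for the `selected`
#'   flag; exactly one may be non-`NULL` (default: raw p < 0.05).
#' @return A `vim_table`: a tibble with one row per variable — `id`, `beta`
#'   (targeted estimate), `se`, `t`, `p`, `p_adj` (Benjamini-Hochberg),
#'   `rank` (1 = smallest p, ties broken by column order), `selected`,
#'   `n_confounders`, `delta_used`, `flag` — ordered as the input columns.
#'   Binary outcomes are accepted and treated as continuous
#'   (linear-probability) with a warning.
#' @examples
#' d <- sim_cluster(cluster_design(m = 2, n = 120, seed = 7))
#' head(tmle_vim(d, folds = 3, nlambda = 20, seed = 1))
#' @export
tmle_vim <- function(data, outcome = "y", initial = c("grand_lasso", "univariate"),
                     delta = 0.7, adaptive = NULL, folds = 10, nlambda = 100,
                     lambda_min_ratio = NULL, seed = 1L,
                     p_threshold = NULL, top_k = NULL, fdr_threshold = NULL) {
  initial <- match.arg(initial)
  data <- as_vim_dataset(data, outcome = outcome)
  check_binaryish(data$y)
  n <- nrow(data$v); p <- ncol(data$v)
  learner <- learner_lasso(folds = folds, nlambda = nlambda,
                           lambda_min_ratio = lambda_min_ratio)
  grand <- if (initial == "grand_lasso") {
    grand_initial(data, learner, seed = derive_seed(seed, 0L))
  }
  sds <- apply(data$v, 2, sd)
  if (any(sds == 0)) warn(sprintf("%d constant column(s) flagged with p = 1", sum(sds == 0)))
  cmat <- suppressWarnings(cor(data$v))  # NA rows/cols for constant columns

  rows <- vector("list", p)
  for (j in seq_len(p)) {
    if (sds[j] == 0) {
      rows[[j]] <- degenerate_row(data$ids[j])
      next
    }
    init_j <- if (initial == "univariate") {
      fit_univariate_initial(data$y, data$v[, j])
    } else {
      offset_initial_for(grand, data, j)
    }
    rows[[j]] <- tryCatch({
      if (!is.null(adaptive)) {
        ad <- adaptive_delta(data, j, adaptive, init_j, learner = learner,
                             seed = derive_seed(seed, j))
        fit <- ad$fit
        tibble::tibble(
          id = fit$id, beta = fit$beta_star, se = fit$sigma, t = fit$t_stat,
          p = fit$p_value, n_confounders = fit$n_confounders,
          delta_used = ad$delta_star,
          flag = if (ad$qualified) "" else "non_qualifying")
      } else {
        w <- select_confounders(data$v, j, delta, cor_with_a = cmat[, j])
        g <- fit_confounding(data, j, w, learner = learner,
                             seed = derive_seed(seed, j), delta = delta)
        fit <- tmle_single(data, j, init_j, g)
        tibble::tibble(
          id = fit$id, beta = fit$beta_star, se = fit$sigma, t = fit$t_stat,
          p = fit$p_value, n_confounders = fit$n_confounders,
          delta_used = delta, flag = "")
      }
    }, tmlevim_degenerate_error = function(e) degenerate_row(data$ids[j]))
  }
  finish_vim_table(dplyr::bind_rows(rows), method = paste0("tmle_", initial),
                   seed = seed, p_threshold = p_threshold, top_k = top_k,
                   fdr_threshold = fdr_threshold,
                   config = list(initial = initial, delta = delta,
                                 adaptive = adaptive, folds = folds,
                                 nlambda = nlambda,
                                 lambda_min_ratio = lambda_min_ratio))
}

#' Univariate-regression variable importance (baseline)
#'
#' Per-variable ordinary least squares of Y on (intercept, A) with the
#' textbook two-sided t-test on the slope. Shares the [tmle_vim()] table
#' schema so the two rankings are directly comparable.
#'
#' @inheritParams tmle_vim
#' @return A `vim_table` (see [tmle_vim()]); `n_confounders` is 0 and
#'   `delta_used` is `NA` throughout.
#' @export
ur_vim <- function(data, outcome = "y", p_threshold = NULL, top_k = NULL,
                   fdr_threshold = NULL) {
  data <- as_vim_dataset(data, outcome = outcome)
  check_binaryish(data$y)
  n <- nrow(data$v)
  if (n < 3L) abort("need at least 3 samples", class = "tmlevim_input_error")
  y <- data$y
  yc <- y - mean(y)
  vm <- colMeans(data$v)
  vc <- sweep(data$v, 2, vm)
  sxx <- colSums(vc^2)
  ok <- sxx > 0
  if (any(!ok)) warn(sprintf("%d constant column(s) flagged with p = 1", sum(!ok)))
  beta <- se <- tval <- rep(NA_real_, ncol(data$v))
  pval <- rep(1, ncol(data$v))
  sxy <- as.numeric(crossprod(vc, yc))
  beta[ok] <- sxy[ok] / sxx[ok]
  rss <- sum(yc^2) - beta[ok]^2 * sxx[ok]
  rss <- pmax(rss, 0)
  se[ok] <- sqrt(rss / (n - 2) / sxx[ok])
  tval[ok] <- ifelse(se[ok] > 0, beta[ok] / se[ok],
                     ifelse(beta[ok] == 0, 0, sign(beta[ok]) * Inf))
  pval[ok] <- 2 * pt(-abs(tval[ok]), df = n - 2)
  tbl <- tibble::tibble(
    id = data$ids, beta = beta, se = se, t = tval, p = pval,
    n_confounders = unname(ifelse(ok, 0L, NA_integer_)), delta_used = NA_real_,
    flag = unname(ifelse(ok, "", "degenerate")))
  finish_vim_table(tbl, method = "ur", seed = NA_integer_,
                   p_threshold = p_threshold, top_k = top_k,
                   fdr_threshold = fdr_threshold, config = list())
}

#' False-discovery-rate adjustment
#'
#' Benjamini-Hochberg step-up adjusted p-values, order-preserving with respect
#' to the input order.
#'
#' @param p_values Numeric vector in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
adjust_fdr <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  p.adjust(p_values, method = "BH")
}

#' Truncate a variable-importance table to a candidate list
#'
#' @param table A `vim_table`.
#' @param p_threshold Keep variables with raw `p` below this value.
#' @param top_k Keep the first `k` variables by rank (ties already broken by
#'   column order); `k` larger than the table keeps everything with a warning.
#' @param fdr_threshold Keep variables with adjusted `p_adj` below this value.
#' @return The selected rows, in rank order. Exactly one rule must be given.
#' @export
vim_reduce <- function(table, p_threshold = NULL, top_k = NULL, fdr_threshold = NULL) {
  rule <- check_one_rule(p_threshold, top_k, fdr_threshold, default_p = FALSE)
  tbl <- dplyr::arrange(tibble::as_tibble(table), .data$rank)
  out <- switch(rule,
    p = dplyr::filter(tbl, .data$p < p_threshold),
    fdr = dplyr::filter(tbl, .data$p_adj < fdr_threshold),
    k = {
      if (top_k > nrow(tbl)) {
        warn("`top_k` exceeds the number of variables; returning all")
        top_k <- nrow(tbl)
      }
      dplyr::slice_head(tbl, n = top_k)
    })
  out
}

## ---- internals -------------------------------------------------------------

degenerate_row <- function(id) {
  tibble::tibble(id = id, beta = NA_real_, se = NA_real_, t = NA_real_, p = 1,
                 n_confounders = NA_integer_, delta_used = NA_real_,
                 flag = "degenerate")
}

check_binaryish <- function(y) {
  if (all(y %in% c(0, 1))) {
    warn("binary outcome treated as continuous (linear-probability model)")
  }
  invisible(y)
}

check_one_rule <- function(p_threshold, top_k, fdr_threshold, default_p = TRUE) {
  given <- c(p = !is.null(p_threshold), k = !is.null(top_k),
             fdr = !is.null(fdr_threshold))
  if (sum(given) > 1L) {
    abort("give exactly one of `p_threshold`, `top_k`, `fdr_threshold`",
          class = "tmlevim_input_error")
  }
  if (sum(given) == 0L) {
    if (!default_p) abort("give one of `p_threshold`, `top_k`, `fdr_threshold`",
                          class = "tmlevim_input_error")
    return("p")
  }
  names(given)[given]
}

finish_vim_table <- function(tbl, method, seed, p_threshold, top_k,
                             fdr_threshold, config) {
  rule <- check_one_rule(p_threshold, top_k, fdr_threshold)
  if (rule == "p" && is.null(p_threshold)) p_threshold <- 0.05
  tbl$p_adj <- adjust_fdr(tbl$p)
  rk <- integer(nrow(tbl))
  rk[order(tbl$p, seq_len(nrow(tbl)))] <- seq_len(nrow(tbl))
  tbl$rank <- rk
  tbl$selected <- switch(rule,
    p = tbl$p < p_threshold,
    fdr = tbl$p_adj < fdr_threshold,
    k = rk <= min(top_k, nrow(tbl)))
  tbl <- tbl[, c("id", "beta", "se", "t", "p", "p_adj", "rank", "selected",
                 "n_confounders", "delta_used", "flag")]
  structure(tbl, class = c("vim_table", class(tibble::tibble()))) |>
    set_vim_attrs(method = method, seed = seed,
                  rule = list(kind = rule, p_threshold = p_threshold,
                              top_k = top_k, fdr_threshold = fdr_threshold),
                  config = config)
}

set_vim_attrs <- function(tbl, ...) {
  at <- list(...)
  for (nm in names(at)) attr(tbl, paste0("vim_", nm)) <- at[[nm]]
  tbl
}
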