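## Downstream prediction on reduced candidate lists and the benchmark
## summaries: L2 risk, R^2, risk-reduction and true/false-positive recovery
## ratios of the targeted ranking against the univariate baseline.

#' L2 prediction risk
#'
#' Mean squared prediction error of a downstream predictor on a test set.
#'
#' @param predictor A predictor from [fit_downstream()] (or any function
#'   mapping a `vim_dataset` to predictions).
#' @param test_data A `vim_dataset` (or data frame with the outcome column).
#' @param outcome Outcome column name for data-frame input.
#' @return Mean of `(Y - Yhat)^2` over the test samples.
#' @export
l2_risk <- function(predictor, test_data, outcome = "y") {
  test_data <- as_vim_dataset(test_data, outcome = outcome)
  yhat <- if (inherits(predictor, "vim_downstream")) {
    predictor$predict(test_data)
  } else {
    predictor(test_data)
  }
  mean((test_data$y - yhat)^2)
}

#' Proportion of explained variance
#'
#' `R^2 = 1 - risk / MST`, where MST is the mean squared deviation of the test
#' outcome from its own mean (the risk of the intercept-only model).
#'
#' @param risk L2 risk of the predictor on the test set.
#' @param y_test Test outcome vector (must have positive variance).
#' @return Scalar `R^2` (at most 1; negative when the predictor does worse
#'   than the test mean).
#' @export
r_squared <- function(risk, y_test) {
  mst <- mean((y_test - mean(y_test))^2)
  if (mst <= 0) abort("zero-variance test outcome", class = "tmlevim_input_error")
  1 - risk / mst
}

#' Fit a downstream predictor on a reduced variable list
#'
#' @param data Training `vim_dataset` or data frame.
#' @param selected_ids Nonempty character vector of variable identifiers (or
#'   integer indices).
#' @param method `"mvr"` (multivariate ordinary least squares) or `"l1"`
#'   (cross-validated lasso on the selected columns).
#' @param allow_singular For `"mvr"`: when the selected count reaches the
#'   sample size the normal equations are rank deficient; by default this is
#'   an error advising `"l1"`. Setting `TRUE` fits by pivoted QR with aliased
#'   columns dropped, reproducing the breakdown behaviour of a naive
#'   multivariate regression rather than halting.
#' @param folds,nlambda,lambda_min_ratio,seed Lasso controls for `"l1"`.
#' @param outcome Outcome column name for data-frame input.
#' @return A `vim_downstream` predictor for use with [l2_risk()].
#' @export
fit_downstream <- function(data, selected_ids, method = c("mvr", "l1"),
                           allow_singular = FALSE, folds = 10, nlambda = 100,
                           lambda_min_ratio = NULL, seed = 1L, outcome = "y") {
  method <- match.arg(method)
  data <- as_vim_dataset(data, outcome = outcome)
  if (length(selected_ids) == 0L) {
    abort("empty selection: nothing to fit", class = "tmlevim_input_error")
  }
  ids <- if (is.numeric(selected_ids)) data$ids[selected_ids] else as.character(selected_ids)
  idx <- match(ids, data$ids)
  if (anyNA(idx)) {
    abort(sprintf("unknown identifiers: %s", paste(ids[is.na(idx)], collapse = ", ")),
          class = "tmlevim_input_error")
  }
  x <- data$v[, idx, drop = FALSE]
  n <- nrow(x)
  pred <- if (method == "mvr") {
    if (length(idx) >= n && !allow_singular) {
      abort(paste0("MVR with ", length(idx), " variables and ", n,
                   " samples is rank deficient; use method = 'l1' ",
                   "(or allow_singular = TRUE to fit anyway)"),
            class = "tmlevim_rank_error")
    }
    learner_lm()$fit(x, data$y)
  } else {
    fit_lasso_learner(x, data$y, folds = folds, seed = seed, nlambda = nlambda,
                      lambda_min_ratio = lambda_min_ratio)
  }
  structure(list(
    method = method, ids = ids,
    predict = function(newdata) {
      newdata <- as_vim_dataset(newdata)
      jj <- match(ids, newdata$ids)
      if (anyNA(jj)) abort("test data is missing selected variables",
                           class = "tmlevim_input_error")
      pred$predict(newdata$v[, jj, drop = FALSE])
    },
    fit = pred
  ), class = "vim_downstream")
}

#' Benchmark targeted against univariate screening on simulated designs
#'
#' For each design and replicate: simulate a training set, a matched test set
#' ("a", same correlation) and a cross-examination test set ("b", correlation
#' `rho_b`, same causal coefficients); rank variables with [ur_vim()] and
#' [tmle_vim()]; truncate both lists at raw `p < p_threshold`; fit the
#' downstream predictor(s) on each list; and score risks and recovery against
#' the truth flags.
#'
#' Reported per design x method (averaged over replicates, with standard
#' errors): the L2 risks, the proportional risk reduction
#' `R_r = (UR risk - TMLE risk) / UR risk` on both test sets, the causal-count
#' ratio `R_A = TMLE TP / UR TP`, the non-causal-count ratio
#' `R_W = TMLE FP / UR FP`, and raw TP/FP counts. Ratio denominators of zero
#' yield `NA` with the counts retained. Every number is reproducible
#' bit-for-bit from `(designs, replicates, seed)`.
#'
#' @param designs A [cluster_design()] or list of them.
#' @param methods Downstream predictors, subset of `c("mvr", "l1")`.
#' @param replicates Replicates per design.
#' @param seed Integer master seed.
#' @param p_threshold Raw p-value truncation of both candidate lists.
#' @param n_test Test-set size (both sets).
#' @param rho_b Correlation of test set (b).
#' @param initial,delta Passed to [tmle_vim()]. The sweep default `delta = 1`
#'   fits the confounding mechanism on all other variables (only exact copies
#'   are excluded), the protocol used for the cluster-design experiments;
#'   [tmle_vim()]'s own default keeps the conservative universal 0.7 cutoff.
#' @param folds,nlambda,lambda_min_ratio Lasso cross-validation controls used
#'   throughout (leaner defaults than [tmle_vim()]'s, sized for sweeps).
#' @return A `vim_benchmark`: list with `replicates` (one row per
#'   design x replicate x method) and `summary` tibbles. Has `tidy()` and
#'   `autoplot()` methods.
#' @export
vim_benchmark <- function(designs, methods = "mvr", replicates = 3, seed = 1L,
                          p_threshold = 0.05, n_test = 5000, rho_b = 0.1,
                          initial = "grand_lasso", delta = 1, folds = 3,
                          nlambda = 20, lambda_min_ratio = 0.05) {
  if (inherits(designs, "cluster_design")) designs <- list(designs)
  stopifnot(all(vapply(designs, inherits, logical(1), "cluster_design")),
            all(methods %in% c("mvr", "l1")))
  rows <- list()
  for (i in seq_along(designs)) {
    des <- designs[[i]]
    for (r in seq_len(replicates)) {
      train <- sim_cluster(des, seed = derive_seed(seed, i, r, 1L))
      test_a <- sim_cluster(des, n = n_test, seed = derive_seed(seed, i, r, 2L))
      test_b <- sim_cluster(des, rho = rho_b, n = n_test,
                            seed = derive_seed(seed, i, r, 3L))
      ur <- ur_vim(train, p_threshold = p_threshold)
      tm <- tmle_vim(train, initial = initial, delta = delta, folds = folds,
                     nlambda = nlambda, lambda_min_ratio = lambda_min_ratio,
                     seed = derive_seed(seed, i, r, 4L),
                     p_threshold = p_threshold)
      lists <- list(ur = ur$id[ur$selected], tmle = tm$id[tm$selected])
      counts <- lapply(lists, function(ids) {
        jj <- match(ids, train$ids)
        c(tp = sum(train$truth[jj]), fp = sum(!train$truth[jj]))
      })
      for (mth in methods) {
        risk <- lapply(lists, function(ids) {
          if (length(ids) == 0L) {
            mu <- mean(train$y)
            pr <- structure(list(predict = function(nd) {
              rep(mu, nrow(as_vim_dataset(nd)$v))
            }), class = "vim_downstream")
          } else {
            pr <- fit_downstream(train, ids, method = mth, allow_singular = TRUE,
                                 folds = folds, nlambda = nlambda,
                                 lambda_min_ratio = lambda_min_ratio,
                                 seed = derive_seed(seed, i, r, 5L))
          }
          c(a = l2_risk(pr, test_a), b = l2_risk(pr, test_b))
        })
        rows[[length(rows) + 1L]] <- tibble::tibble(
          design = i, m = des$m, m_w = des$m_w, rho = des$rho,
          sigma_e = des$sigma_e, replicate = r, method = mth,
          risk_ur_a = risk$ur[["a"]], risk_tmle_a = risk$tmle[["a"]],
          risk_ur_b = risk$ur[["b"]], risk_tmle_b = risk$tmle[["b"]],
          rr_a = safe_ratio(risk$ur[["a"]] - risk$tmle[["a"]], risk$ur[["a"]]),
          rr_b = safe_ratio(risk$ur[["b"]] - risk$tmle[["b"]], risk$ur[["b"]]),
          tp_ur = counts$ur[["tp"]], fp_ur = counts$ur[["fp"]],
          tp_tmle = counts$tmle[["tp"]], fp_tmle = counts$tmle[["fp"]],
          r_a = safe_ratio(counts$tmle[["tp"]], counts$ur[["tp"]]),
          r_w = safe_ratio(counts$tmle[["fp"]], counts$ur[["fp"]]))
      }
    }
  }
  reps <- dplyr::bind_rows(rows)
  numcols <- setdiff(names(reps), c("design", "m", "m_w", "rho", "sigma_e",
                                    "replicate", "method"))
  summary <- reps |>
    dplyr::group_by(.data$design, .data$m, .data$m_w, .data$rho,
                    .data$sigma_e, .data$method) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      dplyr::across(dplyr::all_of(numcols),
                    list(mean = ~mean(.x, na.rm = TRUE),
                         se = ~sd(.x, na.rm = TRUE) / sqrt(sum(!is.na(.x))))),
      .groups = "drop")
  structure(list(replicates = reps, summary = summary,
                 seed = seed, p_threshold = p_threshold),
            class = "vim_benchmark")
}

#' @export
print.vim_benchmark <- function(x, ...) {
  cat(sprintf("<vim_benchmark> %d design(s), %d replicate rows (seed %d)\n",
              length(unique(x$replicates$design)), nrow(x$replicates), x$seed))
  print(dplyr::select(x$summary, "rho", "m_w", "method",
                      dplyr::any_of(c("rr_a_mean", "rr_b_mean", "r_a_mean", "r_w_mean"))))
  invisible(x)
}

#' Risk of a truncated candidate list across p-value thresholds
#'
#' Supports risk-versus-threshold curves: for each threshold, truncate the
#' table at raw `p < threshold`, refit the downstream predictor, and record
#' the L2 risk on each supplied test set.
#'
#' @param table A `vim_table`.
#' @param train Training dataset the table was computed from.
#' @param tests Named list of test `vim_dataset`s.
#' @param thresholds P-value thresholds to scan.
#' @param method Downstream method (see [fit_downstream()]).
#' @param ... Passed to [fit_downstream()].
#' @return A tibble: `threshold`, `n_selected`, one risk column per test set.
#' @export
risk_curve <- function(table, train, tests, thresholds = c(0.001, 0.01, 0.05, 0.1, 0.2),
                       method = "mvr", ...) {
  train <- as_vim_dataset(train)
  purrr::map_dfr(thresholds, function(th) {
    ids <- table$id[table$p < th]
    risks <- if (length(ids) == 0L) {
      mu <- mean(train$y)
      vapply(tests, function(ts) mean((as_vim_dataset(ts)$y - mu)^2), numeric(1))
    } else {
      pr <- fit_downstream(train, ids, method = method, allow_singular = TRUE, ...)
      vapply(tests, function(ts) l2_risk(pr, ts), numeric(1))
    }
    tibble::tibble(threshold = th, n_selected = length(ids),
                   !!!stats::setNames(as.list(risks), paste0("risk_", names(tests))))
  })
}

safe_ratio <- function(num, den) {
  if (!is.finite(den) || den == 0) return(NA_real_)
  num / den
}
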