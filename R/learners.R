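## Regression learner contract used for both the grand outcome fit and the
## per-variable confounding mechanism. A learner is a list with a name and a
## fit(x, y, seed) function returning a predictor: list(predict = function(newx),
## fitted, coef) where coef is c(intercept, slopes) on the original scale.

#' Ordinary least-squares learner
#'
#' @return A learner usable by [grand_initial()] and [fit_confounding()].
#' @export
learner_lm <- function() {
  structure(list(
    name = "lm",
    fit = function(x, y, seed = NULL) {
      x <- as.matrix(x)
      fit <- lm.fit(cbind(`(Intercept)` = 1, x), y)
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0
      structure(list(
        coef = cf,
        fitted = as.numeric(cbind(1, x) %*% cf),
        predict = function(newx) as.numeric(cbind(1, as.matrix(newx)) %*% cf)
      ), class = "vim_predictor")
    }
  ), class = "vim_learner")
}

#' Cross-validated L1-penalized (lasso) learner
#'
#' Linear model with an L1 penalty chosen by k-fold cross-validation minimizing
#' squared error over a geometric penalty path (glmnet). Columns are
#' standardized internally; coefficients are returned on the original scale.
#' Fold assignment is derived deterministically from the seed, so identical
#' seed and inputs give bitwise-identical coefficients.
#'
#' @param folds Number of cross-validation folds (default 10).
#' @param nlambda Length of the penalty path.
#' @param lambda_min_ratio Smallest penalty as a fraction of the largest;
#'   `NULL` keeps glmnet's default.
#' @return A learner object.
#' @export
learner_lasso <- function(folds = 10, nlambda = 100, lambda_min_ratio = NULL) {
  force(folds); force(nlambda); force(lambda_min_ratio)
  structure(list(
    name = "lasso",
    fit = function(x, y, seed = NULL) {
      fit_lasso_learner(x, y, folds = folds, seed = seed %||% 1L,
                        nlambda = nlambda, lambda_min_ratio = lambda_min_ratio)
    }
  ), class = "vim_learner")
}

#' Fit a cross-validated lasso predictor
#'
#' @param x Predictor matrix (n x p). Zero-variance columns are dropped with a
#'   warning. A single-column matrix falls back to ordinary least squares
#'   (the penalty path needs at least two predictors).
#' @param y Response vector.
#' @param folds Number of cross-validation folds.
#' @param seed Integer seed controlling fold assignment.
#' @param nlambda,lambda_min_ratio Penalty-path controls passed to glmnet.
#' @return A `vim_predictor` (predict/fitted/coef) with the selected penalty in
#'   `$lambda`.
#' @export
fit_lasso_learner <- function(x, y, folds = 10, seed = 1L, nlambda = 100,
                              lambda_min_ratio = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < folds || folds < 2) {
    abort("need n >= folds >= 2", class = "tmlevim_input_error")
  }
  keep <- which(apply(x, 2, function(col) max(col) > min(col)))
  if (length(keep) < ncol(x)) {
    warn(sprintf("dropping %d zero-variance column(s)", ncol(x) - length(keep)))
  }
  if (length(keep) == 0L) {
    cf <- c(`(Intercept)` = mean(y))
    return(structure(list(
      coef = cf, fitted = rep(cf[[1]], n), lambda = Inf,
      predict = function(newx) rep(cf[[1]], nrow(as.matrix(newx)))
    ), class = "vim_predictor"))
  }
  if (length(keep) == 1L) {
    pred <- learner_lm()$fit(x[, keep, drop = FALSE], y)
    cf <- numeric(ncol(x) + 1L)
    names(cf) <- c("(Intercept)", colnames(x) %||% paste0("V", seq_len(ncol(x))))
    cf[1] <- pred$coef[1]; cf[keep + 1L] <- pred$coef[2]
    return(structure(list(
      coef = cf, fitted = pred$fitted, lambda = 0,
      predict = function(newx) as.numeric(cbind(1, as.matrix(newx)) %*% cf)
    ), class = "vim_predictor"))
  }
  xk <- x[, keep, drop = FALSE]
  foldid <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(derive_seed(seed, 17L))
    sample(rep(seq_len(folds), length.out = n))
  }
  args <- list(x = xk, y = y, foldid = foldid, nlambda = nlambda,
               family = "gaussian")
  if (!is.null(lambda_min_ratio)) args$lambda.min.ratio <- lambda_min_ratio
  cv <- do.call(glmnet::cv.glmnet, args)
  cfk <- as.numeric(coef(cv, s = "lambda.min"))
  cf <- numeric(ncol(x) + 1L)
  names(cf) <- c("(Intercept)", colnames(x) %||% paste0("V", seq_len(ncol(x))))
  cf[1] <- cfk[1]
  cf[keep + 1L] <- cfk[-1]
  structure(list(
    coef = cf,
    fitted = as.numeric(cbind(1, x) %*% cf),
    lambda = cv$lambda.min,
    predict = function(newx) as.numeric(cbind(1, as.matrix(newx)) %*% cf)
  ), class = "vim_predictor")
}

#' @export
print.vim_learner <- function(x, ...) {
  cat(sprintf("<vim_learner> %s\n", x$name)); invisible(x)
}
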