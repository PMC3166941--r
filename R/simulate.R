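## Seeded generators for the two simulation designs (independent
## exchangeable-correlation clusters; arbitrary correlation matrix) plus pure
## null data. Defaults are the study conditions: 25 causal variables with unit
## main effects, Gaussian noise, training n = 500.

#' Exchangeable-cluster simulation design
#'
#' Describes data made of `n_clusters` independent blocks, each holding one
#' causal variable A and `m` correlated companions W. Within a block the
#' variables are jointly Gaussian with an exchangeable correlation `rho`;
#' blocks are mutually independent. The outcome is a main-effect model of the
#' A's plus Gaussian noise.
#'
#' @param m Companions per cluster (the total non-causal count is
#'   `n_clusters * m`).
#' @param rho Exchangeable within-cluster correlation, in \[0, 1).
#' @param sigma_e Noise standard deviation.
#' @param n Sample size.
#' @param coefficients Main-effect sizes of the causal variables (length
#'   `n_clusters`; default all 1).
#' @param n_clusters Number of clusters (default 25).
#' @param seed Integer seed.
#' @return A `cluster_design` list.
#' @export
cluster_design <- function(m = 10, rho = 0.5, sigma_e = 5, n = 500,
                           coefficients = rep(1, n_clusters), n_clusters = 25,
                           seed = 1L) {
  stopifnot(m >= 1, n >= 2, sigma_e > 0, n_clusters >= 1,
            length(coefficients) == n_clusters)
  if (!(rho >= 0 && rho < 1)) {
    abort("`rho` must lie in [0, 1)", class = "tmlevim_input_error")
  }
  structure(list(m = m, m_w = n_clusters * m, rho = rho, sigma_e = sigma_e,
                 n = n, coefficients = as.numeric(coefficients),
                 n_clusters = n_clusters, seed = as.integer(seed)),
            class = "cluster_design")
}

#' Simulate from an exchangeable-cluster design
#'
#' Columns are laid out block by block (`A01, W01.01, ..., W01.mm, A02, ...`),
#' truth flags mark the A columns, and the realized noise vector is kept as an
#' attribute so the outcome can be reconstructed exactly from the flagged
#' columns. `rho`, `n` and `seed` can be overridden without touching the
#' coefficients — that is how matched test sets with a different covariate
#' joint distribution but the same causal mechanism are drawn.
#'
#' @param design A [cluster_design()].
#' @param rho,n,seed Optional overrides of the design fields.
#' @return A `vim_dataset` with truth flags and a `"noise"` attribute.
#' @examples
#' d <- sim_cluster(cluster_design(m = 2, n = 50, seed = 3))
#' dim(d)  # 50 x 75
#' @export
sim_cluster <- function(design, rho = NULL, n = NULL, seed = NULL) {
  stopifnot(inherits(design, "cluster_design"))
  rho <- rho %||% design$rho
  n <- n %||% design$n
  seed <- seed %||% design$seed
  if (!(rho >= 0 && rho < 1)) {
    abort("`rho` must lie in [0, 1)", class = "tmlevim_input_error")
  }
  blk <- design$m + 1L
  S <- matrix(rho, blk, blk); diag(S) <- 1
  L <- tryCatch(chol(S), error = function(e) {
    abort("cluster correlation matrix is not positive definite",
          class = "tmlevim_input_error")
  })
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(derive_seed(seed, 1L))
  v <- matrix(0, n, design$n_clusters * blk)
  ids <- character(ncol(v))
  truth <- logical(ncol(v))
  for (k in seq_len(design$n_clusters)) {
    cols <- (k - 1L) * blk + seq_len(blk)
    v[, cols] <- matrix(rnorm(n * blk), n, blk) %*% L
    ids[cols] <- c(sprintf("A%02d", k), sprintf("W%02d.%02d", k, seq_len(design$m)))
    truth[cols[1]] <- TRUE
  }
  colnames(v) <- ids
  e <- rnorm(n, 0, design$sigma_e)
  y <- as.numeric(v[, truth, drop = FALSE] %*% design$coefficients) + e
  out <- vim_dataset(v, outcome = y, truth = truth,
                     provenance = sprintf("sim_cluster(m=%d, rho=%g, sigma_e=%g, n=%d, seed=%d)",
                                          design$m, rho, design$sigma_e, n, seed))
  attr(out, "noise") <- e
  attr(out, "design") <- design
  out
}

#' General correlation-matrix simulation design
#'
#' Rows are drawn multivariate Gaussian with a user-supplied correlation
#' matrix (any symmetric matrix with unit diagonal; mild non-positive-definite
#' input is repaired by eigenvalue clipping). The outcome uses a configurable
#' set of causal columns through a linear or polynomial form.
#'
#' @param correlation p x p symmetric numeric matrix with unit diagonal, e.g.
#'   from [synthetic_expression_corr()] or read from a TSV/CSV.
#' @param causal Indices of the causal columns (default: 20 evenly spaced).
#' @param outcome `"linear"`, `"polynomial"`, or a function of the causal
#'   submatrix returning the noiseless signal. The polynomial default adds
#'   half-weighted squares of every causal column and the product of the first
#'   two to the linear part.
#' @param coefficients Linear coefficients of the causal columns. The default
#'   mixes signs 3:2 (up- and down-regulated effects): with correlated
#'   variables, opposite-signed effects partially cancel in the marginal
#'   association — univariate screening misses the cancelled causal columns
#'   yet flags their many correlates, while adjusted effects stay at full
#'   strength. This is the confounded regime the design probes.
#' @param noise_sd Noise standard deviation (default 4, placing the explained
#'   variance of a good predictor near 0.6 under the default coefficients).
#' @param n Sample size.
#' @param seed Integer seed.
#' @return A `general_design` list.
#' @export
general_design <- function(correlation, causal = NULL, outcome = "linear",
                           coefficients = NULL, noise_sd = 4, n = 500,
                           seed = 1L) {
  correlation <- as.matrix(correlation)
  p <- ncol(correlation)
  if (!isSymmetric(unname(correlation), tol = 1e-8)) {
    abort("correlation matrix must be symmetric", class = "tmlevim_input_error")
  }
  if (max(abs(diag(correlation) - 1)) > 1e-8) {
    abort("correlation matrix must have unit diagonal", class = "tmlevim_input_error")
  }
  causal <- causal %||% unique(round(seq(1, p, length.out = min(20, p))))
  stopifnot(all(causal >= 1), all(causal <= p), noise_sd > 0, n >= 2)
  coefficients <- coefficients %||% rep(c(1, 1, 1, -1, -1), length.out = length(causal))
  stopifnot(length(coefficients) == length(causal))
  structure(list(correlation = correlation, causal = as.integer(causal),
                 outcome = outcome, coefficients = as.numeric(coefficients),
                 noise_sd = noise_sd, n = n, seed = as.integer(seed)),
            class = "general_design")
}

#' Simulate from a general correlation-matrix design
#'
#' @param design A [general_design()].
#' @param n,seed Optional overrides (coefficients and correlation reused).
#' @return A `vim_dataset` with truth flags and a `"noise"` attribute.
#' @export
sim_general <- function(design, n = NULL, seed = NULL) {
  stopifnot(inherits(design, "general_design"))
  n <- n %||% design$n
  seed <- seed %||% design$seed
  S <- design$correlation
  p <- ncol(S)
  L <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(L)) {
    message("correlation matrix not positive definite; repairing by eigenvalue clipping")
    ee <- eigen(S, symmetric = TRUE)
    vals <- pmax(ee$values, 1e-8)
    S <- ee$vectors %*% (vals * t(ee$vectors))
    d <- sqrt(diag(S))
    S <- S / tcrossprod(d)
    L <- chol(S)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(derive_seed(seed, 2L))
  v <- matrix(rnorm(n * p), n, p) %*% L
  colnames(v) <- colnames(design$correlation) %||% sprintf("V%04d", seq_len(p))
  vc <- v[, design$causal, drop = FALSE]
  signal <- if (is.function(design$outcome)) {
    design$outcome(vc)
  } else if (identical(design$outcome, "linear")) {
    as.numeric(vc %*% design$coefficients)
  } else if (identical(design$outcome, "polynomial")) {
    lin <- as.numeric(vc %*% design$coefficients)
    sq <- 0.5 * rowSums(vc^2)
    inter <- if (ncol(vc) >= 2) vc[, 1] * vc[, 2] else 0
    lin + sq + inter
  } else {
    abort("unknown outcome form", class = "tmlevim_input_error")
  }
  e <- rnorm(n, 0, design$noise_sd)
  truth <- seq_len(p) %in% design$causal
  out <- vim_dataset(v, outcome = signal + e, truth = truth,
                     provenance = sprintf("sim_general(p=%d, n=%d, seed=%d)", p, n, seed))
  attr(out, "noise") <- e
  attr(out, "design") <- design
  out
}

#' Synthetic expression-style correlation matrix
#'
#' Single-factor structure `C = diag(1 - l^2) + l l'` with loadings spread so
#' the off-diagonal absolute correlations have quartiles close to
#' (0.16, 0.26, 0.37), the pattern typical of co-regulated expression panels.
#' Which columns carry large loadings is shuffled by the seed.
#'
#' @param p Number of variables.
#' @param seed Integer seed.
#' @return A p x p correlation matrix.
#' @export
synthetic_expression_corr <- function(p, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(derive_seed(seed, 3L))
  l <- sample(seq(0.205, 0.853, length.out = p))
  C <- tcrossprod(l)
  diag(C) <- 1
  colnames(C) <- rownames(C) <- sprintf("V%04d", seq_len(p))
  C
}

#' Null-data generator
#'
#' Variables are Gaussian (independent, or with a common exchangeable
#' correlation when `rho > 0`) and the outcome is pure `N(0, 1)` noise
#' independent of everything — the reference distribution for test-statistic
#' calibration.
#'
#' @param n,p Sample and variable counts.
#' @param rho Exchangeable correlation among the variables (default 0).
#' @param seed Integer seed.
#' @return A `vim_dataset` with all-`FALSE` truth flags.
#' @export
sim_null <- function(n, p, rho = 0, seed = 1L) {
  stopifnot(n >= 1, p >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(derive_seed(seed, 4L))
  v <- matrix(rnorm(n * p), n, p)
  if (rho > 0) {
    S <- matrix(rho, p, p); diag(S) <- 1
    v <- v %*% chol(S)
  }
  colnames(v) <- sprintf("V%03d", seq_len(p))
  vim_dataset(v, outcome = rnorm(n), truth = rep(FALSE, p),
              provenance = sprintf("sim_null(n=%d, p=%d, rho=%g, seed=%d)", n, p, rho, seed))
}
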