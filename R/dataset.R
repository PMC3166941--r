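#' Construct a variable-importance dataset
#'
#' Bundles a continuous outcome with a samples-by-variables numeric matrix, the
#' container consumed by [tmle_vim()], [ur_vim()] and the benchmarking helpers.
#' Most users never call this directly: the pipeline functions accept a plain
#' data frame with the outcome as one of its columns, and the simulators return
#' a ready-made `vim_dataset`.
#'
#' @param data A data frame (or numeric matrix) of candidate variables,
#'   samples in rows. If `outcome` names one of its columns, that column is
#'   split off as the outcome.
#' @param outcome Either the name of the outcome column in `data`, or a numeric
#'   vector of length `nrow(data)`.
#' @param truth Optional logical vector flagging the truly causal variables
#'   (used by the simulators and the benchmark scoring). Length `p` or `NULL`.
#' @param na_action `"error"` (default) rejects missing values; `"impute"`
#'   replaces them by the column mean with a warning.
#' @param provenance Optional string recording where the data came from.
#'
#' @return An object of class `vim_dataset`: a list with elements `y` (numeric
#'   outcome), `v` (numeric matrix, samples x variables), `ids` (unique
#'   variable identifiers), `outcome_name`, optional `truth`, and `provenance`.
#' @examples
#' d <- vim_dataset(data.frame(y = rnorm(10), g1 = rnorm(10), g2 = rnorm(10)),
#'                  outcome = "y")
#' dim(d)
#' @export
vim_dataset <- function(data, outcome, truth = NULL, na_action = c("error", "impute"),
                        provenance = NULL) {
  na_action <- match.arg(na_action)
  if (is.character(outcome) && length(outcome) == 1L) {
    if (!outcome %in% colnames(data)) {
      abort(sprintf("outcome column '%s' not found in `data`", outcome),
            class = "tmlevim_input_error")
    }
    y <- as.numeric(data[[outcome]])
    outcome_name <- outcome
    v <- data[, setdiff(colnames(data), outcome), drop = FALSE]
  } else {
    y <- as.numeric(outcome)
    outcome_name <- "y"
    v <- data
  }
  v <- as.matrix(v)
  storage.mode(v) <- "double"
  if (is.null(colnames(v))) colnames(v) <- paste0("V", seq_len(ncol(v)))
  if (length(y) != nrow(v)) {
    abort("outcome length does not match the number of rows in `data`",
          class = "tmlevim_input_error")
  }
  if (nrow(v) < 1L || ncol(v) < 1L) {
    abort("dataset needs at least one sample and one variable",
          class = "tmlevim_input_error")
  }
  if (anyDuplicated(colnames(v))) {
    abort(sprintf("duplicate variable identifiers: %s",
                  paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", ")),
          class = "tmlevim_input_error")
  }
  if (anyNA(y)) abort("missing values in the outcome", class = "tmlevim_input_error")
  if (anyNA(v)) {
    if (na_action == "error") {
      abort("missing values in the variable matrix (set na_action = 'impute' to mean-impute)",
            class = "tmlevim_input_error")
    }
    warn("missing values mean-imputed by column")
    for (j in which(colSums(is.na(v)) > 0L)) {
      v[is.na(v[, j]), j] <- mean(v[, j], na.rm = TRUE)
    }
  }
  if (!is.null(truth)) {
    truth <- as.logical(truth)
    stopifnot(length(truth) == ncol(v))
  }
  structure(
    list(y = y, v = v, ids = colnames(v), outcome_name = outcome_name,
         truth = truth, provenance = provenance %||% "in-memory"),
    class = "vim_dataset"
  )
}

#' Coerce to a vim_dataset
#'
#' @param x A `vim_dataset` or a data frame containing the outcome column.
#' @param outcome Outcome column name (ignored when `x` already is a
#'   `vim_dataset`).
#' @param ... Passed to [vim_dataset()].
#' @return A `vim_dataset`.
#' @export
as_vim_dataset <- function(x, outcome = "y", ...) {
  if (inherits(x, "vim_dataset")) return(x)
  vim_dataset(x, outcome = outcome, ...)
}

#' @export
dim.vim_dataset <- function(x) dim(x$v)

#' @export
print.vim_dataset <- function(x, ...) {
  cat(sprintf("<vim_dataset> %d samples x %d variables, outcome '%s'\n",
              nrow(x$v), ncol(x$v), x$outcome_name))
  if (!is.null(x$truth)) cat(sprintf("  %d variables flagged causal\n", sum(x$truth)))
  cat(sprintf("  provenance: %s\n", x$provenance))
  invisible(x)
}

#' @export
as.data.frame.vim_dataset <- function(x, ...) {
  out <- as.data.frame(x$v)
  out[[x$outcome_name]] <- x$y
  out[c(x$outcome_name, x$ids)]
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.vim_dataset <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

## deterministic sub-seed derivation: keeps every stream reproducible from one
## user seed while independent of evaluation order; stays inside 32-bit range
derive_seed <- function(seed, ...) {
  ks <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (k in ks) s <- (s * 69069 + as.double(k) * 104729 + 1) %% 2147483647
  as.integer(s)
}
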