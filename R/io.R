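## Delimited-text input and output. Canonical orientation is samples-in-rows;
## the genes-in-rows dialect common for expression matrices is handled by a
## flag. Comma/tab delimiters are sniffed, with an override.

sniff_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  lines <- readLines(path, n = 20L)
  first <- c(lines[!startsWith(lines, "#")], "")[1]
  if (grepl("\t", first)) "\t" else ","
}

read_delim_quiet <- function(path, delim) {
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    comment = "#", progress = FALSE)
}

#' Read an expression matrix and phenotype table
#'
#' Loads a numeric matrix and a phenotype file, aligns them on sample
#' identifiers (first column of each file), and returns a [vim_dataset()].
#' Sample mismatches are hard errors listing the offenders.
#'
#' @param matrix_path Delimited text; first column holds identifiers (sample
#'   identifiers for `orientation = "samples"`, variable identifiers for
#'   `orientation = "genes"` where samples are the remaining columns).
#' @param phenotype_path Delimited text with sample identifiers in the first
#'   column and the outcome in `outcome`.
#' @param orientation `"samples"` (samples in rows, canonical) or `"genes"`.
#' @param outcome Name of the outcome column in the phenotype file.
#' @param delim Field delimiter; `NULL` sniffs tab versus comma.
#' @param na_action Passed to [vim_dataset()].
#' @return A `vim_dataset`.
#' @export
read_dataset <- function(matrix_path, phenotype_path,
                         orientation = c("samples", "genes"), outcome = "y",
                         delim = NULL, na_action = "error") {
  orientation <- match.arg(orientation)
  mat <- read_delim_quiet(matrix_path, sniff_delim(matrix_path, delim))
  phe <- read_delim_quiet(phenotype_path, sniff_delim(phenotype_path, delim))
  if (ncol(phe) < 2L) abort("phenotype file needs id and outcome columns",
                            class = "tmlevim_input_error")
  if (!outcome %in% colnames(phe)) {
    abort(sprintf("outcome column '%s' not in phenotype file", outcome),
          class = "tmlevim_input_error")
  }
  row_ids <- as.character(mat[[1]])
  m <- as.matrix(mat[, -1, drop = FALSE])
  if (!is.numeric(m)) abort("non-numeric cells in the matrix file",
                            class = "tmlevim_input_error")
  if (orientation == "genes") {
    gene_ids <- row_ids
    sample_ids <- colnames(m)
    m <- t(m)
    colnames(m) <- gene_ids
    rownames(m) <- sample_ids
  } else {
    rownames(m) <- row_ids
  }
  samples <- rownames(m)
  if (anyDuplicated(samples)) {
    abort("duplicate sample identifiers in the matrix file",
          class = "tmlevim_input_error")
  }
  phe_ids <- as.character(phe[[1]])
  missing <- setdiff(samples, phe_ids)
  extra <- setdiff(phe_ids, samples)
  if (length(missing) || length(extra)) {
    abort(sprintf("sample mismatch between matrix and phenotype files%s%s",
                  if (length(missing)) paste0("; missing from phenotype: ",
                                              paste(missing, collapse = ", ")) else "",
                  if (length(extra)) paste0("; missing from matrix: ",
                                            paste(extra, collapse = ", ")) else ""),
          class = "tmlevim_input_error")
  }
  y <- as.numeric(phe[[outcome]][match(samples, phe_ids)])
  vim_dataset(m, outcome = y, na_action = na_action,
              provenance = sprintf("read_dataset('%s', '%s')", matrix_path, phenotype_path))
}

#' Write a simulated dataset to delimited files
#'
#' Writes the variable matrix (samples in rows, `sample` id column first), the
#' phenotype table, and — when truth flags exist — a `<prefix>_truth.tsv`
#' marking the causal variables. Each file starts with a comment header
#' recording the provenance and a config hash, sufficient to regenerate it.
#'
#' @param data A `vim_dataset`.
#' @param prefix Output path prefix; files are `<prefix>_matrix.tsv`,
#'   `<prefix>_phenotype.tsv`, `<prefix>_truth.tsv`.
#' @return Invisibly, the written paths.
#' @export
write_dataset <- function(data, prefix) {
  data <- as_vim_dataset(data)
  hdr <- output_header(data$provenance)
  sample <- sprintf("S%04d", seq_len(nrow(data$v)))
  paths <- c(matrix = paste0(prefix, "_matrix.tsv"),
             phenotype = paste0(prefix, "_phenotype.tsv"),
             truth = paste0(prefix, "_truth.tsv"))
  write_with_header(tibble::as_tibble(cbind(data.frame(sample = sample),
                                            as.data.frame(data$v))),
                    paths[["matrix"]], hdr)
  write_with_header(tibble::tibble(sample = sample, y = data$y),
                    paths[["phenotype"]], hdr)
  if (!is.null(data$truth)) {
    write_with_header(tibble::tibble(id = data$ids, causal = data$truth),
                      paths[["truth"]], hdr)
  } else {
    paths <- paths[1:2]
  }
  invisible(paths)
}

#' Write a variable-importance table to TSV
#'
#' Full-precision TSV, rows in rank order, preceded by comment headers
#' embedding the method, seed and config hash that produced it.
#'
#' @param table A `vim_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vim_table <- function(table, path) {
  tbl <- dplyr::arrange(tibble::as_tibble(table), .data$rank)
  hdr <- output_header(
    sprintf("method=%s seed=%s", attr(table, "vim_method") %||% "unknown",
            attr(table, "vim_seed") %||% "NA"),
    config = list(rule = attr(table, "vim_rule"), config = attr(table, "vim_config")))
  write_with_header(tbl, path, hdr)
  invisible(path)
}

#' Read back a variable-importance table
#'
#' @param path A TSV written by [write_vim_table()].
#' @return A `vim_table` tibble (header comments are skipped).
#' @export
read_vim_table <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  tbl$flag[is.na(tbl$flag)] <- ""
  structure(tbl, class = c("vim_table", class(tibble::tibble())))
}

#' Write a benchmark report to TSV
#'
#' One row per design and method (the replicate-averaged summary), with the
#' seed and config hash in comment headers.
#'
#' @param report A `vim_benchmark`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_benchmark <- function(report, path) {
  hdr <- output_header(sprintf("benchmark seed=%d p_threshold=%g",
                               report$seed, report$p_threshold))
  write_with_header(report$summary, path, hdr)
  invisible(path)
}

## ---- internals -------------------------------------------------------------

## 32-bit FNV-1a over the serialized object; enough to fingerprint a config
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

output_header <- function(note, config = NULL) {
  c(sprintf("# tmlevim %s", as.character(utils::packageVersion("tmlevim"))),
    sprintf("# %s", note),
    sprintf("# config_hash=%s", config_hash(list(note = note, config = config))))
}

write_with_header <- function(tbl, path, header) {
  writeLines(header, path)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE, progress = FALSE)
}
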