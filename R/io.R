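# Plain-text readers/writers: tab-separated tables with BED-style 0-based
# half-open coordinates, MTX expression, Newick trees.

#' Write per-cell binned counts as tab-separated files
#'
#' One file per cell (`<cell_id>.bins.tsv`) with columns `chrom`, `start`,
#' `end`, `gc`, `mappability`, `count`.
#' @param profiles Raw or corrected profile tibble.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_bins <- function(profiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- profiles |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_map(function(df, key) {
      p <- file.path(dir, paste0(key$cell_id, ".bins.tsv"))
      readr::write_tsv(
        df[, c("chrom", "start", "end", "gc", "mappability", "count")], p)
      p
    }) |>
    unlist()
  invisible(paths)
}

#' Read a directory (or files) of binned-count tables
#'
#' @param path Directory containing `*.bins.tsv` files, or a character
#'   vector of file paths. Cell ids are taken from file names.
#' @return A raw profile tibble suitable for [correct_profile()].
#' @export
read_bins <- function(path) {
  files <- if (length(path) == 1 && dir.exists(path)) {
    list.files(path, pattern = "\\.bins\\.tsv$", full.names = TRUE)
  } else path
  abort_if(length(files) == 0, "no .bins.tsv files found")
  purrr::map_dfr(files, function(f) {
    df <- readr::read_tsv(f, show_col_types = FALSE)
    df$cell_id <- sub("\\.bins\\.tsv$", "", basename(f))
    df[, c("cell_id", "chrom", "start", "end", "gc", "mappability", "count")]
  })
}

#' Write CNV calls as a BED-like tab-separated table
#' @param calls Call tibble from [call_cnvs()].
#' @param path Output file.
#' @export
write_calls <- function(calls, path) {
  readr::write_tsv(calls[, c("chrom", "start", "end", "cell_id", "direction",
                             "mean_log2_ratio", "scope")], path)
  invisible(path)
}

#' Read a BED-like CNV call table written by [write_calls()]
#' @param path Input file.
#' @return Call tibble with `size_bp` recomputed.
#' @export
read_calls <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE) |>
    dplyr::mutate(size_bp = .data$end - .data$start) |>
    dplyr::select("cell_id", "chrom", "start", "end", "direction", "size_bp",
                  "scope", "mean_log2_ratio")
}

#' Write an expression matrix as MatrixMarket + name files
#'
#' Writes `<prefix>.mtx`, `<prefix>.genes.txt`, `<prefix>.cells.txt`.
#' @param counts Genes x cells matrix.
#' @param prefix Path prefix.
#' @export
write_expression_mtx <- function(counts, prefix) {
  abort_if(!requireNamespace("Matrix", quietly = TRUE),
           "the Matrix package is required for MTX output")
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                  paste0(prefix, ".mtx"))
  writeLines(rownames(counts), paste0(prefix, ".genes.txt"))
  writeLines(colnames(counts), paste0(prefix, ".cells.txt"))
  invisible(prefix)
}

#' Read an expression matrix written by [write_expression_mtx()]
#' @param prefix Path prefix.
#' @return Dense genes x cells matrix with dimnames.
#' @export
read_expression_mtx <- function(prefix) {
  abort_if(!requireNamespace("Matrix", quietly = TRUE),
           "the Matrix package is required for MTX input")
  m <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  dimnames(m) <- list(readLines(paste0(prefix, ".genes.txt")),
                      readLines(paste0(prefix, ".cells.txt")))
  m
}
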