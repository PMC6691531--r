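#' Read an expression batch from disk
#'
#' Supports a dense CSV/TSV (genes x cells; first column gene IDs, header
#' cell IDs) or a Matrix Market directory containing `matrix.mtx`,
#' `genes.tsv` and `barcodes.tsv`. The stage is inferred (all nonnegative
#' integers -> `"counts"`, otherwise `"tpm"`) unless given.
#'
#' @param path file (csv/tsv) or directory (mtx triplet).
#' @param batch_id batch name; defaults to the file/directory name.
#' @param stage `"auto"` (default), `"counts"` or `"tpm"`.
#' @return an `expression_batch`.
#' @export
read_expression <- function(path, batch_id = NULL, stage = "auto") {
  if (is.null(batch_id))
    batch_id <- sub("\\.(csv|tsv)$", "", basename(path))
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    gf <- file.path(path, "genes.tsv")
    bf <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, gf, bf)) if (!file.exists(f))
      stop(sprintf("missing file '%s'", f), call. = FALSE)
    m <- tryCatch(as.matrix(Matrix::readMM(mtx)),
                  error = function(e)
                    stop(sprintf("malformed Matrix Market file '%s': %s",
                                 mtx, conditionMessage(e)), call. = FALSE))
    genes <- utils::read.table(gf, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    cells <- utils::read.table(bf, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    if (length(genes) != nrow(m))
      stop(sprintf("'%s': %d rows but %d gene IDs in genes.tsv", mtx,
                   nrow(m), length(genes)), call. = FALSE)
    if (length(cells) != ncol(m))
      stop(sprintf("'%s': %d columns but %d barcodes in barcodes.tsv", mtx,
                   ncol(m), length(cells)), call. = FALSE)
    dimnames(m) <- list(genes, cells)
  } else {
    if (!file.exists(path)) stop(sprintf("no such file '%s'", path),
                                 call. = FALSE)
    sep <- if (grepl("\\.tsv$", path)) "\t" else ","
    df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                            check.names = FALSE)
    m <- as.matrix(df)
  }
  if (stage == "auto")
    stage <- if (all(m >= 0) && all(m == round(m))) "counts" else "tpm"
  expression_batch(m, batch_id = batch_id, stage = stage)
}

#' Write an expression batch to disk
#'
#' @param batch an `expression_batch`.
#' @param path output file (`format = "csv"`/`"tsv"`) or directory
#'   (`format = "mtx"`, writing matrix.mtx + genes.tsv + barcodes.tsv).
#' @param format `"csv"`, `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(batch, path, format = c("csv", "tsv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(batch, "expression_batch"))
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(batch$values, sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    writeLines(batch$gene_ids, file.path(path, "genes.tsv"))
    writeLines(batch$cell_ids, file.path(path, "barcodes.tsv"))
  } else {
    sep <- if (format == "tsv") "\t" else ","
    df <- data.frame(gene_id = batch$gene_ids, batch$values,
                     check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write per-cell labels
#'
#' @param batches list of `expression_batch`.
#' @param path output TSV with columns cell_id, batch, cell_type.
#' @return `path`, invisibly.
#' @export
write_labels <- function(batches, path) {
  utils::write.table(batch_labels(batches), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read per-cell labels
#'
#' @param path TSV with columns cell_id, batch, cell_type.
#' @return tibble.
#' @export
read_labels <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE))
}
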