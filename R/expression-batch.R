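#' Construct an expression batch
#'
#' Container for one batch: a gene-by-cell expression matrix together with
#' gene/cell identifiers, a processing-stage tag and optional per-cell
#' cell-type labels. The stage tag tracks where the matrix sits in the
#' preprocessing chain and is checked by every downstream operation.
#'
#' @param values numeric matrix, genes in rows, cells in columns.
#' @param batch_id single string naming the batch.
#' @param gene_ids character vector, one per row. Defaults to rownames.
#' @param cell_ids character vector, one per column. Defaults to colnames.
#' @param stage one of `"counts"`, `"tpm"`, `"log"`, `"standardized"`,
#'   `"scaled"`.
#' @param cell_type_labels optional character/factor vector of per-cell type
#'   labels (used only for evaluation and removal experiments).
#'
#' @return An object of class `expression_batch`.
#' @export
expression_batch <- function(values, batch_id, gene_ids = rownames(values),
                             cell_ids = colnames(values), stage = "counts",
                             cell_type_labels = NULL) {
  stage <- match.arg(stage, c("counts", "tpm", "log", "standardized", "scaled"))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values))
    stop("length(gene_ids) must equal nrow(values)", call. = FALSE)
  if (length(cell_ids) != ncol(values))
    stop("length(cell_ids) must equal ncol(values)", call. = FALSE)
  if (!is.null(cell_type_labels)) {
    cell_type_labels <- as.character(cell_type_labels)
    if (length(cell_type_labels) != ncol(values))
      stop("cell_type_labels must have one entry per cell", call. = FALSE)
  }
  if (stage == "counts") {
    if (any(values < 0) || any(values != round(values)))
      stop("stage 'counts' requires nonnegative integer values", call. = FALSE)
  }
  if (stage == "scaled" && (any(values < -1e-9) || any(values > 1 + 1e-9)))
    stop("stage 'scaled' requires values in [0, 1]", call. = FALSE)
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(
    list(batch_id = as.character(batch_id), gene_ids = gene_ids,
         cell_ids = cell_ids, values = values, stage = stage,
         cell_type_labels = cell_type_labels),
    class = "expression_batch"
  )
}

#' @export
print.expression_batch <- function(x, ...) {
  cat(sprintf("<expression_batch> '%s': %d genes x %d cells, stage = %s%s\n",
              x$batch_id, nrow(x$values), ncol(x$values), x$stage,
              if (is.null(x$cell_type_labels)) "" else
                sprintf(", %d cell types", length(unique(x$cell_type_labels)))))
  invisible(x)
}

#' @export
dim.expression_batch <- function(x) dim(x$values)

n_cells <- function(batch) ncol(batch$values)

stopifnot_stage <- function(batch, stage, op) {
  if (!identical(batch$stage, stage))
    stop(sprintf("%s() expects stage '%s', got '%s'", op, stage, batch$stage),
         call. = FALSE)
}

check_batch_list <- function(batches) {
  if (length(batches) == 0) stop("empty batch list", call. = FALSE)
  if (!all(vapply(batches, inherits, logical(1), "expression_batch")))
    stop("all elements must be expression_batch objects", call. = FALSE)
  g <- batches[[1]]$gene_ids
  for (b in batches[-1])
    if (!identical(b$gene_ids, g))
      stop("all batches must share the same gene ID list", call. = FALSE)
  invisible(batches)
}

#' Per-cell label table for a list of batches
#'
#' @param batches list of `expression_batch`.
#' @return A tibble with columns `cell_id`, `batch`, `cell_type` (NA when a
#'   batch carries no labels).
#' @export
batch_labels <- function(batches) {
  check_batch_list(batches)
  purrr::map_dfr(batches, function(b) {
    tibble::tibble(
      cell_id = b$cell_ids, batch = b$batch_id,
      cell_type = if (is.null(b$cell_type_labels)) NA_character_
                  else b$cell_type_labels)
  })
}
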