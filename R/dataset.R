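#' Bundle a UMI count matrix with its cell and gene metadata
#'
#' The package's central container: a sparse genes-by-cells matrix of raw UMI
#' counts plus a cell metadata tibble and a gene metadata tibble. Downstream
#' stages (QC, normalisation, noise, differential expression, scoring) consume
#' and return these bundles or plain tibbles derived from them.
#'
#' @param counts A genes-by-cells matrix of non-negative integer UMI counts;
#'   coerced to a sparse `dgCMatrix`. Row names are gene names, column names
#'   cell barcodes (generated when absent).
#' @param cells Tibble of per-cell metadata, one row per column of `counts`.
#'   Must contain a `cell` column matching `colnames(counts)`; typical columns
#'   are `sample`, `age` (`"young"`/`"old"`) and `cell_type`.
#' @param genes Tibble of per-gene metadata, one row per row of `counts`, with
#'   a `gene` column matching `rownames(counts)` and a logical `mito` flag.
#'   When `NULL`, mitochondrial genes are flagged by the `"MT-"` name prefix.
#' @param provenance Optional named list recording how the bundle was made
#'   (input paths, config hash, seed); carried through the pipeline.
#'
#' @return A `muscle_dataset` object: a list with elements `counts`, `cells`,
#'   `genes`, `provenance` and (after [normalize_counts()]) `lognorm`.
#' @export
#' @examples
#' m <- Matrix::rsparsematrix(20, 10, density = 0.3,
#'                            rand.x = function(n) rpois(n, 2) + 1)
#' rownames(m) <- paste0("G", 1:20)
#' ds <- muscle_dataset(m)
muscle_dataset <- function(counts, cells = NULL, genes = NULL,
                           provenance = list()) {
  counts <- as(as(as(counts, "dMatrix"), "CsparseMatrix"), "generalMatrix")
  if (any(counts@x < 0)) abort("counts must be non-negative")
  if (any(counts@x != round(counts@x))) {
    abort("non-integer counts: the raw layer must hold integer UMI counts")
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("G%04d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("cell%05d", seq_len(ncol(counts)))
  }
  if (is.null(cells)) cells <- tibble(cell = colnames(counts))
  cells <- as_tibble(cells)
  if (!"cell" %in% names(cells)) abort("cell metadata needs a 'cell' column")
  if (nrow(cells) != ncol(counts)) {
    abort(sprintf("dimension mismatch: %d cells in matrix, %d metadata rows",
                  ncol(counts), nrow(cells)))
  }
  if (!identical(as.character(cells$cell), colnames(counts))) {
    abort("cell metadata rows must match matrix columns (same order)")
  }
  if (is.null(genes)) {
    genes <- tibble(gene = rownames(counts),
                    mito = startsWith(rownames(counts), "MT-"))
  }
  genes <- as_tibble(genes)
  if (!"gene" %in% names(genes)) abort("gene metadata needs a 'gene' column")
  if (nrow(genes) != nrow(counts) ||
      !identical(as.character(genes$gene), rownames(counts))) {
    abort("gene metadata rows must match matrix rows (same order)")
  }
  if (!"mito" %in% names(genes)) {
    genes$mito <- startsWith(genes$gene, "MT-")
  }
  structure(
    list(counts = counts, cells = cells, genes = genes,
         provenance = provenance),
    class = "muscle_dataset"
  )
}

#' @export
print.muscle_dataset <- function(x, ...) {
  cat(sprintf("<muscle_dataset> %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  if ("age" %in% names(x$cells)) {
    tab <- table(x$cells$age)
    cat("  age groups:", paste(sprintf("%s=%d", names(tab), tab),
                               collapse = ", "), "\n")
  }
  if ("cell_type" %in% names(x$cells)) {
    cat("  cell types:", paste(sort(unique(x$cells$cell_type)),
                               collapse = ", "), "\n")
  }
  cat(sprintf("  mito genes: %d; normalized layer: %s\n",
              sum(x$genes$mito), if (is.null(x$lognorm)) "absent" else "present"))
  invisible(x)
}

#' @export
dim.muscle_dataset <- function(x) dim(x$counts)

#' Subset a dataset bundle to a set of cells
#'
#' @param x A [muscle_dataset()].
#' @param cells Character vector of cell barcodes, or logical/integer index
#'   over columns.
#' @return A `muscle_dataset` restricted to those cells, original order
#'   preserved; the normalized layer (if present) is subset alongside.
#' @export
subset_cells <- function(x, cells) {
  stopifnot(is(x, "muscle_dataset"))
  idx <- if (is.character(cells)) {
    match(cells, colnames(x$counts))
  } else if (is.logical(cells)) {
    which(cells)
  } else {
    as.integer(cells)
  }
  if (anyNA(idx)) abort("unknown cell barcodes in subset")
  idx <- sort(idx) # keep original column order
  out <- x
  out$counts <- x$counts[, idx, drop = FALSE]
  out$cells <- x$cells[idx, , drop = FALSE]
  if (!is.null(x$lognorm)) out$lognorm <- x$lognorm[, idx, drop = FALSE]
  out
}

# derive a reproducible per-stage seed from the user's single seed; offsets
# are fixed per stage so stages are independent but the whole run is a pure
# function of one integer
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, qc = 211L, noise = 307L, deg = 401L,
               score = 503L, hubs = 601L, regulons = 701L)
  if (!stage %in% names(offsets)) abort(paste("unknown stage:", stage))
  (as.integer(seed) %% 2000000L) * 1000L + offsets[[stage]]
}
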