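#' Per-nucleus quality-control metrics
#'
#' Computes, for every cell, the number of detected genes (count > 0), the
#' total UMI count and the mitochondrial UMI fraction (mito UMIs / total
#' UMIs). Cells with zero total get mito fraction 0 and a `degenerate` flag
#' rather than NaN; nothing is dropped here — see [filter_cells()].
#'
#' @param x A [muscle_dataset()] whose gene metadata carries a logical `mito`
#'   column (set up by default from the `MT-` name prefix).
#' @return The cell metadata tibble with columns `n_detected_genes`,
#'   `total_umis`, `mito_fraction` and `degenerate` appended (replacing any
#'   previous QC columns).
#' @export
#' @examples
#' sim <- simulate_dataset(simulation_config(cells_per_sample = 20))
#' compute_cell_qc(sim$dataset)
compute_cell_qc <- function(x) {
  stopifnot(is(x, "muscle_dataset"))
  if (!"mito" %in% names(x$genes)) abort("gene metadata lacks a 'mito' flag")
  total <- Matrix::colSums(x$counts)
  detected <- Matrix::colSums(x$counts > 0)
  mito_tot <- if (any(x$genes$mito)) {
    Matrix::colSums(x$counts[x$genes$mito, , drop = FALSE])
  } else {
    rep(0, ncol(x$counts))
  }
  degenerate <- total == 0
  if (any(degenerate)) {
    warn(sprintf("%d cell(s) have zero total UMIs; mito_fraction set to 0",
                 sum(degenerate)))
  }
  qc <- tibble(
    cell = colnames(x$counts),
    n_detected_genes = as.integer(detected),
    total_umis = as.numeric(total),
    mito_fraction = unname(ifelse(degenerate, 0, mito_tot / pmax(total, 1))),
    degenerate = unname(degenerate)
  )
  meta <- x$cells[, setdiff(names(x$cells), names(qc)[-1]), drop = FALSE]
  left_join(meta, qc, by = "cell")
}

#' Quality-control thresholds for nucleus filtering
#'
#' Discarding uses strict inequalities, matching "fewer than 200 genes" and
#' "mitochondrial ratio more than 1%": a cell is removed when
#' `n_detected_genes < min_genes` or `mito_fraction > max_mito`, so boundary
#' cells are retained.
#'
#' @param min_genes Minimum detected genes per nucleus (default 200).
#' @param max_mito Maximum mitochondrial UMI fraction (default 0.01).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_genes = 200L, max_mito = 0.01) {
  if (min_genes < 0) abort("min_genes must be >= 0")
  if (max_mito < 0 || max_mito > 1) abort("max_mito must lie in [0,1]")
  structure(list(min_genes = as.integer(min_genes), max_mito = max_mito),
            class = "qc_thresholds")
}

#' Filter nuclei on QC thresholds
#'
#' Retains cells with at least `min_genes` detected genes and mitochondrial
#' fraction at most `max_mito`; cell order is preserved and retained counts
#' are untouched, making the filter idempotent. The numbers removed by each
#' criterion are reported and recorded in the bundle's provenance.
#'
#' @param x A [muscle_dataset()].
#' @param thresholds A [qc_thresholds()].
#' @param verbose Print the per-criterion removal counts.
#' @return The filtered `muscle_dataset`, with the QC columns joined into its
#'   cell metadata.
#' @export
filter_cells <- function(x, thresholds = qc_thresholds(), verbose = TRUE) {
  stopifnot(is(x, "muscle_dataset"), is(thresholds, "qc_thresholds"))
  qc <- suppressWarnings(compute_cell_qc(x))
  low_genes <- qc$n_detected_genes < thresholds$min_genes
  high_mito <- qc$mito_fraction > thresholds$max_mito
  keep <- !(low_genes | high_mito)
  if (!any(keep)) abort("no cells survive QC filtering")
  log <- list(n_input = length(keep),
              removed_low_genes = sum(low_genes),
              removed_high_mito = sum(high_mito),
              n_retained = sum(keep))
  if (verbose) {
    message(sprintf(
      "filter_cells: %d cells in; %d below %d genes, %d above mito %.3g; %d retained",
      log$n_input, log$removed_low_genes, thresholds$min_genes,
      log$removed_high_mito, thresholds$max_mito, log$n_retained))
  }
  out <- x
  out$cells <- qc
  out <- subset_cells(out, which(keep))
  out$provenance$qc <- c(list(thresholds = unclass(thresholds)), log)
  out
}

#' Library-size normalisation (log counts-per-`scale`)
#'
#' Adds a normalized expression layer: each count is scaled to
#' `count * scale / total` within its cell and transformed with `log1p`. The
#' sparsity pattern is unchanged (zeros map to zero) and the transform is
#' monotone within a cell. Downstream statistics — rank-sum tests, centroid
#' distances, module scores — only need such a monotone, library-size
#' corrected layer.
#'
#' @param x A [muscle_dataset()]; all retained cells must have total > 0
#'   (filter first).
#' @param scale Target library size (default 1e4, i.e. counts per 10k).
#' @return The dataset with a sparse `lognorm` layer added.
#' @export
normalize_counts <- function(x, scale = 1e4) {
  stopifnot(is(x, "muscle_dataset"))
  totals <- Matrix::colSums(x$counts)
  if (any(totals == 0)) {
    abort("zero-total cell encountered; run filter_cells() first")
  }
  m <- x$counts
  m@x <- log1p(m@x * scale / rep.int(totals, diff(m@p)))
  x$lognorm <- m
  x
}

# fetch an expression layer by name
get_layer <- function(x, layer = c("lognorm", "raw")) {
  layer <- match.arg(layer)
  if (layer == "raw") return(x$counts)
  if (is.null(x$lognorm)) abort("no normalized layer; run normalize_counts()")
  x$lognorm
}
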