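# fixture builders shared across test files

# tiny hand-specified dataset: rows genes, cols cells
toy_dataset <- function(mat, gene_names = NULL, cells = NULL) {
  if (is.null(gene_names)) gene_names <- rownames(mat)
  rownames(mat) <- gene_names
  if (is.null(colnames(mat))) {
    colnames(mat) <- sprintf("c%02d", seq_len(ncol(mat)))
  }
  if (!is.null(cells)) cells$cell <- colnames(mat)
  muscle_dataset(Matrix::Matrix(mat, sparse = TRUE), cells = cells)
}

# default null simulation, QC-filtered and normalized
null_normalized <- function(seed = 1L, ...) {
  sim <- simulate_dataset(simulation_config(seed = seed, ...))
  # permissive thresholds: small fixture gene counts sit below the
  # production min_genes default, and QC behaviour is tested separately
  normalize_counts(filter_cells(sim$dataset, qc_thresholds(0L, 1),
                                verbose = FALSE))
}

# randomized DEG table over a gene and cell-type universe, for the
# aggregation oracles
random_deg_table <- function(n_genes = 30L, n_celltypes = 8L, seed = 1L,
                             sig_rate = 0.3) {
  withr::with_seed(seed, {
    tab <- tidyr::expand_grid(gene = sprintf("g%02d", seq_len(n_genes)),
                              cell_type = sprintf("ct%02d", seq_len(n_celltypes)))
    tab$log_fc <- stats::rnorm(nrow(tab), 0, 0.6)
    tab$p_value <- stats::runif(nrow(tab))
    tab$adj_p <- pmin(1, tab$p_value * 1.5)
    tab$direction <- ifelse(tab$log_fc > 0, "up", "down")
    tab$significant <- stats::runif(nrow(tab)) < sig_rate
    class(tab) <- c("deg_table", class(tab))
    tab
  })
}
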