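#' Configure a synthetic multi-sample snRNA-seq simulation
#'
#' Builds the parameter set for [simulate_dataset()]. The generative model is
#' negative binomial per gene and cell: the mean is a per-gene lognormal
#' baseline times a cell-type program factor, a per-sample lognormal factor,
#' a per-cell lognormal library factor and, for old cells of affected
#' (gene, cell type) pairs, an age fold change; the dispersion is theta
#' (variance mu + mu^2/theta), divided by an age multiplier for old cells of
#' noise-affected cell types so that variance is inflated without moving the
#' mean. Defaults are desk scale: 4 young + 4 old samples, 150 nuclei per
#' sample, 1,000 genes, 3 cell types.
#'
#' @param n_young_samples,n_old_samples Number of young / old animals.
#' @param cells_per_sample Nuclei captured per animal.
#' @param n_genes Number of genes (including mitochondrial).
#' @param cell_types Named numeric vector of mixing proportions (sum to 1).
#' @param base_mean_log_mu,base_mean_log_sigma Lognormal parameters of the
#'   per-gene baseline mean (per-cell expected counts at unit factors).
#' @param dispersion NB dispersion theta, scalar or length `n_genes`.
#' @param celltype_program_size,celltype_program_fc Number of genes up-shifted
#'   in each cell type and their fold factor (marker-gene structure).
#' @param libsize_log_sigma Lognormal sd of per-cell library factors.
#' @param sample_effect_log_sigma Lognormal sd of per-sample factors
#'   (gene-independent, so a null configuration stays group-exchangeable).
#' @param age_de Tibble/data frame of old-cell mean effects with columns
#'   `cell_type`, `gene` (integer index) and `fold_change` (> 0; < 1 means
#'   down in old). Empty for a null simulation.
#' @param age_dispersion Tibble/data frame of old-cell dispersion inflation
#'   with columns `cell_type` and `multiplier` (>= 1); theta is divided by
#'   the multiplier for old cells of that type.
#' @param mito_fraction_genes Proportion of genes flagged mitochondrial
#'   (named with the `MT-` prefix, placed last).
#' @param mito_mean_multiplier Baseline-mean multiplier for mitochondrial
#'   genes. Below 1 by default: nuclei carry little mitochondrial RNA, and
#'   the QC filter discards nuclei above a small mito fraction.
#' @param baseline_mean_override Optional tibble (`gene` index, `mean`) pinning
#'   chosen genes' baseline means, e.g. to make designated ground-truth genes
#'   well expressed in recovery studies.
#' @param keep_model_means Also return the dense per-gene, per-cell model
#'   mean and variance matrices in the truth (for generator validation;
#'   memory-heavy at scale).
#' @param seed Integer seed; the whole simulation is a pure function of the
#'   config including this seed.
#'
#' @return A `simulation_config` (validated named list).
#' @export
simulation_config <- function(n_young_samples = 4L,
                              n_old_samples = 4L,
                              cells_per_sample = 150L,
                              n_genes = 1000L,
                              cell_types = c("FastIIA" = 0.45,
                                             "FastIIX" = 0.35,
                                             "SlowI"   = 0.20),
                              base_mean_log_mu = -1,
                              base_mean_log_sigma = 1,
                              dispersion = 2,
                              celltype_program_size = 25L,
                              celltype_program_fc = 3,
                              libsize_log_sigma = 0.3,
                              sample_effect_log_sigma = 0.15,
                              age_de = NULL,
                              age_dispersion = NULL,
                              mito_fraction_genes = 0.015,
                              mito_mean_multiplier = 0.25,
                              baseline_mean_override = NULL,
                              keep_model_means = FALSE,
                              seed = 1L) {
  cfg <- list(
    n_young_samples = as.integer(n_young_samples),
    n_old_samples = as.integer(n_old_samples),
    cells_per_sample = as.integer(cells_per_sample),
    n_genes = as.integer(n_genes),
    cell_types = cell_types,
    base_mean_log_mu = base_mean_log_mu,
    base_mean_log_sigma = base_mean_log_sigma,
    dispersion = dispersion,
    celltype_program_size = as.integer(celltype_program_size),
    celltype_program_fc = celltype_program_fc,
    libsize_log_sigma = libsize_log_sigma,
    sample_effect_log_sigma = sample_effect_log_sigma,
    age_de = if (is.null(age_de)) {
      tibble(cell_type = character(), gene = integer(),
             fold_change = double())
    } else as_tibble(age_de),
    age_dispersion = if (is.null(age_dispersion)) {
      tibble(cell_type = character(), multiplier = double())
    } else as_tibble(age_dispersion),
    mito_fraction_genes = mito_fraction_genes,
    mito_mean_multiplier = mito_mean_multiplier,
    baseline_mean_override = if (is.null(baseline_mean_override)) {
      tibble(gene = integer(), mean = double())
    } else as_tibble(baseline_mean_override),
    keep_model_means = isTRUE(keep_model_means),
    seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    if (n_young_samples < 1L || n_old_samples < 1L || cells_per_sample < 1L ||
        n_genes < 1L) {
      abort("all sample/cell/gene counts must be positive")
    }
    if (is.null(names(cell_types)) || any(!nzchar(names(cell_types)))) {
      abort("cell_types must be a named proportion vector")
    }
    if (any(cell_types <= 0) || any(cell_types > 1) ||
        abs(sum(cell_types) - 1) > 1e-9) {
      abort("cell-type proportions must lie in (0,1] and sum to 1")
    }
    n_cells <- (n_young_samples + n_old_samples) * cells_per_sample
    if (any(cell_types * n_cells < 1)) {
      abort("config rejected: a cell type has expected cell count < 1")
    }
    if (any(dispersion <= 0)) abort("dispersion theta must be > 0")
    if (!length(dispersion) %in% c(1L, n_genes)) {
      abort("dispersion must be scalar or one value per gene")
    }
    if (nrow(age_de)) {
      if (!all(c("cell_type", "gene", "fold_change") %in% names(age_de))) {
        abort("age_de needs columns cell_type, gene, fold_change")
      }
      if (any(age_de$fold_change <= 0)) abort("fold changes must be > 0")
      if (any(age_de$gene < 1 | age_de$gene > n_genes)) {
        abort("age_de gene index out of range")
      }
      if (anyDuplicated(age_de[, c("cell_type", "gene")])) {
        abort("contradictory age_de: duplicate (gene, cell_type) entries")
      }
      if (!all(age_de$cell_type %in% names(cell_types))) {
        abort("age_de refers to an unknown cell type")
      }
    }
    if (nrow(age_dispersion)) {
      if (any(age_dispersion$multiplier < 1)) {
        abort("age dispersion multipliers must be >= 1")
      }
      if (!all(age_dispersion$cell_type %in% names(cell_types))) {
        abort("age_dispersion refers to an unknown cell type")
      }
      if (anyDuplicated(age_dispersion$cell_type)) {
        abort("duplicate cell type in age_dispersion")
      }
    }
    if (mito_fraction_genes < 0 || mito_fraction_genes >= 1) {
      abort("mito_fraction_genes must lie in [0,1)")
    }
  })
  invisible(cfg)
}

#' Simulate a multi-sample, multi-cell-type UMI count dataset
#'
#' Draws a negative-binomial genes-by-cells count matrix under the model
#' described in [simulation_config()], together with the ground truth needed
#' to test downstream stages: the table of true old-cell expression effects,
#' the cell types carrying dispersion (noise) inflation, and every cell's true
#' labels. Identical configs (including seed) give bit-identical output.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `dataset` (a [muscle_dataset()]) and `truth`
#'   (list: `true_de`, `true_noise`, `cells`, `genes`, `gene_means`).
#' @export
#' @examples
#' sim <- simulate_dataset(simulation_config(cells_per_sample = 30, seed = 7))
#' sim$dataset
simulate_dataset <- function(config) {
  if (!inherits(config, "simulation_config")) {
    config <- do.call(simulation_config, as.list(config))
  }
  validate_simulation_config(config)
  withr::with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  n_mito <- round(cfg$n_genes * cfg$mito_fraction_genes)
  n_plain <- cfg$n_genes - n_mito
  gene_names <- c(sprintf("G%04d", seq_len(n_plain)),
                  if (n_mito > 0) sprintf("MT-G%04d", seq_len(n_mito)))
  types <- names(cfg$cell_types)

  # per-gene baseline means and dispersions (RNG order is fixed)
  base_mean <- rlnorm(cfg$n_genes, cfg$base_mean_log_mu, cfg$base_mean_log_sigma)
  if (n_mito > 0) {
    base_mean[(n_plain + 1):cfg$n_genes] <-
      base_mean[(n_plain + 1):cfg$n_genes] * cfg$mito_mean_multiplier
  }
  if (nrow(cfg$baseline_mean_override)) {
    base_mean[cfg$baseline_mean_override$gene] <- cfg$baseline_mean_override$mean
  }
  theta <- rep_len(cfg$dispersion, cfg$n_genes)

  # cell-type programs: marker genes up-shifted per type
  prog <- matrix(1, cfg$n_genes, length(types), dimnames = list(NULL, types))
  for (ct in types) {
    if (cfg$celltype_program_size > 0) {
      idx <- sample.int(cfg$n_genes, min(cfg$celltype_program_size, cfg$n_genes))
      prog[idx, ct] <- cfg$celltype_program_fc
    }
  }

  samples <- tibble(
    sample = c(sprintf("Y%02d", seq_len(cfg$n_young_samples)),
               sprintf("O%02d", seq_len(cfg$n_old_samples))),
    age = rep(c("young", "old"), c(cfg$n_young_samples, cfg$n_old_samples)),
    sample_factor = rlnorm(cfg$n_young_samples + cfg$n_old_samples,
                           0, cfg$sample_effect_log_sigma)
  )
  n_cells <- nrow(samples) * cfg$cells_per_sample
  cells <- tibble(
    cell = sprintf("cell%05d", seq_len(n_cells)),
    sample = rep(samples$sample, each = cfg$cells_per_sample),
    age = rep(samples$age, each = cfg$cells_per_sample),
    cell_type = sample(types, n_cells, replace = TRUE, prob = cfg$cell_types),
    lib_factor = rlnorm(n_cells, 0, cfg$libsize_log_sigma)
  )

  # old-cell mean fold changes per (gene, type)
  age_fc <- matrix(1, cfg$n_genes, length(types), dimnames = list(NULL, types))
  if (nrow(cfg$age_de)) {
    for (i in seq_len(nrow(cfg$age_de))) {
      age_fc[cfg$age_de$gene[i], cfg$age_de$cell_type[i]] <-
        cfg$age_de$fold_change[i]
    }
  }
  disp_mult <- setNames(rep(1, length(types)), types)
  if (nrow(cfg$age_dispersion)) {
    disp_mult[cfg$age_dispersion$cell_type] <- cfg$age_dispersion$multiplier
  }

  sf <- setNames(samples$sample_factor, samples$sample)
  ii <- vector("list", n_cells); xx <- vector("list", n_cells)
  mu_mat <- var_mat <- NULL
  if (cfg$keep_model_means) {
    mu_mat <- var_mat <- matrix(0, cfg$n_genes, n_cells)
  }
  for (j in seq_len(n_cells)) {
    ct <- cells$cell_type[j]
    mu <- base_mean * prog[, ct] * sf[[cells$sample[j]]] * cells$lib_factor[j]
    th <- theta
    if (cells$age[j] == "old") {
      mu <- mu * age_fc[, ct]
      if (disp_mult[[ct]] > 1) th <- theta / disp_mult[[ct]]
    }
    if (cfg$keep_model_means) {
      mu_mat[, j] <- mu
      var_mat[, j] <- mu + mu^2 / th
    }
    cnt <- rnbinom(cfg$n_genes, size = th, mu = mu)
    nz <- which(cnt > 0L)
    ii[[j]] <- nz
    xx[[j]] <- cnt[nz]
  }
  counts <- Matrix::sparseMatrix(
    i = unlist(ii), j = rep.int(seq_len(n_cells), lengths(ii)),
    x = unlist(xx), dims = c(cfg$n_genes, n_cells),
    dimnames = list(gene_names, cells$cell)
  )

  genes <- tibble(gene = gene_names,
                  mito = startsWith(gene_names, "MT-"),
                  base_mean = base_mean)
  cell_meta <- cells[, c("cell", "sample", "age", "cell_type")]
  ds <- muscle_dataset(counts, cells = cell_meta, genes = genes,
                       provenance = list(source = "simulate_dataset",
                                         seed = cfg$seed))
  truth <- list(
    true_de = if (nrow(cfg$age_de)) {
      tibble(gene = gene_names[cfg$age_de$gene],
             cell_type = cfg$age_de$cell_type,
             fold_change = cfg$age_de$fold_change,
             direction = ifelse(cfg$age_de$fold_change > 1, "up", "down"))
    } else {
      tibble(gene = character(), cell_type = character(),
             fold_change = double(), direction = character())
    },
    true_noise = as_tibble(cfg$age_dispersion),
    cells = cell_meta,
    genes = gene_names,
    gene_means = base_mean,
    model_mean = mu_mat,
    model_var = var_mat
  )
  list(dataset = ds, truth = truth)
}

#' Simulate a TF-to-target regulon map consistent with a ground truth
#'
#' Draws a transcription-factor regulon map over the simulated gene universe.
#' When `hub_tf_spec` is supplied, one designated TF is wired as a hub: its
#' own transcript and a stated fraction of its targets are chosen from genes
#' that the ground truth marks as differentially expressed (default: down) in
#' the specified cell types — the configuration produced by
#' [hub_simulation_config()] guarantees such genes exist.
#'
#' @param truth The `truth` element returned by [simulate_dataset()].
#' @param n_tfs Number of transcription factors in the map.
#' @param targets_per_tf Targets drawn for each TF.
#' @param hub_tf_spec Optional list with elements `cell_types` (character),
#'   `direction` (`"down"` or `"up"`, default down) and `target_fraction`
#'   (fraction of the hub's targets taken from true DE genes; default 0.5).
#' @param seed Integer seed for the draws.
#' @return Named list mapping TF gene name to a character vector of targets;
#'   the designated hub TF (if any) is recorded in attribute `"hub_tf"`.
#' @export
simulate_regulons <- function(truth, n_tfs, targets_per_tf,
                              hub_tf_spec = NULL, seed = 1L) {
  genes <- truth$genes
  if (targets_per_tf >= length(genes)) {
    abort("targets_per_tf exceeds the simulated gene count")
  }
  if (n_tfs == 0L) {
    out <- setNames(list(), character())
    attr(out, "hub_tf") <- NULL
    return(out)
  }
  withr::with_seed(seed, {
    hub_tf <- NULL
    hub_targets <- NULL
    if (!is.null(hub_tf_spec)) {
      dir <- hub_tf_spec$direction %||% "down"
      frac <- hub_tf_spec$target_fraction %||% 0.5
      cts <- hub_tf_spec$cell_types
      de <- dplyr::filter(truth$true_de, .data$direction == dir,
                          .data$cell_type %in% cts)
      cover <- dplyr::summarise(dplyr::group_by(de, .data$gene),
                                n_ct = dplyr::n_distinct(.data$cell_type))
      candidates <- cover$gene[cover$n_ct == length(cts)]
      if (!length(candidates)) {
        abort(paste("no gene is true", dir, "DE in all requested cell types;",
                    "build the dataset with hub_simulation_config()"))
      }
      hub_tf <- sort(candidates)[1]
      de_pool <- setdiff(sort(candidates), hub_tf)
      n_de <- min(length(de_pool), round(frac * targets_per_tf))
      rest_pool <- setdiff(genes, c(hub_tf, de_pool))
      hub_targets <- c(
        if (n_de > 0) sample(de_pool, n_de),
        sample(rest_pool, targets_per_tf - n_de)
      )
    }
    other_pool <- setdiff(genes, hub_tf)
    tf_names <- sample(other_pool, n_tfs - !is.null(hub_tf))
    regs <- lapply(tf_names, function(tf) {
      sample(setdiff(genes, tf), targets_per_tf)
    })
    names(regs) <- tf_names
    if (!is.null(hub_tf)) {
      regs <- c(setNames(list(hub_targets), hub_tf), regs)
    }
    regs <- regs[order(names(regs))]
    attr(regs, "hub_tf") <- hub_tf
    regs
  })
}

#' Configure a simulation with a designated hub transcription factor
#'
#' Convenience wrapper around [simulation_config()] for hub-recovery studies:
#' one well-expressed gene (the hub TF transcript) and a block of
#' well-expressed target genes are down-regulated in old cells of
#' `n_hub_cell_types` cell types, so that [simulate_regulons()] can wire a
#' regulon map in which that TF's own gene and targets are true down DEGs.
#'
#' @param n_hub_cell_types Number of cell types carrying the down effects.
#' @param n_hub_targets Number of down-regulated target genes.
#' @param hub_fold_change Old/young mean fold change (< 1).
#' @param hub_gene_mean Baseline mean pinned for the hub TF and target genes,
#'   keeping the designated genes detectable at desk scale.
#' @param ... Passed to [simulation_config()]; `cell_types` defaults to six
#'   muscle populations.
#' @return A `simulation_config`.
#' @export
hub_simulation_config <- function(n_hub_cell_types = 6L,
                                  n_hub_targets = 20L,
                                  hub_fold_change = 0.25,
                                  hub_gene_mean = 4,
                                  ...) {
  dots <- list(...)
  if (is.null(dots$cell_types)) {
    dots$cell_types <- c("FastIIA" = 0.22, "FastIIX" = 0.20, "SlowI" = 0.18,
                         "PMF" = 0.15, "MuSC" = 0.13, "EC" = 0.12)
  }
  if (length(dots$cell_types) < n_hub_cell_types) {
    abort("need at least n_hub_cell_types cell types")
  }
  hub_cts <- names(dots$cell_types)[seq_len(n_hub_cell_types)]
  hub_genes <- seq_len(n_hub_targets + 1L)  # gene 1 = hub TF transcript
  dots$age_de <- tidyr::expand_grid(cell_type = hub_cts, gene = hub_genes) |>
    mutate(fold_change = hub_fold_change)
  dots$baseline_mean_override <-
    tibble(gene = hub_genes, mean = hub_gene_mean)
  do.call(simulation_config, dots)
}
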