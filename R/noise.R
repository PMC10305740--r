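#' Equalise library sizes by exact UMI down-sampling
#'
#' Every cell's UMIs are sub-sampled without replacement (multivariate
#' hypergeometric) down to a common target, so that after the operation each
#' cell's total equals the target exactly and no per-gene count increases.
#' Cells already at the target are returned unchanged. This removes library
#' size as a source of apparent cell-to-cell variability before distances are
#' computed.
#'
#' @param x A [muscle_dataset()].
#' @param target Target library size; defaults to the minimum cell total in
#'   `x`. Must not exceed any cell's total.
#' @param seed Integer seed for the sub-sampling draws.
#' @return The dataset with down-sampled counts (any normalized layer is
#'   dropped, as it no longer matches the raw layer).
#' @export
downsample_library <- function(x, target = NULL, seed = 1L) {
  stopifnot(is(x, "muscle_dataset"))
  totals <- Matrix::colSums(x$counts)
  if (is.null(target)) target <- min(totals)
  target <- as.integer(target)
  if (target < 0) abort("target must be non-negative")
  short <- which(totals < target)
  if (length(short)) {
    abort(sprintf(
      "target %d exceeds the library size (%d) of cell '%s'%s",
      target, totals[short[1]], colnames(x$counts)[short[1]],
      if (length(short) > 1) sprintf(" and %d more", length(short) - 1) else ""))
  }
  m <- x$counts
  withr::with_seed(seed, {
    p <- m@p
    newx <- m@x
    for (j in seq_len(ncol(m))) {
      if (totals[j] == target) next
      sel <- (p[j] + 1L):p[j + 1L]
      cnt <- m@x[sel]
      cum <- cumsum(cnt)
      pos <- sample.int(totals[j], target)           # UMIs kept, as positions
      slot <- findInterval(pos - 0.5, c(0, cum))     # map position -> gene slot
      newx[sel] <- tabulate(slot, nbins = length(sel))
    }
    m@x <- newx
  })
  m <- Matrix::drop0(m)
  out <- x
  out$counts <- m
  out$lognorm <- NULL
  out$provenance$downsample <- list(target = target, seed = seed)
  out
}

#' Balance young and old cell numbers within one cell type
#'
#' Selects the same number of cells from each age group: all cells of the
#' smaller group and a without-replacement sample of equal size from the
#' larger. Cell types with fewer than `min_cells_per_group` cells in either
#' group are skipped, mirroring the "at least 10 young and old cells" rule.
#'
#' @param cells Cell metadata tibble with `cell`, `age` and `cell_type`
#'   columns.
#' @param cell_type The cell-type label to balance.
#' @param min_cells_per_group Minimum group size (default 10).
#' @param seed Integer seed for the sampling draw.
#' @return Character vector of selected cell barcodes; zero-length with a
#'   `reason` attribute when a group is too small.
#' @export
balance_groups <- function(cells, cell_type, min_cells_per_group = 10L,
                           seed = 1L) {
  if (!cell_type %in% cells$cell_type) {
    abort(paste("unknown cell type:", cell_type))
  }
  ct <- cells[cells$cell_type == cell_type, ]
  young <- ct$cell[ct$age == "young"]
  old <- ct$cell[ct$age == "old"]
  for (grp in c("young", "old")) {
    ids <- if (grp == "young") young else old
    if (length(ids) < min_cells_per_group) {
      out <- character()
      attr(out, "reason") <- sprintf("insufficient %s cells (%d < %d)",
                                     grp, length(ids), min_cells_per_group)
      return(out)
    }
  }
  n <- min(length(young), length(old))
  withr::with_seed(seed, {
    if (length(young) > n) young <- sample(young, n)
    if (length(old) > n) old <- sample(old, n)
  })
  c(young, old)
}

#' Per-cell transcriptional noise as distance to the group centroid
#'
#' For each age group within one cell type, the centroid is the arithmetic
#' mean expression vector over the group's cells; each cell's transcriptional
#' noise is its Euclidean distance to its own group's centroid.
#'
#' @param expr Genes-by-cells expression matrix (a layer of the dataset,
#'   typically `log1p` of down-sampled counts).
#' @param cells Tibble with `cell` and `age` for the (balanced) cells of one
#'   cell type; every barcode must be a column of `expr`.
#' @return Tibble `(cell, age, noise_distance)`.
#' @export
cell_noise <- function(expr, cells) {
  if (!all(cells$cell %in% colnames(expr))) {
    abort("cells missing from the expression matrix")
  }
  out <- lapply(split(cells$cell, cells$age), function(ids) {
    if (length(ids) < 2) {
      abort("need at least 2 cells per age group to compute noise distances")
    }
    sub <- as.matrix(expr[, ids, drop = FALSE])
    centroid <- rowMeans(sub)
    tibble(cell = ids,
           noise_distance = unname(sqrt(colSums((sub - centroid)^2))))
  })
  res <- bind_rows(out, .id = "age")
  left_join(cells, res[, c("cell", "noise_distance")], by = "cell")
}

#' Old/young noise ratios for one cell type
#'
#' Two estimators on the log2 scale: the single-cell estimator is the ratio
#' of the mean distance over old cells to the mean over young cells; the
#' sample-average estimator first averages distances within each animal, then
#' ratios the old-sample mean against the young-sample mean, giving each
#' animal equal weight.
#'
#' @param noise Tibble of per-cell distances with `sample`, `age` and
#'   `noise_distance` columns (one cell type).
#' @return One-row tibble with `log2_ratio_single_cell`,
#'   `log2_ratio_sample_average`, `n_cells_young`, `n_cells_old`.
#' @export
noise_ratios <- function(noise) {
  young <- noise[noise$age == "young", ]
  old <- noise[noise$age == "old", ]
  if (!nrow(young) || !nrow(old)) abort("both age groups required")
  my <- mean(young$noise_distance)
  mo <- mean(old$noise_distance)
  if (my == 0) abort("degenerate young group: zero mean noise distance")
  per_sample <- function(d) {
    vapply(split(d$noise_distance, d$sample), mean, numeric(1))
  }
  sy <- mean(per_sample(young))
  so <- mean(per_sample(old))
  tibble(
    log2_ratio_single_cell = log2(mo / my),
    log2_ratio_sample_average = log2(so / sy),
    n_cells_young = nrow(young),
    n_cells_old = nrow(old)
  )
}

#' Transcriptional-noise analysis across cell types
#'
#' Runs the full procedure: equalise library sizes by exact down-sampling,
#' balance young/old cell numbers within each cell type, compute each cell's
#' Euclidean distance to its cell-type/age-group centroid, and summarise per
#' cell type as log2 old/young ratios by the single-cell and sample-average
#' estimators. With `n_resamples > 1` the down-sample/balance/distance pass
#' is repeated with fresh draws and the estimators are averaged; the per-cell
#' table reports the first pass.
#'
#' @param x A filtered [muscle_dataset()] with `sample`, `age` and
#'   `cell_type` cell metadata.
#' @param min_cells_per_group Cell types need at least this many cells in
#'   both age groups (default 10) or they are skipped with a reason.
#' @param target_library_size `"auto-min"` (the minimum library size among
#'   cells entering the analysis) or an explicit integer.
#' @param n_resamples Number of independent down-sample/balance passes.
#' @param distance_layer `"lognorm"` (distances on `log1p` of down-sampled
#'   counts, default) or `"raw"` (down-sampled counts directly).
#' @param equalize_first Equalise library sizes before balancing cell numbers
#'   (default) or after.
#' @param seed Integer seed driving all draws.
#' @return A `noise_result`: list with `cell_noise` (per-cell tibble),
#'   `summary` (per-cell-type tibble), `skipped` (cell types with reasons)
#'   and `params`. Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
#' @examples
#' sim <- simulate_dataset(simulation_config(cells_per_sample = 40, seed = 3))
#' nr <- transcriptional_noise(sim$dataset, seed = 3)
#' tidy(nr)
transcriptional_noise <- function(x,
                                  min_cells_per_group = 10L,
                                  target_library_size = "auto-min",
                                  n_resamples = 1L,
                                  distance_layer = c("lognorm", "raw"),
                                  equalize_first = TRUE,
                                  seed = 1L) {
  stopifnot(is(x, "muscle_dataset"))
  distance_layer <- match.arg(distance_layer)
  if (min_cells_per_group < 2) abort("min_cells_per_group must be >= 2")
  if (n_resamples < 1) abort("n_resamples must be >= 1")
  need <- c("sample", "age", "cell_type")
  if (!all(need %in% names(x$cells))) {
    abort("cell metadata must carry sample, age and cell_type")
  }

  # eligibility: cell types with enough cells in both groups
  tab <- table(x$cells$cell_type, x$cells$age)
  types <- sort(rownames(tab))
  eligible <- types[apply(tab[, c("young", "old"), drop = FALSE] >=
                            min_cells_per_group, 1, all)[types]]
  skipped <- tibble(cell_type = character(), reason = character())
  for (ct in setdiff(types, eligible)) {
    ids <- balance_groups(x$cells, ct, min_cells_per_group, seed = 1L)
    skipped <- bind_rows(skipped,
                         tibble(cell_type = ct, reason = attr(ids, "reason")))
  }
  if (!length(eligible)) {
    abort("no cell type has enough young and old cells")
  }
  pool <- subset_cells(x, x$cells$cell %in%
                            x$cells$cell[x$cells$cell_type %in% eligible])

  one_pass <- function(r) {
    sd_seed <- seed + 7919L * (r - 1L)
    if (equalize_first) {
      tgt <- if (identical(target_library_size, "auto-min")) {
        min(Matrix::colSums(pool$counts))
      } else as.integer(target_library_size)
      ds <- downsample_library(pool, target = tgt, seed = sd_seed)
      sel <- lapply(setNames(eligible, eligible), function(ct) {
        balance_groups(ds$cells, ct, min_cells_per_group,
                       seed = sd_seed + match(ct, eligible))
      })
    } else {
      sel <- lapply(setNames(eligible, eligible), function(ct) {
        balance_groups(pool$cells, ct, min_cells_per_group,
                       seed = sd_seed + match(ct, eligible))
      })
      keep <- subset_cells(pool, unlist(sel))
      tgt <- if (identical(target_library_size, "auto-min")) {
        min(Matrix::colSums(keep$counts))
      } else as.integer(target_library_size)
      ds <- downsample_library(keep, target = tgt, seed = sd_seed)
    }
    expr <- ds$counts
    if (distance_layer == "lognorm") {
      expr@x <- log1p(expr@x)
    }
    per_type <- lapply(eligible, function(ct) {
      meta <- ds$cells[ds$cells$cell %in% sel[[ct]],
                       c("cell", "sample", "age", "cell_type")]
      cn <- cell_noise(expr, meta)
      list(noise = cn, summary = mutate(noise_ratios(cn), cell_type = ct,
                                        .before = 1))
    })
    list(
      noise = bind_rows(lapply(per_type, `[[`, "noise")),
      summary = bind_rows(lapply(per_type, `[[`, "summary")),
      target = tgt
    )
  }

  passes <- lapply(seq_len(n_resamples), one_pass)
  summary <- bind_rows(lapply(passes, `[[`, "summary")) |>
    group_by(.data$cell_type) |>
    summarise(
      log2_ratio_single_cell = mean(.data$log2_ratio_single_cell),
      log2_ratio_sample_average = mean(.data$log2_ratio_sample_average),
      n_cells_young = .data$n_cells_young[1],
      n_cells_old = .data$n_cells_old[1],
      .groups = "drop"
    )
  structure(
    list(cell_noise = passes[[1]]$noise,
         summary = summary,
         skipped = skipped,
         params = list(min_cells_per_group = min_cells_per_group,
                       target_library_size = passes[[1]]$target,
                       n_resamples = n_resamples,
                       distance_layer = distance_layer,
                       equalize_first = equalize_first,
                       seed = seed)),
    class = "noise_result"
  )
}

#' @export
print.noise_result <- function(x, ...) {
  cat(sprintf("<noise_result> %d cell type(s), target library %d, %d resample(s)\n",
              nrow(x$summary), x$params$target_library_size,
              x$params$n_resamples))
  print(x$summary)
  if (nrow(x$skipped)) {
    cat("skipped:\n")
    print(x$skipped)
  }
  invisible(x)
}

#' @rdname transcriptional_noise
#' @param x A `noise_result`.
#' @param ... Unused.
#' @method tidy noise_result
#' @export
tidy.noise_result <- function(x, ...) x$summary

#' @rdname transcriptional_noise
#' @method glance noise_result
#' @export
glance.noise_result <- function(x, ...) {
  tibble(
    n_celltypes = nrow(x$summary),
    n_skipped = nrow(x$skipped),
    target_library_size = x$params$target_library_size,
    mean_log2_ratio_single_cell = mean(x$summary$log2_ratio_single_cell),
    mean_log2_ratio_sample_average = mean(x$summary$log2_ratio_sample_average)
  )
}

#' Scatter of the two noise-ratio estimators per cell type
#'
#' X axis: sample-average estimator; Y axis: single-cell estimator — one
#' point per cell type, with the origin marked. Cell types in the upper-right
#' quadrant gained transcriptional noise with age under both estimators.
#'
#' @param object A `noise_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot noise_result
#' @export
autoplot.noise_result <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$log2_ratio_sample_average,
                               y = .data$log2_ratio_single_cell,
                               label = .data$cell_type)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(
      x = "log2 noise ratio (old/young), sample averages",
      y = "log2 noise ratio (old/young), single cells",
      title = "Age-related transcriptional noise by cell type"
    ) +
    ggplot2::theme_minimal()
}
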