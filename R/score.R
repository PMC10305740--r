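#' Per-cell gene-set module score with bin-matched controls
#'
#' Scores each cell for a gene set against expression-matched control genes:
#' genes are ranked by their mean normalized expression across all cells and
#' cut into `n_bins` equal-size bins; for every set gene, `n_ctrl` control
#' genes are drawn from its bin (without replacement, or with replacement
#' when the bin is smaller than `n_ctrl`); the score is the mean expression
#' of the set genes minus the mean expression of the pooled control draw,
#' per cell. Positive scores mean the set is expressed above genes of
#' comparable average abundance.
#'
#' @param x A normalized [muscle_dataset()].
#' @param genes Character vector: the gene set. Genes absent from the dataset
#'   are dropped; an empty intersection is an error naming the missing genes.
#' @param name Label for the set (default `"set"`).
#' @param n_bins Number of average-expression bins (default 24).
#' @param n_ctrl Control genes drawn per set gene (default 100).
#' @param seed Integer seed for the control draws.
#' @return Tibble `(cell, set, score)`, one row per cell.
#' @export
module_score <- function(x, genes, name = "set", n_bins = 24L, n_ctrl = 100L,
                         seed = 1L) {
  stopifnot(is(x, "muscle_dataset"))
  expr <- get_layer(x, "lognorm")
  universe <- rownames(expr)
  set <- intersect(genes, universe)
  if (!length(set)) {
    abort(paste0("gene set '", name, "' has no genes in the dataset; missing: ",
                 paste(head(setdiff(genes, universe), 10), collapse = ", ")))
  }
  avg <- Matrix::rowMeans(expr)
  bin <- dplyr::ntile(rank(avg, ties.method = "first"), n_bins)
  names(bin) <- universe
  ctrl <- withr::with_seed(seed, {
    unlist(lapply(set, function(g) {
      mates <- universe[bin == bin[[g]]]
      if (length(mates) >= n_ctrl) sample(mates, n_ctrl)
      else sample(mates, n_ctrl, replace = TRUE)
    }))
  })
  set_mean <- Matrix::colMeans(expr[set, , drop = FALSE])
  # pooled control is a multiset: duplicated draws keep their weight
  ctrl_mean <- colMeans(as.matrix(expr[ctrl, , drop = FALSE]))
  tibble(cell = colnames(expr), set = name,
         score = as.numeric(set_mean - ctrl_mean))
}

#' Score several gene sets
#'
#' @param x A normalized [muscle_dataset()].
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param ... Passed to [module_score()].
#' @param seed Integer seed; each set gets a derived seed so set order does
#'   not leak randomness across sets.
#' @return Tibble `(cell, set, score)` over all sets.
#' @export
score_gene_sets <- function(x, sets, ..., seed = 1L) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  bind_rows(imap(sets, function(genes, nm) {
    module_score(x, genes, name = nm, ...,
                 seed = seed + match(nm, names(sets)))
  }))
}

#' Compare gene-set scores between age groups per cell type
#'
#' For every (set, cell type), compares per-cell scores of old versus young
#' cells with a two-sided Wilcoxon rank-sum test and reports group medians
#' and the mode of a Gaussian kernel density estimate of each group's scores
#' (Silverman's rule-of-thumb bandwidth). Combinations with an absent group
#' are kept with a `reason` and NA statistics.
#'
#' @param scores Tibble from [module_score()]/[score_gene_sets()].
#' @param cells Cell metadata tibble with `cell`, `age`, `cell_type`.
#' @return Tibble with one row per (set, cell_type): group sizes, medians,
#'   density peaks, `p_value`, and `reason` (NA when computed).
#' @export
compare_group_scores <- function(scores, cells) {
  dat <- left_join(scores, cells[, c("cell", "age", "cell_type")], by = "cell")
  if (anyNA(dat$age)) abort("scores contain cells absent from the metadata")
  kde_peak <- function(v) {
    if (length(v) < 2 || stats::sd(v) == 0) return(v[1])
    d <- density(v, bw = "nrd0")
    d$x[which.max(d$y)]
  }
  dat |>
    group_by(.data$set, .data$cell_type) |>
    summarise(
      n_young = sum(.data$age == "young"),
      n_old = sum(.data$age == "old"),
      median_young = if (.data$n_young[1] > 0)
        median(.data$score[.data$age == "young"]) else NA_real_,
      median_old = if (.data$n_old[1] > 0)
        median(.data$score[.data$age == "old"]) else NA_real_,
      peak_young = if (.data$n_young[1] > 0)
        kde_peak(.data$score[.data$age == "young"]) else NA_real_,
      peak_old = if (.data$n_old[1] > 0)
        kde_peak(.data$score[.data$age == "old"]) else NA_real_,
      p_value = if (.data$n_young[1] > 0 && .data$n_old[1] > 0) {
        rank_sum_p(c(.data$score[.data$age == "old"],
                     .data$score[.data$age == "young"]),
                   n1 = .data$n_old[1])
      } else NA_real_,
      reason = if (.data$n_young[1] == 0) "no young cells"
        else if (.data$n_old[1] == 0) "no old cells" else NA_character_,
      .groups = "drop"
    )
}

#' Density plot of gene-set scores by age group
#'
#' One panel per cell type; dashed vertical lines mark each group's density
#' peak.
#'
#' @param scores Tibble from [module_score()] (one set).
#' @param cells Cell metadata with `cell`, `age`, `cell_type`.
#' @return A ggplot object.
#' @export
plot_score_density <- function(scores, cells) {
  dat <- left_join(scores, cells[, c("cell", "age", "cell_type")], by = "cell")
  peaks <- compare_group_scores(scores, cells) |>
    tidyr::pivot_longer(c("peak_young", "peak_old"),
                        names_to = "age", values_to = "peak") |>
    mutate(age = sub("peak_", "", .data$age))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$score, colour = .data$age)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(data = peaks,
                        ggplot2::aes(xintercept = .data$peak,
                                     colour = .data$age),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~cell_type, scales = "free") +
    ggplot2::labs(x = "module score", y = "density", colour = NULL) +
    ggplot2::theme_minimal()
}
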