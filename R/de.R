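#' Benjamini-Hochberg step-up adjustment
#'
#' Standard FDR step-up: with m p-values sorted ascending, the i-th adjusted
#' value is `min_{j >= i} min(1, m * p_(j) / j)`, mapped back to the input
#' order. Enforces monotonicity and never drops below the raw p-value.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @export
benjamini_hochberg <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1] with no NA")
  }
  m <- length(p)
  if (m <= 1) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

# two-sided Wilcoxon rank-sum p-value for one gene.
# Exact doubled-tail p from the null U distribution when both groups are
# small and there are no ties; otherwise normal approximation with tie and
# continuity correction.
rank_sum_p <- function(xy, n1, exact_max = 25L) {
  n2 <- length(xy) - n1
  r <- rank(xy)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  tie_sizes <- tabulate(match(r, unique(r)))
  has_ties <- any(tie_sizes > 1L)
  if (!has_ties && n1 <= exact_max && n2 <= exact_max) {
    p <- 2 * min(pwilcox(u, n1, n2),
                 pwilcox(u - 1, n1, n2, lower.tail = FALSE))
    return(min(1, p))
  }
  n <- n1 + n2
  sigma2 <- (n1 * n2 / 12) *
    ((n + 1) - sum(tie_sizes^3 - tie_sizes) / (n * (n - 1)))
  if (sigma2 <= 0) return(1) # constant gene
  z <- u - n1 * n2 / 2
  z <- sign(z) * max(0, abs(z) - 0.5)
  min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
}

# log fold change old/young on the normalized layer, matching the
# exponentiate-mean-then-log convention of single-cell DE tools
log_fold_change <- function(m_old, m_young, pseudocount = 1e-9,
                            base = c("ln", "log2")) {
  base <- match.arg(base)
  lfc <- log((m_old + pseudocount) / (m_young + pseudocount))
  if (base == "log2") lfc <- lfc / log(2)
  lfc
}

#' Old-versus-young differential expression within one cell type
#'
#' Two-sided Wilcoxon rank-sum test per gene on the normalized layer, with
#' log fold change computed as `log(mean(expm1(old)) + pc) -
#' log(mean(expm1(young)) + pc)` in natural-log units (the convention under
#' which the 0.25 cutoff is meaningful), BH adjustment across genes within
#' the cell type, and the significance call `|log_fc| > lfc_cutoff` and
#' `adj_p < p_cutoff`.
#'
#' @param x A normalized [muscle_dataset()] with `age` and `cell_type` cell
#'   metadata.
#' @param cell_type Cell type to test; both age groups need at least 3 cells.
#' @param lfc_cutoff,p_cutoff Significance cutoffs (defaults 0.25 and 0.05).
#' @param base `"ln"` (default) or `"log2"` fold-change units; the cutoff is
#'   interpreted on the chosen scale.
#' @param pseudocount Added to both group means before the log ratio.
#' @param min_detect_frac Genes detected in fewer than this fraction of cells
#'   in both groups are excluded from testing (default 0: test everything).
#' @param exact_max Use the exact rank-sum null distribution when both group
#'   sizes are at most this and the gene has no tied values.
#' @return A `deg_table` tibble: `gene`, `cell_type`, `log_fc`, `p_value`,
#'   `adj_p`, `direction`, `significant`.
#' @export
wilcoxon_deg <- function(x, cell_type, lfc_cutoff = 0.25, p_cutoff = 0.05,
                         base = c("ln", "log2"), pseudocount = 1e-9,
                         min_detect_frac = 0, exact_max = 25L) {
  stopifnot(is(x, "muscle_dataset"))
  base <- match.arg(base)
  expr <- get_layer(x, "lognorm")
  meta <- x$cells[x$cells$cell_type == cell_type, ]
  young <- meta$cell[meta$age == "young"]
  old <- meta$cell[meta$age == "old"]
  if (!length(young) || !length(old)) {
    abort(sprintf("cell type '%s': one age group is empty", cell_type))
  }
  if (length(young) < 3 || length(old) < 3) {
    abort(sprintf("cell type '%s': need at least 3 cells per age group",
                  cell_type))
  }
  My <- as.matrix(expr[, young, drop = FALSE])
  Mo <- as.matrix(expr[, old, drop = FALSE])
  keep <- rep(TRUE, nrow(My))
  if (min_detect_frac > 0) {
    keep <- rowMeans(My > 0) >= min_detect_frac |
      rowMeans(Mo > 0) >= min_detect_frac
  }
  genes <- rownames(expr)[keep]
  My <- My[keep, , drop = FALSE]
  Mo <- Mo[keep, , drop = FALSE]
  n1 <- ncol(Mo)
  p <- vapply(seq_along(genes), function(i) {
    rank_sum_p(c(Mo[i, ], My[i, ]), n1, exact_max = exact_max)
  }, numeric(1))
  lfc <- unname(log_fold_change(rowMeans(expm1(Mo)), rowMeans(expm1(My)),
                                pseudocount = pseudocount, base = base))
  lfc[rowSums(Mo) == 0 & rowSums(My) == 0] <- 0
  adj <- benjamini_hochberg(p)
  out <- tibble(
    gene = genes,
    cell_type = cell_type,
    log_fc = lfc,
    p_value = p,
    adj_p = adj,
    direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "none")),
    significant = abs(lfc) > lfc_cutoff & adj < p_cutoff
  )
  class(out) <- c("deg_table", class(out))
  out
}

#' Old-versus-young differential expression across all cell types
#'
#' Runs [wilcoxon_deg()] for every cell type with at least 3 cells in both
#' age groups (others are skipped with a warning) and binds the per-type
#' tables.
#'
#' @inheritParams wilcoxon_deg
#' @param cell_types Cell types to test; default all present.
#' @param ... Passed to [wilcoxon_deg()].
#' @return A `deg_table` tibble over all tested cell types.
#' @export
#' @examples
#' sim <- simulate_dataset(simulation_config(cells_per_sample = 40))
#' degs <- sim$dataset |> normalize_counts() |> run_deg()
#' dplyr::count(degs, cell_type, significant)
run_deg <- function(x, cell_types = NULL, ...) {
  stopifnot(is(x, "muscle_dataset"))
  if (is.null(cell_types)) cell_types <- sort(unique(x$cells$cell_type))
  out <- list()
  for (ct in cell_types) {
    meta <- x$cells[x$cells$cell_type == ct, ]
    if (sum(meta$age == "young") < 3 || sum(meta$age == "old") < 3) {
      warn(sprintf("skipping cell type '%s': fewer than 3 cells in a group", ct))
      next
    }
    out[[ct]] <- wilcoxon_deg(x, ct, ...)
  }
  res <- bind_rows(out)
  class(res) <- c("deg_table", class(res))
  res
}

#' One-versus-rest marker genes by Welch t-test
#'
#' For each cell type, every gene is tested against all remaining cells with
#' a two-sided Welch two-sample t-test on the normalized layer; fold change
#' uses the same convention as [wilcoxon_deg()]. BH adjustment is applied
#' within each cell type and markers must satisfy `|log_fc| > lfc_cutoff`
#' and `adj_p < p_cutoff` (defaults 0.5 and 0.05).
#'
#' @inheritParams wilcoxon_deg
#' @param lfc_cutoff,p_cutoff Marker cutoffs (defaults 0.5 and 0.05).
#' @return Tibble `(gene, cell_type, log_fc, p_value, adj_p, significant)`
#'   over all cell types with at least 3 cells (smaller ones are skipped with
#'   a warning).
#' @export
ttest_markers <- function(x, lfc_cutoff = 0.5, p_cutoff = 0.05,
                          base = c("ln", "log2"), pseudocount = 1e-9) {
  stopifnot(is(x, "muscle_dataset"))
  base <- match.arg(base)
  expr <- get_layer(x, "lognorm")
  types <- sort(unique(x$cells$cell_type))
  if (length(types) < 2) abort("marker detection needs at least 2 cell types")
  M <- as.matrix(expr)
  out <- list()
  for (ct in types) {
    in_ct <- x$cells$cell_type == ct
    if (sum(in_ct) < 3) {
      warn(sprintf("skipping cell type '%s': fewer than 3 cells", ct))
      next
    }
    A <- M[, in_ct, drop = FALSE]
    B <- M[, !in_ct, drop = FALSE]
    n1 <- ncol(A); n2 <- ncol(B)
    m1 <- rowMeans(A); m2 <- rowMeans(B)
    v1 <- rowSums((A - m1)^2) / (n1 - 1)
    v2 <- rowSums((B - m2)^2) / (n2 - 1)
    se2 <- v1 / n1 + v2 / n2
    tstat <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
    df <- ifelse(se2 > 0,
                 se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1))),
                 1)
    p <- ifelse(se2 > 0, 2 * pt(-abs(tstat), df), 1)
    lfc <- log_fold_change(rowMeans(expm1(A)), rowMeans(expm1(B)),
                           pseudocount = pseudocount, base = base)
    adj <- benjamini_hochberg(p)
    out[[ct]] <- tibble(
      gene = rownames(M), cell_type = ct,
      log_fc = unname(lfc), t_statistic = unname(tstat),
      p_value = unname(p), adj_p = unname(adj),
      significant = abs(lfc) > lfc_cutoff & adj < p_cutoff
    )
  }
  bind_rows(out)
}

#' Genes differentially expressed across many cell types
#'
#' Collects genes significant in at least `min_celltypes` cell types and
#' classifies each as consistently up, consistently down, or mixed according
#' to its direction across the member cell types.
#'
#' @param degs A `deg_table` (from [run_deg()]) covering several cell types.
#' @param min_celltypes Minimum number of cell types a gene must be
#'   significant in (default 5).
#' @return Tibble `(gene, n_celltypes_de, direction_class, cell_types)`,
#'   `cell_types` a comma-separated member list, ordered by descending
#'   `n_celltypes_de` then gene name.
#' @export
shared_degs <- function(degs, min_celltypes = 5L) {
  sig <- degs[degs$significant, ]
  if (!nrow(sig)) {
    return(tibble(gene = character(), n_celltypes_de = integer(),
                  direction_class = character(), cell_types = character()))
  }
  sig |>
    group_by(.data$gene) |>
    summarise(
      n_celltypes_de = dplyr::n_distinct(.data$cell_type),
      direction_class = if (all(.data$direction == "up")) "consistently_up"
        else if (all(.data$direction == "down")) "consistently_down"
        else "mixed",
      cell_types = paste(sort(unique(.data$cell_type)), collapse = ","),
      .groups = "drop"
    ) |>
    filter(.data$n_celltypes_de >= min_celltypes) |>
    arrange(desc(.data$n_celltypes_de), .data$gene)
}

#' Hub-gene scores: in how many cell types is each gene a DEG?
#'
#' @param degs A `deg_table` covering several cell types.
#' @return Tibble `(gene, score)` over the table's gene universe (genes
#'   significant nowhere score 0), ranked by descending score with gene name
#'   as the tie-break.
#' @export
gene_hub_scores <- function(degs) {
  degs |>
    group_by(.data$gene) |>
    summarise(score = dplyr::n_distinct(.data$cell_type[.data$significant]),
              .groups = "drop") |>
    arrange(desc(.data$score), .data$gene)
}

#' @method tidy deg_table
#' @export
tidy.deg_table <- function(x, ...) as_tibble(x)

#' @method glance deg_table
#' @export
glance.deg_table <- function(x, ...) {
  x |>
    group_by(.data$cell_type) |>
    summarise(n_genes = n(),
              n_deg = sum(.data$significant),
              n_up = sum(.data$significant & .data$direction == "up"),
              n_down = sum(.data$significant & .data$direction == "down"),
              .groups = "drop")
}

#' Bar chart of DEG counts per cell type
#'
#' @param degs A `deg_table`.
#' @return A ggplot object: up- and down-regulated significant gene counts
#'   per cell type.
#' @export
plot_deg_counts <- function(degs) {
  dat <- glance.deg_table(degs) |>
    tidyr::pivot_longer(c("n_up", "n_down"), names_to = "direction",
                        values_to = "n") |>
    mutate(direction = ifelse(.data$direction == "n_up", "up", "down"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cell_type, y = .data$n,
                                    fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "DEGs (old vs young)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
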