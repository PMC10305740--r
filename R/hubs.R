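#' Coerce a regulon representation to a named list
#'
#' Accepts a named list (TF -> character vector of targets) or a two-column
#' data frame (`tf`, `target`, optional `confidence`).
#'
#' @param regulons Named list or data frame.
#' @return Named list mapping TF to a unique, sorted target vector.
#' @export
as_regulon_map <- function(regulons) {
  if (is.data.frame(regulons)) {
    if (!all(c("tf", "target") %in% names(regulons))) {
      abort("regulon table needs 'tf' and 'target' columns")
    }
    regulons <- split(regulons$target, regulons$tf)
  }
  if (!is.list(regulons) || is.null(names(regulons)) ||
      any(!nzchar(names(regulons)))) {
    abort("regulons must be a named list or a (tf, target) table")
  }
  if (anyDuplicated(names(regulons))) abort("duplicate TF names in regulons")
  out <- lapply(regulons, function(t) sort(unique(as.character(t))))
  if (length(out) && any(lengths(out) == 0)) abort("empty target set in regulons")
  out
}

#' Count differentially expressed regulon targets per TF and cell type
#'
#' For each transcription factor, counts how many of its targets are
#' significant DEGs in each cell type, optionally restricted to one
#' direction. This is the node-size statistic of regulon network plots.
#'
#' @param regulons Regulon map ([as_regulon_map()] input).
#' @param degs A `deg_table` over the cell types of interest.
#' @param direction `"any"` (default), `"down"` or `"up"`.
#' @param tfs TFs to report (default all in the map); an unknown TF is an
#'   error.
#' @return Tibble `(tf, cell_type, n_de_targets)` for every combination.
#' @export
regulon_deg_counts <- function(regulons, degs,
                               direction = c("any", "down", "up"),
                               tfs = NULL) {
  regulons <- as_regulon_map(regulons)
  direction <- match.arg(direction)
  if (is.null(tfs)) tfs <- names(regulons)
  missing <- setdiff(tfs, names(regulons))
  if (length(missing)) {
    abort(paste("TF absent from the regulon map:",
                paste(missing, collapse = ", ")))
  }
  sig <- degs[degs$significant, ]
  if (direction != "any") sig <- sig[sig$direction == direction, ]
  cts <- sort(unique(degs$cell_type))
  sig_by_ct <- split(sig$gene, factor(sig$cell_type, levels = cts))
  tidyr::expand_grid(tf = tfs, cell_type = cts) |>
    mutate(n_de_targets = map_int(seq_len(n()), function(i) {
      length(intersect(regulons[[.data$tf[i]]], sig_by_ct[[.data$cell_type[i]]]))
    }))
}

#' Hypergeometric enrichment of regulon targets among DEGs
#'
#' One-sided (over-representation) hypergeometric tail probability of the
#' overlap between each TF's targets and the direction-matched significant
#' DEGs of one cell type. The universe is the set of genes tested in that
#' cell type, which avoids detection bias; targets outside the universe are
#' ignored. BH adjustment is applied across TFs.
#'
#' @inheritParams regulon_deg_counts
#' @param cell_type The cell type to test.
#' @return Tibble `(tf, cell_type, n_targets_tested, n_de_targets, p_value,
#'   adj_p)`. With no direction-matched DEGs every p is 1.
#' @export
target_enrichment <- function(regulons, degs, cell_type,
                              direction = c("down", "up", "any")) {
  regulons <- as_regulon_map(regulons)
  direction <- match.arg(direction)
  tab <- degs[degs$cell_type == cell_type, ]
  if (!nrow(tab)) abort(paste("no DEG table for cell type", cell_type))
  universe <- unique(tab$gene)
  sig <- tab[tab$significant, ]
  if (direction != "any") sig <- sig[sig$direction == direction, ]
  deg_set <- unique(sig$gene)
  N <- length(universe); K <- length(deg_set)
  res <- imap(regulons, function(targets, tf) {
    tt <- intersect(targets, universe)
    k <- length(intersect(tt, deg_set))
    p <- if (K == 0 || length(tt) == 0) 1 else {
      phyper(k - 1, K, N - K, length(tt), lower.tail = FALSE)
    }
    tibble(tf = tf, cell_type = cell_type,
           n_targets_tested = length(tt), n_de_targets = k, p_value = p)
  })
  out <- bind_rows(res)
  out$adj_p <- benjamini_hochberg(out$p_value)
  out
}

#' Rank hub transcription factors
#'
#' A TF is flagged as a hub when its own transcript is significantly
#' down-regulated in more than `min_self_down_celltypes` cell types. TFs are
#' ranked by the number of cell types with self down-regulation, then by the
#' total number of differentially expressed targets across cell types, then
#' by name.
#'
#' @inheritParams regulon_deg_counts
#' @param min_self_down_celltypes Strict threshold: hub requires self
#'   down-regulation in more than this many cell types (default 5, i.e. at
#'   least 6).
#' @param target_direction Direction used for the target DE counts
#'   (default `"any"`).
#' @return Tibble `(tf, n_celltypes_self_down, total_de_targets, hub, rank)`
#'   in rank order.
#' @export
rank_hub_tfs <- function(regulons, degs, min_self_down_celltypes = 5L,
                         target_direction = "any") {
  regulons <- as_regulon_map(regulons)
  sig_down <- degs[degs$significant & degs$direction == "down", ]
  self_down <- vapply(names(regulons), function(tf) {
    length(unique(sig_down$cell_type[sig_down$gene == tf]))
  }, integer(1))
  counts <- regulon_deg_counts(regulons, degs, direction = target_direction) |>
    group_by(.data$tf) |>
    summarise(total_de_targets = sum(.data$n_de_targets), .groups = "drop")
  out <- tibble(tf = names(regulons),
                n_celltypes_self_down = as.integer(self_down)) |>
    left_join(counts, by = "tf") |>
    mutate(hub = .data$n_celltypes_self_down > min_self_down_celltypes) |>
    arrange(desc(.data$n_celltypes_self_down), desc(.data$total_de_targets),
            .data$tf) |>
    mutate(rank = dplyr::row_number())
  out
}
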