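#' Run the full analysis pipeline from a configuration
#'
#' Executes, in order: data acquisition (simulation or a 10x-style input
#' directory), nucleus QC filtering, normalisation, the transcriptional-noise
#' analysis, per-cell-type differential expression, shared-DEG and hub-gene
#' aggregation, gene-set scoring with group comparison, and hub-TF ranking
#' over a regulon map. Every stage writes a headered TSV with a stable column
#' order into `out_dir`, plus a `provenance.json` recording the expanded
#' configuration and seed; an identical config and seed reproduce
#' byte-identical outputs. A failing stage aborts with the stage named.
#'
#' The configuration is a named list (or a YAML/JSON path, see
#' [read_config()]) with optional sections:
#' \describe{
#'   \item{seed}{Single integer; per-stage seeds are derived from it.}
#'   \item{simulation}{Arguments for [simulation_config()]; alternatively}
#'   \item{input}{`dir`: a 10x-style directory with `cells.tsv`.}
#'   \item{qc}{`min_genes`, `max_mito` for [qc_thresholds()].}
#'   \item{noise}{`min_cells_per_group`, `n_resamples`, `distance_layer`,
#'     `target_library_size`.}
#'   \item{deg}{`lfc_cutoff`, `p_cutoff`.}
#'   \item{shared}{`min_celltypes`.}
#'   \item{score}{`gmt` path, or `n_sets`/`set_size` for seeded random sets;
#'     `n_bins`, `n_ctrl`.}
#'   \item{regulons}{`path` to a TSV map, or `n_tfs`/`targets_per_tf` (+
#'     optional `hub` spec) for [simulate_regulons()].}
#'   \item{hubs}{`min_self_down`.}
#' }
#'
#' @param config Named list or path to a YAML/JSON file.
#' @param out_dir Output directory for the TSV artifacts.
#' @return Invisibly, a list with all in-memory results (`dataset`, `truth`,
#'   `noise`, `degs`, `shared`, `hub_genes`, `scores`, `score_comparison`,
#'   `regulons`, `hub_tfs`, `paths`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) config <- read_config(config)
  stopifnot(is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)))
    })
  }
  paths <- list()
  emit <- function(tab, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(tab, p)
    paths[[name]] <<- p
    p
  }

  # --- acquire ---
  truth <- NULL
  if (!is.null(config$input)) {
    ds <- run_stage("input", read_counts_10x(config$input$dir))
  } else {
    sim_args <- config$simulation %||% list()
    if (is.null(sim_args$seed)) sim_args$seed <- stage_seed(seed, "simulate")
    sim <- run_stage("simulate", {
      cfg <- do.call(simulation_config, sim_args)
      simulate_dataset(cfg)
    })
    ds <- sim$dataset
    truth <- sim$truth
    if (nrow(truth$true_de)) emit(truth$true_de, "truth_de.tsv")
    if (nrow(truth$true_noise)) emit(truth$true_noise, "truth_noise.tsv")
  }

  # --- QC + normalize ---
  qc_args <- config$qc %||% list()
  thr <- qc_thresholds(min_genes = qc_args$min_genes %||% 200L,
                       max_mito = qc_args$max_mito %||% 0.01)
  qc_tab <- run_stage("qc", suppressWarnings(compute_cell_qc(ds)))
  emit(qc_tab, "qc.tsv")
  ds <- run_stage("qc", filter_cells(ds, thr, verbose = FALSE))
  ds <- run_stage("normalize", normalize_counts(ds))

  # --- noise ---
  na <- config$noise %||% list()
  noise <- run_stage("noise", transcriptional_noise(
    ds,
    min_cells_per_group = na$min_cells_per_group %||% 10L,
    target_library_size = na$target_library_size %||% "auto-min",
    n_resamples = na$n_resamples %||% 1L,
    distance_layer = na$distance_layer %||% "lognorm",
    seed = stage_seed(seed, "noise")
  ))
  emit(noise$cell_noise, "noise_cells.tsv")
  emit(noise$summary, "noise.tsv")
  if (nrow(noise$skipped)) {
    message("noise: skipped ", paste(noise$skipped$cell_type, "(",
                                     noise$skipped$reason, ")", collapse = "; "))
    emit(noise$skipped, "noise_skipped.tsv")
  }

  # --- DEG ---
  da <- config$deg %||% list()
  degs <- run_stage("deg", suppressWarnings(run_deg(
    ds, lfc_cutoff = da$lfc_cutoff %||% 0.25,
    p_cutoff = da$p_cutoff %||% 0.05
  )))
  emit(degs, "degs.tsv")
  shared <- run_stage("shared-degs", shared_degs(
    degs, min_celltypes = (config$shared %||% list())$min_celltypes %||% 5L))
  emit(shared, "shared.tsv")
  hub_genes <- run_stage("shared-degs", gene_hub_scores(degs))
  emit(hub_genes, "hub_genes.tsv")

  # --- gene-set scoring ---
  sc <- config$score %||% list()
  sets <- run_stage("score", {
    if (!is.null(sc$gmt)) {
      read_gmt(sc$gmt)
    } else {
      n_sets <- sc$n_sets %||% 3L
      set_size <- sc$set_size %||% 30L
      withr::with_seed(stage_seed(seed, "score"), {
        setNames(lapply(seq_len(n_sets), function(i) {
          sample(rownames(ds$counts), set_size)
        }), sprintf("random_set_%02d", seq_len(n_sets)))
      })
    }
  })
  scores <- run_stage("score", score_gene_sets(
    ds, sets, n_bins = sc$n_bins %||% 24L, n_ctrl = sc$n_ctrl %||% 100L,
    seed = stage_seed(seed, "score")))
  emit(scores, "scores.tsv")
  score_cmp <- run_stage("score", compare_group_scores(scores, ds$cells))
  emit(score_cmp, "score_comparison.tsv")

  # --- regulons + hub TFs ---
  rg <- config$regulons %||% list()
  regulons <- run_stage("hubs", {
    if (!is.null(rg$path)) {
      read_regulons(rg$path, high_confidence_only = isTRUE(rg$high_confidence_only))
    } else if (!is.null(truth)) {
      simulate_regulons(truth,
                        n_tfs = rg$n_tfs %||% 10L,
                        targets_per_tf = rg$targets_per_tf %||% 20L,
                        hub_tf_spec = rg$hub,
                        seed = stage_seed(seed, "regulons"))
    } else {
      NULL
    }
  })
  hub_tfs <- NULL
  if (!is.null(regulons) && length(regulons)) {
    hub_tfs <- run_stage("hubs", rank_hub_tfs(
      regulons, degs,
      min_self_down_celltypes = (config$hubs %||% list())$min_self_down %||% 5L))
    emit(hub_tfs, "hubs.tsv")
    emit(tibble(tf = rep(names(regulons), lengths(regulons)),
                target = unlist(regulons, use.names = FALSE)),
         "regulons.tsv")
  }

  prov <- list(seed = seed, config = config,
               n_cells_retained = ncol(ds$counts),
               package_version = as.character(utils::packageVersion("agenoise")))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths[["provenance.json"]] <- file.path(out_dir, "provenance.json")

  invisible(list(dataset = ds, truth = truth, noise = noise, degs = degs,
                 shared = shared, hub_genes = hub_genes, scores = scores,
                 score_comparison = score_cmp, regulons = regulons,
                 hub_tfs = hub_tfs, paths = paths))
}
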