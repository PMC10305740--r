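#' Write a dataset bundle as 10x-style triplet files
#'
#' Emits `matrix.mtx` (genes as rows), `features.tsv`, `barcodes.tsv` and
#' `cells.tsv` (full cell metadata) into a directory, all uncompressed with
#' tab separators.
#'
#' @param x A [muscle_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts_10x <- function(x, dir) {
  stopifnot(is(x, "muscle_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  readr::write_tsv(x$genes, file.path(dir, "features.tsv"))
  readr::write_tsv(tibble(barcode = colnames(x$counts)),
                   file.path(dir, "barcodes.tsv"))
  readr::write_tsv(x$cells, file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' Read a 10x-style triplet directory into a dataset bundle
#'
#' Expects `matrix.mtx` (genes x cells), `features.tsv` (column `gene`,
#' optional `mito` and others) and `barcodes.tsv`; an optional `cells.tsv`
#' supplies per-cell `sample`, `age` and `cell_type`. Counts must be
#' integers; dimensions must match the metadata; duplicate gene names are
#' disambiguated deterministically with `.1`, `.2`, ... suffixes.
#'
#' @param dir Directory holding the files.
#' @param require_cell_metadata When `TRUE` (default) a present `cells.tsv`
#'   must carry `sample`, `age` and `cell_type` columns.
#' @return A [muscle_dataset()] with provenance recording the input paths.
#' @export
read_counts_10x <- function(dir, require_cell_metadata = TRUE) {
  mtx_path <- file.path(dir, "matrix.mtx")
  feat_path <- file.path(dir, "features.tsv")
  bc_path <- file.path(dir, "barcodes.tsv")
  for (p in c(mtx_path, feat_path, bc_path)) {
    if (!file.exists(p)) abort(paste("missing input file:", p))
  }
  m <- as(Matrix::readMM(mtx_path), "CsparseMatrix")
  if (is(m, "dMatrix") && any(m@x != round(m@x))) {
    abort("non-integer counts in matrix.mtx")
  }
  feats <- readr::read_tsv(feat_path, show_col_types = FALSE)
  if (!"gene" %in% names(feats)) {
    names(feats)[1] <- "gene"
  }
  bcs <- readr::read_tsv(bc_path, show_col_types = FALSE)
  barcodes <- as.character(bcs[[1]])
  if (nrow(feats) != nrow(m)) {
    abort(sprintf("dimension mismatch: %d matrix rows vs %d features",
                  nrow(m), nrow(feats)))
  }
  if (length(barcodes) != ncol(m)) {
    abort(sprintf("dimension mismatch: %d matrix columns vs %d barcodes",
                  ncol(m), length(barcodes)))
  }
  if (anyDuplicated(feats$gene)) {
    feats$gene <- make.unique(as.character(feats$gene), sep = ".")
  }
  rownames(m) <- feats$gene
  colnames(m) <- barcodes
  cells <- tibble(cell = barcodes)
  cells_path <- file.path(dir, "cells.tsv")
  if (file.exists(cells_path)) {
    meta <- readr::read_tsv(cells_path, show_col_types = FALSE)
    if (!"cell" %in% names(meta)) names(meta)[1] <- "cell"
    need <- c("sample", "age", "cell_type")
    if (require_cell_metadata && !all(need %in% names(meta))) {
      abort(paste("cells.tsv is missing required metadata columns:",
                  paste(setdiff(need, names(meta)), collapse = ", ")))
    }
    meta$cell <- as.character(meta$cell)
    if (!identical(meta$cell, barcodes)) {
      idx <- match(barcodes, meta$cell)
      if (anyNA(idx)) abort("cells.tsv does not cover every barcode")
      meta <- meta[idx, ]
    }
    cells <- meta
  }
  muscle_dataset(m, cells = cells, genes = feats,
                 provenance = list(source = "read_counts_10x", dir = dir))
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`, then
#' gene names.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) abort(sprintf("malformed GMT line %d: need name, description, genes",
                              which(bad)[1]))
  setNames(lapply(parts, function(p) unique(p[-(1:2)])),
           vapply(parts, `[[`, character(1), 1))
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a TF-to-target regulon map from TSV
#'
#' Two required columns `tf` and `target`; an optional `confidence` column
#' can be filtered on with `min_confidence` (rows whose confidence is below
#' it are dropped) or by keeping only rows flagged `"high"`.
#'
#' @param path TSV path with a header.
#' @param high_confidence_only Keep only rows whose `confidence` column
#'   equals `"high"` (ignored when the column is absent).
#' @return Named list mapping TF to target genes.
#' @export
read_regulons <- function(path, high_confidence_only = FALSE) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("tf", "target") %in% names(tab))) {
    abort("regulon TSV needs 'tf' and 'target' columns")
  }
  if (high_confidence_only && "confidence" %in% names(tab)) {
    tab <- tab[tab$confidence == "high", ]
  }
  as_regulon_map(tab)
}

#' Write a regulon map as TSV
#'
#' @param regulons Named list (TF -> targets).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regulons <- function(regulons, path) {
  regulons <- as_regulon_map(regulons)
  tab <- tibble(tf = rep(names(regulons), lengths(regulons)),
                target = unlist(regulons, use.names = FALSE))
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path File ending in `.yaml`/`.yml` or `.json`.
#' @return Named list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    abort("config must be .yaml, .yml or .json")
  }
}
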