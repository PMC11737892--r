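# Expression file IO: Matrix Market triplet directories (matrix.mtx +
# features.tsv + barcodes.tsv, 10x layout, gzip transparent) and dense
# CSV/TSV. Values travel as an expression_matrix; an orientation flag states
# how the stored matrix is laid out relative to cells x genes.

.find_member <- function(dir, base) {
  for (cand in c(file.path(dir, base), file.path(dir, paste0(base, ".gz")))) {
    if (file.exists(cand)) return(cand)
  }
  stop("missing '", base, "(.gz)' in ", dir)
}

.read_mtx_file <- function(path) {
  if (grepl("\\.gz$", path)) {
    tmp <- tempfile(fileext = ".mtx")
    on.exit(unlink(tmp))
    writeLines(.read_tab_lines(path), tmp)
    path <- tmp
  }
  as.matrix(Matrix::readMM(path))
}

#' Read an expression matrix from disk
#'
#' `layout = "mtx_dir"` expects a directory with `matrix.mtx(.gz)`,
#' `features.tsv(.gz)` (column 1 = id, optional column 2 = symbol; the symbol
#' is preferred when present) and `barcodes.tsv(.gz)`. `layout = "dense_csv"`
#' expects a delimited file with a header; for `cells_by_genes` rows are
#' cells (optional leading id column), for `genes_by_cells` rows are genes
#' with gene names in the first column. The `orientation` flag states how the
#' stored matrix is oriented; output is always cells x genes. Duplicate gene
#' names are made unique with deterministic suffixes.
#'
#' @param path Directory (`mtx_dir`) or file (`dense_csv`).
#' @param layout `"mtx_dir"` or `"dense_csv"`.
#' @param orientation `"cells_by_genes"` or `"genes_by_cells"` (how the file
#'   stores the matrix; 10x MTX convention is `genes_by_cells`).
#' @param sep Field separator for `dense_csv` (`NULL`: infer from the
#'   extension, comma for `.csv` else tab).
#' @return An `expression_matrix`.
#' @export
read_expression <- function(path, layout = c("mtx_dir", "dense_csv"),
                            orientation = c("cells_by_genes", "genes_by_cells"),
                            sep = NULL) {
  layout <- match.arg(layout)
  orientation <- match.arg(orientation)
  if (layout == "mtx_dir") {
    mat <- .read_mtx_file(.find_member(path, "matrix.mtx"))
    feat <- utils::read.delim(.find_member(path, "features.tsv"),
                              header = FALSE, colClasses = "character")
    barcodes <- readLines(con <- .open_text(.find_member(path, "barcodes.tsv")))
    close(con)
    genes <- if (ncol(feat) >= 2L && all(nzchar(feat[[2L]]))) feat[[2L]] else feat[[1L]]
    if (orientation == "genes_by_cells") mat <- t(mat)
    if (ncol(mat) != length(genes)) {
      stop("matrix has ", ncol(mat), " genes but features file lists ", length(genes))
    }
    if (nrow(mat) != length(barcodes)) {
      stop("matrix has ", nrow(mat), " cells but barcodes file lists ", length(barcodes))
    }
  } else {
    if (is.null(sep)) sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (orientation == "cells_by_genes") {
      id_col <- !vapply(df, is.numeric, TRUE)
      if (any(id_col)) {
        barcodes <- as.character(df[[which(id_col)[1L]]])
        df <- df[, !id_col, drop = FALSE]
      } else {
        barcodes <- sprintf("cell%04d", seq_len(nrow(df)))
      }
      mat <- as.matrix(df)
      genes <- colnames(df)
    } else {
      genes <- as.character(df[[1L]])
      mat <- t(as.matrix(df[, -1L, drop = FALSE]))
      barcodes <- colnames(df)[-1L]
    }
  }
  if (anyDuplicated(genes)) {
    warning("duplicate gene names made unique")
    genes <- make.unique(genes, sep = ".")
  }
  expression_matrix(mat, gene_names = genes, cell_ids = barcodes)
}

#' Write an expression matrix to disk
#'
#' `mtx_dir` writes the 10x triplet layout (`matrix.mtx` stored genes x
#' cells, `features.tsv` with id and symbol columns, `barcodes.tsv`);
#' `dense_csv` writes cells x genes with a leading `cell_id` column.
#'
#' @param x An `expression_matrix` (or cells-by-genes matrix).
#' @param path Output directory (`mtx_dir`) or file (`dense_csv`).
#' @param layout `"mtx_dir"` or `"dense_csv"`.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(x, path, layout = c("mtx_dir", "dense_csv")) {
  layout <- match.arg(layout)
  if (!inherits(x, "expression_matrix")) x <- expression_matrix(x)
  if (layout == "mtx_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(t(x$values), sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    utils::write.table(data.frame(id = x$gene_names, symbol = x$gene_names),
                       file.path(path, "features.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    writeLines(x$cell_ids, file.path(path, "barcodes.tsv"))
  } else {
    df <- data.frame(cell_id = x$cell_ids, x$values, check.names = FALSE)
    sep <- if (grepl("\\.csv$", path)) "," else "\t"
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write a full synthetic scenario to disk
#'
#' Emits the generator's outputs in the package's interchange formats so the
#' real readers are exercised end to end: an MTX triplet directory of raw
#' counts, `labels.tsv` (barcode, label), `annotations.tsv` and
#' `tf_targets.tsv` two-column knowledge tables, and `planted_truth.json`.
#'
#' @param scenario A `synthetic_scenario`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the generated objects (`knowledge`, `cells`).
#' @export
write_scenario_files <- function(scenario, dir) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  knowledge <- make_knowledge(scenario)
  cells <- simulate_cells(scenario, knowledge)
  counts_em <- expression_matrix(cells$counts)
  write_expression(counts_em, file.path(dir, "counts"), layout = "mtx_dir")
  utils::write.table(data.frame(barcode = rownames(cells$counts),
                                label = cells$labels),
                     file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(knowledge$annotations[, c("gene", "go_term")],
                     file.path(dir, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(knowledge$tf_targets, file.path(dir, "tf_targets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(knowledge$planted_truth,
                       file.path(dir, "planted_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(scenario), file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(knowledge = knowledge, cells = cells))
}

#' Read a cell label file
#'
#' Header-less TSV, one `barcode<TAB>label` per line (a single-column file is
#' taken as labels in barcode order).
#'
#' @param path Path to the TSV.
#' @return Character vector of labels, named by barcode when present.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(df) >= 2L) stats::setNames(df[[2L]], df[[1L]]) else df[[1L]]
}
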