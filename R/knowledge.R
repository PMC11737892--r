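# Knowledge ingestion: GO annotation tables, TF-target tables, and their
# compilation into the binary connectivity masks that prune the network.

GO_ID_PATTERN <- "^GO:[0-9]{7}$"

.open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, open = "rt") else file(path, open = "rt")
}

.read_tab_lines <- function(path) {
  con <- .open_text(path)
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Read gene-to-GO annotations
#'
#' Parses either a GAF 2.x association file or a minimal header-less
#' two-column `gene<TAB>GO-id` table into a deduplicated annotation table.
#' Only a documented subset of the GAF is consumed: column 3 (object symbol),
#' column 5 (GO id) and column 9 (aspect); rows whose qualifier (column 4)
#' contains `NOT` are skipped, as are `!`-prefixed comment lines. GO
#' identifiers must match `GO:` followed by seven digits; malformed ids are
#' dropped with a warning rather than aborting the load.
#'
#' @param path Path to the annotation file (gzip-compressed files are read
#'   transparently).
#' @param format `"gaf"` for GAF 2.x, `"tsv2col"` for the two-column dialect.
#' @return A data frame of class `annotation_table` with columns `gene`,
#'   `go_term` and `aspect` (`BP`, `MF`, `CC` or `unknown`), one row per
#'   distinct (gene, term) pair.
#' @seealso [build_masks()]
#' @export
load_go_annotations <- function(path, format = c("tsv2col", "gaf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- .read_tab_lines(path)
  lines <- lines[nzchar(lines)]
  if (format == "gaf") {
    lines <- lines[!startsWith(lines, "!")]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    keep <- vapply(fields, length, 1L) >= 9L
    fields <- fields[keep]
    qual <- vapply(fields, `[[`, "", 4L)
    fields <- fields[!grepl("(^|\\|)NOT($|\\|)", qual)]
    gene <- vapply(fields, `[[`, "", 3L)
    term <- vapply(fields, `[[`, "", 5L)
    aspect_code <- vapply(fields, `[[`, "", 9L)
    aspect <- c(P = "BP", F = "MF", C = "CC")[aspect_code]
    aspect[is.na(aspect)] <- "unknown"
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    keep <- vapply(fields, length, 1L) >= 2L
    fields <- fields[keep]
    gene <- vapply(fields, `[[`, "", 1L)
    term <- vapply(fields, `[[`, "", 2L)
    aspect <- rep("unknown", length(gene))
  }
  ok <- nzchar(gene) & grepl(GO_ID_PATTERN, term)
  n_bad <- sum(!ok)
  if (n_bad > 0L) {
    warning(n_bad, " record(s) with malformed or empty gene/GO ids skipped")
  }
  tab <- data.frame(gene = gene[ok], go_term = term[ok], aspect = aspect[ok],
                    stringsAsFactors = FALSE)
  tab <- tab[!duplicated(tab[, c("gene", "go_term")]), , drop = FALSE]
  rownames(tab) <- NULL
  if (nrow(tab) == 0L) stop("no annotations parsed from ", path)
  class(tab) <- c("annotation_table", "data.frame")
  tab
}

#' Read a TF-target table
#'
#' Reads a header-less two-column `tf<TAB>target` table, typically the product
#' of annotating TF binding peaks (e.g. DAP-seq) to transcription start sites.
#' Duplicate edges collapse; self-targeting edges are retained.
#'
#' @param path Path to the TSV (optionally gzipped).
#' @return A data frame of class `tf_target_table` with columns `tf`, `target`.
#' @export
load_tf_targets <- function(path) {
  if (!file.exists(path)) stop("TF-target file not found: ", path)
  lines <- .read_tab_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, length, 1L) >= 2L
  fields <- fields[keep]
  tf <- vapply(fields, `[[`, "", 1L)
  target <- vapply(fields, `[[`, "", 2L)
  ok <- nzchar(tf) & nzchar(target)
  tab <- data.frame(tf = tf[ok], target = target[ok], stringsAsFactors = FALSE)
  tab <- tab[!duplicated(tab), , drop = FALSE]
  rownames(tab) <- NULL
  if (nrow(tab) == 0L) stop("no TF-target records parsed from ", path)
  class(tab) <- c("tf_target_table", "data.frame")
  tab
}

#' Compile knowledge tables into binary connectivity masks
#'
#' Builds the three 0/1 matrices that prune the network: `M_gene_go` (gene i
#' is annotated to GO term j), `M_gene_tf` (gene i is a target of TF t) and
#' `M_tf_go` (TF t feeds GO term j). GO terms are restricted to those whose
#' membership within `gene_vocab` falls in `[min_term_size, max_term_size]`;
#' TFs are restricted to TF genes present in `gene_vocab`. Genes absent from
#' all knowledge remain rows of zeros: they carry no signal through the masked
#' layers but stay addressable in the vocabulary.
#'
#' The TF-to-GO wiring is not dictated by the annotation table itself. Under
#' `tf_go_wiring = "inherit"` (default) a TF node inherits the GO annotations
#' of its own gene, which keeps the layer sparse and gives every TF-GO edge a
#' concrete biological reading; `"dense"` connects every TF to every term.
#'
#' @param annotations An `annotation_table` from [load_go_annotations()].
#' @param tf_targets A `tf_target_table` from [load_tf_targets()], or `NULL`
#'   for a model without a TF layer.
#' @param gene_vocab Ordered character vector of gene ids (usually the
#'   expression matrix columns).
#' @param min_term_size,max_term_size Inclusive bounds on GO-term membership
#'   counted within `gene_vocab`.
#' @param tf_go_wiring `"inherit"` or `"dense"` (see Details).
#' @return A `mask_set`: list with `genes`, `tfs`, `go_terms` vocabularies and
#'   binary matrices `M_gene_go`, `M_gene_tf`, `M_tf_go`.
#' @export
build_masks <- function(annotations, tf_targets = NULL, gene_vocab,
                        min_term_size = 5L, max_term_size = 500L,
                        tf_go_wiring = c("inherit", "dense")) {
  tf_go_wiring <- match.arg(tf_go_wiring)
  if (length(gene_vocab) == 0L) stop("gene_vocab must be non-empty")
  if (anyDuplicated(gene_vocab)) stop("gene_vocab contains duplicates")
  if (min_term_size < 1L || min_term_size > max_term_size) {
    stop("require 1 <= min_term_size <= max_term_size")
  }
  ann <- annotations[annotations$gene %in% gene_vocab, , drop = FALSE]
  ann <- ann[!duplicated(ann[, c("gene", "go_term")]), , drop = FALSE]
  sizes <- table(ann$go_term)
  keep_terms <- sort(names(sizes)[sizes >= min_term_size & sizes <= max_term_size])
  if (length(keep_terms) == 0L) stop("knowledge too sparse for vocabulary")
  ann <- ann[ann$go_term %in% keep_terms, , drop = FALSE]

  M_gene_go <- matrix(0, length(gene_vocab), length(keep_terms),
                      dimnames = list(gene_vocab, keep_terms))
  M_gene_go[cbind(match(ann$gene, gene_vocab), match(ann$go_term, keep_terms))] <- 1

  if (!is.null(tf_targets)) {
    tfs <- sort(unique(tf_targets$tf[tf_targets$tf %in% gene_vocab]))
  } else {
    tfs <- character(0)
  }
  M_gene_tf <- matrix(0, length(gene_vocab), length(tfs),
                      dimnames = list(gene_vocab, tfs))
  if (length(tfs) > 0L) {
    tt <- tf_targets[tf_targets$tf %in% tfs & tf_targets$target %in% gene_vocab, ,
                     drop = FALSE]
    M_gene_tf[cbind(match(tt$target, gene_vocab), match(tt$tf, tfs))] <- 1
  }
  if (tf_go_wiring == "inherit") {
    M_tf_go <- M_gene_go[match(tfs, gene_vocab), , drop = FALSE]
    rownames(M_tf_go) <- tfs
  } else {
    M_tf_go <- matrix(1, length(tfs), length(keep_terms),
                      dimnames = list(tfs, keep_terms))
  }
  structure(list(genes = gene_vocab, tfs = tfs, go_terms = keep_terms,
                 M_gene_go = M_gene_go, M_gene_tf = M_gene_tf, M_tf_go = M_tf_go,
                 min_term_size = as.integer(min_term_size),
                 max_term_size = as.integer(max_term_size),
                 tf_go_wiring = tf_go_wiring),
            class = "mask_set")
}

#' Align masks to an expression vocabulary
#'
#' Restricts and reorders the mask rows to the intersection with
#' `expression_genes`, preserving the expression order, so the mask set can sit
#' directly under an expression matrix. GO columns emptied by the restriction
#' are dropped, as are TFs whose own gene leaves the vocabulary. The fraction
#' of `expression_genes` covered by the knowledge vocabulary is recorded in
#' the `coverage` element.
#'
#' @param masks A `mask_set`.
#' @param expression_genes Ordered gene ids of the expression matrix.
#' @return The aligned `mask_set`.
#' @export
align_masks <- function(masks, expression_genes) {
  stopifnot(inherits(masks, "mask_set"))
  if (length(expression_genes) == 0L) stop("expression_genes must be non-empty")
  keep <- expression_genes[expression_genes %in% masks$genes]
  if (length(keep) == 0L) stop("no overlap between mask genes and expression genes")
  ridx <- match(keep, masks$genes)
  M_gene_go <- masks$M_gene_go[ridx, , drop = FALSE]
  M_gene_tf <- masks$M_gene_tf[ridx, , drop = FALSE]
  keep_tf <- masks$tfs %in% keep
  tfs <- masks$tfs[keep_tf]
  M_gene_tf <- M_gene_tf[, keep_tf, drop = FALSE]
  M_tf_go <- masks$M_tf_go[keep_tf, , drop = FALSE]
  keep_go <- colSums(M_gene_go) >= 1
  if (!any(keep_go)) stop("knowledge too sparse for vocabulary after alignment")
  out <- masks
  out$genes <- keep
  out$tfs <- tfs
  out$go_terms <- masks$go_terms[keep_go]
  out$M_gene_go <- M_gene_go[, keep_go, drop = FALSE]
  out$M_gene_tf <- M_gene_tf
  out$M_tf_go <- M_tf_go[, keep_go, drop = FALSE]
  out$coverage <- length(keep) / length(expression_genes)
  out
}

#' @export
print.mask_set <- function(x, ...) {
  cat("mask_set:", length(x$genes), "genes,", length(x$tfs), "TFs,",
      length(x$go_terms), "GO terms\n")
  cat("  nnz gene-GO:", sum(x$M_gene_go), " gene-TF:", sum(x$M_gene_tf),
      " TF-GO:", sum(x$M_tf_go), "\n")
  if (!is.null(x$coverage)) cat("  expression coverage:", round(x$coverage, 4), "\n")
  invisible(x)
}

# -- serialization ------------------------------------------------------------

.write_coo <- function(mat, file) {
  nz <- which(mat != 0, arr.ind = TRUE)
  lines <- sprintf("%d\t%d\t%.17g", nz[, 1L], nz[, 2L], mat[nz])
  writeLines(c(sprintf("%d\t%d\t%d", nrow(mat), ncol(mat), nrow(nz)), lines), file)
}

.read_coo <- function(file) {
  lines <- readLines(file)
  hdr <- as.integer(strsplit(lines[1L], "\t")[[1L]])
  mat <- matrix(0, hdr[1L], hdr[2L])
  if (hdr[3L] > 0L) {
    body <- strsplit(lines[-1L], "\t", fixed = TRUE)
    i <- as.integer(vapply(body, `[[`, "", 1L))
    j <- as.integer(vapply(body, `[[`, "", 2L))
    v <- as.numeric(vapply(body, `[[`, "", 3L))
    mat[cbind(i, j)] <- v
  }
  mat
}

#' Serialize or restore a mask set
#'
#' The on-disk form is a gzipped tar archive holding the three connectivity
#' matrices in coordinate (row, column, value) text format, the three
#' vocabularies one id per line, and a JSON manifest recording the filter
#' parameters and per-matrix nonzero checksums.
#'
#' @param masks A `mask_set`.
#' @param path Archive path (conventionally `.tar.gz`).
#' @return `write_maskset` returns `path` invisibly; `read_maskset` the
#'   restored `mask_set`.
#' @export
write_maskset <- function(masks, path) {
  stopifnot(inherits(masks, "mask_set"))
  dir <- tempfile("maskset")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  writeLines(masks$genes, file.path(dir, "genes.txt"))
  writeLines(masks$tfs, file.path(dir, "tfs.txt"))
  writeLines(masks$go_terms, file.path(dir, "go_terms.txt"))
  .write_coo(masks$M_gene_go, file.path(dir, "M_gene_go.coo"))
  .write_coo(masks$M_gene_tf, file.path(dir, "M_gene_tf.coo"))
  .write_coo(masks$M_tf_go, file.path(dir, "M_tf_go.coo"))
  manifest <- list(format = "sparsego_maskset", format_version = 1L,
                   min_term_size = masks$min_term_size,
                   max_term_size = masks$max_term_size,
                   tf_go_wiring = masks$tf_go_wiring,
                   nnz = list(gene_go = sum(masks$M_gene_go),
                              gene_tf = sum(masks$M_gene_tf),
                              tf_go = sum(masks$M_tf_go)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  .tar_dir(dir, path)
  invisible(path)
}

.tar_dir <- function(dir, path) {
  owd <- getwd()
  on.exit(setwd(owd))
  if (!grepl("^(/|[A-Za-z]:)", path)) path <- file.path(owd, path)
  setwd(dir)
  utils::tar(path, files = list.files("."),
             compression = "gzip", tar = "internal")
}

.untar_archive <- function(path) {
  if (!file.exists(path)) stop("archive not found: ", path)
  dir <- tempfile("untar")
  dir.create(dir)
  ok <- tryCatch(utils::untar(path, exdir = dir) == 0L, error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok || !file.exists(file.path(dir, "manifest.json"))) {
    unlink(dir, recursive = TRUE)
    stop("archive is unreadable or truncated: ", path)
  }
  dir
}

#' @rdname write_maskset
#' @export
read_maskset <- function(path) {
  dir <- .untar_archive(path)
  on.exit(unlink(dir, recursive = TRUE))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  if (!identical(manifest$format, "sparsego_maskset")) {
    stop("not a mask_set archive: ", path)
  }
  if (!identical(as.integer(manifest$format_version), 1L)) {
    stop("unsupported mask_set format version: ", manifest$format_version)
  }
  genes <- readLines(file.path(dir, "genes.txt"))
  tfs <- .read_lines_maybe_empty(file.path(dir, "tfs.txt"))
  go_terms <- readLines(file.path(dir, "go_terms.txt"))
  dimn <- function(m, rn, cn) { dimnames(m) <- list(rn, cn); m }
  structure(list(genes = genes, tfs = tfs, go_terms = go_terms,
                 M_gene_go = dimn(.read_coo(file.path(dir, "M_gene_go.coo")), genes, go_terms),
                 M_gene_tf = dimn(.read_coo(file.path(dir, "M_gene_tf.coo")), genes, tfs),
                 M_tf_go = dimn(.read_coo(file.path(dir, "M_tf_go.coo")), tfs, go_terms),
                 min_term_size = as.integer(manifest$min_term_size),
                 max_term_size = as.integer(manifest$max_term_size),
                 tf_go_wiring = manifest$tf_go_wiring),
            class = "mask_set")
}

.read_lines_maybe_empty <- function(path) {
  if (!file.exists(path) || file.size(path) == 0L) return(character(0))
  readLines(path)
}
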