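# Synthetic study system: random gene-GO and TF-target knowledge graphs with
# one planted GO term and one planted TF regulon per cell type, plus
# negative-binomial counts in which each type's marker program is shifted up
# on the log scale. Everything is deterministic given the scenario seed, so
# mask construction, training, attribution and perturbation can all be
# validated against the planted ground truth without external data.

#' Define a synthetic scenario
#'
#' The defaults describe the reference study condition used throughout the
#' package's validation: 5 cell types x 200 cells, 500 genes, 10 markers per
#' type with a log-scale effect of 2 (about 7.4-fold), negative-binomial
#' counts with dispersion 0.5.
#'
#' @param n_genes,n_tfs,n_terms Sizes of the gene, TF and GO-term universes.
#' @param genes_per_term Genes annotated to each non-planted GO term.
#' @param targets_per_tf Targets per TF regulon (planted regulons contain at
#'   least the type's markers).
#' @param n_cell_types,n_cells_per_type Population design.
#' @param marker_genes_per_type Planted marker genes per cell type; marker
#'   sets of distinct types are disjoint.
#' @param effect_size Log-scale mean shift of a type's markers in that type
#'   (default 2.0).
#' @param program_genes Genes per direction in the continuous-state programs
#'   of [simulate_continuous()] (default 40, the scale of published
#'   senescence expression signatures, which span tens of genes).
#' @param dispersion Negative-binomial overdispersion (`size = 1/dispersion`;
#'   default 0.5).
#' @param baseline_mean Baseline NB mean per gene (default 1.0).
#' @param seed Scenario seed; all generator draws derive from it.
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(n_genes = 500L, n_tfs = 25L, n_terms = 40L,
                               genes_per_term = 10L, targets_per_tf = 10L,
                               n_cell_types = 5L, n_cells_per_type = 200L,
                               marker_genes_per_type = 10L,
                               effect_size = 2.0, dispersion = 0.5,
                               baseline_mean = 1.0, program_genes = 40L,
                               seed = 1L) {
  sc <- list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
             n_terms = as.integer(n_terms),
             genes_per_term = as.integer(genes_per_term),
             targets_per_tf = as.integer(targets_per_tf),
             n_cell_types = as.integer(n_cell_types),
             n_cells_per_type = as.integer(n_cells_per_type),
             marker_genes_per_type = as.integer(marker_genes_per_type),
             effect_size = effect_size, dispersion = dispersion,
             baseline_mean = baseline_mean,
             program_genes = as.integer(program_genes),
             seed = as.integer(seed))
  counts <- unlist(sc[c("n_genes", "n_tfs", "n_terms", "genes_per_term",
                        "targets_per_tf", "n_cell_types", "n_cells_per_type",
                        "marker_genes_per_type")])
  if (any(counts < 1L)) stop("all scenario counts must be positive")
  if (sc$dispersion <= 0 || sc$baseline_mean <= 0) {
    stop("dispersion and baseline_mean must be positive")
  }
  structure(sc, class = "synthetic_scenario")
}

#' Generate a knowledge graph with planted class programs
#'
#' Draws random gene-GO and TF-target bipartite graphs at the scenario sizes
#' and plants, for each cell type k, a designated GO term annotated exactly to
#' the type's marker genes (plus its designated TF's own gene, so the TF node
#' inherits the term) and a designated TF whose regulon covers those markers.
#' The planted assignments are returned as `planted_truth` for recovery
#' checks.
#'
#' @param scenario A `synthetic_scenario`.
#' @return List with `annotations` (an `annotation_table`), `tf_targets`
#'   (a `tf_target_table`) and `planted_truth` (per-type list of `label`,
#'   `markers`, `go_term`, `tf`).
#' @export
make_knowledge <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  s <- scenario
  n_marker <- s$n_cell_types * s$marker_genes_per_type
  if (n_marker + s$n_tfs > s$n_genes) {
    stop("scenario too small: markers + TFs exceed the gene universe")
  }
  if (s$genes_per_term > s$n_genes || s$targets_per_tf > s$n_genes) {
    stop("genes_per_term/targets_per_tf exceed the gene universe")
  }
  if (s$n_terms < s$n_cell_types || s$n_tfs < s$n_cell_types) {
    stop("need at least one GO term and one TF per cell type")
  }
  set.seed(s$seed)
  genes <- sprintf("G%04d", seq_len(s$n_genes))
  terms <- sprintf("GO:%07d", seq_len(s$n_terms))
  labels <- paste0("type", seq_len(s$n_cell_types))

  marker_pool <- sample(genes, n_marker)
  markers <- split(marker_pool, rep(seq_len(s$n_cell_types),
                                    each = s$marker_genes_per_type))
  tf_genes <- sample(setdiff(genes, marker_pool), s$n_tfs)

  ann <- list(); tt <- list(); truth <- list()
  for (k in seq_len(s$n_cell_types)) {
    term_k <- terms[k]; tf_k <- tf_genes[k]
    member_k <- c(markers[[k]], tf_k)   # TF gene inherits the planted term
    ann[[k]] <- data.frame(gene = member_k, go_term = term_k,
                           aspect = "BP", stringsAsFactors = FALSE)
    extra <- max(0L, s$targets_per_tf - s$marker_genes_per_type)
    targets_k <- c(markers[[k]],
                   if (extra > 0L) sample(setdiff(genes, markers[[k]]), extra))
    tt[[k]] <- data.frame(tf = tf_k, target = targets_k, stringsAsFactors = FALSE)
    truth[[labels[k]]] <- list(label = labels[k], markers = markers[[k]],
                               go_term = term_k, tf = tf_k)
  }
  if (s$n_terms > s$n_cell_types) {
    for (j in seq(s$n_cell_types + 1L, s$n_terms)) {
      ann[[length(ann) + 1L]] <- data.frame(
        gene = sample(genes, s$genes_per_term), go_term = terms[j],
        aspect = sample(c("BP", "MF", "CC"), 1L), stringsAsFactors = FALSE)
    }
  }
  if (s$n_tfs > s$n_cell_types) {
    for (t in seq(s$n_cell_types + 1L, s$n_tfs)) {
      tt[[length(tt) + 1L]] <- data.frame(
        tf = tf_genes[t], target = sample(genes, s$targets_per_tf),
        stringsAsFactors = FALSE)
    }
  }
  annotations <- do.call(rbind, ann)
  annotations <- annotations[!duplicated(annotations[, c("gene", "go_term")]), ]
  rownames(annotations) <- NULL
  class(annotations) <- c("annotation_table", "data.frame")
  tf_targets <- do.call(rbind, tt)
  tf_targets <- tf_targets[!duplicated(tf_targets), ]
  rownames(tf_targets) <- NULL
  class(tf_targets) <- c("tf_target_table", "data.frame")
  list(annotations = annotations, tf_targets = tf_targets,
       planted_truth = truth, genes = genes, labels = labels)
}

#' Simulate classed cell populations
#'
#' Counts are negative binomial with per-gene mean `baseline_mean`, scaled by
#' `exp(effect_size)` for the markers of the cell's type. Draws come from a
#' seed derived from the scenario seed, so cells are reproducible and
#' independent of the knowledge-graph draws.
#'
#' @param scenario A `synthetic_scenario`.
#' @param knowledge Output of [make_knowledge()].
#' @return List with `counts` (cells x genes integer matrix, cells named
#'   `cell0001...`), `labels` (cell type per cell).
#' @export
simulate_cells <- function(scenario, knowledge) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  s <- scenario
  genes <- knowledge$genes
  n_cells <- s$n_cell_types * s$n_cells_per_type
  type_of <- rep(knowledge$labels, each = s$n_cells_per_type)
  mu_type <- matrix(s$baseline_mean, s$n_cell_types, s$n_genes,
                    dimnames = list(knowledge$labels, genes))
  for (k in seq_len(s$n_cell_types)) {
    mk <- knowledge$planted_truth[[k]]$markers
    mu_type[k, mk] <- s$baseline_mean * exp(s$effect_size)
  }
  set.seed(s$seed + 1000L)
  mu <- mu_type[type_of, , drop = FALSE]
  counts <- matrix(stats::rnbinom(n_cells * s$n_genes, mu = mu,
                                  size = 1 / s$dispersion),
                   n_cells, s$n_genes,
                   dimnames = list(sprintf("cell%04d", seq_len(n_cells)), genes))
  list(counts = counts, labels = type_of)
}

#' Simulate a continuous cell state
#'
#' Mirrors a graded cell state such as a senescence score: each cell draws a
#' latent score s ~ U(0, 1); an "up-program" gene set has its NB mean scaled
#' by `exp(effect_size * s)` and a disjoint "down-program" by
#' `exp(-effect_size * s)`. Both programs hold `program_genes` genes sampled
#' from the GO-annotated part of the universe, emulating signature-scale
#' state programs (real senescence signatures span tens of annotated genes)
#' that a knowledge-masked model can see through its GO layer.
#'
#' @param scenario A `synthetic_scenario`.
#' @param knowledge Output of [make_knowledge()].
#' @return List with `counts`, `scores` (in \[0, 1\]), `up_program`,
#'   `down_program`.
#' @export
simulate_continuous <- function(scenario, knowledge) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  s <- scenario
  genes <- knowledge$genes
  n_cells <- s$n_cell_types * s$n_cells_per_type
  annotated <- unique(knowledge$annotations$gene)
  if (length(annotated) < 2L * s$program_genes) {
    stop("not enough GO-annotated genes for two disjoint programs of ",
         s$program_genes)
  }
  set.seed(s$seed + 2000L)
  pool <- sample(annotated)
  up <- pool[seq_len(s$program_genes)]
  down <- pool[s$program_genes + seq_len(s$program_genes)]
  scores <- stats::runif(n_cells)
  mu <- matrix(s$baseline_mean, n_cells, s$n_genes,
               dimnames = list(sprintf("cell%04d", seq_len(n_cells)), genes))
  mu[, up] <- mu[, up] * exp(s$effect_size * scores)
  mu[, down] <- mu[, down] * exp(-s$effect_size * scores)
  counts <- matrix(stats::rnbinom(n_cells * s$n_genes, mu = mu,
                                  size = 1 / s$dispersion),
                   n_cells, s$n_genes, dimnames = dimnames(mu))
  list(counts = counts, scores = scores, up_program = up, down_program = down)
}

#' Depth-normalize and log-transform counts
#'
#' The standard single-cell convention: per cell,
#' `log(1 + scale_factor * count / total_counts)`. Cells with zero total
#' counts are dropped with a warning.
#'
#' @param counts Non-negative cells-by-genes count matrix.
#' @param scale_factor Library-size target (default 10000).
#' @return An `expression_matrix` (list with `values`, `gene_names`,
#'   `cell_ids`).
#' @export
lognormalize <- function(counts, scale_factor = 10000) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("gene%04d", seq_len(ncol(counts)))
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  totals <- rowSums(counts)
  if (all(totals == 0)) stop("all cells have zero total counts")
  if (any(totals == 0)) {
    warning(sum(totals == 0), " cell(s) with zero total counts dropped")
    counts <- counts[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  values <- log1p(scale_factor * counts / totals)
  expression_matrix(values,
                    gene_names = colnames(counts),
                    cell_ids = rownames(counts))
}

#' Construct an expression matrix container
#'
#' A light container for log-normalized cells-by-genes values with unique
#' gene names; used as the common currency between the readers, the
#' generator and the model.
#'
#' @param values Numeric cells-by-genes matrix (non-negative).
#' @param gene_names,cell_ids Optional vocabularies (default: dimnames).
#' @return An `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_names = NULL, cell_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(gene_names)) gene_names <- colnames(values)
  if (is.null(cell_ids)) cell_ids <- rownames(values)
  if (is.null(gene_names)) stop("gene names are required")
  if (anyDuplicated(gene_names)) stop("gene names must be unique")
  if (any(values < 0)) stop("log-normalized values must be non-negative")
  if (is.null(cell_ids)) cell_ids <- sprintf("cell%04d", seq_len(nrow(values)))
  dimnames(values) <- list(cell_ids, gene_names)
  structure(list(values = values, gene_names = gene_names, cell_ids = cell_ids),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "cells x", ncol(x$values), "genes\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)
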