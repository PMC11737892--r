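# The masked network. Every hidden node is a named biological entity:
# genes feed TF nodes and GO-term nodes through mask-pruned linear layers,
# GO nodes feed the output head (cell type logits or one regression node).
#
#   h_tf = act( X (W_gene_tf . M_gene_tf) + b_tf )
#   h_go = act( X (W_gene_go . M_gene_go) + h_tf (W_tf_go . M_tf_go) + b_go )
#   classification: q = softmax( h_go W_go_out + b_out )
#   regression:     score = h_go W_go_out + b_out
#
# The sparsity contract is exact: weights at mask-zero positions are 0 after
# initialization and after every optimizer step.

.act_fun <- function(name) {
  switch(name,
         relu = function(z) pmax(z, 0),
         tanh = tanh,
         identity = function(z) z,
         stop("unknown activation: ", name))
}

.act_grad <- function(name) {
  switch(name,
         relu = function(z) (z > 0) * 1,
         tanh = function(z) 1 - tanh(z)^2,
         identity = function(z) array(1, dim(z)),
         stop("unknown activation: ", name))
}

#' Initialize a knowledge-masked model
#'
#' Weights are drawn at mask-one positions only, as scaled Gaussians
#' (He-style, sd = sqrt(2 / fan-in)); mask-zero positions are exactly zero and
#' stay so through training. Biases start at zero. Initialization is
#' deterministic given `seed`.
#'
#' @param masks A `mask_set` aligned to the expression vocabulary
#'   (see [align_masks()]).
#' @param labels Ordered output labels (cell types) for classification;
#'   ignored in regression mode, where the single output node is the
#'   continuous score.
#' @param mode `"classification"` or `"regression"`.
#' @param seed Integer RNG seed for the weight draws.
#' @param activation Hidden nonlinearity: `"relu"` (default), `"tanh"`, or
#'   `"identity"` (linear; mainly for attribution sanity checks).
#' @param use_direct_gene_go Keep the direct gene-to-GO path alongside the
#'   gene-to-TF-to-GO path (default `TRUE`); disabling it routes all signal
#'   through TF nodes, for ablation.
#' @return A `sparsego_model`.
#' @export
init_model <- function(masks, labels = NULL,
                       mode = c("classification", "regression"),
                       seed = 1L,
                       activation = c("relu", "tanh", "identity"),
                       use_direct_gene_go = TRUE) {
  mode <- match.arg(mode)
  activation <- match.arg(activation)
  stopifnot(inherits(masks, "mask_set"))
  if (mode == "classification") {
    if (length(labels) == 0L) stop("classification mode requires non-empty labels")
    labels <- as.character(labels)
    if (anyDuplicated(labels)) stop("labels must be unique")
  } else {
    labels <- "score"
  }
  n_out <- if (mode == "classification") length(labels) else 1L
  n_gene <- length(masks$genes); n_tf <- length(masks$tfs)
  n_go <- length(masks$go_terms)
  if (n_go == 0L) stop("mask set has no GO terms")
  masks_eff <- masks
  if (!use_direct_gene_go) masks_eff$M_gene_go[] <- 0

  set.seed(as.integer(seed))
  draw <- function(nr, nc, fan_in) {
    matrix(stats::rnorm(nr * nc, sd = sqrt(2 / max(fan_in, 1L))), nr, nc)
  }
  # Masked layers start half-normal (positive): expression is non-negative, so
  # every knowledge-supported edge begins as usable positive evidence for its
  # GO/TF node instead of half of them starting inhibitory and risking getting
  # stuck behind a dead relu. The dense head stays symmetric.
  W_gene_tf <- abs(draw(n_gene, n_tf, n_gene)) * masks_eff$M_gene_tf
  W_gene_go <- abs(draw(n_gene, n_go, n_gene)) * masks_eff$M_gene_go
  W_tf_go <- abs(draw(n_tf, n_go, max(n_tf, 1L))) * masks_eff$M_tf_go
  W_go_out <- draw(n_go, n_out, n_go)
  dimnames(W_gene_tf) <- dimnames(masks_eff$M_gene_tf)
  dimnames(W_gene_go) <- dimnames(masks_eff$M_gene_go)
  dimnames(W_tf_go) <- dimnames(masks_eff$M_tf_go)
  dimnames(W_go_out) <- list(masks$go_terms, labels)

  structure(list(
    masks = masks_eff,
    W = list(gene_tf = W_gene_tf, gene_go = W_gene_go,
             tf_go = W_tf_go, go_out = W_go_out),
    b = list(tf = stats::setNames(numeric(n_tf), masks$tfs),
             go = stats::setNames(numeric(n_go), masks$go_terms),
             out = stats::setNames(numeric(n_out), labels)),
    labels = labels, mode = mode, activation = activation,
    use_direct_gene_go = use_direct_gene_go,
    seed = as.integer(seed), trained = FALSE,
    normalization = "unspecified"
  ), class = "sparsego_model")
}

.as_matrix_input <- function(model, X) {
  if (inherits(X, "expression_matrix")) X <- X$values
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (ncol(X) != length(model$masks$genes)) {
    stop("expression has ", ncol(X), " genes; model expects ",
         length(model$masks$genes))
  }
  gn <- colnames(X)
  if (!is.null(gn) && !identical(gn, model$masks$genes)) {
    if (!setequal(gn, model$masks$genes)) {
      stop("expression gene names do not match the model vocabulary")
    }
    X <- X[, model$masks$genes, drop = FALSE]
  }
  X
}

# Full forward pass; keeps pre-activations for backprop / attribution.
.forward_pass <- function(model, X) {
  act <- .act_fun(model$activation)
  Z_tf <- X %*% model$W$gene_tf
  Z_tf <- sweep(Z_tf, 2L, model$b$tf, "+")
  H_tf <- act(Z_tf)
  Z_go <- X %*% model$W$gene_go + H_tf %*% model$W$tf_go
  Z_go <- sweep(Z_go, 2L, model$b$go, "+")
  H_go <- act(Z_go)
  logits <- sweep(H_go %*% model$W$go_out, 2L, model$b$out, "+")
  out <- list(Z_tf = Z_tf, H_tf = H_tf, Z_go = Z_go, H_go = H_go,
              logits = logits)
  if (model$mode == "classification") out$probs <- .softmax_rows(logits)
  out
}

.softmax_rows <- function(logits) {
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

#' Run the network forward on expression input
#'
#' @param model A `sparsego_model`.
#' @param x A single expression row or a cells-by-genes matrix (or
#'   `expression_matrix`), aligned to the model's gene vocabulary.
#' @return In classification mode a matrix of class probabilities (rows sum
#'   to 1); in regression mode a numeric score per cell. A single input row
#'   yields a vector.
#' @export
forward <- function(model, x) {
  stopifnot(inherits(model, "sparsego_model"))
  one_row <- is.null(dim(x)) && !inherits(x, "expression_matrix")
  X <- .as_matrix_input(model, x)
  fw <- .forward_pass(model, X)
  out <- if (model$mode == "classification") fw$probs else fw$logits[, 1L]
  if (model$mode == "classification") {
    colnames(out) <- model$labels
    if (one_row) out <- out[1L, ]
  }
  out
}

#' Count trainable parameters
#'
#' Reports the parameter budget of the masked network next to its dense
#' equivalent (same layer shapes with all-ones masks). The masked layers are
#' the gene-TF, gene-GO and TF-GO blocks; the GO-to-output head and biases
#' are dense in both.
#'
#' @param model A `sparsego_model`.
#' @return List with `sparse_count`, `dense_equivalent_count`, the masked-layer
#'   subtotals `masked_nnz` / `masked_dense`, and `head_and_bias`.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "sparsego_model"))
  m <- model$masks
  masked_nnz <- sum(m$M_gene_tf) + sum(m$M_gene_go) + sum(m$M_tf_go)
  masked_dense <- length(m$M_gene_tf) + length(m$M_gene_go) + length(m$M_tf_go)
  head_and_bias <- length(model$W$go_out) +
    length(model$b$tf) + length(model$b$go) + length(model$b$out)
  list(sparse_count = masked_nnz + head_and_bias,
       dense_equivalent_count = masked_dense + head_and_bias,
       masked_nnz = masked_nnz, masked_dense = masked_dense,
       head_and_bias = head_and_bias)
}

#' @export
print.sparsego_model <- function(x, ...) {
  p <- count_parameters(x)
  cat("sparsego_model (", x$mode, ", ", x$activation, ")\n", sep = "")
  cat("  ", length(x$masks$genes), "genes ->", length(x$masks$tfs), "TFs ->",
      length(x$masks$go_terms), "GO terms ->", length(x$labels), "outputs\n")
  cat("  parameters:", p$sparse_count, "(dense equivalent",
      p$dense_equivalent_count, ")\n")
  cat("  trained:", x$trained, "\n")
  invisible(x)
}

# -- persistence --------------------------------------------------------------

MODEL_FORMAT_VERSION <- 1L

#' Save or restore a trained model archive
#'
#' The archive is a gzipped tar directory: a JSON manifest (format version,
#' mode, activation, labels, normalization convention), vocabularies as text,
#' masks and masked weights in coordinate text format, and the dense head and
#' biases. Weight round-trips are bit-exact ("%.17g" text encoding).
#'
#' @param model A `sparsego_model`.
#' @param path Archive path (conventionally `.tar.gz`).
#' @return `save_model` returns `path` invisibly; `load_model` the restored
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sparsego_model"))
  dir <- tempfile("model")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  m <- model$masks
  writeLines(m$genes, file.path(dir, "genes.txt"))
  writeLines(m$tfs, file.path(dir, "tfs.txt"))
  writeLines(m$go_terms, file.path(dir, "go_terms.txt"))
  for (nm in c("M_gene_go", "M_gene_tf", "M_tf_go")) {
    .write_coo(m[[nm]], file.path(dir, paste0(nm, ".coo")))
  }
  for (nm in names(model$W)) {
    .write_coo(model$W[[nm]], file.path(dir, paste0("W_", nm, ".coo")))
  }
  for (nm in names(model$b)) {
    writeLines(sprintf("%.17g", model$b[[nm]]), file.path(dir, paste0("b_", nm, ".txt")))
  }
  manifest <- list(format = "sparsego_model",
                   format_version = MODEL_FORMAT_VERSION,
                   mode = model$mode, activation = model$activation,
                   labels = as.list(model$labels),
                   use_direct_gene_go = model$use_direct_gene_go,
                   seed = model$seed, trained = model$trained,
                   normalization = model$normalization,
                   target_center = model$target_center,
                   target_scale = model$target_scale,
                   mask_filters = list(min_term_size = m$min_term_size,
                                       max_term_size = m$max_term_size,
                                       tf_go_wiring = m$tf_go_wiring))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  .tar_dir(dir, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  dir <- .untar_archive(path)
  on.exit(unlink(dir, recursive = TRUE))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  if (!identical(manifest$format, "sparsego_model")) {
    stop("not a sparsego model archive: ", path)
  }
  if (!identical(as.integer(manifest$format_version), MODEL_FORMAT_VERSION)) {
    stop("unsupported model format version: ", manifest$format_version)
  }
  if (is.null(manifest$mode)) stop("model manifest is missing 'mode'")
  genes <- readLines(file.path(dir, "genes.txt"))
  tfs <- .read_lines_maybe_empty(file.path(dir, "tfs.txt"))
  go_terms <- readLines(file.path(dir, "go_terms.txt"))
  labels <- unlist(manifest$labels)
  dimn <- function(m, rn, cn) { dimnames(m) <- list(rn, cn); m }
  masks <- structure(list(
    genes = genes, tfs = tfs, go_terms = go_terms,
    M_gene_go = dimn(.read_coo(file.path(dir, "M_gene_go.coo")), genes, go_terms),
    M_gene_tf = dimn(.read_coo(file.path(dir, "M_gene_tf.coo")), genes, tfs),
    M_tf_go = dimn(.read_coo(file.path(dir, "M_tf_go.coo")), tfs, go_terms),
    min_term_size = as.integer(manifest$mask_filters$min_term_size),
    max_term_size = as.integer(manifest$mask_filters$max_term_size),
    tf_go_wiring = manifest$mask_filters$tf_go_wiring), class = "mask_set")
  W <- list(
    gene_tf = dimn(.read_coo(file.path(dir, "W_gene_tf.coo")), genes, tfs),
    gene_go = dimn(.read_coo(file.path(dir, "W_gene_go.coo")), genes, go_terms),
    tf_go = dimn(.read_coo(file.path(dir, "W_tf_go.coo")), tfs, go_terms),
    go_out = dimn(.read_coo(file.path(dir, "W_go_out.coo")), go_terms, labels))
  b <- list(tf = stats::setNames(as.numeric(.read_lines_maybe_empty(file.path(dir, "b_tf.txt"))), tfs),
            go = stats::setNames(as.numeric(readLines(file.path(dir, "b_go.txt"))), go_terms),
            out = stats::setNames(as.numeric(readLines(file.path(dir, "b_out.txt"))), labels))
  out <- structure(list(masks = masks, W = W, b = b, labels = labels,
                        mode = manifest$mode, activation = manifest$activation,
                        use_direct_gene_go = isTRUE(manifest$use_direct_gene_go),
                        seed = as.integer(manifest$seed),
                        trained = isTRUE(manifest$trained),
                        normalization = manifest$normalization),
                   class = "sparsego_model")
  if (!is.null(manifest$target_scale)) {
    out$target_center <- as.numeric(manifest$target_center)
    out$target_scale <- as.numeric(manifest$target_scale)
  }
  out
}
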