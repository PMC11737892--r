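# Interpretation: reference-based per-gene contribution scores (the rescale
# rule) and weight tracing of GO-term / TF contributions to an output class.
#
# The rescale rule replaces the derivative of each nonlinearity by the finite
# difference (act(z) - act(z0)) / (z - z0) against a reference forward pass.
# Because the rest of the network is linear, the per-gene contributions
# (x - x0) * backpropagated multipliers telescope exactly:
#   sum_genes contribution = logit_target(x) - logit_target(x0)
# which is asserted as the completeness property. Attribution is computed on
# pre-softmax logits, where the identity is exact.

.rescale_multipliers <- function(model, Z, Z0, eps = 1e-10) {
  act <- .act_fun(model$activation)
  agrad <- .act_grad(model$activation)
  dZ <- sweep(Z, 2L, Z0, "-")
  num <- sweep(act(Z), 2L, act(Z0), "-")
  m <- num / dZ
  small <- abs(dZ) < eps
  if (any(small)) {
    g <- agrad(Z)
    m[small] <- g[small]
  }
  m
}

#' Per-cell gene contributions to a class logit
#'
#' Backpropagates rescale-rule multipliers from the target class logit down to
#' the gene layer and returns `(x - reference) * multiplier` per cell and
#' gene. The contributions of each cell sum exactly to the difference between
#' its target logit and the reference logit.
#'
#' @param model A trained classification `sparsego_model`.
#' @param X Cells-by-genes matrix or `expression_matrix`.
#' @param target_label Output class to explain.
#' @param reference `"zeros"` (all-zero expression, the default) or `"mean"`
#'   (column means of `X`), or a numeric reference row.
#' @return List with `contributions` (cells x genes), `delta_logit` (per-cell
#'   target logit minus reference logit) and `reference` (the reference row).
#' @export
gene_contributions <- function(model, X, target_label,
                               reference = c("zeros", "mean")) {
  stopifnot(inherits(model, "sparsego_model"))
  if (model$mode != "classification") stop("attribution requires a classification model")
  X <- .as_matrix_input(model, X)
  if (nrow(X) == 0L) stop("X is empty")
  t_idx <- match(target_label, model$labels)
  if (is.na(t_idx)) stop("target_label not in model label map: ", target_label)
  if (is.character(reference)) {
    reference <- match.arg(reference)
    x0 <- if (reference == "zeros") numeric(ncol(X)) else colMeans(X)
    ref_desc <- reference
  } else {
    x0 <- as.numeric(reference)
    if (length(x0) != ncol(X)) stop("numeric reference has wrong length")
    ref_desc <- "custom"
  }

  fw <- .forward_pass(model, X)
  fw0 <- .forward_pass(model, matrix(x0, nrow = 1L))
  m_tf <- .rescale_multipliers(model, fw$Z_tf, fw0$Z_tf[1L, ])
  m_go <- .rescale_multipliers(model, fw$Z_go, fw0$Z_go[1L, ])

  w_out <- model$W$go_out[, t_idx]                     # |go|
  r_go <- sweep(m_go, 2L, w_out, "*")                  # cells x go
  r_tf <- (r_go %*% t(model$W$tf_go)) * m_tf           # cells x tf
  mult_gene <- r_go %*% t(model$W$gene_go) + r_tf %*% t(model$W$gene_tf)
  dX <- sweep(X, 2L, x0, "-")
  contrib <- dX * mult_gene
  colnames(contrib) <- model$masks$genes
  list(contributions = contrib,
       delta_logit = unname(fw$logits[, t_idx] - fw0$logits[1L, t_idx]),
       reference = x0, reference_description = ref_desc)
}

.new_attribution_report <- function(target_label, gene_scores = NULL,
                                    go_scores = NULL, tf_scores = NULL,
                                    reference_description = "") {
  structure(list(target_label = target_label, gene_scores = gene_scores,
                 go_scores = go_scores, tf_scores = tf_scores,
                 reference_description = reference_description),
            class = "attribution_report")
}

#' Rank genes by importance for a predicted class
#'
#' Averages the rescale-rule contributions of [gene_contributions()] over the
#' cells the model predicts as `target_label`, yielding one importance score
#' per gene in the model vocabulary. High-scoring genes are candidate markers
#' of that class.
#'
#' @inheritParams gene_contributions
#' @return An `attribution_report` with `gene_scores` (named, model gene
#'   order; see `sort()` on the vector for a ranking).
#' @export
gene_importance <- function(model, X, target_label,
                            reference = c("zeros", "mean")) {
  stopifnot(inherits(model, "sparsego_model"))
  if (!target_label %in% model$labels) {
    stop("target_label not in model label map: ", target_label)
  }
  X <- .as_matrix_input(model, X)
  pred <- predict(model, X, novelty_threshold = 0)
  sel <- pred$predicted_label == target_label
  if (!any(sel)) stop("no cells predicted as '", target_label, "'")
  gc <- gene_contributions(model, X[sel, , drop = FALSE], target_label, reference)
  scores <- colMeans(gc$contributions)
  .new_attribution_report(target_label, gene_scores = scores,
                          reference_description = gc$reference_description)
}

#' Ensemble-averaged gene importance
#'
#' Averages [gene_importance()] scores over several independently trained
#' models (training restarts). Single-restart rankings can let tight-margin
#' background genes displace genuine markers; averaging over restarts is the
#' standard variance-reduction device and gives markedly more stable
#' rankings.
#'
#' @param models List of trained classification models sharing one
#'   vocabulary and label map.
#' @inheritParams gene_contributions
#' @return An `attribution_report` with the averaged `gene_scores`.
#' @export
ensemble_gene_importance <- function(models, X, target_label,
                                     reference = c("zeros", "mean")) {
  stopifnot(is.list(models), length(models) >= 1L)
  reports <- lapply(models, function(m) {
    gene_importance(m, X, target_label, reference = reference)
  })
  scores <- Reduce(`+`, lapply(reports, `[[`, "gene_scores")) / length(reports)
  .new_attribution_report(target_label, gene_scores = scores,
                          reference_description = paste0(
                            reports[[1L]]$reference_description,
                            " (ensemble of ", length(models), ")"))
}

#' GO-term contributions to a class by weight tracing
#'
#' In `"weight"` mode the score of a GO node is the absolute output weight
#' `|W_go_out[g, target]|`; `"weight_times_activation"` additionally scales by
#' the node's mean activation over the supplied cells, giving a data-dependent
#' ranking. The default picks `weight_times_activation` when cells are
#' supplied and `weight` otherwise.
#'
#' @param model A trained `sparsego_model`.
#' @param target_label Output class (ignored for regression models, which have
#'   a single output).
#' @param aggregation `"weight"` or `"weight_times_activation"`.
#' @param X Optional cells for the activation-weighted mode.
#' @return An `attribution_report` with `go_scores` sorted descending (ties
#'   keep vocabulary order).
#' @export
go_contributions <- function(model, target_label = NULL, aggregation = NULL,
                             X = NULL) {
  stopifnot(inherits(model, "sparsego_model"))
  if (is.null(aggregation)) {
    aggregation <- if (is.null(X)) "weight" else "weight_times_activation"
  }
  aggregation <- match.arg(aggregation, c("weight", "weight_times_activation"))
  t_idx <- if (model$mode == "regression") 1L else match(target_label, model$labels)
  if (is.na(t_idx)) stop("target_label not in model label map: ", target_label)
  scores <- abs(model$W$go_out[, t_idx])
  if (aggregation == "weight_times_activation") {
    if (is.null(X)) stop("weight_times_activation aggregation requires X")
    X <- .as_matrix_input(model, X)
    fw <- .forward_pass(model, X)
    scores <- scores * colMeans(fw$H_go)
  }
  names(scores) <- model$masks$go_terms
  ord <- order(-scores)   # stable: ties keep vocabulary order
  .new_attribution_report(if (is.null(target_label)) model$labels[t_idx] else target_label,
                          go_scores = scores[ord],
                          reference_description = aggregation)
}

#' TF contributions to a class by two-layer weight tracing
#'
#' Extends the GO-term tracing one layer deeper: the score of TF `t` is
#' `sum_g |W_tf_go[t, g]| * |W_go_out[g, target]|` over its mask-supported
#' GO edges, i.e. the total absolute weight of all TF-to-GO-to-output paths.
#'
#' @inheritParams go_contributions
#' @return An `attribution_report` with `tf_scores` sorted descending.
#' @export
tf_contributions <- function(model, target_label = NULL) {
  stopifnot(inherits(model, "sparsego_model"))
  t_idx <- if (model$mode == "regression") 1L else match(target_label, model$labels)
  if (is.na(t_idx)) stop("target_label not in model label map: ", target_label)
  scores <- as.numeric(abs(model$W$tf_go) %*% abs(model$W$go_out[, t_idx]))
  names(scores) <- model$masks$tfs
  ord <- order(-scores)
  .new_attribution_report(if (is.null(target_label)) model$labels[t_idx] else target_label,
                          tf_scores = scores[ord])
}

#' @export
print.attribution_report <- function(x, n = 10L, ...) {
  cat("attribution_report for class '", x$target_label, "'\n", sep = "")
  show <- function(v, what) {
    if (is.null(v)) return()
    v <- sort(v, decreasing = TRUE)
    cat("  top ", what, ":\n", sep = "")
    print(utils::head(v, n))
  }
  show(x$gene_scores, "genes")
  show(x$go_scores, "GO terms")
  show(x$tf_scores, "TFs")
  invisible(x)
}

#' Write an attribution report as TSV plus JSON manifest
#'
#' One TSV per populated score set (`<prefix>_genes.tsv` etc., columns
#' entity/score/rank, sorted descending) and `<prefix>_manifest.json`
#' recording the target label and reference/aggregation mode.
#'
#' @param report An `attribution_report`.
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_attribution_report <- function(report, prefix) {
  stopifnot(inherits(report, "attribution_report"))
  paths <- character(0)
  for (what in c("gene", "go", "tf")) {
    v <- report[[paste0(what, "_scores")]]
    if (is.null(v)) next
    v <- sort(v, decreasing = TRUE)
    p <- paste0(prefix, "_", what, "s.tsv")
    utils::write.table(data.frame(entity = names(v), score = v,
                                  rank = seq_along(v)),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  mp <- paste0(prefix, "_manifest.json")
  jsonlite::write_json(list(target_label = report$target_label,
                            reference = report$reference_description),
                       mp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp))
}
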