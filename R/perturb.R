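# In-silico gene perturbation: scale one gene's expression (x0.5 inhibition,
# x2 activation), re-predict, and rank genes by the fraction of source-class
# cells whose predicted label flips to the target class. Also a de-novo
# TF-target mode: embed TF expression into a latent space, project onto the
# full expression space, and score TF-gene pairs by the decoded fluctuation
# under TF perturbation.

#' Perturb a single gene in an expression profile
#'
#' Multiplies the named gene's expression by the perturbation factor: 0.5 for
#' in-silico inhibition, 2 for in-silico activation. All other values are
#' returned bit-identical.
#'
#' @param x Expression row (named numeric) or cells-by-genes matrix.
#' @param gene Gene name (or column index).
#' @param direction `"inhibit"` (x0.5) or `"activate"` (x2).
#' @param factor Override the scale factor directly (ignores `direction`).
#' @return The perturbed profile, same shape as `x`.
#' @export
perturb_expression <- function(x, gene, direction = c("inhibit", "activate"),
                               factor = NULL) {
  if (is.null(factor)) {
    direction <- match.arg(direction)
    factor <- if (direction == "inhibit") 0.5 else 2
  }
  mat <- !is.null(dim(x))
  nms <- if (mat) colnames(x) else names(x)
  j <- if (is.numeric(gene)) as.integer(gene) else match(gene, nms)
  if (is.na(j) || j < 1L || j > (if (mat) ncol(x) else length(x))) {
    stop("unknown gene: ", gene)
  }
  if (mat) x[, j] <- x[, j] * factor else x[j] <- x[j] * factor
  x
}

#' Screen genes for perturbations that shift cells between classes
#'
#' For every gene and direction (inhibit x0.5, activate x2), perturbs the
#' expression of the source-class cells, re-runs the classifier, and records
#' the fraction of cells whose predicted label flips from `source_label` to
#' `target_label` (hard-flip criterion; set `criterion = "prob_gain"` to
#' instead count cells whose target-class probability rises by more than
#' `delta`). Candidate state-shifting genes are those with a large shift
#' fraction.
#'
#' @param model A trained classification `sparsego_model`.
#' @param X_source Cells of the source class (rows predicted as another class
#'   are dropped before screening).
#' @param source_label,target_label Class to shift from / to.
#' @param min_shift_fraction Report only genes reaching this shift fraction
#'   in at least one direction row (default 0: report all).
#' @param genes Subset of genes to screen (default: full vocabulary).
#' @param criterion `"flip"` or `"prob_gain"`.
#' @param delta Probability gain threshold for `criterion = "prob_gain"`.
#' @return Data frame of class `perturbation_result`: columns `gene`,
#'   `direction`, `scale_factor`, `shift_fraction`, `n_cells`, sorted by
#'   decreasing shift fraction then gene name.
#' @export
screen_genes <- function(model, X_source, source_label, target_label,
                         min_shift_fraction = 0, genes = NULL,
                         criterion = c("flip", "prob_gain"), delta = 0.1) {
  stopifnot(inherits(model, "sparsego_model"))
  criterion <- match.arg(criterion)
  if (model$mode != "classification") stop("screening requires a classification model")
  if (!source_label %in% model$labels || !target_label %in% model$labels) {
    stop("source/target label not in model label map")
  }
  X <- .as_matrix_input(model, X_source)
  base_pred <- predict(model, X, novelty_threshold = 0)
  keep <- base_pred$predicted_label == source_label
  X <- X[keep, , drop = FALSE]
  if (nrow(X) == 0L) stop("no cells predicted as source class '", source_label, "'")
  t_idx <- match(target_label, model$labels)
  base_p <- base_pred$probabilities[keep, t_idx]
  if (is.null(genes)) genes <- model$masks$genes
  gidx <- match(genes, model$masks$genes)
  if (anyNA(gidx)) stop("unknown gene(s): ", paste(genes[is.na(gidx)], collapse = ", "))

  dirs <- c(inhibit = 0.5, activate = 2)
  rows <- vector("list", length(genes) * 2L)
  k <- 0L
  for (gi in seq_along(genes)) {
    for (d in names(dirs)) {
      Xp <- X
      Xp[, gidx[gi]] <- Xp[, gidx[gi]] * dirs[[d]]
      pp <- predict(model, Xp, novelty_threshold = 0)
      frac <- if (criterion == "flip") {
        mean(pp$predicted_label == target_label)
      } else {
        mean(pp$probabilities[, t_idx] - base_p > delta)
      }
      k <- k + 1L
      rows[[k]] <- data.frame(gene = genes[gi], direction = d,
                              scale_factor = dirs[[d]], shift_fraction = frac,
                              n_cells = nrow(X), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res <- res[res$shift_fraction >= min_shift_fraction, , drop = FALSE]
  res <- res[order(-res$shift_fraction, res$gene, res$direction), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("perturbation_result", "data.frame")
  res
}

#' Write a perturbation screen as TSV plus JSON manifest
#'
#' @param result A `perturbation_result` from [screen_genes()].
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_screen_result <- function(result, prefix) {
  p <- paste0(prefix, "_screen.tsv")
  utils::write.table(as.data.frame(result), p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mp <- paste0(prefix, "_manifest.json")
  jsonlite::write_json(list(n_rows = nrow(result),
                            n_cells = if (nrow(result)) result$n_cells[1L] else 0L),
                       mp, auto_unbox = TRUE, digits = NA)
  invisible(c(p, mp))
}

#' De-novo TF-target inference by latent-space perturbation
#'
#' Fits a small encoder-decoder from the TF expression columns to the full
#' expression space: a single hidden layer of size `latent_dim` (relu)
#' trained by Adam to reconstruct the expression matrix (mean squared
#' error). Each TF input is then scaled by `perturb_factor`, re-encoded and
#' decoded, and the pair score is the mean absolute fluctuation of the
#' decoded expression of each gene over cells. Genes whose decoded output
#' reacts strongly to a TF's perturbation are its inferred targets.
#'
#' @param expression Cells-by-genes matrix or `expression_matrix`
#'   (log-normalized).
#' @param tf_list TF gene names; must be columns of `expression`.
#' @param latent_dim Latent dimensionality (default 8; must not exceed the
#'   number of cells).
#' @param seed RNG seed for weight init and batch order.
#' @param perturb_factor Input scale applied to each TF in turn (default 2,
#'   in-silico activation; 1 is the identity and yields all-zero scores).
#' @param epochs,learning_rate,batch_size Reconstruction-training settings
#'   (default 1000 epochs; the mapping is tiny, so epochs are cheap, and the
#'   perturbation scores are only meaningful once reconstruction has
#'   converged).
#' @param score_quantile Return only pairs scoring at or above this quantile
#'   of the full score distribution (default 0: all pairs).
#' @return Data frame `tf`, `target`, `score`, sorted by decreasing score.
#' @export
infer_de_novo_tf_targets <- function(expression, tf_list, latent_dim = 8L,
                                     seed = 1L, perturb_factor = 2,
                                     epochs = 1000L, learning_rate = 0.001,
                                     batch_size = 64L, score_quantile = 0) {
  if (inherits(expression, "expression_matrix")) expression <- expression$values
  X <- as.matrix(expression)
  genes <- colnames(X)
  if (is.null(genes)) stop("expression must have gene column names")
  tf_idx <- match(tf_list, genes)
  if (anyNA(tf_idx)) stop("tf_list contains genes absent from expression")
  n <- nrow(X); k <- length(tf_idx); g <- ncol(X)
  if (n < latent_dim) stop("fewer cells than latent_dim")

  Xtf <- X[, tf_idx, drop = FALSE]
  set.seed(as.integer(seed))
  W1 <- matrix(stats::rnorm(k * latent_dim, sd = sqrt(2 / k)), k, latent_dim)
  b1 <- numeric(latent_dim)
  W2 <- matrix(stats::rnorm(latent_dim * g, sd = sqrt(2 / latent_dim)), latent_dim, g)
  b2 <- numeric(g)
  params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  adam <- .adam_init(params)
  t_step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1L, n)]
      Xb <- Xtf[idx, , drop = FALSE]
      Yb <- X[idx, , drop = FALSE]
      Z1 <- sweep(Xb %*% params$W1, 2L, params$b1, "+")
      H1 <- pmax(Z1, 0)
      Yhat <- sweep(H1 %*% params$W2, 2L, params$b2, "+")
      dY <- 2 * (Yhat - Yb) / (nrow(Xb) * g)
      if (!all(is.finite(dY))) stop("de-novo reconstruction diverged (non-finite loss)")
      gr <- list(W1 = crossprod(Xb, (dY %*% t(params$W2)) * (Z1 > 0)),
                 b1 = colSums((dY %*% t(params$W2)) * (Z1 > 0)),
                 W2 = crossprod(H1, dY), b2 = colSums(dY))
      t_step <- t_step + 1L
      for (nm in names(params)) {
        upd <- .adam_step(params[[nm]], gr[[nm]], adam[[nm]], learning_rate, t_step)
        params[[nm]] <- upd$param
        adam[[nm]] <- upd$state
      }
    }
  }
  decode <- function(Xin) {
    H1 <- pmax(sweep(Xin %*% params$W1, 2L, params$b1, "+"), 0)
    sweep(H1 %*% params$W2, 2L, params$b2, "+")
  }
  base <- decode(Xtf)
  out <- vector("list", k)
  for (ti in seq_len(k)) {
    Xp <- Xtf
    Xp[, ti] <- Xp[, ti] * perturb_factor
    fluct <- colMeans(abs(decode(Xp) - base))
    out[[ti]] <- data.frame(tf = genes[tf_idx[ti]], target = genes,
                            score = fluct, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (score_quantile > 0) {
    cutoff <- stats::quantile(res$score, score_quantile)
    res <- res[res$score >= cutoff, , drop = FALSE]
  }
  res <- res[order(-res$score), , drop = FALSE]
  rownames(res) <- NULL
  res
}
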