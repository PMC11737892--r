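# Independent fully connected reference network used as the oracle for the
# dense-equivalence property: same layer shapes, plain dense linear algebra,
# its own Adam and backprop code. It shares only the *initial* weights with
# the model under test (initialization is not the property being checked);
# every training-step computation is written here from the textbook formulas.

dense_reference_train <- function(W0, b0, X, Z, lr = 0.001, steps = 50L,
                                  batch_size = 16L, weight_decay = 0,
                                  activation = "relu") {
  act <- switch(activation, relu = function(z) pmax(z, 0), tanh = tanh)
  dact <- switch(activation, relu = function(z) (z > 0) * 1,
                 tanh = function(z) 1 - tanh(z)^2)
  params <- c(W0, b0)
  mstate <- lapply(params, function(p) p * 0)
  vstate <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  n <- nrow(X)
  losses <- numeric(steps)
  pos <- 1L
  for (t in seq_len(steps)) {
    idx <- pos:min(pos + batch_size - 1L, n)
    pos <- if (max(idx) >= n) 1L else max(idx) + 1L
    Xb <- X[idx, , drop = FALSE]
    Zb <- Z[idx, , drop = FALSE]
    nb <- length(idx)

    Ztf <- sweep(Xb %*% params$gene_tf, 2L, params$tf, "+")
    Htf <- act(Ztf)
    Zgo <- sweep(Xb %*% params$gene_go + Htf %*% params$tf_go, 2L, params$go, "+")
    Hgo <- act(Zgo)
    logits <- sweep(Hgo %*% params$go_out, 2L, params$out, "+")
    P <- exp(logits - apply(logits, 1L, max))
    P <- P / rowSums(P)
    losses[t] <- -sum(Zb * log(P)) / nb

    dlogit <- (P - Zb) / nb
    g <- list()
    g$go_out <- t(Hgo) %*% dlogit
    g$out <- colSums(dlogit)
    dHgo <- dlogit %*% t(params$go_out)
    dZgo <- dHgo * dact(Zgo)
    g$gene_go <- t(Xb) %*% dZgo
    g$tf_go <- t(Htf) %*% dZgo
    g$go <- colSums(dZgo)
    dHtf <- dZgo %*% t(params$tf_go)
    dZtf <- dHtf * dact(Ztf)
    g$gene_tf <- t(Xb) %*% dZtf
    g$tf <- colSums(dZtf)
    if (weight_decay > 0) {
      for (nm in c("gene_tf", "gene_go", "tf_go", "go_out")) {
        g[[nm]] <- g[[nm]] + weight_decay * params[[nm]]
      }
    }
    for (nm in names(params)) {
      mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * g[[nm]]
      vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * g[[nm]]^2
      mhat <- mstate[[nm]] / (1 - beta1^t)
      vhat <- vstate[[nm]] / (1 - beta2^t)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, losses = losses)
}
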