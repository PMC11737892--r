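# Small study systems shared across tests. Everything is generated in code;
# sizes are kept small so single tests run in seconds.

tiny_scenario <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_genes = 60L, n_tfs = 6L, n_terms = 8L, genes_per_term = 5L,
         targets_per_tf = 5L, n_cell_types = 3L, n_cells_per_type = 40L,
         marker_genes_per_type = 4L, program_genes = 10L, seed = seed),
    list(...))
  do.call(synthetic_scenario, args)
}

tiny_fit <- function(seed = 1L, epochs = 120L, scenario = tiny_scenario(seed)) {
  kn <- make_knowledge(scenario)
  cells <- simulate_cells(scenario, kn)
  em <- lognormalize(cells$counts)
  masks <- align_masks(build_masks(kn$annotations, kn$tf_targets,
                                   gene_vocab = em$gene_names,
                                   min_term_size = 2L),
                       em$gene_names)
  model <- init_model(masks, labels = sort(unique(cells$labels)), seed = seed)
  fit <- train(model, em, cells$labels,
               training_config(max_epochs = epochs, seed = seed))
  list(scenario = scenario, knowledge = kn, cells = cells, em = em,
       masks = masks, fit = fit)
}

# direct MaskSet construction for unit tests that need exact connectivity
manual_masks <- function(M_gene_go, M_gene_tf = NULL, M_tf_go = NULL,
                         genes = NULL, tfs = NULL, go_terms = NULL) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(M_gene_go)))
  if (is.null(go_terms)) go_terms <- sprintf("GO:%07d", seq_len(ncol(M_gene_go)))
  if (is.null(M_gene_tf)) M_gene_tf <- matrix(0, nrow(M_gene_go), 0)
  if (is.null(tfs)) tfs <- if (ncol(M_gene_tf)) sprintf("tf%02d", seq_len(ncol(M_gene_tf))) else character(0)
  if (is.null(M_tf_go)) M_tf_go <- matrix(0, length(tfs), ncol(M_gene_go))
  dimnames(M_gene_go) <- list(genes, go_terms)
  dimnames(M_gene_tf) <- list(genes, tfs)
  dimnames(M_tf_go) <- list(tfs, go_terms)
  structure(list(genes = genes, tfs = tfs, go_terms = go_terms,
                 M_gene_go = M_gene_go, M_gene_tf = M_gene_tf,
                 M_tf_go = M_tf_go, min_term_size = 1L, max_term_size = 500L,
                 tf_go_wiring = "inherit"),
            class = "mask_set")
}

all_masked_zero <- function(model) {
  m <- model$masks
  all(model$W$gene_go[m$M_gene_go == 0] == 0) &&
    all(model$W$gene_tf[m$M_gene_tf == 0] == 0) &&
    all(model$W$tf_go[m$M_tf_go == 0] == 0)
}
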