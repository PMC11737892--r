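# sparsego

Knowledge-primed sparse neural networks for interpretable cell status
annotation from single-cell RNA-seq.

## The problem

Deep classifiers annotate scRNA-seq cell types accurately but opaquely: a
dense network gives no account of *why* a cell was called a beta cell or a
diseased cardiomyocyte. `sparsego` builds networks whose every hidden node is
a named biological entity. Gene Ontology annotations and transcription-factor
binding tables are compiled into binary masks that prune the connectivity, so
genes connect only to the GO terms they are annotated to and to the TFs that
target them:

```
genes ──(M_gene_tf)──> TF nodes ──(M_tf_go)──┐
  └───────(M_gene_go)────────────────────────┴──> GO-term nodes ──> cell types
```

Each mask `M` is 0/1 (`M[i,j] = 1` iff the knowledge base supports the edge)
and is multiplied elementwise into its weight matrix at every step, so pruned
weights are exactly zero throughout training. The forward pass is

```
h_tf   = relu( x (W_gene_tf ⊙ M_gene_tf) + b_tf )
h_go   = relu( x (W_gene_go ⊙ M_gene_go) + h_tf (W_tf_go ⊙ M_tf_go) + b_go )
q      = softmax( h_go W_go_out + b_out )          # cell type probabilities
```

trained with Adam (learning rate 0.001) on cross-entropy
`Loss = −Σ_i z_i log(q_i)`; a regression variant with one linear output node
and squared-error loss scores continuous cell states (senescence, disease
severity). Sparsity cuts the parameter count dramatically (typically to a few
percent of the dense equivalent) and makes three interpretation tools exact
or near-exact:

* **Gene importance** — reference-based contribution scores (DeepLIFT-style
  rescale rule) whose per-cell sums equal the target logit difference from
  the reference, to machine precision.
* **GO/TF tracing** — absolute-weight paths from GO-term and TF nodes to an
  output class.
* **In-silico perturbation** — scale one gene ×0.5 (inhibition) or ×2
  (activation), re-predict, and rank genes by how often the predicted state
  flips; a latent-embedding variant infers de-novo TF→target edges.

Cells whose maximum class probability falls below a cutoff (0.95 by
convention) are flagged as putative **novel cell types** not seen in
training.

The package ships a negative-binomial synthetic-data generator that plants
marker programs, GO terms and TF regulons with known ground truth, so the
whole pipeline is testable offline.

## Worked example

```r
library(sparsego)

scenario <- synthetic_scenario(seed = 1)        # 5 types x 200 cells, 500 genes
kn    <- make_knowledge(scenario)
cells <- simulate_cells(scenario, kn)
em    <- lognormalize(cells$counts)

masks <- build_masks(kn$annotations, kn$tf_targets, gene_vocab = em$gene_names)
masks <- align_masks(masks, em$gene_names)
masks
#> mask_set: 500 genes, 25 TFs, 40 GO terms
#>   nnz gene-GO: 405  gene-TF: 250  TF-GO: 21
#>   expression coverage: 1

model <- init_model(masks, labels = sort(unique(cells$labels)), seed = 1)
count_parameters(model)[c("sparse_count", "dense_equivalent_count")]
#> $sparse_count        [1] 946
#> $dense_equivalent_count  [1] 33770

set.seed(501)
test  <- sample(nrow(em$values), 200)
fit   <- train(model, em$values[-test, ], cells$labels[-test],
               training_config(seed = 1))
pred  <- predict(fit, em$values[test, ], novelty_threshold = 0.95)
accuracy(cells$labels[test], pred$predicted_label)
#> [1] 1
f1_score(cells$labels[test], pred$predicted_label, average = "macro")
#> [1] 1
```

The model uses 946 of the 33,770 weights a dense network of the same shape
would need (~3%), and recovers the held-out labels perfectly because the
planted markers are strong (e² ≈ 7.4-fold). Interpretation recovers the
planted structure:

```r
imp <- gene_importance(fit, em$values, "type1")   # rescale-rule attribution
head(sort(imp$gene_scores, decreasing = TRUE))    # planted markers rank on top
go_contributions(fit, "type1")                    # planted GO term ranks first
screen_genes(fit, em$values[cells$labels == "type1", ], "type1", "type2")
```

## Command line

```sh
Rscript inst/cli/sparsego.R simulate     --seed 1 --out sim
Rscript inst/cli/sparsego.R build-masks  --annotations sim/annotations.tsv \
    --tf-targets sim/tf_targets.tsv --genes genes.txt --out masks
Rscript inst/cli/sparsego.R train        --expression sim/counts --orientation genes_by_cells \
    --lognormalize --labels sim/labels.tsv --masks masks/masks.tar.gz --out fit
Rscript inst/cli/sparsego.R predict      --expression sim/counts --orientation genes_by_cells \
    --lognormalize --model fit/model.tar.gz --novelty-threshold 0.95 --out pred
Rscript inst/cli/sparsego.R evaluate     --truth sim/labels.tsv \
    --predictions pred/predictions.tsv --out eval
```

Every subcommand writes a `manifest.json` (resolved options, package
version, input checksums) sufficient to re-run it identically. Expression
inputs may be Matrix Market triplet directories (`matrix.mtx` +
`features.tsv` + `barcodes.tsv`, gzip transparent) or dense CSV/TSV in either
orientation; GO annotations may be GAF 2.x or two-column TSV.

## Vignette

`vignettes/knowledge-masked-networks.Rmd` documents the model and its
assumptions, every tunable parameter with its default and rationale, what the
synthetic generator does and does not emulate, and known limitations.
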