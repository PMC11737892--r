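# GO/TF knowledge parsing and mask compilation.

write_tmp <- function(lines, ext = ".tsv") {
  p <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, p)
  p
}

test_that("two-column annotation files are parsed and deduplicated", {
  p <- write_tmp(c("GENE1\tGO:0000001", "GENE1\tGO:0000001", "GENE2\tGO:0000002"))
  tab <- load_go_annotations(p, format = "tsv2col")
  expect_s3_class(tab, "annotation_table")
  expect_equal(nrow(tab), 2L)
  expect_setequal(tab$gene, c("GENE1", "GENE2"))
})

test_that("GAF comment lines, NOT qualifiers and aspect codes are handled", {
  gaf_row <- function(gene, go, qual = "", aspect = "P") {
    paste(c("DB", paste0("ID_", gene), gene, qual, go, "REF", "IEA", "",
            aspect, "", "", "protein", "taxon:9606", "20240101", "DB"),
          collapse = "\t")
  }
  p <- write_tmp(c("!gaf-version: 2.2", "! generated for tests",
                   gaf_row("A", "GO:0000001"),
                   gaf_row("B", "GO:0000002", aspect = "F"),
                   gaf_row("C", "GO:0000003", qual = "NOT|involved_in"),
                   gaf_row("D", "GO:0000004", aspect = "C")))
  tab <- load_go_annotations(p, format = "gaf")
  expect_equal(nrow(tab), 3L)          # NOT record dropped, comments skipped
  expect_false("C" %in% tab$gene)
  expect_equal(tab$aspect[tab$gene == "A"], "BP")
  expect_equal(tab$aspect[tab$gene == "B"], "MF")
  expect_equal(tab$aspect[tab$gene == "D"], "CC")
})

test_that("malformed GO ids are skipped with a warning; empty result errors", {
  p <- write_tmp(c("GENE3\tGO:12", "GENE4\tGO:0000004"))
  expect_warning(tab <- load_go_annotations(p), "malformed")
  expect_equal(nrow(tab), 1L)
  p2 <- write_tmp("GENE3\tGO:12")
  suppressWarnings(expect_error(load_go_annotations(p2), "no annotations"))
  expect_error(load_go_annotations(tempfile()), "not found")
})

test_that("TF-target tables deduplicate and keep self-targets", {
  p <- write_tmp(c("TF1\tG1", "TF1\tG2", "TF1\tG1"))
  tt <- load_tf_targets(p)
  expect_equal(nrow(tt), 2L)
  p2 <- write_tmp("TF1\tTF1")
  expect_equal(nrow(load_tf_targets(p2)), 1L)
  expect_error(load_tf_targets(tempfile()), "not found")
})

make_ann <- function(genes, terms) {
  structure(data.frame(gene = genes, go_term = terms, aspect = "unknown",
                       stringsAsFactors = FALSE),
            class = c("annotation_table", "data.frame"))
}

test_that("build_masks applies the term-size filter and the 0/1 rule", {
  ann <- make_ann(c("A", "B", "C"),
                  c("GO:0000001", "GO:0000001", "GO:0000002"))
  masks <- build_masks(ann, NULL, gene_vocab = c("A", "B", "C"),
                       min_term_size = 2L)
  expect_equal(masks$go_terms, "GO:0000001")
  expect_equal(unname(masks$M_gene_go[, 1L]), c(1, 1, 0))
  expect_error(build_masks(make_ann("Z", "GO:0000009"), NULL,
                           gene_vocab = c("A", "B"), min_term_size = 1L),
               "too sparse")
})

test_that("build_masks wires TF targets and the inherit rule", {
  ann <- make_ann(c("A", "B"), c("GO:0000001", "GO:0000001"))
  tt <- structure(data.frame(tf = "A", target = "B"),
                  class = c("tf_target_table", "data.frame"))
  masks <- build_masks(ann, tt, gene_vocab = c("A", "B"), min_term_size = 1L)
  expect_equal(masks$tfs, "A")
  expect_equal(unname(masks$M_gene_tf), matrix(c(0, 1), 2L))
  # inherit: TF node A carries gene A's annotation to GO:0000001
  expect_equal(unname(masks$M_tf_go), matrix(1, 1L, 1L))
  dense <- build_masks(ann, tt, gene_vocab = c("A", "B"), min_term_size = 1L,
                       tf_go_wiring = "dense")
  expect_true(all(dense$M_tf_go == 1))
})

test_that("build_masks reproduces a random bipartite graph exactly", {
  # brute-force oracle: membership recomputed independently over all pairs
  set.seed(31)
  genes <- sprintf("g%02d", 1:20)
  terms <- sprintf("GO:%07d", 1:6)
  edges <- expand.grid(gene = genes, go_term = terms,
                       stringsAsFactors = FALSE)
  edges <- edges[runif(nrow(edges)) < 0.3, ]
  masks <- build_masks(make_ann(edges$gene, edges$go_term), NULL,
                       gene_vocab = genes, min_term_size = 1L)
  expected <- matrix(0, 20L, length(masks$go_terms),
                     dimnames = list(genes, masks$go_terms))
  for (i in seq_along(genes)) for (j in masks$go_terms) {
    expected[i, j] <- as.numeric(any(edges$gene == genes[i] & edges$go_term == j))
  }
  expect_identical(unname(masks$M_gene_go), unname(expected))
})

test_that("raising min_term_size never increases the GO-term count", {
  set.seed(7)
  for (rep in 1:3) {
    genes <- sprintf("g%02d", 1:30)
    edges <- expand.grid(gene = genes, go_term = sprintf("GO:%07d", 1:10),
                         stringsAsFactors = FALSE)
    edges <- edges[runif(nrow(edges)) < 0.4, ]
    ann <- make_ann(edges$gene, edges$go_term)
    n_terms <- vapply(1:6, function(k) {
      length(tryCatch(build_masks(ann, NULL, genes, min_term_size = k)$go_terms,
                      error = function(e) character(0)))
    }, 0L)
    expect_true(all(diff(n_terms) <= 0L))
  }
})

test_that("align_masks restricts, reorders and is idempotent", {
  ann <- make_ann(c("A", "B", "C"),
                  c("GO:0000001", "GO:0000001", "GO:0000002"))
  masks <- build_masks(ann, NULL, gene_vocab = c("A", "B", "C"),
                       min_term_size = 1L)
  al <- align_masks(masks, c("C", "A"))
  expect_equal(al$genes, c("C", "A"))
  expect_equal(nrow(al$M_gene_go), 2L)
  expect_equal(al$coverage, 1)
  # permutation preserved
  expect_equal(al$M_gene_go["C", "GO:0000002"], 1)
  # empty GO columns dropped when membership drops to zero
  al2 <- align_masks(masks, c("A", "B"))
  expect_equal(al2$go_terms, "GO:0000001")
  # identity and idempotence
  same <- align_masks(masks, c("A", "B", "C"))
  expect_equal(same$M_gene_go, masks$M_gene_go)
  twice <- align_masks(al, c("C", "A"))
  expect_equal(twice[c("genes", "go_terms")], al[c("genes", "go_terms")])
  expect_equal(twice$M_gene_go, al$M_gene_go)
  expect_error(align_masks(masks, c("X", "Y")), "no overlap")
})

test_that("mask archives round-trip through tar.gz", {
  sc <- tiny_scenario(seed = 2)
  kn <- make_knowledge(sc)
  masks <- build_masks(kn$annotations, kn$tf_targets, gene_vocab = kn$genes,
                       min_term_size = 2L)
  p <- withr::local_tempfile(fileext = ".tar.gz")
  write_maskset(masks, p)
  back <- read_maskset(p)
  expect_identical(back$genes, masks$genes)
  expect_identical(back$tfs, masks$tfs)
  expect_equal(back$M_gene_go, masks$M_gene_go)
  expect_equal(back$M_gene_tf, masks$M_gene_tf)
  expect_equal(back$M_tf_go, masks$M_tf_go)
  # truncation is detected
  raw_bytes <- readBin(p, "raw", file.size(p))
  p2 <- withr::local_tempfile(fileext = ".tar.gz")
  writeBin(raw_bytes[1:50], p2)
  expect_error(suppressWarnings(read_maskset(p2)), "truncated|unreadable")
})
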