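sample_nodes <- data.frame(
  node_id = c("GO:0031753", "C0023448", "5345", "9409", "GO:0032474"),
  node_type = c("molecular_function", "side_effect", "gene", "gene",
                "biological_process"),
  name = c("Endothelial differentiation GPCR activity",
           "Lymphocytic leukemia", "SERPINF2", "PEX16",
           "Otolith morphogenesis"),
  stringsAsFactors = FALSE)

sample_edges <- data.frame(
  source = c("GO:0031753", "C0023448", "5345", "9409", "GO:0032474"),
  relation = c("involved_in", "drug_causes_side_effect",
               "gene_associates_disease", "gene_involved_in_pathway",
               "participates_in"),
  target = c("5345", "9409", "GO:0031753", "C0023448", "9409"),
  stringsAsFactors = FALSE)

test_that("loading curated-style node/edge tables builds the expected graph", {
  nd <- tempfile(fileext = ".tsv")
  ed <- tempfile(fileext = ".tsv")
  write.table(sample_nodes, nd, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sample_edges, ed, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- load_graph(nd, ed)
  expect_equal(nrow(g$nodes), 5)
  expect_equal(nrow(g$edges), 5)
  expect_true(all(c("gene_associates_disease", "participates_in") %in%
                    g$relation_set))
  expect_equal(g$edges$confidence, rep(1, 5))
})

test_that("load_graph enforces referential integrity and id uniqueness", {
  nd <- tempfile(fileext = ".tsv")
  ed <- tempfile(fileext = ".tsv")
  write.table(sample_nodes, nd, sep = "\t", quote = FALSE, row.names = FALSE)
  bad <- rbind(sample_edges,
               data.frame(source = "5345", relation = "treats",
                          target = "MISSING", stringsAsFactors = FALSE))
  write.table(bad, ed, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_graph(nd, ed), "MISSING")

  dup <- rbind(sample_nodes, sample_nodes[1, ])
  write.table(dup, nd, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sample_edges, ed, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_graph(nd, ed), "duplicate node id")
})

test_that("empty edge table yields a graph with no edges or relations", {
  g <- hetero_graph(sample_nodes, NULL)
  expect_equal(nrow(g$edges), 0)
  expect_length(g$relation_set, 0)
  st <- graph_statistics(g)
  expect_equal(st$total_edges, 0)
})

test_that("duplicate triples and self-loops are rejected at construction", {
  expect_error(hetero_graph(sample_nodes,
                            rbind(sample_edges, sample_edges[2, ])),
               "duplicate edge triple")
  expect_error(hetero_graph(sample_nodes,
                            data.frame(source = "5345", relation = "r",
                                       target = "5345")),
               "self-loop")
})

test_that("write/load round trip is the identity, including confidences", {
  g <- hetero_graph(sample_nodes, transform(sample_edges,
                                            confidence = c(1, 0.73, 1,
                                                           0.25, 1)))
  nd <- tempfile(fileext = ".tsv")
  ed <- tempfile(fileext = ".tsv")
  write_graph(g, nd, ed)
  g2 <- load_graph(nd, ed)
  expect_equal(g2$nodes, g$nodes)
  expect_equal(g2$edges, g$edges)
  expect_setequal(g2$relation_set, g$relation_set)
})

test_that("round trip holds on random small graphs", {
  for (seed in 1:20) {
    tg <- random_tiny_graph(seed)
    nd <- tempfile(fileext = ".tsv")
    ed <- tempfile(fileext = ".tsv")
    write_graph(tg$graph, nd, ed)
    g2 <- load_graph(nd, ed)
    expect_equal(g2$nodes, tg$graph$nodes)
    expect_equal(g2$edges, tg$graph$edges)
  }
})

test_that("graph statistics match direct arithmetic", {
  # complete directed triangle
  nodes <- data.frame(node_id = c("a", "b", "c"), node_type = "gene")
  edges <- expand.grid(source = nodes$node_id, target = nodes$node_id,
                       stringsAsFactors = FALSE)
  edges <- edges[edges$source != edges$target, ]
  edges$relation <- "gene_gene"
  st <- graph_statistics(hetero_graph(nodes, edges))
  expect_equal(st$density, 1.0)

  # the directed-density formula on curated-scale counts: the ratio is fixed
  # by arithmetic, not by any printed summary value
  expect_equal(2250000 / (36570 * 36569), 0.00168247, tolerance = 1e-5)

  cfg <- synthetic_config(n_drugs = 10, n_genes = 30, n_diseases = 4,
                          n_pathways = 5, seed = 11)
  kg <- generate_kg(cfg)
  st2 <- graph_statistics(kg$graph)
  expect_equal(st2$node_count_by_type$drug, 10)
  expect_equal(st2$node_count_by_type$gene, 30)
  expect_equal(st2$node_count_by_type$disease, 4)
  expect_equal(st2$node_count_by_type$pathway, 5)
  expect_equal(st2$total_nodes, Reduce(`+`, st2$node_count_by_type))
  expect_equal(st2$total_edges, Reduce(`+`, st2$edge_count_by_relation))

  g1 <- hetero_graph(nodes[1, , drop = FALSE], NULL)
  expect_warning(st3 <- graph_statistics(g1), "fewer than 2")
  expect_equal(st3$density, 0)
})

test_that("confidence-ranked augmentation selects, dedupes and is monotone", {
  g <- hetero_graph(sample_nodes, sample_edges)
  cand <- data.frame(
    source = rep("5345", 5), relation = sprintf("lit_%d", 1:5),
    target = rep("9409", 5), confidence = c(0.9, 0.8, 0.7, 0.2, 0.1))
  g3 <- augment_with_confidence_edges(g, cand, top_k = 3)
  added <- setdiff(g3$edges$relation, g$edges$relation)
  expect_setequal(added, c("lit_1", "lit_2", "lit_3"))
  expect_equal(nrow(g$edges), 5)  # input untouched

  # duplicate of an existing triple is skipped
  g4 <- augment_with_confidence_edges(
    g, transform(sample_edges[1, ], confidence = 0.99), top_k = 10)
  expect_equal(nrow(g4$edges), nrow(g$edges))

  # monotone superset, |added| <= top_k
  for (k in c(0, 2, 10)) {
    gk <- augment_with_confidence_edges(g, cand, top_k = k)
    expect_true(all(paste(g$edges$source, g$edges$relation, g$edges$target)
                    %in% paste(gk$edges$source, gk$edges$relation,
                               gk$edges$target)))
    expect_lte(nrow(gk$edges) - nrow(g$edges), k)
  }

  expect_error(augment_with_confidence_edges(
    g, data.frame(source = "nope", relation = "r", target = "5345",
                  confidence = 1), 5), "nope")
  expect_equal(formals(augment_with_confidence_edges)$top_k, 10000L)
})

test_that("inverse relations double the edge set and conserve node counts", {
  g <- hetero_graph(sample_nodes, sample_edges)
  g2 <- add_inverse_relations(g)
  expect_equal(nrow(g2$edges), 2 * nrow(g$edges))
  expect_true(all(paste0(g$relation_set, "_inv") %in% g2$relation_set))
  expect_true(any(g2$edges$source == "5345" &
                    g2$edges$relation == "involved_in_inv" &
                    g2$edges$target == "GO:0031753"))
  st <- graph_statistics(g2)
  expect_equal(st$total_edges, 2 * graph_statistics(g)$total_edges)
  expect_equal(st$node_count_by_type, graph_statistics(g)$node_count_by_type)
  expect_error(add_inverse_relations(g2), "_inv")

  ge <- hetero_graph(sample_nodes, NULL)
  expect_equal(nrow(add_inverse_relations(ge)$edges), 0)
})
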