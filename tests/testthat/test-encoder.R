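make_small_model <- function(seed = 1, d_hidden = 8, n_heads = 2,
                             n_layers = 2) {
  cfg <- synthetic_config(n_drugs = 6, n_genes = 12, n_diseases = 3,
                          n_pathways = 3, targets_per_drug = 2,
                          genes_per_disease = 4, overlap_threshold = 1,
                          fingerprint_bits = 16, gene_embed_dim = 6,
                          seed = seed)
  kg <- generate_kg(cfg)
  feat <- preprocess_features(generate_node_features(kg$graph, cfg))
  g2 <- add_inverse_relations(kg$graph)
  params <- hetgnn_params(g2, feat, d_hidden = d_hidden, n_heads = n_heads,
                          n_layers = n_layers, dropout = 0, seed = seed)
  list(graph = g2, features = feat, params = params)
}

test_that("attention coefficients are a probability vector per head", {
  m <- make_small_model()
  r <- m$graph$edges$relation[1]
  h_i <- rnorm(8)
  nb <- list(rnorm(8), rnorm(8), rnorm(8))
  for (k in 1:2) {
    cf <- relation_attention_coefficients(h_i, nb, r, k, m$params, 1)
    expect_length(cf, 3)
    expect_true(all(cf > 0))
    expect_equal(sum(cf), 1, tolerance = 1e-12)
  }
  # singleton softmax
  expect_equal(relation_attention_coefficients(h_i, nb[1], r, 1, m$params, 1),
               1.0)
  # identical neighbours share the weight equally
  cf2 <- relation_attention_coefficients(h_i, list(nb[[1]], nb[[1]]), r, 1,
                                         m$params, 1)
  expect_equal(cf2, c(0.5, 0.5), tolerance = 1e-12)
  expect_error(relation_attention_coefficients(h_i, list(), r, 1, m$params,
                                               1),
               "empty")
})

test_that("attention coefficients match a hand-coded dense evaluation", {
  m <- make_small_model()
  r <- m$graph$edges$relation[1]
  set.seed(3)
  h_i <- rnorm(8)
  nb <- list(rnorm(8), rnorm(8), rnorm(8))
  W <- m$params$values[[paste0("L1_W_", r)]]
  a_src <- m$params$values[[paste0("L1_asrc_", r)]]
  a_dst <- m$params$values[[paste0("L1_adst_", r)]]
  for (k in 1:2) {
    cols <- ((k - 1) * 4 + 1):(k * 4)
    lrelu <- function(x) ifelse(x > 0, x, 0.2 * x)
    logits <- sapply(nb, function(hj) {
      lrelu(sum(a_dst[cols] * as.numeric(h_i %*% W[, cols])) +
              sum(a_src[cols] * as.numeric(hj %*% W[, cols])))
    })
    want <- exp(logits) / sum(exp(logits))
    got <- relation_attention_coefficients(h_i, nb, r, k, m$params, 1)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("relation aggregation concatenates heads and averages at the top", {
  m <- make_small_model(n_layers = 2)
  r <- m$graph$edges$relation[1]
  nb <- list(rnorm(8), rnorm(8))
  # hidden layer: output length K * d_head = 8
  agg <- relation_aggregate(list(c(0.25, 0.75), c(0.5, 0.5)), nb, r,
                            m$params, 1)
  expect_length(agg, 8)
  # hand-check the first head block
  W <- m$params$values[[paste0("L1_W_", r)]]
  want <- 0.25 * as.numeric(nb[[1]] %*% W[, 1:4]) +
    0.75 * as.numeric(nb[[2]] %*% W[, 1:4])
  expect_equal(agg[1:4], want, tolerance = 1e-12)

  # final layer: heads averaged, output length d_hidden
  agg2 <- relation_aggregate(list(1, 1), nb[1], r, m$params, 2)
  expect_length(agg2, 8)
  W2 <- m$params$values[[paste0("L2_W_", r)]]
  expect_equal(agg2, (as.numeric(nb[[1]] %*% W2[, 1:8]) +
                        as.numeric(nb[[1]] %*% W2[, 9:16])) / 2,
               tolerance = 1e-12)
  expect_error(relation_aggregate(list(1), nb[1], r, m$params, 1),
               "per head")
})

test_that("relation fusion is a softmax-weighted combination", {
  h_rs <- list(a = c(1, 0), b = c(0, 1))
  q <- c(1, 1)
  f <- relation_fusion(h_rs, q)
  expect_equal(sum(f$beta), 1)
  expect_equal(unname(f$beta), c(0.5, 0.5))  # symmetric scores
  expect_equal(f$h, c(0.5, 0.5))
  # single relation: weight exactly 1
  f1 <- relation_fusion(h_rs["a"], q)
  expect_equal(unname(f1$beta), 1.0)
  expect_equal(f1$h, h_rs$a)
  # brute-force softmax of the dot products
  set.seed(5)
  hs <- list(x = rnorm(4), y = rnorm(4), z = rnorm(4))
  qv <- rnorm(4)
  sc <- sapply(hs, function(h) sum(qv * h))
  want <- exp(sc) / sum(exp(sc))
  expect_equal(unname(relation_fusion(hs, qv)$beta), unname(want),
               tolerance = 1e-12)
  expect_error(relation_fusion(list(), qv), "fuse")
})

test_that("single-layer forward equals the dense oracle on random graphs", {
  # a focused version of the large-scale equivalence exercised in acceptance
  for (seed in 1:25) {
    tg <- random_tiny_graph(seed)
    params <- hetgnn_params(tg$graph, tg$features, d_hidden = 4,
                            n_heads = 2, n_layers = 1, dropout = 0,
                            seed = seed)
    got <- forward_encoder(tg$graph, tg$features, params)
    H0 <- matrix(0, nrow(tg$graph$nodes), 4)
    rownames(H0) <- tg$graph$nodes$node_id
    for (id in rownames(H0)) {
      tp <- tg$graph$nodes$node_type[tg$graph$nodes$node_id == id]
      H0[id, ] <- project_to_shared_space(tg$features[[tp]]$x[id, ], tp,
                                          params)
    }
    want <- dense_layer_oracle(tg$graph, H0, params, 1)
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("inference forward is deterministic and permutation-equivariant", {
  m <- make_small_model(seed = 4, n_layers = 3)
  h1 <- forward_encoder(m$graph, m$features, m$params)
  h2 <- forward_encoder(m$graph, m$features, m$params)
  expect_identical(h1, h2)

  # relabel nodes by a fixed permutation: outputs permute identically
  set.seed(1)
  ids <- m$graph$nodes$node_id
  perm <- setNames(sprintf("x_%s", sample(ids)), ids)
  nodes2 <- transform(m$graph$nodes, node_id = unname(perm[node_id]),
                      name = unname(perm[node_id]))
  edges2 <- transform(m$graph$edges, source = unname(perm[source]),
                      target = unname(perm[target]))
  feats2 <- m$features
  for (tp in names(feats2)) {
    rownames(feats2[[tp]]$x) <- unname(perm[rownames(feats2[[tp]]$x)])
    rownames(feats2[[tp]]$mask) <- rownames(feats2[[tp]]$x)
  }
  g2 <- hetero_graph(nodes2, edges2, relations = m$graph$relation_set)
  h3 <- forward_encoder(g2, feats2, m$params)
  expect_lt(max(abs(h3[unname(perm[ids]), ] - h1[ids, ])), 1e-9)
})

test_that("per-node attention rows and fusion weights sum to one everywhere", {
  m <- make_small_model(seed = 6, n_layers = 2)
  cache <- hetgnn:::build_graph_cache(m$graph, m$features)
  tape <- hetgnn:::ad_tape()
  leaves <- hetgnn:::ad_wrap_params(tape, m$params$values)
  # reproduce the first layer's attention internals and check normalisation
  H <- NULL
  n <- cache$n
  for (type in names(cache$X)) {
    Xt <- hetgnn:::ad_const(tape, cache$X[[type]])
    Ht <- hetgnn:::ad_add_bias(
      tape,
      hetgnn:::ad_matmul_bt(tape, Xt, leaves[[paste0("proj_W_", type)]]),
      leaves[[paste0("proj_b_", type)]])
    St <- hetgnn:::ad_scatter_rows(tape, Ht, cache$type_rows[[type]], n)
    H <- if (is.null(H)) St else hetgnn:::ad_add(tape, H, St)
  }
  for (r in names(cache$rels)) {
    re <- cache$rels[[r]]
    Wh <- hetgnn:::ad_matmul_rows(tape, H,
                                  leaves[[paste0("L1_W_", r)]], re$rows)
    logits <- hetgnn:::ad_edge_logits(tape, Wh,
                                      leaves[[paste0("L1_asrc_", r)]],
                                      leaves[[paste0("L1_adst_", r)]],
                                      re$src_l, re$dst_l, 2L)
    e <- hetgnn:::ad_leakyrelu(tape, logits, 0.2)
    alpha <- hetgnn:::ad_segment_softmax(tape, e, re$dst, n)
    sums <- rowsum(alpha$value, re$dst)
    expect_lt(max(abs(sums - 1)), 1e-9)
    expect_true(all(alpha$value > 0))
  }
})

test_that("unknown relations in the graph are rejected at forward time", {
  m <- make_small_model()
  extra <- m$graph
  edges <- rbind(extra$edges,
                 data.frame(source = extra$nodes$node_id[1],
                            relation = "mystery_relation",
                            target = extra$nodes$node_id[2],
                            confidence = 1))
  g2 <- hetero_graph(extra$nodes, edges)
  expect_error(forward_encoder(g2, m$features, m$params),
               "mystery_relation")
})
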