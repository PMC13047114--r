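# Scalar quadratic loss used for the hand-derivable first-order checks.
toy_loss <- function(c) {
  function(params, batch) {
    th <- params$theta
    list(loss = as.numeric((th - c)^2),
         grads = list(theta = matrix(2 * (th - c), 1, 1)))
  }
}

test_that("one inner step reproduces the hand gradient on a scalar toy", {
  # L(theta) = (theta - 3)^2 at theta = 1: gradient -4, so theta' = 1.04
  params <- list(theta = matrix(1, 1, 1))
  cfg <- meta_config(inner_lr = 0.01, inner_steps = 1)
  adapted <- inner_adapt(params, list(), toy_loss(3), cfg)
  expect_equal(as.numeric(adapted$theta), 1.04, tolerance = 1e-12)
  # zero learning rate: parameters unchanged
  cfg0 <- meta_config(inner_lr = 0, inner_steps = 1)
  expect_equal(inner_adapt(params, list(), toy_loss(3), cfg0)$theta,
               params$theta)
  # default is exactly one inner step
  expect_equal(meta_config()$inner_steps, 1L)
  expect_equal(meta_config()$inner_lr, 0.01)
  expect_equal(meta_config()$outer_lr, 0.001)
})

test_that("first-order meta gradient equals the symbolic two-step chain", {
  # support L_s = (theta - 3)^2, query L_q = (theta - 5)^2, theta = 1.
  # theta' = theta - a*2(theta-3) = 1.04; first-order outer gradient is
  # dL_q/dtheta' = 2(theta' - 5) = -7.92, applied with a plain step.
  params <- list(theta = matrix(1, 1, 1))
  cfg <- meta_config(inner_lr = 0.01, outer_lr = 0.1)
  task <- structure(list(support = "s", query = "q"), class = "toy_task")
  loss_fn <- function(p, batch) {
    c_target <- if (identical(batch$active_split %||% "support",
                              "support")) 3 else 5
    toy_loss(c_target)(p, batch)
  }
  res <- meta_train_step(params, list(task), loss_fn, cfg, plain_sgd = TRUE)
  expect_equal(as.numeric(res$params$theta), 1 + 0.1 * 7.92,
               tolerance = 1e-12)
  expect_equal(res$l_meta, (1.04 - 5)^2, tolerance = 1e-12)

  # duplicated task: the outer gradient doubles exactly
  res2 <- meta_train_step(params, list(task, task), loss_fn, cfg,
                          plain_sgd = TRUE)
  expect_equal(as.numeric(res2$params$theta) - 1,
               2 * (as.numeric(res$params$theta) - 1), tolerance = 1e-12)
  expect_error(meta_train_step(params, list(), loss_fn, cfg), "empty")
})

test_that("inner adaptation never mutates the shared parameters", {
  m_cfg <- synthetic_config(n_drugs = 12, n_genes = 25, n_diseases = 4,
                            n_pathways = 4, targets_per_drug = 3,
                            genes_per_disease = 6, overlap_threshold = 1,
                            fingerprint_bits = 32, gene_embed_dim = 8,
                            seed = 8)
  kg <- generate_kg(m_cfg)
  feat <- preprocess_features(generate_node_features(kg$graph, m_cfg))
  g2 <- add_inverse_relations(kg$graph)
  params <- hetgnn_params(g2, feat, d_hidden = 8, n_heads = 2, n_layers = 2,
                          seed = 1)
  dis <- names(which(table(kg$truth$treats_pairs$disease_id) >= 2))
  task <- build_disease_task(g2, dis[1], seed = 3)
  loss_fn <- hetgnn:::make_task_loss_fn(feat, seed = 5)
  before <- serialize(params$values, NULL)
  adapted <- inner_adapt(params, hetgnn:::list_support(task), loss_fn,
                         meta_config())
  expect_identical(serialize(params$values, NULL), before)
  expect_false(identical(adapted$values, params$values))
})

test_that("task construction splits positives and keeps splits disjoint", {
  m_cfg <- synthetic_config(n_drugs = 20, n_genes = 40, n_diseases = 5,
                            n_pathways = 5, targets_per_drug = 3,
                            genes_per_disease = 8, overlap_threshold = 1,
                            fingerprint_bits = 32, gene_embed_dim = 8,
                            seed = 12)
  kg <- generate_kg(m_cfg)
  g2 <- add_inverse_relations(kg$graph)
  counts <- table(kg$truth$treats_pairs$disease_id)
  dis <- names(which(counts >= 2))
  expect_gt(length(dis), 0)
  for (s in dis) {
    task <- build_disease_task(g2, s, support_size = 5, seed = 4)
    n_pos <- counts[[s]]
    sup <- task$support$pairs[task$support$labels == 1, ]
    qry <- task$query$pairs[task$query$labels == 1, ]
    expect_equal(nrow(sup), max(1, min(5, n_pos %/% 2)))
    expect_equal(nrow(qry), n_pos - nrow(sup))
    expect_true(all(task$support$pairs$disease_id == s))
    expect_true(all(task$query$pairs$disease_id == s))
    # support and query pair sets disjoint (exhaustive)
    sup_key <- paste(task$support$pairs$drug_id,
                     task$support$pairs$disease_id)
    qry_key <- paste(task$query$pairs$drug_id, task$query$pairs$disease_id)
    expect_length(intersect(sup_key, qry_key), 0)
    # subgraph covers the disease and every split drug
    expect_true(s %in% task$subgraph$nodes$node_id)
    expect_true(all(c(task$support$pairs$drug_id,
                      task$query$pairs$drug_id) %in%
                      task$subgraph$nodes$node_id))
    # the task disease's own therapeutic edges are hidden in its subgraph
    se <- task$subgraph$edges
    expect_false(any(se$relation %in% c("treats", "treats_inv") &
                       (se$source == s | se$target == s)))
  }
})

test_that("a disease with fewer than two positives is infeasible as a task", {
  nodes <- data.frame(node_id = c("d1", "d2", "g1", "s1"),
                      node_type = c("drug", "drug", "gene", "disease"))
  edges <- data.frame(source = c("d1", "g1"),
                      relation = c("treats", "gene_associates_disease"),
                      target = c("s1", "s1"))
  g <- hetero_graph(nodes, edges)
  expect_error(build_disease_task(g, "s1", seed = 1),
               class = "task_infeasible")
})

test_that("subgraph nodes lie within the documented hop radius", {
  m_cfg <- synthetic_config(n_drugs = 20, n_genes = 40, n_diseases = 5,
                            n_pathways = 5, targets_per_drug = 3,
                            genes_per_disease = 8, overlap_threshold = 1,
                            fingerprint_bits = 32, gene_embed_dim = 8,
                            seed = 12)
  kg <- generate_kg(m_cfg)
  g2 <- add_inverse_relations(kg$graph)
  dis <- names(which(table(kg$truth$treats_pairs$disease_id) >= 2))
  expect_gt(length(dis), 0)
  task <- build_disease_task(g2, dis[1], k = 2, seed = 2)
  # undirected adjacency for hop counting
  nbr <- split(c(g2$edges$target, g2$edges$source),
               c(g2$edges$source, g2$edges$target))
  dist_from <- function(starts) {
    d <- setNames(rep(Inf, nrow(g2$nodes)), g2$nodes$node_id)
    d[starts] <- 0
    frontier <- starts
    step <- 0
    while (length(frontier)) {
      step <- step + 1
      nxt <- setdiff(unique(unlist(nbr[frontier], use.names = FALSE)),
                     names(d)[is.finite(d)])
      d[nxt] <- step
      frontier <- nxt
    }
    d
  }
  d_dis <- dist_from(task$disease_id)
  drugs <- g2$nodes$node_id[g2$nodes$node_type == "drug"]
  d_drugs <- dist_from(drugs)
  for (id in task$subgraph$nodes$node_id) {
    expect_true(d_dis[id] <= 2 || d_drugs[id] <= 1)
  }
})
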