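test_that("disjoint split is exhaustive, disjoint and largest-remainder sized", {
  dis <- sprintf("s%02d", 1:20)
  sp <- disjoint_disease_split(dis, c(0.70, 0.15, 0.15), seed = 3)
  # 20 diseases at 70/15/15 -> quotas (14, 3, 3), exact under the rounding rule
  expect_length(sp$train, 14)
  expect_length(sp$val, 3)
  expect_length(sp$test, 3)
  expect_setequal(c(sp$train, sp$val, sp$test), dis)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_length(intersect(sp$val, sp$test), 0)
  expect_error(disjoint_disease_split(dis, c(0.5, 0.2, 0.2), seed = 1),
               "sum to 1")
  expect_error(disjoint_disease_split(dis[1:2], seed = 1))
  # default fractions
  expect_equal(eval(formals(disjoint_disease_split)$fractions),
               c(0.70, 0.15, 0.15))
})

test_that("split disjointness holds across many seeds (property)", {
  dis <- sprintf("s%02d", 1:13)
  for (seed in 1:200) {
    sp <- disjoint_disease_split(dis, seed = seed)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_length(intersect(sp$train, sp$val), 0)
    expect_length(intersect(sp$val, sp$test), 0)
    expect_setequal(c(sp$train, sp$val, sp$test), dis)
  }
})

test_that("ranking metrics agree with brute-force oracles", {
  # perfect separation
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  # the worked four-point case: 3 of 4 positive/negative pairs ordered
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_equal(auprc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)),
               brute_auprc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)),
               tolerance = 1e-12)
  # constant scores are all ties
  expect_equal(roc_auc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  # duplicating every observation changes nothing
  s <- c(0.9, 0.5, 0.5, 0.2); y <- c(1, 1, 0, 0)
  expect_equal(auprc(c(s, s), c(y, y)), auprc(s, y), tolerance = 1e-12)
  expect_equal(roc_auc(c(s, s), c(y, y)), roc_auc(s, y), tolerance = 1e-12)
  expect_error(auprc(c(1, 0), c(1, 1)), "negative")
  expect_error(roc_auc(c(1, 0), c(0, 0)), "positive")

  set.seed(42)
  for (i in 1:120) {
    n <- sample(4:50, 1)
    sc <- round(runif(n), sample(c(1, 2, 6), 1))  # force some ties
    lb <- rbinom(n, 1, 0.4)
    if (sum(lb) == 0 || sum(lb) == n) next
    expect_equal(roc_auc(sc, lb), brute_roc_auc(sc, lb), tolerance = 1e-10)
    expect_equal(auprc(sc, lb), brute_auprc(sc, lb), tolerance = 1e-10)
  }
})

test_that("test loss is the mean cross-entropy", {
  s <- c(0.8, 0.3, 0.6); y <- c(1, 0, 1)
  expect_equal(test_loss(s, y), bce_loss(s, y) / 3)
  expect_equal(test_loss(rep(0.5, 4), c(1, 0, 1, 0)), log(2),
               tolerance = 1e-12)
  expect_lt(test_loss(c(1, 0), c(1, 0)), 1e-6)
  expect_error(test_loss(numeric(), numeric()), "empty")
})

test_that("relative improvement matches hand arithmetic", {
  expect_equal(relative_improvement(0.5, 0.5), 0)
  expect_equal(relative_improvement(0.91, 0.79), 15.19, tolerance = 1e-2)
  expect_equal(relative_improvement(0.79, 0.91), -13.19, tolerance = 1e-2)
  expect_error(relative_improvement(0.5, 0), "positive")
})

test_that("confusion counts are exact and conserve the total", {
  expect_equal(confusion_counts(c(0.9, 0.2), c(1, 0)),
               c(TP = 1, TN = 1, FP = 0, FN = 0))
  expect_equal(confusion_counts(c(0.9, 0.2), c(0, 1)),
               c(TP = 0, TN = 0, FP = 1, FN = 1))
  set.seed(11)
  for (i in 1:30) {
    n <- sample(3:40, 1)
    sc <- runif(n); lb <- rbinom(n, 1, 0.5)
    cc <- confusion_counts(sc, lb)
    expect_equal(sum(cc), n)
  }
  # balanced mode equalises class counts before counting
  sc <- runif(30); lb <- c(rep(1, 5), rep(0, 25))
  cb <- confusion_counts(sc, lb, balanced = TRUE, seed = 2)
  expect_equal(sum(cb), 10)
  expect_equal(cb[["TP"]] + cb[["FN"]], 5)
})

test_that("cold-start protocol is deterministic and leakage-free", {
  cfg <- synthetic_config(n_drugs = 25, n_genes = 60, n_diseases = 6,
                          n_pathways = 8, targets_per_drug = 3,
                          genes_per_disease = 8, overlap_threshold = 1,
                          fingerprint_bits = 64, gene_embed_dim = 16,
                          seed = 5)
  kg <- generate_kg(cfg)
  feat <- generate_node_features(kg$graph, cfg)
  run <- function() {
    run_cold_start_protocol(
      kg$graph, feat,
      model_config = list(d_hidden = 8, n_heads = 2, n_layers = 2),
      seed = 5, max_epochs = 4, patience = 4, min_epochs = 1,
      passes_per_epoch = 1)
  }
  r1 <- run()
  r2 <- run()
  expect_equal(r1$trace, r2$trace)
  expect_equal(r1$test_metrics, r2$test_metrics)
  expect_identical(r1$params$values, r2$params$values)
  # selected epoch is the argmax of the recorded validation trace
  expect_equal(r1$selected_epoch,
               r1$trace$epoch[which.max(r1$trace$val_roc_auc)])
  # split covers only diseases with at least one known treatment
  covered <- c(r1$split$train, r1$split$val, r1$split$test)
  expect_setequal(covered, unique(kg$truth$treats_pairs$disease_id))
  # default epoch budget is 100
  expect_equal(eval(formals(run_cold_start_protocol)$max_epochs), 100L)
})

test_that("untrained evaluation never trains and reports finite metrics", {
  cfg <- synthetic_config(n_drugs = 25, n_genes = 60, n_diseases = 6,
                          n_pathways = 8, targets_per_drug = 3,
                          genes_per_disease = 8, overlap_threshold = 1,
                          fingerprint_bits = 64, gene_embed_dim = 16,
                          seed = 5)
  kg <- generate_kg(cfg)
  feat <- generate_node_features(kg$graph, cfg)
  r <- run_cold_start_protocol(
    kg$graph, feat, model_config = list(d_hidden = 8, n_heads = 2,
                                        n_layers = 2),
    seed = 5, skip_training = TRUE)
  expect_equal(nrow(r$trace), 0)
  expect_equal(r$selected_epoch, 0)
  expect_true(is.finite(r$test_metrics$roc_auc))
})
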