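test_that("generation is byte-identical under a fixed seed", {
  cfg <- synthetic_config(seed = 7)
  kg1 <- generate_kg(cfg)
  kg2 <- generate_kg(cfg)
  expect_identical(kg1, kg2)
  f1 <- generate_node_features(kg1$graph, cfg)
  f2 <- generate_node_features(kg2$graph, cfg)
  expect_identical(f1, f2)
  kg3 <- generate_kg(synthetic_config(seed = 8))
  expect_false(identical(kg1$graph$edges, kg3$graph$edges))
})

test_that("node counts equal the configuration exactly", {
  cfg <- synthetic_config(n_drugs = 17, n_genes = 61, n_diseases = 5,
                          n_pathways = 7, seed = 3)
  kg <- generate_kg(cfg)
  tab <- table(kg$graph$nodes$node_type)
  expect_equal(as.integer(tab[c("drug", "gene", "disease", "pathway")]),
               c(17, 61, 5, 7))
  expect_true(all(c("drug_targets_gene", "gene_associates_disease",
                    "gene_involved_in_pathway", "disease_linked_pathway",
                    "gene_gene") %in% kg$graph$relation_set))
})

test_that("infeasible configurations are rejected", {
  expect_error(synthetic_config(targets_per_drug = 500, n_genes = 100),
               "infeasible")
  expect_error(synthetic_config(treat_noise = 0.6))
})

test_that("treats labels are exactly recomputable from graph + threshold", {
  for (sd in c(2, 5)) {
    cfg <- synthetic_config(seed = sd)
    kg <- generate_kg(cfg)
    g <- kg$graph
    dt <- g$edges[g$edges$relation == "drug_targets_gene", ]
    ga <- g$edges[g$edges$relation == "gene_associates_disease", ]
    targets <- split(dt$target, dt$source)
    genes <- split(ga$source, ga$target)
    drugs <- g$nodes$node_id[g$nodes$node_type == "drug"]
    dis <- g$nodes$node_id[g$nodes$node_type == "disease"]
    flip_key <- paste(kg$truth$flipped$drug_id, kg$truth$flipped$disease_id)
    lab_key <- paste(kg$truth$treats_pairs$drug_id,
                     kg$truth$treats_pairs$disease_id)
    edge_key <- paste(g$edges$source[g$edges$relation == "treats"],
                      g$edges$target[g$edges$relation == "treats"])
    expect_setequal(edge_key, lab_key)
    for (d in drugs) {
      for (s in dis) {
        rule <- length(intersect(targets[[d]], genes[[s]])) >=
          cfg$overlap_threshold
        expected <- xor(rule, paste(d, s) %in% flip_key)
        expect_equal(paste(d, s) %in% lab_key, expected)
      }
    }
    # mechanism records shared genes for every rule-positive pair
    for (key in names(kg$truth$mechanism)) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      shared <- intersect(targets[[parts[1]]], genes[[parts[2]]])
      expect_setequal(kg$truth$mechanism[[key]], shared)
      expect_gte(length(shared), cfg$overlap_threshold)
    }
  }
})

test_that("positive pairs share more genes than negatives (rank statistic)", {
  pos_all <- c()
  neg_all <- c()
  for (sd in 1:20) {
    cfg <- synthetic_config(seed = sd)
    kg <- generate_kg(cfg)
    g <- kg$graph
    dt <- g$edges[g$edges$relation == "drug_targets_gene", ]
    ga <- g$edges[g$edges$relation == "gene_associates_disease", ]
    targets <- split(dt$target, dt$source)
    genes <- split(ga$source, ga$target)
    drugs <- g$nodes$node_id[g$nodes$node_type == "drug"]
    dis <- g$nodes$node_id[g$nodes$node_type == "disease"]
    lab_key <- paste(kg$truth$treats_pairs$drug_id,
                     kg$truth$treats_pairs$disease_id)
    set.seed(sd)
    for (i in 1:30) {
      d <- sample(drugs, 1)
      s <- sample(dis, 1)
      ov <- length(intersect(targets[[d]], genes[[s]]))
      if (paste(d, s) %in% lab_key) pos_all <- c(pos_all, ov)
      else neg_all <- c(neg_all, ov)
    }
    pos <- kg$truth$treats_pairs
    ovp <- vapply(seq_len(nrow(pos)), function(i) {
      length(intersect(targets[[pos$drug_id[i]]],
                       genes[[pos$disease_id[i]]]))
    }, numeric(1))
    pos_all <- c(pos_all, ovp)
  }
  expect_gt(mean(pos_all), mean(neg_all))
  # one-sided Mann-Whitney via the brute-force rank statistic
  u <- 0
  for (p in pos_all) u <- u + sum(p > neg_all) + 0.5 * sum(p == neg_all)
  n1 <- length(pos_all); n2 <- length(neg_all)
  z <- (u - n1 * n2 / 2) / sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  expect_gt(z, qnorm(0.99))
})

test_that("indications-per-drug distribution is left-skewed with mode 1", {
  modes <- integer(0)
  for (sd in 1:20) {
    kg <- generate_kg(synthetic_config(seed = sd))
    tab <- table(table(kg$truth$treats_pairs$drug_id))
    modes <- c(modes, as.integer(names(tab))[which.max(tab)])
  }
  # modal indications-per-drug value over seeds is 1
  expect_equal(as.integer(names(which.max(table(modes)))), 1L)
})

test_that("gene degrees are heavy-tailed relative to a uniform wiring", {
  shares <- vapply(1:5, function(sd) {
    kg <- generate_kg(synthetic_config(seed = sd))
    deg <- graph_statistics(kg$graph)$degree_by_type$gene
    top <- sum(sort(deg, decreasing = TRUE)[seq_len(length(deg) %/% 10)])
    top / sum(deg)
  }, numeric(1))
  # the top decile of genes holds at least twice its uniform share of edges
  expect_gt(mean(shares), 2 * 0.1)
})

test_that("drug feature vectors are strictly binary, gene mask ~5% missing", {
  cfg <- synthetic_config(seed = 9)
  kg <- generate_kg(cfg)
  feat <- generate_node_features(kg$graph, cfg)
  expect_true(all(feat$drug$x %in% c(0, 1)))
  expect_true(all(feat$pathway$x %in% c(0, 1)))
  expect_true(feat$drug$binary)
  expect_false(feat$gene$binary)
  expect_equal(mean(feat$gene$mask == 0), 0.05, tolerance = 0.01)
  expect_equal(dim(feat$drug$x), c(cfg$n_drugs, cfg$fingerprint_bits))
  expect_equal(dim(feat$gene$x), c(cfg$n_genes, cfg$gene_embed_dim))
})

test_that("with zero noise a disease feature is the exact mean of its genes", {
  cfg <- synthetic_config(seed = 11)
  kg <- generate_kg(cfg)
  feat <- generate_node_features(kg$graph, cfg, disease_noise = 0)
  ga <- kg$graph$edges[kg$graph$edges$relation == "gene_associates_disease", ]
  s <- ga$target[1]
  gset <- ga$source[ga$target == s]
  expect_equal(feat$disease$x[s, ],
               colMeans(feat$gene$x[gset, , drop = FALSE]),
               tolerance = 1e-12)
})

test_that("graph-adjacent genes are more similar than random gene pairs", {
  adj_sims <- c(); rnd_sims <- c()
  for (sd in 1:10) {
    cfg <- synthetic_config(seed = sd)
    kg <- generate_kg(cfg)
    feat <- generate_node_features(kg$graph, cfg)
    gx <- feat$gene$x
    cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    gg <- kg$graph$edges[kg$graph$edges$relation == "gene_gene", ]
    set.seed(sd)
    take <- sample(nrow(gg), min(40, nrow(gg)))
    for (i in take) {
      adj_sims <- c(adj_sims, cosine(gx[gg$source[i], ], gx[gg$target[i], ]))
      rnd <- sample(rownames(gx), 2)
      rnd_sims <- c(rnd_sims, cosine(gx[rnd[1], ], gx[rnd[2], ]))
    }
  }
  expect_gt(mean(adj_sims), mean(rnd_sims))
})

test_that("scaling drug count scales target-edge count within 3 sigma", {
  cfg1 <- synthetic_config(n_drugs = 40, seed = 13)
  cfg2 <- synthetic_config(n_drugs = 80, seed = 13)
  e1 <- sum(generate_kg(cfg1)$graph$edges$relation == "drug_targets_gene")
  e2 <- sum(generate_kg(cfg2)$graph$edges$relation == "drug_targets_gene")
  # per-drug target counts are 1 + Geom(mean-1): variance m(m-1) per drug
  m <- cfg1$targets_per_drug
  expect_lt(abs(e2 - 2 * e1), 3 * sqrt(120 * m * (m - 1)) + 6)
})

test_that("synthetic omics plant exactly the configured signal", {
  om <- generate_omics(n_samples = 200, effect_size = 3, seed = 5)
  expect_identical(om, generate_omics(n_samples = 200, effect_size = 3,
                                      seed = 5))
  expect_equal(om$planted$features, 1:5)
  # the 5 planted features have the 5 largest |mean difference| (brute force)
  gaps <- abs(colMeans(om$modalities[[1]][om$labels == 1, ]) -
                colMeans(om$modalities[[1]][om$labels == 0, ]))
  expect_setequal(order(gaps, decreasing = TRUE)[1:5], 1:5)

  # null case: no feature separates the classes
  om0 <- generate_omics(n_samples = 400, effect_size = 0, seed = 6)
  aucs <- c()
  for (m in 1:3) {
    for (j in seq_len(ncol(om0$modalities[[m]]))) {
      aucs <- c(aucs, roc_auc(om0$modalities[[m]][, j], om0$labels))
    }
  }
  expect_lt(max(abs(aucs - 0.5)), 0.1)
  expect_error(generate_omics(informative_modality = 4), "modality")
})
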