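#' Configuration for the synthetic knowledge-graph generator
#'
#' The generator emulates, at desk scale, the structure of a curated
#' biomedical knowledge graph: a few node classes with heavy-tailed gene
#' connectivity, a strongly left-skewed indications-per-drug distribution, and
#' a mechanistic ground truth in which a drug treats a disease exactly when
#' its target genes overlap the disease's associated genes.
#'
#' @param n_drugs,n_genes,n_diseases,n_pathways node counts per class.
#' @param targets_per_drug mean of the geometric law for targets per drug.
#' @param genes_per_disease mean of the geometric law for associated genes per
#'   disease.
#' @param overlap_threshold minimum number of shared genes for a true
#'   `treats` edge.
#' @param treat_noise probability that a treats label is flipped (curation
#'   noise); must be below 0.5.
#' @param fingerprint_bits length of binary drug substructure fingerprints.
#' @param gene_embed_dim length of dense gene embeddings.
#' @param seed integer seed; the single source of randomness for generation.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_drugs = 50L, n_genes = 200L, n_diseases = 10L,
                             n_pathways = 20L, targets_per_drug = 4,
                             genes_per_disease = 12, overlap_threshold = 2L,
                             treat_noise = 0.005, fingerprint_bits = 1024L,
                             gene_embed_dim = 128L, seed = 1L) {
  cfg <- list(n_drugs = as.integer(n_drugs), n_genes = as.integer(n_genes),
              n_diseases = as.integer(n_diseases),
              n_pathways = as.integer(n_pathways),
              targets_per_drug = targets_per_drug,
              genes_per_disease = genes_per_disease,
              overlap_threshold = as.integer(overlap_threshold),
              treat_noise = treat_noise,
              fingerprint_bits = as.integer(fingerprint_bits),
              gene_embed_dim = as.integer(gene_embed_dim),
              seed = as.integer(seed))
  stopifnot(cfg$n_drugs >= 1, cfg$n_genes >= 1, cfg$n_diseases >= 1,
            cfg$n_pathways >= 1, cfg$overlap_threshold >= 1,
            cfg$treat_noise >= 0, cfg$treat_noise < 0.5)
  if (cfg$targets_per_drug > cfg$n_genes ||
      cfg$genes_per_disease > cfg$n_genes) {
    stop("infeasible config: mean gene counts exceed n_genes")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

# 1 + geometric draw with the requested mean (>= 1), capped at `cap`.
draw_counts <- function(n, mean_count, cap) {
  m <- max(mean_count, 1)
  pmin(1L + stats::rgeom(n, 1 / m), cap)
}

# Preferential-attachment sampler: draw `k` distinct genes with probability
# proportional to current degree + 1, then bump their degrees.
pa_sample <- function(k, degree) {
  chosen <- integer(0)
  for (i in seq_len(k)) {
    w <- degree + 1
    if (length(chosen)) w[chosen] <- 0
    g <- sample.int(length(degree), 1L, prob = w)
    chosen <- c(chosen, g)
    degree[g] <- degree[g] + 1L
  }
  list(chosen = chosen, degree = degree)
}

#' Generate a synthetic heterogeneous knowledge graph with planted mechanism
#'
#' Drug target sets and disease gene sets are drawn by preferential attachment
#' over a shared gene popularity, giving heavy-tailed gene degrees and making
#' hub genes a common cause of drug-disease overlap. A `treats` edge is
#' planted for pair `(d, s)` exactly when the drug's targets and the disease's
#' genes share at least `overlap_threshold` members; each label is then
#' independently flipped with probability `treat_noise`. The full generative
#' state (true pairs, per-pair shared-gene mechanism, noise flips) is returned
#' as ground truth so downstream recovery can be verified.
#'
#' @param config a [synthetic_config()].
#' @return A list with components `graph` (a [hetero_graph()] containing
#'   relations `drug_targets_gene`, `gene_associates_disease`, `gene_gene`,
#'   `gene_involved_in_pathway`, `disease_linked_pathway` and `treats`) and
#'   `truth` (list with `treats_pairs` data.frame, `mechanism` named list of
#'   shared-gene vectors, `rule_pairs` pre-noise labels, and `flipped` pairs).
#' @export
generate_kg <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(derive_seed(config$seed, "kg"), {
    drugs <- sprintf("drug_%03d", seq_len(config$n_drugs))
    genes <- sprintf("gene_%04d", seq_len(config$n_genes))
    diseases <- sprintf("disease_%02d", seq_len(config$n_diseases))
    pathways <- sprintf("pathway_%03d", seq_len(config$n_pathways))

    nodes <- data.frame(
      node_id = c(drugs, genes, diseases, pathways),
      node_type = rep(c("drug", "gene", "disease", "pathway"),
                      c(length(drugs), length(genes), length(diseases),
                        length(pathways))),
      stringsAsFactors = FALSE)
    nodes$name <- nodes$node_id

    gene_degree <- integer(config$n_genes)

    # drug targets (preferential attachment onto genes)
    n_targets <- draw_counts(config$n_drugs, config$targets_per_drug,
                             config$n_genes)
    targets <- vector("list", config$n_drugs)
    for (d in seq_len(config$n_drugs)) {
      s <- pa_sample(n_targets[d], gene_degree)
      targets[[d]] <- sort(s$chosen)
      gene_degree <- s$degree
    }

    # disease gene associations (same popularity -> shared hubs)
    n_assoc <- draw_counts(config$n_diseases, config$genes_per_disease,
                           config$n_genes)
    assoc <- vector("list", config$n_diseases)
    for (s in seq_len(config$n_diseases)) {
      r <- pa_sample(n_assoc[s], gene_degree)
      assoc[[s]] <- sort(r$chosen)
      gene_degree <- r$degree
    }

    # gene-gene interactions by preferential attachment among genes
    gg_src <- integer(0); gg_tgt <- integer(0)
    for (g in 2:config$n_genes) {
      k <- min(1L + stats::rgeom(1L, 1 / 1.5), g - 1L)
      w <- gene_degree[seq_len(g - 1L)] + 1
      nb <- sample.int(g - 1L, k, prob = w)
      gg_src <- c(gg_src, rep(g, k)); gg_tgt <- c(gg_tgt, nb)
      gene_degree[nb] <- gene_degree[nb] + 1L
      gene_degree[g] <- gene_degree[g] + k
    }

    # pathway memberships: each gene joins 1-3 pathways
    n_path <- pmin(1L + stats::rpois(config$n_genes, 0.6), config$n_pathways)
    memb_gene <- rep(seq_len(config$n_genes), n_path)
    memb_path <- unlist(lapply(n_path, function(k) {
      sample.int(config$n_pathways, k)
    }))

    # diseases link to the pathways most represented among their genes
    dl_dis <- integer(0); dl_path <- integer(0)
    for (s in seq_len(config$n_diseases)) {
      pw <- memb_path[memb_gene %in% assoc[[s]]]
      if (length(pw)) {
        top <- as.integer(names(sort(table(pw), decreasing = TRUE)))
        top <- top[seq_len(min(3L, length(top)))]
        dl_dis <- c(dl_dis, rep(s, length(top))); dl_path <- c(dl_path, top)
      }
    }

    # planted treats rule + label noise
    rule <- matrix(FALSE, config$n_drugs, config$n_diseases)
    mechanism <- list()
    for (d in seq_len(config$n_drugs)) {
      for (s in seq_len(config$n_diseases)) {
        shared <- intersect(targets[[d]], assoc[[s]])
        if (length(shared) >= config$overlap_threshold) {
          rule[d, s] <- TRUE
          mechanism[[paste(drugs[d], diseases[s], sep = "|")]] <- genes[shared]
        }
      }
    }
    flips <- matrix(stats::runif(length(rule)) < config$treat_noise,
                    config$n_drugs, config$n_diseases)
    label <- xor(rule, flips)

    treats_idx <- which(label, arr.ind = TRUE)
    flipped_idx <- which(flips, arr.ind = TRUE)

    edges <- rbind(
      data.frame(source = rep(drugs, lengths(targets)),
                 relation = "drug_targets_gene",
                 target = genes[unlist(targets)],
                 stringsAsFactors = FALSE),
      data.frame(source = genes[unlist(assoc)],
                 relation = "gene_associates_disease",
                 target = rep(diseases, lengths(assoc)),
                 stringsAsFactors = FALSE),
      data.frame(source = genes[gg_src], relation = "gene_gene",
                 target = genes[gg_tgt], stringsAsFactors = FALSE),
      data.frame(source = genes[memb_gene],
                 relation = "gene_involved_in_pathway",
                 target = pathways[memb_path], stringsAsFactors = FALSE),
      data.frame(source = diseases[dl_dis],
                 relation = "disease_linked_pathway",
                 target = pathways[dl_path], stringsAsFactors = FALSE),
      if (nrow(treats_idx)) {
        data.frame(source = drugs[treats_idx[, 1]], relation = "treats",
                   target = diseases[treats_idx[, 2]],
                   stringsAsFactors = FALSE)
      }
    )
    edges$confidence <- 1.0
    key <- paste(edges$source, edges$relation, edges$target, sep = "\r")
    edges <- edges[!duplicated(key), ]

    graph <- hetero_graph(nodes, edges,
                          relations = c("drug_targets_gene",
                                        "gene_associates_disease",
                                        "gene_gene",
                                        "gene_involved_in_pathway",
                                        "disease_linked_pathway", "treats"))

    treats_pairs <- data.frame(
      drug_id = drugs[treats_idx[, 1]],
      disease_id = diseases[treats_idx[, 2]],
      stringsAsFactors = FALSE)
    truth <- list(
      treats_pairs = treats_pairs,
      mechanism = mechanism,
      rule_pairs = data.frame(
        drug_id = drugs[which(rule, arr.ind = TRUE)[, 1]],
        disease_id = diseases[which(rule, arr.ind = TRUE)[, 2]],
        stringsAsFactors = FALSE),
      flipped = data.frame(
        drug_id = drugs[flipped_idx[, 1]],
        disease_id = diseases[flipped_idx[, 2]],
        stringsAsFactors = FALSE),
      overlap_threshold = config$overlap_threshold)

    list(graph = graph, truth = truth)
  })
}

#' Generate synthetic per-type node feature matrices
#'
#' Stand-ins for the real initialisations: binary substructure fingerprints
#' for drugs (bit banks tied to target genes, so chemistry proxies mechanism),
#' dense embeddings for genes smoothed over the gene-gene network (adjacent
#' genes more similar than random pairs), disease vectors equal to the mean of
#' their genes' vectors plus noise, and binary pathway membership encodings.
#' A random 5% of gene feature entries are marked missing (mask 0) to
#' exercise imputation.
#'
#' @param graph the graph returned by [generate_kg()].
#' @param config the matching [synthetic_config()].
#' @param disease_noise standard deviation of the noise added to disease
#'   vectors; 0 makes each disease exactly the mean of its genes.
#' @return A `node_feature_set`: named list of per-type lists with elements
#'   `x` (matrix, rows named by node id), `mask` (same shape, in `{0,1}`) and
#'   `binary` flag.
#' @export
generate_node_features <- function(graph, config, disease_noise = 0.1) {
  stopifnot(inherits(graph, "hetero_graph"),
            inherits(config, "synthetic_config"))
  known <- c("drug", "gene", "disease", "pathway")
  if (!all(graph$nodes$node_type %in% known)) {
    stop("unknown node type(s): ",
         paste(setdiff(graph$nodes$node_type, known), collapse = ", "))
  }
  with_seed(derive_seed(config$seed, "features"), {
    ids <- split(graph$nodes$node_id, graph$nodes$node_type)
    genes <- ids$gene
    gi <- stats::setNames(seq_along(genes), genes)

    # gene embeddings: latent noise smoothed over the gene-gene network
    z <- matrix(stats::rnorm(length(genes) * config$gene_embed_dim),
                length(genes), config$gene_embed_dim)
    gg <- graph$edges[graph$edges$relation == "gene_gene", ]
    adj_sum <- matrix(0, length(genes), config$gene_embed_dim)
    adj_n <- numeric(length(genes))
    if (nrow(gg)) {
      a <- gi[gg$source]; b <- gi[gg$target]
      for (e in seq_along(a)) {
        adj_sum[a[e], ] <- adj_sum[a[e], ] + z[b[e], ]
        adj_sum[b[e], ] <- adj_sum[b[e], ] + z[a[e], ]
        adj_n[a[e]] <- adj_n[a[e]] + 1; adj_n[b[e]] <- adj_n[b[e]] + 1
      }
    }
    gene_x <- z + 0.8 * adj_sum / pmax(adj_n, 1)
    rownames(gene_x) <- genes
    gene_mask <- matrix(1, nrow(gene_x), ncol(gene_x),
                        dimnames = dimnames(gene_x))
    gene_mask[sample.int(length(gene_mask),
                         round(0.05 * length(gene_mask)))] <- 0

    # drug fingerprints: union of per-target bit banks + sparse background
    bank <- lapply(seq_along(genes), function(i) {
      sample.int(config$fingerprint_bits, 8L)
    })
    dt <- graph$edges[graph$edges$relation == "drug_targets_gene", ]
    drug_x <- matrix(0, length(ids$drug), config$fingerprint_bits,
                     dimnames = list(ids$drug, NULL))
    background <- stats::runif(length(drug_x)) < 0.01
    drug_x[background] <- 1
    if (nrow(dt)) {
      for (e in seq_len(nrow(dt))) {
        drug_x[dt$source[e], bank[[gi[dt$target[e]]]]] <- 1
      }
    }

    # disease vectors: mean of associated genes' embeddings + noise
    ga <- graph$edges[graph$edges$relation == "gene_associates_disease", ]
    dis_x <- matrix(0, length(ids$disease), config$gene_embed_dim,
                    dimnames = list(ids$disease, NULL))
    for (s in ids$disease) {
      gset <- ga$source[ga$target == s]
      if (length(gset)) {
        dis_x[s, ] <- colMeans(gene_x[gset, , drop = FALSE])
      }
    }
    dis_x <- dis_x + disease_noise * matrix(stats::rnorm(length(dis_x)),
                                            nrow(dis_x), ncol(dis_x))

    # pathway encodings: binary gene-membership vectors
    gp <- graph$edges[graph$edges$relation == "gene_involved_in_pathway", ]
    path_x <- matrix(0, length(ids$pathway), length(genes),
                     dimnames = list(ids$pathway, NULL))
    if (nrow(gp)) {
      for (e in seq_len(nrow(gp))) {
        path_x[gp$target[e], gi[gp$source[e]]] <- 1
      }
    }

    ones <- function(m) matrix(1, nrow(m), ncol(m), dimnames = dimnames(m))
    structure(list(
      drug = list(x = drug_x, mask = ones(drug_x), binary = TRUE),
      gene = list(x = gene_x, mask = gene_mask, binary = FALSE),
      disease = list(x = dis_x, mask = ones(dis_x), binary = FALSE),
      pathway = list(x = path_x, mask = ones(path_x), binary = TRUE)
    ), class = "node_feature_set")
  })
}

#' Generate synthetic multi-omics matrices with one informative modality
#'
#' Three modality matrices over the same samples with balanced binary labels.
#' In the informative modality the first five features carry a class mean
#' shift of `effect_size`; every other entry is standard normal noise.
#'
#' @param n_samples number of samples (>= 10).
#' @param n_features_per_modality integer vector of length 3.
#' @param informative_modality which modality (1, 2 or 3) carries signal.
#' @param effect_size class mean shift on the five planted features (>= 0).
#' @param seed integer seed.
#' @return A list with `modalities` (list of 3 matrices), `labels` (0/1
#'   vector), `planted` (list with `modality` and `features` indices).
#' @export
generate_omics <- function(n_samples = 200L,
                           n_features_per_modality = c(20L, 20L, 20L),
                           informative_modality = 1L, effect_size = 3,
                           seed = 1L) {
  stopifnot(n_samples >= 10, effect_size >= 0,
            length(n_features_per_modality) == 3)
  if (!informative_modality %in% 1:3) {
    stop("informative_modality must be 1, 2 or 3")
  }
  with_seed(derive_seed(seed, "omics"), {
    labels <- sample(rep(c(0L, 1L), length.out = n_samples))
    modalities <- lapply(seq_len(3), function(m) {
      p <- n_features_per_modality[m]
      x <- matrix(stats::rnorm(n_samples * p), n_samples, p)
      colnames(x) <- sprintf("m%d_f%03d", m, seq_len(p))
      x
    })
    planted <- seq_len(min(5L, n_features_per_modality[informative_modality]))
    modalities[[informative_modality]][labels == 1L, planted] <-
      modalities[[informative_modality]][labels == 1L, planted] + effect_size
    list(modalities = modalities, labels = labels,
         planted = list(modality = informative_modality, features = planted))
  })
}
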