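# Independent brute-force oracles used to pin the package implementations.
# These are written naively (loops, full recounts) on purpose: they share no
# code with the implementations they check.

# ROC-AUC by exhaustive positive/negative pair comparison.
brute_roc_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Average precision by a descending threshold sweep with a full recount at
# every distinct score.
brute_auprc <- function(scores, labels) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  area <- 0
  recall_prev <- 0
  for (t in thresholds) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    precision <- tp / sum(sel)
    recall <- tp / n_pos
    area <- area + (recall - recall_prev) * precision
    recall_prev <- recall
  }
  area
}

# Dense single-layer oracle of the relation-aware attention layer: per-head
# attention, per-relation aggregation, relation-level softmax fusion and the
# isolated-node self-projection, written with scalar loops straight from the
# definitions. `layer` indexes into a hetgnn_params container; `H` holds the
# input embeddings (n x d).
dense_layer_oracle <- function(graph, H, params, layer) {
  meta <- params$meta
  K <- meta$n_heads
  d <- meta$d_hidden
  final <- layer == meta$n_layers
  dh <- if (final) d else d %/% K
  ids <- graph$nodes$node_id
  n <- length(ids)
  out <- matrix(0, n, d)
  for (i in seq_len(n)) {
    h_rel <- list()
    for (r in unique(graph$edges$relation)) {
      nbr <- graph$edges$source[graph$edges$relation == r &
                                  graph$edges$target == ids[i]]
      if (!length(nbr)) next
      W <- params$values[[sprintf("L%d_W_%s", layer, r)]]
      a_src <- params$values[[sprintf("L%d_asrc_%s", layer, r)]]
      a_dst <- params$values[[sprintf("L%d_adst_%s", layer, r)]]
      acc <- if (final) numeric(dh) else NULL
      per_head <- list()
      for (k in seq_len(K)) {
        cols <- ((k - 1) * dh + 1):(k * dh)
        whi <- as.numeric(H[i, ] %*% W[, cols])
        e <- numeric(length(nbr))
        msgs <- matrix(0, length(nbr), dh)
        for (j in seq_along(nbr)) {
          whj <- as.numeric(H[match(nbr[j], ids), ] %*% W[, cols])
          # a_dst weights the receiver, a_src the neighbour
          z <- sum(a_dst[cols, 1] * whi) + sum(a_src[cols, 1] * whj)
          e[j] <- if (z > 0) z else meta$leaky_slope * z
        }
        alpha <- exp(e - max(e))
        alpha <- alpha / sum(alpha)
        msg <- numeric(dh)
        for (j in seq_along(nbr)) {
          whj <- as.numeric(H[match(nbr[j], ids), ] %*% W[, cols])
          msg <- msg + alpha[j] * whj
        }
        per_head[[k]] <- msg
      }
      h_rel[[r]] <- if (final) {
        Reduce(`+`, per_head) / K
      } else {
        unlist(per_head)
      }
    }
    if (length(h_rel)) {
      q <- as.numeric(params$values[[sprintf("L%d_q", layer)]])
      sc <- vapply(h_rel, function(v) sum(q * v), numeric(1))
      beta <- exp(sc - max(sc))
      beta <- beta / sum(beta)
      out[i, ] <- Reduce(`+`, Map(function(b, v) b * v, beta, h_rel))
    } else {
      out[i, ] <- as.numeric(
        H[i, ] %*% params$values[[sprintf("L%d_Wself", layer)]])
    }
  }
  rownames(out) <- ids
  out
}

# Random tiny heterogeneous graph + matching feature set for oracle tests.
random_tiny_graph <- function(seed, n_nodes = 6, n_relations = 3, p_in = 3) {
  set.seed(seed)
  n <- sample(2:n_nodes, 1)
  types <- sample(c("drug", "gene", "disease"), n, replace = TRUE)
  ids <- sprintf("n%02d", seq_len(n))
  rels <- sprintf("rel%d", seq_len(sample(seq_len(n_relations), 1)))
  edges <- NULL
  for (r in rels) {
    m <- sample(0:4, 1)
    if (m == 0) next
    src <- sample(ids, m, replace = TRUE)
    tgt <- sample(ids, m, replace = TRUE)
    keep <- src != tgt
    if (!any(keep)) next
    edges <- rbind(edges, data.frame(source = src[keep], relation = r,
                                     target = tgt[keep],
                                     stringsAsFactors = FALSE))
  }
  if (!is.null(edges)) {
    key <- paste(edges$source, edges$relation, edges$target)
    edges <- edges[!duplicated(key), ]
  }
  graph <- hetero_graph(data.frame(node_id = ids, node_type = types,
                                   stringsAsFactors = FALSE),
                        edges, relations = rels)
  feats <- list()
  for (tp in unique(types)) {
    rows <- ids[types == tp]
    x <- matrix(rnorm(length(rows) * p_in), length(rows), p_in,
                dimnames = list(rows, NULL))
    feats[[tp]] <- list(x = x, mask = matrix(1, nrow(x), ncol(x),
                                             dimnames = dimnames(x)),
                        binary = FALSE)
  }
  list(graph = graph, features = structure(feats,
                                           class = "node_feature_set"))
}
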