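# Relation-aware multi-head graph attention encoder.
#
# Per relation r and head k, neighbour j of node i receives attention
#   alpha_ij = softmax_j( LeakyReLU( a^T [W h_i || W h_j] ) ),
# messages are aggregated per relation (heads concatenated in hidden layers,
# averaged in the final layer), and a second attention stage fuses the
# per-relation embeddings with weights beta_r = softmax_r( q . h_i^r ) over
# the relations actually present at node i. Three such layers are stacked
# with ELU between layers and dropout after each layer during training.

#' Initialise encoder parameters
#'
#' Creates all learnable tensors for the relation-aware attention encoder:
#' type-specific input projections to the shared latent dimension, and, per
#' layer and relation, per-head projection matrices and attention vectors,
#' plus the relation-level fusion query and an isolated-node self-projection.
#' Weights are Glorot-initialised from the given seed.
#'
#' @param graph a [hetero_graph()] that already contains inverse relations
#'   (see [add_inverse_relations()]); every relation present gets parameters
#'   in every layer.
#' @param features a `node_feature_set` supplying per-type input widths.
#' @param d_hidden shared latent and hidden dimension (default 256; must be a
#'   multiple of `n_heads`).
#' @param n_heads attention heads per relation (default 4).
#' @param n_layers stacked attention layers (default 3).
#' @param dropout dropout rate applied after each layer during training
#'   (default 0.3).
#' @param leaky_slope negative slope of the attention LeakyReLU (default 0.2).
#' @param seed integer seed for initialisation.
#' @return An object of class `hetgnn_params`: list with `values` (flat named
#'   list of numeric matrices) and `meta` (architecture description including
#'   the relation vocabulary).
#' @export
hetgnn_params <- function(graph, features, d_hidden = 256L, n_heads = 4L,
                          n_layers = 3L, dropout = 0.3, leaky_slope = 0.2,
                          seed = 1L) {
  stopifnot(inherits(graph, "hetero_graph"),
            inherits(features, "node_feature_set"),
            n_heads >= 1, d_hidden %% n_heads == 0, n_layers >= 1)
  relations <- sort(graph$relation_set)
  types <- sort(intersect(unique(graph$nodes$node_type), names(features)))
  if (!all(unique(graph$nodes$node_type) %in% names(features))) {
    stop("feature set lacks node type(s): ",
         paste(setdiff(unique(graph$nodes$node_type), names(features)),
               collapse = ", "))
  }
  d <- as.integer(d_hidden)
  with_seed(derive_seed(seed, "init"), {
    values <- list()
    for (type in types) {
      p <- ncol(features[[type]]$x)
      values[[paste0("proj_W_", type)]] <- glorot(d, p)
      values[[paste0("proj_b_", type)]] <- matrix(0, 1L, d)
    }
    for (l in seq_len(n_layers)) {
      dh <- if (l < n_layers) d %/% n_heads else d
      for (r in relations) {
        values[[sprintf("L%d_W_%s", l, r)]] <- glorot(d, n_heads * dh)
        values[[sprintf("L%d_asrc_%s", l, r)]] <-
          glorot(n_heads * dh, 1L)
        values[[sprintf("L%d_adst_%s", l, r)]] <-
          glorot(n_heads * dh, 1L)
      }
      values[[sprintf("L%d_q", l)]] <- glorot(d, 1L)
      values[[sprintf("L%d_Wself", l)]] <- glorot(d, d)
    }
    structure(list(
      values = values,
      meta = list(d_hidden = d, n_heads = as.integer(n_heads),
                  n_layers = as.integer(n_layers), dropout = dropout,
                  leaky_slope = leaky_slope, relations = relations,
                  types = types,
                  feature_dims = vapply(types, function(t) {
                    ncol(features[[t]]$x)
                  }, integer(1)),
                  format_version = 1L)
    ), class = "hetgnn_params")
  })
}

# Precompute the index structures a forward pass needs: global node order,
# per-type feature matrices aligned to it, and per-relation edge indices.
#' @keywords internal
build_graph_cache <- function(graph, features) {
  ids <- graph$nodes$node_id
  idx <- stats::setNames(seq_along(ids), ids)
  types <- unique(graph$nodes$node_type)
  type_rows <- lapply(stats::setNames(types, types), function(t) {
    unname(idx[ids[graph$nodes$node_type == t]])
  })
  X <- lapply(stats::setNames(types, types), function(t) {
    rows <- ids[graph$nodes$node_type == t]
    m <- features[[t]]$x
    missing <- setdiff(rows, rownames(m))
    if (length(missing)) {
      stop("feature rows missing for node(s): ",
           paste(utils::head(missing, 3), collapse = ", "))
    }
    m[rows, , drop = FALSE]
  })
  rels <- list()
  for (r in unique(graph$edges$relation)) {
    sel <- graph$edges$relation == r
    src <- unname(idx[graph$edges$source[sel]])
    dst <- unname(idx[graph$edges$target[sel]])
    present <- logical(length(ids))
    present[unique(dst)] <- TRUE
    rows <- sort(unique(c(src, dst)))
    local <- integer(length(ids))
    local[rows] <- seq_along(rows)
    rels[[r]] <- list(src = src, dst = dst, present = present,
                      rows = rows, src_l = local[src], dst_l = local[dst],
                      src_l_uniq = unique(local[src]),
                      dst_l_uniq = unique(local[dst]),
                      dst_uniq = unique(dst))
  }
  has_any <- Reduce(`|`, lapply(rels, `[[`, "present"),
                    accumulate = FALSE) %||% logical(length(ids))
  list(n = length(ids), ids = ids, idx = idx, type_rows = type_rows, X = X,
       rels = rels, isolated = !has_any)
}

# Tape forward pass of the full encoder. `leaves` wraps params$values on
# `tape`; returns the ad node holding the n x d embedding matrix.
#' @keywords internal
encoder_forward_tape <- function(tape, cache, leaves, meta, training = FALSE) {
  n <- cache$n
  K <- meta$n_heads
  d <- meta$d_hidden
  slope <- meta$leaky_slope

  # type-specific projection into the shared space
  H <- NULL
  for (type in names(cache$X)) {
    Xt <- ad_const(tape, cache$X[[type]])
    Ht <- ad_add_bias(tape,
                      ad_matmul_bt(tape, Xt, leaves[[paste0("proj_W_", type)]]),
                      leaves[[paste0("proj_b_", type)]])
    St <- ad_scatter_rows(tape, Ht, cache$type_rows[[type]], n)
    H <- if (is.null(H)) St else ad_add(tape, H, St)
  }

  iso_rows <- which(cache$isolated)
  for (l in seq_len(meta$n_layers)) {
    final <- l == meta$n_layers
    dh <- if (final) d else d %/% K
    h_rel <- list()
    present <- list()
    for (r in names(cache$rels)) {
      re <- cache$rels[[r]]
      h_rel[[r]] <- ad_relation_layer(
        tape, H, leaves[[sprintf("L%d_W_%s", l, r)]],
        leaves[[sprintf("L%d_asrc_%s", l, r)]],
        leaves[[sprintf("L%d_adst_%s", l, r)]],
        re, n, K, slope, final)
      present[[r]] <- cache$rels[[r]]$present
    }

    if (length(h_rel)) {
      scores <- ad_relation_scores(tape, h_rel, leaves[[sprintf("L%d_q", l)]])
      mask <- do.call(cbind, present)
      beta <- ad_masked_row_softmax(tape, scores, mask)
      fused <- ad_fusion_combine(tape, beta, h_rel)
    } else {
      fused <- ad_const(tape, matrix(0, n, d))
    }

    if (length(iso_rows)) {
      self_proj <- ad_matmul_rows(tape, H,
                                  leaves[[sprintf("L%d_Wself", l)]],
                                  iso_rows)
      H <- ad_add(tape, fused,
                  ad_scatter_rows(tape, self_proj, iso_rows, n))
    } else {
      H <- fused
    }
    if (!final) H <- ad_elu(tape, H)
    H <- ad_dropout(tape, H, meta$dropout, training)
  }
  H
}

# Broadcast a (p x 1) column parameter as an n x p constant-height row
# pattern (each row equals t(v)); gradient sums over rows.
ad_node_rowvec <- function(tape, v, n) {
  p <- nrow(v$value)
  out <- ad_node(tape, matrix(as.numeric(v$value), n, p, byrow = TRUE))
  out$backward <- function(g) {
    ad_accum(v, matrix(colSums(g), p, 1L))
  }
  out
}

# Select one column as an n x 1 node.
ad_col <- function(tape, a, j) {
  p <- ncol(a$value)
  out <- ad_node(tape, a$value[, j, drop = FALSE])
  out$backward <- function(g) {
    full <- matrix(0, nrow(g), p)
    full[, j] <- g
    ad_accum(a, full)
  }
  out
}

#' Run the encoder over a graph
#'
#' Computes shared-space embeddings for every node by three (by default)
#' relation-aware attention layers with relation-level fusion. With
#' `training = FALSE` (the default) dropout is disabled and the output is a
#' deterministic function of graph, features and parameters.
#'
#' @param graph a [hetero_graph()] with inverse relations present.
#' @param features a preprocessed `node_feature_set`
#'   (see [preprocess_features()]).
#' @param params a [hetgnn_params()] object.
#' @param training logical; enables dropout.
#' @param seed seed for the dropout masks (required when `training = TRUE`).
#' @return Numeric matrix `n_nodes x d_hidden`, rows named by node id.
#' @export
forward_encoder <- function(graph, features, params, training = FALSE,
                            seed = NULL) {
  stopifnot(inherits(params, "hetgnn_params"))
  unknown <- setdiff(unique(graph$edges$relation), params$meta$relations)
  if (length(unknown)) {
    stop("graph has relation(s) unknown to the parameters: ",
         paste(unknown, collapse = ", "))
  }
  cache <- build_graph_cache(graph, features)
  run <- function() {
    tape <- ad_tape()
    leaves <- ad_wrap_params(tape, params$values)
    H <- encoder_forward_tape(tape, cache, leaves, params$meta, training)
    H$value
  }
  out <- if (training) {
    if (is.null(seed)) stop("training forward pass needs a seed for dropout")
    with_seed(derive_seed(seed, "dropout"), run())
  } else {
    run()
  }
  rownames(out) <- cache$ids
  out
}

## ---- reference-style single-node operations --------------------------------

rel_head_block <- function(meta, layer) {
  if (layer < meta$n_layers) meta$d_hidden %/% meta$n_heads else meta$d_hidden
}

#' Attention coefficients of one node's neighbours under one relation head
#'
#' Evaluates, for a single node and head, the softmax-normalised attention
#' over its neighbours: `softmax_j(LeakyReLU(a^T [W h_i || W h_j]))`.
#'
#' @param h_i the node's current embedding (length `d_hidden`).
#' @param neighbor_feats list of neighbour embeddings (each length
#'   `d_hidden`); must be nonempty.
#' @param relation relation label.
#' @param head head index in `1..n_heads`.
#' @param params a [hetgnn_params()] object.
#' @param layer layer index in `1..n_layers`.
#' @return Numeric vector of coefficients, strictly positive, summing to 1.
#' @export
relation_attention_coefficients <- function(h_i, neighbor_feats, relation,
                                            head, params, layer) {
  stopifnot(inherits(params, "hetgnn_params"))
  if (length(neighbor_feats) == 0L) {
    stop("empty neighbour list for relation '", relation,
         "'; skip the relation instead")
  }
  meta <- params$meta
  stopifnot(head >= 1, head <= meta$n_heads, layer >= 1,
            layer <= meta$n_layers)
  W <- params$values[[sprintf("L%d_W_%s", layer, relation)]]
  if (is.null(W)) stop("no parameters for relation '", relation, "'")
  dh <- rel_head_block(meta, layer)
  cols <- ((head - 1L) * dh + 1L):(head * dh)
  a_src <- params$values[[sprintf("L%d_asrc_%s", layer, relation)]][cols, 1]
  a_dst <- params$values[[sprintf("L%d_adst_%s", layer, relation)]][cols, 1]
  # convention: `a_dst` weights the receiving node's projection, `a_src` the
  # message source's (neighbour's) projection
  whi <- as.numeric(h_i %*% W[, cols, drop = FALSE])
  logits <- vapply(neighbor_feats, function(h_j) {
    whj <- as.numeric(h_j %*% W[, cols, drop = FALSE])
    z <- sum(a_dst * whi) + sum(a_src * whj)
    if (z > 0) z else meta$leaky_slope * z
  }, numeric(1))
  e <- exp(logits - max(logits))
  e / sum(e)
}

#' Aggregate one node's relation-specific message
#'
#' Per head, the weighted sum of projected neighbour embeddings; heads are
#' concatenated in hidden layers and averaged in the final layer.
#'
#' @param coefficients list (one element per head) of attention coefficient
#'   vectors, each summing to 1 over the neighbours.
#' @inheritParams relation_attention_coefficients
#' @return Numeric vector of length `n_heads * d_head` (hidden layers) or
#'   `d_hidden` (final layer).
#' @export
relation_aggregate <- function(coefficients, neighbor_feats, relation, params,
                               layer) {
  stopifnot(inherits(params, "hetgnn_params"))
  meta <- params$meta
  if (length(coefficients) != meta$n_heads) {
    stop("expected one coefficient vector per head (", meta$n_heads, ")")
  }
  W <- params$values[[sprintf("L%d_W_%s", layer, relation)]]
  dh <- rel_head_block(meta, layer)
  final <- layer == meta$n_layers
  per_head <- lapply(seq_len(meta$n_heads), function(k) {
    cols <- ((k - 1L) * dh + 1L):(k * dh)
    msg <- numeric(dh)
    for (j in seq_along(neighbor_feats)) {
      msg <- msg + coefficients[[k]][j] *
        as.numeric(neighbor_feats[[j]] %*% W[, cols, drop = FALSE])
    }
    msg
  })
  if (final) Reduce(`+`, per_head) / meta$n_heads else unlist(per_head)
}

#' Fuse per-relation embeddings with relation-level attention
#'
#' `beta_r = softmax_r(q . h_i^r)` over the relations present at the node;
#' the fused embedding is the beta-weighted sum.
#'
#' @param h_rs named list mapping relation label to that relation's embedding
#'   vector; must be nonempty, all the same length as `q`.
#' @param q the relation-level query vector.
#' @return List with `h` (fused vector) and `beta` (named weight vector
#'   summing to 1).
#' @export
relation_fusion <- function(h_rs, q) {
  if (length(h_rs) == 0L) stop("no relation embeddings to fuse")
  scores <- vapply(h_rs, function(h) sum(q * h), numeric(1))
  e <- exp(scores - max(scores))
  beta <- e / sum(e)
  h <- Reduce(`+`, Map(function(b, v) b * v, beta, h_rs))
  list(h = h, beta = beta)
}
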