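# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every differentiable quantity is a tape node: an environment holding the
# forward value, an accumulated gradient, and a backward closure. Nodes are
# appended to a tape in execution order; ad_backward() walks the tape in
# reverse. All values are plain numeric matrices (scalars are 1x1), which keeps
# the op set small and the per-op overhead low enough for full-graph training
# loops in pure R. Gradient correctness is pinned against central finite
# differences in the test suite.

# Nodes form a linked list through $prev (creation order), so appending is
# O(1) and the reverse pass simply walks the chain from the loss node.
ad_tape <- function() {
  tape <- new.env(parent = emptyenv())
  tape$last <- NULL
  tape
}

ad_node <- function(tape, value, backward = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$backward <- backward
  node$prev <- tape$last
  tape$last <- node
  node
}

# Leaf holding a constant (no gradient ever requested).
ad_const <- function(tape, value) ad_node(tape, as_matrix(value))

# Leaf holding a parameter; gradients accumulate into $grad.
ad_leaf <- function(tape, value) ad_node(tape, as_matrix(value))

as_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1L)
}

ad_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Run reverse pass seeding d(loss)/d(loss) = 1.
ad_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- matrix(1, 1L, 1L)
  node <- tape$last
  while (!is.null(node)) {
    if (!is.null(node$grad) && !is.null(node$backward)) {
      node$backward(node$grad)
    }
    node <- node$prev
  }
  invisible(NULL)
}

## ---- core ops --------------------------------------------------------------

ad_matmul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  out <- ad_node(tape, av %*% bv)
  out$backward <- function(g) {
    ad_accum(a, g %*% t(bv))
    ad_accum(b, crossprod(av, g))
  }
  out
}

# out = a %*% t(b)
ad_matmul_bt <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  out <- ad_node(tape, tcrossprod(av, bv))
  out$backward <- function(g) {
    ad_accum(a, g %*% bv)
    ad_accum(b, crossprod(g, av))
  }
  out
}

# Place the rows of `a` at positions `idx` (unique) of an n_out-row zero
# matrix.
ad_scatter_rows <- function(tape, a, idx, n_out) {
  p <- ncol(a$value)
  full <- matrix(0, n_out, p)
  full[idx, ] <- a$value
  out <- ad_node(tape, full)
  out$backward <- function(g) ad_accum(a, g[idx, , drop = FALSE])
  out
}

ad_add <- function(tape, a, b) {
  out <- ad_node(tape, a$value + b$value)
  out$backward <- function(g) {
    ad_accum(a, g)
    ad_accum(b, g)
  }
  out
}

ad_sub <- function(tape, a, b) {
  out <- ad_node(tape, a$value - b$value)
  out$backward <- function(g) {
    ad_accum(a, g)
    ad_accum(b, -g)
  }
  out
}

ad_mul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  out <- ad_node(tape, av * bv)
  out$backward <- function(g) {
    ad_accum(a, g * bv)
    ad_accum(b, g * av)
  }
  out
}

ad_scale <- function(tape, a, k) {
  out <- ad_node(tape, a$value * k)
  out$backward <- function(g) ad_accum(a, g * k)
  out
}

# Add a 1 x p bias row to every row of an n x p matrix.
ad_add_bias <- function(tape, a, bias) {
  bv <- bias$value
  out <- ad_node(tape, sweep(a$value, 2L, as.numeric(bv), "+"))
  out$backward <- function(g) {
    ad_accum(a, g)
    ad_accum(bias, matrix(colSums(g), nrow(bv), ncol(bv)))
  }
  out
}

# Row gather: out = a[idx, ].
ad_rows <- function(tape, a, idx) {
  n_in <- nrow(a$value)
  p <- ncol(a$value)
  out <- ad_node(tape, a$value[idx, , drop = FALSE])
  out$backward <- function(g) {
    acc <- rowsum(g, group = idx, reorder = FALSE)
    full <- matrix(0, n_in, p)
    full[as.integer(rownames(acc)), ] <- acc
    ad_accum(a, full)
  }
  out
}

# Segment sum of rows: out[k, ] = sum over rows i with groups[i] == k,
# k in 1..n_out; groups with no rows yield zero rows.
ad_group_rowsum <- function(tape, a, groups, n_out) {
  p <- ncol(a$value)
  acc <- rowsum(a$value, group = groups, reorder = FALSE)
  full <- matrix(0, n_out, p)
  full[as.integer(rownames(acc)), ] <- acc
  out <- ad_node(tape, full)
  out$backward <- function(g) ad_accum(a, g[groups, , drop = FALSE])
  out
}

# Repeat each column `each` times (block expansion used to broadcast per-head
# attention coefficients over head feature blocks).
ad_repcols <- function(tape, a, each) {
  k <- ncol(a$value)
  sel <- rep(seq_len(k), each = each)
  out <- ad_node(tape, a$value[, sel, drop = FALSE])
  out$backward <- function(g) {
    gc <- matrix(0, nrow(g), k)
    for (j in seq_len(k)) {
      cols <- ((j - 1L) * each + 1L):(j * each)
      gc[, j] <- rowSums(g[, cols, drop = FALSE])
    }
    ad_accum(a, gc)
  }
  out
}

# Sum columns within K equal-width blocks: n x (K*w) -> n x K.
ad_block_rowsums <- function(tape, a, k_blocks) {
  p <- ncol(a$value)
  w <- p %/% k_blocks
  stopifnot(w * k_blocks == p)
  v <- a$value
  outv <- matrix(0, nrow(v), k_blocks)
  for (j in seq_len(k_blocks)) {
    outv[, j] <- rowSums(v[, ((j - 1L) * w + 1L):(j * w), drop = FALSE])
  }
  out <- ad_node(tape, outv)
  out$backward <- function(g) {
    ad_accum(a, g[, rep(seq_len(k_blocks), each = w), drop = FALSE])
  }
  out
}

# Average K equal-width column blocks: n x (K*w) -> n x w.
ad_mean_blocks <- function(tape, a, k_blocks) {
  p <- ncol(a$value)
  w <- p %/% k_blocks
  stopifnot(w * k_blocks == p)
  v <- a$value
  outv <- matrix(0, nrow(v), w)
  for (j in seq_len(k_blocks)) {
    outv <- outv + v[, ((j - 1L) * w + 1L):(j * w), drop = FALSE]
  }
  outv <- outv / k_blocks
  out <- ad_node(tape, outv)
  out$backward <- function(g) {
    ad_accum(a, g[, rep(seq_len(w), times = k_blocks), drop = FALSE] /
               k_blocks)
  }
  out
}

ad_concat_cols <- function(tape, nodes) {
  widths <- vapply(nodes, function(n) ncol(n$value), integer(1))
  out <- ad_node(tape, do.call(cbind, lapply(nodes, function(n) n$value)))
  out$backward <- function(g) {
    at <- 0L
    for (i in seq_along(nodes)) {
      ad_accum(nodes[[i]], g[, (at + 1L):(at + widths[i]), drop = FALSE])
      at <- at + widths[i]
    }
  }
  out
}

ad_rowsums <- function(tape, a) {
  p <- ncol(a$value)
  out <- ad_node(tape, matrix(.rowSums(a$value, nrow(a$value), p),
                              ncol = 1L))
  out$backward <- function(g) {
    ad_accum(a, matrix(g, nrow(g), p))
  }
  out
}

ad_sum <- function(tape, a) {
  dims <- dim(a$value)
  out <- ad_node(tape, matrix(sum(a$value), 1L, 1L))
  out$backward <- function(g) {
    ad_accum(a, matrix(as.numeric(g), dims[1], dims[2]))
  }
  out
}

ad_mean <- function(tape, a) {
  n <- length(a$value)
  dims <- dim(a$value)
  out <- ad_node(tape, matrix(mean(a$value), 1L, 1L))
  out$backward <- function(g) {
    ad_accum(a, matrix(as.numeric(g) / n, dims[1], dims[2]))
  }
  out
}

## ---- nonlinearities --------------------------------------------------------

ad_leakyrelu <- function(tape, a, slope = 0.2) {
  v <- a$value
  neg <- v < 0
  fwd <- v
  fwd[neg] <- slope * v[neg]
  out <- ad_node(tape, fwd)
  out$backward <- function(g) {
    gb <- g
    gb[neg] <- slope * g[neg]
    ad_accum(a, gb)
  }
  out
}

ad_relu <- function(tape, a) {
  v <- a$value
  out <- ad_node(tape, pmax(v, 0))
  out$backward <- function(g) ad_accum(a, g * (v > 0))
  out
}

ad_elu <- function(tape, a) {
  v <- a$value
  neg <- v < 0
  ev <- v
  ev[neg] <- expm1(v[neg])
  out <- ad_node(tape, ev)
  out$backward <- function(g) {
    gb <- g
    gb[neg] <- g[neg] * (ev[neg] + 1)
    ad_accum(a, gb)
  }
  out
}

ad_tanh <- function(tape, a) {
  tv <- tanh(a$value)
  out <- ad_node(tape, tv)
  out$backward <- function(g) ad_accum(a, g * (1 - tv^2))
  out
}

ad_sigmoid <- function(tape, a) {
  sv <- stats::plogis(a$value)
  out <- ad_node(tape, sv)
  out$backward <- function(g) ad_accum(a, g * sv * (1 - sv))
  out
}

ad_exp <- function(tape, a) {
  ev <- exp(a$value)
  out <- ad_node(tape, ev)
  out$backward <- function(g) ad_accum(a, g * ev)
  out
}

ad_square <- function(tape, a) {
  v <- a$value
  out <- ad_node(tape, v^2)
  out$backward <- function(g) ad_accum(a, 2 * g * v)
  out
}

ad_abs <- function(tape, a) {
  v <- a$value
  out <- ad_node(tape, abs(v))
  out$backward <- function(g) ad_accum(a, g * sign(v))
  out
}

## ---- structured softmax ops ------------------------------------------------

# Column-wise softmax within segments: logits is E x K, groups maps each row to
# a segment in 1..n_groups. Each column is normalised independently so that
# rows in the same segment sum to 1 per column. A global per-column shift keeps
# exponentials bounded without changing the result.
ad_segment_softmax <- function(tape, logits, groups, n_groups,
                               uniq = NULL) {
  force(uniq); force(groups); force(n_groups)
  v <- logits$value
  e <- exp(v - max(v))
  denom <- scatter_rowsum(e, groups, n_groups, uniq)
  alpha <- e / denom[groups, , drop = FALSE]
  out <- ad_node(tape, alpha)
  out$backward <- function(g) {
    inner <- scatter_rowsum(alpha * g, groups, n_groups, uniq)
    ad_accum(logits, alpha * (g - inner[groups, , drop = FALSE]))
  }
  out
}

# Row-wise softmax over the columns allowed by a {0,1} mask; fully masked rows
# yield all-zero rows (callers treat those separately).
ad_masked_row_softmax <- function(tape, scores, mask) {
  v <- scores$value
  n <- nrow(v); p <- ncol(v)
  off <- mask == 0
  e <- exp(v - max(v[!off], 0))
  e[off] <- 0
  denom <- .rowSums(e, n, p)
  denom[denom == 0] <- 1
  beta <- e / denom
  out <- ad_node(tape, beta)
  out$backward <- function(g) {
    inner <- .rowSums(beta * g, n, p)
    ad_accum(scores, beta * (g - inner))
  }
  out
}

# Restricted product: out = a[rows, ] %*% b, avoiding work on rows that a
# relation never touches.
ad_matmul_rows <- function(tape, a, b, rows) {
  av <- a$value[rows, , drop = FALSE]
  bv <- b$value
  n_full <- nrow(a$value)
  out <- ad_node(tape, av %*% bv)
  out$backward <- function(g) {
    da <- g %*% t(bv)
    full <- matrix(0, n_full, ncol(a$value))
    full[rows, ] <- da
    ad_accum(a, full)
    ad_accum(b, crossprod(av, g))
  }
  out
}

# Whole-relation attention node backed by the compiled kernel: projection,
# per-edge logits, LeakyReLU, segment softmax and message aggregation in one
# tape node. `re` is a relation entry from build_graph_cache().
ad_relation_layer <- function(tape, H, W, a_src, a_dst, re, n_out, k_heads,
                              slope, final_mean) {
  force(re); force(n_out); force(k_heads); force(slope); force(final_mean)
  h_rows <- H$value[re$rows, , drop = FALSE]
  wv <- W$value
  asv <- as.numeric(a_src$value)
  adv <- as.numeric(a_dst$value)
  fw <- rel_attn_forward(h_rows, wv, asv, adv, re$src_l, re$dst_l, re$dst,
                         n_out, k_heads, slope, final_mean)
  out <- ad_node(tape, fw$hr)
  out$backward <- function(g) {
    bw <- rel_attn_backward(g, h_rows, wv, asv, adv, re$src_l, re$dst_l,
                            re$dst, fw$wh, fw$raw, fw$alpha, k_heads, slope,
                            final_mean)
    full <- matrix(0, nrow(H$value), ncol(H$value))
    full[re$rows, ] <- bw$dh_rows
    ad_accum(H, full)
    ad_accum(W, bw$dw)
    ad_accum(a_src, matrix(bw$da_src, ncol = 1L))
    ad_accum(a_dst, matrix(bw$da_dst, ncol = 1L))
  }
  out
}

## ---- fused graph-attention ops ---------------------------------------------
# These fold several primitive ops into one tape node each; they exist purely
# to keep the node count (and R dispatch overhead) low on full-graph passes.
# Their gradients are covered by the same finite-difference tests as the
# primitives.

# Per-edge attention logits for all K heads at once:
#   logit[e, k] = sum(a_src[blk_k] * Wh[src_e, blk_k]) +
#                 sum(a_dst[blk_k] * Wh[dst_e, blk_k])
ad_edge_logits <- function(tape, Wh, a_src, a_dst, src, dst, k_heads,
                           src_uniq = NULL, dst_uniq = NULL) {
  # force backward-only arguments now; the closure must not see later loop
  # iterations' bindings
  force(src_uniq); force(dst_uniq)
  whv <- Wh$value
  n <- nrow(whv)
  p <- ncol(whv)
  dh <- p %/% k_heads
  sel <- rep(seq_len(k_heads), each = dh)
  asv <- as.numeric(a_src$value)
  adv <- as.numeric(a_dst$value)
  s1 <- rowsum_cols(whv * rep(asv, each = n), k_heads, dh)
  s2 <- rowsum_cols(whv * rep(adv, each = n), k_heads, dh)
  out <- ad_node(tape, s1[src, , drop = FALSE] + s2[dst, , drop = FALSE])
  out$backward <- function(g) {
    ds1 <- scatter_rowsum(g, src, n, src_uniq)
    ds2 <- scatter_rowsum(g, dst, n, dst_uniq)
    e1 <- ds1[, sel, drop = FALSE]
    e2 <- ds2[, sel, drop = FALSE]
    ad_accum(Wh, e1 * rep(asv, each = n) + e2 * rep(adv, each = n))
    ad_accum(a_src, matrix(.colSums(whv * e1, n, p), p, 1L))
    ad_accum(a_dst, matrix(.colSums(whv * e2, n, p), p, 1L))
  }
  out
}

# Weighted message aggregation: broadcast per-head coefficients over head
# blocks, weight the source rows of Wh, and segment-sum into target rows.
ad_attention_message <- function(tape, alpha, Wh, src, dst, n_out, k_heads,
                                 dst_uniq = NULL, src_uniq = NULL) {
  force(src_uniq); force(dst_uniq)
  whv <- Wh$value
  dh <- ncol(whv) %/% k_heads
  sel <- rep(seq_len(k_heads), each = dh)
  a_exp <- alpha$value[, sel, drop = FALSE]
  wh_src <- whv[src, , drop = FALSE]
  out <- ad_node(tape, scatter_rowsum(a_exp * wh_src, dst, n_out, dst_uniq))
  out$backward <- function(g) {
    dm <- g[dst, , drop = FALSE]
    ad_accum(Wh, scatter_rowsum(dm * a_exp, src, nrow(whv), src_uniq))
    da_exp <- dm * wh_src
    ad_accum(alpha, rowsum_cols(da_exp, k_heads, dh))
  }
  out
}

# Relation-level scores: column r is h_list[[r]] %*% q.
ad_relation_scores <- function(tape, h_list, q) {
  qv <- as.numeric(q$value)
  vals <- lapply(h_list, `[[`, "value")
  out <- ad_node(tape, do.call(cbind, lapply(vals, function(v) v %*% qv)))
  out$backward <- function(g) {
    dq <- numeric(length(qv))
    for (r in seq_along(h_list)) {
      gr <- g[, r]
      ad_accum(h_list[[r]], outer(gr, qv))
      dq <- dq + as.numeric(crossprod(vals[[r]], gr))
    }
    ad_accum(q, matrix(dq, length(qv), 1L))
  }
  out
}

# Fused embedding: sum over relations of beta[, r] * h_list[[r]].
ad_fusion_combine <- function(tape, beta, h_list) {
  bv <- beta$value
  vals <- lapply(h_list, `[[`, "value")
  acc <- vals[[1]] * bv[, 1]
  for (r in seq_along(h_list)[-1]) acc <- acc + vals[[r]] * bv[, r]
  out <- ad_node(tape, acc)
  out$backward <- function(g) {
    n <- nrow(bv)
    p <- ncol(vals[[1]])
    db <- matrix(0, n, ncol(bv))
    for (r in seq_along(h_list)) {
      ad_accum(h_list[[r]], g * bv[, r])
      db[, r] <- .rowSums(g * vals[[r]], n, p)
    }
    ad_accum(beta, db)
  }
  out
}

# column-block row sums: n x (K*dh) -> n x K (helper, no tape involvement)
rowsum_cols <- function(m, k_blocks, dh) {
  n <- nrow(m)
  out <- matrix(0, n, k_blocks)
  for (j in seq_len(k_blocks)) {
    out[, j] <- .rowSums(m[, ((j - 1L) * dh + 1L):(j * dh), drop = FALSE],
                         n, dh)
  }
  out
}

# segment row sum aligned to n_out rows (helper, no tape involvement);
# `uniq` optionally carries unique(groups) to skip rowname parsing
scatter_rowsum <- function(m, groups, n_out, uniq = NULL) {
  acc <- rowsum(m, group = groups, reorder = FALSE)
  full <- matrix(0, n_out, ncol(m))
  full[uniq %||% as.integer(rownames(acc)), ] <- acc
  full
}

## ---- losses ----------------------------------------------------------------

# Numerically stable mean binary cross-entropy from logits.
ad_bce_with_logits <- function(tape, logits, labels) {
  z <- logits$value
  y <- as.numeric(labels)
  n <- length(z)
  softplus <- pmax(z, 0) + log1p(exp(-abs(z)))
  out <- ad_node(tape, matrix(mean(softplus - y * z), 1L, 1L))
  out$backward <- function(g) {
    ad_accum(logits,
             matrix((stats::plogis(z) - y) * as.numeric(g) / n, nrow(z), 1L))
  }
  out
}

ad_mse <- function(tape, pred, target) {
  d <- pred$value - as_matrix(target)
  n <- length(d)
  out <- ad_node(tape, matrix(mean(d^2), 1L, 1L))
  out$backward <- function(g) {
    ad_accum(pred, 2 * d * as.numeric(g) / n)
  }
  out
}

# Inverted dropout; the mask is drawn from the current RNG stream at forward
# time, so callers control determinism through seeding.
ad_dropout <- function(tape, a, rate, training) {
  if (!training || rate <= 0) return(a)
  keep <- (stats::runif(length(a$value)) >= rate) / (1 - rate)
  mask <- matrix(keep, nrow(a$value), ncol(a$value))
  out <- ad_node(tape, a$value * mask)
  out$backward <- function(g) ad_accum(a, g * mask)
  out
}

## ---- parameter plumbing ----------------------------------------------------

# Wrap a flat named list of numeric matrices as tape leaves.
ad_wrap_params <- function(tape, params) {
  lapply(params, function(p) ad_leaf(tape, p))
}

# Collect accumulated gradients from wrapped leaves (zeros where untouched).
ad_collect_grads <- function(leaves, params) {
  out <- vector("list", length(params))
  names(out) <- names(params)
  for (nm in names(params)) {
    g <- leaves[[nm]]$grad
    out[[nm]] <- if (is.null(g)) {
      array(0, dim = dim(as_matrix(params[[nm]])))
    } else {
      g
    }
  }
  out
}
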