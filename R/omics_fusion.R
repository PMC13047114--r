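# Attention-weighted multi-omics fusion classifier.
#
# Each modality m runs through its own two-layer encoder to a shared latent
# width; per sample, modality weights are softmax(u^T tanh(W h^m)); the
# weighted sum feeds a linear-sigmoid outcome classifier trained with binary
# cross-entropy. Biomarkers are ranked by integrated gradients of the
# predicted probability with respect to the raw inputs.

#' Initialise omics-fusion parameters
#'
#' Per modality: a two-layer encoder (ReLU after the first layer, linear
#' second layer) to latent width `d_om`; shared fusion parameters `W`
#' (`d_att x d_om`) and `u` (length `d_att`); classifier weights `w` (length
#' `d_om`).
#'
#' @param n_features_per_modality integer vector of input widths.
#' @param d_om encoder latent width (default 64).
#' @param d_att fusion attention width (default 32).
#' @param seed integer seed.
#' @return An object of class `omics_params`.
#' @export
omics_params <- function(n_features_per_modality, d_om = 64L, d_att = 32L,
                         seed = 1L) {
  d_om <- as.integer(d_om)
  d_att <- as.integer(d_att)
  with_seed(derive_seed(seed, "omics_init"), {
    values <- list()
    for (m in seq_along(n_features_per_modality)) {
      p <- n_features_per_modality[m]
      values[[sprintf("enc%d_W1", m)]] <- glorot(p, d_om)
      values[[sprintf("enc%d_b1", m)]] <- matrix(0, 1L, d_om)
      values[[sprintf("enc%d_W2", m)]] <- glorot(d_om, d_om)
      values[[sprintf("enc%d_b2", m)]] <- matrix(0, 1L, d_om)
    }
    values$fusion_W <- glorot(d_att, d_om)
    values$fusion_u <- glorot(d_att, 1L)
    values$clf_w <- glorot(d_om, 1L)
    structure(list(values = values,
                   meta = list(
                     n_modalities = length(n_features_per_modality),
                     n_features = as.integer(n_features_per_modality),
                     d_om = d_om, d_att = d_att)),
              class = "omics_params")
  })
}

#' Encode one omics modality
#'
#' Row-wise deterministic encoding `linear(relu(X W1 + b1)) W2 + b2` to the
#' shared latent width; modalities are fully independent of each other.
#'
#' @param X_m numeric sample-by-feature matrix for the modality.
#' @param params an [omics_params()] object.
#' @param modality modality index.
#' @return Latent matrix `n_samples x d_om`.
#' @export
encode_modality <- function(X_m, params, modality) {
  stopifnot(inherits(params, "omics_params"))
  v <- params$values
  W1 <- v[[sprintf("enc%d_W1", modality)]]
  if (ncol(X_m) != nrow(W1)) {
    stop(sprintf("modality %d width mismatch: got %d features, expected %d",
                 modality, ncol(X_m), nrow(W1)))
  }
  h <- pmax(X_m %*% W1 +
              matrix(v[[sprintf("enc%d_b1", modality)]],
                     nrow(X_m), ncol(W1), byrow = TRUE), 0)
  h %*% v[[sprintf("enc%d_W2", modality)]] +
    matrix(v[[sprintf("enc%d_b2", modality)]], nrow(X_m),
           ncol(W1), byrow = TRUE)
}

#' Attention-weighted fusion of modality latents
#'
#' For one sample: `w_m = softmax_m(u^T tanh(W h^m))`;
#' the fused representation is the weight-averaged latent.
#'
#' @param latents list of latent vectors (one per modality, equal lengths).
#' @param W fusion matrix (`d_att x d_om`).
#' @param u fusion query vector (length `d_att`).
#' @return List with `fused` (vector) and `weights` (vector summing to 1).
#' @export
fuse_modalities <- function(latents, W, u) {
  if (length(latents) == 0L) stop("no modality latents to fuse")
  scores <- vapply(latents, function(h) sum(u * tanh(W %*% h)), numeric(1))
  e <- exp(scores - max(scores))
  weights <- e / sum(e)
  fused <- Reduce(`+`, Map(function(a, h) a * h, weights, latents))
  list(fused = fused, weights = weights)
}

#' Predict the outcome probability from a fused representation
#'
#' `sigmoid(w . h_fused)`.
#'
#' @param fused fused latent vector.
#' @param w classifier weight vector of the same length.
#' @return Scalar probability in `(0, 1)`.
#' @export
predict_outcome <- function(fused, w) {
  stopifnot(length(fused) == length(w))
  sigmoid(sum(w * fused))
}

#' Omics classification loss
#'
#' Summed binary cross-entropy over samples with probability clipping.
#'
#' @param probs predicted probabilities.
#' @param labels labels in `{0, 1}`.
#' @return Nonnegative scalar.
#' @export
omics_loss <- function(probs, labels) {
  bce_loss(probs, labels, mean_reduced = FALSE)
}

# Tape forward over all samples; returns prediction node and intermediates.
omics_forward_tape <- function(tape, leaves, modalities, meta,
                               inputs_as_leaves = FALSE) {
  n <- nrow(modalities[[1]])
  latents <- list()
  input_nodes <- list()
  for (m in seq_len(meta$n_modalities)) {
    Xn <- if (inputs_as_leaves) {
      ad_leaf(tape, modalities[[m]])
    } else {
      ad_const(tape, modalities[[m]])
    }
    input_nodes[[m]] <- Xn
    h1 <- ad_relu(tape, ad_add_bias(tape,
                                    ad_matmul(tape, Xn,
                                              leaves[[sprintf("enc%d_W1", m)]]),
                                    leaves[[sprintf("enc%d_b1", m)]]))
    latents[[m]] <- ad_add_bias(tape,
                                ad_matmul(tape, h1,
                                          leaves[[sprintf("enc%d_W2", m)]]),
                                leaves[[sprintf("enc%d_b2", m)]])
  }
  scores <- ad_concat_cols(tape, lapply(latents, function(H) {
    ad_matmul(tape, ad_tanh(tape, ad_matmul_bt(tape, H, leaves$fusion_W)),
              leaves$fusion_u)
  }))
  attn <- ad_masked_row_softmax(tape, scores,
                                matrix(1, n, meta$n_modalities))
  fused <- NULL
  for (m in seq_len(meta$n_modalities)) {
    term <- ad_mul(tape, ad_repcols(tape, ad_col(tape, attn, m), meta$d_om),
                   latents[[m]])
    fused <- if (is.null(fused)) term else ad_add(tape, fused, term)
  }
  logits <- ad_matmul(tape, fused, leaves$clf_w)
  list(logits = logits, attn = attn, inputs = input_nodes)
}

#' Train the omics-fusion classifier
#'
#' Full-batch Adam on mean binary cross-entropy.
#'
#' @param modalities list of sample-by-feature matrices (shared sample axis).
#' @param labels binary outcome labels.
#' @param params an [omics_params()] (initialised if `NULL`).
#' @param steps optimisation steps (default 300).
#' @param lr Adam learning rate (default 0.01).
#' @param seed integer seed.
#' @return List with `params`, `history` (loss per step), `attention`
#'   (final per-sample modality weight matrix) and `mean_attention`.
#' @export
train_omics_fusion <- function(modalities, labels, params = NULL,
                               steps = 300L, lr = 0.01, seed = 1L) {
  if (is.null(params)) {
    params <- omics_params(vapply(modalities, ncol, integer(1)), seed = seed)
  }
  stopifnot(inherits(params, "omics_params"))
  meta <- params$meta
  state <- adam_init(params$values, lr = lr)
  history <- numeric(steps)
  attn <- NULL
  for (s in seq_len(steps)) {
    tape <- ad_tape()
    leaves <- ad_wrap_params(tape, params$values)
    fw <- omics_forward_tape(tape, leaves, modalities, meta)
    loss <- ad_bce_with_logits(tape, fw$logits, labels)
    ad_backward(tape, loss)
    grads <- ad_collect_grads(leaves, params$values)
    upd <- adam_step(params$values, grads, state)
    params$values <- upd$params
    state <- upd$state
    history[s] <- as.numeric(loss$value)
    attn <- fw$attn$value
  }
  list(params = params, history = history, attention = attn,
       mean_attention = colMeans(attn))
}

#' Rank input features by integrated gradients
#'
#' Attribution of the predicted probability to each raw input feature along
#' the straight-line path from the per-feature mean baseline, using a
#' midpoint Riemann sum with `steps` path points. Importances are mean
#' absolute attributions over samples, normalised to sum 1, in descending
#' order with lexicographic `(modality, feature)` tie-break. An untrained
#' (all-zero-gradient) model yields uniform importances with a warning.
#'
#' @param modalities list of sample-by-feature matrices.
#' @param params trained [omics_params()].
#' @param steps path steps for the Riemann sum (default 50).
#' @return data.frame with columns `modality`, `feature`, `importance`.
#' @export
rank_biomarkers <- function(modalities, params, steps = 50L) {
  stopifnot(inherits(params, "omics_params"))
  meta <- params$meta
  baselines <- lapply(modalities, function(X) {
    matrix(colMeans(X), nrow(X), ncol(X), byrow = TRUE)
  })
  grad_sum <- lapply(modalities, function(X) matrix(0, nrow(X), ncol(X)))
  for (k in seq_len(steps)) {
    alpha <- (k - 0.5) / steps
    Xk <- Map(function(X, B) B + alpha * (X - B), modalities, baselines)
    tape <- ad_tape()
    leaves <- ad_wrap_params(tape, params$values)
    fw <- omics_forward_tape(tape, leaves, Xk, meta, inputs_as_leaves = TRUE)
    prob <- ad_sigmoid(tape, fw$logits)
    total <- ad_sum(tape, prob)
    ad_backward(tape, total)
    for (m in seq_along(grad_sum)) {
      g <- fw$inputs[[m]]$grad
      if (!is.null(g)) grad_sum[[m]] <- grad_sum[[m]] + g
    }
  }
  rows <- list()
  for (m in seq_along(modalities)) {
    ig <- (modalities[[m]] - baselines[[m]]) * grad_sum[[m]] / steps
    imp <- colMeans(abs(ig))
    feat <- colnames(modalities[[m]]) %||%
      sprintf("f%03d", seq_len(ncol(modalities[[m]])))
    rows[[m]] <- data.frame(modality = m, feature = feat, importance = imp,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  total_imp <- sum(out$importance)
  if (total_imp <= 0) {
    warning("model attributes nothing; reporting uniform importances")
    out$importance <- 1 / nrow(out)
  } else {
    out$importance <- out$importance / total_imp
  }
  out <- out[order(-out$importance, out$modality, out$feature), ]
  rownames(out) <- NULL
  out
}

# Per-sample integrated-gradient completeness diagnostic: sum of attributions
# vs f(x) - f(baseline).
#' @keywords internal
ig_completeness <- function(modalities, params, steps = 200L) {
  meta <- params$meta
  baselines <- lapply(modalities, function(X) {
    matrix(colMeans(X), nrow(X), ncol(X), byrow = TRUE)
  })
  predict_batch <- function(Xs) {
    tape <- ad_tape()
    leaves <- ad_wrap_params(tape, params$values)
    fw <- omics_forward_tape(tape, leaves, Xs, meta)
    as.numeric(stats::plogis(fw$logits$value))
  }
  grad_sum <- lapply(modalities, function(X) matrix(0, nrow(X), ncol(X)))
  for (k in seq_len(steps)) {
    alpha <- (k - 0.5) / steps
    Xk <- Map(function(X, B) B + alpha * (X - B), modalities, baselines)
    tape <- ad_tape()
    leaves <- ad_wrap_params(tape, params$values)
    fw <- omics_forward_tape(tape, leaves, Xk, meta, inputs_as_leaves = TRUE)
    total <- ad_sum(tape, ad_sigmoid(tape, fw$logits))
    ad_backward(tape, total)
    for (m in seq_along(grad_sum)) {
      g <- fw$inputs[[m]]$grad
      if (!is.null(g)) grad_sum[[m]] <- grad_sum[[m]] + g
    }
  }
  attr_sum <- Reduce(`+`, Map(function(X, B, G) {
    rowSums((X - B) * G / steps)
  }, modalities, baselines, grad_sum))
  list(attribution_sum = attr_sum,
       delta = predict_batch(modalities) - predict_batch(baselines))
}
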