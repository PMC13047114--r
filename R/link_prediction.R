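#' Score drug-disease pairs
#'
#' Dot-product link predictor with sigmoid activation:
#' `score(d, s) = sigmoid(h_d . h_s)`.
#'
#' @param embeddings numeric matrix of node embeddings, rows named by node id.
#' @param pairs data.frame (or 2-column matrix) whose first two columns name
#'   the two endpoints of each pair.
#' @return Numeric vector of scores in `(0, 1)`.
#' @export
score_pairs <- function(embeddings, pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  a <- as.character(pairs[[1]])
  b <- as.character(pairs[[2]])
  missing <- setdiff(c(a, b), rownames(embeddings))
  if (length(missing)) {
    stop("no embedding for node(s): ", paste(missing, collapse = ", "))
  }
  z <- rowSums(embeddings[a, , drop = FALSE] * embeddings[b, , drop = FALSE])
  unname(sigmoid(z))
}

#' Binary cross-entropy loss over scored pairs
#'
#' `L = -sum(y log y' + (1 - y) log(1 - y'))` with scores clipped to
#' `[eps, 1 - eps]` so the loss is always finite. `mean_reduced = TRUE`
#' divides by the number of pairs (the variant used for optimisation and for
#' test loss).
#'
#' @param scores numeric vector of predicted probabilities.
#' @param labels numeric vector of labels in `{0, 1}`.
#' @param mean_reduced divide by the batch size (default FALSE: summed form).
#' @param eps clipping constant (default 1e-7).
#' @return Nonnegative scalar.
#' @export
bce_loss <- function(scores, labels, mean_reduced = FALSE, eps = 1e-7) {
  if (length(scores) != length(labels)) {
    stop("scores and labels have different lengths")
  }
  stopifnot(all(labels %in% c(0, 1)))
  p <- clip_probs(scores, eps)
  total <- -sum(labels * log(p) + (1 - labels) * log(1 - p))
  if (mean_reduced) total / length(scores) else total
}

#' Sample negative drug-disease pairs
#'
#' Uniform draw of `round(ratio * n_positive)` (drug, disease) pairs from the
#' complement of the positive set, without replacement within the draw.
#' Training default is a 1:1 ratio; evaluation may use 5:1 or rank the full
#' drug pool instead.
#'
#' @param positives data.frame with columns `drug_id`, `disease_id`.
#' @param drugs,diseases character vectors of candidate ids.
#' @param ratio negatives per positive.
#' @param seed integer seed.
#' @return data.frame with columns `drug_id`, `disease_id`, disjoint from
#'   `positives`.
#' @export
sample_negatives <- function(positives, drugs, diseases, ratio, seed) {
  positives <- as.data.frame(positives, stringsAsFactors = FALSE)
  n_needed <- round(ratio * nrow(positives))
  all_pairs <- expand.grid(drug_id = drugs, disease_id = diseases,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pos_key <- paste(positives$drug_id, positives$disease_id, sep = "\r")
  pool <- all_pairs[!(paste(all_pairs$drug_id, all_pairs$disease_id,
                            sep = "\r") %in% pos_key), , drop = FALSE]
  if (n_needed > nrow(pool)) {
    stop(sprintf("requested %d negatives but only %d non-positive pairs exist",
                 n_needed, nrow(pool)))
  }
  with_seed(seed, {
    idx <- sample.int(nrow(pool), n_needed)
    out <- pool[idx, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Rank a drug pool for one disease
#'
#' Scores every drug in the pool against the disease and returns them in
#' descending score order, ties broken lexicographically by drug id.
#'
#' @param disease_id target disease node id.
#' @param drug_pool character vector of drug ids.
#' @param embeddings node embedding matrix, rows named by id.
#' @return data.frame with columns `drug_id`, `rank`, `score`.
#' @export
rank_candidates <- function(disease_id, drug_pool, embeddings) {
  if (length(drug_pool) == 0L) {
    return(data.frame(drug_id = character(), rank = integer(),
                      score = numeric()))
  }
  scores <- score_pairs(embeddings,
                        data.frame(drug_id = drug_pool,
                                   disease_id = disease_id))
  ord <- order(-scores, drug_pool)
  data.frame(drug_id = drug_pool[ord], rank = seq_along(drug_pool),
             score = scores[ord], stringsAsFactors = FALSE)
}

# Loss + gradients of the encoder-and-predictor stack on one pair batch.
# `pairs_idx` is a 2-column integer matrix of global node indices into the
# cache's node order. Returns summed-mean BCE (mean over pairs), parameter
# gradients and the raw logits.
#' @keywords internal
link_loss_and_grads <- function(params, cache, pairs_idx, labels,
                                training = TRUE, dropout_seed = NULL) {
  run <- function() {
    tape <- ad_tape()
    leaves <- ad_wrap_params(tape, params$values)
    H <- encoder_forward_tape(tape, cache, leaves, params$meta, training)
    Hd <- ad_rows(tape, H, pairs_idx[, 1])
    Hs <- ad_rows(tape, H, pairs_idx[, 2])
    z <- ad_rowsums(tape, ad_mul(tape, Hd, Hs))
    loss <- ad_bce_with_logits(tape, z, labels)
    ad_backward(tape, loss)
    list(loss = as.numeric(loss$value),
         grads = ad_collect_grads(leaves, params$values),
         logits = as.numeric(z$value))
  }
  if (training) {
    if (is.null(dropout_seed)) stop("training loss needs a dropout seed")
    with_seed(derive_seed(dropout_seed, "dropout"), run())
  } else {
    run()
  }
}
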