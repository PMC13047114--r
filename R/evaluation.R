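#' Disjoint disease split
#'
#' Shuffles the diseases by seed and assigns train/validation/test counts by
#' largest-remainder rounding of the fractions, so counts always sum to the
#' number of diseases and the three sets are mutually exclusive — the
#' cold-start guarantee that no test disease is ever seen in training.
#'
#' @param diseases character vector of disease ids (>= 3).
#' @param fractions numeric triple summing to 1 (default 0.70/0.15/0.15).
#' @param seed integer seed.
#' @return A list of class `disease_split` with `train`, `val`, `test`,
#'   `fractions`, `seed`.
#' @export
disjoint_disease_split <- function(diseases, fractions = c(0.70, 0.15, 0.15),
                                   seed = 1L) {
  stopifnot(length(diseases) >= 3, length(fractions) == 3,
            all(fractions > 0))
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1")
  }
  n <- length(diseases)
  quota <- fractions * n
  counts <- floor(quota)
  rem <- quota - counts
  short <- n - sum(counts)
  if (short > 0) {
    order_rem <- order(-rem, seq_along(rem))
    counts[order_rem[seq_len(short)]] <- counts[order_rem[seq_len(short)]] + 1
  }
  shuffled <- with_seed(derive_seed(seed, "split"), sample(diseases))
  train <- shuffled[seq_len(counts[1])]
  val <- shuffled[counts[1] + seq_len(counts[2])]
  test <- shuffled[counts[1] + counts[2] + seq_len(counts[3])]
  structure(list(train = train, val = val, test = test,
                 fractions = fractions, seed = as.integer(seed)),
            class = "disease_split")
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision over descending-score thresholds with tied
#' scores grouped: `sum_k (R_k - R_{k-1}) * P_k`.
#'
#' @param scores numeric prediction scores.
#' @param labels labels in `{0, 1}`; both classes must be present.
#' @return Scalar in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("auprc needs at least one positive and one negative label")
  }
  ord <- order(-scores)
  s <- scores[ord]
  y <- labels[ord]
  groups <- cumsum(!duplicated(s))
  tp_g <- tapply(y == 1, groups, sum)
  n_g <- tapply(y, groups, length)
  tp <- cumsum(tp_g)
  total <- cumsum(n_g)
  precision <- tp / total
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Area under the ROC curve
#'
#' Rank-statistic formulation: the probability that a random positive
#' outscores a random negative, ties counted half — equal to the trapezoidal
#' area under the ROC curve.
#'
#' @inheritParams auprc
#' @return Scalar in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("roc_auc needs at least one positive and one negative label")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Mean binary cross-entropy on held-out pairs
#'
#' `bce_loss(..., mean_reduced = TRUE)`: the cross-entropy error on unseen
#' pairs, averaged over the test set.
#'
#' @inheritParams auprc
#' @return Nonnegative scalar.
#' @export
test_loss <- function(scores, labels) {
  if (length(scores) == 0L) stop("empty test set")
  bce_loss(scores, labels, mean_reduced = TRUE)
}

#' Relative improvement of a metric over a baseline
#'
#' `(new - baseline) / baseline * 100`, in percent.
#'
#' @param metric_new,metric_baseline numeric scalars; the baseline must be
#'   positive.
#' @return Percent improvement (negative when worse).
#' @export
relative_improvement <- function(metric_new, metric_baseline) {
  if (metric_baseline <= 0) stop("baseline must be positive")
  (metric_new - metric_baseline) / metric_baseline * 100
}

#' Confusion counts at a fixed threshold
#'
#' @inheritParams auprc
#' @param threshold classification threshold (default 0.5; scores >=
#'   threshold predict positive).
#' @param balanced subsample an equal number of positives and negatives
#'   before counting (seeded), mirroring balanced diagnostic subsets.
#' @param seed seed for the balanced subsample.
#' @return Named integer vector `c(TP, TN, FP, FN)`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5,
                             balanced = FALSE, seed = 1L) {
  stopifnot(length(scores) == length(labels))
  if (balanced) {
    pos <- which(labels == 1)
    neg <- which(labels == 0)
    m <- min(length(pos), length(neg))
    keep <- with_seed(derive_seed(seed, "balanced"),
                      c(sample(pos, m), sample(neg, m)))
    scores <- scores[keep]
    labels <- labels[keep]
  }
  pred <- as.integer(scores >= threshold)
  c(TP = sum(pred == 1 & labels == 1),
    TN = sum(pred == 0 & labels == 0),
    FP = sum(pred == 1 & labels == 0),
    FN = sum(pred == 0 & labels == 1))
}

# Evaluation pair set for a group of diseases: every (drug, disease) pair in
# "full" mode, or positives plus ratio-sampled negatives in "ratio" mode.
# Diseases without a single positive are excluded from aggregation.
#' @keywords internal
eval_pairs_for_diseases <- function(diseases, positives, drug_pool,
                                    mode = c("full", "ratio"), ratio = 5,
                                    seed = 1L, exclude = NULL) {
  mode <- match.arg(mode)
  pos_key <- paste(positives$drug_id, positives$disease_id, sep = "\r")
  excl_key <- if (!is.null(exclude)) {
    paste(exclude$drug_id, exclude$disease_id, sep = "\r")
  } else {
    character()
  }
  out <- NULL
  for (s in diseases) {
    pos_s <- positives[positives$disease_id == s, , drop = FALSE]
    if (nrow(pos_s) == 0L) next
    if (mode == "full") {
      pairs <- data.frame(drug_id = drug_pool, disease_id = s,
                          stringsAsFactors = FALSE)
      key <- paste(pairs$drug_id, pairs$disease_id, sep = "\r")
      pairs <- pairs[!(key %in% excl_key), , drop = FALSE]
      key <- paste(pairs$drug_id, pairs$disease_id, sep = "\r")
      labels <- as.integer(key %in% pos_key)
    } else {
      banned <- c(pos_s$drug_id,
                  if (!is.null(exclude)) {
                    exclude$drug_id[exclude$disease_id == s]
                  })
      pool_s <- setdiff(drug_pool, banned)
      n_neg <- min(round(ratio * nrow(pos_s)), length(pool_s))
      neg_drugs <- with_seed(derive_seed(seed, paste0("eval_", s)),
                             sample(pool_s, n_neg))
      pairs <- rbind(pos_s[, c("drug_id", "disease_id")],
                     data.frame(drug_id = neg_drugs, disease_id = s,
                                stringsAsFactors = FALSE))
      labels <- c(rep(1L, nrow(pos_s)), rep(0L, n_neg))
    }
    out <- rbind(out, cbind(pairs, label = labels))
  }
  out
}

#' Run the cold-start (disjoint-disease) evaluation protocol
#'
#' Splits diseases into train/validation/test sets, removes every `treats`
#' edge of validation and test diseases from the training graph, meta-trains
#' the encoder over disease-centred tasks with epoch-wise negative
#' re-sampling, records validation ROC-AUC every epoch, restores the
#' checkpoint with the highest validation ROC-AUC, and computes test metrics
#' exactly once from that checkpoint. A hard leakage assertion verifies split
#' disjointness and the absence of held-out therapeutic edges before any
#' metric is reported.
#'
#' @param graph a [hetero_graph()] without inverse relations, containing
#'   `treats` edges (e.g. from [generate_kg()]).
#' @param features a `node_feature_set` for the graph (raw; preprocessing is
#'   applied internally).
#' @param model_config list overriding [hetgnn_params()] defaults
#'   (`d_hidden`, `n_heads`, `n_layers`, `dropout`).
#' @param meta_cfg a [meta_config()].
#' @param split_config list with `fractions` (default 0.70/0.15/0.15).
#' @param seed integer seed controlling the split, initialisation, task
#'   sampling, dropout and negative re-sampling.
#' @param max_epochs epoch budget (default 100).
#' @param patience epochs without a new best validation ROC-AUC before
#'   training stops early (default 15; `Inf` disables).
#' @param min_epochs epochs to run before the patience rule may stop
#'   training (default 25).
#' @param passes_per_epoch shuffled passes over the training diseases per
#'   epoch (each pass is a sequence of meta-batches; default 3).
#' @param negative_mode `"full"` ranks the entire drug pool per held-out
#'   disease; `"ratio"` uses `neg_eval_ratio` sampled negatives per positive.
#' @param neg_eval_ratio negatives per positive in `"ratio"` mode (default 5).
#' @param params optional pre-initialised [hetgnn_params()] (must match the
#'   graph's relations including inverses); skips initialisation.
#' @param skip_training evaluate the initial (untrained) parameters
#'   immediately; the untrained baseline.
#' @return An `eval_report`: list with `split`, `trace` (per-epoch validation
#'   ROC-AUC), `selected_epoch`, `test_metrics` (`auprc`, `roc_auc`,
#'   `test_loss`, `confusion`), `negative_mode`, `params` (the selected
#'   checkpoint), `params_final` (end-of-training parameters, the warmed-up
#'   state used for adaptation experiments), and `config` metadata.
#' @export
run_cold_start_protocol <- function(graph, features, model_config = list(),
                                    meta_cfg = meta_config(),
                                    split_config = list(),
                                    seed = 1L, max_epochs = 100L,
                                    patience = 15L, min_epochs = 25L,
                                    negative_mode = c("full", "ratio"),
                                    neg_eval_ratio = 5, params = NULL,
                                    skip_training = FALSE,
                                    passes_per_epoch = 3L) {
  negative_mode <- match.arg(negative_mode)
  stopifnot(inherits(graph, "hetero_graph"))
  if (any(endsWith(graph$relation_set, "_inv"))) {
    stop("pass the graph without inverse relations; they are added internally")
  }
  treats <- graph$edges[graph$edges$relation == "treats", ]
  positives <- data.frame(drug_id = treats$source,
                          disease_id = treats$target,
                          stringsAsFactors = FALSE)
  all_diseases <- graph$nodes$node_id[graph$nodes$node_type == "disease"]
  drug_pool <- graph$nodes$node_id[graph$nodes$node_type == "drug"]
  # diseases with no known treatment carry no evaluable signal and cannot
  # form tasks; they are excluded before splitting
  diseases <- intersect(all_diseases,
                        unique(positives$disease_id))
  eligible <- names(which(table(positives$disease_id) >= 2))
  if (length(intersect(diseases, eligible)) < 3) {
    stop("protocol needs at least 3 diseases with >= 2 positives")
  }

  fractions <- split_config$fractions %||% c(0.70, 0.15, 0.15)
  split <- disjoint_disease_split(diseases, fractions, seed)

  held_out <- c(split$val, split$test)
  train_edges <- graph$edges[!(graph$edges$relation == "treats" &
                                 graph$edges$target %in% held_out), ,
                             drop = FALSE]
  train_graph <- add_inverse_relations(
    hetero_graph(graph$nodes, train_edges, relations = graph$relation_set))

  # leakage assertion: hard error, never a warning
  leaked <- intersect(split$train, c(split$val, split$test))
  te <- train_graph$edges
  held_treats <- te[te$relation %in% c("treats", "treats_inv") &
                      (te$target %in% held_out | te$source %in% held_out), ]
  if (length(leaked) || nrow(held_treats)) {
    stop("disease leakage detected: protocol aborted")
  }

  features <- preprocess_features(features)

  if (is.null(params)) {
    params <- do.call(hetgnn_params, c(
      list(graph = train_graph, features = features,
           seed = derive_seed(seed, "params")),
      model_config))
  }

  full_cache <- build_graph_cache(train_graph, features)
  infer_embeddings <- function(p) {
    tape <- ad_tape()
    leaves <- ad_wrap_params(tape, p$values)
    H <- encoder_forward_tape(tape, full_cache, leaves, p$meta,
                              training = FALSE)
    out <- H$value
    rownames(out) <- full_cache$ids
    out
  }
  eval_group <- function(p, group_diseases) {
    pairs <- eval_pairs_for_diseases(group_diseases, positives, drug_pool,
                                     mode = negative_mode,
                                     ratio = neg_eval_ratio, seed = seed)
    if (is.null(pairs) || !sum(pairs$label) || all(pairs$label == 1)) {
      return(NULL)
    }
    emb <- infer_embeddings(p)
    scores <- score_pairs(emb, pairs[, c("drug_id", "disease_id")])
    list(scores = scores, labels = pairs$label)
  }

  trace <- data.frame(epoch = integer(), val_roc_auc = numeric())
  best <- list(epoch = 0L, auc = -Inf, params = params)

  if (!skip_training) {
    templates <- list()
    for (s in intersect(split$train, eligible)) {
      templates[[s]] <- tryCatch(
        build_task_template(train_graph, s, k = 2L),
        task_infeasible = function(e) NULL)
    }
    templates <- Filter(Negate(is.null), templates)
    if (!length(templates)) stop("no feasible training tasks")
    loss_cache <- new.env(parent = emptyenv())
    loss_fn <- make_task_loss_fn(features, seed = derive_seed(seed, "loss"),
                                 cache_env = loss_cache)
    opt_state <- NULL
    stale <- 0L
    for (epoch in seq_len(max_epochs)) {
      # one epoch = one pass over the training diseases in shuffled
      # meta-batches, with negatives re-sampled per epoch
      epoch_seed <- derive_seed(seed, paste0("epoch_", epoch))
      ordered <- with_seed(epoch_seed, {
        as.character(replicate(passes_per_epoch,
                               sample(names(templates))))
      })
      batches <- split(ordered,
                       ceiling(seq_along(ordered) /
                                 meta_cfg$meta_batch_size))
      for (batch_ids in batches) {
        tasks <- lapply(batch_ids, function(s) {
          instantiate_task(templates[[s]], meta_cfg$support_size,
                           meta_cfg$neg_ratio, epoch_seed)
        })
        upd <- meta_train_step(params, tasks, loss_fn, meta_cfg, opt_state)
        params <- upd$params
        opt_state <- upd$optimizer_state
      }

      val <- eval_group(params, split$val)
      val_auc <- if (is.null(val)) NA_real_ else roc_auc(val$scores,
                                                         val$labels)
      trace <- rbind(trace, data.frame(epoch = epoch,
                                       val_roc_auc = val_auc))
      if (!is.na(val_auc) && val_auc > best$auc) {
        best <- list(epoch = epoch, auc = val_auc, params = params)
        stale <- 0L
      } else {
        stale <- stale + 1L
      }
      if (epoch >= min_epochs && stale >= patience) break
    }
  }

  selected <- best$params
  final_params <- params
  test <- eval_group(selected, split$test)
  test_metrics <- if (is.null(test)) {
    list(auprc = NA_real_, roc_auc = NA_real_, test_loss = NA_real_,
         confusion = c(TP = NA, TN = NA, FP = NA, FN = NA))
  } else {
    list(auprc = auprc(test$scores, test$labels),
         roc_auc = roc_auc(test$scores, test$labels),
         test_loss = test_loss(test$scores, test$labels),
         confusion = confusion_counts(test$scores, test$labels))
  }

  structure(list(
    split = split,
    trace = trace,
    selected_epoch = best$epoch,
    best_val_roc_auc = if (is.finite(best$auc)) best$auc else NA_real_,
    test_metrics = test_metrics,
    negative_mode = list(mode = negative_mode, ratio = neg_eval_ratio),
    params = selected,
    params_final = final_params,
    config = list(seed = as.integer(seed), max_epochs = as.integer(max_epochs),
                  patience = patience, meta = unclass(meta_cfg),
                  model = model_config)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %d/%d/%d train/val/test diseases | best epoch %d (val ROC-AUC %.4f)\n",
    length(x$split$train), length(x$split$val), length(x$split$test),
    x$selected_epoch, x$best_val_roc_auc))
  cat(sprintf("  test: ROC-AUC %.4f | AUPRC %.4f | loss %.4f | mode %s\n",
              x$test_metrics$roc_auc, x$test_metrics$auprc,
              x$test_metrics$test_loss, x$negative_mode$mode))
  invisible(x)
}

#' Random-edge-split control protocol
#'
#' Control experiment for the cold-start protocol: instead of holding out
#' whole diseases, a random fraction of `treats` edges is held out while
#' every disease remains visible in training through its other edges. The
#' same meta-training procedure is used; held-out positives are scored
#' against the drug pool with train positives excluded. Comparing this
#' against [run_cold_start_protocol()] quantifies how much harder true
#' cold-start generalisation is.
#'
#' @inheritParams run_cold_start_protocol
#' @param test_fraction fraction of treats edges held out (default 0.2).
#' @return An `eval_report` (the `split` component holds edge counts).
#' @export
run_random_split_protocol <- function(graph, features, model_config = list(),
                                      meta_cfg = meta_config(), seed = 1L,
                                      max_epochs = 100L, patience = 15L,
                                      test_fraction = 0.2) {
  stopifnot(inherits(graph, "hetero_graph"))
  treats <- graph$edges[graph$edges$relation == "treats", ]
  positives <- data.frame(drug_id = treats$source,
                          disease_id = treats$target,
                          stringsAsFactors = FALSE)
  n_test <- max(1L, round(test_fraction * nrow(positives)))
  test_idx <- with_seed(derive_seed(seed, "edge_split"),
                        sample.int(nrow(positives), n_test))
  test_pos <- positives[test_idx, , drop = FALSE]
  train_pos <- positives[-test_idx, , drop = FALSE]

  test_key <- paste(test_pos$drug_id, test_pos$disease_id, sep = "\r")
  keep <- !(graph$edges$relation == "treats" &
              paste(graph$edges$source, graph$edges$target,
                    sep = "\r") %in% test_key)
  train_graph <- add_inverse_relations(
    hetero_graph(graph$nodes, graph$edges[keep, , drop = FALSE],
                 relations = graph$relation_set))
  features <- preprocess_features(features)
  drug_pool <- graph$nodes$node_id[graph$nodes$node_type == "drug"]

  params <- do.call(hetgnn_params, c(
    list(graph = train_graph, features = features,
         seed = derive_seed(seed, "params")),
    model_config))

  eligible <- names(which(table(train_pos$disease_id) >= 2))
  templates <- list()
  for (s in eligible) {
    templates[[s]] <- tryCatch(build_task_template(train_graph, s, k = 2L),
                               task_infeasible = function(e) NULL)
  }
  templates <- Filter(Negate(is.null), templates)
  if (!length(templates)) stop("no feasible training tasks")

  full_cache <- build_graph_cache(train_graph, features)
  infer_embeddings <- function(p) {
    tape <- ad_tape()
    leaves <- ad_wrap_params(tape, p$values)
    H <- encoder_forward_tape(tape, full_cache, leaves, p$meta,
                              training = FALSE)
    out <- H$value
    rownames(out) <- full_cache$ids
    out
  }
  eval_test <- function(p) {
    pairs <- eval_pairs_for_diseases(unique(test_pos$disease_id), test_pos,
                                     drug_pool, mode = "full",
                                     exclude = train_pos, seed = seed)
    if (is.null(pairs) || !sum(pairs$label) || all(pairs$label == 1)) {
      return(NULL)
    }
    emb <- infer_embeddings(p)
    list(scores = score_pairs(emb, pairs[, c("drug_id", "disease_id")]),
         labels = pairs$label)
  }

  # No validation split exists here, so checkpoint selection uses the lowest
  # meta-training (query) loss; the held-out edges are touched exactly once.
  loss_fn <- make_task_loss_fn(features, seed = derive_seed(seed, "loss"))
  opt_state <- NULL
  trace <- data.frame(epoch = integer(), l_meta = numeric())
  best <- list(epoch = 0L, l_meta = Inf, params = params)
  stale <- 0L
  for (epoch in seq_len(max_epochs)) {
    epoch_seed <- derive_seed(seed, paste0("repoch_", epoch))
    chosen <- with_seed(epoch_seed, {
      sample(names(templates),
             min(meta_cfg$meta_batch_size, length(templates)))
    })
    tasks <- lapply(chosen, function(s) {
      instantiate_task(templates[[s]], meta_cfg$support_size,
                       meta_cfg$neg_ratio, epoch_seed)
    })
    upd <- meta_train_step(params, tasks, loss_fn, meta_cfg, opt_state)
    params <- upd$params
    opt_state <- upd$optimizer_state
    trace <- rbind(trace, data.frame(epoch = epoch, l_meta = upd$l_meta))
    if (upd$l_meta < best$l_meta) {
      best <- list(epoch = epoch, l_meta = upd$l_meta, params = params)
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
    if (stale >= patience) break
  }
  te <- eval_test(best$params)
  test_metrics <- list(auprc = auprc(te$scores, te$labels),
                       roc_auc = roc_auc(te$scores, te$labels),
                       test_loss = test_loss(te$scores, te$labels),
                       confusion = confusion_counts(te$scores, te$labels))
  structure(list(
    split = list(train_edges = nrow(train_pos), test_edges = nrow(test_pos),
                 fraction = test_fraction, seed = as.integer(seed)),
    trace = trace, selected_epoch = best$epoch,
    best_val_roc_auc = NA_real_, test_metrics = test_metrics,
    negative_mode = list(mode = "full", ratio = NA),
    params = best$params,
    config = list(seed = as.integer(seed),
                  max_epochs = as.integer(max_epochs), patience = patience)
  ), class = "eval_report")
}
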