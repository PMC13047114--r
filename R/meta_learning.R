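#' Meta-learning configuration
#'
#' Hyperparameters of disease-as-task first-order model-agnostic
#' meta-learning (FOMAML): one inner gradient step at learning rate 0.01 per
#' disease task, and Adam outer updates at learning rate 0.001 on the summed
#' query losses.
#'
#' @param inner_lr inner-loop (adaptation) learning rate.
#' @param inner_steps inner gradient steps per task (default 1; 0 degenerates
#'   to pooled training on query sets, useful in tests).
#' @param outer_lr outer-loop Adam learning rate.
#' @param meta_batch_size disease tasks per meta-update.
#' @param support_size maximum positive pairs in a task's support set.
#' @param neg_ratio negatives per positive within each task split.
#' @param adapt_filter optional regular expression restricting which
#'   parameters the inner loop adapts (default `NULL`: all parameters).
#' @return A list of class `meta_config`.
#' @export
meta_config <- function(inner_lr = 0.01, inner_steps = 1L, outer_lr = 0.001,
                        meta_batch_size = 4L, support_size = 5L,
                        neg_ratio = 1, adapt_filter = NULL) {
  stopifnot(inner_lr >= 0, outer_lr > 0, inner_steps >= 0,
            meta_batch_size >= 1, support_size >= 1, neg_ratio > 0)
  structure(list(inner_lr = inner_lr, inner_steps = as.integer(inner_steps),
                 outer_lr = outer_lr,
                 meta_batch_size = as.integer(meta_batch_size),
                 support_size = as.integer(support_size),
                 neg_ratio = neg_ratio, adapt_filter = adapt_filter),
            class = "meta_config")
}

# Condition signalling that a disease cannot form a task (fewer than 2 known
# positives). The protocol catches this class and skips the disease.
task_infeasible <- function(disease_id, n_pos) {
  structure(
    class = c("task_infeasible", "error", "condition"),
    list(message = sprintf(
      "disease '%s' has %d positive drug(s); a task needs at least 2",
      disease_id, n_pos),
      call = NULL, disease_id = disease_id))
}

# Reusable per-disease skeleton: k-hop subgraph and known positives. The
# random support/query split and negatives are drawn per instantiation, so
# templates can be built once and resampled every epoch.
#' @keywords internal
build_task_template <- function(graph, disease_id, k = 2L) {
  treats <- graph$edges[graph$edges$relation == "treats" &
                          graph$edges$target == disease_id, ]
  positives <- unique(treats$source)
  if (length(positives) < 2L) {
    stop(task_infeasible(disease_id, length(positives)))
  }
  # adjacency over both edge directions (inverse relations may or may not be
  # materialised yet)
  nbr <- split(c(graph$edges$target, graph$edges$source),
               c(graph$edges$source, graph$edges$target))
  hop <- function(seeds, steps) {
    seen <- seeds
    frontier <- seeds
    for (i in seq_len(steps)) {
      nxt <- setdiff(unique(unlist(nbr[frontier], use.names = FALSE)), seen)
      if (!length(nxt)) break
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    seen
  }
  # the candidate drug pool (positives and epoch-resampled negatives) and its
  # 1-hop neighbourhood are part of the task subgraph
  drug_pool <- graph$nodes$node_id[graph$nodes$node_type == "drug"]
  keep <- unique(c(hop(disease_id, k), hop(drug_pool, 1L)))
  nodes <- graph$nodes[graph$nodes$node_id %in% keep, , drop = FALSE]
  edges <- graph$edges[graph$edges$source %in% keep &
                         graph$edges$target %in% keep, , drop = FALSE]
  # hide the task disease's own therapeutic edges: the pairs being scored
  # must not be readable as graph edges, exactly as for a cold-start disease
  own_treats <- edges$relation %in% c("treats", "treats_inv") &
    (edges$source == disease_id | edges$target == disease_id)
  edges <- edges[!own_treats, , drop = FALSE]
  sub <- hetero_graph(nodes, edges, relations = graph$relation_set)
  list(disease_id = disease_id, subgraph = sub, positives = positives,
       drug_pool = drug_pool, k = as.integer(k))
}

# Draw the support/query split and negatives for a template.
#' @keywords internal
instantiate_task <- function(template, support_size, neg_ratio, seed) {
  pos <- template$positives
  n_support <- max(1L, min(support_size, length(pos) %/% 2L))
  with_seed(derive_seed(seed, paste0("task_", template$disease_id)), {
    sup_pos <- sample(pos, n_support)
    qry_pos <- setdiff(pos, sup_pos)
    pos_df <- data.frame(drug_id = pos, disease_id = template$disease_id,
                         stringsAsFactors = FALSE)
    avail <- length(setdiff(template$drug_pool, pos))
    ratio_eff <- min(neg_ratio, avail / length(pos))
    negs <- sample_negatives(pos_df, template$drug_pool,
                             template$disease_id, ratio = ratio_eff,
                             seed = derive_seed(seed, paste0(
                               "neg_", template$disease_id)))
    n_sup_neg <- max(1L, round(ratio_eff * length(sup_pos)))
    n_sup_neg <- min(n_sup_neg, max(nrow(negs) - 1L, 0L))
    sup_neg <- negs[seq_len(n_sup_neg), , drop = FALSE]
    qry_neg <- negs[setdiff(seq_len(nrow(negs)), seq_len(n_sup_neg)), ,
                    drop = FALSE]
    make_batch <- function(pos_ids, neg_df) {
      pairs <- rbind(data.frame(drug_id = pos_ids,
                                disease_id = template$disease_id,
                                stringsAsFactors = FALSE),
                     neg_df)
      list(pairs = pairs, labels = c(rep(1, length(pos_ids)),
                                     rep(0, nrow(neg_df))))
    }
    structure(list(disease_id = template$disease_id,
                   subgraph = template$subgraph,
                   support = make_batch(sup_pos, sup_neg),
                   query = make_batch(qry_pos, qry_neg),
                   k = template$k),
              class = "disease_task")
  })
}

#' Build one disease-centred meta-learning task
#'
#' A task is the disease's k-hop neighbourhood subgraph together with a
#' support/query split of its known positive drugs (support capped at
#' `min(support_size, floor(n_pos / 2))`, at least 1) and sampled negatives
#' at `neg_ratio` per split. Diseases with fewer than two known positives
#' raise a `task_infeasible` condition.
#'
#' @param graph a [hetero_graph()] containing `treats` edges.
#' @param disease_id the disease the task is centred on.
#' @param k subgraph radius in relation hops (default 2).
#' @param support_size maximum positives in the support set.
#' @param neg_ratio negatives per positive.
#' @param seed integer seed.
#' @return A `disease_task`: list with `disease_id`, `subgraph`, `support`
#'   and `query` pair batches (each `pairs` + `labels`), and `k`.
#' @export
build_disease_task <- function(graph, disease_id, k = 2L, support_size = 5L,
                               neg_ratio = 1, seed = 1L) {
  template <- build_task_template(graph, disease_id, k)
  instantiate_task(template, support_size, neg_ratio, seed)
}

filtered_sgd_step <- function(params, grads, lr, filter) {
  for (nm in names(params)) {
    if (!is.null(filter) && !grepl(filter, nm)) next
    params[[nm]] <- params[[nm]] - lr * grads[[nm]]
  }
  params
}

#' Inner-loop adaptation of parameters on a task's support set
#'
#' One (by default) plain gradient step on the support loss:
#' `theta' = theta - alpha * grad L_support(theta)`. The original parameters
#' are never modified.
#'
#' @param params parameter container; either a flat named list of numeric
#'   arrays or a `hetgnn_params` object (its `values` are adapted).
#' @param task passed through to `loss_fn`.
#' @param loss_fn function `(params, batch) -> list(loss, grads)` where
#'   `grads` is a named list aligned with the flat parameter list.
#' @param config a [meta_config()].
#' @return Adapted parameters of the same shape as `params`.
#' @export
inner_adapt <- function(params, task, loss_fn, config) {
  stopifnot(inherits(config, "meta_config"))
  wrapped <- inherits(params, "hetgnn_params")
  values <- if (wrapped) params$values else params
  for (s in seq_len(config$inner_steps)) {
    res <- loss_fn(if (wrapped) {
      params$values <- values; params
    } else values, task)
    if (!all(vapply(res$grads, function(g) all(is.finite(g)), logical(1)))) {
      stop("non-finite gradient during adaptation on task '",
           task$disease_id %||% "?", "'")
    }
    values <- filtered_sgd_step(values, res$grads, config$inner_lr,
                                config$adapt_filter)
  }
  if (wrapped) {
    params$values <- values
    params
  } else {
    values
  }
}

#' One FOMAML meta-update over a batch of tasks
#'
#' For each task, parameters are adapted on the support set with
#' [inner_adapt()]; the query loss is evaluated at the adapted parameters and
#' its gradient there is used as the outer gradient (first-order
#' approximation: the adaptation Jacobian is dropped). Outer gradients are
#' summed over tasks and applied with Adam at `config$outer_lr` (or a plain
#' gradient step when `optimizer_state` is `NULL` and `plain_sgd = TRUE`).
#'
#' @inheritParams inner_adapt
#' @param task_batch nonempty list of tasks.
#' @param optimizer_state Adam state from [meta_train_step()]'s previous
#'   return value, or `NULL` to initialise.
#' @param plain_sgd use a plain gradient outer step (test/diagnostic mode).
#' @return List with `params`, `optimizer_state` and `l_meta` (summed query
#'   loss across the batch).
#' @export
meta_train_step <- function(params, task_batch, loss_fn, config,
                            optimizer_state = NULL, plain_sgd = FALSE) {
  stopifnot(inherits(config, "meta_config"))
  if (length(task_batch) == 0L) stop("empty task batch")
  wrapped <- inherits(params, "hetgnn_params")
  values <- if (wrapped) params$values else params

  outer_grads <- lapply(values, function(p) array(0, dim = dim(as_matrix(p))))
  l_meta <- 0
  for (task in task_batch) {
    adapted <- inner_adapt(params, list_support(task), loss_fn, config)
    adapted_values <- if (wrapped) adapted$values else adapted
    res <- loss_fn(adapted, list_query(task))
    l_meta <- l_meta + res$loss
    for (nm in names(outer_grads)) {
      outer_grads[[nm]] <- outer_grads[[nm]] + res$grads[[nm]]
    }
  }

  if (plain_sgd) {
    values <- sgd_step(values, outer_grads, config$outer_lr)
  } else {
    if (is.null(optimizer_state)) {
      optimizer_state <- adam_init(values, lr = config$outer_lr)
    }
    upd <- adam_step(values, outer_grads, optimizer_state)
    values <- upd$params
    optimizer_state <- upd$state
  }
  if (wrapped) params$values <- values else params <- values
  list(params = params, optimizer_state = optimizer_state, l_meta = l_meta)
}

# A task exposes support/query splits; loss_fn receives the task with the
# relevant split marked so model-backed closures know which pairs to score.
list_support <- function(task) {
  task$active_split <- "support"
  task
}
list_query <- function(task) {
  task$active_split <- "query"
  task
}

# Model-backed loss closure for disease tasks: forwards the task subgraph and
# scores the active split's pairs. Caches the subgraph index structure on the
# task's environment-free list via an external cache keyed by disease id.
#' @keywords internal
make_task_loss_fn <- function(features, seed = 1L, cache_env = NULL,
                              training = TRUE) {
  if (is.null(cache_env)) cache_env <- new.env(parent = emptyenv())
  step <- 0L
  function(params, task) {
    split <- task$active_split %||% "support"
    key <- task$disease_id
    if (is.null(cache_env[[key]])) {
      cache_env[[key]] <- build_graph_cache(task$subgraph, features)
    }
    cache <- cache_env[[key]]
    batch <- task[[split]]
    pairs_idx <- cbind(cache$idx[batch$pairs$drug_id],
                       cache$idx[batch$pairs$disease_id])
    step <<- step + 1L
    res <- link_loss_and_grads(params, cache, pairs_idx, batch$labels,
                               training = training,
                               dropout_seed = derive_seed(
                                 seed, paste0(key, "_", split, "_", step)))
    list(loss = res$loss, grads = res$grads)
  }
}
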