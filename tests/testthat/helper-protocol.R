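# Shared cache of the expensive cold-start protocol runs. Several acceptance
# properties (planted-signal recovery, adaptation gain, the split-mode
# control) examine the same 20 trained models, so they are computed once per
# test session, on first use.

.protocol_cache <- new.env(parent = emptyenv())

desk_model_config <- function() {
  list(d_hidden = 32L, n_heads = 4L, n_layers = 3L)
}

cold_start_runs <- function(n_seeds = 20) {
  key <- sprintf("cs_%d", n_seeds)
  if (is.null(.protocol_cache[[key]])) {
    .protocol_cache[[key]] <- lapply(seq_len(n_seeds), function(sd) {
      cfg <- synthetic_config(seed = sd)
      kg <- generate_kg(cfg)
      feat <- generate_node_features(kg$graph, cfg)
      trained <- run_cold_start_protocol(
        kg$graph, feat, model_config = desk_model_config(), seed = sd)
      untrained <- run_cold_start_protocol(
        kg$graph, feat, model_config = desk_model_config(), seed = sd,
        skip_training = TRUE)
      list(seed = sd, config = cfg, kg = kg, features = feat,
           trained = trained, untrained = untrained)
    })
  }
  .protocol_cache[[key]]
}

# Rebuild the training graph the protocol used for one run (held-out treats
# removed, inverse relations added).
training_graph_of <- function(run) {
  g <- run$kg$graph
  held <- c(run$trained$split$val, run$trained$split$test)
  edges <- g$edges[!(g$edges$relation == "treats" &
                       g$edges$target %in% held), , drop = FALSE]
  add_inverse_relations(hetero_graph(g$nodes, edges,
                                     relations = g$relation_set))
}
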