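# Checkpoint serialization and the command-line entry point.

CHECKPOINT_FORMAT <- 1L

#' Save model parameters to a checkpoint file
#'
#' Serialises the full parameter container (all tensors, architecture
#' metadata including the relation vocabulary) together with a format-version
#' tag and an arbitrary run configuration. [load_checkpoint()] reproduces
#' every tensor bit-exactly.
#'
#' @param params a [hetgnn_params()] (or any parameter container with
#'   `values` and `meta`).
#' @param config list of run configuration to embed.
#' @param path output file path.
#' @export
save_checkpoint <- function(params, config, path) {
  saveRDS(list(format_version = CHECKPOINT_FORMAT,
               class = class(params),
               params = params,
               config = config),
          path)
  invisible(path)
}

#' Load model parameters from a checkpoint file
#'
#' Verifies the format-version tag (mismatches are errors, never silently
#' reinterpreted) and, when a graph is supplied, that every relation in the
#' graph is covered by the checkpoint's relation vocabulary.
#'
#' @param path checkpoint file written by [save_checkpoint()].
#' @param graph optional [hetero_graph()] to validate against.
#' @return List with `params` and `config`.
#' @export
load_checkpoint <- function(path, graph = NULL) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("corrupt or unreadable checkpoint: ", path)
  })
  if (!is.list(obj) || is.null(obj$format_version)) {
    stop("corrupt checkpoint (no format tag): ", path)
  }
  if (obj$format_version != CHECKPOINT_FORMAT) {
    stop(sprintf("checkpoint format version %s != supported %d",
                 obj$format_version, CHECKPOINT_FORMAT))
  }
  if (!is.null(graph) && !is.null(obj$params$meta$relations)) {
    unknown <- setdiff(unique(graph$edges$relation),
                       c(obj$params$meta$relations,
                         paste0(obj$params$meta$relations, "_inv")))
    if (length(unknown)) {
      stop("graph has relation(s) unknown to the checkpoint: ",
           paste(unknown, collapse = ", "))
    }
  }
  list(params = obj$params, config = obj$config)
}

# -- tiny flag parser: --key value pairs after the command word --------------
parse_flags <- function(argv) {
  flags <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i == length(argv) || startsWith(argv[i + 1L], "--")) {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      flags[[key]] <- argv[i + 1L]
      i <- i + 2L
    }
  }
  flags
}

flag_int <- function(flags, name, default) {
  as.integer(flags[[name]] %||% default)
}
flag_num <- function(flags, name, default) {
  as.numeric(flags[[name]] %||% default)
}

log_line <- function(stage, seed, ...) {
  message(sprintf("[%s seed=%s] %s", stage, seed, paste0(...)))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_feature_tables <- function(features, dir) {
  for (type in names(features)) {
    x <- features[[type]]$x
    df <- data.frame(node_id = rownames(x),
                     signif(x, 10), check.names = FALSE)
    colnames(df) <- c("node_id", sprintf("f%04d", seq_len(ncol(x))))
    write_tsv(df, file.path(dir, sprintf("features_%s.tsv", type)))
    m <- features[[type]]$mask
    mdf <- data.frame(node_id = rownames(x), m, check.names = FALSE)
    colnames(mdf) <- colnames(df)
    write_tsv(mdf, file.path(dir, sprintf("mask_%s.tsv", type)))
  }
}

read_feature_tables <- function(dir, binary_types = c(drug = TRUE,
                                                      gene = FALSE,
                                                      disease = FALSE,
                                                      pathway = TRUE)) {
  out <- list()
  for (f in list.files(dir, pattern = "^features_.*\\.tsv$")) {
    type <- sub("^features_(.*)\\.tsv$", "\\1", f)
    df <- utils::read.delim(file.path(dir, f), sep = "\t",
                            stringsAsFactors = FALSE)
    x <- as.matrix(df[, -1, drop = FALSE])
    rownames(x) <- df$node_id
    mdf <- utils::read.delim(file.path(dir, sub("features", "mask", f)),
                             sep = "\t", stringsAsFactors = FALSE)
    m <- as.matrix(mdf[, -1, drop = FALSE])
    rownames(m) <- mdf$node_id
    out[[type]] <- list(x = x, mask = m,
                        binary = isTRUE(binary_types[[type]]))
  }
  structure(out, class = "node_feature_set")
}

#' Command-line dispatcher
#'
#' Entry point behind the `inst/cli/hetgnn.R` script. Commands:
#' \describe{
#'   \item{generate}{write a synthetic knowledge graph + features to
#'     `--out` (`--seed`, optional `--n_drugs` etc.).}
#'   \item{train}{run the cold-start protocol on a generated directory
#'     (`--data`, `--out`, `--seed`, `--d_hidden`, `--max_epochs`).}
#'   \item{evaluate}{recompute test metrics from a checkpoint (`--data`,
#'     `--checkpoint`, `--out`).}
#'   \item{predict}{ranked candidate drugs for `--disease` (`--data`,
#'     `--checkpoint`, `--out`).}
#'   \item{synergy}{train the pair generator and write ranked combinations
#'     (`--data`, `--checkpoint`, `--disease`, `--out`).}
#'   \item{omics}{train the omics fusion head on synthetic omics and write
#'     the biomarker ranking (`--out`, `--seed`, `--effect_size`).}
#' }
#'
#' @param argv character vector of command-line arguments (command first).
#' @return Integer exit code (0 on success).
#' @export
cli_dispatch <- function(argv) {
  usage <- paste(
    "usage: hetgnn <command> [--flag value ...]",
    "commands: generate | train | evaluate | predict | synergy | omics",
    sep = "\n")
  if (length(argv) == 0L || argv[1] %in% c("-h", "--help", "help")) {
    message(usage)
    return(if (length(argv) == 0L) 2L else 0L)
  }
  cmd <- argv[1]
  if (!cmd %in% c("generate", "train", "evaluate", "predict", "synergy",
                  "omics")) {
    message("unknown command: ", cmd, "\n", usage)
    return(2L)
  }
  flags <- tryCatch(parse_flags(argv[-1]), error = function(e) e)
  if (inherits(flags, "error")) {
    message(conditionMessage(flags))
    return(1L)
  }
  res <- tryCatch({
    switch(cmd,
      generate = cli_generate(flags),
      train = cli_train(flags),
      evaluate = cli_evaluate(flags),
      predict = cli_predict(flags),
      synergy = cli_synergy(flags),
      omics = cli_omics(flags))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  res
}

cli_generate <- function(flags) {
  out <- flags$out %||% stop("--out directory required")
  seed <- flag_int(flags, "seed", 1L)
  cfg <- synthetic_config(
    n_drugs = flag_int(flags, "n_drugs", 50L),
    n_genes = flag_int(flags, "n_genes", 200L),
    n_diseases = flag_int(flags, "n_diseases", 10L),
    n_pathways = flag_int(flags, "n_pathways", 20L),
    fingerprint_bits = flag_int(flags, "fingerprint_bits", 1024L),
    gene_embed_dim = flag_int(flags, "gene_embed_dim", 128L),
    seed = seed)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_line("generate", seed, "building synthetic knowledge graph")
  kg <- generate_kg(cfg)
  features <- generate_node_features(kg$graph, cfg)
  write_graph(kg$graph, file.path(out, "nodes.tsv"),
              file.path(out, "edges.tsv"))
  write_feature_tables(features, out)
  write_tsv(kg$truth$treats_pairs, file.path(out, "truth_treats.tsv"))
  log_line("generate", seed, "wrote graph with ",
           nrow(kg$graph$edges), " edges to ", out)
  invisible(NULL)
}

cli_train <- function(flags) {
  data_dir <- flags$data %||% stop("--data directory required")
  out <- flags$out %||% stop("--out directory required")
  seed <- flag_int(flags, "seed", 1L)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  graph <- load_graph(file.path(data_dir, "nodes.tsv"),
                      file.path(data_dir, "edges.tsv"))
  features <- read_feature_tables(data_dir)
  model_config <- list(d_hidden = flag_int(flags, "d_hidden", 256L),
                       n_heads = flag_int(flags, "n_heads", 4L),
                       n_layers = flag_int(flags, "n_layers", 3L),
                       dropout = flag_num(flags, "dropout", 0.3))
  log_line("train", seed, "running cold-start protocol")
  report <- run_cold_start_protocol(
    graph, features, model_config = model_config,
    meta_cfg = meta_config(), seed = seed,
    max_epochs = flag_int(flags, "max_epochs", 100L),
    patience = flag_int(flags, "patience", 15L))
  save_checkpoint(report$params, report$config,
                  file.path(out, "checkpoint.rds"))
  write_tsv(report$trace, file.path(out, "trace.tsv"))
  write_eval_report(report, out)
  log_line("train", seed, sprintf("test ROC-AUC %.4f (epoch %d)",
                                  report$test_metrics$roc_auc,
                                  report$selected_epoch))
  invisible(NULL)
}

write_eval_report <- function(report, out) {
  km <- report$test_metrics
  kv <- data.frame(
    key = c("selected_epoch", "best_val_roc_auc", "test_roc_auc",
            "test_auprc", "test_loss", "TP", "TN", "FP", "FN",
            "negative_mode", "max_epochs", "seed"),
    value = c(report$selected_epoch,
              sprintf("%.6f", report$best_val_roc_auc),
              sprintf("%.6f", km$roc_auc), sprintf("%.6f", km$auprc),
              sprintf("%.6f", km$test_loss),
              km$confusion[["TP"]], km$confusion[["TN"]],
              km$confusion[["FP"]], km$confusion[["FN"]],
              report$negative_mode$mode, report$config$max_epochs,
              report$config$seed))
  write_tsv(kv, file.path(out, "metrics.tsv"))
  lines <- c(
    "cold-start evaluation report",
    sprintf("train/val/test diseases: %d/%d/%d",
            length(report$split$train), length(report$split$val),
            length(report$split$test)),
    sprintf("selected epoch: %d", report$selected_epoch),
    sprintf("test ROC-AUC: %.6f | AUPRC: %.6f | loss: %.6f",
            km$roc_auc, km$auprc, km$test_loss))
  writeLines(lines, file.path(out, "report.txt"))
}

cli_evaluate <- function(flags) {
  data_dir <- flags$data %||% stop("--data directory required")
  ckpt <- flags$checkpoint %||% stop("--checkpoint required")
  out <- flags$out %||% stop("--out directory required")
  seed <- flag_int(flags, "seed", 1L)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  graph <- load_graph(file.path(data_dir, "nodes.tsv"),
                      file.path(data_dir, "edges.tsv"))
  features <- read_feature_tables(data_dir)
  loaded <- load_checkpoint(ckpt, graph)
  log_line("evaluate", seed, "re-evaluating checkpoint")
  report <- run_cold_start_protocol(
    graph, features, seed = loaded$config$seed %||% seed,
    params = loaded$params, skip_training = TRUE)
  write_eval_report(report, out)
  invisible(NULL)
}

cli_predict <- function(flags) {
  data_dir <- flags$data %||% stop("--data directory required")
  ckpt <- flags$checkpoint %||% stop("--checkpoint required")
  out <- flags$out %||% stop("--out directory required")
  disease <- flags$disease %||% stop("--disease required")
  seed <- flag_int(flags, "seed", 1L)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  graph <- load_graph(file.path(data_dir, "nodes.tsv"),
                      file.path(data_dir, "edges.tsv"))
  features <- preprocess_features(read_feature_tables(data_dir))
  loaded <- load_checkpoint(ckpt, graph)
  g2 <- add_inverse_relations(graph)
  emb <- forward_encoder(g2, features, loaded$params)
  drugs <- graph$nodes$node_id[graph$nodes$node_type == "drug"]
  ranked <- rank_candidates(disease, drugs, emb)
  ranked$score <- sprintf("%.6f", ranked$score)
  ranked <- data.frame(disease_id = disease, ranked)
  write_tsv(ranked[, c("disease_id", "drug_id", "rank", "score")],
            file.path(out, "predictions.tsv"))
  log_line("predict", seed, "ranked ", length(drugs), " drugs for ", disease)
  invisible(NULL)
}

cli_synergy <- function(flags) {
  data_dir <- flags$data %||% stop("--data directory required")
  ckpt <- flags$checkpoint %||% stop("--checkpoint required")
  out <- flags$out %||% stop("--out directory required")
  disease <- flags$disease %||% stop("--disease required")
  seed <- flag_int(flags, "seed", 1L)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  graph <- load_graph(file.path(data_dir, "nodes.tsv"),
                      file.path(data_dir, "edges.tsv"))
  features <- preprocess_features(read_feature_tables(data_dir))
  loaded <- load_checkpoint(ckpt, graph)
  emb <- forward_encoder(add_inverse_relations(graph), features,
                         loaded$params)
  pairs <- synergy_training_pairs(graph, seed = seed)
  if (nrow(pairs) == 0L) stop("no drug pairs share a target in this graph")
  cv <- cvae_params(d = ncol(emb), seed = seed)
  log_line("synergy", seed, "training pair generator on ", nrow(pairs),
           " pairs")
  trained <- train_cvae(cv, pairs, emb,
                        steps = flag_int(flags, "steps", 200L), seed = seed)
  drugs <- graph$nodes$node_id[graph$nodes$node_type == "drug"]
  combos <- generate_combinations(disease,
                                  flag_int(flags, "n_samples", 100L),
                                  trained$params, drugs, emb, seed = seed)
  combos$synergy <- sprintf("%.6f", combos$synergy)
  write_tsv(combos[, c("disease_id", "drug_a", "drug_b", "synergy")],
            file.path(out, "combinations.tsv"))
  invisible(NULL)
}

cli_omics <- function(flags) {
  out <- flags$out %||% stop("--out directory required")
  seed <- flag_int(flags, "seed", 1L)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  om <- generate_omics(n_samples = flag_int(flags, "n_samples", 200L),
                       effect_size = flag_num(flags, "effect_size", 3),
                       seed = seed)
  log_line("omics", seed, "training fusion classifier")
  fit <- train_omics_fusion(om$modalities, om$labels,
                            steps = flag_int(flags, "steps", 300L),
                            seed = seed)
  ranking <- rank_biomarkers(om$modalities, fit$params)
  ranking$importance <- sprintf("%.6f", ranking$importance)
  write_tsv(ranking, file.path(out, "biomarkers.tsv"))
  write_tsv(data.frame(modality = seq_along(fit$mean_attention),
                       mean_attention = sprintf("%.6f",
                                                fit$mean_attention)),
            file.path(out, "attention.tsv"))
  invisible(NULL)
}
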