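#' Typed heterogeneous knowledge graphs
#'
#' A `hetero_graph` is the relational substrate of the package: typed nodes
#' (drugs, genes, diseases, pathways, ...) joined by directed, labelled edges,
#' each carrying a confidence in `[0, 1]`. Message passing, task construction
#' and evaluation all operate on this container.
#'
#' @param nodes data.frame with columns `node_id`, `node_type` and optionally
#'   `name`. Node ids must be unique.
#' @param edges data.frame with columns `source`, `relation`, `target` and
#'   optionally `confidence` (defaults to 1.0). Every endpoint must appear in
#'   `nodes`; duplicate `(source, relation, target)` triples and self-loops are
#'   rejected.
#' @param relations optional character vector of declared relation labels;
#'   labels appearing on edges are always included.
#' @return An object of class `hetero_graph` with components `nodes`, `edges`
#'   and `relation_set`.
#' @examples
#' g <- hetero_graph(
#'   nodes = data.frame(node_id = c("D1", "G1", "S1"),
#'                      node_type = c("drug", "gene", "disease")),
#'   edges = data.frame(source = c("D1", "G1"),
#'                      relation = c("drug_targets_gene",
#'                                   "gene_associates_disease"),
#'                      target = c("G1", "S1"))
#' )
#' graph_statistics(g)$total_edges
#' @export
hetero_graph <- function(nodes, edges, relations = NULL) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!all(c("node_id", "node_type") %in% names(nodes))) {
    stop("node table must have columns node_id and node_type")
  }
  nodes$node_id <- as.character(nodes$node_id)
  nodes$node_type <- as.character(nodes$node_type)
  if (is.null(nodes$name)) nodes$name <- nodes$node_id
  dup <- nodes$node_id[duplicated(nodes$node_id)]
  if (length(dup)) {
    stop("duplicate node id(s): ", paste(unique(dup), collapse = ", "))
  }

  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(source = character(), relation = character(),
                        target = character(), confidence = numeric(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!all(c("source", "relation", "target") %in% names(edges))) {
      stop("edge table must have columns source, relation, target")
    }
    edges$source <- as.character(edges$source)
    edges$relation <- as.character(edges$relation)
    edges$target <- as.character(edges$target)
    if (is.null(edges$confidence)) edges$confidence <- 1.0
    edges$confidence <- as.numeric(edges$confidence)
    edges <- edges[, c("source", "relation", "target", "confidence")]

    missing_src <- !(edges$source %in% nodes$node_id)
    missing_tgt <- !(edges$target %in% nodes$node_id)
    if (any(missing_src | missing_tgt)) {
      row <- which(missing_src | missing_tgt)[1]
      bad <- if (missing_src[row]) edges$source[row] else edges$target[row]
      stop(sprintf(
        "edge row %d references unknown node id '%s' (%s -[%s]-> %s)",
        row, bad, edges$source[row], edges$relation[row], edges$target[row]))
    }
    if (any(edges$source == edges$target)) {
      row <- which(edges$source == edges$target)[1]
      stop(sprintf("self-loop rejected at edge row %d (%s -[%s]-> %s)",
                   row, edges$source[row], edges$relation[row],
                   edges$target[row]))
    }
    key <- paste(edges$source, edges$relation, edges$target, sep = "\r")
    if (anyDuplicated(key)) {
      row <- which(duplicated(key))[1]
      stop(sprintf("duplicate edge triple at row %d (%s -[%s]-> %s)",
                   row, edges$source[row], edges$relation[row],
                   edges$target[row]))
    }
    if (any(edges$confidence < 0 | edges$confidence > 1)) {
      stop("edge confidence must lie in [0, 1]")
    }
  }

  relation_set <- union(unique(edges$relation), relations %||% character())
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(
    list(nodes = nodes[, c("node_id", "node_type", "name")],
         edges = edges,
         relation_set = relation_set),
    class = "hetero_graph"
  )
}

#' @export
print.hetero_graph <- function(x, ...) {
  tab <- table(x$nodes$node_type)
  cat(sprintf("<hetero_graph> %d nodes (%s), %d edges, %d relation types\n",
              nrow(x$nodes),
              paste(sprintf("%s: %d", names(tab), as.integer(tab)),
                    collapse = ", "),
              nrow(x$edges), length(x$relation_set)))
  invisible(x)
}

#' Read a heterogeneous graph from node and edge tables
#'
#' Both tables are UTF-8 tab-separated text with a header row. The node table
#' has columns `node_id`, `node_type`, `name`; the edge table has `source`,
#' `relation`, `target` and optionally `confidence` (assumed 1.0 when the
#' column is absent).
#'
#' @param node_table_path,edge_table_path paths to the TSV files.
#' @return A [hetero_graph()].
#' @export
load_graph <- function(node_table_path, edge_table_path) {
  nodes <- utils::read.delim(node_table_path, sep = "\t", quote = "",
                             stringsAsFactors = FALSE,
                             colClasses = "character")
  edges <- utils::read.delim(edge_table_path, sep = "\t", quote = "",
                             stringsAsFactors = FALSE)
  hetero_graph(nodes, edges)
}

#' Write a heterogeneous graph to node and edge tables
#'
#' Inverse of [load_graph()]: `load_graph()` on the written files reproduces
#' the graph exactly. Confidence values are printed in full precision.
#'
#' @param graph a [hetero_graph()].
#' @param node_table_path,edge_table_path output paths.
#' @export
write_graph <- function(graph, node_table_path, edge_table_path) {
  stopifnot(inherits(graph, "hetero_graph"))
  utils::write.table(graph$nodes, node_table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  edges <- graph$edges
  edges$confidence <- format(edges$confidence, digits = 17, trim = TRUE,
                             scientific = FALSE)
  utils::write.table(edges, edge_table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Summary statistics of a heterogeneous graph
#'
#' Density treats stored edges as directed:
#' `total_edges / (total_nodes * (total_nodes - 1))`. Graphs with fewer than
#' two nodes report density 0 with a warning flag.
#'
#' @param graph a [hetero_graph()].
#' @return A list with `node_count_by_type`, `edge_count_by_relation`,
#'   `total_nodes`, `total_edges`, `density`, `degree_by_type` (total degree,
#'   in + out, of each node grouped by type) and `degenerate` (TRUE when the
#'   density denominator is empty).
#' @export
graph_statistics <- function(graph) {
  stopifnot(inherits(graph, "hetero_graph"))
  n <- nrow(graph$nodes)
  m <- nrow(graph$edges)
  degenerate <- n < 2L
  density <- if (degenerate) 0 else m / (n * (n - 1))
  if (degenerate) {
    warning("graph has fewer than 2 nodes; density reported as 0")
  }
  deg <- table(factor(c(graph$edges$source, graph$edges$target),
                      levels = graph$nodes$node_id))
  list(
    node_count_by_type = as.list(table(graph$nodes$node_type)),
    edge_count_by_relation =
      as.list(table(factor(graph$edges$relation,
                           levels = graph$relation_set))),
    total_nodes = n,
    total_edges = m,
    density = density,
    degree_by_type = split(as.integer(deg), graph$nodes$node_type),
    degenerate = degenerate
  )
}

#' Merge the highest-confidence candidate edges into a graph
#'
#' Mirrors confidence-ranked enrichment from literature mining: the `top_k`
#' candidates by descending confidence (ties broken lexicographically on
#' `(source, relation, target)`) are merged into the graph. Candidates that
#' duplicate existing triples are skipped, so the operation is idempotent; the
#' input graph is never modified.
#'
#' @param graph a [hetero_graph()].
#' @param candidate_edges data.frame with columns `source`, `relation`,
#'   `target`, `confidence`; all endpoints must exist in `graph`.
#' @param top_k number of top-ranked candidates to merge (default 10000).
#' @return A new [hetero_graph()].
#' @export
augment_with_confidence_edges <- function(graph, candidate_edges,
                                          top_k = 10000L) {
  stopifnot(inherits(graph, "hetero_graph"), top_k >= 0)
  cand <- as.data.frame(candidate_edges, stringsAsFactors = FALSE)
  if (nrow(cand) == 0L || top_k == 0L) return(graph)
  cand$source <- as.character(cand$source)
  cand$relation <- as.character(cand$relation)
  cand$target <- as.character(cand$target)
  if (is.null(cand$confidence)) cand$confidence <- 1.0
  unknown <- setdiff(c(cand$source, cand$target), graph$nodes$node_id)
  if (length(unknown)) {
    stop("candidate edge endpoint(s) not in graph: ",
         paste(unknown, collapse = ", "))
  }
  ord <- order(-cand$confidence, cand$source, cand$relation, cand$target)
  keep <- cand[ord, ][seq_len(min(top_k, nrow(cand))), , drop = FALSE]
  existing <- paste(graph$edges$source, graph$edges$relation,
                    graph$edges$target, sep = "\r")
  keep_key <- paste(keep$source, keep$relation, keep$target, sep = "\r")
  keep <- keep[!(keep_key %in% existing) & !duplicated(keep_key), ,
               drop = FALSE]
  edges <- rbind(graph$edges,
                 keep[, c("source", "relation", "target", "confidence")])
  hetero_graph(graph$nodes, edges, relations = graph$relation_set)
}

#' Add explicit inverse relations
#'
#' Stored edges are directed; message passing needs both directions, so for
#' every edge `(u, r, v)` an edge `(v, r_inv, u)` is added. The suffix `_inv`
#' is reserved: calling this on a graph that already contains it is an error,
#' which also makes accidental double application impossible.
#'
#' @param graph a [hetero_graph()].
#' @return A new [hetero_graph()] with twice the edges (for duplicate-free
#'   input).
#' @export
add_inverse_relations <- function(graph) {
  stopifnot(inherits(graph, "hetero_graph"))
  if (any(endsWith(graph$relation_set, "_inv"))) {
    stop("relation label(s) already use the reserved suffix '_inv'")
  }
  if (nrow(graph$edges) == 0L) {
    return(hetero_graph(graph$nodes, graph$edges,
                        relations = graph$relation_set))
  }
  inv <- data.frame(source = graph$edges$target,
                    relation = paste0(graph$edges$relation, "_inv"),
                    target = graph$edges$source,
                    confidence = graph$edges$confidence,
                    stringsAsFactors = FALSE)
  hetero_graph(graph$nodes, rbind(graph$edges, inv),
               relations = c(graph$relation_set,
                             paste0(graph$relation_set, "_inv")))
}
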