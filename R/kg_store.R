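#' @importFrom stats density predict quantile runif sd setNames uniroot
#' @importFrom utils read.delim write.table head
NULL

# Internal constructor: validates node/edge tables and builds the canonical
# undirected simple-graph representation used by all traversal code.
#
# Conventions:
#  * edges are undirected; each is stored once with source_id <= target_id
#  * parallel edges with identical (pair, relation_type) are collapsed
#  * self-loops are dropped (with a message reporting the count)
kg_new <- function(nodes, edges) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  nodes$node_id <- as.character(nodes$node_id)
  nodes$node_type <- as.character(nodes$node_type)
  if (is.null(nodes$display_name)) nodes$display_name <- nodes$node_id
  nodes$display_name <- as.character(nodes$display_name)

  if (anyNA(nodes$node_id) || any(nodes$node_id == "")) {
    stop("node table contains missing/empty node_id values")
  }
  dup <- duplicated(nodes$node_id)
  if (any(dup)) {
    # duplicates allowed only when fully consistent in type
    chk <- tapply(nodes$node_type, nodes$node_id, function(t) length(unique(t)))
    bad <- names(chk)[chk > 1L]
    if (length(bad)) {
      stop("conflicting node_type for node(s): ", paste(head(bad, 5L), collapse = ", "))
    }
    nodes <- nodes[!dup, , drop = FALSE]
  }
  nodes <- nodes[order(nodes$node_id), c("node_id", "node_type", "display_name")]
  rownames(nodes) <- NULL

  edges$source_id <- as.character(edges$source_id)
  edges$target_id <- as.character(edges$target_id)
  edges$relation_type <- as.character(edges$relation_type)

  known <- nodes$node_id
  miss <- setdiff(c(edges$source_id, edges$target_id), known)
  if (length(miss)) {
    stop("edge endpoint(s) absent from node registry: ",
         paste(head(miss, 5L), collapse = ", "))
  }

  loops <- edges$source_id == edges$target_id
  if (any(loops)) {
    message("dropping ", sum(loops), " self-loop edge(s)")
    edges <- edges[!loops, , drop = FALSE]
  }

  # canonical unordered pair, then collapse duplicates per relation_type
  a <- pmin(edges$source_id, edges$target_id)
  b <- pmax(edges$source_id, edges$target_id)
  edges <- data.frame(source_id = a, target_id = b,
                      relation_type = edges$relation_type,
                      stringsAsFactors = FALSE)
  edges <- unique(edges)
  edges <- edges[order(edges$source_id, edges$target_id, edges$relation_type), ,
                 drop = FALSE]
  rownames(edges) <- NULL

  structure(
    list(nodes = nodes, edges = edges),
    class = "knowledge_graph"
  )
}

#' Load a typed knowledge graph from edge/node tables
#'
#' Reads a heterogeneous knowledge graph from a typed edge-list TSV with
#' columns `source_id`, `source_type`, `relation_type`, `target_id`,
#' `target_type`, plus an optional node TSV (`node_id`, `node_type`,
#' optionally `display_name`) supplying isolated nodes and display names.
#' Edges are treated as undirected; parallel edges with the same relation
#' type are collapsed and self-loops dropped.
#'
#' @param edge_table Path to the edge-list TSV (header row required).
#' @param node_table Optional path to a node TSV.
#' @return A `knowledge_graph` object.
#' @export
kg_load <- function(edge_table, node_table = NULL) {
  ed <- tryCatch(
    read.delim(edge_table, stringsAsFactors = FALSE, colClasses = "character",
               fileEncoding = "UTF-8"),
    error = function(e) stop("failed to parse edge table '", edge_table, "': ",
                             conditionMessage(e))
  )
  need <- c("source_id", "source_type", "relation_type", "target_id", "target_type")
  if (!all(need %in% names(ed))) {
    stop("edge table must have columns: ", paste(need, collapse = ", "))
  }
  bad <- which(is.na(ed$source_id) | ed$source_id == "" |
               is.na(ed$target_id) | ed$target_id == "")
  if (length(bad)) {
    stop("malformed edge row at line ", bad[1L] + 1L, " (missing endpoint id)")
  }

  nodes <- data.frame(
    node_id = c(ed$source_id, ed$target_id),
    node_type = c(ed$source_type, ed$target_type),
    stringsAsFactors = FALSE
  )
  nodes$display_name <- nodes$node_id

  if (!is.null(node_table)) {
    nd <- read.delim(node_table, stringsAsFactors = FALSE,
                     colClasses = "character", fileEncoding = "UTF-8")
    if (!all(c("node_id", "node_type") %in% names(nd))) {
      stop("node table must have columns node_id, node_type")
    }
    if (is.null(nd$display_name)) nd$display_name <- nd$node_id
    # node-table rows take precedence for display names
    nodes <- rbind(nd[, c("node_id", "node_type", "display_name")], nodes)
  }

  # detect type conflicts across rows before deduplication
  ntypes <- tapply(nodes$node_type, nodes$node_id, function(t) length(unique(t)))
  conflict <- names(ntypes)[ntypes > 1L]
  if (length(conflict)) {
    stop("node(s) assigned conflicting node_type across rows: ",
         paste(head(conflict, 5L), collapse = ", "))
  }
  nodes <- nodes[!duplicated(nodes$node_id), , drop = FALSE]

  kg <- kg_new(nodes, ed[, c("source_id", "target_id", "relation_type")])
  message("loaded graph: ", nrow(kg$nodes), " nodes, ", nrow(kg$edges), " edges")
  kg
}

#' Save a knowledge graph to edge/node TSVs
#'
#' Writes the same TSV dialect `kg_load()` reads, including header rows, so
#' that `kg_load(edge_table, node_table)` round-trips the graph exactly.
#'
#' @param kg A `knowledge_graph`.
#' @param edge_table Output path for the edge TSV.
#' @param node_table Output path for the node TSV.
#' @return Invisibly, the paths written.
#' @export
kg_save <- function(kg, edge_table, node_table) {
  stopifnot(inherits(kg, "knowledge_graph"))
  tmap <- kg_type_map(kg)
  ed <- data.frame(
    source_id = kg$edges$source_id,
    source_type = unname(tmap[kg$edges$source_id]),
    relation_type = kg$edges$relation_type,
    target_id = kg$edges$target_id,
    target_type = unname(tmap[kg$edges$target_id]),
    stringsAsFactors = FALSE
  )
  write.table(ed, edge_table, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  write.table(kg$nodes, node_table, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(c(edge_table, node_table))
}

# named vector node_id -> node_type
kg_type_map <- function(kg) {
  setNames(kg$nodes$node_type, kg$nodes$node_id)
}

#' Number of nodes / edges
#' @param kg A `knowledge_graph`.
#' @return Integer count.
#' @export
kg_n_nodes <- function(kg) nrow(kg$nodes)

#' @rdname kg_n_nodes
#' @export
kg_n_edges <- function(kg) nrow(kg$edges)

#' @export
print.knowledge_graph <- function(x, ...) {
  tt <- table(x$nodes$node_type)
  cat("<knowledge_graph> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " undirected edges\n", sep = "")
  cat("  node types: ",
      paste(sprintf("%s (%d)", names(tt), as.integer(tt)), collapse = ", "),
      "\n", sep = "")
  cat("  relation types: ", length(unique(x$edges$relation_type)), "\n", sep = "")
  invisible(x)
}

#' Type-filter a knowledge graph
#'
#' Returns the induced subgraph on nodes of the kept types; only edges whose
#' two endpoints both survive (and, if `keep_relation_types` is given, whose
#' relation type is kept) are retained. This is the condensation step that
#' reduces a large heterogeneous graph to the node types a metapath analysis
#' actually touches.
#'
#' @param kg A `knowledge_graph`.
#' @param keep_node_types Non-empty character vector of node types to keep.
#' @param keep_relation_types Optional character vector of relation types.
#' @return A new `knowledge_graph`; the input is unmodified.
#' @export
kg_subset <- function(kg, keep_node_types, keep_relation_types = NULL) {
  stopifnot(inherits(kg, "knowledge_graph"))
  if (length(keep_node_types) == 0L) stop("keep_node_types must be non-empty")
  if (!any(keep_node_types %in% kg$nodes$node_type)) {
    warning("keep_node_types share no types with the graph; returning empty graph")
  }
  nodes <- kg$nodes[kg$nodes$node_type %in% keep_node_types, , drop = FALSE]
  keep_ids <- nodes$node_id
  ed <- kg$edges
  ok <- ed$source_id %in% keep_ids & ed$target_id %in% keep_ids
  if (!is.null(keep_relation_types)) {
    ok <- ok & ed$relation_type %in% keep_relation_types
  }
  out <- kg_new(nodes, ed[ok, , drop = FALSE])
  message("subset graph: ", nrow(out$nodes), " nodes, ", nrow(out$edges), " edges")
  out
}

# Symmetrized half-edge table (from, to), pairs seen once per direction
# regardless of how many relation types connect them.
kg_half_edges <- function(kg) {
  pr <- unique(kg$edges[, c("source_id", "target_id")])
  data.frame(from = c(pr$source_id, pr$target_id),
             to = c(pr$target_id, pr$source_id),
             stringsAsFactors = FALSE)
}

# Vectorized one-hop step: all (from, to) half-edges with from in `ids` and
# to of node type `type`. Backbone of the metapath queries.
kg_step <- function(kg, ids, type) {
  he <- kg_half_edges(kg)
  tmap <- kg_type_map(kg)
  he <- he[he$from %in% ids, , drop = FALSE]
  he[tmap[he$to] == type, , drop = FALSE]
}

#' Typed neighborhood lookup
#'
#' All nodes of a given type adjacent to `node_id` via any relation type,
#' returned sorted lexicographically.
#'
#' @param kg A `knowledge_graph`.
#' @param node_id Node identifier (must exist in the graph).
#' @param neighbor_type Node type to restrict neighbors to.
#' @return Sorted character vector of neighbor node ids.
#' @export
kg_neighbors <- function(kg, node_id, neighbor_type) {
  stopifnot(inherits(kg, "knowledge_graph"), length(node_id) == 1L)
  if (!node_id %in% kg$nodes$node_id) {
    stop("unknown node_id: ", node_id)
  }
  sort(unique(kg_step(kg, node_id, neighbor_type)$to))
}
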