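# Brute-force oracles and random fixtures shared across test files.
# The oracles work directly on flat edge tuples and never touch the
# package's adjacency machinery, so they stay independent of the code
# they check.

# random typed graph as a raw edge data.frame (possibly with duplicate
# and self edges, which kg_new is expected to clean up)
random_typed_edges <- function(n_nodes = 30, n_edges = 60,
                               types = c("Disease", "Compound", "Gene", "EFO"),
                               seed = 1) {
  set.seed(seed)
  ids <- sprintf("N%03d", seq_len(n_nodes))
  ntype <- sample(types, n_nodes, replace = TRUE)
  nodes <- data.frame(node_id = ids, node_type = ntype,
                      display_name = ids, stringsAsFactors = FALSE)
  src <- sample(ids, n_edges, replace = TRUE)
  dst <- sample(ids, n_edges, replace = TRUE)
  rel <- sample(c("rel_a", "rel_b"), n_edges, replace = TRUE)
  list(nodes = nodes,
       edges = data.frame(source_id = src, target_id = dst,
                          relation_type = rel, stringsAsFactors = FALSE))
}

# undirected simple pairs (a < b) from a raw edge table, self-loops dropped
oracle_pairs <- function(edges) {
  a <- pmin(edges$source_id, edges$target_id)
  b <- pmax(edges$source_id, edges$target_id)
  keep <- a != b
  unique(data.frame(a = a[keep], b = b[keep], stringsAsFactors = FALSE))
}

oracle_neighbors <- function(nodes, edges, node, type) {
  pr <- oracle_pairs(edges)
  nb <- c(pr$b[pr$a == node], pr$a[pr$b == node])
  tmap <- setNames(nodes$node_type, nodes$node_id)
  sort(unique(nb[tmap[nb] == type]))
}

# all genes reachable from any listed disease by a 2-path through a compound
oracle_positive_genes <- function(nodes, edges, cuis,
                                  types = list(compound = "Compound",
                                               gene = "Gene")) {
  hits <- character(0)
  for (d in cuis) {
    for (cmp in oracle_neighbors(nodes, edges, d, types$compound)) {
      hits <- c(hits, oracle_neighbors(nodes, edges, cmp, types$gene))
    }
  }
  sort(unique(hits))
}

oracle_unlabeled_genes <- function(nodes, edges, positives,
                                   types = list(term = "EFO", gene = "Gene")) {
  hits <- character(0)
  for (g in positives) {
    for (e in oracle_neighbors(nodes, edges, g, types$term)) {
      hits <- c(hits, oracle_neighbors(nodes, edges, e, types$gene))
    }
  }
  sort(setdiff(unique(hits), positives))
}

oracle_feature_terms <- function(nodes, edges, positives, unlabeled,
                                 term_type = "EFO") {
  terms <- nodes$node_id[nodes$node_type == term_type]
  keep <- vapply(terms, function(e) {
    pr <- oracle_pairs(edges)
    nb <- c(pr$b[pr$a == e], pr$a[pr$b == e])
    any(nb %in% positives) && any(nb %in% unlabeled)
  }, logical(1L))
  sort(terms[keep])
}

# dense 0/1 adjacency restricted to selected rows/columns
oracle_feature_matrix <- function(edges, row_ids, col_ids) {
  pr <- oracle_pairs(edges)
  M <- matrix(0L, length(row_ids), length(col_ids),
              dimnames = list(row_ids, col_ids))
  for (i in seq_len(nrow(pr))) {
    a <- pr$a[i]; b <- pr$b[i]
    if (a %in% row_ids && b %in% col_ids) M[a, b] <- 1L
    if (b %in% row_ids && a %in% col_ids) M[b, a] <- 1L
  }
  M
}

# helper: build a knowledge_graph from inline node/edge specs
toy_kg <- function(node_spec, edge_spec) {
  nodes <- data.frame(
    node_id = names(node_spec),
    node_type = unname(unlist(node_spec)),
    display_name = names(node_spec), stringsAsFactors = FALSE)
  edges <- data.frame(
    source_id = vapply(edge_spec, `[[`, "", 1L),
    target_id = vapply(edge_spec, `[[`, "", 2L),
    relation_type = "rel", stringsAsFactors = FALSE)
  kg_from_tables(nodes, edges)
}

# route through the public TSV loader so tests exercise the real surface
kg_from_tables <- function(nodes, edges) {
  tmap <- setNames(nodes$node_type, nodes$node_id)
  ed <- data.frame(source_id = edges$source_id,
                   source_type = unname(tmap[edges$source_id]),
                   relation_type = edges$relation_type,
                   target_id = edges$target_id,
                   target_type = unname(tmap[edges$target_id]),
                   stringsAsFactors = FALSE)
  ef <- tempfile(fileext = ".tsv"); nf <- tempfile(fileext = ".tsv")
  write.table(ed, ef, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(nodes, nf, sep = "\t", quote = FALSE, row.names = FALSE)
  suppressMessages(kg_load(ef, nf))
}

# small, fast PU dataset built straight from score-friendly features
small_pu_dataset <- function(n_pos = 60, n_unl = 120, n_feat = 20,
                             p_pos = 0.6, p_neg = 0.1, hidden_frac = 0,
                             seed = 1) {
  set.seed(seed)
  n <- n_pos + n_unl
  n_hidden <- round(hidden_frac * n_unl)
  is_pos_law <- c(rep(TRUE, n_pos), rep(TRUE, n_hidden),
                  rep(FALSE, n_unl - n_hidden))
  p <- ifelse(is_pos_law, p_pos, p_neg)
  M <- matrix(rbinom(n * n_feat, 1, rep(p, n_feat)), nrow = n)
  ids <- sprintf("G%04d", seq_len(n))
  X <- methods::as(methods::as(Matrix::Matrix(M, sparse = TRUE),
                               "generalMatrix"), "RsparseMatrix")
  dimnames(X) <- list(ids, sprintf("E%03d", seq_len(n_feat)))
  structure(list(X = X, y = c(rep(1L, n_pos), rep(0L, n_unl)),
                 row_ids = ids, col_ids = colnames(X)),
            class = "pu_dataset")
}

fast_learner <- list(nrounds = 30L)
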