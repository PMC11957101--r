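#' Specification for a synthetic PU knowledge graph
#'
#' Describes a synthetic heterogeneous graph with a planted,
#' SCAR-consistent class prior. Among `n_genes` genes, a subset are true
#' disease-associated genes; a fraction `label_fraction` of them (drawn
#' uniformly at random, so the SCAR assumption holds by construction) are
#' "labeled" by wiring a Disease-Compound-Gene path; the rest stay hidden
#' in the unlabeled pool, where they make up a fraction `alpha_true`.
#' Feature signal is carried by gene--ontology-term edges drawn
#' Bernoulli(`p_feature_pos`) per term for true positives and
#' Bernoulli(`p_feature_neg`) for negatives.
#'
#' @param n_genes,n_terms Number of gene and ontology-term nodes.
#' @param alpha_true Planted fraction of hidden positives among the
#'   unlabeled pool, in \[0, 1\].
#' @param label_fraction Fraction of true positives that get labeled,
#'   in (0, 1\].
#' @param p_feature_pos,p_feature_neg Per-term edge probabilities for
#'   positive-class and negative-class genes (`p_feature_neg <
#'   p_feature_pos`).
#' @param n_diseases Number of disease nodes; positives are split across
#'   them round-robin.
#' @param seed Integer seed; the whole graph is deterministic given it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 3000, n_terms = 200, alpha_true = 0.3,
                           label_fraction = 0.625, p_feature_pos = 0.3,
                           p_feature_neg = 0.05, n_diseases = 1, seed = 1) {
  stopifnot(alpha_true >= 0, alpha_true <= 1,
            label_fraction > 0, label_fraction <= 1,
            p_feature_neg >= 0, p_feature_neg < p_feature_pos,
            p_feature_pos <= 1,
            n_genes >= 2, n_terms >= 1, n_diseases >= 1)
  structure(list(n_genes = as.integer(n_genes), n_terms = as.integer(n_terms),
                 alpha_true = alpha_true, label_fraction = label_fraction,
                 p_feature_pos = p_feature_pos, p_feature_neg = p_feature_neg,
                 n_diseases = as.integer(n_diseases), seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Synthetic spec from target labeled/unlabeled pool sizes
#'
#' Convenience constructor: solves for `n_genes` and `label_fraction` so
#' that the generated graph has `n_labeled` labeled positives and
#' `n_unlabeled` unlabeled genes of which a fraction `alpha_true` are
#' hidden positives.
#'
#' @param n_labeled,n_unlabeled Target pool sizes.
#' @param alpha_true Planted class prior among the unlabeled pool.
#' @param ... Passed to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
synthetic_spec_counts <- function(n_labeled, n_unlabeled, alpha_true, ...) {
  n_hidden <- round(alpha_true * n_unlabeled)
  synthetic_spec(n_genes = n_labeled + n_unlabeled,
                 alpha_true = alpha_true,
                 label_fraction = n_labeled / (n_labeled + n_hidden),
                 ...)
}

#' Generate a synthetic knowledge graph with planted hidden positives
#'
#' Builds the typed graph described by a [synthetic_spec()]:
#' * true-positive genes are chosen so hidden positives form `alpha_true`
#'   of the eventual unlabeled pool;
#' * labeled positives are a uniform random subsample of the true
#'   positives (SCAR by construction), each wired through its own compound
#'   node to a disease node;
#' * every gene gets gene-term edges by per-term Bernoulli draws at the
#'   class-specific rate;
#' * any unlabeled gene left without a term shared with a labeled positive
#'   is re-wired to one such term, so the Gene-term-Gene candidate query
#'   reaches the whole pool.
#'
#' @param spec A `synthetic_spec`.
#' @return A list with elements `kg` (the `knowledge_graph`) and `truth`
#'   (class `synthetic_truth`: `true_positive_genes`,
#'   `labeled_positive_genes`, `hidden_positive_genes`, `realized_alpha`).
#' @export
generate_synthetic_kg <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  f <- spec$label_fraction
  a <- spec$alpha_true

  # L labeled, H hidden, pool U = n - L, with H/U = a and L/(L+H) = f:
  # L = f*a*n / (1 - f*(1 - a)); a = 0 degenerates to H = 0, L = f*n... but
  # with no hidden positives any L is consistent; take L from the same
  # formula's limit (L = 0) unless f = 1, where all positives are labeled.
  if (a == 0) {
    n_lab <- max(1L, round(f * n / 2))  # pool must keep both classes
    n_hid <- 0L
  } else {
    n_lab <- round(f * a * n / (1 - f * (1 - a)))
    n_hid <- round(a * (n - n_lab))
    if (n_hid < 1L) stop("infeasible spec: alpha_true > 0 but no hidden ",
                         "positive can be realized at this n_genes")
  }
  if (n_lab + n_hid > n) stop("infeasible spec: more positives than genes")
  if (n_lab < 1L) stop("infeasible spec: no labeled positive can be realized")

  width <- max(4L, nchar(as.character(n)))
  genes <- sprintf("G%0*d", width, seq_len(n))
  terms <- sprintf("E%04d", seq_len(spec$n_terms))
  diseases <- sprintf("DIS%02d", seq_len(spec$n_diseases))

  true_pos <- sort(sample(genes, n_lab + n_hid))
  labeled <- sort(sample(true_pos, n_lab))
  hidden <- setdiff(true_pos, labeled)
  unlabeled_pool <- setdiff(genes, labeled)

  # Disease-Compound-Gene wiring: one compound per labeled positive (star)
  compounds <- sprintf("C%0*d", width, seq_along(labeled))
  dis_for <- diseases[((seq_along(labeled) - 1L) %% spec$n_diseases) + 1L]
  edges_dc <- data.frame(source_id = dis_for, target_id = compounds,
                         relation_type = "associated_with")
  edges_cg <- data.frame(source_id = compounds, target_id = labeled,
                         relation_type = "targets")

  # Gene-term edges: class-dependent Bernoulli per (gene, term)
  is_pos <- genes %in% true_pos
  p <- ifelse(is_pos, spec$p_feature_pos, spec$p_feature_neg)
  draws <- matrix(runif(n * spec$n_terms) < rep(p, times = spec$n_terms),
                  nrow = n)
  idx <- which(draws, arr.ind = TRUE)
  edges_gt <- data.frame(source_id = genes[idx[, 1L]],
                         target_id = terms[idx[, 2L]],
                         relation_type = "annotated_with")

  # guarantee: every unlabeled gene shares >= 1 term with a labeled positive
  lab_terms <- unique(edges_gt$target_id[edges_gt$source_id %in% labeled])
  if (length(lab_terms) == 0L) {
    lab_terms <- sample(terms, 1L)
    edges_gt <- rbind(edges_gt, data.frame(source_id = labeled[1L],
                                           target_id = lab_terms,
                                           relation_type = "annotated_with"))
  }
  bridged <- unique(edges_gt$source_id[edges_gt$target_id %in% lab_terms])
  orphan <- setdiff(unlabeled_pool, bridged)
  if (length(orphan)) {
    message("re-wiring ", length(orphan),
            " unlabeled gene(s) to a labeled-positive term")
    extra <- data.frame(source_id = orphan,
                        target_id = sample(lab_terms, length(orphan),
                                           replace = TRUE),
                        relation_type = "annotated_with")
    edges_gt <- rbind(edges_gt, extra)
  }

  nodes <- data.frame(
    node_id = c(diseases, compounds, genes, terms),
    node_type = c(rep("Disease", length(diseases)),
                  rep("Compound", length(compounds)),
                  rep("Gene", n), rep("EFO", length(terms))),
    display_name = c(diseases, compounds, genes, terms)
  )
  kg <- kg_new(nodes, rbind(edges_dc, edges_cg, edges_gt))

  truth <- structure(
    list(true_positive_genes = true_pos,
         labeled_positive_genes = labeled,
         hidden_positive_genes = hidden,
         disease_cuis = diseases,
         realized_alpha = length(hidden) / length(unlabeled_pool)),
    class = "synthetic_truth"
  )
  list(kg = kg, truth = truth)
}

#' Write a synthetic graph as a reusable fixture
#'
#' Emits the graph in the TSV dialect [kg_load()] reads, plus a truth table
#' (`gene_id`, `true_class`, `labeled_flag`).
#'
#' @param spec A `synthetic_spec`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the three file paths.
#' @export
emit_fixture <- function(spec, dir) {
  sim <- generate_synthetic_kg(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edge_path <- file.path(dir, "edges.tsv")
  node_path <- file.path(dir, "nodes.tsv")
  truth_path <- file.path(dir, "truth.tsv")
  kg_save(sim$kg, edge_path, node_path)
  genes <- sim$kg$nodes$node_id[sim$kg$nodes$node_type == "Gene"]
  truth <- data.frame(
    gene_id = genes,
    true_class = as.integer(genes %in% sim$truth$true_positive_genes),
    labeled_flag = as.integer(genes %in% sim$truth$labeled_positive_genes)
  )
  write.table(truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(edges = edge_path, nodes = node_path, truth = truth_path))
}
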