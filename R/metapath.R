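#' Node-type role mapping
#'
#' Declares which node types in a graph play the four roles the metapath
#' queries need: the disease concept, the bridging compound, the gene, and
#' the ontology term used as the feature vocabulary.
#'
#' @param disease,compound,gene,term Node-type labels for each role.
#' @return A named list of class `kg_roles`.
#' @export
kg_roles <- function(disease = "Disease", compound = "Compound",
                     gene = "Gene", term = "EFO") {
  r <- list(disease = disease, compound = compound, gene = gene, term = term)
  if (any(vapply(r, function(x) !is.character(x) || length(x) != 1L || is.na(x),
                 logical(1L)))) {
    stop("each role must be a single node-type string")
  }
  structure(r, class = "kg_roles")
}

#' Select positive genes by the Disease-Compound-Gene metapath
#'
#' A gene is a labeled positive for a disease when it is reachable from the
#' disease node by a length-2 path through a compound node (a known
#' disease-compound-gene association chain). Genes directly linked to the
#' disease without a compound intermediary do NOT qualify. Multiple disease
#' identifiers are handled as the union of their positives.
#'
#' @param kg A `knowledge_graph`.
#' @param disease_cuis Character vector of disease concept ids.
#' @param roles A [kg_roles()] mapping.
#' @return Sorted character vector of positive gene ids.
#' @export
select_positive_genes <- function(kg, disease_cuis, roles = kg_roles()) {
  stopifnot(inherits(kg, "knowledge_graph"), length(disease_cuis) >= 1L)
  tmap <- kg_type_map(kg)
  for (cui in disease_cuis) {
    if (!cui %in% names(tmap)) stop("disease CUI not found in graph: ", cui)
    if (tmap[[cui]] != roles$disease) {
      stop("CUI ", cui, " resolves to node type '", tmap[[cui]],
           "', expected '", roles$disease, "'")
    }
  }
  compounds <- unique(kg_step(kg, disease_cuis, roles$compound)$to)
  if (length(compounds) == 0L) return(character(0))
  sort(unique(kg_step(kg, compounds, roles$gene)$to))
}

#' Select unlabeled candidate genes by the Gene-Term-Gene metapath
#'
#' Genes reachable from any positive gene via a shared ontology-term node
#' (length-2 path Gene-EFO-Gene), excluding the positives themselves. These
#' form the unlabeled pool: no explicit disease link, but co-annotated with
#' at least one known positive.
#'
#' @param kg A `knowledge_graph`.
#' @param positives Character vector of positive gene ids (non-empty).
#' @param roles A [kg_roles()] mapping.
#' @return Sorted character vector of unlabeled gene ids (disjoint from
#'   `positives`).
#' @export
select_unlabeled_genes <- function(kg, positives, roles = kg_roles()) {
  stopifnot(inherits(kg, "knowledge_graph"))
  if (length(positives) == 0L) stop("positives must be non-empty")
  terms <- unique(kg_step(kg, positives, roles$term)$to)
  if (length(terms) == 0L) return(character(0))
  g2 <- unique(kg_step(kg, terms, roles$gene)$to)
  sort(setdiff(g2, positives))
}

#' Collect feature terms bridging positive and unlabeled genes
#'
#' The feature vocabulary is the set of ontology-term nodes lying on at
#' least one positive-gene--term--unlabeled-gene path, i.e. terms adjacent
#' to both classes. Terms touching only one class carry no contrast and are
#' excluded.
#'
#' @param kg A `knowledge_graph`.
#' @param positives,unlabeled Disjoint character vectors of gene ids.
#' @param roles A [kg_roles()] mapping.
#' @return Sorted character vector of term node ids.
#' @export
collect_feature_terms <- function(kg, positives, unlabeled, roles = kg_roles()) {
  stopifnot(inherits(kg, "knowledge_graph"))
  if (length(intersect(positives, unlabeled))) {
    stop("positives and unlabeled must be disjoint")
  }
  t_pos <- unique(kg_step(kg, positives, roles$term)$to)
  t_unl <- unique(kg_step(kg, unlabeled, roles$term)$to)
  sort(intersect(t_pos, t_unl))
}

#' Gene sets and feature vocabulary for one disease query
#'
#' Convenience wrapper running the two metapath selections and the feature
#' collection in sequence. A gene matched by both metapaths is kept as a
#' positive only (positives take precedence).
#'
#' @param kg A `knowledge_graph`.
#' @param disease_cuis Character vector of disease concept ids.
#' @param roles A [kg_roles()] mapping.
#' @return A list of class `labeled_gene_sets` with elements `disease_cuis`,
#'   `positive_genes`, `unlabeled_genes`, `feature_terms` (all sorted).
#' @export
label_genes <- function(kg, disease_cuis, roles = kg_roles()) {
  pos <- select_positive_genes(kg, disease_cuis, roles)
  if (length(pos) == 0L) {
    stop("no positive genes: disease node(s) have no Compound-Gene paths")
  }
  unl <- select_unlabeled_genes(kg, pos, roles)
  terms <- collect_feature_terms(kg, pos, unl, roles)
  message("labeled ", length(pos), " positive / ", length(unl),
          " unlabeled genes; ", length(terms), " feature terms")
  structure(
    list(disease_cuis = sort(unique(disease_cuis)),
         positive_genes = pos, unlabeled_genes = unl, feature_terms = terms),
    class = "labeled_gene_sets"
  )
}

#' Build the sparse binary PU feature matrix
#'
#' Encodes each selected gene as a binary indicator vector over the feature
#' terms: entry (i, j) is 1 iff gene i is adjacent to term j in the graph.
#' Rows are ordered positives first, then unlabeled, lexicographically
#' within each block; the label vector is 1 for positives and 0 for
#' unlabeled. The matrix is stored in compressed sparse row layout, the
#' natural format when most genes touch few terms.
#'
#' @param kg A `knowledge_graph`.
#' @param sets A `labeled_gene_sets` object from [label_genes()].
#' @return A list of class `pu_dataset`: `X` (dgRMatrix), `y` (integer 0/1),
#'   `row_ids`, `col_ids`.
#' @export
build_pu_dataset <- function(kg, sets) {
  stopifnot(inherits(kg, "knowledge_graph"), inherits(sets, "labeled_gene_sets"))
  pos <- sort(sets$positive_genes)
  unl <- sort(sets$unlabeled_genes)
  terms <- sort(sets$feature_terms)
  if (length(terms) == 0L) {
    stop("no feature terms: no Gene-term-Gene bridges between positive and ",
         "unlabeled genes exist in this graph")
  }
  row_ids <- c(pos, unl)
  y <- c(rep(1L, length(pos)), rep(0L, length(unl)))

  he <- kg_half_edges(kg)
  hit <- he[he$from %in% row_ids & he$to %in% terms, , drop = FALSE]
  i <- match(hit$from, row_ids)
  j <- match(hit$to, terms)
  X <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(row_ids), length(terms)),
                            dimnames = list(row_ids, terms))
  X <- methods::as(methods::as(X, "generalMatrix"), "RsparseMatrix")

  zero_rows <- row_ids[Matrix::rowSums(X) == 0]
  if (length(zero_rows)) {
    warning(length(zero_rows), " gene(s) have all-zero feature rows: ",
            paste(head(zero_rows, 5L), collapse = ", "))
  }
  structure(list(X = X, y = y, row_ids = row_ids, col_ids = terms),
            class = "pu_dataset")
}

#' @export
print.pu_dataset <- function(x, ...) {
  cat("<pu_dataset> ", length(x$row_ids), " genes x ", length(x$col_ids),
      " binary features (CSR); ", sum(x$y == 1L), " labeled positive, ",
      sum(x$y == 0L), " unlabeled\n", sep = "")
  invisible(x)
}

#' Write / read a PU dataset as plain-text files
#'
#' `write_pu_dataset()` writes `<prefix>.mtx` (MatrixMarket sparse matrix),
#' `<prefix>_rows.tsv` (gene_id, label) and `<prefix>_cols.tsv` (term_id);
#' `read_pu_dataset()` reads them back.
#'
#' @param dataset A `pu_dataset`.
#' @param prefix Path prefix for the three files.
#' @return `write_pu_dataset()` returns the paths invisibly;
#'   `read_pu_dataset()` returns a `pu_dataset`.
#' @export
write_pu_dataset <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "pu_dataset"))
  mtx <- paste0(prefix, ".mtx")
  Matrix::writeMM(methods::as(dataset$X, "CsparseMatrix"), mtx)
  rows <- data.frame(gene_id = dataset$row_ids,
                     label = ifelse(dataset$y == 1L, "positive", "unlabeled"))
  write.table(rows, paste0(prefix, "_rows.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(term_id = dataset$col_ids), paste0(prefix, "_cols.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(mtx, paste0(prefix, "_rows.tsv"), paste0(prefix, "_cols.tsv")))
}

#' @rdname write_pu_dataset
#' @export
read_pu_dataset <- function(prefix) {
  X <- Matrix::readMM(paste0(prefix, ".mtx"))
  rows <- read.delim(paste0(prefix, "_rows.tsv"), colClasses = "character")
  cols <- read.delim(paste0(prefix, "_cols.tsv"), colClasses = "character")
  X <- X * 1  # pattern matrices come back logical; coerce to numeric
  X <- methods::as(methods::as(X, "generalMatrix"), "RsparseMatrix")
  dimnames(X) <- list(rows$gene_id, cols$term_id)
  structure(list(X = X, y = as.integer(rows$label == "positive"),
                 row_ids = rows$gene_id, col_ids = cols$term_id),
            class = "pu_dataset")
}
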