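test_that("positives require a compound intermediary between disease and gene", {
  kg <- toy_kg(
    list(D1 = "Disease", C1 = "Compound", G1 = "Gene", G2 = "Gene", G3 = "Gene"),
    list(c("D1", "C1"), c("C1", "G1"), c("C1", "G2"), c("D1", "G3")))
  expect_identical(select_positive_genes(kg, "D1"), c("G1", "G2"))
})

test_that("unknown or mistyped disease ids raise informative errors", {
  kg <- toy_kg(list(D1 = "Disease", C1 = "Compound", G1 = "Gene"),
               list(c("D1", "C1"), c("C1", "G1")))
  expect_error(select_positive_genes(kg, "C0404040"), "not found")
  expect_error(select_positive_genes(kg, "C1"), "expected 'Disease'")
  expect_identical(select_positive_genes(toy_kg(
    list(D2 = "Disease", G9 = "Gene"), list(c("D2", "G9"))), "D2"),
    character(0))
})

test_that("unlabeled genes are term-coannotated non-positives, deduplicated", {
  kg <- toy_kg(
    list(D1 = "Disease", C1 = "Compound", G1 = "Gene", G4 = "Gene",
         E1 = "EFO", E2 = "EFO"),
    list(c("D1", "C1"), c("C1", "G1"), c("G1", "E1"), c("E1", "G4"),
         c("G1", "E2"), c("E2", "G4")))
  # G4 reachable through two terms appears once; G1 excluded as positive
  expect_identical(select_unlabeled_genes(kg, "G1"), "G4")
  # a positive with no term neighbors yields an empty candidate set
  kg2 <- toy_kg(list(G1 = "Gene", G2 = "Gene"), list(c("G1", "G2")))
  expect_identical(select_unlabeled_genes(kg2, "G1"), character(0))
})

test_that("feature terms must bridge a positive and an unlabeled gene", {
  kg <- toy_kg(
    list(G1 = "Gene", G2 = "Gene", G4 = "Gene", E1 = "EFO", E2 = "EFO"),
    list(c("G1", "E1"), c("E1", "G4"), c("G1", "E2"), c("E2", "G2")))
  # E2 touches only positives (G1, G2), so only E1 qualifies
  expect_identical(collect_feature_terms(kg, c("G1", "G2"), "G4"), "E1")
  expect_identical(collect_feature_terms(kg, c("G1", "G2"), character(0)),
                   character(0))
  expect_error(collect_feature_terms(kg, c("G1", "G4"), "G4"), "disjoint")
})

test_that("the toy feature matrix matches direct adjacency", {
  kg <- toy_kg(
    list(D1 = "Disease", C1 = "Compound", G1 = "Gene", G4 = "Gene", E1 = "EFO"),
    list(c("D1", "C1"), c("C1", "G1"), c("G1", "E1"), c("E1", "G4")))
  sets <- suppressMessages(label_genes(kg, "D1"))
  ds <- build_pu_dataset(kg, sets)
  expect_s4_class(ds$X, "RsparseMatrix")
  expect_equal(as.matrix(ds$X), matrix(c(1, 1), 2, 1,
               dimnames = list(c("G1", "G4"), "E1")))
  expect_identical(ds$y, c(1L, 0L))
})

test_that("metapath selections match brute-force path enumeration on random graphs", {
  for (seed in 1:8) {
    raw <- random_typed_edges(n_nodes = 40, n_edges = 120, seed = 100 + seed)
    kg <- suppressMessages(kg_from_tables(raw$nodes, raw$edges))
    cuis <- raw$nodes$node_id[raw$nodes$node_type == "Disease"]
    if (!length(cuis)) next
    pos <- select_positive_genes(kg, cuis)
    expect_identical(pos, oracle_positive_genes(raw$nodes, raw$edges, cuis))
    if (!length(pos)) next
    unl <- select_unlabeled_genes(kg, pos)
    expect_identical(unl, oracle_unlabeled_genes(raw$nodes, raw$edges, pos))
    expect_length(intersect(pos, unl), 0L)
    genes <- raw$nodes$node_id[raw$nodes$node_type == "Gene"]
    expect_true(all(c(pos, unl) %in% genes))
    terms <- collect_feature_terms(kg, pos, unl)
    expect_identical(terms,
                     oracle_feature_terms(raw$nodes, raw$edges, pos, unl))
  }
})

test_that("the PU matrix equals the dense adjacency oracle and row sums equal degrees", {
  built <- 0L
  for (seed in 1:8) {
    raw <- random_typed_edges(n_nodes = 40, n_edges = 140, seed = 200 + seed)
    kg <- suppressMessages(kg_from_tables(raw$nodes, raw$edges))
    cuis <- raw$nodes$node_id[raw$nodes$node_type == "Disease"]
    if (!length(cuis)) next
    sets <- tryCatch(suppressMessages(label_genes(kg, cuis)),
                     error = function(e) NULL)
    if (is.null(sets) || !length(sets$feature_terms)) next
    ds <- suppressWarnings(build_pu_dataset(kg, sets))
    M <- oracle_feature_matrix(raw$edges, ds$row_ids, ds$col_ids)
    expect_equal(unname(as.matrix(ds$X)), unname(M))
    expect_equal(unname(Matrix::rowSums(ds$X)), unname(rowSums(M)))
    expect_true(all(ds$X@x %in% 1))
    built <- built + 1L
  }
  expect_gte(built, 2L)
})

test_that("permuting edge-list row order changes nothing", {
  raw <- random_typed_edges(n_nodes = 40, n_edges = 120, seed = 301)
  kg1 <- suppressMessages(kg_from_tables(raw$nodes, raw$edges))
  set.seed(9)
  perm <- raw$edges[sample(nrow(raw$edges)), ]
  kg2 <- suppressMessages(kg_from_tables(raw$nodes, perm))
  expect_identical(kg1$edges, kg2$edges)
  cuis <- raw$nodes$node_id[raw$nodes$node_type == "Disease"]
  if (length(cuis)) {
    expect_identical(select_positive_genes(kg1, cuis),
                     select_positive_genes(kg2, cuis))
  }
})

test_that("degenerate datasets are reported, not silently fixed", {
  # all-zero feature row retained with a warning
  kg <- toy_kg(
    list(D1 = "Disease", C1 = "Compound", G1 = "Gene", G2 = "Gene",
         G4 = "Gene", E1 = "EFO"),
    list(c("D1", "C1"), c("C1", "G1"), c("C1", "G2"),
         c("G1", "E1"), c("E1", "G4")))
  sets <- suppressMessages(label_genes(kg, "D1"))
  expect_warning(ds <- build_pu_dataset(kg, sets), "all-zero")
  expect_true("G2" %in% ds$row_ids)
  # no bridging terms at all -> hard error
  kg2 <- toy_kg(
    list(D1 = "Disease", C1 = "Compound", G1 = "Gene", G4 = "Gene", E1 = "EFO"),
    list(c("D1", "C1"), c("C1", "G1"), c("E1", "G4")))
  sets2 <- structure(list(disease_cuis = "D1", positive_genes = "G1",
                          unlabeled_genes = "G4", feature_terms = character(0)),
                     class = "labeled_gene_sets")
  expect_error(build_pu_dataset(kg2, sets2), "no Gene-term-Gene bridges")
})

test_that("PU datasets round-trip through the MatrixMarket writer", {
  sim <- generate_synthetic_kg(synthetic_spec(n_genes = 80, n_terms = 15,
                                              seed = 5))
  ds <- suppressWarnings(build_pu_dataset(
    sim$kg, suppressMessages(label_genes(sim$kg, sim$truth$disease_cuis))))
  prefix <- tempfile()
  write_pu_dataset(ds, prefix)
  ds2 <- read_pu_dataset(prefix)
  expect_equal(as.matrix(ds2$X), as.matrix(ds$X))
  expect_identical(ds2$y, ds$y)
  expect_identical(ds2$row_ids, ds$row_ids)
  expect_identical(ds2$col_ids, ds$col_ids)
})
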