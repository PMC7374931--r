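make_graph <- function(terms_ids, edges, substrates = character(0),
                       labels = NULL, namespaces = NULL) {
  terms <- data.frame(term_id = terms_ids,
                      label = if (is.null(labels)) terms_ids else labels,
                      namespace = if (is.null(namespaces))
                        "chemical_entity" else namespaces,
                      is_substrate_node = terms_ids %in% substrates,
                      stringsAsFactors = FALSE)
  ontology_graph(terms, edges)
}

edge_df <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(source = m[, 1], target = m[, 2], relation = m[, 3],
             stringsAsFactors = FALSE)
}

test_that("extraction keeps the reachable set and drops the rest", {
  g <- make_graph(c("s", "A", "B", "X"),
                  edge_df("s", "A", "is_a", "A", "B", "is_a",
                          "X", "B", "is_a"))
  sub <- extract_subgraph(g, "s")
  expect_setequal(sub$terms$term_id, c("s", "A", "B"))
  expect_true(sub$terms$is_substrate_node[sub$terms$term_id == "s"])
  expect_error(extract_subgraph(g, "nope"), "nope")
})

test_that("the subatomic-particle branch is excluded, substrates kept", {
  g <- make_graph(c("s", "el", "sp", "ce"),
                  edge_df("s", "el", "is_a", "el", "sp", "is_a",
                          "s", "ce", "is_a"),
                  labels = c("s", "toy electron", "subatomic particle",
                             "chemical entity"))
  sub <- extract_subgraph(g, "s")
  expect_setequal(sub$terms$term_id, c("s", "ce"))
})

test_that("shared ancestors appear once for multiple substrates", {
  g <- make_graph(c("s1", "s2", "A"),
                  edge_df("s1", "A", "is_a", "s2", "A", "is_a"))
  sub <- extract_subgraph(g, c("s1", "s2"))
  expect_equal(sum(sub$terms$term_id == "A"), 1)
})

test_that("a conjugate 2-cycle contracts to one merged substrate term", {
  g <- make_graph(c("acetate", "acetic", "parent"),
                  edge_df("acetate", "acetic", "is_conjugate_base_of",
                          "acetic", "acetate", "is_conjugate_acid_of",
                          "acetate", "parent", "is_a",
                          "acetic", "parent", "is_a"),
                  substrates = "acetate")
  m <- merge_equivalent_terms(g)
  expect_equal(nrow(m$terms), 2)
  merged <- m$terms$term_id[m$terms$term_id != "parent"]
  expect_equal(merged, "acetate")   # lexicographically smallest member
  expect_setequal(m$members[["acetate"]], c("acetate", "acetic"))
  expect_true(m$terms$is_substrate_node[m$terms$term_id == "acetate"])
  expect_equal(nrow(m$edges), 1)    # duplicated is_a edges deduplicated
  expect_equal(m$edges$relation, "is_a")
})

test_that("merging is the identity on graphs without equivalence edges", {
  g <- make_graph(c("a", "b", "c"),
                  edge_df("a", "b", "is_a", "b", "c", "has_role"),
                  substrates = "a")
  m <- merge_equivalent_terms(g)
  expect_setequal(m$terms$term_id, g$terms$term_id)
  expect_equal(nrow(m$edges), nrow(g$edges))
})

test_that("single-child chains collapse to a derived edge", {
  g <- make_graph(c("s", "A", "B", "C"),
                  edge_df("s", "A", "is_a", "A", "B", "is_a",
                          "B", "C", "is_a"),
                  substrates = c("s", "C"))
  p <- prune_single_child_terms(g)
  expect_setequal(p$terms$term_id, c("s", "C"))
  expect_equal(nrow(p$edges), 1)
  expect_equal(p$edges$relation, "derived")
  expect_equal(p$edges$source, "s")
  expect_equal(p$edges$target, "C")
})

test_that("non-substrate terms with two children are retained", {
  g <- make_graph(c("s1", "s2", "A", "B"),
                  edge_df("s1", "A", "is_a", "s2", "A", "is_a",
                          "A", "B", "is_a"),
                  substrates = c("s1", "s2", "B"))
  p <- prune_single_child_terms(g)
  expect_true("A" %in% p$terms$term_id)
})

test_that("parallel relations to the same child count as one sub-term", {
  # A has one distinct child s (via two relation types) -> pruned
  g <- make_graph(c("s", "A", "B1", "B2"),
                  edge_df("s", "A", "is_a", "s", "A", "has_role",
                          "A", "B1", "is_a", "A", "B2", "is_a",
                          "s", "B1", "is_a", "s", "B2", "has_role"),
                  substrates = c("s", "B1", "B2"))
  p <- prune_single_child_terms(g)
  expect_false("A" %in% p$terms$term_id)
  # connectivity to both parents preserved without duplicating edges
  tc <- transitive_closure(p$terms$term_id, p$edges)
  expect_true(tc["s", "B1"] && tc["s", "B2"])
})

test_that("transporter closures match a breadth-first-search oracle", {
  for (seed in 1:100) {
    set.seed(seed)
    spec <- fixture_spec(
      seed = seed,
      n_substrates = sample(c(12L, 16L, 20L), 1),
      n_parents = sample(2:4, 1), n_cycles = sample(0:3, 1),
      n_chains = sample(0:2, 1), chain_len = sample(2:4, 1),
      n_slc = 12L, orphan_fraction = 0.25)
    obo <- make_toy_obo(spec)
    ann <- make_annotation_fixture(spec, obo)
    g <- parse_obo(obo$path)
    mapping <- map_substrates(ann$annotation, g, ann$manual_map)
    red <- prune_single_child_terms(merge_equivalent_terms(
      extract_subgraph(g, unique(mapping$term_id))))
    w <- attach_slc_terms(red, ann$annotation, mapping)
    cl <- all_slc_closures(w)
    pick <- names(cl)[c(1, length(cl))]
    for (slc in pick) {
      expect_setequal(slc_term_closure(w, slc),
                      bfs_reachable(w$edges, paste0("SLC:", slc)))
    }
  }
})

test_that("closure of an SLC equals the union over its cargo closures", {
  spec <- fixture_spec(seed = 42)
  obo <- make_toy_obo(spec)
  ann <- make_annotation_fixture(spec, obo)
  g <- parse_obo(obo$path)
  mapping <- map_substrates(ann$annotation, g, ann$manual_map)
  red <- prune_single_child_terms(merge_equivalent_terms(
    extract_subgraph(g, unique(mapping$term_id))))
  w <- attach_slc_terms(red, ann$annotation, mapping)
  slc <- names(all_slc_closures(w))[1]
  cargo_terms <- w$edges$target[
    w$edges$source == paste0("SLC:", slc) & w$edges$relation == "transports"]
  expected <- unique(c(cargo_terms,
                       unlist(lapply(cargo_terms, function(t)
                         bfs_reachable(w$edges, t)))))
  expect_setequal(slc_term_closure(w, slc), expected)
})

test_that("orphans get no node unless requested; cargo loss is an error", {
  g <- make_graph(c("t"), edge_df("t", "t", "is_a")[0, ], substrates = "t")
  df <- data.frame(slc_id = c("A1", "O1"), family = "F",
                   substrates = c("term-t", ""), coupled_ions = "",
                   mechanism = c("uniporter", "unknown"),
                   substrate_class = c("ion", "orphan"),
                   localizations = "", stringsAsFactors = FALSE)
  ann <- tiny_annotation(df)
  mapping <- data.frame(substrate_name = "term-t", term_id = "t",
                        method = "manual", stringsAsFactors = FALSE)
  w <- attach_slc_terms(g, ann, mapping)
  expect_setequal(w$terms$term_id[w$terms$namespace == "slc"], "SLC:A1")
  w2 <- attach_slc_terms(g, ann, mapping, keep_orphans = TRUE)
  expect_setequal(w2$terms$term_id[w2$terms$namespace == "slc"],
                  c("SLC:A1", "SLC:O1"))

  bad_map <- data.frame(substrate_name = "term-t", term_id = "gone",
                        method = "manual", stringsAsFactors = FALSE)
  expect_error(map_substrates(ann, g, bad_map), "absent")
})

test_that("merge then prune is idempotent", {
  for (seed in c(2, 9, 23)) {
    spec <- fixture_spec(seed = seed, n_cycles = 4, n_chains = 2)
    obo <- make_toy_obo(spec)
    g <- parse_obo(obo$path)
    red1 <- prune_single_child_terms(merge_equivalent_terms(
      extract_subgraph(g, obo$truth$substrate_ids)))
    red2 <- prune_single_child_terms(merge_equivalent_terms(red1))
    expect_setequal(red2$terms$term_id, red1$terms$term_id)
    expect_equal(nrow(red2$edges), nrow(red1$edges))
  }
})
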