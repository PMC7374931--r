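test_that("upregulation filter applies strict cutoffs and SLC intersection", {
  de <- data.frame(gene = c("A", "B", "C", "D", "E"),
                   log2fc = c(0.5, 1.2, 0.6, 2.0, -1.5),
                   fdr = c(0.01, 0.01, 0.05, 0.2, 0.001),
                   stringsAsFactors = FALSE)
  slc <- c("A", "B", "C", "E")
  up <- filter_upregulated(de, slc)
  # A fails log2fc == 0.5 (strict), C fails fdr == 0.05 (strict),
  # D passes thresholds but is not an SLC, E is downregulated
  expect_equal(up, "B")
  expect_equal(filter_upregulated(de, slc, lfc_min = 0.4), c("A", "B"))
})

test_that("planted upregulated sets are recovered exactly from DE fixtures", {
  spec <- fixture_preset("small", seed = 3)
  obo <- make_toy_obo(spec)
  ann <- make_annotation_fixture(spec, obo)
  g <- parse_obo(obo$path)
  mapping <- map_substrates(ann$annotation, g, ann$manual_map)
  red <- prune_single_child_terms(merge_equivalent_terms(
    extract_subgraph(g, unique(mapping$term_id))))
  w <- attach_slc_terms(red, ann$annotation, mapping)
  closures <- all_slc_closures(w)
  de <- make_de_fixture(spec, obo$truth$parent_ids[2], closures,
                        ann$truth$slc_ids)
  up <- filter_upregulated(de$de, ann$truth$slc_ids)
  expect_setequal(up, de$truth$planted)
})

test_that("testable-term selection enforces count, fraction and namespace", {
  # 10 annotated SLCs; terms with 4, 5, 7 (= 70%) SLCs and one role term
  slcs <- sprintf("S%02d", 1:10)
  terms <- data.frame(
    term_id = c("t4", "t5", "t7", "r5"),
    label = c("t4", "t5", "t7", "r5"),
    namespace = c("chemical_entity", "chemical_entity", "chemical_entity",
                  "role"),
    is_substrate_node = FALSE, stringsAsFactors = FALSE)
  slc_terms <- data.frame(
    term_id = paste0("SLC:", slcs), label = slcs, namespace = "slc",
    is_substrate_node = FALSE, stringsAsFactors = FALSE)
  edges <- do.call(rbind, list(
    data.frame(source = paste0("SLC:", slcs[1:4]), target = "t4",
               relation = "transports", stringsAsFactors = FALSE),
    data.frame(source = paste0("SLC:", slcs[1:5]), target = "t5",
               relation = "transports", stringsAsFactors = FALSE),
    data.frame(source = paste0("SLC:", slcs[1:7]), target = "t7",
               relation = "transports", stringsAsFactors = FALSE),
    data.frame(source = paste0("SLC:", slcs[1:5]), target = "r5",
               relation = "transports", stringsAsFactors = FALSE)))
  g <- ontology_graph(rbind(terms, slc_terms), edges)
  testable <- select_testable_terms(g, min_slc = 5, max_fraction = 0.7)
  # t4 below the count floor, t7 at exactly 70% (strict <), r5 wrong
  # namespace
  expect_equal(testable, "t5")
})

test_that("Fisher p-values match the hypergeometric summation oracle", {
  expect_equal(fisher_enrichment(
    hits = sprintf("h%02d", 1:10),
    universe = sprintf("%s%02d", rep(c("h", "u"), c(10, 90)),
                       c(1:10, 1:90)),
    term_to_slcs = list(T = c(sprintf("h%02d", 1:5),
                              sprintf("u%02d", 1:5))))$p_value,
    hyper_oracle(5, 5, 5, 85), tolerance = 1e-12)

  # cross-check against fisher.test on a handful of random tables
  set.seed(7)
  for (i in 1:20) {
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
    p_pkg <- slcsub:::hyper_tail_p(tab[1, 1], tab[1, 2],
                                   tab[2, 1], tab[2, 2])
    p_ft <- stats::fisher.test(tab, alternative = "greater")$p.value
    expect_equal(p_pkg, p_ft, tolerance = 1e-10)
  }
})

test_that("zero overlap is never significant", {
  res <- fisher_enrichment(
    hits = c("a", "b"), universe = c("a", "b", "c", "d", "e"),
    term_to_slcs = list(T = c("c", "d")))
  expect_equal(res$a, 0)
  expect_equal(res$p_value, 1)   # P[X >= 0] spans the whole distribution
  expect_false(res$significant)
})

test_that("BH adjustment equals the hand-applied step-up on a fixed vector", {
  # p = (0.001, 0.02, 0.04, 0.9), m = 4:
  # raw m*p/i = (0.004, 0.04, 0.0533..., 0.9); step-up leaves them ordered
  p <- c(0.001, 0.02, 0.04, 0.9)
  expect_equal(stats::p.adjust(p, "BH"),
               c(0.004, 0.04, 0.04 * 4 / 3, 0.9), tolerance = 1e-12)
  # the same vector flows through fisher_enrichment's q-values: monotone
  # non-decreasing in p-rank and bounded by 1
  set.seed(1)
  u <- sprintf("s%02d", 1:40)
  t2s <- lapply(1:8, function(i) sample(u, sample(5:20, 1)))
  names(t2s) <- paste0("T", 1:8)
  res <- fisher_enrichment(sample(u, 10), u, t2s)
  expect_true(all(diff(res$q_value[order(res$p_value)]) >= -1e-15))
  expect_true(all(res$q_value <= 1))
})

test_that("adding an annotated hit never increases a term's p-value", {
  u <- sprintf("s%02d", 1:30)
  t2s <- list(T = u[1:10])
  hits0 <- u[c(1:3, 20:24)]
  for (extra in u[4:6]) {
    p0 <- fisher_enrichment(hits0, u, t2s)$p_value
    p1 <- fisher_enrichment(c(hits0, extra), u, t2s)$p_value
    expect_lte(p1, p0)
    hits0 <- c(hits0, extra)
  }
})

test_that("most-specific flagging keeps only the deepest enriched terms", {
  terms <- data.frame(
    term_id = c("aa", "saa", "met", "sib"),
    label = c("amino acid", "sulfur-containing amino acid",
              "L-methionine", "sibling"),
    namespace = "chemical_entity", is_substrate_node = FALSE,
    stringsAsFactors = FALSE)
  edges <- data.frame(source = c("met", "saa"), target = c("saa", "aa"),
                      relation = "is_a", stringsAsFactors = FALSE)
  g <- ontology_graph(terms, edges)

  res <- structure(data.frame(
    term_id = c("aa", "saa", "met", "sib"),
    term_label = terms$label, a = 5, b = 1, c = 1, d = 10,
    odds_ratio = 1, p_value = 0.001, q_value = 0.001,
    significant = c(TRUE, TRUE, TRUE, TRUE),
    most_specific = NA, stringsAsFactors = FALSE),
    class = c("slc_enrichment", "data.frame"))
  out <- most_specific_terms(res, g)
  # chain aa <- saa <- met: only the deepest survives; the incomparable
  # sibling also survives
  expect_equal(out$most_specific,
               c(FALSE, FALSE, TRUE, TRUE))

  res$significant <- c(TRUE, FALSE, FALSE, FALSE)
  out2 <- most_specific_terms(res, g)
  expect_equal(out2$most_specific, c(TRUE, FALSE, FALSE, FALSE))

  # the most-specific set is an antichain: no member reachable from another
  gi <- as_igraph(g)
  ms <- out$term_id[out$most_specific]
  for (x in ms) for (y in setdiff(ms, x))
    expect_false(y %in% names(igraph::subcomponent(gi, x, mode = "out")))
})

test_that("hits outside the universe are a precondition error", {
  expect_error(fisher_enrichment("x", c("a", "b"), list(T = "a")),
               "universe")
})
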