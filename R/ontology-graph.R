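#' Relationship types used by the substrate ontology
#'
#' Only five ChEBI relationship types take part in subgraph extraction and
#' reduction; `transports` links transporter nodes to chemical terms and
#' `derived` replaces elided single-child chains.
#'
#' @format Character vectors of relation names.
#' @name slc_relations
NULL

#' @rdname slc_relations
#' @export
ONTOLOGY_RELATIONS <- c("is_a", "has_role", "is_tautomer_of",
                        "is_conjugate_acid_of", "is_conjugate_base_of")

#' @rdname slc_relations
#' @export
EQUIVALENCE_RELATIONS <- c("is_tautomer_of", "is_conjugate_acid_of",
                           "is_conjugate_base_of")

ALL_RELATIONS <- c(ONTOLOGY_RELATIONS, "transports", "derived")

#' Construct an ontology graph object
#'
#' A directed multigraph of typed ontology relationships. The edge direction
#' convention is specific-to-general: `child -> parent` for `is_a`,
#' `entity -> role` for `has_role`, and `SLC -> chemical term` for
#' `transports`. After cycle merging the graph restricted to all relations is
#' a DAG.
#'
#' @param terms data.frame with columns `term_id`, `label`, `namespace`
#'   (one of `chemical_entity`, `role`, `slc`) and `is_substrate_node`.
#' @param edges data.frame with columns `source`, `target`, `relation`.
#' @param members named list mapping each `term_id` to the original ids it
#'   contains (singletons unless terms were merged).
#' @param synonyms optional named list of exact synonyms per term id.
#' @return An object of class `ontology_graph`.
#' @export
ontology_graph <- function(terms, edges, members = NULL, synonyms = NULL) {
  stopifnot(is.data.frame(terms), is.data.frame(edges))
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need_t <- c("term_id", "label", "namespace", "is_substrate_node")
  if (!all(need_t %in% names(terms)))
    stop("terms must have columns: ", paste(need_t, collapse = ", "))
  need_e <- c("source", "target", "relation")
  if (!all(need_e %in% names(edges)))
    stop("edges must have columns: ", paste(need_e, collapse = ", "))
  if (anyDuplicated(terms$term_id))
    stop("duplicate term ids: ",
         paste(unique(terms$term_id[duplicated(terms$term_id)]), collapse = ", "))
  bad_rel <- setdiff(unique(edges$relation), ALL_RELATIONS)
  if (length(bad_rel))
    stop("unknown relation type(s): ", paste(bad_rel, collapse = ", "))
  dangling <- setdiff(unique(c(edges$source, edges$target)), terms$term_id)
  if (length(dangling))
    stop("edges reference unknown terms: ", paste(dangling, collapse = ", "))
  if (is.null(members)) {
    members <- as.list(terms$term_id)
    names(members) <- terms$term_id
  }
  rownames(terms) <- NULL
  rownames(edges) <- NULL
  structure(list(terms = terms, edges = edges, members = members,
                 synonyms = synonyms),
            class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  ns <- table(x$terms$namespace)
  cat("ontology_graph: ", nrow(x$terms), " terms, ", nrow(x$edges),
      " edges\n", sep = "")
  cat("  namespaces: ",
      paste(sprintf("%s=%d", names(ns), as.integer(ns)), collapse = ", "),
      "\n", sep = "")
  cat("  substrate nodes: ", sum(x$terms$is_substrate_node), "\n", sep = "")
  invisible(x)
}

#' Convert an ontology graph to igraph
#'
#' @param graph an `ontology_graph`.
#' @param relations optional subset of relation types to keep.
#' @return An `igraph` directed graph whose vertex names are term ids and
#'   whose edges carry a `relation` attribute.
#' @export
as_igraph <- function(graph, relations = NULL) {
  stopifnot(inherits(graph, "ontology_graph"))
  ed <- graph$edges
  if (!is.null(relations)) ed <- ed[ed$relation %in% relations, , drop = FALSE]
  igraph::graph_from_data_frame(
    ed[, c("source", "target", "relation")],
    directed = TRUE,
    vertices = data.frame(name = graph$terms$term_id,
                          stringsAsFactors = FALSE))
}

#' Map original term ids to their (possibly merged) containing term
#'
#' @param graph an `ontology_graph`.
#' @return Named character vector: original id -> current term id.
#' @export
member_index <- function(graph) {
  stopifnot(inherits(graph, "ontology_graph"))
  reps <- rep(names(graph$members), lengths(graph$members))
  stats::setNames(reps, unlist(graph$members, use.names = FALSE))
}

# ids of vertices reachable from `from` following out-edges (excludes
# unreachable vertices; includes the start set itself)
reachable_from <- function(g, from) {
  if (!length(from)) return(character(0))
  # breadth-first from a virtual super-source so one traversal covers all
  # start vertices even on large graphs
  gg <- igraph::add_vertices(g, 1, name = ".super.")
  gg <- igraph::add_edges(gg, c(rbind(".super.", from)))
  out <- igraph::subcomponent(gg, ".super.", mode = "out")
  setdiff(names(out), ".super.")
}
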