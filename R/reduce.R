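#' Extract the substrate-reachable sub-ontology
#'
#' Keeps every term reachable from at least one mapped substrate term via
#' directed paths over the five allowed relationship types, and marks the
#' substrate terms. Terms of the subatomic-particle sub-ontology — any term
#' whose `is_a` ancestry reaches (or is) a term labelled "subatomic particle"
#' — are excluded, except terms that are themselves substrate nodes, which
#' are never removed.
#'
#' @param graph an [ontology_graph()] (full parsed ontology).
#' @param substrate_ids term ids that are images of the substrate mapping.
#' @return The induced `ontology_graph` with `is_substrate_node` set.
#' @export
extract_subgraph <- function(graph, substrate_ids) {
  stopifnot(inherits(graph, "ontology_graph"))
  substrate_ids <- unique(substrate_ids)
  absent <- setdiff(substrate_ids, graph$terms$term_id)
  if (length(absent))
    stop("substrate id(s) absent from ontology: ",
         paste(absent, collapse = ", "))

  g <- as_igraph(graph, relations = ONTOLOGY_RELATIONS)
  keep <- reachable_from(g, substrate_ids)

  sp_ids <- graph$terms$term_id[
    tolower(graph$terms$label) == "subatomic particle"]
  if (length(sp_ids)) {
    g_isa <- as_igraph(graph, relations = "is_a")
    subatomic <- unique(unlist(lapply(sp_ids, function(s)
      names(igraph::subcomponent(g_isa, s, mode = "in")))))
    keep <- setdiff(keep, setdiff(subatomic, substrate_ids))
  }

  terms <- graph$terms[graph$terms$term_id %in% keep, , drop = FALSE]
  terms$is_substrate_node <- terms$term_id %in% substrate_ids
  edges <- graph$edges[graph$edges$source %in% keep &
                         graph$edges$target %in% keep &
                         graph$edges$relation %in% ONTOLOGY_RELATIONS, ,
                       drop = FALSE]
  ontology_graph(terms, edges,
                 members = graph$members[terms$term_id],
                 synonyms = graph$synonyms)
}

#' Merge tautomer and conjugate acid/base cycles
#'
#' Contracts every strongly connected component of the graph restricted to
#' the circular relationship types (`is_tautomer_of`, `is_conjugate_acid_of`,
#' `is_conjugate_base_of`) into a single merged term, re-points all other
#' edges, removes the resulting self-loops and duplicate parallel edges, and
#' verifies that the result is a DAG. The merged term id is the
#' lexicographically smallest member id (deterministic, diff-stable); its
#' substrate flag is the OR over members.
#'
#' @param graph an extracted `ontology_graph`.
#' @return The contracted `ontology_graph` (a DAG).
#' @export
merge_equivalent_terms <- function(graph) {
  stopifnot(inherits(graph, "ontology_graph"))
  g_cyc <- as_igraph(graph, relations = EQUIVALENCE_RELATIONS)
  comp <- igraph::components(g_cyc, mode = "strong")
  grp <- split(names(comp$membership), comp$membership)

  rep_of <- character(0)
  for (members in grp) {
    rep_id <- min(members)
    rep_of[members] <- rep_id
  }

  old <- graph$terms
  new_ids <- unique(unname(rep_of[old$term_id]))
  idx <- match(new_ids, old$term_id)
  terms <- data.frame(term_id = new_ids, label = old$label[idx],
                      namespace = old$namespace[idx],
                      is_substrate_node = vapply(new_ids, function(id) {
                        any(old$is_substrate_node[rep_of[old$term_id] == id])
                      }, logical(1)),
                      stringsAsFactors = FALSE)
  members <- lapply(new_ids, function(id) {
    sort(unique(unlist(graph$members[old$term_id[rep_of[old$term_id] == id]],
                       use.names = FALSE)))
  })
  names(members) <- new_ids

  edges <- graph$edges
  edges$source <- unname(rep_of[edges$source])
  edges$target <- unname(rep_of[edges$target])
  edges <- unique(edges[edges$source != edges$target, , drop = FALSE])

  out <- ontology_graph(terms, edges, members = members,
                        synonyms = graph$synonyms)
  if (!igraph::is_dag(as_igraph(out)))
    stop("integrity error: graph still cyclic after contracting ",
         "tautomer/conjugate components")
  out
}

#' Prune single-child non-substrate terms
#'
#' Removes every non-substrate term with exactly one incoming edge — i.e.,
#' exactly one distinct more-specific child term; parallel edges of different
#' relation types between the same pair count once. Such terms add a level of
#' specificity without distinguishing between instances of their branch. To
#' preserve connectivity, a `derived` edge is introduced from the removed
#' term's single child to each of its parents (unless an edge between that
#' pair already exists). The rule is applied iteratively, in topological
#' order, until a fixpoint: removals can expose new single-child terms.
#' Reachability among all retained term pairs is preserved exactly, and
#' substrate nodes are never removed.
#'
#' @param graph a DAG `ontology_graph` (after [merge_equivalent_terms()]).
#' @return The pruned `ontology_graph`.
#' @export
prune_single_child_terms <- function(graph) {
  stopifnot(inherits(graph, "ontology_graph"))
  terms <- graph$terms
  edges <- graph$edges

  protected <- terms$term_id[terms$is_substrate_node |
                               terms$namespace == "slc"]

  repeat {
    pair <- unique(edges[, c("source", "target")])
    n_children <- table(pair$target)
    cand <- names(n_children)[n_children == 1L]
    cand <- setdiff(cand, protected)
    if (!length(cand)) break

    # children first: removing a term can change its parents' child counts,
    # so re-check the count at removal time
    g <- igraph::graph_from_data_frame(
      pair, directed = TRUE,
      vertices = data.frame(name = terms$term_id))
    topo <- names(igraph::topo_sort(g, mode = "out"))
    cand <- topo[topo %in% cand]

    removed_any <- FALSE
    for (t in cand) {
      into <- edges$target == t
      children <- unique(edges$source[into])
      if (length(children) != 1L) next
      child <- children
      parents <- unique(edges$target[edges$source == t])
      edges <- edges[!into & edges$source != t, , drop = FALSE]
      for (p in parents) {
        if (!any(edges$source == child & edges$target == p))
          edges <- rbind(edges, data.frame(source = child, target = p,
                                           relation = "derived",
                                           stringsAsFactors = FALSE))
      }
      terms <- terms[terms$term_id != t, , drop = FALSE]
      removed_any <- TRUE
    }
    if (!removed_any) break
  }

  ontology_graph(terms, edges, members = graph$members[terms$term_id],
                 synonyms = graph$synonyms)
}

#' Attach transporter nodes via "transports" edges
#'
#' Adds one `slc`-namespace node per cargo-bearing transporter and a
#' `transports` edge from it to the (possibly merged) term containing each of
#' its mapped cargo ids. Orphan transporters get no node unless
#' `keep_orphans = TRUE`. A cargo whose mapped term was eliminated by the
#' reduction (i.e., is inside no retained term's member set) is an integrity
#' error: substrate nodes must never be pruned.
#'
#' @param graph the reduced `ontology_graph`.
#' @param table an `slc_annotation`.
#' @param mapping resolved mapping as from [map_substrates()].
#' @param keep_orphans emit nodes (without edges) for orphan transporters.
#' @return `ontology_graph` including transporter nodes.
#' @export
attach_slc_terms <- function(graph, table, mapping, keep_orphans = FALSE) {
  stopifnot(inherits(graph, "ontology_graph"),
            inherits(table, "slc_annotation"))
  midx <- member_index(graph)
  map_lut <- split(mapping$term_id, tolower(mapping$substrate_name))

  new_terms <- list(); new_edges <- list()
  for (i in seq_len(nrow(table))) {
    if (table$is_orphan[i] && !keep_orphans) next
    slc_node <- paste0("SLC:", table$slc_id[i])
    new_terms[[length(new_terms) + 1L]] <-
      data.frame(term_id = slc_node, label = table$slc_id[i],
                 namespace = "slc", is_substrate_node = FALSE,
                 stringsAsFactors = FALSE)
    cargoes <- unique(tolower(trimws(
      c(table$substrates[[i]], table$coupled_ions[[i]]))))
    if (!length(cargoes)) next
    unmapped <- cargoes[!cargoes %in% names(map_lut)]
    if (length(unmapped))
      stop("cargo name(s) of ", table$slc_id[i], " missing from mapping: ",
           paste(unmapped, collapse = ", "))
    cargo_ids <- unique(unlist(map_lut[cargoes], use.names = FALSE))
    lost <- cargo_ids[!cargo_ids %in% names(midx)]
    if (length(lost))
      stop("integrity error: mapped cargo term(s) of ", table$slc_id[i],
           " were eliminated by the reduction: ",
           paste(lost, collapse = ", "))
    new_edges[[length(new_edges) + 1L]] <-
      data.frame(source = slc_node, target = unique(unname(midx[cargo_ids])),
                 relation = "transports", stringsAsFactors = FALSE)
  }
  terms <- rbind(graph$terms, do.call(rbind, new_terms))
  edges <- rbind(graph$edges, do.call(rbind, new_edges))
  members <- graph$members
  for (tt in terms$term_id[terms$namespace == "slc"]) members[[tt]] <- tt
  ontology_graph(terms, edges, members = members, synonyms = graph$synonyms)
}

#' Ontology-term closure of one transporter
#'
#' All ontology terms reachable from the transporter's node via directed
#' paths (its `transports` edges followed by specific-to-general ontology
#' edges); the transporter node itself is excluded.
#'
#' @param graph `ontology_graph` with transporter nodes attached.
#' @param slc_id gene symbol of the transporter.
#' @return Character vector of term ids.
#' @export
slc_term_closure <- function(graph, slc_id) {
  stopifnot(inherits(graph, "ontology_graph"))
  node <- paste0("SLC:", slc_id)
  if (!node %in% graph$terms$term_id)
    stop("unknown transporter: ", slc_id)
  g <- as_igraph(graph)
  setdiff(names(igraph::subcomponent(g, node, mode = "out")), node)
}

#' Closures for every attached transporter
#'
#' @param graph `ontology_graph` with transporter nodes attached.
#' @return Named list: slc_id -> character vector of reachable term ids.
#' @export
all_slc_closures <- function(graph) {
  stopifnot(inherits(graph, "ontology_graph"))
  slc_nodes <- graph$terms$term_id[graph$terms$namespace == "slc"]
  g <- as_igraph(graph)
  out <- lapply(slc_nodes, function(v)
    setdiff(names(igraph::subcomponent(g, v, mode = "out")), v))
  names(out) <- sub("^SLC:", "", slc_nodes)
  out
}

#' Invert closures into a term -> transporters map
#'
#' @param closures named list from [all_slc_closures()].
#' @return Named list: term_id -> character vector of slc_ids annotated to it.
#' @export
term_slc_map <- function(closures) {
  if (!length(closures)) return(list())
  slc <- rep(names(closures), lengths(closures))
  split(slc, unlist(closures, use.names = FALSE))
}

#' Summarize an ontology graph
#'
#' Term and relationship counts (transporter nodes and `transports` edges
#' excluded from the headline counts), per-namespace term counts, and the
#' distributions of transporters per term and terms per transporter with
#' their medians.
#'
#' @param graph an `ontology_graph` (transporter nodes optional).
#' @return A list of class `slc_ontology_summary`.
#' @export
summarize_ontology <- function(graph) {
  stopifnot(inherits(graph, "ontology_graph"))
  is_slc <- graph$terms$namespace == "slc"
  ns <- table(graph$terms$namespace[!is_slc])
  closures <- if (any(is_slc)) all_slc_closures(graph) else list()
  t2s <- term_slc_map(closures)
  res <- list(
    n_terms = sum(!is_slc),
    n_edges = sum(graph$edges$relation != "transports"),
    n_slc_nodes = sum(is_slc),
    namespace_counts = stats::setNames(as.integer(ns), names(ns)),
    slcs_per_term = lengths(t2s),
    terms_per_slc = lengths(closures),
    median_slcs_per_term = if (length(t2s)) stats::median(lengths(t2s)) else NA_real_,
    median_terms_per_slc = if (length(closures)) stats::median(lengths(closures)) else NA_real_)
  class(res) <- "slc_ontology_summary"
  res
}

#' @export
print.slc_ontology_summary <- function(x, ...) {
  cat(sprintf("reduced ontology: %d terms, %d relationships (+%d transporter nodes)\n",
              x$n_terms, x$n_edges, x$n_slc_nodes))
  cat("  namespaces: ",
      paste(sprintf("%s=%d", names(x$namespace_counts), x$namespace_counts),
            collapse = ", "), "\n", sep = "")
  if (length(x$slcs_per_term))
    cat(sprintf("  median SLCs/term = %g, median terms/SLC = %g\n",
                x$median_slcs_per_term, x$median_terms_per_slc))
  invisible(x)
}
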