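#' Parse an OBO ontology file
#'
#' Reads an OBO 1.2/1.4 flat file (optionally gzip-compressed) into an
#' [ontology_graph()]. Only the five relationship types relevant to substrate
#' ontology construction are kept (`is_a`, `has_role`, `is_tautomer_of`,
#' `is_conjugate_acid_of`, `is_conjugate_base_of`); all other relationship
#' tags are ignored. Obsolete terms are skipped. Exact synonyms are retained
#' for substrate-name matching.
#'
#' Term namespaces are assigned structurally: a term belongs to the `role`
#' sub-ontology if its `is_a` ancestry reaches a term labelled "role"
#' (case-insensitive); every other term is `chemical_entity`. This mirrors
#' how ChEBI separates its role and chemical-entity branches without relying
#' on hard-coded identifiers, so it works on toy ontologies too.
#'
#' @param path path to an `.obo` or `.obo.gz` file.
#' @return An [ontology_graph()].
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) stop("cannot read OBO file: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)

  # stanza boundaries
  stanza_starts <- grep("^\\[", lines)
  if (!length(stanza_starts))
    stop("malformed OBO file (no stanzas found): ", path)
  stanza_ends <- c(stanza_starts[-1] - 1L, length(lines))
  heads <- lines[stanza_starts]

  ids <- character(0); labels <- character(0)
  syns <- list()
  src <- character(0); tgt <- character(0); rel <- character(0)

  term_idx <- which(heads == "[Term]")
  for (k in term_idx) {
    body <- lines[(stanza_starts[k] + 1L):stanza_ends[k]]
    body <- body[nzchar(body)]
    get_tag <- function(tag) {
      hit <- body[startsWith(body, paste0(tag, ": "))]
      sub(paste0("^", tag, ": "), "", hit)
    }
    if (any(grepl("^is_obsolete: *true", body))) next
    id <- get_tag("id")
    if (length(id) != 1L)
      stop("malformed [Term] stanza near line ", stanza_starts[k],
           ": expected exactly one id tag")
    id <- strip_comment(id[1])
    name <- get_tag("name")
    name <- if (length(name)) strip_comment(name[1]) else id
    ids <- c(ids, id)
    labels <- c(labels, name)

    # exact synonyms: synonym: "text" EXACT []
    syn_lines <- get_tag("synonym")
    syn_lines <- syn_lines[grepl("\"\\s+EXACT\\b", syn_lines)]
    if (length(syn_lines)) {
      vals <- sub("^\"(.*)\"\\s+EXACT\\b.*$", "\\1", syn_lines)
      syns[[id]] <- vals
    }

    for (parent in get_tag("is_a")) {
      src <- c(src, id); tgt <- c(tgt, strip_comment(parent)); rel <- c(rel, "is_a")
    }
    for (rl in get_tag("relationship")) {
      rl <- strip_comment(rl)
      parts <- strsplit(trimws(rl), "\\s+")[[1]]
      if (length(parts) < 2)
        stop("malformed relationship tag near line ", stanza_starts[k], ": ", rl)
      if (parts[1] %in% setdiff(ONTOLOGY_RELATIONS, "is_a")) {
        src <- c(src, id); tgt <- c(tgt, parts[2]); rel <- c(rel, parts[1])
      } # other relationship types (has_part, ...) are ignored
    }
  }

  if (!length(ids)) stop("no non-obsolete [Term] stanzas in ", path)

  keep <- src %in% ids & tgt %in% ids   # drop edges to obsolete/absent terms
  edges <- data.frame(source = src[keep], target = tgt[keep],
                      relation = rel[keep], stringsAsFactors = FALSE)
  edges <- unique(edges)

  terms <- data.frame(term_id = ids, label = labels,
                      namespace = "chemical_entity",
                      is_substrate_node = FALSE, stringsAsFactors = FALSE)
  g <- ontology_graph(terms, edges, synonyms = syns)
  g$terms$namespace <- assign_namespaces(g)
  g
}

strip_comment <- function(x) trimws(sub("\\s*!.*$", "", x))

# role namespace = terms whose is_a ancestry reaches a term labelled "role"
assign_namespaces <- function(graph) {
  ns <- rep("chemical_entity", nrow(graph$terms))
  role_roots <- graph$terms$term_id[tolower(graph$terms$label) == "role"]
  if (length(role_roots)) {
    g_isa <- as_igraph(graph, relations = "is_a")
    below <- unique(unlist(lapply(role_roots, function(r)
      names(igraph::subcomponent(g_isa, r, mode = "in")))))
    ns[graph$terms$term_id %in% below] <- "role"
  }
  ns[startsWith(graph$terms$term_id, "SLC:")] <- "slc"
  ns
}
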