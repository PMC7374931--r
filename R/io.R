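#' Serialize a reduced ontology back to OBO
#'
#' Merged terms carry their collapsed member ids as `alt_id` lines;
#' `transports` and `derived` are declared as `[Typedef]` stanzas.
#'
#' @param graph an `ontology_graph`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_ontology_obo <- function(graph, path) {
  stopifnot(inherits(graph, "ontology_graph"))
  lines <- c("format-version: 1.2", "ontology: slc-substrate-ontology", "")
  by_src <- split(seq_len(nrow(graph$edges)), graph$edges$source)
  for (i in seq_len(nrow(graph$terms))) {
    id <- graph$terms$term_id[i]
    lines <- c(lines, "[Term]", paste0("id: ", id),
               paste0("name: ", graph$terms$label[i]),
               paste0("namespace: ", graph$terms$namespace[i]))
    alt <- setdiff(graph$members[[id]], id)
    for (a in alt) lines <- c(lines, paste0("alt_id: ", a))
    ed <- graph$edges[by_src[[id]], , drop = FALSE]
    if (!is.null(ed) && nrow(ed)) {
      for (j in seq_len(nrow(ed))) {
        lines <- c(lines, if (ed$relation[j] == "is_a")
          paste0("is_a: ", ed$target[j])
          else paste0("relationship: ", ed$relation[j], " ", ed$target[j]))
      }
    }
    lines <- c(lines, "")
  }
  for (td in c("has_role", "is_tautomer_of", "is_conjugate_acid_of",
               "is_conjugate_base_of", "transports", "derived"))
    lines <- c(lines, "[Typedef]", paste0("id: ", td),
               paste0("name: ", gsub("_", " ", td)), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write the edge list of an ontology graph to TSV
#'
#' @param graph an `ontology_graph`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_edges_tsv <- function(graph, path) {
  stopifnot(inherits(graph, "ontology_graph"))
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write per-transporter term closures to TSV
#'
#' Long format: one row per (slc_id, term_id) pair.
#'
#' @param closures named list from [all_slc_closures()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_closures_tsv <- function(closures, path) {
  out <- data.frame(slc_id = rep(names(closures), lengths(closures)),
                    term_id = unlist(closures, use.names = FALSE),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read closures written by [write_closures_tsv()]
#'
#' @param path closures TSV.
#' @return Named list slc_id -> term ids.
#' @export
read_closures_tsv <- function(path) {
  x <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  split(x$term_id, x$slc_id)
}
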