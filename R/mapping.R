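#' Read a substrate-to-term mapping table
#'
#' Tab-separated file with columns `substrate_name`, `term_id`, `method`
#' (`exact_label`, `translation` or `manual`). Such a file plays the role of
#' the offline curation tiers: whatever exact label/synonym matching cannot
#' resolve is looked up here.
#'
#' @param path path to the mapping TSV.
#' @return data.frame with the three columns.
#' @export
read_mapping <- function(path) {
  if (!file.exists(path)) stop("mapping file not found: ", path)
  m <- utils::read.delim(path, sep = "\t", header = TRUE,
                         colClasses = "character", stringsAsFactors = FALSE,
                         quote = "")
  need <- c("substrate_name", "term_id", "method")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols))
    stop("mapping schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(m$method), c("exact_label", "translation", "manual"))
  if (length(bad))
    stop("mapping vocabulary error: unknown method(s): ",
         paste(bad, collapse = ", "))
  m[, need]
}

#' Map annotation cargo names to ontology terms
#'
#' Resolution order per distinct cargo name: (1) exact case-insensitive match
#' against term labels and exact synonyms of the loaded ontology
#' (`method = exact_label`; all matching terms are reported when a name is
#' ambiguous); (2) lookup in the supplied offline mapping table, keeping that
#' entry's method. Names resolved by neither route are collected in the
#' `rejects` attribute and reported with a warning, never silently dropped.
#'
#' @param table an `slc_annotation`.
#' @param graph the parsed full ontology ([parse_obo()]).
#' @param manual_map optional data.frame as from [read_mapping()].
#' @return data.frame (`substrate_name`, `term_id`, `method`) with attribute
#'   `rejects` (character vector of unresolved names).
#' @export
map_substrates <- function(table, graph, manual_map = NULL) {
  stopifnot(inherits(table, "slc_annotation"),
            inherits(graph, "ontology_graph"))
  cargo <- distinct_cargoes(table)
  if (!length(cargo)) stop("mapping error: annotation has no cargo names")

  label_lut <- split(graph$terms$term_id, tolower(graph$terms$label))
  syn_lut <- list()
  if (length(graph$synonyms)) {
    syn_ids <- rep(names(graph$synonyms), lengths(graph$synonyms))
    syn_lut <- split(syn_ids,
                     tolower(unlist(graph$synonyms, use.names = FALSE)))
  }
  if (!is.null(manual_map)) {
    unknown_terms <- setdiff(manual_map$term_id, graph$terms$term_id)
    if (length(unknown_terms))
      stop("mapping integrity error: manual_map term_id(s) absent from ",
           "ontology: ", paste(unknown_terms, collapse = ", "))
  }

  rows <- vector("list", length(cargo))
  rejects <- character(0)
  for (i in seq_along(cargo)) {
    key <- tolower(cargo[i])
    hits <- unique(c(label_lut[[key]], syn_lut[[key]]))
    if (length(hits)) {
      rows[[i]] <- data.frame(substrate_name = cargo[i], term_id = hits,
                              method = "exact_label",
                              stringsAsFactors = FALSE)
    } else if (!is.null(manual_map) &&
               any(tolower(manual_map$substrate_name) == key)) {
      mm <- manual_map[tolower(manual_map$substrate_name) == key, ,
                       drop = FALSE]
      rows[[i]] <- data.frame(substrate_name = cargo[i],
                              term_id = mm$term_id, method = mm$method,
                              stringsAsFactors = FALSE)
    } else {
      rejects <- c(rejects, cargo[i])
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || !nrow(out))
    stop("mapping error: no cargo name could be resolved")
  if (length(rejects))
    warning(length(rejects), " cargo name(s) unresolved: ",
            paste(utils::head(rejects, 10), collapse = ", "),
            if (length(rejects) > 10) ", ...")
  rownames(out) <- NULL
  attr(out, "rejects") <- rejects
  out
}
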