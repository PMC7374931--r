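#' Read a differential-expression table
#'
#' Expects columns `gene`, `log2fc`, `fdr` (BH-adjusted p-values in `[0,1]`).
#'
#' @param path path to a TSV file.
#' @return data.frame with the three columns, numeric where appropriate.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop("DE table not found: ", path)
  de <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  need <- c("gene", "log2fc", "fdr")
  missing_cols <- setdiff(need, names(de))
  if (length(missing_cols))
    stop("DE schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  de$log2fc <- as.numeric(de$log2fc)
  de$fdr <- as.numeric(de$fdr)
  if (any(!is.na(de$fdr) & (de$fdr < 0 | de$fdr > 1)))
    stop("DE integrity error: fdr outside [0,1]")
  de[, need]
}

#' Select significantly upregulated transporters
#'
#' Genes with `log2fc > lfc_min` and `fdr < fdr_max` (both strict),
#' intersected with the supplied transporter symbols by exact
#' case-insensitive equality (no alias resolution).
#'
#' @param de_table data.frame with `gene`, `log2fc`, `fdr`.
#' @param slc_ids transporter gene symbols.
#' @param lfc_min log2 fold-change cutoff (default 0.5, exclusive).
#' @param fdr_max FDR cutoff (default 0.05, exclusive).
#' @return Character vector of transporter symbols (spelling of `slc_ids`).
#' @export
filter_upregulated <- function(de_table, slc_ids, lfc_min = 0.5,
                               fdr_max = 0.05) {
  if (!nrow(de_table)) stop("DE table is empty")
  up <- de_table$gene[!is.na(de_table$log2fc) & !is.na(de_table$fdr) &
                        de_table$log2fc > lfc_min & de_table$fdr < fdr_max]
  slc_ids[tolower(slc_ids) %in% tolower(up)]
}

#' Select testable ontology terms
#'
#' Terms eligible for enrichment testing: chemical-entity terms annotated to
#' at least `min_slc` different transporters but fewer than
#' `max_fraction` of the annotated transporters. Role terms are excluded.
#'
#' @param graph reduced `ontology_graph` with transporter nodes.
#' @param min_slc minimum transporters per term (default 5, inclusive).
#' @param max_fraction exclusive upper bound as a fraction of annotated
#'   transporters (default 0.7).
#' @param universe optional transporter symbols defining "annotated SLCs";
#'   defaults to every transporter attached to the graph.
#' @return Character vector of term ids.
#' @export
select_testable_terms <- function(graph, min_slc = 5, max_fraction = 0.7,
                                  universe = NULL) {
  stopifnot(inherits(graph, "ontology_graph"))
  closures <- all_slc_closures(graph)
  if (!is.null(universe)) closures <- closures[names(closures) %in% universe]
  t2s <- term_slc_map(closures)
  n_annot <- length(closures)
  chem <- graph$terms$term_id[graph$terms$namespace == "chemical_entity"]
  cnt <- lengths(t2s)
  ok <- names(cnt)[cnt >= min_slc & cnt < max_fraction * n_annot]
  intersect(ok, chem)
}

# one-sided over-representation p-value: upper hypergeometric tail P[X >= a]
hyper_tail_p <- function(a, b, c, d) {
  stats::phyper(a - 1, m = a + c, n = b + d, k = a + b, lower.tail = FALSE)
}

#' Ontology term enrichment by one-sided Fisher's exact test
#'
#' For each term, builds the 2x2 table of upregulated vs other transporters
#' against annotated-to-term vs not, computes the one-sided
#' (over-representation) exact p-value as the upper hypergeometric tail, and
#' corrects across terms with Benjamini-Hochberg. Terms are significant at
#' `q < alpha`.
#'
#' @param hits upregulated transporter symbols (must be a subset of
#'   `universe`).
#' @param universe transporter symbols forming the test universe.
#' @param term_to_slcs named list term_id -> transporter symbols (as from
#'   [term_slc_map()]); each set is intersected with `universe` before
#'   counting.
#' @param labels optional named character vector of term labels.
#' @param alpha FDR significance cutoff (default 0.05).
#' @return data.frame of class `slc_enrichment` with columns `term_id`,
#'   `term_label`, `a`, `b`, `c`, `d`, `odds_ratio`, `p_value`, `q_value`,
#'   `significant`, `most_specific` (initialised `NA`, see
#'   [most_specific_terms()]).
#' @export
fisher_enrichment <- function(hits, universe, term_to_slcs, labels = NULL,
                              alpha = 0.05) {
  hits <- unique(hits); universe <- unique(universe)
  extra <- setdiff(hits, universe)
  if (length(extra))
    stop("precondition error: hits not contained in universe: ",
         paste(extra, collapse = ", "))
  if (!length(term_to_slcs)) stop("no terms to test")
  N <- length(universe); K <- length(hits)
  res <- lapply(names(term_to_slcs), function(t) {
    annot <- intersect(term_to_slcs[[t]], universe)
    a <- length(intersect(hits, annot))
    b <- K - a
    c <- length(annot) - a
    d <- N - a - b - c
    or <- (a * d) / (b * c)
    data.frame(term_id = t,
               term_label = if (!is.null(labels) && t %in% names(labels))
                 unname(labels[t]) else t,
               a = a, b = b, c = c, d = d, odds_ratio = or,
               p_value = hyper_tail_p(a, b, c, d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value < alpha
  out$most_specific <- NA
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("slc_enrichment", "data.frame")
  out
}

#' Flag the most specific enriched terms of each branch
#'
#' A significant term is `most_specific` iff no other significant term in the
#' result is one of its descendants (i.e., no more-specific significant term
#' can reach it via directed specific-to-general paths). Reporting only these
#' removes redundancy along ontology branches — if both a general class and
#' one of its members are enriched, only the member is kept. Non-significant
#' rows are left untouched (`most_specific = FALSE`).
#'
#' @param results an `slc_enrichment` data.frame.
#' @param graph the `ontology_graph` used for the enrichment.
#' @return `results` with the `most_specific` column filled in.
#' @export
most_specific_terms <- function(results, graph) {
  stopifnot(inherits(results, "slc_enrichment"),
            inherits(graph, "ontology_graph"))
  absent <- setdiff(results$term_id, graph$terms$term_id)
  if (length(absent))
    stop("term(s) absent from graph: ", paste(absent, collapse = ", "))
  results$most_specific <- FALSE
  sig <- results$term_id[results$significant]
  if (!length(sig)) return(results)
  g <- as_igraph(graph,
                 relations = setdiff(ALL_RELATIONS, "transports"))
  # reach[i, j] small: only among significant terms
  reach <- vapply(sig, function(s)
    sig %in% names(igraph::subcomponent(g, s, mode = "out")),
    logical(length(sig)))
  reach <- matrix(reach, nrow = length(sig),
                  dimnames = list(to = sig, from = sig))
  has_sig_descendant <- vapply(sig, function(t) {
    others <- setdiff(sig, t)
    any(reach[t, others])
  }, logical(1))
  results$most_specific[match(sig, results$term_id)] <- !has_sig_descendant
  results
}

#' Write enrichment results to TSV
#'
#' @param results an `slc_enrichment` data.frame (or a named list of them,
#'   one per condition, written in long format with a `condition` column).
#' @param path output file.
#' @return Invisibly, the written data.frame.
#' @export
write_enrichment <- function(results, path) {
  if (is.data.frame(results)) {
    out <- as.data.frame(results)
  } else {
    out <- do.call(rbind, lapply(names(results), function(cond) {
      df <- as.data.frame(results[[cond]])
      cbind(condition = cond, df, stringsAsFactors = FALSE)
    }))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
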