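#' Build the reduced substrate ontology from files
#'
#' Runs the construction chain: parse the OBO file, map the annotation's
#' cargo names to terms, extract the substrate-reachable subgraph, contract
#' tautomer/conjugate cycles, prune single-child non-substrate terms and
#' attach transporter nodes. Stage-by-stage term/edge counts are recorded so
#' the reduction can be audited.
#'
#' @param obo_path OBO ontology file.
#' @param annotation_path curated annotation TSV.
#' @param mapping_path optional offline mapping TSV (manual tier).
#' @param out_dir optional output directory; when given, the reduced
#'   ontology (OBO + edge TSV), per-transporter closures and a counts JSON
#'   are written there.
#' @param keep_orphans attach nodes for orphan transporters too.
#' @param merge,prune set `FALSE` to bypass a reduction step.
#' @return List with the final `graph`, `closures`, `mapping`, `annotation`
#'   and the `counts` record.
#' @export
build_ontology <- function(obo_path, annotation_path, mapping_path = NULL,
                           out_dir = NULL, keep_orphans = FALSE,
                           merge = TRUE, prune = TRUE) {
  annotation <- read_annotation(annotation_path)
  full <- parse_obo(obo_path)
  manual <- if (!is.null(mapping_path)) read_mapping(mapping_path) else NULL
  mapping <- map_substrates(annotation, full, manual)

  g <- extract_subgraph(full, unique(mapping$term_id))
  counts <- list(extracted = c(terms = nrow(g$terms), edges = nrow(g$edges)))
  if (merge) {
    g <- merge_equivalent_terms(g)
    counts$post_merge <- c(terms = nrow(g$terms), edges = nrow(g$edges))
    counts$merge_removed <- counts$extracted - counts$post_merge
  }
  if (prune) {
    g <- prune_single_child_terms(g)
    counts$post_prune <- c(terms = nrow(g$terms), edges = nrow(g$edges))
  }
  g <- attach_slc_terms(g, annotation, mapping, keep_orphans = keep_orphans)
  closures <- all_slc_closures(g)
  counts$final <- c(terms = sum(g$terms$namespace != "slc"),
                    edges = sum(g$edges$relation != "transports"),
                    slc_nodes = sum(g$terms$namespace == "slc"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_ontology_obo(g, file.path(out_dir, "reduced.obo"))
    write_edges_tsv(g, file.path(out_dir, "edges.tsv"))
    write_closures_tsv(closures, file.path(out_dir, "closures.tsv"))
    jsonlite::write_json(counts, file.path(out_dir, "counts.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(graph = g, closures = closures, mapping = mapping,
       annotation = annotation, counts = counts)
}

#' Enrichment analysis of one differential-expression table
#'
#' Wires the enrichment steps together for a built ontology: select the
#' upregulated transporters, the testable chemical-entity terms, run the
#' one-sided Fisher test with BH correction and flag the most specific
#' enriched terms.
#'
#' @param built result of [build_ontology()].
#' @param de_table data.frame (`gene`, `log2fc`, `fdr`).
#' @param lfc_min,fdr_max upregulation filter cutoffs.
#' @param min_slc,max_fraction testable-term filter.
#' @param alpha FDR significance cutoff for enriched terms.
#' @return An `slc_enrichment` data.frame (attribute `hits` carries the
#'   upregulated transporter set).
#' @export
enrich_condition <- function(built, de_table, lfc_min = 0.5,
                             fdr_max = 0.05, min_slc = 5,
                             max_fraction = 0.7, alpha = 0.05) {
  universe <- names(built$closures)[lengths(built$closures) > 0]
  hits <- filter_upregulated(de_table, universe, lfc_min, fdr_max)
  testable <- select_testable_terms(built$graph, min_slc, max_fraction,
                                    universe = universe)
  if (!length(testable)) stop("no testable terms under the current filter")
  t2s <- term_slc_map(built$closures)[testable]
  labels <- stats::setNames(built$graph$terms$label,
                            built$graph$terms$term_id)
  res <- fisher_enrichment(hits, universe, t2s, labels = labels,
                           alpha = alpha)
  res <- most_specific_terms(res, built$graph)
  attr(res, "hits") <- hits
  res
}

#' Run the end-to-end workflow
#'
#' Executes build-ontology, annotation and ontology summaries, and — when
#' the config provides them — per-condition enrichment and classifier
#' training plus orphan prediction. All artifacts land in `config$out_dir`
#' together with a run manifest (config snapshot, input digests, seed,
#' package version, timestamps). Any stage error aborts with the stage name;
#' artifacts of completed stages are preserved.
#'
#' @param config named list: `obo`, `annotation`, `mapping` (optional),
#'   `de_tables` (named character vector of TSV paths, optional), `fasta` +
#'   `topology` + `terms` (optional, for training), `seed`, `out_dir`, plus
#'   optional overrides `lfc_min`, `fdr_max`, `min_slc`, `max_fraction`,
#'   `alpha`, `min_precision`, `keep_orphans`, `merge`, `prune`, `grid`.
#' @return Invisibly, a list of stage results.
#' @export
run_pipeline <- function(config) {
  need <- c("obo", "annotation", "out_dir")
  missing_keys <- setdiff(need, names(config))
  if (length(missing_keys))
    stop("pipeline config error: missing key(s): ",
         paste(missing_keys, collapse = ", "))
  cfg <- utils::modifyList(
    list(mapping = NULL, de_tables = NULL, fasta = NULL, topology = NULL,
         terms = NULL, seed = 1L, lfc_min = 0.5, fdr_max = 0.05,
         min_slc = 5, max_fraction = 0.7, alpha = 0.05,
         min_precision = 0.75, keep_orphans = FALSE, merge = TRUE,
         prune = TRUE, grid = NULL),
    config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  results <- list()

  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  results$build <- stage("build-ontology",
    build_ontology(cfg$obo, cfg$annotation, cfg$mapping,
                   out_dir = cfg$out_dir, keep_orphans = cfg$keep_orphans,
                   merge = cfg$merge, prune = cfg$prune))

  results$stats <- stage("stats", {
    s_ann <- summarize_annotation(results$build$annotation)
    write_annotation_summary(
      s_ann, txt_path = file.path(cfg$out_dir, "annotation_summary.txt"),
      json_path = file.path(cfg$out_dir, "annotation_summary.json"))
    s_ont <- summarize_ontology(results$build$graph)
    jsonlite::write_json(
      lapply(unclass(s_ont), unclass),
      file.path(cfg$out_dir, "ontology_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(annotation = s_ann, ontology = s_ont)
  })

  if (!is.null(cfg$de_tables)) {
    results$enrich <- stage("enrich", {
      conds <- lapply(cfg$de_tables, function(p)
        enrich_condition(results$build, read_de_table(p),
                         lfc_min = cfg$lfc_min, fdr_max = cfg$fdr_max,
                         min_slc = cfg$min_slc,
                         max_fraction = cfg$max_fraction,
                         alpha = cfg$alpha))
      names(conds) <- names(cfg$de_tables)
      write_enrichment(conds, file.path(cfg$out_dir, "enrichment.tsv"))
      conds
    })
  }

  if (!is.null(cfg$fasta) && !is.null(cfg$topology) &&
        !is.null(cfg$terms)) {
    results$train <- stage("train", {
      prots <- read_topologies(cfg$fasta, cfg$topology)
      feats <- feature_matrix(prots)
      ann <- results$build$annotation
      trainable <- ann$slc_id[!ann$is_orphan &
                                ann$substrate_class != "accessory protein"]
      train_feats <- feats[rownames(feats) %in% trainable, , drop = FALSE]
      terms <- readLines(cfg$terms)
      terms <- terms[nzchar(terms)]
      specs <- train_classifiers(
        train_feats, results$build$closures, terms, seed = cfg$seed,
        grid = if (is.null(cfg$grid)) default_grid() else cfg$grid,
        min_precision = cfg$min_precision)
      utils::write.table(classifier_metrics(specs),
                         file.path(cfg$out_dir, "classifier_metrics.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      for (t in names(specs))
        write_classifier_spec(specs[[t]], file.path(
          cfg$out_dir, paste0("classifier_", gsub("[^A-Za-z0-9]", "_", t),
                              ".json")))
      list(specs = specs, features = feats)
    })

    results$predict <- stage("predict", {
      ann <- results$build$annotation
      orphans <- ann$slc_id[ann$is_orphan]
      feats <- results$train$features
      orphan_feats <- feats[rownames(feats) %in% orphans, , drop = FALSE]
      preds <- predict_orphans(results$train$specs, orphan_feats)
      utils::write.table(preds,
                         file.path(cfg$out_dir, "orphan_predictions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      preds
    })
  }

  manifest <- list(
    command = "run_pipeline",
    config = cfg[!vapply(cfg, is.null, logical(1)) &
                   !names(cfg) %in% "grid"],
    inputs = {
      paths <- unlist(cfg[c("obo", "annotation", "mapping", "fasta",
                            "topology", "terms")], use.names = TRUE)
      paths <- c(paths, unlist(cfg$de_tables))
      as.list(tools::md5sum(paths[file.exists(paths)]))
    },
    seed = cfg$seed,
    version = as.character(utils::packageVersion("slcsub")),
    started = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

#' Command-line entry point
#'
#' Subcommand dispatcher used by the `slcsub` executable script
#' (`inst/exec/slcsub`). Flags are `--key value` pairs mapped onto the
#' corresponding function arguments.
#'
#' Subcommands: `make-fixtures --seed N --preset small|medium --out DIR`;
#' `build-ontology --obo FILE --annotation FILE [--mapping FILE] --out DIR
#' [--keep-orphans] [--no-merge] [--no-prune]`; `stats --obo ... --annotation
#' ... --out DIR`; `enrich --obo ... --annotation ... [--mapping ...] --de
#' FILE[,FILE...] --out DIR`; `run-all --dir FIXTURE_DIR --seed N --out DIR`
#' (full workflow on a fixture directory, training included); `--version`.
#'
#' @param args character vector of command-line arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status, invisibly (0 on success).
#' @export
slc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1] %in% c("--help", "-h")) {
    message("usage: slcsub <make-fixtures|build-ontology|stats|enrich|run-all> [--flags]")
    return(invisible(0L))
  }
  if (args[1] == "--version") {
    message("slcsub ", as.character(utils::packageVersion("slcsub")))
    return(invisible(0L))
  }
  cmd <- args[1]
  flags <- parse_flags(args[-1])
  get <- function(key, default = NULL) {
    if (!is.null(flags[[key]])) flags[[key]] else default
  }
  status <- tryCatch({
    switch(cmd,
      "make-fixtures" = {
        spec <- fixture_preset(get("preset", "small"),
                               seed = as.integer(get("seed", "1")))
        write_fixture_set(spec, get("out", "fixtures"))
      },
      "build-ontology" = ,
      "stats" = {
        run_pipeline(list(
          obo = get("obo"), annotation = get("annotation"),
          mapping = get("mapping"), out_dir = get("out", "out"),
          keep_orphans = isTRUE(flags[["keep-orphans"]]),
          merge = !isTRUE(flags[["no-merge"]]),
          prune = !isTRUE(flags[["no-prune"]])))
      },
      "enrich" = {
        de <- strsplit(get("de", ""), ",", fixed = TRUE)[[1]]
        names(de) <- tools::file_path_sans_ext(basename(de))
        run_pipeline(list(
          obo = get("obo"), annotation = get("annotation"),
          mapping = get("mapping"), de_tables = de,
          lfc_min = as.numeric(get("lfc", "0.5")),
          fdr_max = as.numeric(get("fdr", "0.05")),
          min_slc = as.numeric(get("min-slc", "5")),
          max_fraction = as.numeric(get("max-frac", "0.7")),
          out_dir = get("out", "out")))
      },
      "run-all" = {
        d <- get("dir")
        if (is.null(d)) stop("run-all needs --dir FIXTURE_DIR")
        de <- file.path(d, "de_condition1.tsv")
        run_pipeline(list(
          obo = file.path(d, "toy.obo"),
          annotation = file.path(d, "annotation.tsv"),
          mapping = file.path(d, "mapping.tsv"),
          de_tables = c(condition1 = de),
          fasta = file.path(d, "proteins.fasta"),
          topology = file.path(d, "topology.tsv"),
          terms = file.path(d, "target_terms.txt"),
          seed = as.integer(get("seed", "1")),
          grid = data.frame(mtry = 20L, ntree = 300L,
                            classwt_mode = "unweighted",
                            stringsAsFactors = FALSE),
          out_dir = get("out", "out")))
      },
      stop("unknown subcommand: ", cmd))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      flags[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  flags
}
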