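#' Specification of a synthetic fixture set
#'
#' Deterministic, seeded generators stand in for every pipeline input: a toy
#' OBO ontology with seeded tautomer/conjugate 2-cycles and single-child
#' chains (known post-merge and post-prune counts), a curated-style
#' annotation table with a mapping file, differential-expression tables with
#' planted upregulation, and protein sequences whose residue composition
#' carries a planted class signal. Toy ontology ids use the `TOY:` prefix so
#' fixture artifacts can never be confused with real ChEBI ids.
#'
#' @param seed integer seed; identical specs give byte-identical outputs.
#' @param n_substrates number of substrate leaf terms.
#' @param n_parents number of chemical class terms (each gets >= 2 substrate
#'   children so it survives pruning).
#' @param n_roles number of role terms under the role root.
#' @param n_cycles number of seeded conjugate acid/base 2-cycles.
#' @param n_chains number of single-child chains.
#' @param chain_len chain length in edges; each chain has `chain_len - 1`
#'   prunable interior terms.
#' @param n_slc number of transporters in the annotation fixture.
#' @param orphan_fraction fraction of transporters without any cargo.
#' @param n_genes total genes in a differential-expression fixture.
#' @param de_effect planted log2 fold change for upregulated transporters.
#' @param class_signal compositional effect size for classifier positives
#'   (added to the transmembrane leucine sampling weight).
#' @param include_subatomic add a subatomic-particle branch reachable from
#'   one substrate, to exercise the exclusion rule.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_substrates = 20L, n_parents = 4L,
                         n_roles = 2L, n_cycles = 3L, n_chains = 2L,
                         chain_len = 4L, n_slc = 30L, orphan_fraction = 0.3,
                         n_genes = 400L, de_effect = 2.0,
                         class_signal = 0.25, include_subatomic = FALSE) {
  stopifnot(n_substrates >= 2L * n_parents, n_substrates >= 2L * n_roles,
            n_parents >= 2L, n_roles >= 2L,
            orphan_fraction >= 0, orphan_fraction <= 1,
            chain_len >= 2L, n_cycles >= 0L, n_chains >= 0L)
  if (n_cycles + n_chains > n_substrates)
    stop("fixture spec error: n_cycles + n_chains exceeds n_substrates")
  structure(as.list(environment()), class = "fixture_spec")
}

#' Preset fixture specifications
#'
#' `small` keeps everything hand-checkable; `medium` is sized for the
#' classifier-recovery experiments.
#'
#' @param preset `"small"` or `"medium"`.
#' @param seed integer seed.
#' @return A `fixture_spec`.
#' @export
fixture_preset <- function(preset = c("small", "medium"), seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
         small = fixture_spec(seed = seed),
         medium = fixture_spec(seed = seed, n_substrates = 40L,
                               n_parents = 6L, n_roles = 3L, n_cycles = 5L,
                               n_chains = 3L, chain_len = 5L, n_slc = 120L,
                               orphan_fraction = 0.25, n_genes = 800L))
}

toy_id <- function(i) sprintf("TOY:%07d", i)

#' Generate a toy OBO ontology with known reduction ground truth
#'
#' Skeleton: a chemical-entity root with `n_parents` class terms, each the
#' `is_a` parent of several substrate leaves; a role root with `n_roles`
#' role terms receiving `has_role` edges from every substrate. On top of the
#' skeleton, `n_cycles` substrates get a conjugate partner (reciprocal
#' conjugate acid/base edges plus a duplicate `is_a` to the parent: merging
#' removes exactly 1 term and 3 relationships per cycle) and `n_chains`
#' substrates get a single-child chain to the root (pruning removes exactly
#' `chain_len - 1` terms and edges per chain). Every other internal term has
#' at least two distinct children, so the printed ground-truth counts are
#' exact.
#'
#' @param spec a [fixture_spec()].
#' @param path where to write the OBO file (`NULL` for a tempfile).
#' @return List with `path`, the `truth` record (term/edge counts at each
#'   reduction stage, substrate ids/labels, per-parent membership) and
#'   `spec`.
#' @export
make_toy_obo <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (is.null(path)) path <- tempfile(fileext = ".obo")

  next_id <- 0L
  fresh <- function() { next_id <<- next_id + 1L; toy_id(next_id) }

  ce_root <- fresh(); role_root <- fresh()
  parents <- vapply(seq_len(spec$n_parents), function(i) fresh(),
                    character(1))
  roles <- vapply(seq_len(spec$n_roles), function(i) fresh(), character(1))
  subs <- vapply(seq_len(spec$n_substrates), function(i) fresh(),
                 character(1))

  terms <- list()
  add_term <- function(id, label, parents_isa = character(0),
                       rels = character(0), syn = NULL) {
    terms[[id]] <<- list(id = id, label = label, isa = parents_isa,
                         rels = rels, syn = syn)
  }
  add_term(ce_root, "chemical entity")
  add_term(role_root, "role")
  for (i in seq_along(parents))
    add_term(parents[i], sprintf("toyclass-%02d", i), ce_root)
  for (i in seq_along(roles))
    add_term(roles[i], sprintf("toyrole-%d", i), role_root)

  sub_parent <- parents[(seq_along(subs) - 1L) %% spec$n_parents + 1L]
  sub_role <- roles[(seq_along(subs) - 1L) %% spec$n_roles + 1L]
  sub_labels <- sprintf("toychem-%03d", seq_along(subs))
  for (i in seq_along(subs))
    add_term(subs[i], sub_labels[i], sub_parent[i],
             rels = paste("has_role", sub_role[i]),
             syn = if (i <= 2L) sprintf("syn-toychem-%03d", i) else NULL)

  n_edges <- spec$n_parents + spec$n_roles + 2L * spec$n_substrates

  # conjugate 2-cycles on the first n_cycles substrates
  cycle_partners <- character(0)
  for (j in seq_len(spec$n_cycles)) {
    pid <- fresh(); sid <- subs[j]
    cycle_partners <- c(cycle_partners, pid)
    add_term(pid, sprintf("conjugate base of %s", sub_labels[j]),
             sub_parent[j],
             rels = paste("is_conjugate_acid_of", sid))
    terms[[sid]]$rels <- c(terms[[sid]]$rels,
                           paste("is_conjugate_base_of", pid))
    n_edges <- n_edges + 3L
  }

  # single-child chains from the next n_chains substrates up to the root
  chain_interiors <- list()
  for (j in seq_len(spec$n_chains)) {
    sid <- subs[spec$n_cycles + j]
    interior <- vapply(seq_len(spec$chain_len - 1L), function(i) fresh(),
                       character(1))
    chain_interiors[[j]] <- interior
    below <- sid
    for (i in seq_along(interior)) {
      add_term(interior[i], sprintf("toychain-%d-%d", j, i))
      terms[[below]]$isa <- c(terms[[below]]$isa, interior[i])
      below <- interior[i]
    }
    terms[[below]]$isa <- c(terms[[below]]$isa, ce_root)
    n_edges <- n_edges + spec$chain_len
  }

  if (isTRUE(spec$include_subatomic)) {
    sp <- fresh(); el <- fresh()
    add_term(sp, "subatomic particle", ce_root)
    add_term(el, "toy electron", sp)
    # last substrate also sits under the subatomic branch
    terms[[subs[spec$n_substrates]]]$isa <-
      c(terms[[subs[spec$n_substrates]]]$isa, el)
  }

  lines <- c("format-version: 1.2", "ontology: toy", "")
  for (t in terms) {
    lines <- c(lines, "[Term]", paste0("id: ", t$id),
               paste0("name: ", t$label))
    if (!is.null(t$syn))
      lines <- c(lines, sprintf("synonym: \"%s\" EXACT []", t$syn))
    for (p in t$isa) lines <- c(lines, paste0("is_a: ", p))
    for (r in t$rels) lines <- c(lines, paste0("relationship: ", r))
    lines <- c(lines, "")
  }
  lines <- c(lines, "[Typedef]", "id: has_role", "name: has role", "",
             "[Typedef]", "id: is_conjugate_acid_of",
             "name: is conjugate acid of", "",
             "[Typedef]", "id: is_conjugate_base_of",
             "name: is conjugate base of", "")
  writeLines(lines, path)

  n_terms <- length(terms)
  n_extract_terms <- 2L + spec$n_parents + spec$n_roles +
    spec$n_substrates + spec$n_cycles +
    spec$n_chains * (spec$chain_len - 1L)
  n_extract_edges <- n_edges
  truth <- list(
    n_terms_file = n_terms,
    n_terms_extracted = n_extract_terms,
    n_edges_extracted = n_extract_edges,
    n_terms_post_merge = n_extract_terms - spec$n_cycles,
    n_edges_post_merge = n_extract_edges - 3L * spec$n_cycles,
    n_terms_post_prune = n_extract_terms - spec$n_cycles -
      spec$n_chains * (spec$chain_len - 1L),
    n_edges_post_prune = n_extract_edges - 3L * spec$n_cycles -
      spec$n_chains * (spec$chain_len - 1L),
    substrate_ids = subs, substrate_labels = sub_labels,
    substrate_parent = stats::setNames(sub_parent, subs),
    parent_ids = parents, role_ids = roles,
    ce_root = ce_root, role_root = role_root,
    cycle_partners = cycle_partners, chain_interiors = chain_interiors)
  list(path = path, truth = truth, spec = spec)
}

#' Generate an annotation table and mapping file over a toy ontology
#'
#' Distributes every substrate leaf of the toy ontology over the non-orphan
#' transporters (so mapping and extraction cover all leaves), assigns each
#' record a substrate class consistent with its first cargo's parent term, a
#' transport mechanism (records with a coupled ion alternate
#' symporter/antiporter, the rest are uniporters) and one of three
#' localization labels. Two cargo names use alternate spellings resolved
#' only through the manual mapping tier, so the fallback path is exercised
#' end to end.
#'
#' @param spec a [fixture_spec()].
#' @param obo result of [make_toy_obo()] for the same spec.
#' @return List with `annotation` (an `slc_annotation`), `manual_map`
#'   (data.frame for the unresolvable names) and `truth` (orphan count,
#'   cargo assignment).
#' @export
make_annotation_fixture <- function(spec, obo) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 1000L)
  truth <- obo$truth
  n_orphan <- round(spec$orphan_fraction * spec$n_slc)
  n_cargo <- spec$n_slc - n_orphan
  if (n_cargo < 1L) stop("fixture spec error: no cargo-bearing transporters")

  slc_ids <- sprintf("SLCT%02dA%d", (seq_len(spec$n_slc) - 1L) %/% 5L + 1L,
                     (seq_len(spec$n_slc) - 1L) %% 5L + 1L)
  family <- sub("A[0-9]+$", "", slc_ids)
  is_orphan <- c(rep(FALSE, n_cargo), rep(TRUE, n_orphan))

  # round-robin so every substrate leaf is some transporter's cargo; if
  # there are more cargo-bearing transporters than leaves, leaves are reused
  leaves <- truth$substrate_labels
  assign_to <- rep(seq_len(n_cargo), length.out = length(leaves))
  cargo_sets <- split(leaves, factor(assign_to, levels = seq_len(n_cargo)))
  empty <- which(lengths(cargo_sets) == 0L)
  for (i in empty)
    cargo_sets[[i]] <- leaves[(i - 1L) %% length(leaves) + 1L]
  # a second cargo per record so coupled ions and mechanisms get populated
  for (i in seq_len(n_cargo))
    cargo_sets[[i]] <- unique(c(cargo_sets[[i]],
                                leaves[(i * 7L) %% length(leaves) + 1L]))

  # two names resolvable only via the manual tier
  alt_names <- character(0); manual_rows <- list()
  if (length(leaves) >= 4L) {
    alt_idx <- c(3L, 4L)   # avoid the synonym-bearing leaves 1:2
    alt_names <- paste0("alt-", leaves[alt_idx])
    for (k in seq_along(alt_idx)) {
      manual_rows[[k]] <- data.frame(
        substrate_name = alt_names[k],
        term_id = truth$substrate_ids[alt_idx[k]],
        method = "manual", stringsAsFactors = FALSE)
    }
  }
  rename_lut <- stats::setNames(alt_names,
                                leaves[c(3L, 4L)][seq_along(alt_names)])

  class_pool <- c("amino acid", "ion", "carbohydrate", "lipid",
                  "nucleoside/nucleotide", "vitamin", "peptide",
                  "heavy metal", "other")
  parent_class <- stats::setNames(
    class_pool[(seq_along(truth$parent_ids) - 1L) %% length(class_pool) + 1L],
    truth$parent_ids)
  loc_pool <- c("plasma membrane", "mitochondria", "lysosome")

  rows <- vector("list", spec$n_slc)
  for (i in seq_len(spec$n_slc)) {
    if (is_orphan[i]) {
      rows[[i]] <- data.frame(slc_id = slc_ids[i], family = family[i],
                              substrates = "", coupled_ions = "",
                              mechanism = "unknown",
                              substrate_class = "orphan",
                              localizations = "", stringsAsFactors = FALSE)
      next
    }
    cargo <- cargo_sets[[as.character(i)]]
    cargo_out <- ifelse(cargo %in% names(rename_lut),
                        rename_lut[cargo], cargo)
    with_ion <- length(cargo_out) >= 2L && i %% 3L != 0L
    ions <- if (with_ion) cargo_out[length(cargo_out)] else character(0)
    sub_only <- if (with_ion) cargo_out[-length(cargo_out)] else cargo_out
    mech <- if (with_ion) c("symporter", "antiporter")[i %% 2L + 1L]
            else "uniporter"
    first_leaf <- cargo[1]
    parent <- truth$substrate_parent[
      truth$substrate_ids[match(first_leaf, truth$substrate_labels)]]
    rows[[i]] <- data.frame(
      slc_id = slc_ids[i], family = family[i],
      substrates = paste(sub_only, collapse = ";"),
      coupled_ions = paste(ions, collapse = ";"),
      mechanism = mech,
      substrate_class = unname(parent_class[parent]),
      localizations = paste(
        loc_pool[seq_len(1L + i %% 2L)], collapse = ";"),
      stringsAsFactors = FALSE)
  }
  raw <- do.call(rbind, rows)
  annotation <- as_annotation(raw, provenance = "synthetic fixture")
  manual_map <- if (length(manual_rows)) do.call(rbind, manual_rows) else
    data.frame(substrate_name = character(0), term_id = character(0),
               method = character(0), stringsAsFactors = FALSE)
  list(annotation = annotation, manual_map = manual_map,
       truth = list(n_orphan = n_orphan, n_cargo = n_cargo,
                    cargo_sets = cargo_sets, slc_ids = slc_ids,
                    orphan_ids = slc_ids[is_orphan],
                    alt_names = alt_names))
}

#' Generate a differential-expression fixture with planted upregulation
#'
#' All transporters whose closure contains `target_term` receive
#' `log2fc = de_effect` with a tiny raw p-value; every other gene (the
#' remaining transporters plus background filler genes) draws a null log2
#' fold change (centred normal, sd 0.2) and a uniform raw p-value. The `fdr`
#' column is produced by BH-adjusting the whole table, so it has the same
#' provenance as real DE output. With `de_effect = 0` nothing is planted and
#' the table is pure null.
#'
#' @param spec a [fixture_spec()].
#' @param target_term term id whose annotated transporters are upregulated.
#' @param closures named list from [all_slc_closures()].
#' @param all_slc_ids all transporter symbols of the annotation fixture.
#' @param seed optional seed override (defaults to `spec$seed`).
#' @return List with `de` (data.frame `gene`, `log2fc`, `fdr`) and `truth`
#'   (`planted` hit set).
#' @export
make_de_fixture <- function(spec, target_term, closures, all_slc_ids,
                            seed = spec$seed) {
  stopifnot(inherits(spec, "fixture_spec"))
  planted <- if (spec$de_effect > 0)
    names(closures)[vapply(closures, function(cl) target_term %in% cl,
                           logical(1))] else character(0)
  if (spec$de_effect > 0 && !length(planted))
    stop("fixture spec error: target term annotates no transporter")
  set.seed(seed + 2000L)
  n_bg <- max(spec$n_genes - length(all_slc_ids), 0L)
  genes <- c(all_slc_ids, sprintf("GENE%04d", seq_len(n_bg)))
  log2fc <- stats::rnorm(length(genes), 0, 0.2)
  p_raw <- stats::runif(length(genes))
  idx <- match(planted, genes)
  log2fc[idx] <- spec$de_effect
  p_raw[idx] <- 1e-10 * stats::runif(length(idx))
  de <- data.frame(gene = genes, log2fc = log2fc,
                   fdr = stats::p.adjust(p_raw, method = "BH"),
                   stringsAsFactors = FALSE)
  list(de = de, truth = list(planted = planted, target_term = target_term))
}

AA_BACKGROUND <- c(A = 0.08, C = 0.02, D = 0.05, E = 0.06, F = 0.04,
                   G = 0.07, H = 0.02, I = 0.06, K = 0.05, L = 0.10,
                   M = 0.02, N = 0.04, P = 0.05, Q = 0.04, R = 0.05,
                   S = 0.07, T = 0.05, V = 0.07, W = 0.01, Y = 0.03)

sample_peptide <- function(n, probs) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

#' Generate protein sequences and topologies with a planted class signal
#'
#' Multi-pass membrane-protein-like architectures: an optional signal
#' peptide, then alternating cytoplasmic loops, 21-residue transmembrane
#' helices and non-cytoplasmic loops. Residues draw from a fixed background
#' composition; for proteins in `positive_ids` the transmembrane leucine
#' sampling weight is raised by `class_signal` (renormalized), planting a
#' compositional difference that the feature extractor can expose.
#'
#' @param spec a [fixture_spec()].
#' @param slc_ids proteins to generate.
#' @param positive_ids subset carrying the planted signal.
#' @param seed optional seed override (defaults to `spec$seed`).
#' @return List with `proteins` (named list of [protein_topology()]),
#'   and `truth` (`positive_ids`, `signal`).
#' @export
make_sequence_fixture <- function(spec, slc_ids, positive_ids = character(0),
                                  seed = spec$seed) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(seed + 3000L)
  probs_bg <- AA_BACKGROUND
  probs_pos <- AA_BACKGROUND
  probs_pos["L"] <- probs_pos["L"] + spec$class_signal
  probs_pos <- probs_pos / sum(probs_pos)

  proteins <- lapply(slc_ids, function(id) {
    tm_probs <- if (id %in% positive_ids) probs_pos else probs_bg
    n_tm <- sample(8:12, 1)
    has_sp <- stats::runif(1) < 0.5
    segs <- list(); seq_parts <- character(0); pos <- 1L
    add_seg <- function(len, kind, probs) {
      seq_parts <<- c(seq_parts, sample_peptide(len, probs))
      segs[[length(segs) + 1L]] <<- data.frame(
        start = pos, end = pos + len - 1L, kind = kind,
        stringsAsFactors = FALSE)
      pos <<- pos + len
    }
    if (has_sp) add_seg(sample(15:25, 1), "signal_peptide", probs_bg)
    inside <- TRUE   # N-terminus cytoplasmic
    for (t in seq_len(n_tm)) {
      add_seg(sample(10:40, 1),
              if (inside) "cytoplasmic" else "non_cytoplasmic", probs_bg)
      add_seg(21L, "transmembrane", tm_probs)
      inside <- !inside
    }
    add_seg(sample(10:40, 1),
            if (inside) "cytoplasmic" else "non_cytoplasmic", probs_bg)
    protein_topology(id, paste(seq_parts, collapse = ""),
                     do.call(rbind, segs))
  })
  names(proteins) <- slc_ids
  list(proteins = proteins,
       truth = list(positive_ids = positive_ids,
                    signal = spec$class_signal))
}

#' Write fixture files to a directory
#'
#' Serializes a complete fixture set in the exact external formats the
#' consuming modules read: OBO ontology, annotation TSV, mapping TSV, DE
#' TSV, FASTA and topology TSV.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list of the written paths and the truth records.
#' @export
write_fixture_set <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  obo <- make_toy_obo(spec, file.path(out_dir, "toy.obo"))
  ann <- make_annotation_fixture(spec, obo)
  write_annotation_tsv(ann$annotation, file.path(out_dir, "annotation.tsv"))
  utils::write.table(ann$manual_map, file.path(out_dir, "mapping.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  graph <- parse_obo(obo$path)
  mapping <- map_substrates(ann$annotation, graph, ann$manual_map)
  reduced <- prune_single_child_terms(merge_equivalent_terms(
    extract_subgraph(graph, unique(mapping$term_id))))
  withslc <- attach_slc_terms(reduced, ann$annotation, mapping)
  closures <- all_slc_closures(withslc)

  # plant upregulation of the transporters under the first class term
  target <- obo$truth$parent_ids[1]
  de <- make_de_fixture(spec, target, closures, ann$truth$slc_ids)
  utils::write.table(de$de, file.path(out_dir, "de_condition1.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  positives <- names(closures)[vapply(closures, function(cl)
    target %in% cl, logical(1))]
  seqs <- make_sequence_fixture(spec, ann$truth$slc_ids, positives)
  write_sequence_fixture(seqs$proteins, file.path(out_dir, "proteins.fasta"),
                         file.path(out_dir, "topology.tsv"))
  writeLines(target, file.path(out_dir, "target_terms.txt"))

  invisible(list(dir = out_dir, obo = obo, annotation = ann, de = de,
                 sequences = seqs, target_term = target,
                 closures = closures))
}

#' Write an annotation table back to TSV
#'
#' @param table an `slc_annotation`.
#' @param path output path.
#' @param list_sep separator for list-valued cells.
#' @return Invisibly, `path`.
#' @export
write_annotation_tsv <- function(table, path, list_sep = ";") {
  stopifnot(inherits(table, "slc_annotation"))
  join <- function(col) vapply(col, paste, character(1), collapse = list_sep)
  out <- data.frame(slc_id = table$slc_id, family = table$family,
                    substrates = join(table$substrates),
                    coupled_ions = join(table$coupled_ions),
                    mechanism = table$mechanism,
                    substrate_class = table$substrate_class,
                    localizations = join(table$localizations),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sequence fixtures as FASTA plus topology TSV
#'
#' @param proteins named list of [protein_topology()].
#' @param fasta_path,topology_path output paths.
#' @return Invisibly, the paths.
#' @export
write_sequence_fixture <- function(proteins, fasta_path, topology_path) {
  seqs <- vapply(proteins, `[[`, character(1), "sequence")
  ss <- Biostrings::AAStringSet(seqs)
  names(ss) <- names(proteins)
  Biostrings::writeXStringSet(ss, fasta_path)
  topo <- do.call(rbind, lapply(proteins, function(p)
    cbind(slc_id = p$slc_id, p$domains)))
  utils::write.table(topo, topology_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta_path, topology_path))
}
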