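# Independent oracles used across the suite. These deliberately avoid the
# code paths (igraph traversals, phyper, vectorized sweeps) that the package
# itself uses.

# breadth-first reachability over a raw edge list; returns the set of nodes
# reachable from `start` via directed edges, excluding `start` itself
bfs_reachable <- function(edges, start) {
  adj <- split(edges$target, edges$source)
  seen <- character(0)
  queue <- start
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    nb <- setdiff(adj[[v]], seen)
    nb <- setdiff(nb, start)
    seen <- c(seen, nb)
    queue <- c(queue, nb)
  }
  unique(seen)
}

# boolean transitive closure by repeated matrix squaring (reflexive)
transitive_closure <- function(ids, edges) {
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  ed <- edges[edges$source %in% ids & edges$target %in% ids, , drop = FALSE]
  if (nrow(ed)) A[cbind(ed$source, ed$target)] <- TRUE
  R <- A | diag(TRUE, n)
  repeat {
    R2 <- R | ((R %*% R) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R
}

# one-sided over-representation p by explicit hypergeometric summation
hyper_oracle <- function(a, b, c, d) {
  N <- a + b + c + d; K <- a + b; M <- a + c
  if (K == 0 || M == 0) return(1)
  ks <- a:min(K, M)
  sum(exp(lchoose(M, ks) + lchoose(N - M, K - ks) - lchoose(N, K)))
}

# exhaustive threshold sweep: loops over every distinct score cut-point and
# recomputes precision/recall from scratch
threshold_sweep_oracle <- function(scores, labels, min_precision) {
  s <- pmin(pmax(scores, 1e-6), 1 - 1e-6)
  cand <- sort(unique(s))
  best <- NULL
  for (t in cand) {
    call <- s >= t
    tp <- sum(call & labels); fp <- sum(call & !labels)
    fn <- sum(!call & labels)
    prec <- if (tp + fp) tp / (tp + fp) else 0
    rec <- if (tp + fn) tp / (tp + fn) else 0
    row <- c(t = t, prec = prec, rec = rec)
    if (prec >= min_precision) {
      if (is.null(best) || rec > best["rec"] ||
            (rec == best["rec"] && prec > best["prec"]) ||
            (rec == best["rec"] && prec == best["prec"] && t > best["t"]))
        best <- row
    }
  }
  if (is.null(best)) {  # fallback: precision-maximizing, then higher t
    for (t in cand) {
      call <- s >= t
      tp <- sum(call & labels); fp <- sum(call & !labels)
      prec <- if (tp + fp) tp / (tp + fp) else 0
      row <- c(t = t, prec = prec, rec = NA)
      if (is.null(best) || prec > best["prec"] ||
            (prec == best["prec"] && t > best["t"]))
        best <- row
    }
  }
  unname(best["t"])
}

# a random DAG ontology_graph with randomly marked substrate nodes;
# edges always point from higher index to lower ("more general") index,
# guaranteeing acyclicity
random_dag_graph <- function(n, p_edge = 0.15, p_substrate = 0.3,
                             seed = 1) {
  set.seed(seed)
  ids <- sprintf("N%02d", seq_len(n))
  src <- character(0); tgt <- character(0)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (stats::runif(1) < p_edge) {
        src <- c(src, ids[i]); tgt <- c(tgt, ids[j])
      }
    }
  }
  terms <- data.frame(term_id = ids, label = ids,
                      namespace = "chemical_entity",
                      is_substrate_node = stats::runif(n) < p_substrate,
                      stringsAsFactors = FALSE)
  edges <- data.frame(source = src, target = tgt,
                      relation = sample(c("is_a", "has_role"),
                                        length(src), replace = TRUE),
                      stringsAsFactors = FALSE)
  ontology_graph(terms, edges)
}

# tiny OBO files written inline for parser tests
write_tiny_obo <- function(lines) {
  path <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", lines), path)
  path
}

# minimal in-memory annotation table
tiny_annotation <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  read_annotation(path)
}
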