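AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

DOMAIN_KINDS <- c("cytoplasmic", "non_cytoplasmic", "transmembrane",
                  "signal_peptide")

#' Construct a protein topology record
#'
#' Holds an amino-acid sequence (20-letter alphabet; `X` tolerated as
#' unknown residue) and its topological domain segmentation: 1-based
#' inclusive `(start, end, kind)` ranges with kind one of `cytoplasmic`,
#' `non_cytoplasmic`, `transmembrane`, `signal_peptide`. Segments may leave
#' gaps but must not overlap.
#'
#' @param slc_id transporter gene symbol.
#' @param sequence amino-acid string.
#' @param domains data.frame with columns `start`, `end`, `kind`.
#' @return An object of class `protein_topology`.
#' @export
protein_topology <- function(slc_id, sequence, domains) {
  sequence <- toupper(sequence)
  bad_res <- setdiff(unique(strsplit(sequence, "")[[1]]),
                     c(AMINO_ACIDS, "X"))
  if (length(bad_res))
    stop("sequence error for ", slc_id, ": residue(s) outside alphabet: ",
         paste(bad_res, collapse = ", "))
  domains <- as.data.frame(domains, stringsAsFactors = FALSE)
  stopifnot(all(c("start", "end", "kind") %in% names(domains)))
  domains$start <- as.integer(domains$start)
  domains$end <- as.integer(domains$end)
  bad_kind <- setdiff(unique(domains$kind), DOMAIN_KINDS)
  if (length(bad_kind))
    stop("topology error for ", slc_id, ": unknown domain kind(s): ",
         paste(bad_kind, collapse = ", "))
  n <- nchar(sequence)
  if (nrow(domains)) {
    if (any(domains$start < 1L | domains$end > n |
              domains$start > domains$end))
      stop("topology error for ", slc_id,
           ": domain coordinates outside 1..", n)
    o <- order(domains$start)
    if (any(domains$start[o][-1] <= domains$end[o][-nrow(domains)]))
      stop("topology error for ", slc_id, ": overlapping domains")
  }
  structure(list(slc_id = slc_id, sequence = sequence, domains = domains),
            class = "protein_topology")
}

#' Read protein topologies from FASTA plus a topology table
#'
#' @param fasta_path FASTA file of amino-acid sequences; record names must be
#'   transporter symbols.
#' @param topology_path TSV with columns `slc_id`, `start`, `end`, `kind`
#'   (UniProt-style 1-based inclusive ranges).
#' @return Named list of [protein_topology()] objects.
#' @export
read_topologies <- function(fasta_path, topology_path) {
  seqs <- read_fasta(fasta_path)
  topo <- utils::read.delim(topology_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, quote = "")
  need <- c("slc_id", "start", "end", "kind")
  missing_cols <- setdiff(need, names(topo))
  if (length(missing_cols))
    stop("topology schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  no_seq <- setdiff(unique(topo$slc_id), names(seqs))
  if (length(no_seq))
    stop("topology references sequence(s) absent from FASTA: ",
         paste(no_seq, collapse = ", "))
  out <- lapply(names(seqs), function(id)
    protein_topology(id, seqs[[id]],
                     topo[topo$slc_id == id, c("start", "end", "kind"),
                          drop = FALSE]))
  names(out) <- names(seqs)
  out
}

read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readAAStringSet(path)
  out <- as.list(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Feature names of the sequence-feature scheme
#'
#' @return Character vector giving the fixed feature order: per domain kind,
#'   20 amino-acid frequencies, segment count, residue count and mean segment
#'   length, plus the N-glycosylation sequon count of the non-cytoplasmic
#'   domain.
#' @export
feature_names <- function() {
  per_domain <- unlist(lapply(DOMAIN_KINDS, function(k)
    c(paste0(k, ".freq_", AMINO_ACIDS),
      paste0(k, c(".n_segments", ".n_residues", ".mean_segment_length")))))
  c(per_domain, "non_cytoplasmic.n_glyc_sequons")
}

# overlapping N-glycosylation sequons N-[^P]-[S/T] in one segment string
count_sequons <- function(s) {
  if (nchar(s) < 3) return(0L)
  m <- gregexpr("N(?=[^P][ST])", s, perl = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

#' Extract sequence-derived features for one protein
#'
#' For each of the four topological domain kinds (residues pooled across all
#' segments of that kind): the 20 amino-acid frequencies (fractions of the
#' pooled standard residues, summing to 1 when any exist and all zero when
#' the domain is absent; `X` residues count toward the residue total but
#' carry no frequency mass), the number of segments, the total
#' residue count and the mean segment length. N-glycosylation sequons
#' (`N-[^P]-[S/T]`, overlapping matches, scanned within each segment) are
#' counted in the non-cytoplasmic domain only, where glycosylation occurs.
#'
#' @param prot a [protein_topology()].
#' @return Named numeric vector in the fixed [feature_names()] order.
#' @export
extract_features <- function(prot) {
  stopifnot(inherits(prot, "protein_topology"))
  out <- stats::setNames(numeric(length(feature_names())), feature_names())
  for (k in DOMAIN_KINDS) {
    seg <- prot$domains[prot$domains$kind == k, , drop = FALSE]
    if (!nrow(seg)) next
    pieces <- substring(prot$sequence, seg$start, seg$end)
    residues <- strsplit(paste(pieces, collapse = ""), "")[[1]]
    n_res <- length(residues)
    freqs <- table(factor(residues, levels = AMINO_ACIDS))
    n_std <- sum(freqs)   # X residues carry no frequency mass
    if (n_std > 0)
      out[paste0(k, ".freq_", AMINO_ACIDS)] <- as.numeric(freqs) / n_std
    out[paste0(k, ".n_segments")] <- nrow(seg)
    out[paste0(k, ".n_residues")] <- n_res
    out[paste0(k, ".mean_segment_length")] <- mean(seg$end - seg$start + 1)
    if (k == "non_cytoplasmic")
      out["non_cytoplasmic.n_glyc_sequons"] <-
        sum(vapply(pieces, count_sequons, integer(1)))
  }
  out
}

#' Feature matrix for a set of proteins
#'
#' @param prots list of [protein_topology()] objects.
#' @return Numeric matrix, one row per protein (rownames = slc_id), columns
#'   in [feature_names()] order.
#' @export
feature_matrix <- function(prots) {
  if (!length(prots)) {
    m <- matrix(numeric(0), nrow = 0, ncol = length(feature_names()))
    colnames(m) <- feature_names()
    return(m)
  }
  m <- t(vapply(prots, extract_features,
                numeric(length(feature_names()))))
  rownames(m) <- vapply(prots, `[[`, character(1), "slc_id")
  m
}
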