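#' Controlled vocabularies for the curated SLC annotation
#'
#' Eleven substrate classes (exactly one per transporter) and four transport
#' mechanisms. "heavy metal" covers divalent/trivalent trace-metal cations;
#' "other" collects substrates fitting none of the remaining classes.
#'
#' @name slc_vocabularies
NULL

#' @rdname slc_vocabularies
#' @export
SUBSTRATE_CLASSES <- c("accessory protein", "amino acid", "carbohydrate",
                       "ion", "lipid", "heavy metal", "nucleoside/nucleotide",
                       "orphan", "peptide", "vitamin", "other")

#' @rdname slc_vocabularies
#' @export
TRANSPORT_MECHANISMS <- c("symporter", "antiporter", "uniporter", "unknown")

REQUIRED_ANNOTATION_COLUMNS <- c("slc_id", "family", "substrates",
                                 "coupled_ions", "mechanism",
                                 "substrate_class", "localizations")

is_unknown_cell <- function(x) {
  x <- trimws(x)
  is.na(x) | x == "" | tolower(x) %in% c("unknown", "na")
}

split_list_cell <- function(x, list_sep) {
  if (is_unknown_cell(x)) return(character(0))
  parts <- trimws(strsplit(x, list_sep, fixed = TRUE)[[1]])
  parts[nzchar(parts)]
}

#' Read a curated SLC annotation table
#'
#' Loads one row per solute carrier from delimited text: gene symbol, family,
#' substrates, coupled ions, transport mechanism, substrate class and
#' subcellular localizations. List-valued cells use a secondary separator.
#' Empty cells, `NA` and `unknown` (any case) all encode missing knowledge.
#'
#' A transporter is an orphan iff it has neither substrates nor coupled ions;
#' orphan rows must carry the class `orphan` (or `accessory protein`, the two
#' non-transporting family members counted among the orphans), and rows with
#' annotated cargo must not be classed `orphan`.
#'
#' @param path path to a delimited text file with a header row.
#' @param sep field delimiter (default tab).
#' @param list_sep separator inside list-valued cells (default `";"`).
#' @param provenance free-text source descriptor stored on the result.
#' @return A data.frame of class `slc_annotation` with list-columns
#'   `substrates`, `coupled_ions`, `localizations` and a logical `is_orphan`.
#' @export
read_annotation <- function(path, sep = "\t", list_sep = ";",
                            provenance = path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(0),
                           stringsAsFactors = FALSE, quote = "")
  missing_cols <- setdiff(REQUIRED_ANNOTATION_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("annotation schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!nrow(raw)) stop("annotation table is empty")
  as_annotation(raw, list_sep = list_sep, provenance = provenance)
}

# validate a character data.frame and build the slc_annotation object
as_annotation <- function(raw, list_sep = ";", provenance = "in-memory") {
  slc_id <- trimws(raw$slc_id)
  dup <- unique(slc_id[duplicated(slc_id)])
  if (length(dup))
    stop("annotation integrity error: duplicate slc_id: ",
         paste(dup, collapse = ", "))

  cls <- tolower(trimws(raw$substrate_class))
  bad <- which(!cls %in% SUBSTRATE_CLASSES)
  if (length(bad))
    stop("annotation vocabulary error: substrate_class outside the ",
         length(SUBSTRATE_CLASSES), "-value vocabulary in row(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(unique(raw$substrate_class[bad]), collapse = "; "))

  mech <- tolower(trimws(raw$mechanism))
  mech[is_unknown_cell(mech)] <- "unknown"
  bad_m <- which(!mech %in% TRANSPORT_MECHANISMS)
  if (length(bad_m))
    stop("annotation vocabulary error: mechanism outside vocabulary in row(s) ",
         paste(bad_m, collapse = ", "))

  substrates <- lapply(raw$substrates, split_list_cell, list_sep = list_sep)
  ions <- lapply(raw$coupled_ions, split_list_cell, list_sep = list_sep)
  locs <- lapply(raw$localizations, split_list_cell, list_sep = list_sep)
  is_orphan <- lengths(substrates) == 0L & lengths(ions) == 0L

  viol_orphan <- which(is_orphan & !cls %in% c("orphan", "accessory protein"))
  if (length(viol_orphan))
    stop("annotation integrity error: row(s) without any cargo must be ",
         "classed 'orphan' (or 'accessory protein'): ",
         paste(viol_orphan, collapse = ", "))
  viol_cargo <- which(!is_orphan & cls == "orphan")
  if (length(viol_cargo))
    stop("annotation integrity error: row(s) with annotated cargo classed ",
         "'orphan': ", paste(viol_cargo, collapse = ", "))

  out <- data.frame(slc_id = slc_id, family = trimws(raw$family),
                    mechanism = mech, substrate_class = cls,
                    stringsAsFactors = FALSE)
  out$substrates <- substrates
  out$coupled_ions <- ions
  out$localizations <- locs
  out$is_orphan <- is_orphan
  attr(out, "provenance") <- provenance
  class(out) <- c("slc_annotation", "data.frame")
  out
}

#' Distinct cargo names of an annotation table
#'
#' Union of substrates and coupled ions, deduplicated by case-insensitive
#' exact match after whitespace trimming; the first-seen spelling is kept.
#' No chemical normalization is applied at this stage — name unification
#' happens later through the ontology mapping.
#'
#' @param table an `slc_annotation`.
#' @return Character vector of distinct cargo names.
#' @export
distinct_cargoes <- function(table) {
  stopifnot(inherits(table, "slc_annotation"))
  all_names <- trimws(unlist(c(table$substrates, table$coupled_ions),
                             use.names = FALSE))
  all_names[!duplicated(tolower(all_names))]
}

#' Summary statistics of a curated SLC annotation
#'
#' Counts records, orphans (no substrate and no coupled ion), cargo-bearing
#' transporters, distinct cargo names, and the per-class, per-mechanism,
#' per-ion and per-localization distributions, plus the fraction of unknown
#' annotations per category.
#'
#' @param table an `slc_annotation`.
#' @return A list of class `slc_annotation_summary`.
#' @export
summarize_annotation <- function(table) {
  stopifnot(inherits(table, "slc_annotation"))
  n <- nrow(table)
  n_orphan <- sum(table$is_orphan)
  cargo <- distinct_cargoes(table)

  count_sorted <- function(x) {
    if (!length(x)) return(integer(0))
    tb <- table(x)
    tb <- tb[order(-as.integer(tb), names(tb))]
    stats::setNames(as.integer(tb), names(tb))
  }
  ions <- tolower(trimws(unlist(table$coupled_ions, use.names = FALSE)))
  # per-ion counts count transporters, not mentions: dedupe within record
  ion_per_rec <- unlist(lapply(table$coupled_ions,
                               function(x) unique(tolower(trimws(x)))),
                        use.names = FALSE)
  loc_per_rec <- unlist(lapply(table$localizations,
                               function(x) unique(tolower(trimws(x)))),
                        use.names = FALSE)

  res <- list(
    n_records = n,
    n_orphan = n_orphan,
    n_with_cargo = n - n_orphan,
    n_distinct_cargo = length(cargo),
    class_counts = count_sorted(table$substrate_class),
    mechanism_counts = count_sorted(table$mechanism),
    ion_counts = count_sorted(ion_per_rec),
    localization_counts = count_sorted(loc_per_rec),
    fraction_unknown = c(
      substrate = mean(lengths(table$substrates) == 0L),
      coupled_ion = mean(lengths(table$coupled_ions) == 0L),
      mechanism = mean(table$mechanism == "unknown"),
      localization = mean(lengths(table$localizations) == 0L))
  )
  class(res) <- "slc_annotation_summary"
  res
}

#' @export
print.slc_annotation_summary <- function(x, ...) {
  cat(sprintf("SLC annotation: %d records, %d orphan (%.0f%%), %d with cargo, %d distinct cargoes\n",
              x$n_records, x$n_orphan, 100 * x$n_orphan / x$n_records,
              x$n_with_cargo, x$n_distinct_cargo))
  cat("substrate classes:\n")
  print(x$class_counts)
  cat("mechanisms:\n")
  print(x$mechanism_counts)
  cat("fraction unknown per category:\n")
  print(round(x$fraction_unknown, 3))
  invisible(x)
}

#' Write an annotation summary to text and JSON
#'
#' @param summary an `slc_annotation_summary`.
#' @param txt_path,json_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the summary.
#' @export
write_annotation_summary <- function(summary, txt_path = NULL,
                                     json_path = NULL) {
  stopifnot(inherits(summary, "slc_annotation_summary"))
  if (!is.null(txt_path)) {
    con <- file(txt_path, "wt"); sink(con); print(summary); sink(); close(con)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(summary), json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(summary)
}
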