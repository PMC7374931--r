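#' Default hyperparameter grid for the substrate classifiers
#'
#' Even coverage of the tuned ranges: `mtry` 20-200, `ntree` 300-1500,
#' class weights either unweighted or the class priors. `mtry` values larger
#' than the number of features are clamped (and deduplicated) at training
#' time.
#'
#' @return data.frame with columns `mtry`, `ntree`, `classwt_mode`.
#' @export
default_grid <- function() {
  expand.grid(mtry = c(20L, 50L, 100L, 150L, 200L),
              ntree = c(300L, 700L, 1100L, 1500L),
              classwt_mode = c("unweighted", "class_prior"),
              stringsAsFactors = FALSE)
}

# binary-classification metrics at a score cutoff (call = score >= t)
confusion_metrics <- function(scores, labels, threshold) {
  call <- scores >= threshold
  tp <- sum(call & labels); fp <- sum(call & !labels)
  fn <- sum(!call & labels); tn <- sum(!call & !labels)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  c(sensitivity = recall,
    specificity = if (fp + tn > 0) tn / (fp + tn) else 0,
    precision = precision, recall = recall, f1 = f1)
}

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation with midrank tie handling.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical labels.
#' @return AUROC in `[0,1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Average of precision at each positive hit, descending score order; tied
#' scores are grouped so the result is order-independent.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0,1]`.
#' @export
auprc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  if (n_pos == 0 || all(labels)) return(NA_real_)
  # group tied scores: precision evaluated at the end of each tie block,
  # recall increment = positives inside the block
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  blocks <- cumsum(!duplicated(s))
  tp_cum <- cumsum(y); n_cum <- seq_along(y)
  last <- !duplicated(blocks, fromLast = TRUE)
  tp_b <- tp_cum[last]; n_b <- n_cum[last]
  dtp <- diff(c(0, tp_b))
  sum(dtp * tp_b / n_b) / n_pos
}

#' Pick a decision threshold at a precision floor
#'
#' Among candidate thresholds (the distinct score values, clamped into
#' `(0,1)` so the gamma exponent stays finite), returns the one maximizing
#' recall subject to precision >= `min_precision`; ties are broken toward
#' higher precision, then toward the higher threshold. If no candidate
#' reaches the floor, falls back to the precision-maximizing threshold and
#' flags the result (`attr(x, "fallback")`).
#'
#' @param oob_scores out-of-bag probabilities, aligned with `labels`.
#' @param labels logical labels.
#' @param min_precision precision floor (default 0.75).
#' @return Numeric threshold with attributes `precision`, `recall`,
#'   `fallback`.
#' @export
select_threshold <- function(oob_scores, labels, min_precision = 0.75) {
  stopifnot(length(oob_scores) == length(labels))
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("degenerate labels: need both classes to set a threshold")
  cand <- sort(unique(pmin(pmax(oob_scores, 1e-6), 1 - 1e-6)))
  stats_at <- t(vapply(cand, function(t)
    confusion_metrics(pmin(pmax(oob_scores, 1e-6), 1 - 1e-6), labels, t),
    numeric(5)))
  feasible <- stats_at[, "precision"] >= min_precision
  if (any(feasible)) {
    idx <- which(feasible)
    o <- idx[order(-stats_at[idx, "recall"], -stats_at[idx, "precision"],
                   -cand[idx])]
    pick <- o[1]
    fallback <- FALSE
  } else {
    o <- order(-stats_at[, "precision"], -cand)
    pick <- o[1]
    fallback <- TRUE
  }
  structure(cand[pick],
            precision = unname(stats_at[pick, "precision"]),
            recall = unname(stats_at[pick, "recall"]),
            fallback = fallback)
}

#' Gamma-normalize classifier scores
#'
#' Power transform `s^(ln 0.5 / ln t)` relocating the decision threshold `t`
#' to 0.5 while preserving score order and fixing 0 and 1.
#'
#' @param score probabilities in `[0,1]` (vectorized).
#' @param threshold decision threshold(s) in the open interval (0,1),
#'   recycled against `score`.
#' @return Normalized scores.
#' @export
gamma_normalize <- function(score, threshold) {
  if (!length(threshold) || any(threshold <= 0 | threshold >= 1))
    stop("domain error: threshold must lie strictly inside (0,1)")
  if (any(score < 0 | score > 1)) stop("scores must lie in [0,1]")
  score ^ (log(0.5) / log(threshold))
}

#' Train one per-term binary random-forest classifier
#'
#' Grid search over `mtry`, `ntree` and class weighting, selecting the cell
#' maximizing out-of-bag F1 (computed at the 0.5 vote cutoff by default;
#' ties broken toward the smallest `ntree`, then smallest `mtry`, then
#' unweighted). Out-of-bag vote fractions serve as training-set
#' probabilities for both grid selection and threshold selection; no
#' separate validation split is used. Labels follow the closure convention:
#' positives are transporters whose term closure contains the target term,
#' negatives the remaining cargo-bearing transporters.
#'
#' @param features numeric feature matrix (rows = proteins, named).
#' @param labels logical vector aligned with `features` rows.
#' @param term_id identifier stored on the result.
#' @param grid hyperparameter grid (default [default_grid()]).
#' @param seed integer seed; the RNG is re-seeded identically before every
#'   grid cell so a fixed seed and grid give an identical result.
#' @param min_pos minimum positives and negatives required (default 10);
#'   below it training is skipped with an explicit report object.
#' @param min_precision precision floor for [select_threshold()].
#' @param f1_cutoff vote cutoff at which grid-search F1 is computed.
#' @return An object of class `slc_classifier` (or `slc_classifier_skip`
#'   when the class is too small): term id, chosen hyperparameters, OOB
#'   scores, OOB metrics (AUROC, AUPRC, sensitivity, specificity, precision,
#'   F1 at the threshold), decision threshold and gamma exponent, plus the
#'   fitted forest.
#' @export
train_term_classifier <- function(features, labels, term_id = "term",
                                  grid = default_grid(), seed,
                                  min_pos = 10, min_precision = 0.75,
                                  f1_cutoff = 0.5) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2)
    stop("degenerate labels: single class for term ", term_id)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos < min_pos || n_neg < min_pos) {
    return(structure(list(term_id = term_id, skipped = TRUE,
                          n_pos = n_pos, n_neg = n_neg,
                          reason = sprintf(
                            "needs >= %d per class, got %d positive / %d negative",
                            min_pos, n_pos, n_neg)),
                     class = "slc_classifier_skip"))
  }

  grid$mtry <- pmin(as.integer(grid$mtry), ncol(features))
  grid <- unique(grid)
  y <- factor(ifelse(labels, "pos", "neg"), levels = c("neg", "pos"))
  priors <- prop.table(table(y))

  fits <- vector("list", nrow(grid))
  f1s <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cw <- if (grid$classwt_mode[i] == "class_prior")
      c(neg = unname(priors["neg"]), pos = unname(priors["pos"])) else NULL
    set.seed(seed)
    fits[[i]] <- randomForest::randomForest(
      x = features, y = y, mtry = grid$mtry[i], ntree = grid$ntree[i],
      classwt = cw, keep.forest = TRUE)
    oob <- fits[[i]]$votes[, "pos"]
    f1s[i] <- confusion_metrics(oob, labels, f1_cutoff)["f1"]
  }
  pick <- order(-f1s, grid$ntree, grid$mtry,
                grid$classwt_mode != "unweighted")[1]
  fit <- fits[[pick]]
  oob <- fit$votes[, "pos"]

  thr <- select_threshold(oob, labels, min_precision = min_precision)
  cm <- confusion_metrics(oob, labels, as.numeric(thr))
  spec_obj <- list(
    term_id = term_id,
    hyperparams = list(mtry = grid$mtry[pick], ntree = grid$ntree[pick],
                       classwt_mode = grid$classwt_mode[pick]),
    n_pos = n_pos, n_neg = n_neg,
    oob_scores = stats::setNames(as.numeric(oob), rownames(features)),
    metrics = c(auroc = auroc(oob, labels), auprc = auprc(oob, labels),
                cm["sensitivity"], cm["specificity"], cm["precision"],
                f1 = unname(cm["f1"]), grid_f1 = unname(f1s[pick])),
    threshold = as.numeric(thr),
    threshold_fallback = attr(thr, "fallback"),
    gamma = log(0.5) / log(as.numeric(thr)),
    seed = seed,
    feature_names = colnames(features),
    model = fit)
  class(spec_obj) <- "slc_classifier"
  spec_obj
}

#' @export
print.slc_classifier <- function(x, ...) {
  cat(sprintf("classifier[%s]: mtry=%d ntree=%d classwt=%s | AUROC=%.3f AUPRC=%.3f F1=%.3f thr=%.3f gamma=%.3f\n",
              x$term_id, x$hyperparams$mtry, x$hyperparams$ntree,
              x$hyperparams$classwt_mode, x$metrics["auroc"],
              x$metrics["auprc"], x$metrics["f1"], x$threshold, x$gamma))
  invisible(x)
}

#' @export
print.slc_classifier_skip <- function(x, ...) {
  cat(sprintf("classifier[%s]: skipped (%s)\n", x$term_id, x$reason))
  invisible(x)
}

#' Train classifiers for a list of substrate terms
#'
#' Builds the training labels for every target term from the transporter
#' closures (positive = closure contains the term; negative = other
#' cargo-bearing transporters in the feature matrix) and trains one
#' classifier per term. Terms whose positive or negative class is too small
#' yield an explicit skip report.
#'
#' @param features feature matrix of cargo-bearing transporters (rownames =
#'   slc_id). Accessory proteins and transporters without usable topology
#'   should already be absent.
#' @param closures named list from [all_slc_closures()].
#' @param terms character vector of target term ids.
#' @param seed integer seed.
#' @param ... passed to [train_term_classifier()].
#' @return Named list of `slc_classifier` / `slc_classifier_skip` objects.
#' @export
train_classifiers <- function(features, closures, terms, seed, ...) {
  closures <- closures[names(closures) %in% rownames(features)]
  feats <- features[names(closures), , drop = FALSE]
  out <- lapply(terms, function(t) {
    labels <- vapply(closures, function(cl) t %in% cl, logical(1))
    train_term_classifier(feats, labels, term_id = t, seed = seed, ...)
  })
  names(out) <- terms
  out
}

#' Score orphan transporters with trained classifiers
#'
#' @param specs list of `slc_classifier` objects (skips are ignored).
#' @param orphan_features feature matrix of orphan transporters; column
#'   names must match the training feature order exactly.
#' @return data.frame with one row per (term, orphan): `term_id`, `slc_id`,
#'   `raw` ensemble probability, `normalized` gamma-corrected score and
#'   logical `call` (`normalized >= 0.5`).
#' @export
predict_orphans <- function(specs, orphan_features) {
  specs <- specs[vapply(specs, inherits, logical(1), "slc_classifier")]
  if (!nrow(orphan_features) || !length(specs)) {
    return(data.frame(term_id = character(0), slc_id = character(0),
                      raw = numeric(0), normalized = numeric(0),
                      call = logical(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(specs, function(sp) {
    if (!identical(colnames(orphan_features), sp$feature_names))
      stop("contract error: orphan feature names do not match training ",
           "features for term ", sp$term_id)
    raw <- stats::predict(sp$model, orphan_features,
                          type = "prob")[, "pos"]
    norm <- gamma_normalize(raw, sp$threshold)
    data.frame(term_id = sp$term_id, slc_id = rownames(orphan_features),
               raw = as.numeric(raw), normalized = as.numeric(norm),
               call = as.numeric(norm) >= 0.5, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize a classifier specification to JSON
#'
#' Writes everything except the fitted forest (hyperparameters, OOB scores
#' and metrics, threshold, gamma), so runs can be compared byte-for-byte.
#'
#' @param spec an `slc_classifier` or `slc_classifier_skip`.
#' @param path output JSON path.
#' @return Invisibly, the serialized list.
#' @export
write_classifier_spec <- function(spec, path) {
  x <- unclass(spec)
  x$model <- NULL
  x$skipped <- inherits(spec, "slc_classifier_skip")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(x)
}

#' Metrics table across classifiers
#'
#' @param specs list from [train_classifiers()].
#' @return data.frame: term, n_pos, n_neg, AUROC, AUPRC, sensitivity,
#'   specificity, precision, F1, threshold (NA rows for skipped terms).
#' @export
classifier_metrics <- function(specs) {
  rows <- lapply(names(specs), function(t) {
    sp <- specs[[t]]
    if (inherits(sp, "slc_classifier_skip")) {
      data.frame(term_id = t, n_pos = sp$n_pos, n_neg = sp$n_neg,
                 auroc = NA_real_, auprc = NA_real_, sensitivity = NA_real_,
                 specificity = NA_real_, precision = NA_real_,
                 f1 = NA_real_, threshold = NA_real_, skipped = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      m <- sp$metrics
      data.frame(term_id = t, n_pos = sp$n_pos, n_neg = sp$n_neg,
                 auroc = unname(m["auroc"]), auprc = unname(m["auprc"]),
                 sensitivity = unname(m["sensitivity"]),
                 specificity = unname(m["specificity"]),
                 precision = unname(m["precision"]), f1 = unname(m["f1"]),
                 threshold = sp$threshold, skipped = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
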