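test_that("threshold selection maximizes recall at the precision floor", {
  thr <- select_threshold(c(0.9, 0.8, 0.4, 0.2),
                          c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(as.numeric(thr), 0.4)
  expect_equal(attr(thr, "precision"), 1)
  expect_equal(attr(thr, "recall"), 1)
  expect_false(attr(thr, "fallback"))
})

test_that("threshold selection equals the exhaustive sweep oracle", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(6:30, 1)
    scores <- round(stats::runif(n), 2)
    labels <- stats::runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    for (floor_p in c(0.5, 0.75, 0.9)) {
      thr <- select_threshold(scores, labels, min_precision = floor_p)
      expect_equal(as.numeric(thr),
                   threshold_sweep_oracle(scores, labels, floor_p))
    }
  }
})

test_that("inverted score order triggers the precision fallback", {
  thr <- select_threshold(c(0.1, 0.2, 0.8, 0.9),
                          c(TRUE, TRUE, FALSE, FALSE))
  expect_true(attr(thr, "fallback"))
})

test_that("perfect separation reaches recall 1 at precision 1", {
  thr <- select_threshold(c(0.9, 0.8, 0.2, 0.1),
                          c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(attr(thr, "precision"), 1)
  expect_equal(attr(thr, "recall"), 1)
})

test_that("gamma normalization fixes endpoints, the threshold and order", {
  expect_equal(gamma_normalize(0.3, 0.3), 0.5)
  expect_equal(gamma_normalize(c(0, 1), 0.7), c(0, 1))
  expect_error(gamma_normalize(0.5, 1), "domain")
  expect_error(gamma_normalize(0.5, 0), "domain")

  set.seed(5)
  s1 <- stats::runif(1000); s2 <- stats::runif(1000)
  lo <- pmin(s1, s2); hi <- pmax(s1, s2)
  t <- stats::runif(1000, 0.01, 0.99)
  expect_true(all(gamma_normalize(lo, t) <= gamma_normalize(hi, t)))
  # strictly increasing wherever scores differ
  neq <- lo < hi
  expect_true(all(gamma_normalize(lo, t)[neq] < gamma_normalize(hi, t)[neq]))
})

test_that("AUROC/AUPRC agree with pROC on random score vectors", {
  skip_if_not_installed("pROC")
  set.seed(13)
  for (i in 1:10) {
    n <- 40
    labels <- stats::runif(n) < 0.35
    if (!any(labels) || all(labels)) next
    scores <- stats::runif(n) + labels * stats::runif(1)
    roc <- pROC::roc(response = labels, predictor = scores,
                     quiet = TRUE, direction = "<")
    expect_equal(auroc(scores, labels), as.numeric(pROC::auc(roc)),
                 tolerance = 1e-10)
  }
  # AUPRC sanity: perfect ranking gives 1, degenerate anti-ranking ~ base
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_lt(auprc(c(0.1, 0.2, 0.8, 0.9), c(TRUE, TRUE, FALSE, FALSE)), 1)
})

test_that("stored metrics are consistent with the confusion matrix", {
  set.seed(31)
  spec <- fixture_spec(seed = 31, class_signal = 0.25)
  ids <- sprintf("P%03d", 1:60)
  pos <- ids[1:20]
  fx <- make_sequence_fixture(spec, ids, pos)
  feats <- feature_matrix(fx$proteins)
  cs <- train_term_classifier(
    feats, ids %in% pos, term_id = "T", seed = 17,
    grid = data.frame(mtry = 10L, ntree = 300L,
                      classwt_mode = "unweighted"))
  scores <- pmin(pmax(cs$oob_scores, 1e-6), 1 - 1e-6)
  call <- scores >= cs$threshold
  labels <- ids %in% pos
  tp <- sum(call & labels); fp <- sum(call & !labels)
  fn <- sum(!call & labels); tn <- sum(!call & !labels)
  expect_equal(unname(cs$metrics["precision"]), tp / (tp + fp))
  expect_equal(unname(cs$metrics["sensitivity"]), tp / (tp + fn))
  expect_equal(unname(cs$metrics["specificity"]), tn / (tn + fp))
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  expect_equal(unname(cs$metrics["f1"]), 2 * p * r / (p + r))
  expect_equal(cs$gamma, log(0.5) / log(cs$threshold))
})

test_that("training is deterministic for a fixed seed and grid", {
  spec <- fixture_spec(seed = 8, class_signal = 0.25)
  ids <- sprintf("P%03d", 1:50)
  pos <- ids[1:15]
  fx <- make_sequence_fixture(spec, ids, pos)
  feats <- feature_matrix(fx$proteins)
  grid <- data.frame(mtry = c(10L, 20L), ntree = 300L,
                     classwt_mode = c("unweighted", "class_prior"),
                     stringsAsFactors = FALSE)
  a <- train_term_classifier(feats, ids %in% pos, "T", grid, seed = 5,
                             min_pos = 10)
  b <- train_term_classifier(feats, ids %in% pos, "T", grid, seed = 5,
                             min_pos = 10)
  fa <- tempfile(); fb <- tempfile()
  write_classifier_spec(a, fa); write_classifier_spec(b, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("small positive classes are skipped with an explicit report", {
  feats <- matrix(stats::rnorm(40 * 5), 40,
                  dimnames = list(NULL, paste0("f", 1:5)))
  labels <- c(rep(TRUE, 3), rep(FALSE, 37))
  cs <- train_term_classifier(feats, labels, "tiny", seed = 1)
  expect_s3_class(cs, "slc_classifier_skip")
  expect_match(cs$reason, "positive")
  expect_error(train_term_classifier(feats, rep(TRUE, 40), "one", seed = 1),
               "degenerate")
})

test_that("orphans resembling the positive class score above threshold", {
  spec <- fixture_spec(seed = 19, class_signal = 0.25)
  ids <- sprintf("P%03d", 1:80)
  pos <- ids[1:25]
  fx <- make_sequence_fixture(spec, ids, pos)
  feats <- feature_matrix(fx$proteins)
  cs <- train_term_classifier(
    feats[ids[1:70], ], ids[1:70] %in% pos, "T", seed = 23,
    grid = data.frame(mtry = 10L, ntree = 500L,
                      classwt_mode = "unweighted"))
  # held-out proteins drawn from the positive distribution
  held <- make_sequence_fixture(fixture_spec(seed = 77,
                                             class_signal = 0.25),
                                sprintf("O%02d", 1:10),
                                positive_ids = sprintf("O%02d", 1:10))
  preds <- predict_orphans(list(cs), feature_matrix(held$proteins))
  expect_gte(mean(preds$call), 0.8)

  # empty orphan set is fine; mismatched features are a contract error
  empty <- predict_orphans(list(cs), feats[0, , drop = FALSE])
  expect_equal(nrow(empty), 0)
  bad <- feats[1:2, rev(colnames(feats))]
  expect_error(predict_orphans(list(cs), bad), "contract")
})
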