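test_that("configuration defaults and validation match the design contract", {
  cfg <- classifier_config()
  expect_equal(cfg$dropout_rate, 0.2)
  expect_equal(cfg$n_classes, 6L)
  expect_equal(cfg$val_fraction, 0.2)   # the 8:2 split
  expect_error(classifier_config(dropout_rate = 1), "dropout")
  expect_error(classifier_config(confidence_threshold = 1.5), "confidence")
  expect_error(classifier_config(conv_filters = 0), "conv_filters")
})

test_that("stratified training demands at least two recordings per class", {
  one_each <- generate_dataset(stats::setNames(rep(1L, 6), NORMAL_CATEGORIES),
                               default_protocol(1), seed = 1)
  expect_error(train_classifier(one_each, classifier_config(epochs = 1)),
               "fewer than 2")
})

test_that("training is bit-reproducible under a fixed seed", {
  corp <- small_classifier_corpus()
  cfg <- classifier_config(epochs = 3, seed = 5, conv_filters = 8,
                           dense_units = 16, lstm_units = 8, attn_units = 8)
  m1 <- train_classifier(corp$train, cfg)
  m2 <- train_classifier(corp$train, cfg)
  f1 <- patchkin:::flatten_params(m1$params$rising)
  f2 <- patchkin:::flatten_params(m2$params$rising)
  expect_identical(f1, f2)
  expect_identical(m1$history$val_acc, m2$history$val_acc)
})

test_that("whole-phase aggregation is a convex combination of phase outputs", {
  p <- matrix(c(0.5, 0.2, 0.1, 0.1, 0.05, 0.05), 1)
  fwds <- list(rising = list(probs = p), sustaining = list(probs = p),
               falling = list(probs = p))
  for (u in list(c(0, 0, 0), c(2, -1, 0.5), rnorm(3))) {
    out <- patchkin:::combine_probs(fwds, u)
    expect_equal(out, p, tolerance = 1e-12)  # identical inputs pass through
  }
  set.seed(1)
  rp <- function() { v <- runif(6); matrix(v / sum(v), 1) }
  fwds2 <- list(rising = list(probs = rp()), sustaining = list(probs = rp()),
                falling = list(probs = rp()))
  out <- patchkin:::combine_probs(fwds2, rnorm(3))
  expect_equal(sum(out), 1, tolerance = 1e-9)  # stays in the simplex
  expect_true(all(out >= 0))
})

test_that("prediction applies the confidence and majority-vote acceptance rule", {
  corp <- small_classifier_corpus()
  m <- small_trained_model()
  # rejection off: labels are always categories
  pr <- predict(m, corp$test, reject = FALSE)
  expect_true(all(pr$label %in% NORMAL_CATEGORIES))
  probs <- attr(pr, "final_probs")
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-6)
  # attention weights are normalized per phase
  for (ph in c("rising", "sustaining", "falling")) {
    a <- attr(pr, "attention")[[ph]]
    expect_equal(rowSums(a), rep(1, nrow(a)), tolerance = 1e-6)
  }
  # an impossible confidence bar rejects everything
  m_strict <- m
  m_strict$config$confidence_threshold <- 1
  m_strict$config$vote_threshold <- 0
  pr2 <- predict(m_strict, corp$test$recordings[[1]])
  expect_true(pr2$label %in% c("REJECTED", pr2$raw_label))
  if (pr2$confidence < 1) expect_identical(pr2$label, "REJECTED")
  # a free acceptance bar accepts everything
  m_free <- m
  m_free$config$confidence_threshold <- 0
  m_free$config$vote_threshold <- 0
  pr3 <- predict(m_free, corp$test)
  expect_true(all(pr3$accepted))
  # vote rule: >= ceiling(3 * vote_threshold) phase labels must agree
  votes <- rowSums(cbind(pr$rising, pr$sustaining, pr$falling) == pr$raw_label)
  need <- ceiling(3 * m$config$vote_threshold)
  expect_identical(unname(pr$accepted),
                   unname(pr$confidence >= m$config$confidence_threshold &
                            votes >= need))
})

test_that("a protocol mismatch is rejected at prediction time", {
  m <- small_trained_model()
  other <- recording(matrix(0, 5, 5000), default_protocol(10), 20)
  expect_error(predict(m, other), "protocol mismatch")
})

test_that("multiclass metrics match a closed-form oracle on a fixed confusion matrix", {
  truth <- rep(NORMAL_CATEGORIES, times = c(10, 10, 10, 10, 10, 10))
  pred <- truth
  pred[c(1, 2, 12, 23, 34)] <- NORMAL_CATEGORIES[c(2, 3, 1, 4, 6)]
  m <- multiclass_metrics(truth, pred, classes = NORMAL_CATEGORIES)
  cm <- table(factor(truth, NORMAL_CATEGORIES), factor(pred, NORMAL_CATEGORIES))
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  expect_equal(m$accuracy, po)
  expect_equal(m$kappa, (po - pe) / (1 - pe))
  tvec <- rowSums(cm); pvec <- colSums(cm)
  num <- sum(diag(cm)) * n - sum(tvec * pvec)
  den <- sqrt(n^2 - sum(pvec^2)) * sqrt(n^2 - sum(tvec^2))
  expect_equal(m$mcc, num / den)
  expect_equal(unname(rowSums(m$confusion)), rep(10, 6))  # row sums = class counts
  perfect <- multiclass_metrics(truth, truth, classes = NORMAL_CATEGORIES)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$kappa, 1)
  expect_true(all(perfect$confusion[row(perfect$confusion) !=
                                      col(perfect$confusion)] == 0))
})

test_that("uniform-random probabilities give chance-level AUC", {
  set.seed(42)
  n <- 10000
  truth <- sample(NORMAL_CATEGORIES, n, replace = TRUE)
  probs <- matrix(runif(n * 6), n, 6)
  probs <- probs / rowSums(probs)
  colnames(probs) <- NORMAL_CATEGORIES
  pred <- NORMAL_CATEGORIES[max.col(probs)]
  m <- multiclass_metrics(truth, pred, probs)
  expect_true(all(abs(m$auc - 0.5) < 0.03))
})

test_that("AP and AUC agree with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  truth <- sample(c(TRUE, FALSE), 200, replace = TRUE)
  scores <- rnorm(200) + truth
  ours <- patchkin:::roc_curve(scores, truth)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-9)
  # AP equals the direct sum over positives of precision at their ranks
  pr <- patchkin:::pr_curve(scores, truth)
  o <- order(scores, decreasing = TRUE)
  y <- truth[o]
  prec_at_pos <- cumsum(y)[y] / which(y)
  expect_equal(pr$ap, sum(prec_at_pos) / sum(y), tolerance = 1e-9)
})

test_that("training on shuffled labels stays at chance on the test set", {
  corp <- small_classifier_corpus()
  shuffled <- corp$train
  set.seed(77)
  labs <- sample(set_labels(shuffled))
  for (i in seq_along(shuffled$recordings))
    shuffled$recordings[[i]]$label <- labs[i]
  cfg <- classifier_config(epochs = 10, seed = 2, conv_filters = 8,
                           dense_units = 16, lstm_units = 8, attn_units = 8)
  m <- train_classifier(shuffled, cfg)
  ev <- evaluate_classifier(m, corp$test)
  expect_gt(ev$entire$accuracy, 1 / 6 - 0.1)
  expect_lt(ev$entire$accuracy, 1 / 6 + 0.125)
})

test_that("grid search is exhaustive with a deterministic small-model tie-break", {
  expect_error(grid_search(small_classifier_corpus()$train, list()), "non-empty")
  corp <- small_classifier_corpus()
  base <- classifier_config(epochs = 4, seed = 3, conv_filters = 6,
                            dense_units = 8, lstm_units = 6, attn_units = 6)
  gs <- grid_search(corp$train, list(lstm_units = c(4, 6)), base = base)
  expect_equal(nrow(gs$table), 2L)
  expect_true(gs$best_config$lstm_units %in% c(4, 6))
  expect_equal(gs$table$val_acc[gs$table$lstm_units == gs$best_config$lstm_units][1],
               max(gs$table$val_acc))
  one <- grid_search(corp$train, list(conv_kernel = 7), base = base)
  expect_equal(one$best_config$conv_kernel, 7L)
})
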