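test_that("feature extraction is deterministic and zero-safe", {
  p <- default_protocol(1)
  rec0 <- recording(matrix(0, 5, 500), p, 20)
  v <- extract_features(rec0)
  expect_true(all(v[grepl("_d[0-9]+$", names(v))] == 0))
  expect_equal(unname(v[grepl("peak_out$", names(v))]), rep(0, 5))
  expect_equal(unname(v[grepl("peak_in$", names(v))]), rep(0, 5))
  rec <- generate_recording("category_II", p, seed = 6)
  expect_identical(extract_features(rec), extract_features(rec))
  expect_equal(length(v), 5 * 107 + 4)
  expect_identical(attr(v, "version"), "pk-feat-1")
})

test_that("the SNR feature separates low-SNR anomalies from typical recordings", {
  p <- default_protocol()  # the detection-corpus sampling rate
  for (seed in 1:30) {
    bad <- extract_features(generate_recording("anomaly_III", p, seed = seed))
    good <- extract_features(generate_recording("category_I", p, seed = seed + 500))
    expect_lt(max(bad[grepl("snr$", names(bad))]), 2)
    expect_gt(min(good[grepl("snr$", names(good))]), 10)
  }
})

test_that("fit_knn validates its inputs and stores the training set verbatim", {
  set.seed(3)
  x <- matrix(rnorm(40), 20, 2)
  y <- rep(c("normal", "abnormal"), each = 10)
  m <- fit_knn(x, y, k = 5)
  expect_equal(nrow(m$x), 20L)
  expect_error(fit_knn(x, y, k = 21), "between 1 and")
  expect_error(fit_knn(x, rep("normal", 20), k = 3), "both classes")
  expect_error(fit_knn(x, rep(c("good", "bad"), 10), k = 3), "normal")
  expect_error(predict(m, matrix(0, 1, 3)), "dimension")
})

test_that("nearest-neighbour prediction matches the hand-worked examples", {
  x <- rbind(c(0, 0), c(1, 0), c(10, 0))
  y <- c("normal", "normal", "abnormal")
  no_std <- rep(1, 2)  # raw Euclidean geometry for the worked examples
  m_raw <- fit_knn(x, y, k = 3, weighting = "uniform")
  m_raw$center <- c(0, 0); m_raw$scale <- c(1, 1); m_raw$weights <- no_std
  m_raw$x <- x
  # query (0.4, 0): votes 2 normal vs 1 abnormal
  expect_identical(predict(m_raw, c(0.4, 0)), "normal")
  # query equal to a training point, k = 1: its label at distance 0
  m1 <- m_raw; m1$k <- 1L
  out <- predict(m1, c(10, 0), type = "full")
  expect_identical(out$label, "abnormal")
  expect_equal(out$distances[1, 1], 0)
  # inverse-distance weighting agrees with the independent vote oracle
  m_inv <- m_raw; m_inv$weighting <- "inverse"
  expect_identical(predict(m_inv, c(5.6, 0)),
                   knn_oracle(x, y, c(5.6, 0), 3, "inverse"))
})

test_that("uniform-vote prediction agrees with the brute-force oracle", {
  set.seed(11)
  for (rep_ in 1:200) {
    n <- sample(4:20, 1)
    m_dim <- sample(1:5, 1)
    x <- matrix(rnorm(n * m_dim), n, m_dim)
    y <- sample(c("normal", "abnormal"), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c("normal", "abnormal")
    k <- sample(seq_len(n), 1)
    fit <- fit_knn(x, y, k = k, weighting = "uniform")
    fit$center <- rep(0, m_dim); fit$scale <- rep(1, m_dim)
    fit$weights <- rep(1, m_dim); fit$x <- x
    q <- rnorm(m_dim)
    expect_identical(predict(fit, q), knn_oracle(x, y, q, k, "uniform"))
  }
})

test_that("prediction is invariant to training-set permutation (modulo tie rule)", {
  set.seed(21)
  x <- matrix(rnorm(60), 30, 2)
  y <- rep(c("normal", "abnormal"), 15)
  q <- matrix(rnorm(20), 10, 2)
  m1 <- fit_knn(x, y, k = 5)
  perm <- sample(30)
  m2 <- fit_knn(x[perm, ], y[perm], k = 5)
  expect_identical(predict(m1, q), predict(m2, q))
})

test_that("PCA embedding is centered, deterministic in sign and error-guarded", {
  expect_error(pca_embed(matrix(1, 5, 3)), "zero variance")
  expect_error(pca_embed(matrix(rnorm(2), 1, 2)), "at least")
  toy <- rbind(c(0, 0), c(1, 1), c(2, 2))
  sc <- pca_embed(toy)
  expect_gt(attr(sc, "var_explained")[1], 0.999)  # collinear: PC1 is everything
  expect_lt(abs(mean(sc[, 1])), 1e-12)            # centered scores
  set.seed(2)
  x <- matrix(rnorm(200), 50, 4)
  expect_identical(pca_embed(x), pca_embed(x))
})

test_that("detector evaluation handles perfect and degenerate predictions", {
  y <- rep(c("normal", "abnormal"), each = 10)
  perfect <- evaluate_metrics <- binary_metrics(y, y)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$mcc, 1)
  allnorm <- binary_metrics(y, rep("normal", 20))
  expect_equal(allnorm$accuracy, 0.5)
  expect_equal(allnorm$mcc, 0)      # undefined denominator maps to 0
  expect_equal(allnorm$f1, 0)
})

test_that("binary metrics agree with the closed-form confusion-matrix oracle", {
  set.seed(7)
  for (rep_ in 1:50) {
    truth <- sample(c("normal", "abnormal"), 40, replace = TRUE)
    pred <- sample(c("normal", "abnormal"), 40, replace = TRUE)
    m <- binary_metrics(truth, pred)
    tp <- sum(truth == "abnormal" & pred == "abnormal")
    tn <- sum(truth == "normal" & pred == "normal")
    fp <- sum(truth == "normal" & pred == "abnormal")
    fn <- sum(truth == "abnormal" & pred == "normal")
    expect_equal(m$accuracy, (tp + tn) / 40)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    expect_equal(m$precision, prec)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    expect_equal(m$f1, f1)
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    expect_equal(m$mcc, if (den == 0) 0 else (tp * tn - fp * fn) / den)
  }
})

test_that("the benchmark harness wraps the classical detectors coherently", {
  expect_error(benchmark_detectors(NULL, NULL, NULL, NULL, "svm"), "unknown")
  empty <- benchmark_detectors(NULL, NULL, NULL, NULL, character(0))
  expect_equal(nrow(empty), 0L)
  set.seed(31)
  x <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 3), 30, 2))
  y <- rep(c("normal", "abnormal"), each = 30)
  xt <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 3), 10, 2))
  yt <- rep(c("normal", "abnormal"), each = 10)
  tab <- benchmark_detectors(x, y, xt, yt, "knn", k = 3)
  ref <- evaluate_detector(fit_knn(x, y, k = 3), xt, yt)
  expect_equal(tab$accuracy, ref$accuracy)
  expect_equal(tab$mcc, ref$mcc)
})

test_that("all seven detectors run on the synthetic corpus and KNN stays competitive", {
  corp <- anomaly_corpus_seed1()
  X <- corpus_features(corp$train)
  Xt <- corpus_features(corp$test)
  set.seed(1)
  tab <- benchmark_detectors(X, binary_labels(corp$train),
                             Xt, binary_labels(corp$test))
  expect_equal(nrow(tab), 7L)
  knn_acc <- tab$accuracy[tab$detector == "knn"]
  expect_gte(knn_acc, max(tab$accuracy) - 0.02)
})
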