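# Shared fixtures, generated once per test session and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# small six-category corpus at 1 kHz for classifier unit tests
small_classifier_corpus <- function() {
  fixture("small_classifier", function() {
    list(train = generate_dataset(stats::setNames(rep(8L, 6), NORMAL_CATEGORIES),
                                  default_protocol(1), seed = 11),
         test = generate_dataset(stats::setNames(rep(4L, 6), NORMAL_CATEGORIES),
                                 default_protocol(1), seed = 22))
  })
}

# full anomaly corpus (seed 1) shared by anomaly-module tests
anomaly_corpus_seed1 <- function() {
  fixture("anomaly1", function() anomaly_corpus(seed = 1))
}

# a small trained classifier shared by prediction/evaluation tests
small_trained_model <- function() {
  fixture("small_model", function() {
    corp <- small_classifier_corpus()
    train_classifier(corp$train, classifier_config(epochs = 25, seed = 1))
  })
}

# brute-force KNN oracle implementing the Euclidean-distance /
# majority-vote definition directly (independent of the package path)
knn_oracle <- function(train_x, train_y, query, k, weighting = "uniform") {
  d <- apply(train_x, 1L, function(r) sqrt(sum((query - r)^2)))
  o <- order(d)[seq_len(k)]
  if (weighting == "uniform") {
    va <- sum(train_y[o] == "abnormal")
    vn <- sum(train_y[o] == "normal")
  } else {
    w <- 1 / (d[o] + 1e-9)
    va <- sum(w[train_y[o] == "abnormal"])
    vn <- sum(w[train_y[o] == "normal"])
  }
  if (va >= vn) "abnormal" else "normal"
}
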