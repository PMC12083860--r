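# Stage-1 anomaly detection: a versioned feature map, a weighted
# k-nearest-neighbour detector (Euclidean distance, majority or
# inverse-distance vote), PCA visualization, and a benchmark harness over
# classical detectors wrapped from standard libraries.

FEATURE_VERSION <- "pk-feat-1"

#' Extract the anomaly-detection feature vector of a recording
#'
#' Concatenates, per sweep (sweeps ordered by ascending step potential):
#' (a) the sweep's waveform shape, decimated to 100 samples by anti-aliased
#' block mean pooling of the jointly z-scored recording (so shape features
#' are invariant to the absolute current scale), and (b) seven summary
#' statistics on the raw currents: baseline-subtracted peak outward and peak
#' inward current in the stimulus window, the mean of the last 50 ms of the
#' stimulus, the tail-region mean and s.d. (tail measured from 5 ms after
#' stimulus offset, past the capacitive transient), a signal-to-noise
#' estimate (peak absolute evoked current after ~5 ms smoothing, over the
#' pre-stimulus baseline s.d. — smoothing keeps noise maxima from inflating
#' the estimate), and the largest positive tail excursion in baseline-noise
#' units. Four recording-level consistency statistics follow: the Spearman
#' correlation of the late-stimulus mean with the step potential and the
#' absolute Spearman correlation of the smoothed evoked amplitude with the
#' step potential (voltage-dependence consistency), plus the shape
#' correlation and log-amplitude ratio of the two largest-amplitude sweeps
#' (cross-sweep kinetic consistency). Feature dimension is
#' \code{n_sweeps * 107 + 4}.
#'
#' Each feature carries a metric weight (attribute \code{weights}) used by
#' \code{\link{fit_knn}}: a sweep's 100-dim shape block receives, in
#' aggregate, the squared-distance weight of one summary statistic, and the
#' recording-level consistency block receives, in aggregate, the same weight
#' as all per-sweep blocks combined — so neither dimensionality nor block
#' granularity dominates the Euclidean metric. The map is versioned
#' (\code{"pk-feat-1"}) so results are reproducible.
#'
#' @param rec A \code{\link{recording}}.
#' @return Named numeric vector with attributes \code{version} and
#'   \code{weights}.
#' @export
extract_features <- function(rec) {
  p <- rec$protocol
  t <- time_axis(p)
  stim <- t >= p$onset & t < p$offset
  base <- t < p$onset
  tail_r <- t >= (p$offset + 5)
  late <- t >= (p$offset - 50) & t < p$offset
  ord <- order(p$steps)
  z <- zscore(rec)
  k <- max(1L, as.integer(round(5 * p$rate)))
  ev_m <- t(apply(rec$traces, 1L, function(x) x[stim] - mean(x[base])))
  feats <- lapply(ord, function(i) {
    x <- rec$traces[i, ]
    bs <- length(x) %/% 100L
    dec <- colMeans(matrix(z[i, seq_len(100L * bs)], nrow = bs))
    b <- mean(x[base])
    noise <- max(stats::sd(x[base]), .Machine$double.eps)
    ev <- x[stim] - b
    sm <- stats::filter(ev, rep(1 / k, k), sides = 2)
    tl <- x[tail_r]
    c(dec,
      peak_out = max(ev), peak_in = min(ev), late_mean = mean(x[late] - b),
      tail_mean = mean(tl) - b, tail_sd = stats::sd(tl),
      snr = max(abs(sm), na.rm = TRUE) / noise,
      tail_burst = max(tl - mean(tl)) / noise,
      amp_sm = max(abs(sm), na.rm = TRUE))
  })
  late_means <- vapply(feats, `[[`, numeric(1), "late_mean")
  amps_sm <- vapply(feats, `[[`, numeric(1), "amp_sm")
  spearman0 <- function(a, b) {
    r <- suppressWarnings(stats::cor(a, b, method = "spearman"))
    if (is.na(r)) 0 else r
  }
  vcor <- spearman0(late_means, p$steps[ord])
  amp_vcor <- abs(spearman0(amps_sm, p$steps[ord]))
  amp <- apply(abs(ev_m), 1L, max)
  top2 <- order(amp, decreasing = TRUE)[1:2]
  sc <- suppressWarnings(stats::cor(ev_m[top2[1], ], ev_m[top2[2], ]))
  if (is.na(sc)) sc <- 0
  feats <- lapply(feats, function(f) f[names(f) != "amp_sm"])
  v <- c(unlist(feats), vcor = vcor, amp_vcor = amp_vcor, top2_cor = sc,
         top2_lratio = log(max(amp[top2[1]], 1e-9) / max(amp[top2[2]], 1e-9)))
  stat_names <- c("peak_out", "peak_in", "late_mean", "tail_mean", "tail_sd",
                  "snr", "tail_burst")
  names(v) <- c(paste0("s", rep(seq_along(ord), each = 107L), "_",
                       c(paste0("d", 1:100), stat_names)),
                "vcor", "amp_vcor", "top2_cor", "top2_lratio")
  w <- rep(1, length(v))
  w[grepl("_d[0-9]+$", names(v))] <- sqrt(1 / 100)
  # 8 blocks per sweep (shape + 7 stats) vs 4 recording-level dims
  w[names(v) %in% c("vcor", "amp_vcor", "top2_cor", "top2_lratio")] <-
    sqrt(length(ord) * 8 / 4)
  attr(v, "version") <- FEATURE_VERSION
  attr(v, "weights") <- w
  v
}

#' Feature matrix of a recording set
#'
#' @param set A \code{\link{recording_set}}.
#' @return Numeric matrix, one row per recording.
#' @export
corpus_features <- function(set) {
  fl <- lapply(set$recordings, extract_features)
  m <- do.call(rbind, fl)
  attr(m, "weights") <- attr(fl[[1]], "weights")
  attr(m, "version") <- attr(fl[[1]], "version")
  m
}

#' Fit the weighted-KNN anomaly detector
#'
#' A lazy learner: stores the training features verbatim together with
#' per-dimension standardization statistics (training mean and s.d.), the
#' neighbour count \code{k} and the weighting mode. Standardization precedes
#' the Euclidean distance so no single large-amplitude feature dominates.
#'
#' @param x Numeric feature matrix (rows = recordings).
#' @param y Labels, coercible to the two classes \code{normal}/
#'   \code{abnormal}; both classes must be present.
#' @param k Neighbour count (default 5), \code{1 <= k <= nrow(x)}.
#' @param weighting \code{"inverse"} (inverse-distance vote, the default) or
#'   \code{"uniform"} (plain majority vote).
#' @param feature_weights Optional per-feature metric weights applied after
#'   standardization; defaults to the \code{weights} attribute of \code{x}
#'   when present (as set by \code{\link{extract_features}}), else 1 for all
#'   features (plain Euclidean distance).
#' @return An object of class \code{knn_detector}.
#' @export
fit_knn <- function(x, y, k = 5, weighting = c("inverse", "uniform"),
                    feature_weights = NULL) {
  weighting <- match.arg(weighting)
  if (is.null(feature_weights)) feature_weights <- attr(x, "weights")
  x <- as.matrix(x)
  if (is.null(feature_weights)) feature_weights <- rep(1, ncol(x))
  if (length(feature_weights) != ncol(x))
    stop("feature_weights length must match feature dimension")
  y <- as.character(y)
  if (!all(y %in% c("normal", "abnormal")))
    stop("labels must be 'normal' or 'abnormal'")
  if (length(unique(y)) < 2L)
    stop("training set must contain both classes")
  if (k < 1L || k > nrow(x))
    stop(sprintf("k (%d) must be between 1 and the training size (%d)", k, nrow(x)))
  mu <- colMeans(x)
  sd_ <- apply(x, 2L, stats::sd)
  sd_[sd_ == 0] <- 1
  xs <- sweep(sweep(sweep(x, 2L, mu), 2L, sd_, "/"), 2L, feature_weights, "*")
  structure(list(x = xs, y = y,
                 k = as.integer(k), weighting = weighting,
                 center = mu, scale = sd_, weights = feature_weights,
                 feature_version = FEATURE_VERSION),
            class = "knn_detector")
}

#' @export
print.knn_detector <- function(x, ...) {
  cat(sprintf("Weighted-KNN anomaly detector: n = %d, m = %d, k = %d, %s vote\n",
              nrow(x$x), ncol(x$x), x$k, x$weighting))
  invisible(x)
}

#' @export
summary.knn_detector <- function(object, ...) {
  print(object)
  cat(sprintf("  training classes: %s\n",
              paste(sprintf("%s=%d", names(table(object$y)), table(object$y)),
                    collapse = ", ")))
  invisible(object)
}

#' Predict with the KNN detector
#'
#' For each query, ranks training points by Euclidean distance (distance ties
#' broken by lower training index), takes the \code{k} nearest, and votes:
#' uniform weighting counts neighbours per class; inverse-distance weighting
#' scores each class by \eqn{\sum 1/(d + 10^{-9})}. Class-score ties resolve
#' to \code{abnormal} (fail-safe).
#'
#' @param object A \code{\link{fit_knn}} model.
#' @param newdata Feature matrix (or single vector) of queries; dimension
#'   must match the training features.
#' @param type \code{"class"} for labels only, \code{"full"} for labels plus
#'   neighbour indices and distances.
#' @param ... Unused.
#' @return Character vector of labels, or (for \code{type = "full"}) a list
#'   with \code{label}, \code{neighbors} and \code{distances}.
#' @export
predict.knn_detector <- function(object, newdata, type = c("class", "full"),
                                 ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$x))
    stop(sprintf("query dimension (%d) does not match training dimension (%d)",
                 ncol(newdata), ncol(object$x)))
  q <- sweep(sweep(sweep(newdata, 2L, object$center), 2L, object$scale, "/"),
             2L, object$weights, "*")
  n <- nrow(q)
  labels <- character(n)
  nb <- matrix(0L, n, object$k)
  dist_m <- matrix(0, n, object$k)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(object$x) - q[i, ])^2))
    o <- order(d)[seq_len(object$k)]  # stable: distance ties by train index
    nb[i, ] <- o
    dist_m[i, ] <- d[o]
    if (object$weighting == "uniform") {
      votes <- c(normal = sum(object$y[o] == "normal"),
                 abnormal = sum(object$y[o] == "abnormal"))
    } else {
      w <- 1 / (d[o] + 1e-9)
      votes <- c(normal = sum(w[object$y[o] == "normal"]),
                 abnormal = sum(w[object$y[o] == "abnormal"]))
    }
    labels[i] <- if (votes["abnormal"] >= votes["normal"]) "abnormal" else "normal"
  }
  if (type == "class") labels else
    list(label = labels, neighbors = nb, distances = dist_m)
}

#' PCA embedding of a feature corpus
#'
#' Centered principal-component scores. For determinism, each component's
#' sign is fixed so that its largest-magnitude loading is positive.
#'
#' @param x Feature matrix (rows = recordings), \code{nrow >=
#'   n_components}.
#' @param n_components Number of components (default 2).
#' @return Matrix of scores \code{nrow(x) x n_components} with attribute
#'   \code{var_explained}.
#' @export
pca_embed <- function(x, n_components = 2) {
  x <- as.matrix(x)
  if (nrow(x) < n_components)
    stop("corpus size must be at least n_components")
  if (sum(apply(x, 2L, stats::var)) == 0)
    stop("degenerate corpus: zero variance in every feature")
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  nc <- min(n_components, ncol(pr$x))
  scores <- pr$x[, seq_len(nc), drop = FALSE]
  for (j in seq_len(nc)) {
    i <- which.max(abs(pr$rotation[, j]))
    if (pr$rotation[i, j] < 0) scores[, j] <- -scores[, j]
  }
  ve <- pr$sdev^2 / sum(pr$sdev^2)
  attr(scores, "var_explained") <- ve[seq_len(nc)]
  scores
}

#' Evaluate a detector on a labelled test set
#'
#' @param model A \code{\link{fit_knn}} model.
#' @param x Test feature matrix.
#' @param y True labels (\code{normal}/\code{abnormal}).
#' @return \code{\link{binary_metrics}} with abnormal as the positive class.
#' @export
evaluate_detector <- function(model, x, y) {
  binary_metrics(y, predict(model, x))
}

#' Benchmark classical detectors against the KNN detector
#'
#' Fits each named off-the-shelf detector on the same features and reports
#' accuracy, precision, F1 and MCC on the test set. Available names:
#' \code{knn} (this package's detector), \code{lda} (MASS), \code{nb}
#' (e1071 naive Bayes), \code{rf} (randomForest), \code{dt} (rpart),
#' \code{et} (ranger extra-trees), \code{gbm} (xgboost gradient boosting).
#'
#' @param train_x,train_y Training features and labels.
#' @param test_x,test_y Test features and labels.
#' @param detectors Character vector of detector names.
#' @param k,weighting Passed to \code{\link{fit_knn}} for the KNN row.
#' @return Data frame with one row per detector.
#' @export
benchmark_detectors <- function(train_x, train_y, test_x, test_y,
                                detectors = c("knn", "lda", "nb", "rf", "dt",
                                              "et", "gbm"),
                                k = 5, weighting = "inverse") {
  known <- c("knn", "lda", "nb", "rf", "dt", "et", "gbm")
  bad <- setdiff(detectors, known)
  if (length(bad))
    stop(sprintf("unknown detector name(s): %s", paste(bad, collapse = ", ")))
  if (!length(detectors))
    return(data.frame(detector = character(), accuracy = numeric(),
                      precision = numeric(), f1 = numeric(), mcc = numeric()))
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  train_y <- factor(as.character(train_y), c("normal", "abnormal"))
  keep <- apply(train_x, 2L, stats::sd) > 0
  colnames(train_x) <- colnames(test_x) <- paste0("f", seq_len(ncol(train_x)))
  tr_df <- data.frame(train_x[, keep, drop = FALSE])
  te_df <- data.frame(test_x[, keep, drop = FALSE])
  need_pkg <- function(p) if (!requireNamespace(p, quietly = TRUE))
    stop(sprintf("package '%s' is required for this detector", p))
  rows <- lapply(detectors, function(det) {
    pred <- switch(det,
      knn = predict(fit_knn(train_x, train_y, k, weighting), test_x),
      lda = {
        need_pkg("MASS")
        # collinear decimated features are expected; LDA handles them
        fit <- suppressWarnings(
          MASS::lda(train_x[, keep, drop = FALSE], grouping = train_y))
        as.character(stats::predict(fit, test_x[, keep, drop = FALSE])$class)
      },
      nb = {
        need_pkg("e1071")
        as.character(stats::predict(e1071::naiveBayes(tr_df, train_y), te_df))
      },
      rf = {
        need_pkg("randomForest")
        as.character(stats::predict(
          randomForest::randomForest(tr_df, train_y, ntree = 200), te_df))
      },
      dt = {
        need_pkg("rpart")
        d <- cbind(tr_df, .y = train_y)
        fit <- rpart::rpart(.y ~ ., d, method = "class")
        as.character(stats::predict(fit, te_df, type = "class"))
      },
      et = {
        need_pkg("ranger")
        d <- cbind(tr_df, .y = train_y)
        fit <- ranger::ranger(.y ~ ., d, num.trees = 200,
                              splitrule = "extratrees", num.threads = 1)
        as.character(stats::predict(fit, te_df,
                                    num.threads = 1)$predictions)
      },
      gbm = {
        need_pkg("xgboost")
        fit <- xgboost::xgboost(train_x[, keep, drop = FALSE], train_y,
                                nrounds = 100, nthread = 1, verbosity = 0)
        # predict() returns P(second level) = P(abnormal)
        ifelse(stats::predict(fit, test_x[, keep, drop = FALSE]) > 0.5,
               "abnormal", "normal")
      })
    m <- binary_metrics(test_y, pred)
    data.frame(detector = det, accuracy = m$accuracy, precision = m$precision,
               f1 = m$f1, mcc = m$mcc)
  })
  if (!length(rows))
    return(data.frame(detector = character(), accuracy = numeric(),
                      precision = numeric(), f1 = numeric(), mcc = numeric()))
  do.call(rbind, rows)
}
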