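#' Classifier configuration
#'
#' Hyperparameters of the three-branch phase classifier. None of these are
#' physical constants; all are exercised by \code{\link{grid_search}}.
#'
#' @param conv_filters Conv1D filters per branch (default 32).
#' @param conv_kernel Conv1D kernel length in samples (default 7); must not
#'   exceed the window length in samples.
#' @param pool_size Max-pooling size (default 2).
#' @param dense_units Window-embedding width (default 64).
#' @param lstm_units LSTM units per direction (default 64).
#' @param attn_units Additive-attention hidden width (default 32).
#' @param dropout_rate Dropout on the BiLSTM outputs (default 0.2).
#' @param n_classes Number of categories (default 6).
#' @param r_ms Rising-phase duration, ms (default 30).
#' @param window_ms Time-window length, ms (default 10).
#' @param epochs Training epochs (default 100; the cosine schedule stretches
#'   over whatever count is chosen).
#' @param batch_size Minibatch size (default 16).
#' @param learning_rate Adam base learning rate (default 1e-3, cosine decay).
#' @param seed RNG seed for initialization, the train/validation split,
#'   shuffling and dropout.
#' @param confidence_threshold Minimum final-probability confidence for
#'   acceptance at deployment (default 0.8).
#' @param vote_threshold Fraction of the three phase labels that must agree
#'   with the final label for acceptance (default 0.5, i.e. at least 2 of 3).
#' @param val_fraction Validation share of the stratified split (default 0.2,
#'   the 8:2 split).
#' @param lambda_phase Weight of the per-phase loss terms relative to the
#'   whole-phase loss (default 1).
#' @return An object of class \code{classifier_config}.
#' @export
classifier_config <- function(conv_filters = 32, conv_kernel = 7,
                              pool_size = 2, dense_units = 64,
                              lstm_units = 64, attn_units = 32,
                              dropout_rate = 0.2, n_classes = 6,
                              r_ms = 30, window_ms = 10, epochs = 100,
                              batch_size = 16, learning_rate = 1e-3,
                              seed = 42L, confidence_threshold = 0.8,
                              vote_threshold = 0.5, val_fraction = 0.2,
                              lambda_phase = 1) {
  cfg <- list(conv_filters = as.integer(conv_filters),
              conv_kernel = as.integer(conv_kernel),
              pool_size = as.integer(pool_size),
              dense_units = as.integer(dense_units),
              lstm_units = as.integer(lstm_units),
              attn_units = as.integer(attn_units),
              dropout_rate = dropout_rate, n_classes = as.integer(n_classes),
              r_ms = r_ms, window_ms = window_ms, epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              learning_rate = learning_rate, seed = as.integer(seed),
              confidence_threshold = confidence_threshold,
              vote_threshold = vote_threshold, val_fraction = val_fraction,
              lambda_phase = lambda_phase)
  stopifnot(cfg$conv_filters >= 1, cfg$conv_kernel >= 1, cfg$pool_size >= 1,
            cfg$dense_units >= 1, cfg$lstm_units >= 1, cfg$attn_units >= 1,
            cfg$epochs >= 1, cfg$batch_size >= 1)
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  for (th in c("confidence_threshold", "vote_threshold"))
    if (cfg[[th]] < 0 || cfg[[th]] > 1) stop(sprintf("%s must be in [0, 1]", th))
  structure(cfg, class = "classifier_config")
}

PHASES <- c("rising", "sustaining", "falling")

# stack a recording set into per-phase tensors [N, nw, wl, n_sweeps]
stack_tensors <- function(set, r_ms, window_ms) {
  tens <- lapply(set$recordings, preprocess_recording, r_ms = r_ms,
                 window_ms = window_ms)
  out <- list()
  for (ph in PHASES) {
    dm <- dim(tens[[1]][[ph]])
    arr <- array(0, dim = c(length(tens), dm))
    for (i in seq_along(tens)) arr[i, , , ] <- tens[[i]][[ph]]
    out[[ph]] <- arr
  }
  out
}

stratified_split <- function(y, val_fraction) {
  val <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < 2L)
      stop(sprintf("class '%s' has fewer than 2 recordings; stratified split impossible", cl))
    nv <- max(1L, round(length(idx) * val_fraction))
    val <- c(val, sample(idx, nv))
  }
  sort(val)
}

forward_all <- function(params, tensors, idx, dropout_rate = 0, train = FALSE) {
  lapply(PHASES, function(ph)
    branch_forward(params[[ph]], tensors[[ph]][idx, , , , drop = FALSE],
                   dropout_rate = dropout_rate, train = train)) |>
    stats::setNames(PHASES)
}

phase_weights <- function(u) {
  e <- exp(u - max(u))
  e / sum(e)
}

combine_probs <- function(fwds, u) {
  wp <- phase_weights(u)
  wp[1] * fwds$rising$probs + wp[2] * fwds$sustaining$probs +
    wp[3] * fwds$falling$probs
}

#' Train the three-branch phase classifier
#'
#' Each branch (rising, sustaining, falling) is a 1DCNN-BiLSTM-attention
#' network over that phase's window tensor; the whole-phase probability is
#' the convex combination of the three per-phase probabilities under a
#' learned softmax of three phase weights. Branches and phase weights are
#' trained jointly by Adam on the sum of the whole-phase and per-phase
#' cross-entropies, with a seeded stratified 8:2 train/validation split and
#' per-epoch accuracy history.
#'
#' @param set Labelled six-category \code{\link{recording_set}}.
#' @param config A \code{\link{classifier_config}}.
#' @param verbose Print per-epoch progress (default \code{FALSE}).
#' @return An object of class \code{patch_classifier} with elements
#'   \code{params}, \code{u} (phase-weight logits), \code{config},
#'   \code{classes}, \code{history} (per-epoch train/val accuracy and loss)
#'   and the preprocessing contract.
#' @export
train_classifier <- function(set, config = classifier_config(),
                             verbose = FALSE) {
  labels <- set_labels(set)
  classes <- NORMAL_CATEGORIES[seq_len(config$n_classes)]
  if (!all(labels %in% classes))
    stop("training set contains labels outside the category vocabulary")
  y <- match(labels, classes)
  set.seed(config$seed)
  tensors <- stack_tensors(set, config$r_ms, config$window_ms)
  n <- length(y)
  val_idx <- stratified_split(labels, config$val_fraction)
  tr_idx <- setdiff(seq_len(n), val_idx)
  wl <- dim(tensors$rising)[3]
  nsw <- dim(tensors$rising)[4]
  params <- lapply(PHASES, function(ph) init_branch(config, wl, nsw)) |>
    stats::setNames(PHASES)
  u <- rep(0, 3)
  flat <- flatten_params(list(rising = params$rising,
                              sustaining = params$sustaining,
                              falling = params$falling, u = u))
  opt <- adam_init(flat)
  history <- data.frame(epoch = integer(), lr = numeric(), loss = numeric(),
                        train_acc = numeric(), val_acc = numeric())
  nc <- config$n_classes
  onehot <- function(idx) {
    m <- matrix(0, length(idx), nc)
    m[cbind(seq_along(idx), idx)] <- 1
    m
  }
  for (epoch in seq_len(config$epochs)) {
    lr <- config$learning_rate *
      0.5 * (1 + cos(pi * (epoch - 1) / config$epochs))
    ord <- sample(tr_idx)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0; ep_correct <- 0
    for (bidx in batches) {
      params <- assign_flat(list(rising = params$rising,
                                 sustaining = params$sustaining,
                                 falling = params$falling), flat)
      uu <- flat$u
      fwds <- forward_all(params, tensors, bidx,
                          dropout_rate = config$dropout_rate, train = TRUE)
      bsz <- length(bidx)
      yb <- y[bidx]
      yoh <- onehot(yb)
      wp <- phase_weights(uu)
      final <- wp[1] * fwds$rising$probs + wp[2] * fwds$sustaining$probs +
        wp[3] * fwds$falling$probs
      eps <- 1e-12
      loss <- -mean(log(final[cbind(seq_len(bsz), yb)] + eps))
      for (ph in PHASES)
        loss <- loss - config$lambda_phase *
          mean(log(fwds[[ph]]$probs[cbind(seq_len(bsz), yb)] + eps))
      ep_loss <- ep_loss + loss * bsz
      ep_correct <- ep_correct + sum(max.col(final) == yb)
      # gradients
      dfinal <- -(yoh / (final + eps)) / bsz
      grads <- list()
      dwp <- numeric(3)
      for (pi_ in seq_along(PHASES)) {
        ph <- PHASES[pi_]
        pprobs <- fwds[[ph]]$probs
        dwp[pi_] <- sum(dfinal * pprobs)
        gprob <- wp[pi_] * dfinal
        dlog_final <- pprobs * (gprob - rowSums(gprob * pprobs))
        dlog_phase <- config$lambda_phase * (pprobs - yoh) / bsz
        grads[[ph]] <- branch_backward(params[[ph]], fwds[[ph]],
                                       dlog_final + dlog_phase)
      }
      grads$u <- wp * (dwp - sum(wp * dwp))
      gflat <- flatten_params(grads)
      stepped <- adam_step(flat, gflat, opt, lr)
      flat <- stepped$flat; opt <- stepped$state
    }
    params <- assign_flat(list(rising = params$rising,
                               sustaining = params$sustaining,
                               falling = params$falling), flat)
    vf <- forward_all(params, tensors, val_idx)
    val_final <- combine_probs(vf, flat$u)
    val_acc <- mean(max.col(val_final) == y[val_idx])
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, loss = ep_loss / length(tr_idx),
      train_acc = ep_correct / length(tr_idx), val_acc = val_acc))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  train %.3f  val %.3f",
                      epoch, ep_loss / length(tr_idx),
                      ep_correct / length(tr_idx), val_acc))
  }
  proto <- set$recordings[[1]]$protocol
  structure(list(params = params, u = flat$u, config = config,
                 classes = classes, history = history,
                 protocol_template = list(onset = proto$onset,
                                          offset = proto$offset,
                                          duration = proto$duration,
                                          rate = proto$rate,
                                          n_sweeps = length(proto$steps)),
                 val_idx = val_idx),
            class = "patch_classifier")
}

#' @export
print.patch_classifier <- function(x, ...) {
  np <- sum(vapply(x$params, n_branch_params, numeric(1))) + 3
  cat(sprintf("Phase classifier: 3 x 1DCNN-BiLSTM-Attention, %d classes, %s parameters\n",
              x$config$n_classes, format(np, big.mark = ",")))
  cat(sprintf("  phase weights (r/s/f): %s\n",
              paste(sprintf("%.3f", phase_weights(x$u)), collapse = " / ")))
  if (nrow(x$history))
    cat(sprintf("  trained %d epochs; final val accuracy %.4f (max %.4f)\n",
                nrow(x$history), x$history$val_acc[nrow(x$history)],
                max(x$history$val_acc)))
  invisible(x)
}

#' @export
summary.patch_classifier <- function(object, ...) {
  print(object)
  cat("  per-branch parameters:\n")
  for (ph in PHASES)
    cat(sprintf("    %-10s %s\n", ph,
                format(n_branch_params(object$params[[ph]]), big.mark = ",")))
  invisible(object)
}

#' @export
plot.patch_classifier <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$val_acc, type = "l", col = "firebrick", lwd = 2,
                 ylim = range(c(h$train_acc, h$val_acc)),
                 xlab = "epoch", ylab = "accuracy",
                 main = "Learning curve", ...)
  graphics::lines(h$epoch, h$train_acc, col = "steelblue", lwd = 2)
  graphics::legend("bottomright", c("validation", "train"),
                   col = c("firebrick", "steelblue"), lwd = 2, bty = "n")
  invisible(x)
}

check_protocol_match <- function(model, protocol) {
  tm <- model$protocol_template
  ok <- isTRUE(all.equal(tm$onset, protocol$onset)) &&
    isTRUE(all.equal(tm$offset, protocol$offset)) &&
    isTRUE(all.equal(tm$duration, protocol$duration)) &&
    isTRUE(all.equal(tm$rate, protocol$rate)) &&
    tm$n_sweeps == length(protocol$steps)
  if (!ok) stop("protocol mismatch: recording does not match the training protocol")
}

predict_probs <- function(object, set) {
  tensors <- stack_tensors(set, object$config$r_ms, object$config$window_ms)
  fwds <- forward_all(object$params, tensors, seq_along(set$recordings))
  final <- combine_probs(fwds, object$u)
  colnames(final) <- object$classes
  per_phase <- lapply(fwds, function(f) {
    colnames(f$probs) <- object$classes
    f$probs
  })
  attn <- lapply(fwds, `[[`, "alpha")
  list(final = final, per_phase = per_phase, attention = attn)
}

#' Predict the category of recordings
#'
#' Computes per-phase class probabilities from each branch, combines them as
#' a convex combination under the learned phase weights, and applies the
#' acceptance rule: a prediction is accepted when its confidence (maximum
#' final probability) reaches \code{confidence_threshold} \emph{and} at least
#' \code{ceiling(3 * vote_threshold)} of the three per-phase labels agree
#' with the final label; otherwise the recording is flagged \code{REJECTED}.
#'
#' @param object A trained \code{\link{train_classifier}} model.
#' @param newdata A \code{\link{recording}} or \code{\link{recording_set}}
#'   matching the training protocol.
#' @param reject Apply the low-confidence rejection rule (default
#'   \code{TRUE}; evaluation disables it).
#' @param ... Unused.
#' @return A data frame with one row per recording: \code{label} (category or
#'   \code{"REJECTED"}), \code{raw_label}, per-phase labels, \code{confidence}
#'   and \code{accepted}; the final and per-phase probability matrices and
#'   per-phase attention weights are attached as attributes.
#' @export
predict.patch_classifier <- function(object, newdata, reject = TRUE, ...) {
  set <- if (inherits(newdata, "recording"))
    recording_set(list(newdata)) else newdata
  if (!inherits(set, "recording_set"))
    stop("newdata must be a recording or recording_set")
  for (r in set$recordings) check_protocol_match(object, r$protocol)
  pr <- predict_probs(object, set)
  final_idx <- max.col(pr$final)
  raw_label <- object$classes[final_idx]
  conf <- pr$final[cbind(seq_along(final_idx), final_idx)]
  phase_lab <- sapply(PHASES, function(ph)
    object$classes[max.col(pr$per_phase[[ph]])])
  phase_lab <- matrix(phase_lab, ncol = 3,
                      dimnames = list(NULL, PHASES))
  votes <- rowSums(phase_lab == raw_label)
  need <- ceiling(3 * object$config$vote_threshold)
  accepted <- conf >= object$config$confidence_threshold & votes >= need
  out <- data.frame(
    label = if (reject) ifelse(accepted, raw_label, "REJECTED") else raw_label,
    raw_label = raw_label,
    rising = phase_lab[, "rising"], sustaining = phase_lab[, "sustaining"],
    falling = phase_lab[, "falling"],
    confidence = conf, accepted = accepted)
  rownames(out) <- NULL
  attr(out, "final_probs") <- pr$final
  attr(out, "phase_probs") <- pr$per_phase
  attr(out, "attention") <- pr$attention
  out
}

#' Evaluate the classifier on a labelled test set
#'
#' Rejection is disabled: every test recording is scored. Returns one
#' \code{\link{multiclass_metrics}} report per phase branch plus the
#' whole-phase ("entire") report, the latter two with one-vs-rest AP and
#' ROC AUC per class.
#'
#' @param model A trained \code{\link{train_classifier}} model.
#' @param set Labelled \code{\link{recording_set}}.
#' @return List with elements \code{entire}, \code{rising},
#'   \code{sustaining}, \code{falling}, each a \code{metrics_report}.
#' @export
evaluate_classifier <- function(model, set) {
  truth <- set_labels(set)
  pred <- predict(model, set, reject = FALSE)
  final_probs <- attr(pred, "final_probs")
  phase_probs <- attr(pred, "phase_probs")
  out <- list(entire = multiclass_metrics(truth, pred$raw_label, final_probs,
                                          classes = model$classes))
  for (ph in PHASES)
    out[[ph]] <- multiclass_metrics(truth, pred[[ph]], phase_probs[[ph]],
                                    classes = model$classes)
  out
}

#' Grid search over classifier hyperparameters
#'
#' Exhaustively trains one model per combination of the supplied candidate
#' values (all other fields taken from \code{base}) and selects the
#' configuration with the highest final validation accuracy; ties break
#' toward the smaller model (fewer parameters).
#'
#' @param set Labelled training \code{\link{recording_set}}.
#' @param grid Named list mapping \code{\link{classifier_config}} fields to
#'   candidate value vectors; must be non-empty.
#' @param base Base configuration (default \code{classifier_config()}).
#' @param verbose Print progress.
#' @return List with \code{best_config}, \code{best_model} and \code{table}
#'   (one row per combination with its validation accuracy and size).
#' @export
grid_search <- function(set, grid, base = classifier_config(),
                        verbose = FALSE) {
  if (!length(grid)) stop("grid must be non-empty")
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  results <- vector("list", nrow(combos))
  models <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cfg <- base
    for (nm in names(combos)) cfg[[nm]] <- combos[[nm]][i]
    cfg <- do.call(classifier_config, unclass(cfg))
    m <- train_classifier(set, cfg)
    np <- sum(vapply(m$params, n_branch_params, numeric(1))) + 3
    results[[i]] <- cbind(combos[i, , drop = FALSE],
                          val_acc = m$history$val_acc[nrow(m$history)],
                          n_params = np)
    models[[i]] <- m
    if (verbose)
      message(sprintf("grid %d/%d: val %.4f (%s params)", i, nrow(combos),
                      results[[i]]$val_acc, format(np, big.mark = ",")))
  }
  tab <- do.call(rbind, results)
  best <- order(-tab$val_acc, tab$n_params)[1]
  list(best_config = models[[best]]$config, best_model = models[[best]],
       table = tab)
}
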