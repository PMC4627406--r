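# Three-layer feed-forward network trained by backpropagation with
# momentum on the mean squared error, sigmoid activations throughout.
# The implementation is deliberately plain full-batch gradient descent:
# the training scheme itself (learning rate, momentum, epoch selection)
# is part of the method under study, so it is written out rather than
# delegated to a generic optimizer.

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Training configuration for the network
#'
#' @param hidden_neurons Hidden layer width (>= 1).
#' @param learning_rate Gradient step size (> 0); default 0.5.
#' @param momentum Momentum coefficient in `[0, 1)`; default 0.9.
#' @param max_epochs Training epochs; default 200.
#' @param early_stop_frac Fraction of the training pool held out as an
#'   internal early-stopping slice; the reported model is the epoch with
#'   minimal slice MSE. `0` disables epoch selection (the last epoch is
#'   kept). Default 0.1.
#' @param batch_size Minibatch size; `NULL` (default) trains full batch.
#' @param decision_threshold Probability cut for classification, in
#'   `(0, 1)`; default 0.5.
#' @param seed Integer seed for weight initialization and slice draw.
#' @return Object of class `ann_config`.
#' @export
ann_config <- function(hidden_neurons, learning_rate = 0.5, momentum = 0.9,
                       max_epochs = 200L, early_stop_frac = 0.1,
                       batch_size = NULL, decision_threshold = 0.5,
                       seed = 1L) {
  if (!is.numeric(hidden_neurons) || hidden_neurons < 1 ||
      hidden_neurons != floor(hidden_neurons))
    stop("hidden_neurons must be a positive integer")
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    stop("learning_rate must be > 0")
  if (!is.numeric(momentum) || momentum < 0 || momentum >= 1)
    stop("momentum must be in [0, 1)")
  if (!is.numeric(decision_threshold) || decision_threshold <= 0 ||
      decision_threshold >= 1)
    stop("decision_threshold must be in (0, 1)")
  if (!is.numeric(early_stop_frac) || early_stop_frac < 0 || early_stop_frac >= 1)
    stop("early_stop_frac must be in [0, 1)")
  structure(list(hidden_neurons = as.integer(hidden_neurons),
                 learning_rate = learning_rate, momentum = momentum,
                 max_epochs = as.integer(max_epochs),
                 early_stop_frac = early_stop_frac,
                 batch_size = if (is.null(batch_size)) NULL else as.integer(batch_size),
                 decision_threshold = decision_threshold,
                 seed = as.integer(seed)),
            class = "ann_config")
}

# Forward pass; returns hidden activations and output vector.
ann_forward <- function(W1, b1, w2, b2, X) {
  H <- sigmoid(sweep(X %*% W1, 2, b1, `+`))
  o <- as.vector(sigmoid(H %*% w2 + b2))
  list(H = H, o = o)
}

#' Analytic backpropagation gradient of the batch MSE
#'
#' Gradient of `mean((o - y)^2)` with respect to all weights and biases,
#' as backpropagation computes it. Exposed so the analytic gradient can
#' be verified against finite differences.
#'
#' @param W1,b1 Input-to-hidden weights (d x h) and hidden bias (h).
#' @param w2,b2 Hidden-to-output weights (h) and output bias (scalar).
#' @param X Feature matrix (n x d), `y` 0/1 labels (n).
#' @param y Binary label vector.
#' @return List `gW1`, `gb1`, `gw2`, `gb2` plus the batch `mse`.
#' @export
ann_gradient <- function(W1, b1, w2, b2, X, y) {
  n <- nrow(X)
  f <- ann_forward(W1, b1, w2, b2, X)
  err <- f$o - y
  delta_o <- (2 / n) * err * f$o * (1 - f$o)
  gw2 <- as.vector(crossprod(f$H, delta_o))
  gb2 <- sum(delta_o)
  delta_h <- (delta_o %o% w2) * f$H * (1 - f$H)
  gW1 <- crossprod(X, delta_h)
  gb1 <- colSums(delta_h)
  list(gW1 = gW1, gb1 = gb1, gw2 = gw2, gb2 = gb2, mse = mean(err^2))
}

#' Train the three-layer network
#'
#' Gradient descent with momentum on the batch MSE; sigmoid activations
#' at the hidden and output layer; weights initialized uniformly in
#' `[-0.5, 0.5]` from the configured seed. When `early_stop_frac > 0`, a
#' stratified slice of the rows is held out of the gradient updates and
#' the returned weights are those of the epoch minimizing slice MSE.
#'
#' @param X 0/1 (or numeric) feature matrix, one row per patient.
#' @param y Binary label vector aligned with `X` rows.
#' @param config An [ann_config()].
#' @return Object of class `ann_model`: weights, config, `best_epoch`,
#'   `training_mse_trace` and (if a slice was used) `slice_mse_trace`.
#' @export
ann_train <- function(X, y, config) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("rows of X must align with y")
  if (anyNA(X) || anyNA(y)) stop("X and y must be complete")
  if (length(unique(y)) < 2L)
    stop("y contains a single class; cannot train a classifier")
  d <- ncol(X); h <- config$hidden_neurons
  with_seed(config$seed, {
    slice <- integer(0)
    if (config$early_stop_frac > 0 && length(y) >= 10L) {
      slice <- stratified_sample(y, config$early_stop_frac)
      # slice must keep a trainable remainder
      if (length(unique(y[-slice])) < 2L) slice <- integer(0)
    }
    tr <- if (length(slice)) setdiff(seq_along(y), slice) else seq_along(y)
    W1 <- matrix(stats::runif(d * h, -0.5, 0.5), d, h)
    b1 <- stats::runif(h, -0.5, 0.5)
    w2 <- stats::runif(h, -0.5, 0.5)
    b2 <- stats::runif(1, -0.5, 0.5)
    vW1 <- matrix(0, d, h); vb1 <- numeric(h); vw2 <- numeric(h); vb2 <- 0
    lr <- config$learning_rate; mom <- config$momentum
    mse_trace <- numeric(config$max_epochs)
    slice_trace <- if (length(slice)) numeric(config$max_epochs) else NULL
    best <- list(mse = Inf, epoch = NA_integer_)
    batches <- if (is.null(config$batch_size)) list(tr) else
      split(tr, ceiling(seq_along(tr) / config$batch_size))
    for (epoch in seq_len(config$max_epochs)) {
      for (b in batches) {
        g <- ann_gradient(W1, b1, w2, b2, X[b, , drop = FALSE], y[b])
        vW1 <- mom * vW1 - lr * g$gW1; W1 <- W1 + vW1
        vb1 <- mom * vb1 - lr * g$gb1; b1 <- b1 + vb1
        vw2 <- mom * vw2 - lr * g$gw2; w2 <- w2 + vw2
        vb2 <- mom * vb2 - lr * g$gb2; b2 <- b2 + vb2
      }
      mse_trace[epoch] <-
        mean((ann_forward(W1, b1, w2, b2, X[tr, , drop = FALSE])$o - y[tr])^2)
      sel_mse <- if (length(slice)) {
        slice_trace[epoch] <-
          mean((ann_forward(W1, b1, w2, b2, X[slice, , drop = FALSE])$o - y[slice])^2)
        slice_trace[epoch]
      } else mse_trace[epoch]
      if (sel_mse < best$mse) {
        best <- list(mse = sel_mse, epoch = epoch,
                     W1 = W1, b1 = b1, w2 = w2, b2 = b2)
      }
    }
    keep_last <- length(slice) == 0L
    structure(list(
      W1 = if (keep_last) W1 else best$W1,
      b1 = if (keep_last) b1 else best$b1,
      w2 = if (keep_last) w2 else best$w2,
      b2 = if (keep_last) b2 else best$b2,
      config = config, features = colnames(X),
      best_epoch = if (keep_last) config$max_epochs else best$epoch,
      training_mse_trace = mse_trace, slice_mse_trace = slice_trace),
      class = "ann_model")
  })
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf("ANN model: %d-%d-1 (sigmoid), lr %.3g, momentum %.3g\n",
              nrow(x$W1), ncol(x$W1), x$config$learning_rate,
              x$config$momentum))
  cat(sprintf("  selected epoch %d, final training MSE %.5f\n",
              x$best_epoch, utils::tail(x$training_mse_trace, 1)))
  invisible(x)
}

#' Network output probabilities
#'
#' The output neuron's activation is interpreted as the probability of a
#' positive diagnosis; classification compares it with the configured
#' decision threshold.
#'
#' @param model An [ann_train()] model.
#' @param X Feature matrix with the model's feature count.
#' @return Numeric vector of probabilities in `(0, 1)`.
#' @export
ann_predict <- function(model, X) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  if (ncol(X) != nrow(model$W1))
    stop("feature count mismatch: model expects ", nrow(model$W1),
         ", got ", ncol(X))
  ann_forward(model$W1, model$b1, model$w2, model$b2, X)$o
}

#' @rdname ann_predict
#' @return `ann_classify()` returns a 0/1 integer vector.
#' @export
ann_classify <- function(model, X) {
  as.integer(ann_predict(model, X) >= model$config$decision_threshold)
}

# Stratified sample of ceiling(frac * class size) indices per class.
stratified_sample <- function(y, frac) {
  idx <- split(seq_along(y), y)
  sort(unlist(lapply(idx, function(i)
    sample(i, max(1L, round(length(i) * frac)))), use.names = FALSE))
}

# Stratified k-fold assignment: within each class, shuffled indices are
# dealt round-robin so every fold holds both classes when feasible.
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (i in split(seq_along(y), y)) {
    folds[sample(i)] <- rep_len(seq_len(k), length(i))
  }
  folds
}

#' Stratified train/validation holdout split
#'
#' @param y Binary labels (the split is stratified on them).
#' @param train_fraction Fraction assigned to the training pool; default
#'   0.85 (an 85/15 split).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `validation`.
#' @export
holdout_split <- function(y, train_fraction = 0.85, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  with_seed(seed, {
    for (attempt in 1:25) {
      val <- stratified_sample(y, 1 - train_fraction)
      ok <- length(unique(y[val])) == length(unique(y)) &&
        length(unique(y[-val])) == length(unique(y))
      if (ok) break
      message("holdout split attempt ", attempt,
              " left a side single-class; re-drawing")
    }
    if (!ok) warning("holdout split could not place every class on both sides")
    list(train = setdiff(seq_along(y), val), validation = val)
  })
}

#' Hidden-layer width sweep under stratified k-fold cross-validation
#'
#' For each candidate width, trains on k-1 folds and scores the held-out
#' fold by AUC; reports the mean and SD across folds and the width
#' attaining the maximal mean AUC (ties broken toward the smallest
#' width).
#'
#' @param X Feature matrix; `y` binary labels.
#' @param y Binary label vector.
#' @param sizes Candidate hidden widths; default `1:77`.
#' @param k Number of folds; default 10.
#' @param base_config An [ann_config()] supplying the remaining
#'   hyperparameters (its `hidden_neurons` is overridden per candidate).
#' @param seed Integer seed for fold assignment and per-fit init.
#' @return Object of class `ann_sweep`: `table` (data frame `hidden`,
#'   `mean_auc`, `sd_auc`), `best_hidden`, `folds`, `seed`.
#' @export
sweep_hidden <- function(X, y, sizes = 1:77, k = 10L,
                         base_config = ann_config(hidden_neurons = 1),
                         seed = 1L) {
  y <- as.numeric(y)
  if (k > length(y)) stop("k exceeds the number of rows")
  if (k < 2L) stop("k must be >= 2")
  folds <- with_seed(seed, stratified_folds(y, k))
  aucs <- matrix(NA_real_, length(sizes), k)
  for (si in seq_along(sizes)) {
    cfg <- base_config
    cfg$hidden_neurons <- as.integer(sizes[si])
    for (fold in seq_len(k)) {
      test <- which(folds == fold)
      if (length(unique(y[test])) < 2L || length(unique(y[-test])) < 2L) next
      cfg$seed <- as.integer((seed + 1009L * fold + 31L * si) %% .Machine$integer.max)
      fit <- ann_train(X[-test, , drop = FALSE], y[-test], cfg)
      aucs[si, fold] <- roc_auc(ann_predict(fit, X[test, , drop = FALSE]),
                                y[test])$auc
    }
  }
  tab <- data.frame(hidden = sizes,
                    mean_auc = rowMeans(aucs, na.rm = TRUE),
                    sd_auc = apply(aucs, 1, stats::sd, na.rm = TRUE))
  structure(list(table = tab,
                 best_hidden = sizes[which.max(tab$mean_auc)],
                 folds = folds, seed = seed),
            class = "ann_sweep")
}

#' @export
print.ann_sweep <- function(x, ...) {
  cat("Hidden-width sweep over", nrow(x$table), "candidates,",
      max(x$folds), "folds\n")
  cat(sprintf("  best width %d (mean AUC %.3f)\n", x$best_hidden,
              max(x$table$mean_auc)))
  invisible(x)
}

#' Serialize a trained model to portable text
#'
#' Layout: a header with layer shapes and hyperparameters, then the
#' weight blocks as full-precision decimal text, one row per line.
#'
#' @param model An `ann_model`.
#' @param path Output file.
#' @return `path` (writer) or the model (reader).
#' @export
write_ann_model <- function(model, path) {
  num <- function(x) paste(format(x, digits = 17, trim = TRUE), collapse = " ")
  lines <- c(
    "neuralhypernet ann model v1",
    paste("shape", nrow(model$W1), ncol(model$W1), 1),
    paste("learning_rate", num(model$config$learning_rate)),
    paste("momentum", num(model$config$momentum)),
    paste("decision_threshold", num(model$config$decision_threshold)),
    paste("best_epoch", model$best_epoch),
    paste("features", paste(model$features, collapse = "\t")),
    "W1", apply(model$W1, 1, num),
    "b1", num(model$b1),
    "w2", num(model$w2),
    "b2", num(model$b2))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ann_model
#' @export
read_ann_model <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "neuralhypernet ann model v1") stop("unrecognized model file")
  shape <- as.integer(strsplit(lines[2], " ")[[1]][-1])
  d <- shape[1]; h <- shape[2]
  val <- function(key) sub(paste0("^", key, " "), "", grep(paste0("^", key, " "),
                                                           lines, value = TRUE)[1])
  parse_row <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  i_w1 <- which(lines == "W1")[1]
  W1 <- do.call(rbind, lapply(lines[i_w1 + seq_len(d)], parse_row))
  b1 <- parse_row(lines[which(lines == "b1")[1] + 1L])
  w2 <- parse_row(lines[which(lines == "w2")[1] + 1L])
  b2 <- parse_row(lines[which(lines == "b2")[1] + 1L])
  feats <- strsplit(val("features"), "\t", fixed = TRUE)[[1]]
  if (length(feats) == d) rownames(W1) <- feats
  cfg <- ann_config(hidden_neurons = h,
                    learning_rate = as.numeric(val("learning_rate")),
                    momentum = as.numeric(val("momentum")),
                    decision_threshold = as.numeric(val("decision_threshold")))
  structure(list(W1 = W1, b1 = b1, w2 = w2, b2 = b2, config = cfg,
                 features = feats,
                 best_epoch = as.integer(val("best_epoch")),
                 training_mse_trace = numeric(0), slice_mse_trace = NULL),
            class = "ann_model")
}
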