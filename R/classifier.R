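#' Classifier configuration
#'
#' `"LM-CNN"` is the layer-modified network: two 3x3 tanh convolutions each
#' followed by batch normalization, one 2x2 max-pool, dropout 0.5, a dense
#' layer of 100 ReLU units and a softmax output. `"CNN2"`, `"CNN3"` and
#' `"CNN4"` are the comparison stacks (ReLU convolutions, selu dense
#' layers of 100/256/256 units, one or two pooling layers, no batch norm).
#'
#' @param architecture One of `"LM-CNN"`, `"CNN2"`, `"CNN3"`, `"CNN4"`.
#' @param n_classes Number of output classes (>= 2), default 3.
#' @param conv_activation Convolution activation; default tanh for LM-CNN,
#'   relu otherwise.
#' @param dense_activation Hidden dense activation for LM-CNN (default relu).
#' @param dense_units Hidden dense width for LM-CNN (default 100).
#' @param dropout_rate Dropout rate in `[0, 1)` (default 0.5).
#' @param batch_norm Use batch normalization after each convolution
#'   (LM-CNN only; default `TRUE`).
#' @param conv_filters Filter counts for the (up to) two convolutions.
#' @param optimizer List with `name` (`"adam"`), `learning_rate`, `beta_1`,
#'   `beta_2`; defaults 0.001 / 0.9 / 0.999.
#' @param batch_size Minibatch size (default 32).
#' @param epochs Training epochs (default 50).
#' @param seed RNG seed governing initialization, shuffling and dropout.
#' @return An object of class `model_config`.
#' @export
model_config <- function(architecture = c("LM-CNN", "CNN2", "CNN3", "CNN4"),
                         n_classes = 3L,
                         conv_activation = NULL,
                         dense_activation = "relu",
                         dense_units = 100L,
                         dropout_rate = 0.5,
                         batch_norm = TRUE,
                         conv_filters = c(32L, 64L),
                         optimizer = list(name = "adam", learning_rate = 0.001,
                                          beta_1 = 0.9, beta_2 = 0.999),
                         batch_size = 32L,
                         epochs = 50L,
                         seed = 1L) {
  architecture <- match.arg(architecture)
  if (is.null(conv_activation)) {
    conv_activation <- if (architecture == "LM-CNN") "tanh" else "relu"
  }
  if (dropout_rate < 0 || dropout_rate >= 1) stopf("dropout_rate must be in [0, 1)")
  if (optimizer$learning_rate <= 0) stopf("learning_rate must be > 0")
  if (n_classes < 2L) stopf("n_classes must be >= 2")
  structure(
    list(architecture = architecture, n_classes = as.integer(n_classes),
         conv_activation = conv_activation,
         dense_activation = dense_activation,
         dense_units = as.integer(dense_units),
         dropout_rate = dropout_rate, batch_norm = isTRUE(batch_norm),
         conv_filters = as.integer(conv_filters), optimizer = optimizer,
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         seed = as.integer(seed)),
    class = "model_config"
  )
}

as_input_array <- function(x) {
  if (is.list(x)) {
    d <- dim(x[[1]])
    arr <- array(0, c(length(x), d[1], d[2]))
    for (i in seq_along(x)) arr[i, , ] <- unclass(x[[i]])
    x <- arr
  }
  if (length(dim(x)) != 3L) stopf("inputs must be a list of matrices or an N x rows x cols array")
  x
}

labels_of <- function(mats) {
  vapply(mats, function(m) attr(m, "label") %||% NA_character_, character(1))
}

#' Build an untrained classifier
#'
#' @param cfg A [model_config()].
#' @param input_shape `(rows, cols)` of the feature grid, e.g. `c(8, 14)`.
#' @param class_labels Class label order of the softmax output.
#' @return An object of class `trained_classifier` with freshly initialized
#'   (seeded) parameters, empty history.
#' @export
build_model <- function(cfg, input_shape,
                        class_labels = c("RELAX", "LEFT", "RIGHT")) {
  stopifnot(inherits(cfg, "model_config"))
  if (length(class_labels) != cfg$n_classes) {
    stopf("class_labels must have n_classes = %d entries", cfg$n_classes)
  }
  if (min(input_shape) < 2L) stopf("input too small for the conv/pool stack")
  layers <- layer_stack(cfg$architecture, cfg$n_classes, cfg)
  layers <- with_seed(cfg$seed, init_network(layers, as.integer(input_shape)))
  structure(
    list(cfg = cfg, layers = layers, input_shape = as.integer(input_shape),
         class_labels = class_labels,
         history = data.frame(epoch = integer(0), loss = numeric(0),
                              accuracy = numeric(0)),
         feature_stats = NULL),
    class = "trained_classifier"
  )
}

#' @export
print.trained_classifier <- function(x, ...) {
  types <- vapply(x$layers, `[[`, character(1), "type")
  cat(sprintf("<trained_classifier> %s, input %s, classes: %s\n",
              x$cfg$architecture, paste(x$input_shape, collapse = "x"),
              paste(x$class_labels, collapse = "/")))
  cat(sprintf("  layers: %s\n", paste(types, collapse = " -> ")))
  cat(sprintf("  trained epochs: %d\n", nrow(x$history)))
  invisible(x)
}

#' Count layers of each type in a model
#'
#' @param clf A `trained_classifier`.
#' @return Named integer table of layer types.
#' @export
layer_summary <- function(clf) {
  table(vapply(clf$layers, `[[`, character(1), "type"))
}

#' Train a classifier with Adam
#'
#' Minimizes softmax cross-entropy with Adam (defaults: learning rate
#' 0.001, beta1 0.9, beta2 0.999). Shuffling, dropout and initialization
#' are all driven by `seed`, so a run is bit-reproducible. With
#' `cfg$epochs = 0` the initialized model is returned untouched with an
#' empty history.
#'
#' @param model A model from [build_model()].
#' @param x Training inputs: list of standardized feature matrices (with
#'   `label` attributes) or an `N x rows x cols` array.
#' @param y Labels (taken from the matrices' attributes when omitted).
#' @param epochs,batch_size Optional overrides of the config.
#' @param seed Seed for shuffling/dropout; default `model$cfg$seed`.
#' @return The trained `trained_classifier` with a per-epoch history.
#' @export
train <- function(model, x, y = NULL, epochs = NULL, batch_size = NULL,
                  seed = NULL) {
  stopifnot(inherits(model, "trained_classifier"))
  if (is.null(y) && is.list(x)) y <- labels_of(x)
  xa <- as_input_array(x)
  if (anyNA(y)) stopf("missing training labels")
  if (length(unique(y)) < 2L) stopf("single-class training set rejected")
  bad <- setdiff(unique(y), model$class_labels)
  if (length(bad)) stopf("label(s) outside the class set: %s", paste(bad, collapse = ", "))
  cfg <- model$cfg
  epochs <- epochs %||% cfg$epochs
  batch_size <- batch_size %||% cfg$batch_size
  seed <- seed %||% cfg$seed
  if (epochs == 0L) return(model)

  N <- dim(xa)[1]
  yi <- match(y, model$class_labels)
  onehot <- matrix(0, N, cfg$n_classes)
  onehot[cbind(seq_len(N), yi)] <- 1
  hw <- dim(xa)[2:3]
  x2 <- matrix(xa, N, prod(hw))      # rows = samples; fast minibatch slicing
  layers <- model$layers
  state <- adam_state(layers)
  opt <- cfg$optimizer
  t_ <- 0L
  hist <- data.frame(epoch = integer(0), loss = numeric(0), accuracy = numeric(0))

  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      ep_loss <- 0; ep_hit <- 0L
      for (start in seq(1L, N, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, N)]
        xb <- x2[idx, , drop = FALSE]
        dim(xb) <- c(length(idx), hw, 1L)
        yb <- onehot[idx, , drop = FALSE]
        fw <- network_forward(layers, xb, training = TRUE)
        layers <- fw$layers          # batch-norm running stats advanced
        probs <- softmax_rows(fw$out)
        eps <- 1e-12
        loss <- -mean(log(rowSums(probs * yb) + eps))
        if (!is.finite(loss)) {
          stopf("divergence: NaN loss at epoch %d", ep)
        }
        ep_loss <- ep_loss + loss * length(idx)
        ep_hit <- ep_hit + sum(max.col(probs) == max.col(yb))
        grads <- network_backward(layers, fw$caches,
                                  (probs - yb) / length(idx))
        t_ <- t_ + 1L
        up <- adam_update(layers, grads, state, t_, opt$learning_rate,
                          opt$beta_1, opt$beta_2)
        layers <- up$layers; state <- up$state
      }
      hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / N,
                                     accuracy = ep_hit / N))
    }
  })
  model$layers <- layers
  model$history <- rbind(model$history, hist)
  model
}

#' Predict class labels and probabilities
#'
#' Runs the network in inference mode (batch-norm running statistics, no
#' dropout). Probabilities per row sum to 1.
#'
#' @param object A `trained_classifier`.
#' @param x Inputs as in [train()]; a zero-length list yields empty output.
#' @param ... Unused.
#' @return List with `labels` (character) and `probabilities`
#'   (`N x n_classes` matrix with class-label column names).
#' @export
predict.trained_classifier <- function(object, x, ...) {
  if (is.list(x) && length(x) == 0L) {
    return(list(labels = character(0),
                probabilities = matrix(numeric(0), 0L, object$cfg$n_classes,
                                       dimnames = list(NULL, object$class_labels))))
  }
  xa <- as_input_array(x)
  if (!all(dim(xa)[2:3] == object$input_shape)) {
    stopf("shape mismatch: expected %s grids", paste(object$input_shape, collapse = "x"))
  }
  x4 <- array(xa, c(dim(xa), 1L))
  fw <- network_forward(object$layers, x4, training = FALSE)
  probs <- softmax_rows(fw$out)
  colnames(probs) <- object$class_labels
  list(labels = object$class_labels[max.col(probs, ties.method = "first")],
       probabilities = probs)
}

#' Classification metrics from a test set
#'
#' Builds the confusion matrix (rows = truth, columns = prediction) and
#' derives accuracy and macro-averaged precision, recall and F1. Per-class
#' ratios with zero denominators contribute 0 to the macro averages.
#'
#' @param clf A `trained_classifier`.
#' @param x Test inputs.
#' @param y True labels (from the matrices' attributes when omitted).
#' @return An object of class `bci_metrics`: accuracy, precision, recall,
#'   f1, confusion (matrix), n.
#' @export
evaluate <- function(clf, x, y = NULL) {
  if (is.null(y) && is.list(x)) y <- labels_of(x)
  if (is.null(y) || length(y) == 0L) stopf("empty test set")
  pred <- predict(clf, x)$labels
  metrics_from_labels(y, pred, clf$class_labels)
}

#' Metrics from paired truth/prediction labels
#'
#' @param truth,pred Character vectors of equal length.
#' @param classes Class label order for the confusion matrix.
#' @return A `bci_metrics` object.
#' @export
metrics_from_labels <- function(truth, pred, classes = sort(unique(truth))) {
  if (!length(truth)) stopf("empty test set")
  cm <- table(factor(truth, levels = classes), factor(pred, levels = classes))
  cm <- unclass(as.matrix(cm))
  n <- sum(cm)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(
    list(accuracy = sum(tp) / n, precision = mean(prec), recall = mean(rec),
         f1 = mean(f1), confusion = cm, n = n),
    class = "bci_metrics"
  )
}

#' @export
print.bci_metrics <- function(x, ...) {
  cat(sprintf("<bci_metrics> n=%d  accuracy %.3f  precision %.3f  recall %.3f  F1 %.3f\n",
              x$n, x$accuracy, x$precision, x$recall, x$f1))
  print(x$confusion)
  invisible(x)
}

stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      if (length(idx) < k) stopf("class '%s' has fewer samples than k = %d folds", cl, k)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Grid-search cross-validation over batch size and epoch count
#'
#' Stratified k-fold CV over every (batch size, epochs) cell; returns the
#' cell with the highest mean validation accuracy, breaking ties toward the
#' smaller batch size and then fewer epochs.
#'
#' @param x Training inputs (list of feature matrices or array).
#' @param y Labels (from attributes when omitted).
#' @param batch_sizes,epoch_grid Candidate values; defaults
#'   `c(16, 32, 64)` and `c(20, 50, 100)`.
#' @param k Folds (default 3); every class needs at least `k` samples.
#' @param cfg Base [model_config()].
#' @param seed Seed for fold assignment and fold training.
#' @return List with `batch_size`, `epochs`, and the full `results` table.
#' @export
grid_search_cv <- function(x, y = NULL, batch_sizes = c(16L, 32L, 64L),
                           epoch_grid = c(20L, 50L, 100L), k = 3L,
                           cfg = model_config(), seed = cfg$seed) {
  if (is.null(y) && is.list(x)) y <- labels_of(x)
  if (!length(batch_sizes) || !length(epoch_grid)) stopf("empty grid")
  xa <- as_input_array(x)
  classes <- sort(unique(y))
  fold <- stratified_folds(y, k, seed)
  grid <- expand.grid(batch_size = sort(batch_sizes),
                      epochs = sort(epoch_grid))
  grid$mean_accuracy <- NA_real_
  for (gi in seq_len(nrow(grid))) {
    accs <- numeric(k)
    for (f in seq_len(k)) {
      tr <- fold != f
      m <- build_model(
        model_config(architecture = cfg$architecture, n_classes = length(classes),
                     conv_activation = cfg$conv_activation,
                     dense_activation = cfg$dense_activation,
                     dense_units = cfg$dense_units,
                     dropout_rate = cfg$dropout_rate,
                     batch_norm = cfg$batch_norm,
                     conv_filters = cfg$conv_filters,
                     optimizer = cfg$optimizer,
                     batch_size = grid$batch_size[gi],
                     epochs = grid$epochs[gi], seed = seed + f),
        input_shape = dim(xa)[2:3], class_labels = classes)
      m <- train(m, xa[tr, , , drop = FALSE], y[tr])
      accs[f] <- evaluate(m, xa[!tr, , , drop = FALSE], y[!tr])$accuracy
    }
    grid$mean_accuracy[gi] <- mean(accs)
  }
  # ties break toward smaller batch then fewer epochs (grid is so ordered
  # that which.max picks the first maximal row after sorting)
  o <- order(grid$batch_size, grid$epochs)
  grid <- grid[o, ]
  best <- grid[which.max(grid$mean_accuracy), ]
  list(batch_size = best$batch_size, epochs = best$epochs, results = grid)
}
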