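#' SMOTE: synthetic minority over-sampling
#'
#' Every minority class is brought up to the majority-class count by
#' interpolated synthetic points: each new point is
#' `x + u * (x_nn - x)` with `u ~ U[0, 1]`, `x` a randomly chosen
#' minority sample and `x_nn` one of its `k` nearest same-class
#' neighbors (Euclidean, brute force).  Original rows are returned
#' unchanged, synthetic rows appended.
#'
#' @param X numeric feature matrix (rows = beats).
#' @param y class labels (character or factor), one per row.
#' @param k neighbor count (default 5); lowered per class (with a
#'   message) when a class has fewer than `k + 1` members.
#' @param seed integer RNG seed.
#' @return list with `X`, `y` (balanced), and `n_synthetic` per class.
#' @export
smote_oversample <- function(X, y, k = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.character(y)
  stopifnot(nrow(X) == length(y))
  counts <- table(y)
  target <- max(counts)
  if (all(counts == target))
    return(list(X = X, y = y, n_synthetic = stats::setNames(
      rep(0L, length(counts)), names(counts))))

  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  newX <- list(); newy <- character(0)
  n_syn <- stats::setNames(rep(0L, length(counts)), names(counts))
  for (cl in names(counts)) {
    need <- target - counts[[cl]]
    if (need == 0L) next
    idx <- which(y == cl)
    if (length(idx) < 2L)
      stop("class '", cl, "' has a single member; SMOTE cannot interpolate")
    kc <- min(k, length(idx) - 1L)
    if (kc < k)
      message("SMOTE: class '", cl, "' has only ", length(idx),
              " members; using k = ", kc)
    Xc <- X[idx, , drop = FALSE]
    d2 <- as.matrix(stats::dist(Xc))^2
    diag(d2) <- Inf
    nn <- t(apply(d2, 1L, function(r) order(r)[seq_len(kc)]))
    pick <- rep_len(seq_along(idx), need)  # spread seed points evenly
    if (length(pick) > 1L) pick <- sample(pick)
    nnpick <- nn[cbind(pick, sample.int(kc, need, replace = TRUE))]
    u <- stats::runif(need)
    syn <- Xc[pick, , drop = FALSE] +
      u * (Xc[nnpick, , drop = FALSE] - Xc[pick, , drop = FALSE])
    newX[[cl]] <- syn
    newy <- c(newy, rep(cl, need))
    n_syn[cl] <- need
  }
  list(X = rbind(X, do.call(rbind, newX)), y = c(y, newy),
       n_synthetic = n_syn)
}

#' Classifier training configuration
#'
#' Defaults follow the reference topology (hidden layers of 300 and 275
#' ReLU units, softmax output over the 12 classes, cross-entropy loss);
#' optimizer settings are package choices: Adam at 1e-3, mini-batch 64,
#' up to 200 epochs with early stopping on a 10 percent validation split.
#'
#' @param hidden hidden layer widths.
#' @param epochs maximum epochs.
#' @param batch_size mini-batch size.
#' @param learning_rate Adam learning rate.
#' @param validation_frac fraction held out for early stopping.
#' @param patience epochs without validation improvement before stopping.
#' @param seed integer RNG seed.
#' @return a list of class `clf_config`.
#' @export
clf_config <- function(hidden = c(300L, 275L), epochs = 200L,
                       batch_size = 64L, learning_rate = 1e-3,
                       validation_frac = 0.1, patience = 20L, seed = 1L) {
  structure(list(hidden = as.integer(hidden), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 validation_frac = validation_frac,
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "clf_config")
}

#' Train the multilayer-perceptron beat classifier
#'
#' Feature rows are z-scored (constants fitted here and stored in the
#' model), targets are one-hot encoded over `labels`, and the network is
#' trained by backpropagation of the cross-entropy loss.
#'
#' @param X numeric feature matrix (one row per beat, e.g. 52 columns).
#' @param y class labels, all present in `labels`.
#' @param config a [clf_config()].
#' @param labels full label set defining the output order (default
#'   [mi_classes()]).
#' @return an object of class `mi_mlp`.
#' @export
train_classifier <- function(X, y, config = clf_config(),
                             labels = mi_classes()) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (!all(y %in% labels))
    stop("unknown label(s): ", paste(setdiff(y, labels), collapse = ", "))
  if (nrow(X) < length(unique(y))) stop("fewer rows than classes")
  center <- colMeans(X)
  scale_ <- apply(X, 2L, stats::sd)
  scale_[!is.finite(scale_) | scale_ == 0] <- 1
  Xs <- sweep(sweep(X, 2L, center), 2L, scale_, "/")
  Y <- matrix(0, nrow(X), length(labels))
  Y[cbind(seq_len(nrow(X)), match(y, labels))] <- 1
  net <- dense_net_train(Xs, Y, hidden = config$hidden, output = "softmax",
                         loss = "cross_entropy", epochs = config$epochs,
                         batch_size = config$batch_size,
                         learning_rate = config$learning_rate,
                         seed = config$seed,
                         validation_frac = config$validation_frac,
                         patience = config$patience)
  structure(list(net = net, labels = labels, center = center,
                 scale = scale_, config = config),
            class = "mi_mlp")
}

#' Predict beat classes
#'
#' @param object a trained `mi_mlp`.
#' @param newdata feature matrix with the training feature width.
#' @param ... unused.
#' @return list with `class` (character labels), `index` (1-based class
#'   indices; softmax ties break to the lowest index) and `prob`
#'   (row-stochastic probability matrix, one column per label).
#' @export
predict.mi_mlp <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$center))
    stop("feature width ", ncol(X), " does not match the model (",
         length(object$center), ")")
  Xs <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  prob <- dense_net_forward(object$net, Xs)$output
  colnames(prob) <- object$labels
  idx <- max.col(prob, ties.method = "first")
  list(class = object$labels[idx], index = idx, prob = prob)
}
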