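#' Compose two child embeddings with the shared weight matrix
#'
#' The binary composition \code{tanh(W [left; right])}, where \code{[;]} is
#' vertical concatenation and \code{W} is the shared n x 2n composition
#' matrix applied recursively over the tree. Outputs lie strictly in
#' \code{(-1, 1)}.
#'
#' @param left,right numeric vectors of length n.
#' @param W n x 2n matrix.
#' @return Length-n numeric vector.
#' @export
compose <- function(left, right, W) {
  n <- length(left)
  assert_that(length(right) == n, "left and right must have equal length")
  assert_that(all(dim(W) == c(n, 2 * n)),
              sprintf("W must be %d x %d", n, 2 * n))
  as.numeric(tanh(W %*% c(left, right)))
}

#' Initialize RvNN parameters
#'
#' Three per-modality affine leaf maps into an n-dimensional embedding, a
#' shared n x 2n composition matrix, and an affine softmax head. Weights are
#' drawn from scaled uniform distributions (fan-in scaling), reproducibly
#' from the seed.
#'
#' @param span_dims integer vector: input dimension of each modality span
#'   (ambient, motion, vision).
#' @param n hidden width (default 64).
#' @param n_classes number of classes.
#' @param seed RNG seed.
#' @return Object of class \code{rvnn_params}.
#' @export
rvnn_init <- function(span_dims, n = 64, n_classes, seed = 1) {
  set.seed(seed)
  rmat <- function(r, c) matrix(stats::runif(r * c, -1, 1) / sqrt(c), r, c)
  leaf <- lapply(span_dims, function(d)
    list(U = if (d > 0) rmat(n, d) else matrix(0, n, 0), b = numeric(n)))
  names(leaf) <- c("ambient", "motion", "vision")
  structure(list(leaf = leaf,
                 W = rmat(n, 2 * n),
                 V = rmat(n_classes, n), c = numeric(n_classes),
                 n = n, n_classes = n_classes, span_dims = span_dims),
            class = "rvnn_params")
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# batch forward pass; X is samples x dims, spans a list of column indices.
# tree_shape "left-deep": ((ambient . motion) . vision)
#            "balanced" : ((ambient . motion) . (motion . vision))
rvnn_forward_batch <- function(params, X, spans, tree_shape = "left-deep") {
  leaf_act <- function(map, cols) {
    if (length(cols) == 0 || ncol(map$U) == 0)
      return(matrix(0, nrow(X), params$n))
    tanh(X[, cols, drop = FALSE] %*% t(map$U) +
           matrix(map$b, nrow(X), params$n, byrow = TRUE))
  }
  La <- leaf_act(params$leaf$ambient, spans$ambient)
  Lm <- leaf_act(params$leaf$motion, spans$motion)
  Lv <- leaf_act(params$leaf$vision, spans$vision)
  H1 <- tanh(cbind(La, Lm) %*% t(params$W))
  right2 <- if (tree_shape == "balanced") tanh(cbind(Lm, Lv) %*% t(params$W)) else Lv
  H2 <- tanh(cbind(H1, right2) %*% t(params$W))
  Z <- H2 %*% t(params$V) + matrix(params$c, nrow(X), params$n_classes, byrow = TRUE)
  if (any(!is.finite(Z)))
    mf_stop("non-finite activations at the softmax head", "momofuse_numeric_error")
  list(La = La, Lm = Lm, Lv = Lv, H1 = H1, R2 = right2, H2 = H2,
       probs = softmax_rows(Z))
}

#' Forward pass: class probabilities for fused window features
#'
#' Leaves are per-modality affine+tanh embeddings of the corresponding span;
#' branches apply the shared composition [compose()]; the head is an affine
#' map with softmax. Default tree is left-deep:
#' \code{compose(compose(ambient, motion), vision)}.
#'
#' @param params an \code{rvnn_params}.
#' @param x single fused feature vector, or samples x dims matrix.
#' @param spans list of column index ranges (\code{ambient}, \code{motion},
#'   \code{vision}).
#' @param tree_shape "left-deep" or "balanced".
#' @return Probability vector (or samples x classes matrix), rows sum to 1.
#' @export
rvnn_forward <- function(params, x, spans, tree_shape = "left-deep") {
  X <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  p <- rvnn_forward_batch(params, X, spans, tree_shape)$probs
  if (is.null(dim(x))) as.numeric(p) else p
}

# cross-entropy loss + gradients for a batch (manual backpropagation
# through the composition tree; both uses of W accumulate into one gradient)
rvnn_loss_grad <- function(params, X, y_onehot, spans,
                           tree_shape = "left-deep", l2 = 0) {
  B <- nrow(X)
  f <- rvnn_forward_batch(params, X, spans, tree_shape)
  loss <- -sum(y_onehot * log(pmax(f$probs, 1e-12))) / B
  dZ <- (f$probs - y_onehot) / B                    # B x C
  gV <- t(dZ) %*% f$H2
  gc <- colSums(dZ)
  dH2 <- dZ %*% params$V
  g2 <- dH2 * (1 - f$H2^2)                          # pre-activation grad
  gW <- t(g2) %*% cbind(f$H1, f$R2)
  back2 <- g2 %*% params$W                          # B x 2n
  n <- params$n
  dH1 <- back2[, 1:n, drop = FALSE]
  dR2 <- back2[, (n + 1):(2 * n), drop = FALSE]
  g1 <- dH1 * (1 - f$H1^2)
  gW <- gW + t(g1) %*% cbind(f$La, f$Lm)
  back1 <- g1 %*% params$W
  dLa <- back1[, 1:n, drop = FALSE]
  dLm <- back1[, (n + 1):(2 * n), drop = FALSE]
  if (tree_shape == "balanced") {
    gr <- dR2 * (1 - f$R2^2)
    gW <- gW + t(gr) %*% cbind(f$Lm, f$Lv)
    backr <- gr %*% params$W
    dLm <- dLm + backr[, 1:n, drop = FALSE]
    dLv <- backr[, (n + 1):(2 * n), drop = FALSE]
  } else {
    dLv <- dR2
  }
  leaf_grad <- function(map, cols, dL, L) {
    if (length(cols) == 0 || ncol(map$U) == 0)
      return(list(U = map$U * 0, b = numeric(params$n)))
    gpre <- dL * (1 - L^2)
    list(U = t(gpre) %*% X[, cols, drop = FALSE], b = colSums(gpre))
  }
  grads <- list(leaf = list(
    ambient = leaf_grad(params$leaf$ambient, spans$ambient, dLa, f$La),
    motion  = leaf_grad(params$leaf$motion, spans$motion, dLm, f$Lm),
    vision  = leaf_grad(params$leaf$vision, spans$vision, dLv, f$Lv)),
    W = gW, V = gV, c = gc)
  if (l2 > 0) {
    loss <- loss + l2 / 2 * (sum(params$W^2) + sum(params$V^2) +
      sum(vapply(params$leaf, function(m) sum(m$U^2), numeric(1))))
    grads$W <- grads$W + l2 * params$W
    grads$V <- grads$V + l2 * params$V
    for (m in names(grads$leaf))
      grads$leaf[[m]]$U <- grads$leaf[[m]]$U + l2 * params$leaf[[m]]$U
  }
  list(loss = loss, grads = grads)
}

#' Training configuration for the RvNN
#'
#' @param n hidden width (default 64).
#' @param epochs training epochs (default 200).
#' @param learning_rate gradient-descent step (default 0.01).
#' @param batch_size mini-batch size (default 32).
#' @param l2 L2 penalty on weight matrices (default 1e-4).
#' @param seed seed fixing initialization and batch order.
#' @param tree_shape "left-deep" or "balanced".
#' @return \code{train_config} list.
#' @export
train_config <- function(n = 64, epochs = 200, learning_rate = 0.01,
                         batch_size = 32, l2 = 1e-4, seed = 1,
                         tree_shape = c("left-deep", "balanced")) {
  tree_shape <- match.arg(tree_shape)
  assert_that(n >= 1 && epochs >= 1 && learning_rate > 0 && batch_size >= 1,
              "n, epochs, learning_rate, batch_size must be positive")
  list(n = n, epochs = epochs, learning_rate = learning_rate,
       batch_size = batch_size, l2 = l2, seed = seed, tree_shape = tree_shape)
}

#' Train the recursive neural network
#'
#' Minimizes multiclass cross-entropy by mini-batch gradient descent with
#' seeded initialization and batch order. Features are standardized
#' (train-set mean/sd) before the leaf maps; the scaler is stored with the
#' parameters.
#'
#' @param features \code{fused_features} object, or samples x dims matrix.
#' @param labels per-window class ids (>= 2 classes).
#' @param cfg a [train_config()].
#' @param spans span list when \code{features} is a plain matrix.
#' @return \code{rvnn_model}: \code{params}, \code{spans}, \code{classes},
#'   \code{scaler}, \code{loss_history}, \code{train_accuracy}, \code{config}.
#' @export
rvnn_train <- function(features, labels = NULL, cfg = train_config(),
                       spans = NULL) {
  if (inherits(features, "fused_features")) {
    if (is.null(labels)) labels <- features$labels
    spans <- features$spans
    X <- features$x
  } else X <- as.matrix(features)
  if (is.null(spans)) spans <- list(ambient = integer(0),
                                    motion = seq_len(ncol(X)),
                                    vision = integer(0))
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    mf_stop("training needs >= 2 classes", "momofuse_training_error")
  if (min(table(labels)) < 10)
    warning("rvnn_train: fewer than 10 windows in some class")
  y <- match(labels, classes)
  N <- nrow(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd); sdv[sdv < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  Y <- matrix(0, N, length(classes)); Y[cbind(seq_len(N), y)] <- 1
  params <- rvnn_init(vapply(spans, length, integer(1)), n = cfg$n,
                      n_classes = length(classes), seed = cfg$seed)
  set.seed(cfg$seed + 1)
  loss_hist <- numeric(cfg$epochs)
  lr <- cfg$learning_rate
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(N)
    ep_loss <- 0
    for (b0 in seq(1, N, by = cfg$batch_size)) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1, N)]
      lg <- rvnn_loss_grad(params, Xs[idx, , drop = FALSE],
                           Y[idx, , drop = FALSE], spans,
                           cfg$tree_shape, cfg$l2)
      if (!is.finite(lg$loss))
        mf_stop(sprintf("non-finite loss at epoch %d", ep),
                "momofuse_numeric_error")
      ep_loss <- ep_loss + lg$loss * length(idx)
      g <- lg$grads
      params$W <- params$W - lr * g$W
      params$V <- params$V - lr * g$V
      params$c <- params$c - lr * g$c
      for (m in names(params$leaf)) {
        params$leaf[[m]]$U <- params$leaf[[m]]$U - lr * g$leaf[[m]]$U
        params$leaf[[m]]$b <- params$leaf[[m]]$b - lr * g$leaf[[m]]$b
      }
    }
    loss_hist[ep] <- ep_loss / N
  }
  pred <- classes[max.col(rvnn_forward(params, Xs, spans, cfg$tree_shape),
                          ties.method = "first")]
  structure(list(params = params, spans = spans, classes = classes,
                 scaler = list(mu = mu, sd = sdv),
                 loss_history = loss_hist,
                 train_accuracy = mean(pred == labels),
                 config = cfg),
            class = "rvnn_model")
}

#' Predict class labels with a trained RvNN
#'
#' @param object an \code{rvnn_model} from [rvnn_train()].
#' @param newdata samples x dims matrix (unstandardized, same columns as
#'   training).
#' @param type "class" (default) or "prob".
#' @param ... unused.
#' @return Class ids, or a samples x classes probability matrix.
#' @export
predict.rvnn_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  Xs <- sweep(sweep(X, 2, object$scaler$mu), 2, object$scaler$sd, "/")
  p <- rvnn_forward(object$params, Xs, object$spans, object$config$tree_shape)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  if (type == "prob") p else object$classes[max.col(p, ties.method = "first")]
}

#' Stratified k-fold cross-validated evaluation
#'
#' Splits windows into k stratified folds (seeded), trains on k-1 folds and
#' predicts the held-out fold; pools all held-out predictions into one
#' row-normalized confusion matrix. If some class has fewer than k windows
#' the fold count is reduced with a warning.
#'
#' @param features \code{fused_features} or samples x dims matrix.
#' @param labels per-window class ids.
#' @param k number of folds (default 10).
#' @param cfg a [train_config()].
#' @param seed seed for the fold assignment.
#' @param spans span list for plain-matrix input.
#' @return List: \code{fold_accuracy} (per-fold), \code{confusion}
#'   ([confusion_matrix()] result), \code{mean_class_accuracy},
#'   \code{predictions}, \code{folds}.
#' @export
kfold_evaluate <- function(features, labels = NULL, k = 10,
                           cfg = train_config(), seed = 1, spans = NULL) {
  assert_that(k >= 2, "k must be >= 2")
  if (inherits(features, "fused_features")) {
    if (is.null(labels)) labels <- features$labels
    spans <- features$spans
    X <- features$x
  } else X <- as.matrix(features)
  min_n <- min(table(labels))
  if (min_n < k) {
    warning(sprintf("kfold_evaluate: smallest class has %d windows; reducing k to %d",
                    min_n, min_n))
    k <- max(2L, as.integer(min_n))
  }
  folds <- stratified_folds(labels, k, seed)
  pred <- rep(NA, length(labels))
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    model <- rvnn_train(X[tr, , drop = FALSE], labels[tr], cfg, spans = spans)
    pf <- predict(model, X[!tr, , drop = FALSE])
    pred[!tr] <- pf
    fold_acc[f] <- mean(pf == labels[!tr])
  }
  cm <- confusion_matrix(labels, pred, sort(unique(labels)))
  list(fold_accuracy = fold_acc, confusion = cm,
       mean_class_accuracy = mean_class_accuracy(cm),
       predictions = pred, folds = folds)
}
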