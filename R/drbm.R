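# Discriminative RBM: an RBM whose visible layer is augmented with a one-hot
# label group. With two classes the label posterior p(y|x) is computed
# exactly by free-energy comparison, so the discriminative objective needs
# no sampling.

#' Create a discriminative RBM
#'
#' @param n_features width of the (real-valued) input visible group.
#' @param n_hidden hidden layer size.
#' @param n_classes number of label states (one-hot visible group).
#' @param seed initialisation seed.
#' @param init \code{"gaussian"} (N(0, 0.01) weights) or \code{"zero"}.
#' @return Object of class \code{drbm} with input-to-hidden weights \code{W},
#'   label-to-hidden weights \code{U}, hidden biases \code{c} and label
#'   biases \code{d}.
#' @export
drbm_new <- function(n_features, n_hidden, n_classes = 2, seed = 1,
                     init = c("gaussian", "zero")) {
  init <- match.arg(init)
  if (init == "gaussian") {
    withr::with_seed(seed, {
      W <- matrix(stats::rnorm(n_features * n_hidden, 0, 0.01), n_features, n_hidden)
      U <- matrix(stats::rnorm(n_classes * n_hidden, 0, 0.01), n_classes, n_hidden)
    })
  } else {
    W <- matrix(0, n_features, n_hidden)
    U <- matrix(0, n_classes, n_hidden)
  }
  structure(list(W = W, U = U, c = numeric(n_hidden), d = numeric(n_classes),
                 n_classes = n_classes),
            class = "drbm")
}

# Per-class scores s_y(x) = d_y + sum_j softplus(c_j + U_yj + (W'x)_j);
# p(y|x) = softmax_y s_y(x). Returns n x n_classes matrix.
drbm_scores <- function(model, X) {
  if (ncol(X) != nrow(model$W))
    stop("feature width mismatch: got ", ncol(X), ", expected ", nrow(model$W))
  Z <- X %*% model$W
  vapply(seq_len(model$n_classes), function(y)
    model$d[y] + rowSums(softplus(sweep(Z, 2, model$c + model$U[y, ], "+"))),
    numeric(nrow(X)))
}

#' Exact class posterior of a discriminative RBM
#'
#' @param object a \code{drbm}.
#' @param X instances x features matrix (or single vector).
#' @param ... unused.
#' @return List with \code{prob} (n x n_classes, rows sum to 1) and
#'   \code{labels} (0-based argmax).
#' @export
predict.drbm <- function(object, X, ...) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  S <- drbm_scores(object, X)
  S <- S - apply(S, 1, max)
  P <- exp(S) / rowSums(exp(S))
  list(prob = P, labels = max.col(P) - 1L)
}

#' Train a discriminative RBM on labelled features
#'
#' Mini-batch gradient ascent with momentum on the exact conditional
#' log-likelihood \eqn{\sum_i \log p(y_i | x_i)} (purely discriminative
#' objective; the two-state label sum is closed form).
#'
#' @param features instances x features matrix.
#' @param labels binary vector (0/1) of length \code{nrow(features)}.
#' @param n_hidden hidden layer size.
#' @param lr learning rate.
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param momentum velocity coefficient.
#' @param seed RNG seed (initialisation and shuffling).
#' @return A trained \code{drbm}.
#' @export
train_drbm <- function(features, labels, n_hidden = 50, lr = 0.1,
                       epochs = 100, batch_size = 8, momentum = 0.5,
                       seed = 1) {
  if (nrow(features) != length(labels)) stop("features/labels length mismatch")
  if (length(unique(labels)) < 2)
    stop("labels contain a single class; two classes are required")
  model <- drbm_new(ncol(features), n_hidden, seed = seed)
  vel <- list(W = 0 * model$W, U = 0 * model$U, c = 0 * model$c, d = 0 * model$d)
  y1 <- as.integer(labels)
  withr::with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      idx <- sample(nrow(features))
      for (s in seq(1, nrow(features), by = batch_size)) {
        rows <- idx[s:min(s + batch_size - 1, nrow(features))]
        g <- drbm_gradient(model, features[rows, , drop = FALSE], y1[rows])
        vel$W <- momentum * vel$W + lr * g$dW
        vel$U <- momentum * vel$U + lr * g$dU
        vel$c <- momentum * vel$c + lr * g$dc
        vel$d <- momentum * vel$d + lr * g$dd
        model$W <- model$W + vel$W
        model$U <- model$U + vel$U
        model$c <- model$c + vel$c
        model$d <- model$d + vel$d
      }
    }
  })
  model
}

# Mean gradient of log p(y|x) over a batch (labels 0-based).
drbm_gradient <- function(model, X, y) {
  n <- nrow(X)
  Z <- X %*% model$W
  sig <- lapply(seq_len(model$n_classes), function(k)
    stats::plogis(sweep(Z, 2, model$c + model$U[k, ], "+")))
  S <- drbm_scores(model, X)
  S <- S - apply(S, 1, max)
  P <- exp(S) / rowSums(exp(S))
  Y <- matrix(0, n, model$n_classes)
  Y[cbind(seq_len(n), y + 1L)] <- 1
  # R = sigma_{y_i} - sum_y p_y sigma_y  (n x n_hidden)
  R <- 0
  sig_true <- matrix(0, n, ncol(model$W))
  for (k in seq_len(model$n_classes)) {
    R <- R - P[, k] * sig[[k]]
    sel <- y + 1L == k
    if (any(sel)) sig_true[sel, ] <- sig[[k]][sel, , drop = FALSE]
  }
  R <- R + sig_true
  dU <- t(vapply(seq_len(model$n_classes), function(k)
    colSums((Y[, k] - P[, k]) * sig[[k]]) / n, numeric(ncol(model$W))))
  list(dW = crossprod(X, R) / n,
       dU = dU,
       dc = colMeans(R),
       dd = colMeans(Y - P))
}
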