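# Deep belief network with optional glia chains: greedy layer-wise CD
# pretraining, supervised fine-tuning through a 2-neuron softmax head, and
# extraction of last-hidden-layer abstractions.

#' Create a DBN (stack of RBMs)
#'
#' @param layer_sizes integer vector \code{c(v1, h1, ..., hL)}; the hidden
#'   size of each RBM is the visible size of the next. \code{length 1} gives
#'   a degenerate stack whose abstraction is the input itself.
#' @param visible_type type of the first layer's visible units
#'   (\code{"gaussian"} for z-scored features); layers above are
#'   binary-probability units.
#' @param seed initialisation seed.
#' @param init_sd weight initialisation SD, see [rbm_new()].
#' @return Object of class \code{dbn_gc}.
#' @export
dbn_new <- function(layer_sizes, visible_type = "gaussian", seed = 1,
                    init_sd = 0.1) {
  stopifnot(length(layer_sizes) >= 1, all(layer_sizes >= 1))
  n_rbm <- length(layer_sizes) - 1
  layers <- vector("list", n_rbm)
  if (n_rbm > 0) {
    for (k in seq_len(n_rbm)) {
      layers[[k]] <- rbm_new(layer_sizes[k], layer_sizes[k + 1],
                             visible_type = if (k == 1) visible_type else "binary",
                             seed = seed + k, init_sd = init_sd)
    }
  }
  structure(list(layers = layers, layer_sizes = as.integer(layer_sizes),
                 head = NULL, seed = seed),
            class = "dbn_gc")
}

#' @export
print.dbn_gc <- function(x, ...) {
  cat(sprintf("<dbn_gc> layers %s%s\n",
              paste(x$layer_sizes, collapse = "/"),
              if (is.null(x$head)) "" else " + 2-neuron head"))
  invisible(x)
}

# Deterministic forward pass: list of activations per layer (input first).
dbn_forward <- function(dbn, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  acts <- vector("list", length(dbn$layers) + 1)
  acts[[1]] <- X
  for (k in seq_along(dbn$layers))
    acts[[k + 1]] <- hidden_probability(hidden_preactivation(dbn$layers[[k]], acts[[k]]))
  acts
}

#' Greedy layer-wise pretraining
#'
#' Each RBM is trained by CD-1 on the hidden activation probabilities of the
#' layer below; when \code{glia_params} is supplied every layer gets a fresh
#' glia chain that modulates hidden outputs during its own pretraining (and
#' nowhere else). Training layer k never modifies layers below it.
#'
#' @param dbn a [dbn_new()] stack.
#' @param data samples x v1 matrix.
#' @param hp hyperparameters from [rbm_hyperparams()]; the seed is offset per
#'   layer.
#' @param glia_params \code{NULL} for a plain DBN, or a list with
#'   \code{alpha}, \code{beta}, \code{theta}, \code{T_refractory} (and
#'   optionally \code{order}) for glia-chain pretraining.
#' @return The pretrained \code{dbn_gc}; per-layer reconstruction-error
#'   histories are kept in \code{$pretrain_history}.
#' @export
pretrain <- function(dbn, data, hp = rbm_hyperparams(), glia_params = NULL) {
  if (ncol(data) != dbn$layer_sizes[1])
    stop("data width (", ncol(data), ") must equal v1 (", dbn$layer_sizes[1], ")")
  input <- data
  history <- vector("list", length(dbn$layers))
  for (k in seq_along(dbn$layers)) {
    chain <- if (is.null(glia_params)) NULL
      else glia_chain(ncol(dbn$layers[[k]]$W),
                      alpha = glia_params$alpha, beta = glia_params$beta,
                      theta = glia_params$theta,
                      T_refractory = glia_params$T_refractory %||% 5,
                      order = glia_params$order %||% seq_len(ncol(dbn$layers[[k]]$W)))
    hp_k <- hp; hp_k$seed <- hp$seed + 131 * k
    fit <- train_rbm_gc(dbn$layers[[k]], input, hp = hp_k, chain = chain)
    dbn$layers[[k]] <- fit$rbm
    history[[k]] <- list(recon_error = fit$recon_error,
                         fire_count = fit$fire_count)
    input <- hidden_probability(hidden_preactivation(fit$rbm, input))
  }
  dbn$pretrain_history <- history
  dbn
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cross-entropy loss and gradients of the full stack + softmax head.
dbn_loss_grad <- function(dbn, X, y) {
  n <- nrow(X)
  acts <- dbn_forward(dbn, X)
  A <- acts[[length(acts)]]
  logits <- sweep(A %*% dbn$head$W, 2, dbn$head$b, "+")
  logits <- logits - apply(logits, 1, max)
  P <- exp(logits) / rowSums(exp(logits))
  Y <- matrix(0, n, 2)
  Y[cbind(seq_len(n), y + 1L)] <- 1
  loss <- -mean(log(rowSums(P * Y) + 1e-300))
  dlogit <- (P - Y) / n
  gW_head <- crossprod(A, dlogit)
  gb_head <- colSums(dlogit)
  dA <- dlogit %*% t(dbn$head$W)
  gW <- vector("list", length(dbn$layers))
  gc_ <- vector("list", length(dbn$layers))
  for (k in rev(seq_along(dbn$layers))) {
    Ak <- acts[[k + 1]]
    dZ <- dA * Ak * (1 - Ak)
    gW[[k]] <- crossprod(acts[[k]], dZ)
    gc_[[k]] <- colSums(dZ)
    dA <- dZ %*% t(dbn$layers[[k]]$W)
  }
  list(loss = loss, gW = gW, gc = gc_, gW_head = gW_head, gb_head = gb_head)
}

#' Supervised fine-tuning with a 2-neuron softmax head
#'
#' Adds (or reuses) a 2-class linear-softmax output layer and trains the
#' whole stack by mini-batch SGD with momentum on the cross-entropy; glia
#' terms play no role here. Optional early stopping when the epoch training
#' loss stops improving.
#'
#' @param dbn a pretrained [dbn_new()] stack.
#' @param data samples x v1 matrix.
#' @param labels binary vector (0/1).
#' @param lr learning rate.
#' @param epochs maximum epochs.
#' @param batch_size mini-batch size.
#' @param momentum velocity coefficient.
#' @param seed RNG seed (head init and shuffling).
#' @param patience early-stopping patience in epochs (\code{Inf} disables).
#' @param min_delta minimum relative loss improvement counted as progress.
#' @return The fine-tuned \code{dbn_gc} (with \code{$head} and
#'   \code{$finetune_loss}).
#' @export
finetune <- function(dbn, data, labels, lr = 0.5, epochs = 80,
                     batch_size = 8, momentum = 0.9, seed = 1,
                     patience = Inf, min_delta = 1e-4) {
  if (length(unique(labels)) < 2)
    stop("labels contain a single class; two classes are required")
  y <- as.integer(labels)
  n_last <- dbn$layer_sizes[length(dbn$layer_sizes)]
  if (is.null(dbn$head)) {
    dbn$head <- withr::with_seed(seed + 7L, list(
      W = matrix(stats::rnorm(n_last * 2, 0, 0.1), n_last, 2),
      b = numeric(2)))
  }
  vW <- lapply(dbn$layers, function(l) 0 * l$W)
  vc <- lapply(dbn$layers, function(l) 0 * l$c)
  vWh <- 0 * dbn$head$W; vbh <- 0 * dbn$head$b
  losses <- numeric(epochs)
  best <- Inf; stall <- 0
  withr::with_seed(seed, {
    for (ep in seq_len(epochs)) {
      idx <- sample(nrow(data))
      tot <- 0
      for (s in seq(1, nrow(data), by = batch_size)) {
        rows <- idx[s:min(s + batch_size - 1, nrow(data))]
        g <- dbn_loss_grad(dbn, data[rows, , drop = FALSE], y[rows])
        for (k in seq_along(dbn$layers)) {
          vW[[k]] <- momentum * vW[[k]] - lr * g$gW[[k]]
          vc[[k]] <- momentum * vc[[k]] - lr * g$gc[[k]]
          dbn$layers[[k]]$W <- dbn$layers[[k]]$W + vW[[k]]
          dbn$layers[[k]]$c <- dbn$layers[[k]]$c + vc[[k]]
        }
        vWh <- momentum * vWh - lr * g$gW_head
        vbh <- momentum * vbh - lr * g$gb_head
        dbn$head$W <- dbn$head$W + vWh
        dbn$head$b <- dbn$head$b + vbh
        tot <- tot + g$loss * length(rows)
      }
      losses[ep] <- tot / nrow(data)
      if (losses[ep] < best * (1 - min_delta)) { best <- losses[ep]; stall <- 0 }
      else stall <- stall + 1
      if (stall >= patience) { losses <- losses[seq_len(ep)]; break }
    }
  })
  dbn$finetune_loss <- losses
  dbn
}

#' Last-hidden-layer abstraction
#'
#' Deterministic forward pass through all layers using sigmoid activation
#' probabilities; the supervised head is ignored. For a stack without
#' layers the abstraction is the input itself.
#'
#' @param dbn a \code{dbn_gc}.
#' @param x input vector or samples x v1 matrix.
#' @return Abstraction vector (or matrix), width = last hidden size.
#' @export
abstraction <- function(dbn, x) {
  vec <- !is.matrix(x)
  acts <- dbn_forward(dbn, x)
  out <- acts[[length(acts)]]
  if (vec) drop(out) else out
}

#' Class probabilities from a fine-tuned DBN
#'
#' @param object a fine-tuned \code{dbn_gc} (must have a head).
#' @param X samples x v1 matrix.
#' @param ... unused.
#' @return List with \code{prob} (n x 2) and \code{labels} (0/1).
#' @export
predict.dbn_gc <- function(object, X, ...) {
  if (is.null(object$head)) stop("DBN has no supervised head; run finetune() first")
  A <- abstraction(object, X)
  if (!is.matrix(A)) A <- matrix(A, nrow = 1)
  logits <- sweep(A %*% object$head$W, 2, object$head$b, "+")
  logits <- logits - apply(logits, 1, max)
  P <- exp(logits) / rowSums(exp(logits))
  list(prob = P, labels = max.col(P) - 1L)
}
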