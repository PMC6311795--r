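# Restricted Boltzmann machine: energy model, CD-1 training, and exact
# small-model oracles (enumeration of the Boltzmann distribution).

#' Create an RBM
#'
#' Weights are initialised N(0, init_sd^2), biases at zero. \code{visible_type}
#' \code{"gaussian"} treats visible units as real-valued with unit variance
#' (appropriate for z-scored features); \code{"binary"} uses Bernoulli
#' visible units.
#'
#' @param n_visible,n_hidden layer sizes.
#' @param visible_type \code{"gaussian"} or \code{"binary"}.
#' @param seed integer seed for weight initialisation.
#' @param init_sd SD of the Gaussian weight initialisation. The default 0.1
#'   keeps deep sigmoid stacks trainable; very small values leave hidden
#'   activations indistinguishable from 0.5 and stall fine-tuning.
#' @return An object of class \code{rbm} with fields \code{W}
#'   (visible x hidden), \code{b} (visible biases), \code{c} (hidden biases).
#' @export
rbm_new <- function(n_visible, n_hidden, visible_type = c("gaussian", "binary"),
                    seed = 1, init_sd = 0.1) {
  visible_type <- match.arg(visible_type)
  W <- withr::with_seed(seed,
    matrix(stats::rnorm(n_visible * n_hidden, 0, init_sd), n_visible, n_hidden))
  structure(list(W = W, b = numeric(n_visible), c = numeric(n_hidden),
                 visible_type = visible_type),
            class = "rbm")
}

#' Hidden pre-activations h* = W'v + c
#'
#' @param rbm an [rbm_new()] model.
#' @param v visible vector, or matrix with one sample per row.
#' @return Pre-activation vector (or samples x hidden matrix).
#' @export
hidden_preactivation <- function(rbm, v) {
  if (is.matrix(v)) {
    if (ncol(v) != nrow(rbm$W))
      stop("visible dimension mismatch: got ", ncol(v), ", expected ", nrow(rbm$W))
    sweep(v %*% rbm$W, 2, rbm$c, "+")
  } else {
    if (length(v) != nrow(rbm$W))
      stop("visible dimension mismatch: got ", length(v), ", expected ", nrow(rbm$W))
    drop(v %*% rbm$W) + rbm$c
  }
}

#' Hidden activation probabilities
#'
#' Elementwise sigmoid of the pre-activations. Activation probabilities (not
#' Bernoulli samples) are used as the hidden output to reduce sampling noise.
#'
#' @param h_star pre-activation vector or matrix.
#' @return Values in (0, 1), same shape.
#' @export
hidden_probability <- function(h_star) stats::plogis(h_star)

# Visible reconstruction means given hidden states.
visible_mean <- function(rbm, h) {
  pre <- sweep(h %*% t(rbm$W), 2, rbm$b, "+")
  if (rbm$visible_type == "binary") stats::plogis(pre) else pre
}

#' One contrastive-divergence (CD-1) gradient estimate
#'
#' Positive phase from the data batch; negative phase from one Gibbs step
#' (hidden sampled, visible reconstructed as means/probabilities, hidden
#' probabilities reused). Gradients are averaged over the batch and scaled
#' by \code{lr}. When a [glia_chain()] is supplied, hidden activation
#' probabilities in both phases are computed through [glia_hidden_output()].
#'
#' @param rbm an \code{rbm}.
#' @param batch samples x visible matrix.
#' @param lr learning rate.
#' @param chain optional \code{glia_chain} modulating hidden outputs.
#' @return List with \code{dW}, \code{db}, \code{dc} and the batch-mean
#'   pre-activation \code{h_star_mean} and reconstruction error \code{recon}.
#' @export
cd_update <- function(rbm, batch, lr = 0.05, chain = NULL) {
  if (!is.matrix(batch) || nrow(batch) < 1) stop("batch must be a non-empty matrix")
  n <- nrow(batch)
  hs0 <- hidden_preactivation(rbm, batch)
  hp0 <- if (is.null(chain)) hidden_probability(hs0)
         else glia_hidden_output(hs0, chain)
  h0 <- (matrix(stats::runif(length(hp0)), nrow(hp0), ncol(hp0)) < hp0) * 1
  v1 <- visible_mean(rbm, h0)
  hs1 <- hidden_preactivation(rbm, v1)
  hp1 <- if (is.null(chain)) hidden_probability(hs1)
         else glia_hidden_output(hs1, chain)
  list(dW = lr * (crossprod(batch, hp0) - crossprod(v1, hp1)) / n,
       db = lr * colMeans(batch - v1),
       dc = lr * colMeans(hp0 - hp1),
       h_star_mean = colMeans(hs0),
       recon = mean((batch - v1)^2))
}

#' Default RBM training hyperparameters
#'
#' @param lr learning rate; \code{NULL} selects 0.05 for binary and 0.01 for
#'   gaussian visible units at training time.
#' @param epochs passes over the data.
#' @param batch_size mini-batch size.
#' @param momentum velocity coefficient.
#' @param weight_decay L2 penalty on weights.
#' @param seed RNG seed for shuffling and hidden sampling.
#' @return List of hyperparameters.
#' @export
rbm_hyperparams <- function(lr = NULL, epochs = 100, batch_size = 8,
                            momentum = 0.5, weight_decay = 1e-4, seed = 1) {
  list(lr = lr, epochs = epochs, batch_size = batch_size,
       momentum = momentum, weight_decay = weight_decay, seed = seed)
}

#' Train an RBM by CD-1 (optionally glia-modulated)
#'
#' Mini-batch CD-1 with momentum and weight decay. When \code{chain} is
#' given, hidden outputs in both CD phases pass through the glia chain and
#' the chain advances once per mini-batch on the batch-mean pre-activations;
#' inference after training always uses the plain sigmoid.
#'
#' @param rbm an \code{rbm}.
#' @param data samples x visible matrix.
#' @param hp hyperparameters from [rbm_hyperparams()].
#' @param chain optional [glia_chain()].
#' @return List with the trained \code{rbm}, final \code{chain} (or NULL),
#'   per-epoch mean reconstruction error \code{recon_error}, and per-epoch
#'   glia firing counts \code{fire_count}.
#' @export
train_rbm_gc <- function(rbm, data, hp = rbm_hyperparams(), chain = NULL) {
  if (ncol(data) != nrow(rbm$W))
    stop("data width must equal the visible layer size")
  lr <- if (is.null(hp$lr)) { if (rbm$visible_type == "binary") 0.05 else 0.01 } else hp$lr
  vW <- rbm$W * 0; vb <- rbm$b * 0; vc <- rbm$c * 0
  recon_error <- numeric(hp$epochs)
  fire_count <- numeric(hp$epochs)
  withr::with_seed(hp$seed, {
    for (ep in seq_len(hp$epochs)) {
      idx <- sample(nrow(data))
      starts <- seq(1, nrow(data), by = hp$batch_size)
      rec <- 0; fires <- 0
      for (s in starts) {
        rows <- idx[s:min(s + hp$batch_size - 1, nrow(data))]
        upd <- cd_update(rbm, data[rows, , drop = FALSE], lr = lr, chain = chain)
        vW <- hp$momentum * vW + upd$dW - lr * hp$weight_decay * rbm$W
        vb <- hp$momentum * vb + upd$db
        vc <- hp$momentum * vc + upd$dc
        rbm$W <- rbm$W + vW
        rbm$b <- rbm$b + vb
        rbm$c <- rbm$c + vc
        if (!is.null(chain)) {
          chain <- glia_step(chain, upd$h_star_mean)
          fires <- fires + sum(chain$fired)
        }
        rec <- rec + upd$recon
      }
      recon_error[ep] <- rec / length(starts)
      fire_count[ep] <- fires
    }
  })
  list(rbm = rbm, chain = chain, recon_error = recon_error,
       fire_count = fire_count)
}

#' Train a plain RBM (no glia chain)
#'
#' @inheritParams train_rbm_gc
#' @return Same as [train_rbm_gc()] with \code{chain = NULL}.
#' @export
train_rbm <- function(rbm, data, hp = rbm_hyperparams()) {
  train_rbm_gc(rbm, data, hp = hp, chain = NULL)
}

# ---- exact small-model oracles -------------------------------------------

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))
logsumexp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

# Free energy F(v) = -b'v - sum_j softplus(c_j + (W'v)_j), rows of V.
free_energy <- function(rbm, V) {
  -as.vector(V %*% rbm$b) -
    rowSums(softplus(sweep(V %*% rbm$W, 2, rbm$c, "+")))
}

all_binary_configs <- function(n) {
  m <- as.matrix(expand.grid(rep(list(0:1), n)))
  dimnames(m) <- NULL
  m[, rev(seq_len(n)), drop = FALSE]
}

rbm_log_z <- function(rbm) {
  nv <- nrow(rbm$W); nh <- ncol(rbm$W)
  if (nv + nh > 20) stop("model too large for exact enumeration (> 20 units)")
  if (rbm$visible_type != "binary")
    stop("exact enumeration requires binary visible units")
  logsumexp(-free_energy(rbm, all_binary_configs(nv)))
}

#' Exact log-likelihood of a visible configuration
#'
#' log p(v) for a binary-visible RBM by full enumeration of the partition
#' function (energy \eqn{-v'Wh - b'v - c'h}). Only feasible for
#' \code{n_visible + n_hidden <= 20}.
#'
#' @param rbm a binary-visible \code{rbm}.
#' @param v binary visible vector, or matrix of rows.
#' @return log p(v) (vector for matrix input).
#' @export
exact_log_likelihood <- function(rbm, v) {
  if (!is.matrix(v)) v <- matrix(v, nrow = 1)
  -free_energy(rbm, v) - rbm_log_z(rbm)
}

#' Exact Boltzmann distribution over visible configurations
#'
#' @param rbm a small binary-visible \code{rbm}.
#' @return List with \code{configs} (2^nv x nv matrix) and \code{prob}.
#' @export
exact_visible_distribution <- function(rbm) {
  V <- all_binary_configs(nrow(rbm$W))
  lp <- -free_energy(rbm, V)
  lp <- lp - logsumexp(lp)
  list(configs = V, prob = exp(lp))
}

#' Analytic gradient of the exact log-likelihood
#'
#' d log p(v) / d(W, b, c) = -dF(v) + E_p[dF(v')], with the model
#' expectation enumerated exactly.
#'
#' @param rbm a small binary-visible \code{rbm}.
#' @param v binary visible vector.
#' @return List with \code{dW}, \code{db}, \code{dc}.
#' @export
exact_ll_gradient <- function(rbm, v) {
  grad_f <- function(vv) {
    sig <- stats::plogis(drop(vv %*% rbm$W) + rbm$c)
    list(dW = -outer(as.numeric(vv), sig), db = -as.numeric(vv), dc = -sig)
  }
  dist <- exact_visible_distribution(rbm)
  pos <- grad_f(v)
  eW <- 0 * rbm$W; eb <- 0 * rbm$b; ec <- 0 * rbm$c
  for (i in seq_along(dist$prob)) {
    g <- grad_f(dist$configs[i, ])
    eW <- eW + dist$prob[i] * g$dW
    eb <- eb + dist$prob[i] * g$db
    ec <- ec + dist$prob[i] * g$dc
  }
  list(dW = -pos$dW + eW, db = -pos$db + eb, dc = -pos$dc + ec)
}

#' Gibbs sampling of visible configurations
#'
#' Alternating block Gibbs chain v -> h -> v on a binary-visible RBM,
#' recording the visible configuration after each sweep.
#'
#' @param rbm a binary-visible \code{rbm}.
#' @param n_sweeps number of recorded sweeps.
#' @param seed RNG seed.
#' @param burn_in discarded initial sweeps.
#' @return Named probability vector over visible configurations (names are
#'   the 0/1 strings of the configuration).
#' @export
rbm_gibbs_distribution <- function(rbm, n_sweeps = 1e5, seed = 1,
                                   burn_in = 1000) {
  nv <- nrow(rbm$W); nh <- ncol(rbm$W)
  counts <- integer(2^nv)
  pow <- 2^((nv - 1):0)
  withr::with_seed(seed, {
    v <- (stats::runif(nv) < 0.5) * 1
    for (i in seq_len(burn_in + n_sweeps)) {
      h <- (stats::runif(nh) < stats::plogis(drop(v %*% rbm$W) + rbm$c)) * 1
      v <- (stats::runif(nv) < stats::plogis(drop(rbm$W %*% h) + rbm$b)) * 1
      if (i > burn_in) {
        code <- sum(v * pow) + 1
        counts[code] <- counts[code] + 1L
      }
    }
  })
  # align with the row order of all_binary_configs / exact_visible_distribution
  cfg <- all_binary_configs(nv)
  codes <- as.integer(cfg %*% pow + 1)
  out <- counts[codes] / n_sweeps
  names(out) <- apply(cfg, 1, paste, collapse = "")
  out
}
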