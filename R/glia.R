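# Glia chain: a linear chain of auxiliary cells, one per hidden unit. A cell
# fires (glia effect g -> 1) when its hidden unit's activation probability
# exceeds a threshold, or when the preceding cell on the chain fired at the
# previous step; a refractory period forbids re-firing for T steps, and
# silent cells decay g <- beta * g. The glia effect feeds the hidden output
# as sigma(h* + alpha * g) during pretraining only.

#' Create a glia chain
#'
#' @param n number of cells (one per hidden unit of the paired RBM).
#' @param alpha weight of the glia effect on hidden pre-activations, in [0, 1].
#' @param beta decay factor applied to silent cells, in [0, 1].
#' @param theta firing threshold compared against the hidden activation
#'   probability sigma(h*), in [0, 1].
#' @param T_refractory minimum number of steps between firings of one cell
#'   (>= 1).
#' @param order chain order as a permutation of hidden-unit indices; signals
#'   travel from \code{order[1]} towards \code{order[n]}.
#' @return Object of class \code{glia_chain}: glia effects \code{g} (init 0),
#'   \code{last_fire} clocks (init -Inf, all cells eligible), \code{fired}
#'   flags of the most recent step, and the step counter.
#' @export
glia_chain <- function(n, alpha = 0.8, beta = 0.4, theta = 0.75,
                       T_refractory = 5, order = seq_len(n)) {
  stopifnot(n >= 1, alpha >= 0, alpha <= 1, beta >= 0, beta <= 1,
            theta >= 0, theta <= 1, T_refractory >= 1)
  if (!identical(sort(order), seq_len(n)))
    stop("'order' must be a permutation of 1..n")
  structure(list(g = numeric(n), last_fire = rep(-Inf, n),
                 fired = logical(n), step = 0L,
                 alpha = alpha, beta = beta, theta = theta,
                 T_refractory = T_refractory, order = as.integer(order)),
            class = "glia_chain")
}

#' Advance the glia chain by one step
#'
#' Cell j fires iff [sigma(h*_j) > theta, or its predecessor on the chain
#' fired at the previous step] and at least \code{T_refractory} steps have
#' passed since cell j last fired. Firing sets g_j to 1 and stamps the clock;
#' silent cells decay g_j <- beta * g_j. Signals travel one chain link per
#' step; the first cell has no predecessor.
#'
#' @param chain a [glia_chain()].
#' @param h_star hidden pre-activation vector (length n).
#' @return The updated chain; \code{chain$fired} holds this step's flags.
#' @export
glia_step <- function(chain, h_star) {
  n <- length(chain$g)
  if (length(h_star) != n)
    stop("h_star length (", length(h_star), ") must match chain size (", n, ")")
  step <- chain$step + 1L
  drive <- stats::plogis(h_star) > chain$theta
  prev_signal <- logical(n)
  if (n > 1)
    prev_signal[chain$order[-1]] <- chain$fired[chain$order[-n]]
  eligible <- (step - chain$last_fire) >= chain$T_refractory
  fire <- (drive | prev_signal) & eligible
  chain$g[fire] <- 1
  chain$last_fire[fire] <- step
  chain$g[!fire] <- chain$beta * chain$g[!fire]
  chain$fired <- fire
  chain$step <- step
  chain
}

#' Glia-modulated hidden output
#'
#' h = sigma(h* + alpha * g), elementwise. With alpha = 0 (or a fully decayed
#' chain) this is exactly [hidden_probability()].
#'
#' @param h_star pre-activation vector, or samples x hidden matrix.
#' @param chain a [glia_chain()].
#' @return Hidden activation probabilities, same shape as \code{h_star}.
#' @export
glia_hidden_output <- function(h_star, chain) {
  eff <- chain$alpha * chain$g
  if (is.matrix(h_star)) {
    if (ncol(h_star) != length(chain$g)) stop("dimension mismatch with chain")
    stats::plogis(sweep(h_star, 2, eff, "+"))
  } else {
    if (length(h_star) != length(chain$g)) stop("dimension mismatch with chain")
    stats::plogis(h_star + eff)
  }
}
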