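# Model-config dispatch used by the evaluation harness: a config describes a
# classifier family + hyperparameters; fit_model()/predict_model() give the
# harness a uniform surface.

#' Single-DBN model configuration
#'
#' A single (glia-chain) DBN classifier over all features or a feature
#' subset, pretrained greedily and fine-tuned with a 2-neuron head.
#'
#' @param type \code{"dbn_gc"} (glia chains during pretraining) or
#'   \code{"dbn"} (plain).
#' @param hidden_sizes hidden layer widths.
#' @param subset optional integer feature-column indices the model sees.
#' @param glia glia parameters (used when \code{type == "dbn_gc"}).
#' @param pretrain_hp [rbm_hyperparams()] for pretraining.
#' @param finetune_hp list of [finetune()] arguments.
#' @param seed base seed.
#' @return List of class \code{dbn_config}.
#' @export
dbn_config <- function(type = c("dbn_gc", "dbn"),
                       hidden_sizes = c(100, 80, 45),
                       subset = NULL,
                       glia = list(alpha = 0.8, beta = 0.4, theta = 0.75,
                                   T_refractory = 5),
                       pretrain_hp = rbm_hyperparams(epochs = 15),
                       finetune_hp = list(lr = 0.5, epochs = 80,
                                          batch_size = 8, momentum = 0.9),
                       seed = 1) {
  structure(list(type = match.arg(type), hidden_sizes = hidden_sizes,
                 subset = subset, glia = glia, pretrain_hp = pretrain_hp,
                 finetune_hp = finetune_hp, seed = seed),
            class = "dbn_config")
}

#' Fit a model described by a configuration
#'
#' @param config an [ensemble_config()] or [dbn_config()].
#' @param X standardized training matrix.
#' @param y binary labels.
#' @param seed overrides the configuration's seed (used by [run_cv()] to
#'   derive per-fold seeds).
#' @return A fitted model carrying what [predict_model()] needs.
#' @export
fit_model <- function(config, X, y, seed = NULL) {
  if (!is.null(seed)) config$seed <- seed
  if (config$type == "ensemble") {
    train_ensemble(X, y, config)
  } else {
    sub <- config$subset %||% seq_len(ncol(X))
    Xs <- X[, sub, drop = FALSE]
    dbn <- dbn_new(c(ncol(Xs), config$hidden_sizes), seed = config$seed)
    hp <- config$pretrain_hp; hp$seed <- config$seed + 1
    glia <- if (config$type == "dbn_gc") config$glia else NULL
    dbn <- pretrain(dbn, Xs, hp = hp, glia_params = glia)
    ft <- config$finetune_hp
    dbn <- finetune(dbn, Xs, y, lr = ft$lr, epochs = ft$epochs,
                    batch_size = ft$batch_size %||% 8,
                    momentum = ft$momentum %||% 0.5,
                    seed = config$seed + 2)
    structure(list(dbn = dbn, subset = sub), class = "dbn_model")
  }
}

#' Predict with a model fitted by [fit_model()]
#'
#' @param model fitted model.
#' @param X instances x features matrix (full feature width; subsetting is
#'   applied internally).
#' @return List with \code{prob} and \code{labels}.
#' @export
predict_model <- function(model, X) {
  if (inherits(model, "eeg_ensemble")) predict(model, X)
  else predict(model$dbn, X[, model$subset, drop = FALSE])
}

#' Glia-parameter sweep
#'
#' Evaluates the model over a grid of values of one glia parameter (the
#' others held at the configuration's values), recording the mean
#' recognition accuracy per emotion dimension via [run_cv()]. The standard
#' grid takes 20 values 0.05, 0.10, ..., 1.00.
#'
#' @param param one of \code{"alpha"}, \code{"beta"}, \code{"theta"}.
#' @param grid numeric vector of parameter values in [0, 1].
#' @param dataset as in [run_cv()].
#' @param config an [ensemble_config()] or [dbn_config()] with glia enabled.
#' @param k,seed,strict_cv passed to [run_cv()].
#' @return Data frame with columns parameter, value, dimension,
#'   mean_accuracy (\code{length(grid) * 2} rows).
#' @export
sweep_glia_params <- function(param = c("alpha", "beta", "theta"),
                              grid = seq(0.05, 1, by = 0.05),
                              dataset, config, k = 10, seed = 1,
                              strict_cv = FALSE) {
  param <- match.arg(param)
  if (length(grid) == 0) stop("empty parameter grid")
  if (any(grid < 0 | grid > 1)) stop("grid values must lie in [0, 1]")
  rows <- lapply(grid, function(val) {
    cfg <- config
    cfg$glia[[param]] <- val
    cv <- run_cv(dataset, cfg, k = k, seed = seed, strict_cv = strict_cv)
    data.frame(parameter = param, value = val,
               dimension = cv$summary$dimension,
               mean_accuracy = cv$summary$mean_accuracy)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
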