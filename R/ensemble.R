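# Ensemble architecture: the feature vector is split into five subsets, each
# feeds a parallel glia-chain DBN; the five last-hidden abstractions are
# concatenated and classified by a discriminative RBM.

#' Default per-branch hidden layer sizes
#'
#' Three hidden layers per branch; with the standard 664-feature schema the
#' last-hidden widths are (90, 120, 45, 45, 50), so the concatenated
#' abstraction fed to the fusion RBM is 350 wide.
#'
#' @return Named list (F1..F5) of length-3 integer vectors.
#' @export
default_branch_sizes <- function() {
  list(F1 = c(110, 105, 90),
       F2 = c(145, 145, 120),
       F3 = c(55, 55, 45),
       F4 = c(120, 55, 45),
       F5 = c(155, 80, 50))
}

#' Ensemble model configuration
#'
#' @param schema a [feature_schema()].
#' @param branch_sizes named list F1..F5 of hidden layer sizes per branch
#'   (may be \code{integer(0)} for an identity pass-through branch).
#' @param glia glia-chain parameters (\code{alpha}, \code{beta},
#'   \code{theta}, \code{T_refractory}), shared by all branches; NULL
#'   disables glia chains (plain DBN branches).
#' @param pretrain_hp CD pretraining hyperparameters ([rbm_hyperparams()]).
#' @param finetune_hp list of [finetune()] arguments (lr, epochs,
#'   batch_size, momentum).
#' @param fusion list of discriminative-RBM settings (n_hidden, lr, epochs,
#'   batch_size, momentum).
#' @param seed master seed; branch and fusion seeds are derived from it.
#' @return List of class \code{ensemble_config} (with \code{type}
#'   \code{"ensemble"} for the evaluation harness).
#' @export
ensemble_config <- function(schema = feature_schema(),
                            branch_sizes = default_branch_sizes(),
                            glia = list(alpha = 0.8, beta = 0.4,
                                        theta = 0.75, T_refractory = 5),
                            pretrain_hp = rbm_hyperparams(epochs = 15),
                            finetune_hp = list(lr = 0.5, epochs = 80,
                                               batch_size = 8, momentum = 0.9),
                            fusion = list(n_hidden = 50, lr = 0.1,
                                          epochs = 100, batch_size = 8,
                                          momentum = 0.5),
                            seed = 1) {
  stopifnot(identical(names(branch_sizes), names(schema$subset_index)))
  structure(list(type = "ensemble", schema = schema,
                 branch_sizes = branch_sizes, glia = glia,
                 pretrain_hp = pretrain_hp, finetune_hp = finetune_hp,
                 fusion = fusion, seed = seed),
            class = "ensemble_config")
}

#' Split a feature vector (or matrix) into the five subsets
#'
#' @param x length-664 feature vector or instances x 664 matrix.
#' @param schema a [feature_schema()].
#' @return Named list F1..F5 of subvectors (or column-subset matrices);
#'   concatenating them in order reconstructs the input.
#' @export
split_subsets <- function(x, schema = feature_schema()) {
  width <- if (is.matrix(x)) ncol(x) else length(x)
  if (width != length(schema$names))
    stop("feature width (", width, ") does not match schema (",
         length(schema$names), ")")
  lapply(schema$subset_index, function(idx)
    if (is.matrix(x)) x[, idx, drop = FALSE] else x[idx])
}

#' Train the five-branch ensemble with discriminative-RBM fusion
#'
#' Stagewise: each branch DBN is pretrained (with its glia chains) and
#' fine-tuned with a temporary 2-neuron head on its own feature subset; the
#' heads are then discarded, the five last-hidden abstractions are
#' concatenated, and the discriminative RBM is trained on the concatenation.
#' Fusion training never mutates branch weights.
#'
#' @param X standardized instances x 664 training matrix.
#' @param y binary label vector for one emotion dimension.
#' @param config an [ensemble_config()].
#' @return Object of class \code{eeg_ensemble}.
#' @export
train_ensemble <- function(X, y, config = ensemble_config()) {
  subs <- split_subsets(X, config$schema)
  branches <- vector("list", length(subs))
  names(branches) <- names(subs)
  abstractions <- vector("list", length(subs))
  for (i in seq_along(subs)) {
    sizes <- c(ncol(subs[[i]]), config$branch_sizes[[i]])
    dbn <- dbn_new(sizes, seed = config$seed + 100 * i)
    if (length(config$branch_sizes[[i]]) > 0) {
      hp <- config$pretrain_hp; hp$seed <- config$seed + 100 * i + 1
      dbn <- pretrain(dbn, subs[[i]], hp = hp, glia_params = config$glia)
      ft <- config$finetune_hp
      dbn <- finetune(dbn, subs[[i]], y, lr = ft$lr, epochs = ft$epochs,
                      batch_size = ft$batch_size %||% 8,
                      momentum = ft$momentum %||% 0.5,
                      seed = config$seed + 100 * i + 2)
      dbn$head <- NULL                       # head discarded after branch training
    }
    branches[[i]] <- dbn
    abstractions[[i]] <- abstraction(dbn, subs[[i]])
  }
  A <- do.call(cbind, abstractions)
  fu <- config$fusion
  fusion <- train_drbm(A, y, n_hidden = fu$n_hidden, lr = fu$lr,
                       epochs = fu$epochs, batch_size = fu$batch_size %||% 8,
                       momentum = fu$momentum %||% 0.5,
                       seed = config$seed + 999)
  structure(list(branch_models = branches, fusion = fusion,
                 schema = config$schema, config = config,
                 fusion_width = ncol(A)),
            class = "eeg_ensemble")
}

#' Concatenated branch abstraction of an ensemble
#'
#' @param model an \code{eeg_ensemble}.
#' @param X instances x 664 matrix.
#' @return instances x (sum of last hidden sizes) matrix.
#' @export
ensemble_abstraction <- function(model, X) {
  subs <- split_subsets(X, model$schema)
  do.call(cbind, Map(function(dbn, xs) abstraction(dbn, xs),
                     model$branch_models, subs))
}

#' Predict emotion classes with a trained ensemble
#'
#' @param object an \code{eeg_ensemble}.
#' @param X instances x 664 matrix.
#' @param ... unused.
#' @return List with \code{prob} (rows sum to 1) and \code{labels} (0/1).
#' @export
predict.eeg_ensemble <- function(object, X, ...) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  predict(object$fusion, ensemble_abstraction(object, X))
}

#' Save / load trained models
#'
#' Thin single-file serialization of any model object of this package
#' (RBMs, DBNs, ensembles) together with its configuration and seeds.
#'
#' @param model model object.
#' @param path file path.
#' @return \code{path} (save) or the model (load).
#' @export
save_model <- function(model, path) { saveRDS(model, path); invisible(path) }

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
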