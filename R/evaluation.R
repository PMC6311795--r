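# Participant-specific k-fold cross-validation with accuracy and F1.

#' Stratified k-fold assignment
#'
#' Produces k disjoint test sets covering all indices, sizes differing by at
#' most one. When \code{labels} is given and every class has at least k
#' members, folds are label-stratified.
#'
#' @param n_instances number of instances.
#' @param k number of folds (<= n_instances).
#' @param seed RNG seed.
#' @param labels optional label vector for stratification.
#' @return List of k lists with integer \code{train} and \code{test} indices.
#' @export
make_folds <- function(n_instances, k, seed = 1, labels = NULL) {
  if (k > n_instances) stop("k (", k, ") exceeds number of instances (", n_instances, ")")
  withr::with_seed(seed, {
    stratified <- !is.null(labels) && all(table(labels) >= k)
    fold_of <- integer(n_instances)
    if (stratified) {
      counter <- 0
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        fold_of[idx] <- (counter + seq_along(idx) - 1) %% k + 1
        counter <- counter + length(idx)
      }
    } else {
      fold_of[sample(n_instances)] <- (seq_len(n_instances) - 1) %% k + 1
    }
  })
  lapply(seq_len(k), function(f)
    list(train = which(fold_of != f), test = which(fold_of == f)))
}

#' Classification accuracy
#'
#' @param y_true,y_pred equal-length binary vectors.
#' @return Fraction of correct predictions in [0, 1].
#' @export
accuracy <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  mean(y_true == y_pred)
}

#' F1 score of the positive class
#'
#' Harmonic mean of precision and recall for the positive (high) class,
#' 0 by convention when precision + recall is 0 (no true and no predicted
#' positives).
#'
#' @param y_true,y_pred equal-length binary vectors.
#' @param positive label counted as the positive class.
#' @return F1 in [0, 1].
#' @export
f1_score <- function(y_true, y_pred, positive = 1) {
  if (length(y_true) == 0) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  tp <- sum(y_true == positive & y_pred == positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Participant-specific k-fold cross-validation
#'
#' For every subject, features are standardized on that subject's own
#' matrix (the protocol's convention; \code{strict_cv = TRUE} instead
#' standardizes each fold with training-fold statistics only, avoiding any
#' leakage of test statistics), then a model is trained on k-1 folds and
#' tested on the held-out fold, separately per emotion dimension.
#'
#' @param dataset list of subjects, each a list with \code{features}
#'   (instances x n matrix) and \code{labels} (instances x 2, columns
#'   arousal/valence), e.g. from [extract_trials()].
#' @param model_config an [ensemble_config()] or [dbn_config()].
#' @param k number of folds per subject.
#' @param seed RNG seed driving folds and per-fold model seeds.
#' @param strict_cv standardize with training-fold statistics only.
#' @return Object of class \code{cv_result}: per-fold \code{records}
#'   data frame and per-dimension \code{summary} (mean/median/SD over
#'   subject means).
#' @export
run_cv <- function(dataset, model_config, k = 10, seed = 1,
                   strict_cv = FALSE) {
  dims <- c("arousal", "valence")
  records <- list()
  for (s in seq_along(dataset)) {
    X_raw <- dataset[[s]]$features
    labels <- dataset[[s]]$labels
    if (nrow(X_raw) < k) stop("subject ", s, " has fewer instances than folds")
    if (!strict_cv) X_all <- standardize_features(X_raw)$x
    for (d in seq_along(dims)) {
      y <- labels[, d]
      folds <- make_folds(nrow(X_raw), k,
                          seed = (seed * 1009 + s * 101 + d) %% 2147483629,
                          labels = y)
      for (f in seq_along(folds)) {
        tr <- folds[[f]]$train; te <- folds[[f]]$test
        if (strict_cv) {
          std <- standardize_features(X_raw[tr, , drop = FALSE])
          Xtr <- std$x
          Xte <- apply_standardization(X_raw[te, , drop = FALSE],
                                       std$center, std$scale)
        } else {
          Xtr <- X_all[tr, , drop = FALSE]
          Xte <- X_all[te, , drop = FALSE]
        }
        fit_seed <- (seed * 7919 + s * 211 + d * 17 + f) %% 2147483629
        model <- fit_model(model_config, Xtr, y[tr], seed = fit_seed)
        pred <- predict_model(model, Xte)
        records[[length(records) + 1]] <- data.frame(
          subject = s, fold = f, dimension = dims[d],
          accuracy = accuracy(y[te], pred$labels),
          f1 = f1_score(y[te], pred$labels),
          n_test = length(te))
      }
    }
  }
  records <- do.call(rbind, records)
  subj_means <- stats::aggregate(cbind(accuracy, f1) ~ subject + dimension,
                                 records, mean)
  summary <- do.call(rbind, lapply(dims, function(d) {
    sm <- subj_means[subj_means$dimension == d, ]
    data.frame(dimension = d,
               mean_accuracy = mean(sm$accuracy),
               median_accuracy = stats::median(sm$accuracy),
               sd_accuracy = stats::sd(sm$accuracy),
               mean_f1 = mean(sm$f1),
               median_f1 = stats::median(sm$f1),
               sd_f1 = stats::sd(sm$f1))
  }))
  structure(list(records = records, summary = summary,
                 k = k, seed = seed, strict_cv = strict_cv),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d subjects, %d-fold, %s standardization\n",
              length(unique(x$records$subject)), x$k,
              if (x$strict_cv) "train-fold" else "whole-subject"))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Pooled accuracy over all folds of a CV result
#'
#' Test instances are pooled (weighted by fold size) across folds, subjects
#' and optionally dimensions.
#'
#' @param cv a [run_cv()] result.
#' @param dimension \code{"arousal"}, \code{"valence"} or \code{NULL} (both).
#' @return Pooled accuracy in [0, 1].
#' @export
pooled_accuracy <- function(cv, dimension = NULL) {
  r <- cv$records
  if (!is.null(dimension)) r <- r[r$dimension == dimension, ]
  sum(r$accuracy * r$n_test) / sum(r$n_test)
}

#' Paired comparison of plain-DBN and glia-chain variants
#'
#' Runs the same cross-validation twice on one composite feature subset --
#' once with glia chains disabled and once enabled -- with identical seeds
#' and hyperparameters, and returns paired per-subject metrics suitable for
#' box-plot style comparison.
#'
#' @param dataset as in [run_cv()].
#' @param subset integer feature-column indices (e.g. from
#'   [composite_subsets()]); \code{NULL} uses all columns.
#' @param config a [dbn_config()]; its \code{glia} settings are used for the
#'   glia-enabled arm.
#' @param k,seed,strict_cv as in [run_cv()].
#' @return Data frame with subject, dimension, variant, accuracy, f1.
#' @export
compare_dbn_glia <- function(dataset, subset = NULL, config = dbn_config(),
                             k = 10, seed = 1, strict_cv = FALSE) {
  config$subset <- subset
  cfg_plain <- config; cfg_plain$type <- "dbn"
  cfg_glia <- config; cfg_glia$type <- "dbn_gc"
  res <- list(dbn = run_cv(dataset, cfg_plain, k = k, seed = seed,
                           strict_cv = strict_cv),
              dbn_gc = run_cv(dataset, cfg_glia, k = k, seed = seed,
                              strict_cv = strict_cv))
  do.call(rbind, lapply(names(res), function(v) {
    sm <- stats::aggregate(cbind(accuracy, f1) ~ subject + dimension,
                           res[[v]]$records, mean)
    sm$variant <- v
    sm
  }))
}
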