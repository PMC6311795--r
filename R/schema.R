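#' Feature schema: names, subset index and channel pairs
#'
#' Describes the layout of the multi-domain feature vector: per-channel time
#' statistics (subset F1), per-channel band PSDs (F2), right-minus-left band
#' power differences over homologous pairs (F3), and Hilbert-Huang squared
#' amplitude (F4) and instantaneous frequency (F5) band averages. For the
#' standard 32-channel montage with 14 pairs the subset widths are
#' (128, 160, 56, 160, 160), 664 features in total.
#'
#' @param channels ordered channel names; default [deap_channels()].
#' @param pair_list right/left channel pair matrix; default [deap_pairs()].
#'   Required explicitly when \code{channels} is not the 32-name montage.
#' @return A \code{feature_schema} with elements \code{names},
#'   \code{subset_index} (list F1..F5 of integer index vectors),
#'   \code{pair_list} and \code{channels}.
#' @export
feature_schema <- function(channels = deap_channels(), pair_list = NULL) {
  if (is.null(pair_list)) {
    if (identical(sort(channels), sort(deap_channels()))) pair_list <- deap_pairs()
    else stop("an explicit 'pair_list' is required for a non-standard montage")
  }
  if (!all(pair_list %in% channels))
    stop("pair_list contains channels absent from the montage: ",
         paste(setdiff(as.vector(pair_list), channels), collapse = ", "))
  nc <- length(channels); np <- nrow(pair_list)
  f1 <- as.vector(t(outer(channels, c("mean", "var", "zcr", "apen"), paste, sep = ".")))
  f2 <- as.vector(t(outer(channels, paste0("psd.", psd_band_names()), paste, sep = ".")))
  f3 <- as.vector(t(outer(paste(pair_list[, "right"], pair_list[, "left"], sep = "-"),
                          paste0("dpsd.", diff_band_names()), paste, sep = ".")))
  f4 <- as.vector(t(outer(channels, paste0("hhs_amp.", hhs_band_names()), paste, sep = ".")))
  f5 <- as.vector(t(outer(channels, paste0("hhs_if.", hhs_band_names()), paste, sep = ".")))
  lens <- c(length(f1), length(f2), length(f3), length(f4), length(f5))
  ends <- cumsum(lens)
  starts <- c(1, head(ends, -1) + 1)
  subset_index <- Map(function(a, b) seq.int(a, b), starts, ends)
  names(subset_index) <- paste0("F", 1:5)
  structure(list(names = c(f1, f2, f3, f4, f5),
                 subset_index = subset_index,
                 pair_list = pair_list,
                 channels = channels),
            class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  w <- vapply(x$subset_index, length, integer(1))
  cat(sprintf("<feature_schema> %d features over %d channels: %s\n",
              length(x$names), length(x$channels),
              paste(sprintf("%s=%d", names(w), w), collapse = ", ")))
  invisible(x)
}

#' Composite feature subsets for single-network experiments
#'
#' Index sets for the three composite subsets used when comparing a single
#' deep network per domain: time statistics alone (F6 = F1), all frequency-
#' domain features (F7 = F2 u F3) and all time-frequency features
#' (F8 = F4 u F5).
#'
#' @param schema a [feature_schema()].
#' @return Named list of integer index vectors F6, F7, F8.
#' @export
composite_subsets <- function(schema) {
  si <- schema$subset_index
  list(F6 = si$F1, F7 = c(si$F2, si$F3), F8 = c(si$F4, si$F5))
}
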