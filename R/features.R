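# CNN feature assembly and z-score normalization.

#' Assemble the 256-element CNN feature vector
#'
#' Elements 1-126 are the log amplitudes in canonical pair order, 127-252
#' the phases in the same order, and 253-256 the four chest-wall depth
#' features (cm).  Entries of masked pairs are imputed with the value of
#' the slope-fit lines at that pair's separation, so the input length and
#' meaning stay fixed regardless of which pairs were filtered out.
#'
#' @param m a preprocessed \code{fd_measurement} with 126 pairs.
#' @param depths the 4 chest-wall depth features, cm
#'   (see [chestwall_depth_features()]).
#' @return numeric vector of length 256.
#' @export
build_feature_vector <- function(m, depths) {
  stopifnot(inherits(m, "fd_measurement"))
  if (length(m$separations) != 126L)
    stop("feature vector requires the full 126-pair measurement")
  if (length(depths) != 4L || any(!is.finite(depths)) || any(depths <= 0))
    stop("depths must be 4 positive chest-wall depths in cm")
  la <- m$log_amplitude
  ph <- m$phase
  if (!all(m$valid_mask)) {
    s <- fit_slopes(m)
    line <- slope_line_values(s, m$separations)
    la[!m$valid_mask] <- line$log_amplitude[!m$valid_mask]
    ph[!m$valid_mask] <- line$phase[!m$valid_mask]
  }
  c(la, ph, depths)
}

#' Z-score normalization statistics
#'
#' Per-element mean and standard deviation of features (and labels),
#' computed from the training split only and reused verbatim for all later
#' data, including test data and prediction inputs.
#'
#' @param features numeric matrix (n x 256) of training features.
#' @param labels numeric matrix (n x 4) of training labels.
#' @return object of class \code{norm_stats}.
#' @export
norm_stats <- function(features, labels) {
  fm <- colMeans(features)
  fs <- apply(features, 2, stats::sd)
  lm_ <- colMeans(labels)
  ls <- apply(labels, 2, stats::sd)
  if (any(fs <= 0) || any(ls <= 0))
    stop("zero standard deviation in feature/label column(s): ",
         paste(which(c(fs, ls) <= 0), collapse = ", "))
  structure(list(feature_mean = fm, feature_sd = fs,
                 label_mean = lm_, label_sd = ls),
            class = "norm_stats")
}

#' Apply / invert z-score normalization
#'
#' @param x numeric vector or matrix (rows = examples).
#' @param center,scale per-element statistics.
#' @return normalized (or de-normalized) values, same shape as \code{x}.
#' @export
zscore_apply <- function(x, center, scale) {
  if (is.matrix(x)) sweep(sweep(x, 2, center), 2, scale, `/`)
  else (x - center) / scale
}

#' @rdname zscore_apply
#' @export
zscore_invert <- function(x, center, scale) {
  if (is.matrix(x)) sweep(sweep(x, 2, scale, `*`), 2, center, `+`)
  else x * scale + center
}
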