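# Evaluation metrics and method-comparison reports.

#' Relative error
#'
#' \code{|prediction - truth| / truth}: the absolute error normalized by
#' the ground truth.  Note the asymmetry: the denominator is always the
#' truth, never the prediction.
#'
#' @param prediction estimated value(s).
#' @param truth ground-truth value(s); must be non-zero.
#' @return relative error(s) as a fraction.
#' @examples
#' relative_error(0.11, 0.10)  # 0.10
#' relative_error(0.10, 0.11)  # 0.0909...
#' @export
relative_error <- function(prediction, truth) {
  if (any(truth == 0)) stop("relative error undefined for zero ground truth")
  abs(prediction - truth) / abs(truth)
}

#' Mean relative errors per method and parameter
#'
#' @param records data.frame of per-example records with columns
#'   \code{method}, \code{truth_mua, truth_musp, truth_mua_chest,
#'   truth_musp_chest} and matching \code{est_*} columns (NA where an
#'   estimator failed).
#' @return matrix (methods x 4) of mean relative errors in percent.
#' @export
mean_relative_errors <- function(records) {
  stopifnot(nrow(records) >= 1)
  pars <- c("mua", "musp", "mua_chest", "musp_chest")
  methods <- unique(records$method)
  out <- matrix(NA_real_, length(methods), length(pars),
                dimnames = list(methods, pars))
  for (m in methods) {
    sel <- records$method == m
    for (p in pars) {
      re <- relative_error(records[sel, paste0("est_", p)],
                           records[sel, paste0("truth_", p)])
      out[m, p] <- 100 * mean(re, na.rm = TRUE)
    }
  }
  out
}

#' Error reduction in percentage points
#'
#' Difference between a baseline method's mean relative error and another
#' method's, both in percent, rounded to the nearest whole point for
#' reporting (e.g. 67.54 vs 6.64 is a 61-point reduction).
#'
#' @param baseline_pct baseline mean relative error, %.
#' @param method_pct comparison mean relative error, %.
#' @return integer percentage points.
#' @export
error_reduction_pp <- function(baseline_pct, method_pct) {
  stopifnot(all(baseline_pct >= 0), all(method_pct >= 0))
  round(baseline_pct - method_pct)
}

#' Run all three estimators on a set of labelled examples
#'
#' For every example, computes the slope-based estimate (homogeneous,
#' duplicated into the chest slot), the two-layer Nelder-Mead fit and the
#' CNN prediction, and aggregates per-method mean relative errors.
#' Individual estimator failures are recorded per example (NA estimates
#' with a failure tag), not fatal.
#'
#' @param examples list of examples, each a list with elements
#'   \code{measurement} (preprocessed \code{fd_measurement}), \code{geom}
#'   (\code{chestwall_geometry}), \code{truth} (named quadruple) and
#'   optionally \code{depths} (the 4 depth features; derived from
#'   \code{geom} if absent).
#' @param cnn a trained \code{dot_cnn}, or NULL to skip the CNN rows.
#' @param probe the \code{probe_layout}.
#' @param omega angular modulation frequency, rad/s.
#' @param n_index refractive index.
#' @param methods which estimators to run.
#' @return object of class \code{comparison_report}: \code{records}
#'   (per-example data.frame) and \code{mean_errors} (method x parameter
#'   matrix, %).
#' @export
build_comparison_report <- function(examples, cnn = NULL,
                                    probe = default_probe(),
                                    omega = default_omega(), n_index = 1.4,
                                    methods = c("slope", "twolayer", "cnn")) {
  if (is.null(cnn)) methods <- setdiff(methods, "cnn")
  pars <- c("mua", "musp", "mua_chest", "musp_chest")
  rows <- list()
  for (i in seq_along(examples)) {
    ex <- examples[[i]]
    depths <- ex$depths
    if (is.null(depths)) depths <- chestwall_depth_features(ex$geom)
    for (meth in methods) {
      fit <- tryCatch(switch(meth,
        slope = fit_slope_props(ex$measurement, omega, n_index),
        twolayer = fit_two_layer(ex$measurement, ex$geom, probe, omega,
                                 n_index),
        cnn = cnn_fit(cnn, build_feature_vector(ex$measurement, depths))),
        error = function(e) e)
      est <- rep(NA_real_, 4)
      failure <- NA_character_
      if (inherits(fit, "dot_fit")) est <- fit$estimate
      else failure <- conditionMessage(fit)
      row <- data.frame(example = i, method = meth,
                        depth = ex$geom$depth_center, failure = failure)
      for (j in seq_along(pars)) {
        row[[paste0("truth_", pars[j])]] <- unname(ex$truth[pars[j]])
        row[[paste0("est_", pars[j])]] <- unname(est[j])
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  records <- do.call(rbind, rows)
  structure(list(records = records,
                 mean_errors = mean_relative_errors(records)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("mean relative errors (%):\n")
  print(round(x$mean_errors, 2))
  nf <- sum(!is.na(x$records$failure))
  if (nf > 0) cat(sprintf("  (%d estimator failures recorded)\n", nf))
  invisible(x)
}

#' Mean relative errors of a CNN on a dataset split
#'
#' Predicts on every example of the chosen split and computes the mean
#' relative error per output parameter.
#'
#' @param cnn a \code{dot_cnn}.
#' @param dataset a \code{dot_dataset}.
#' @param split "test" (default) or "train".
#' @return named numeric of 4 mean relative errors, %.
#' @export
evaluate_cnn <- function(cnn, dataset, split = "test") {
  part <- dataset_split(dataset, split)
  pred <- predict(cnn, part$features)
  100 * colMeans(abs(pred - part$labels) / abs(part$labels))
}

#' Digital-phantom evaluation pipeline
#'
#' Generates heterogeneous digital breast phantoms, compresses and
#' downsamples them, runs the finite-difference forward solver, adds
#' measurement noise, and scores all three estimators against the
#' weighted-average breast-tissue truth (chest-wall truth is the chest
#' label's properties).
#'
#' @param n_phantoms number of phantoms.
#' @param cnn a trained \code{dot_cnn} (NULL skips CNN rows).
#' @param seed RNG seed.
#' @param fibro_range fibroglandular volume-fraction range.
#' @param depth_range compressed chest-wall depth range, cm.
#' @param chest_mua_range chest-wall absorption range sampled per phantom.
#' @param noise_level measurement noise fraction.
#' @param probe,omega,n_index measurement configuration.
#' @param phantom_args extra arguments passed to
#'   [generate_digital_phantom()].
#' @return a \code{comparison_report}.
#' @export
run_phantom_study <- function(n_phantoms = 24L, cnn = NULL, seed = 1L,
                              fibro_range = c(0.2, 0.8),
                              depth_range = c(1.5, 2.5),
                              chest_mua_range = c(0.1, 0.24),
                              noise_level = 0.01,
                              probe = default_probe(),
                              omega = default_omega(), n_index = 1.4,
                              phantom_args = list()) {
  cfg <- with_seed(seed, {
    data.frame(fibro = stats::runif(n_phantoms, fibro_range[1], fibro_range[2]),
               depth = stats::runif(n_phantoms, depth_range[1], depth_range[2]),
               chest_mua = stats::runif(n_phantoms, chest_mua_range[1],
                                        chest_mua_range[2]),
               chest_musp = stats::runif(n_phantoms, 5.6, 7.1),
               noise_seed = sample.int(1e6, n_phantoms))
  })
  examples <- vector("list", n_phantoms)
  for (i in seq_len(n_phantoms)) {
    ph <- do.call(generate_digital_phantom, c(list(
      fibro_fraction = cfg$fibro[i], chest_depth = cfg$depth[i],
      seed = seed + i,
      chest_props = optical_props(cfg$chest_mua[i], cfg$chest_musp[i])),
      phantom_args))
    ph <- compress_and_downsample(ph)
    truth_tissue <- weighted_average_truth(ph)
    m <- fluence_heterogeneous(ph, probe, omega, n_index)
    m <- add_noise(m, noise_level, seed = cfg$noise_seed[i])
    m <- preprocess_measurement(m)
    examples[[i]] <- list(
      measurement = m,
      geom = chestwall_geometry(ph$chest_depth, ph$chest_tilt),
      truth = c(mua = truth_tissue$mua, musp = truth_tissue$musp,
                mua_chest = cfg$chest_mua[i], musp_chest = cfg$chest_musp[i]))
    rm(ph); gc(FALSE)
  }
  build_comparison_report(examples, cnn, probe, omega, n_index)
}
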