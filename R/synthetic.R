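# Synthetic dataset generation: the parameter sweeps, noise model,
# simulation dataset, and the lab-phantom fixture (intralipid backgrounds
# plus solid chest-wall phantoms with instrument gains and calibration).

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Table of simulation parameter ranges: tissue mua 0.01-0.1, tissue musp
# 4-10, chest mua 0.1-0.24, chest musp 4-10 (cm^-1); chest depth 1.5-3 cm;
# tilt -15..+15 degrees.
.SIM_RANGES <- list(mua = c(0.01, 0.1), musp = c(4, 10),
                    mua_chest = c(0.1, 0.24), musp_chest = c(4, 10),
                    depth = c(1.5, 3), tilt = c(-15, 15))

#' Sample two-layer simulation parameters
#'
#' Draws each of the six parameters (tissue mua/musp, chest mua/musp,
#' interface depth, interface tilt) independently and uniformly over its
#' simulation range; deterministic per seed.
#'
#' @param n number of draws.
#' @param seed RNG seed.
#' @return data.frame of class \code{parameter_draws} with columns
#'   \code{mua, musp, mua_chest, musp_chest, depth, tilt}.
#' @export
sample_parameters <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  draws <- with_seed(seed, {
    as.data.frame(lapply(.SIM_RANGES, function(r)
      stats::runif(n, r[1], r[2])))
  })
  class(draws) <- c("parameter_draws", "data.frame")
  attr(draws, "seed") <- seed
  draws
}

#' Build a two-layer medium from a parameter draw
#'
#' @param draws a \code{parameter_draws} data.frame.
#' @param i row index.
#' @param n_index refractive index.
#' @return a \code{two_layer_medium}.
#' @export
medium_from_draw <- function(draws, i, n_index = 1.4) {
  d <- draws[i, ]
  suppressWarnings(two_layer_medium(
    optical_props(d$mua, d$musp),
    optical_props(d$mua_chest, d$musp_chest),
    chestwall_geometry(d$depth, d$tilt),
    refractive_index = n_index))
}

#' Add measurement noise
#'
#' Multiplies each pair's amplitude by (1 + e), e ~ N(0, level^2) i.i.d.
#' (so the log amplitude receives approximately additive N(0, level) noise)
#' and adds N(0, level) radians to each phase.  Masked entries are
#' perturbed too; the mask itself is unchanged.  Deterministic per seed.
#'
#' @param m an \code{fd_measurement}.
#' @param level noise fraction (default 0.01 = 1%).
#' @param seed optional RNG seed.
#' @return the noisy \code{fd_measurement}.
#' @export
add_noise <- function(m, level = 0.01, seed = NULL) {
  stopifnot(inherits(m, "fd_measurement"), level >= 0)
  if (level == 0) return(m)
  run <- function() {
    n <- length(m$separations)
    eps <- pmax(1 + stats::rnorm(n, 0, level), 1e-12)
    m$log_amplitude <- m$log_amplitude + log(eps)
    m$phase <- m$phase + stats::rnorm(n, 0, level)
    m
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Labelled feature dataset
#'
#' @param features n x 256 feature matrix.
#' @param labels n x 4 label matrix (mua, musp, mua_chest, musp_chest).
#' @param split character vector ("train"/"test") per example.
#' @param geometry data.frame with per-example \code{depth} and \code{tilt}.
#' @param meta provenance list (seeds, noise level, recipe).
#' @return object of class \code{dot_dataset}.
#' @export
dot_dataset <- function(features, labels, split, geometry, meta = list()) {
  n <- nrow(features)
  if (nrow(labels) != n || length(split) != n || nrow(geometry) != n)
    stop("features, labels, split and geometry must agree in length")
  if (!all(split %in% c("train", "test")))
    stop("split entries must be 'train' or 'test'")
  colnames(labels) <- c("mua", "musp", "mua_chest", "musp_chest")
  structure(list(features = features, labels = labels, split = split,
                 geometry = geometry, meta = meta),
            class = "dot_dataset")
}

#' @export
print.dot_dataset <- function(x, ...) {
  cat(sprintf("dot_dataset: %d examples (%d train / %d test), %d features\n",
              nrow(x$features), sum(x$split == "train"),
              sum(x$split == "test"), ncol(x$features)))
  invisible(x)
}

# subset helper: rows of one split
dataset_split <- function(dataset, which = c("train", "test")) {
  which <- match.arg(which)
  if (inherits(dataset, "dot_dataset")) {
    sel <- dataset$split == which
    list(features = dataset$features[sel, , drop = FALSE],
         labels = dataset$labels[sel, , drop = FALSE],
         geometry = dataset$geometry[sel, , drop = FALSE])
  } else {
    # plain list(features, labels): everything is the training split
    list(features = dataset$features, labels = dataset$labels,
         geometry = dataset$geometry)
  }
}

# forward -> noise -> preprocessing -> feature vector for one draw
simulate_example <- function(medium, probe, omega, noise_level,
                             depth_positions = c(-1.5, -0.5, 0.5, 1.5)) {
  m <- fluence_two_layer(medium, probe, omega)
  m <- add_noise(m, noise_level)
  m <- preprocess_measurement(m)
  depths <- chestwall_depth_features(medium$chestwall, depth_positions)
  build_feature_vector(m, depths)
}

#' Generate the simulated two-layer training dataset
#'
#' For each parameter draw: two-layer forward model, measurement noise,
#' standard preprocessing (7 cm cutoff + outlier screening), feature
#' assembly; labels are the four generating optical properties.  Examples
#' are split train/test at random per seed.
#'
#' @param n number of measurement sets (15744 at full scale).
#' @param train_fraction fraction assigned to the training split.
#' @param seed RNG seed (drives parameters, noise and the split).
#' @param noise_level amplitude/phase noise fraction.
#' @param probe the \code{probe_layout}.
#' @param omega angular modulation frequency, rad/s.
#' @param n_index refractive index.
#' @return a \code{dot_dataset}.
#' @export
make_simulation_dataset <- function(n = 15744, train_fraction = 0.9, seed = 1L,
                                    noise_level = 0.01,
                                    probe = default_probe(),
                                    omega = default_omega(), n_index = 1.4) {
  draws <- sample_parameters(n, seed = seed)
  features <- matrix(NA_real_, n, 256L)
  with_seed(seed + 1L, {
    for (i in seq_len(n)) {
      med <- medium_from_draw(draws, i, n_index)
      features[i, ] <- simulate_example(med, probe, omega, noise_level)
    }
  })
  labels <- as.matrix(draws[, c("mua", "musp", "mua_chest", "musp_chest")])
  split <- with_seed(seed + 2L, {
    s <- rep("train", n)
    s[sample.int(n, round((1 - train_fraction) * n))] <- "test"
    s
  })
  dot_dataset(features, labels, split,
              geometry = draws[, c("depth", "tilt")],
              meta = list(recipe = "two_layer_simulation", seed = seed,
                          noise_level = noise_level, n = n,
                          train_fraction = train_fraction))
}

# Fixed solid chest-wall phantom properties spanning the lab-phantom ranges
.LAB_CHEST_PHANTOMS <- data.frame(
  mua = c(0.095, 0.125, 0.150, 0.180),
  musp = c(5.6, 6.3, 7.1, 6.0))

#' Synthetic lab-phantom fixture
#'
#' Emulates the intralipid + solid-phantom experiments used for
#' fine-tuning: liquid backgrounds with absorption 0.02-0.06 cm^-1 and
#' reduced scattering 5.8-6.7 cm^-1, four fixed solid chest-wall phantoms
#' spanning 0.095-0.18 / 5.6-7.1 cm^-1, submersion depths 1.5-2.5 cm and
#' probe tilts within +/-15 degrees.  Each measurement passes through
#' seeded per-source/per-detector instrument gains and 1% noise, then
#' through gain calibration fitted on a separate homogeneous reference run,
#' preprocessing, and feature assembly.  This is a synthetic stand-in for
#' the physical experiment: only the printed ranges are matched.
#'
#' @param n_backgrounds number of liquid backgrounds (196 reproduces the
#'   784-set experiment scale with 4 chest phantoms).
#' @param n_chest_phantoms how many of the 4 solid phantoms to use.
#' @param seed RNG seed.
#' @param train_fraction fraction used for fine-tuning (the experiment used
#'   70/30).
#' @param noise_level measurement noise fraction.
#' @param gains optional \code{gain_set}; by default gains are drawn with
#'   log-moduli uniform(-0.5, 0.5) and phases uniform(-0.3, 0.3) rad.
#' @param reference_props known properties of the homogeneous calibration
#'   run.
#' @param probe the \code{probe_layout}.
#' @param omega angular modulation frequency, rad/s.
#' @param n_index refractive index (1.33 for intralipid).
#' @return a \code{dot_dataset}; the fitted calibration is in
#'   \code{meta$gains_fitted}.
#' @export
make_lab_fixture <- function(n_backgrounds = 196L, n_chest_phantoms = 4L,
                             seed = 1L, train_fraction = 0.7,
                             noise_level = 0.01, gains = NULL,
                             reference_props = optical_props(0.04, 6.2),
                             probe = default_probe(),
                             omega = default_omega(), n_index = 1.33) {
  stopifnot(n_chest_phantoms >= 1L, n_chest_phantoms <= 4L)
  rho <- separations(probe)
  n <- n_backgrounds * n_chest_phantoms
  out <- with_seed(seed, {
    if (is.null(gains)) {
      gmod <- exp(stats::runif(23, -0.5, 0.5))
      gph <- stats::runif(23, -0.3, 0.3)
      gmod[1] <- 1; gph[1] <- 0
      gains <- gain_set(complex(modulus = gmod[1:9], argument = gph[1:9]),
                        complex(modulus = gmod[10:23], argument = gph[10:23]))
    }
    # homogeneous calibration run: known reference, same instrument gains
    ref_phi <- fluence_semi_infinite(reference_props, rho, omega, n_index)
    ref_raw <- measurement_from_fluence(ref_phi, rho, omega / (2 * pi))
    ref_raw <- add_noise(apply_gains(ref_raw, gains), noise_level)
    gains_fitted <- fit_gains(ref_raw, reference_props, probe, omega, n_index)

    feats <- matrix(NA_real_, n, 256L)
    labels <- matrix(NA_real_, n, 4L)
    geometry <- data.frame(depth = numeric(n), tilt = numeric(n))
    i <- 0L
    for (b in seq_len(n_backgrounds)) {
      tissue <- optical_props(stats::runif(1, 0.02, 0.06),
                              stats::runif(1, 5.8, 6.7))
      for (cpi in seq_len(n_chest_phantoms)) {
        i <- i + 1L
        chest <- optical_props(.LAB_CHEST_PHANTOMS$mua[cpi],
                               .LAB_CHEST_PHANTOMS$musp[cpi])
        geomi <- chestwall_geometry(stats::runif(1, 1.5, 2.5),
                                    stats::runif(1, -15, 15))
        med <- suppressWarnings(two_layer_medium(tissue, chest, geomi,
                                                 refractive_index = 1.4))
        med$refractive_index <- n_index
        m <- fluence_two_layer(med, probe, omega)
        m <- add_noise(apply_gains(m, gains), noise_level)
        m <- preprocess_measurement(apply_calibration(m, gains_fitted))
        feats[i, ] <- build_feature_vector(
          m, chestwall_depth_features(geomi))
        labels[i, ] <- c(tissue$mua, tissue$musp, chest$mua, chest$musp)
        geometry$depth[i] <- geomi$depth_center
        geometry$tilt[i] <- geomi$tilt_deg
      }
    }
    split <- rep("train", n)
    split[sample.int(n, round((1 - train_fraction) * n))] <- "test"
    list(feats = feats, labels = labels, split = split, geometry = geometry,
         gains_true = gains, gains_fitted = gains_fitted)
  })
  dot_dataset(out$feats, out$labels, out$split, out$geometry,
              meta = list(recipe = "lab_fixture", seed = seed,
                          noise_level = noise_level,
                          gains_true = out$gains_true,
                          gains_fitted = out$gains_fitted))
}

#' Write / read a dataset as CSV
#'
#' One row per example: split, depth, tilt, the four labels, then the 256
#' feature columns.
#'
#' @param dataset a \code{dot_dataset}.
#' @param path CSV file path.
#' @return \code{dataset_from_csv} returns a \code{dot_dataset}.
#' @export
dataset_to_csv <- function(dataset, path) {
  df <- data.frame(split = dataset$split, dataset$geometry,
                   dataset$labels, dataset$features, check.names = FALSE)
  names(df) <- c("split", "depth", "tilt",
                 colnames(dataset$labels), paste0("f", 1:ncol(dataset$features)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname dataset_to_csv
#' @export
dataset_from_csv <- function(path) {
  df <- utils::read.csv(path)
  fcols <- grep("^f\\d+$", names(df))
  dot_dataset(as.matrix(df[, fcols]),
              as.matrix(df[, c("mua", "musp", "mua_chest", "musp_chest")]),
              df$split, df[, c("depth", "tilt")],
              meta = list(source = path))
}
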