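#' Optical properties of one tissue layer
#'
#' Absorption (\code{mua}) and reduced scattering (\code{musp}) coefficients
#' in cm^-1.  The diffusion approximation underlying every solver in this
#' package assumes musp >> mua; a warning is emitted when musp < 10 * mua.
#'
#' @param mua absorption coefficient, cm^-1.
#' @param musp reduced scattering coefficient, cm^-1.
#' @return An object of class \code{optical_props}.
#' @export
optical_props <- function(mua, musp) {
  if (!is.finite(mua) || !is.finite(musp) || mua <= 0 || musp <= 0)
    stop("mua and musp must be positive, finite (cm^-1)")
  if (musp < 10 * mua)
    warning("musp < 10 * mua: diffusion approximation is questionable here")
  structure(list(mua = mua, musp = musp), class = "optical_props")
}

#' @export
print.optical_props <- function(x, ...) {
  cat(sprintf("optical properties: mua = %.4g cm^-1, musp = %.4g cm^-1\n",
              x$mua, x$musp))
  invisible(x)
}

#' Two-layer medium: breast tissue over chest wall
#'
#' @param tissue \code{optical_props} of the breast-tissue layer.
#' @param chest \code{optical_props} of the chest-wall layer.
#' @param chestwall a \code{chestwall_geometry} describing the interface.
#' @param refractive_index medium refractive index (1.3 - 1.5).
#' @return An object of class \code{two_layer_medium}.
#' @export
two_layer_medium <- function(tissue, chest, chestwall, refractive_index = 1.4) {
  stopifnot(inherits(tissue, "optical_props"),
            inherits(chest, "optical_props"),
            inherits(chestwall, "chestwall_geometry"))
  if (refractive_index < 1.3 || refractive_index > 1.5)
    stop("refractive_index must lie in [1.3, 1.5]")
  structure(list(tissue = tissue, chest = chest, chestwall = chestwall,
                 refractive_index = refractive_index),
            class = "two_layer_medium")
}

#' @export
print.two_layer_medium <- function(x, ...) {
  cat(sprintf(
    "two-layer medium (n = %.2f)\n  tissue: mua = %.4g, musp = %.4g cm^-1\n  chest:  mua = %.4g, musp = %.4g cm^-1\n  interface: %.2f cm depth, %.1f deg tilt\n",
    x$refractive_index, x$tissue$mua, x$tissue$musp,
    x$chest$mua, x$chest$musp,
    x$chestwall$depth_center, x$chestwall$tilt_deg))
  invisible(x)
}

#' Frequency-domain measurement set
#'
#' One modulation frequency's worth of measurements for all source-detector
#' pairs in the canonical source-major order: the natural log of the AC
#' amplitude (arbitrary but consistent units) and the unwrapped phase lag
#' (radians, increasing with separation).  \code{valid_mask} marks the pairs
#' that survive preprocessing; values of masked pairs are retained.
#'
#' @param separations pair separations, cm.
#' @param log_amplitude natural log of AC amplitude per pair.
#' @param phase unwrapped phase lag per pair, radians.
#' @param modulation_freq modulation frequency, Hz.
#' @param valid_mask logical vector of valid pairs (default all TRUE).
#' @param meta optional list of provenance fields.
#' @return An object of class \code{fd_measurement}.
#' @export
fd_measurement <- function(separations, log_amplitude, phase,
                           modulation_freq = 140e6,
                           valid_mask = rep(TRUE, length(separations)),
                           meta = list()) {
  n <- length(separations)
  if (length(log_amplitude) != n || length(phase) != n || length(valid_mask) != n)
    stop("separations, log_amplitude, phase and valid_mask must have equal length")
  if (any(!is.finite(separations)) || any(separations <= 0))
    stop("separations must be positive and finite")
  structure(list(separations = as.numeric(separations),
                 log_amplitude = as.numeric(log_amplitude),
                 phase = as.numeric(phase),
                 modulation_freq = modulation_freq,
                 valid_mask = as.logical(valid_mask),
                 meta = meta),
            class = "fd_measurement")
}

#' @export
print.fd_measurement <- function(x, ...) {
  cat(sprintf(
    "fd_measurement: %d pairs (%d valid), f = %.4g MHz, rho in [%.2f, %.2f] cm\n",
    length(x$separations), sum(x$valid_mask), x$modulation_freq / 1e6,
    min(x$separations), max(x$separations)))
  invisible(x)
}

# Build an fd_measurement from complex fluence values: log|Phi| and the
# phase lag -Arg(Phi), unwrapped along increasing separation.
measurement_from_fluence <- function(phi, separations, modulation_freq,
                                     meta = list()) {
  fd_measurement(separations = separations,
                 log_amplitude = log(Mod(phi)),
                 phase = unwrap_by_rho(separations, -Arg(phi)),
                 modulation_freq = modulation_freq,
                 meta = meta)
}

# Unwrap phases so that the lag varies continuously along increasing rho.
unwrap_by_rho <- function(rho, phase) {
  o <- order(rho)
  p <- phase[o]
  if (length(p) > 1L) {
    jumps <- round(diff(p) / (2 * pi))
    p <- p - c(0, cumsum(jumps)) * 2 * pi
  }
  out <- numeric(length(p))
  out[o] <- p
  out
}

#' Write / read a measurement as tidy CSV
#'
#' Columns: pair, source, detector, separation_cm, log_amplitude, phase_rad,
#' valid.  The modulation frequency is stored in a header comment line.
#'
#' @param m an \code{fd_measurement} (126 pairs).
#' @param path CSV file path.
#' @return \code{measurement_from_csv} returns an \code{fd_measurement}.
#' @export
measurement_to_csv <- function(m, path) {
  stopifnot(inherits(m, "fd_measurement"))
  idx <- if (length(m$separations) == 126L) pair_index() else
    data.frame(source = NA_integer_, detector = NA_integer_)[rep(1, length(m$separations)), ]
  df <- data.frame(pair = seq_along(m$separations),
                   source = idx$source, detector = idx$detector,
                   separation_cm = m$separations,
                   log_amplitude = m$log_amplitude,
                   phase_rad = m$phase,
                   valid = m$valid_mask)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# modulation_freq_hz=%.10g", m$modulation_freq), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname measurement_to_csv
#' @export
measurement_from_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  freq <- as.numeric(sub("# modulation_freq_hz=", "", hdr, fixed = TRUE))
  df <- utils::read.csv(path, comment.char = "#")
  fd_measurement(df$separation_cm, df$log_amplitude, df$phase_rad,
                 modulation_freq = freq, valid_mask = df$valid)
}
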